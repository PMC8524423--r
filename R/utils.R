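# Internal helpers shared across modules.

#' Structured error constructor
#'
#' All user-facing failures in the package signal classed conditions so that
#' callers (and the command-line wrapper) can map them onto exit codes.
#'
#' @param message character message.
#' @param class subclass, e.g. "dak_load_error".
#' @param ... named data attached to the condition.
#' @noRd
dak_abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "dak_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

#' Deterministic slug for FHIR ids
#'
#' Lowercases, drops punctuation/parentheses, collapses runs of
#' non-alphanumerics to single hyphens. "WHO-Core Observation (HIV Status)"
#' becomes "who-core-observation-hiv-status". FHIR ids must match
#' `[A-Za-z0-9\-\.]{1,64}`, which display names do not.
#'
#' @param x character vector.
#' @return character vector of slugs.
#' @export
#' @examples
#' slugify("WHO-Core Observation (HIV Status)")
slugify <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "-", x)
  x <- gsub("^-+|-+$", "", x)
  x
}

# Multi-valued CSV cells (answer options, additional attributes) are stored
# as a single "|"-separated string; empty string means empty list.
split_multi <- function(x, sep = "|") {
  if (length(x) != 1L || is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, sep, fixed = TRUE)[[1L]])
}

join_multi <- function(x, sep = " | ") {
  if (length(x) == 0L) return("")
  paste(trimws(x), collapse = sep)
}

# Case-folded, whitespace-collapsed normal form used for duplicate keys.
norm_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

blank <- function(x) is.na(x) | !nzchar(trimws(x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable JSON serialisation: identical R objects always yield identical bytes.
to_stable_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, digits = NA, null = "null")
}

# Write a file only if absent or identical; differing content requires the
# overwrite flag. Returns "created", "unchanged" or "overwritten".
write_stable <- function(path, content, overwrite = FALSE) {
  content <- paste0(paste(content, collapse = "\n"), "\n")
  if (file.exists(path)) {
    old <- readChar(path, file.info(path)$size, useBytes = TRUE)
    if (identical(old, content)) return("unchanged")
    if (!overwrite) {
      dak_abort(sprintf("refusing to overwrite differing file: %s", path),
                "dak_emit_error", path = path)
    }
    cat(content, file = path)
    return("overwritten")
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cat(content, file = path)
  "created"
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
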