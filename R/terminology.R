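# Terminology module: code-system registry, free-text code parsing,
# normalization and syntactic validation.
#
# The master dictionary carries semantic terminology codes as free text
# ("SNOMED: 14,302,001 (maps to Amenorrhea)"), possibly several per cell.
# This module turns that text into structured codings against the canonical
# code-system URIs, entirely offline: validation is syntactic (per-system
# code shape), never a terminology-server lookup.

#' Code-system registry
#'
#' Maps human labels (as written in dictionary cells) to canonical code-system
#' URIs and per-system code-format rules. Covers the four semantic standards
#' used for DAK mapping (SNOMED CT, LOINC, ICD-10, RxNorm); any absolute URI
#' (e.g. a FHIR code system such as `http://hl7.org/fhir/administrative-gender`)
#' resolves to itself. Extra systems can be added via `extras`.
#'
#' @param extras optional data.frame with columns `label`, `uri` and
#'   optionally `pattern` (a regular expression codes must match).
#' @return data.frame with columns `label`, `uri`, `pattern`, of class
#'   `dak_registry`.
#' @export
#' @examples
#' reg <- code_system_registry()
#' resolve_system("SNOMED CT", reg)
code_system_registry <- function(extras = NULL) {
  base <- data.frame(
    label = c("snomed", "snomed ct", "snomed-ct", "sct",
              "loinc",
              "icd-10", "icd10", "icd 10",
              "rxnorm", "rx norm"),
    uri = c(rep("http://snomed.info/sct", 4L),
            "http://loinc.org",
            rep("http://hl7.org/fhir/sid/icd-10", 3L),
            rep("http://www.nlm.nih.gov/research/umls/rxnorm", 2L)),
    pattern = c(rep("^[0-9]{6,18}$", 4L),
                "^[0-9]{1,7}-[0-9]$",
                rep("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", 3L),
                rep("^[0-9]+$", 2L)),
    stringsAsFactors = FALSE
  )
  if (!is.null(extras)) {
    stopifnot(is.data.frame(extras), all(c("label", "uri") %in% names(extras)))
    if (is.null(extras$pattern)) extras$pattern <- NA_character_
    extras$label <- tolower(trimws(extras$label))
    base <- rbind(base, extras[, c("label", "uri", "pattern")])
  }
  class(base) <- c("dak_registry", "data.frame")
  base
}

#' Resolve a code-system label to its canonical URI
#'
#' Lookup is case-insensitive and tolerant of common spelling variants
#' ("SNOMED", "SNOMED-CT", "SNOMED CT"). A value that is already an absolute
#' URI is returned unchanged.
#'
#' @param label system label or absolute URI.
#' @param registry a [code_system_registry()].
#' @return canonical URI string.
#' @export
resolve_system <- function(label, registry = code_system_registry()) {
  lab <- trimws(label)
  if (grepl("^[a-z][a-z0-9+.-]*://", lab) || grepl("^urn:", lab)) return(lab)
  hit <- match(tolower(lab), registry$label)
  if (is.na(hit)) {
    dak_abort(sprintf("unknown code-system label: '%s'", label),
              "dak_term_error", label = label)
  }
  registry$uri[hit]
}

system_pattern <- function(uri, registry = code_system_registry()) {
  hit <- match(uri, registry$uri)
  if (is.na(hit)) return(NA_character_)
  registry$pattern[hit]
}

#' Normalize a raw code token
#'
#' Dictionary cells print codes with typographic artifacts: thousands
#' separators in SNOMED/RxNorm concept ids ("14,302,001") and en/em dashes in
#' LOINC codes ("11996–6"). Normalization strips whitespace, canonicalizes
#' dash variants to ASCII hyphens and removes comma separators from otherwise
#' all-digit codes. Codes that carry no such artifacts pass through unchanged;
#' the operation is idempotent.
#'
#' @param system canonical system URI (unused by the current rules but part of
#'   the contract so per-system normalization can be added).
#' @param raw raw code text, non-empty.
#' @return normalized code token.
#' @export
#' @examples
#' normalize_code("http://snomed.info/sct", "14,302,001")
normalize_code <- function(system, raw) {
  out <- trimws(raw)
  out <- gsub("[‐‑‒–—−]", "-", out)
  out <- gsub("\\s+", "", out)
  if (grepl("^[0-9,]+$", out)) out <- gsub(",", "", out)
  if (!nzchar(out)) {
    dak_abort(sprintf("code '%s' normalizes to an empty token", raw),
              "dak_term_error", raw = raw)
  }
  out
}

#' Construct a coding
#'
#' @param system canonical system URI.
#' @param code code token.
#' @param display optional display text.
#' @return one-row data.frame with columns `system`, `code`, `display`.
#' @export
coding <- function(system, code, display = NA_character_) {
  data.frame(system = system, code = code, display = display,
             stringsAsFactors = FALSE)
}

empty_codings <- function() {
  data.frame(system = character(0), code = character(0),
             display = character(0), stringsAsFactors = FALSE)
}

#' Parse a free-text semantic-terminology cell into codings
#'
#' Splits the cell on newlines and semicolons; each non-empty segment is
#' expected to read `"Label: code"` optionally followed by
#' `"(maps to Display)"` (the bare parenthetical `"(Display)"` is accepted
#' too). Unknown system labels and malformed segments are collected as parse
#' issues rather than raised, so one bad segment never loses its neighbours:
#' the number of codings plus the number of issues always equals the number of
#' non-empty segments.
#'
#' @param text cell text (may be empty or NA).
#' @param registry a [code_system_registry()].
#' @return list with `codings` (data.frame system/code/display) and `issues`
#'   (character vector).
#' @export
#' @examples
#' parse_code_text("RxNorm: 18,631 (maps to azithromycin)")$codings
parse_code_text <- function(text, registry = code_system_registry()) {
  out <- list(codings = empty_codings(), issues = character(0))
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) return(out)
  segs <- trimws(strsplit(text, "[\n;]+")[[1L]])
  segs <- segs[nzchar(segs)]
  rx <- "^([^:]+?)\\s*:\\s*([^() ]+)\\s*(?:\\((?:maps to\\s+)?(.*?)\\s*\\))?$"
  for (seg in segs) {
    m <- regmatches(seg, regexec(rx, seg))[[1L]]
    if (length(m) == 0L) {
      out$issues <- c(out$issues, sprintf("malformed code segment: '%s'", seg))
      next
    }
    uri <- tryCatch(resolve_system(m[2L], registry), dak_term_error = function(e) NULL)
    if (is.null(uri)) {
      out$issues <- c(out$issues,
                      sprintf("unknown code-system label '%s' in segment '%s'", m[2L], seg))
      next
    }
    code <- tryCatch(normalize_code(uri, m[3L]), dak_term_error = function(e) NULL)
    if (is.null(code)) {
      out$issues <- c(out$issues, sprintf("empty code in segment '%s'", seg))
      next
    }
    disp <- if (length(m) >= 4L && nzchar(m[4L])) m[4L] else NA_character_
    out$codings <- rbind(out$codings, coding(uri, code, disp))
  }
  out
}

#' Syntactically validate a coding against its system's code-format rule
#'
#' Purely syntactic: SNOMED and RxNorm codes must be all digits after
#' normalization, ICD-10 codes letter-digit-digit with an optional dotted
#' suffix, LOINC codes digits-hyphen-checkdigit. Systems without a registered
#' rule (e.g. FHIR code systems) only require a non-empty whitespace-free
#' token. No network lookups are performed.
#'
#' @param c a coding (one-row data.frame from [coding()]) or a data.frame of
#'   codings, validated row-wise.
#' @param registry a [code_system_registry()].
#' @return character vector of issues; empty when valid.
#' @export
validate_coding <- function(c, registry = code_system_registry()) {
  issues <- character(0)
  if (nrow(c) == 0L) return(issues)
  for (i in seq_len(nrow(c))) {
    code <- c$code[i]
    if (is.na(code) || !nzchar(code)) {
      issues <- c(issues, sprintf("row %d: empty code", i))
      next
    }
    if (grepl("\\s", code)) {
      issues <- c(issues, sprintf("code '%s' contains whitespace", code))
      next
    }
    pat <- system_pattern(c$system[i], registry)
    if (!is.na(pat) && !grepl(pat, code)) {
      issues <- c(issues, sprintf(
        "code '%s' does not match the format rule for %s", code, c$system[i]))
    }
  }
  issues
}
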