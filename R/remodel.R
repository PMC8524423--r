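# Remodeling: user-interface model <-> semantically oriented model.
#
# DAK dictionaries are written the way questions appear on a form ("
# Hypertension? yes/no"), while FHIR wants resource-oriented semantics (a
# Condition whose code is bound to a value set of hypertension codes).
# classify_entry() picks a deterministic remodel pattern per entry,
# remodel_entry() applies it, and revert_entry() reconstructs the original
# UI view exactly — reversibility is guaranteed by carrying the original UI
# fields along as metadata rather than by inverting the transform.

REMODEL_COLS <- c("remodel_pattern", "bind_path", "code_path", "value_type",
                  "ui_label", "ui_answer_type", "ui_answer_options")

#' Classify a dictionary entry into a remodel pattern
#'
#' Deterministic selection: an explicit per-entry override in the config wins;
#' otherwise the first rule-table row whose resource type matches the entry's
#' mapped resource and whose answer type matches (empty matches any) decides;
#' entries with no mapped path or no matching rule fall through to
#' `passthrough` with a logged notice (never a guess).
#'
#' @param e one entry row (one-row data.frame).
#' @param config a [ig_config()].
#' @return list with `pattern` and `notice` (possibly NA), class
#'   `remodel_rule`.
#' @export
classify_entry <- function(e, config = ig_config()) {
  notice <- NA_character_
  pattern <- NULL
  ov <- config$rule_overrides
  if (length(ov) && e$element_id %in% names(ov)) {
    pattern <- unname(ov[[e$element_id]])
  } else if (blank(e$fhir_resource_path)) {
    pattern <- "passthrough"
    notice <- "no FHIR resource path; passed through unmodeled"
  } else {
    rt <- strsplit(trimws(strsplit(e$fhir_resource_path, "[,;]")[[1L]][1L]),
                   ".", fixed = TRUE)[[1L]][1L]
    rules <- config$rules
    hit <- which(rules$resource_type == rt &
                   (rules$answer_type == "" | rules$answer_type == e$answer_type))
    if (length(hit)) {
      pattern <- rules$pattern[hit[1L]]
    } else {
      pattern <- "passthrough"
      notice <- sprintf("no remodel rule for %s/%s; passed through",
                        rt, e$answer_type)
    }
  }
  structure(list(pattern = pattern, notice = notice), class = "remodel_rule")
}

# Patterns whose binding target is the resource's concept-set element.
concept_set_patterns <- c(condition_presence = "code",
                          medication_statement = "medication[x]",
                          procedure = "code")

#' Remodel one entry from the UI model into the semantic model
#'
#' `condition_presence` turns a yes/no form question into a condition entry
#' whose `code` element will be bound to a value set of the concept's
#' terminology codes (presence semantics replace the boolean answer; the
#' value set can hold any number of codes for the concept).
#' `coded_observation` keeps the question as an observation: the question's
#' own code is fixed on `code` and the answer options become a value set
#' bound on `value[x]`. Quantity/date patterns narrow the value type instead
#' of binding. The original UI fields are retained on the output row so the
#' transform is exactly reversible.
#'
#' @param e one entry row.
#' @param rule a `remodel_rule` from [classify_entry()].
#' @param config a [ig_config()].
#' @return the remodeled entry row with the remodel metadata columns added.
#' @export
remodel_entry <- function(e, rule, config = ig_config()) {
  stopifnot(inherits(rule, "remodel_rule"))
  out <- e
  out$ui_label <- e$label
  out$ui_answer_type <- e$answer_type
  out$ui_answer_options <- e$answer_options
  out$remodel_pattern <- rule$pattern
  out$bind_path <- ""
  out$code_path <- ""
  out$value_type <- ""
  if (rule$pattern == "passthrough") return(out)

  rt_el <- if (blank(e$fhir_resource_path)) c("", "") else {
    first <- trimws(strsplit(e$fhir_resource_path, "[,;]")[[1L]][1L])
    segs <- strsplit(first, ".", fixed = TRUE)[[1L]]
    c(segs[1L], paste(segs[-1L], collapse = "."))
  }

  if (rule$pattern %in% names(concept_set_patterns)) {
    codes <- parse_code_text(e$semantic_code_text, config$registry)$codings
    if (!nrow(codes) && blank(e$fhir_code) && blank(e$answer_options)) {
      dak_abort(sprintf(
        "entry '%s': %s remodel has no terminology codes to bind",
        e$element_id, rule$pattern), "dak_remodel_error",
        element_id = e$element_id)
    }
    el <- if (nzchar(rt_el[2L])) rt_el[2L] else unname(concept_set_patterns[rule$pattern])
    out$bind_path <- el
    out$fhir_resource_path <- paste0(rt_el[1L], ".", el)
    out$answer_type <- "choice"
    out$answer_options <- ""
  } else if (rule$pattern == "coded_observation") {
    out$bind_path <- if (nzchar(rt_el[2L])) rt_el[2L] else "value[x]"
    out$code_path <- "code"
    out$value_type <- "CodeableConcept"
  } else if (rule$pattern == "quantity_observation") {
    out$code_path <- "code"
    out$value_type <- "Quantity"
    if (!nzchar(rt_el[2L])) out$fhir_resource_path <- paste0(rt_el[1L], ".value")
  } else if (rule$pattern == "date_observation") {
    out$code_path <- "code"
    out$value_type <- "dateTime"
    if (!nzchar(rt_el[2L])) out$fhir_resource_path <- paste0(rt_el[1L], ".value")
  }
  out
}

#' Remodel every entry of a dictionary
#'
#' @param dict a `data_dictionary`.
#' @param config a [ig_config()].
#' @return the entries data.frame with remodel metadata columns; the
#'   per-entry decisions (pattern + notices) are attached as attribute
#'   `"remodel_log"` for audit.
#' @export
remodel_dictionary <- function(dict, config = ig_config()) {
  e <- dict$entries
  out <- NULL
  log <- data.frame(element_id = character(0), pattern = character(0),
                    notice = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(e))) {
    row <- e[i, , drop = FALSE]
    rule <- classify_entry(row, config)
    rem <- remodel_entry(row, rule, config)
    out <- if (is.null(out)) rem else rbind(out, rem)
    log <- rbind(log, data.frame(element_id = row$element_id,
                                 pattern = rule$pattern,
                                 notice = rule$notice %||% NA_character_,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- cbind(empty_entries(), as.data.frame(
      stats::setNames(rep(list(character(0)), length(REMODEL_COLS)), REMODEL_COLS)))
  }
  rownames(out) <- NULL
  attr(out, "remodel_log") <- log
  out
}

#' Revert a remodeled entry to its user-interface view
#'
#' Reconstructs the form question exactly as it stood before remodeling:
#' question label, answer type, and the ordered answer options.
#'
#' @param e one remodeled entry row (must carry the metadata written by
#'   [remodel_entry()]).
#' @return list with `question_label`, `answer_type`, `answer_options`,
#'   class `ui_element`.
#' @export
revert_entry <- function(e) {
  if (is.null(e$remodel_pattern) || is.na(e$remodel_pattern) ||
      !nzchar(e$remodel_pattern)) {
    dak_abort(sprintf("entry '%s' carries no remodel metadata; cannot revert",
                      e$element_id %||% "?"), "dak_revert_error")
  }
  structure(list(
    question_label = e$ui_label,
    answer_type = e$ui_answer_type,
    answer_options = split_multi(e$ui_answer_options)
  ), class = "ui_element")
}

#' UI projection of an (un-remodeled) dictionary entry
#'
#' The view of an entry as a form question; `revert_entry(remodel_entry(e, r))`
#' equals `ui_projection(e)` for every pattern.
#'
#' @param e one entry row.
#' @return a `ui_element` list.
#' @export
ui_projection <- function(e) {
  structure(list(
    question_label = e$label,
    answer_type = e$answer_type,
    answer_options = split_multi(e$answer_options)
  ), class = "ui_element")
}

#' @export
print.ui_element <- function(x, ...) {
  cat(sprintf("<ui_element> %s [%s]", x$question_label, x$answer_type))
  if (length(x$answer_options)) {
    cat(":", paste(x$answer_options, collapse = " / "))
  }
  cat("\n")
  invisible(x)
}
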