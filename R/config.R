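# Run configuration: canonical URLs, dialect, remodel rule table, registry
# extensions and emission switches. Replaces the ad-hoc shared-spreadsheet
# conventions of the original mapping workflow with one reproducible object
# that can be loaded from YAML.

#' Default remodel rule table
#'
#' Maps (resource type, answer type) to a remodel pattern. An explicit
#' per-entry override (by element id) always wins; entries matching no row
#' fall through to `passthrough`. Both modelings of a yes/no clinical concept
#' are expressible: the default routes boolean questions on `Condition` to
#' `condition_presence` (a code-bound condition whose value set can hold any
#' number of terminology codes) while boolean questions on `Observation`
#' stay `coded_observation` (one question code with a yes/no answer set).
#'
#' @return data.frame with columns `resource_type`, `answer_type`, `pattern`
#'   ("" matches any answer type).
#' @export
default_rule_table <- function() {
  data.frame(
    resource_type = c("Condition",
                      "Observation", "Observation", "Observation", "Observation",
                      "Observation", "Observation",
                      "MedicationStatement", "Procedure"),
    answer_type = c("",
                    "quantity", "choice", "multi-choice", "boolean",
                    "date", "datetime",
                    "", ""),
    pattern = c("condition_presence",
                "quantity_observation", "coded_observation", "coded_observation",
                "coded_observation", "date_observation", "date_observation",
                "medication_statement", "procedure"),
    stringsAsFactors = FALSE
  )
}

REMODEL_PATTERNS <- c("condition_presence", "coded_observation",
                      "quantity_observation", "date_observation",
                      "medication_statement", "procedure", "passthrough")

#' Build a run configuration
#'
#' @param canonical_base absolute canonical URL under which all generated
#'   conformance resources live.
#' @param ig_version version string stamped on generated resources.
#' @param publisher publisher string.
#' @param dialect column dialect, see [default_dialect()].
#' @param rules remodel rule table, see [default_rule_table()].
#' @param rule_overrides named character vector element_id -> pattern.
#' @param registry code-system registry, see [code_system_registry()].
#' @param min_card minimum cardinality for constrained elements: 0 (the
#'   default; the dictionary is a minimum data set, so elements are marked
#'   must-support rather than mandatory) or 1.
#' @param fixed_style "pattern" (open, discriminating fixations; default) or
#'   "fixed" (exact fixations).
#' @param overwrite allow emitted files to replace differing existing files.
#' @param allow_partial let generation succeed with uncovered entries.
#' @return object of class `dak_config`.
#' @export
ig_config <- function(canonical_base = "http://fhir.example.org/who-dak",
                      ig_version = "0.1.0",
                      publisher = "dak2fhir",
                      dialect = default_dialect(),
                      rules = default_rule_table(),
                      rule_overrides = character(0),
                      registry = code_system_registry(),
                      min_card = 0L,
                      fixed_style = c("pattern", "fixed"),
                      overwrite = FALSE,
                      allow_partial = FALSE) {
  if (!grepl("^https?://", canonical_base)) {
    dak_abort("canonical_base must be an absolute http(s) URL", "dak_config_error")
  }
  fixed_style <- match.arg(fixed_style)
  stopifnot(min_card %in% c(0L, 1L))
  bad <- setdiff(rules$pattern, REMODEL_PATTERNS)
  if (length(bad)) {
    dak_abort(sprintf("unknown remodel pattern(s): %s", paste(bad, collapse = ", ")),
              "dak_config_error")
  }
  structure(list(
    canonical_base = sub("/+$", "", canonical_base),
    ig_version = ig_version,
    fhir_version = "4.0.1",
    publisher = publisher,
    dialect = dialect,
    rules = rules,
    rule_overrides = rule_overrides,
    registry = registry,
    min_card = as.integer(min_card),
    fixed_style = fixed_style,
    overwrite = isTRUE(overwrite),
    allow_partial = isTRUE(allow_partial)
  ), class = "dak_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [ig_config()]; `dialect` is a
#' field->column map, `rule_overrides` an element_id->pattern map,
#' `registry_extras` a list of `{label, uri, pattern}` records appended to
#' the code-system registry. Unknown keys are rejected. `fhir_version`, if
#' given, must be "4.0.1".
#'
#' @param path YAML file path.
#' @return a `dak_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("canonical_base", "ig_version", "publisher", "dialect",
             "rules", "rule_overrides", "registry_extras", "min_card",
             "fixed_style", "overwrite", "allow_partial", "fhir_version")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    dak_abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
              "dak_config_error")
  }
  if (!is.null(y$fhir_version) && !identical(as.character(y$fhir_version), "4.0.1")) {
    dak_abort("fhir_version must be '4.0.1'", "dak_config_error")
  }
  dialect <- default_dialect()
  if (!is.null(y$dialect)) dialect[names(y$dialect)] <- unlist(y$dialect)
  rules <- if (is.null(y$rules)) default_rule_table() else {
    do.call(rbind, lapply(y$rules, function(r) {
      data.frame(resource_type = r$resource_type %||% "",
                 answer_type = r$answer_type %||% "",
                 pattern = r$pattern, stringsAsFactors = FALSE)
    }))
  }
  extras <- if (is.null(y$registry_extras)) NULL else {
    do.call(rbind, lapply(y$registry_extras, function(r) {
      data.frame(label = r$label, uri = r$uri,
                 pattern = r$pattern %||% NA_character_, stringsAsFactors = FALSE)
    }))
  }
  ig_config(
    canonical_base = y$canonical_base %||% "http://fhir.example.org/who-dak",
    ig_version = y$ig_version %||% "0.1.0",
    publisher = y$publisher %||% "dak2fhir",
    dialect = dialect,
    rules = rules,
    rule_overrides = unlist(y$rule_overrides) %||% character(0),
    registry = code_system_registry(extras),
    min_card = y$min_card %||% 0L,
    fixed_style = y$fixed_style %||% "pattern",
    overwrite = y$overwrite %||% FALSE,
    allow_partial = y$allow_partial %||% FALSE
  )
}
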