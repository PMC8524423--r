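# Dictionary model: the flat "master" data dictionary, its CSV/TSV dialect,
# consolidation of multi-sheet workbooks, and the completeness report.
#
# A dictionary is a data.frame of entries (one row per data element) plus
# provenance and duplicate-group bookkeeping. Multi-valued cells
# (answer options, additional FHIR attributes) are stored as "|"-separated
# strings so the whole object round-trips losslessly through CSV.

DICT_FIELDS <- c(
  "element_id", "label", "description", "answer_type", "answer_options",
  "fhir_resource_path", "additional_fhir_attributes", "target_profile_id",
  "value_set_binding", "binding_strength", "fhir_code_system", "fhir_code",
  "semantic_code_text", "program", "notes", "validation_status",
  "source_sheet"
)

ANSWER_TYPES <- c("boolean", "choice", "multi-choice", "quantity",
                  "date", "datetime", "text")
BINDING_STRENGTHS <- c("required", "extensible", "preferred", "example")
PROGRAMS <- c("core", "fp", "sti")

#' Default column dialect for dictionary files
#'
#' A named character vector mapping internal field names to the column
#' headers expected in input files. Override entries to adapt to a
#' differently-labelled spreadsheet export. The mandatory columns are
#' `label`, `fhir_resource_path` and `target_profile_id`; all others fall
#' back to defaults when absent (`element_id` is derived deterministically,
#' `binding_strength` defaults to "required", `validation_status` to
#' "unmapped").
#'
#' @return named character vector (field -> column header).
#' @export
default_dialect <- function() {
  stats::setNames(DICT_FIELDS, DICT_FIELDS)
}

mandatory_fields <- function() c("label", "fhir_resource_path", "target_profile_id")

empty_entries <- function(n = 0L) {
  as.data.frame(
    stats::setNames(rep(list(character(n)), length(DICT_FIELDS)), DICT_FIELDS),
    stringsAsFactors = FALSE
  )
}

#' Construct a data dictionary
#'
#' Normalizes defaults and enforces the structural invariants: element ids
#' non-empty and unique; a FHIR code requires its code system; choice-type
#' entries must carry answer options or a value-set binding; binding strength
#' defaults to "required".
#'
#' @param entries data.frame of entry rows (missing columns are filled with
#'   defaults).
#' @param source_sheets character vector of provenance labels.
#' @param duplicate_groups list of duplicate-group records (see
#'   [consolidate()]).
#' @return object of class `data_dictionary`.
#' @export
new_dictionary <- function(entries = empty_entries(), source_sheets = character(0),
                           duplicate_groups = list()) {
  for (f in DICT_FIELDS) {
    if (is.null(entries[[f]])) entries[[f]] <- character(nrow(entries))
    entries[[f]] <- as.character(entries[[f]])
    entries[[f]][is.na(entries[[f]])] <- ""
  }
  entries <- entries[, DICT_FIELDS, drop = FALSE]
  entries$binding_strength[blank(entries$binding_strength)] <- "required"
  entries$validation_status[blank(entries$validation_status)] <- "unmapped"
  entries$program[blank(entries$program)] <- "core"

  if (nrow(entries)) {
    need_id <- blank(entries$element_id)
    if (any(need_id)) {
      entries$element_id[need_id] <- derive_ids(
        entries$program[need_id], entries$label[need_id],
        taken = entries$element_id[!need_id])
    }
    dup <- entries$element_id[duplicated(entries$element_id)]
    if (length(dup)) {
      dak_abort(sprintf("duplicate element_id(s): %s",
                        paste(unique(dup), collapse = ", ")),
                "dak_load_error", offenders = unique(dup))
    }
    bad <- !entries$answer_type %in% c(ANSWER_TYPES, "")
    if (any(bad)) {
      dak_abort(sprintf("invalid answer_type(s): %s",
                        paste(unique(entries$answer_type[bad]), collapse = ", ")),
                "dak_load_error")
    }
    bad <- !entries$binding_strength %in% BINDING_STRENGTHS
    if (any(bad)) {
      dak_abort(sprintf("invalid binding_strength(s): %s",
                        paste(unique(entries$binding_strength[bad]), collapse = ", ")),
                "dak_load_error")
    }
    bad <- !entries$program %in% PROGRAMS
    if (any(bad)) {
      dak_abort(sprintf("invalid program tag(s): %s",
                        paste(unique(entries$program[bad]), collapse = ", ")),
                "dak_load_error")
    }
    bad <- !blank(entries$fhir_code) & blank(entries$fhir_code_system)
    if (any(bad)) {
      dak_abort(sprintf(
        "entries with a FHIR code but no FHIR code system: %s",
        paste(entries$element_id[bad], collapse = ", ")), "dak_load_error")
    }
    choice <- entries$answer_type %in% c("choice", "multi-choice")
    bad <- choice & blank(entries$answer_options) & blank(entries$value_set_binding) &
      blank(entries$semantic_code_text)
    if (any(bad)) {
      dak_abort(sprintf(
        "choice entries without answer options, codes or a value-set binding: %s",
        paste(entries$element_id[bad], collapse = ", ")), "dak_load_error")
    }
  }
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 source_sheets = source_sheets,
                 duplicate_groups = duplicate_groups),
            class = "data_dictionary")
}

# Deterministic ids: slug of program + label, numeric disambiguator on clash.
derive_ids <- function(program, label, taken = character(0)) {
  out <- character(length(label))
  seen <- taken
  for (i in seq_along(label)) {
    base <- slugify(paste(program[i], label[i]))
    if (!nzchar(base)) base <- "entry"
    id <- base
    k <- 1L
    while (id %in% seen) {
      k <- k + 1L
      id <- paste0(base, "-", k)
    }
    out[i] <- id
    seen <- c(seen, id)
  }
  out
}

#' @export
print.data_dictionary <- function(x, ...) {
  cat(sprintf("<data_dictionary> %d entries", nrow(x$entries)))
  if (length(x$source_sheets)) {
    cat(sprintf(" from %d sheet(s): %s", length(x$source_sheets),
                paste(x$source_sheets, collapse = ", ")))
  }
  cat("\n")
  if (length(x$duplicate_groups)) {
    kinds <- vapply(x$duplicate_groups, `[[`, "", "kind")
    cat(sprintf("  duplicate groups: %d merged, %d near-duplicate\n",
                sum(kinds == "merged"), sum(kinds == "near_duplicate")))
  }
  progs <- table(factor(x$entries$program, levels = PROGRAMS))
  cat(sprintf("  programs: core %d, fp %d, sti %d\n",
              progs[["core"]], progs[["fp"]], progs[["sti"]]))
  invisible(x)
}

table_sep <- function(path) if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","

#' Read a master dictionary from a delimited file
#'
#' Accepts UTF-8 CSV (or TSV, by extension) with a header row. Columns are
#' mapped to entry fields through the dialect; columns not named in the
#' dialect are preserved by appending `"[column: value]"` segments to the
#' entry's notes. Missing mandatory columns and duplicate element ids raise
#' structured load errors naming the offenders.
#'
#' @param path file path.
#' @param dialect column mapping, see [default_dialect()].
#' @param source_sheet provenance label recorded on the entries (defaults to
#'   the file name).
#' @return a [new_dictionary()] object.
#' @export
read_dictionary <- function(path, dialect = default_dialect(),
                            source_sheet = basename(path)) {
  if (!file.exists(path)) {
    dak_abort(sprintf("dictionary file not found: %s", path), "dak_load_error")
  }
  raw <- utils::read.table(path, sep = table_sep(path), header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  dictionary_from_table(raw, dialect, source_sheet)
}

# Shared by read_dictionary and consolidate: map a raw table into entries.
dictionary_from_table <- function(raw, dialect = default_dialect(),
                                  source_sheet = "") {
  missing_cols <- dialect[mandatory_fields()][!dialect[mandatory_fields()] %in% names(raw)]
  if (length(missing_cols)) {
    dak_abort(sprintf("missing mandatory column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "dak_load_error", columns = unname(missing_cols))
  }
  keep <- rowSums(raw != "" & !is.na(raw)) > 0L
  raw <- raw[keep, , drop = FALSE]
  entries <- empty_entries(nrow(raw))
  for (f in DICT_FIELDS) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(raw)) entries[[f]] <- raw[[col]]
  }
  extra <- setdiff(names(raw), dialect)
  if (length(extra) && nrow(raw)) {
    for (col in extra) {
      has <- !blank(raw[[col]])
      entries$notes[has] <- trimws(paste0(
        entries$notes[has], ifelse(nzchar(entries$notes[has]), " ", ""),
        "[", col, ": ", raw[[col]][has], "]"))
    }
  }
  if (nzchar(source_sheet)) {
    entries$source_sheet[blank(entries$source_sheet)] <- source_sheet
  }
  new_dictionary(entries, source_sheets = if (nzchar(source_sheet)) source_sheet else character(0))
}

#' Write a dictionary to CSV/TSV
#'
#' Inverse of [read_dictionary()]: `read_dictionary(write_dictionary(d, f))`
#' reproduces `d`'s entries field-by-field.
#'
#' @param dict a `data_dictionary`.
#' @param path output file path (.csv or .tsv).
#' @param dialect column mapping used for the header row.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dict, path, dialect = default_dialect()) {
  out <- dict$entries
  names(out) <- unname(dialect[names(out)])
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(out, path, sep = table_sep(path), row.names = FALSE,
                     qmethod = "double", fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Consolidate multiple workflow sheets into one flat master dictionary
#'
#' The source workbooks are organized along the clinical care continuum, so
#' the same concept can recur on several sheets. Consolidation takes the
#' ordered union of all rows, records per-sheet provenance, and groups rows
#' that denote the same concept. Rows identical under the duplicate key
#' (case-folded, whitespace-collapsed label plus FHIR resource path) *and*
#' carrying identical mappings are merged into the first occurrence; rows
#' that share a normalized label but differ in mapping are flagged as a
#' near-duplicate group for human review and never merged.
#'
#' @param sheets named list; each element a file path, a data.frame, or a
#'   `data_dictionary`.
#' @param dialect column mapping for file/table inputs.
#' @return a `data_dictionary` whose `duplicate_groups` records, per
#'   normalized label, `kind` ("merged" or "near_duplicate"), the original
#'   `element_ids`, and `merged` (named map original id -> surviving id).
#' @export
consolidate <- function(sheets, dialect = default_dialect()) {
  if (is.null(names(sheets)) || any(!nzchar(names(sheets)))) {
    names(sheets) <- paste0("sheet", seq_along(sheets))
  }
  parts <- lapply(names(sheets), function(nm) {
    s <- sheets[[nm]]
    d <- if (inherits(s, "data_dictionary")) s
    else if (is.character(s) && length(s) == 1L) read_dictionary(s, dialect, source_sheet = nm)
    else dictionary_from_table(as.data.frame(s, stringsAsFactors = FALSE), dialect, nm)
    e <- d$entries
    if (nrow(e)) e$source_sheet[blank(e$source_sheet)] <- nm
    e
  })
  all <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(all)) all <- empty_entries()

  # ids may clash across sheets; re-derive clashing ones deterministically
  if (nrow(all)) {
    dup <- duplicated(all$element_id) & !blank(all$element_id)
    all$element_id[dup] <- ""
    need <- blank(all$element_id)
    all$element_id[need] <- derive_ids(all$program[need], all$label[need],
                                       taken = all$element_id[!need])
  }

  map_key <- function(e) {
    paste(norm_label(e$label), gsub("\\s+", "", e$fhir_resource_path),
          e$target_profile_id, e$answer_type, e$answer_options,
          e$additional_fhir_attributes, e$value_set_binding,
          e$fhir_code_system, e$fhir_code, e$semantic_code_text, sep = "\r")
  }

  groups <- list()
  keep <- rep(TRUE, nrow(all))
  if (nrow(all)) {
    labels <- norm_label(all$label)
    for (lab in unique(labels[duplicated(labels)])) {
      idx <- which(labels == lab)
      keys <- map_key(all[idx, , drop = FALSE])
      merged <- character(0)
      for (k in unique(keys)) {
        rows <- idx[keys == k]
        if (length(rows) > 1L) {
          surv <- rows[1L]
          gone <- rows[-1L]
          keep[gone] <- FALSE
          sheets_seen <- unique(all$source_sheet[rows])
          all$source_sheet[surv] <- paste(sheets_seen, collapse = " | ")
          m <- stats::setNames(rep(all$element_id[surv], length(gone)),
                               all$element_id[gone])
          merged <- c(merged, m)
        }
      }
      kind <- if (length(unique(keys)) == 1L) "merged" else "near_duplicate"
      if (kind == "merged" && length(idx) < 2L) next
      groups[[length(groups) + 1L]] <- list(
        label = all$label[idx[1L]],
        kind = kind,
        element_ids = all$element_id[idx],
        merged = as.list(merged)
      )
    }
  }
  new_dictionary(all[keep, , drop = FALSE],
                 source_sheets = names(sheets),
                 duplicate_groups = groups)
}

#' Completeness report: is every dictionary concept realized in the guides?
#'
#' Cross-checks a dictionary against the implementation-guide packages
#' generated from it: for every entry, reports the profile and element
#' constraint realizing it, or lists it as uncovered (entries with a blank
#' FHIR resource path are always uncovered). Also tallies mapping-progress
#' counts by `validation_status`.
#'
#' @param dict the source `data_dictionary`.
#' @param packages list of `ig_package` objects generated from `dict` (e.g.
#'   `compile_dictionary(dict)$packages`).
#' @return object of class `coverage_report`: data.frame `rows` (element_id,
#'   label, covered, guide, profile, path), `coverage` fraction, and
#'   `status_counts`.
#' @export
completeness_report <- function(dict, packages) {
  e <- dict$entries
  rows <- data.frame(element_id = e$element_id, label = e$label,
                     covered = FALSE, guide = "", profile = "", path = "",
                     stringsAsFactors = FALSE)
  for (pkg in packages) {
    for (p in pkg$profiles) {
      prov <- attr(p, "provenance")  # constraint path -> element ids
      if (is.null(prov)) next
      for (path in names(prov)) {
        hit <- match(prov[[path]], rows$element_id)
        hit <- hit[!is.na(hit)]
        newly <- hit[!rows$covered[hit]]
        rows$covered[newly] <- TRUE
        rows$guide[newly] <- pkg$guide_id
        rows$profile[newly] <- p$name
        rows$path[newly] <- path
      }
    }
  }
  structure(list(
    rows = rows,
    coverage = if (nrow(rows)) mean(rows$covered) else 1,
    uncovered = rows$element_id[!rows$covered],
    status_counts = table(factor(e$validation_status,
                                 levels = c("unmapped", "mapped", "validated")))
  ), class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %.1f%% covered (%d/%d entries)\n",
              100 * x$coverage, sum(x$rows$covered), nrow(x$rows)))
  if (length(x$uncovered)) {
    cat("  uncovered:", paste(x$uncovered, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a coverage report as JSON and/or Markdown
#'
#' @param report a `coverage_report`.
#' @param json,md optional output paths.
#' @return invisibly, the report.
#' @export
write_coverage <- function(report, json = NULL, md = NULL) {
  if (!is.null(json)) {
    payload <- list(
      coverage = report$coverage,
      n_entries = nrow(report$rows),
      n_uncovered = length(report$uncovered),
      uncovered = report$uncovered,
      validation_status = as.list(report$status_counts),
      rows = report$rows
    )
    write_stable(json, as.character(to_stable_json(payload)), overwrite = TRUE)
  }
  if (!is.null(md)) {
    lines <- c(
      "# Dictionary coverage report", "",
      sprintf("Coverage: **%.1f%%** (%d of %d entries).", 100 * report$coverage,
              sum(report$rows$covered), nrow(report$rows)), "",
      "| Element | Covered | Guide | Profile | Path |",
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s |", report$rows$element_id,
              ifelse(report$rows$covered, "yes", "NO"), report$rows$guide,
              report$rows$profile, report$rows$path)
    )
    write_stable(md, lines, overwrite = TRUE)
  }
  invisible(report)
}
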