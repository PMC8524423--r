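# Shared test helpers: compact entry construction and a cached compile of
# the bundled dictionary (several files inspect the same build).

.test_cache <- new.env(parent = emptyenv())

bundled_build <- function() {
  if (is.null(.test_cache$build)) {
    .test_cache$build <- compile_dictionary(who_fp_sti_dictionary())
  }
  .test_cache$build
}

# One-row dictionary from named fields (defaults fill the rest).
make_dict <- function(...) {
  rows <- list(...)
  if (!is.null(rows$label)) rows <- list(rows)  # single row given inline
  entries <- NULL
  for (r in rows) {
    e <- as.data.frame(r, stringsAsFactors = FALSE)
    entries <- if (is.null(entries)) e else merge_rows(entries, e)
  }
  new_dictionary(entries)
}

merge_rows <- function(a, b) {
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- ""
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- ""
  rbind(a, b[names(a)])
}

# Compile a dictionary built from rows and return the build.
compile_rows <- function(..., config = ig_config()) {
  compile_dictionary(make_dict(...), config)
}

amenorrhea_row <- function() {
  list(label = "Amenorrhea", program = "fp", answer_type = "boolean",
       fhir_resource_path = "Condition.code",
       target_profile_id = "WHO-FP Condition (Medical Eligibility)",
       semantic_code_text = paste("ICD-10: N91.2 (maps to Amenorrhea)",
                                  "SNOMED: 14,302,001 (maps to Amenorrhea)",
                                  sep = "\n"))
}

azithromycin_row <- function() {
  list(label = "Azithromycin", program = "sti", answer_type = "choice",
       fhir_resource_path = "MedicationStatement.medication",
       target_profile_id = "WHO-STI MedicationStatement (Current Medication)",
       semantic_code_text = "RxNorm: 18,631 (maps to azithromycin)")
}

# All codings across a build's value sets, as one data.frame.
all_vs_codings <- function(build) {
  do.call(rbind, lapply(build$value_sets, `[[`, "codings"))
}
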