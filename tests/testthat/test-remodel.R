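# UI-model -> semantic-model remodeling and its reverse transform.

entry_of <- function(...) make_dict(list(...))$entries

test_that("rule classification is deterministic and follows the rule table", {
  cfg <- ig_config()
  e <- entry_of(label = "Hypertension", answer_type = "boolean",
                fhir_resource_path = "Condition.code",
                target_profile_id = "WHO-Core Condition (Hypertension)",
                semantic_code_text = "SNOMED: 38341003 (maps to Hypertension)")
  expect_identical(classify_entry(e, cfg)$pattern, "condition_presence")

  q <- entry_of(label = "Body Weight", answer_type = "quantity",
                fhir_resource_path = "Observation.value",
                target_profile_id = "WHO-Core Observation (Body Weight)")
  expect_identical(classify_entry(q, cfg)$pattern, "quantity_observation")

  blank_path <- entry_of(label = "X", answer_type = "text",
                         fhir_resource_path = "", target_profile_id = "P")
  r <- classify_entry(blank_path, cfg)
  expect_identical(r$pattern, "passthrough")
  expect_false(is.na(r$notice))

  # an explicit override beats the rule table (both condition modelings
  # of a yes/no concept are expressible)
  cfg2 <- ig_config(rule_overrides = c(`core-hypertension` = "passthrough"))
  expect_identical(classify_entry(e, cfg2)$pattern, "passthrough")
})

test_that("condition presence binds the concept's codes and drops the boolean", {
  e <- entry_of(label = "Hypertension", answer_type = "boolean",
                fhir_resource_path = "Condition.code",
                target_profile_id = "WHO-Core Condition (Hypertension)",
                semantic_code_text = "ICD-10: I10 (maps to Hypertension)")
  out <- remodel_entry(e, classify_entry(e))
  expect_identical(out$remodel_pattern, "condition_presence")
  expect_identical(out$bind_path, "code")
  expect_identical(out$answer_type, "choice")
  expect_identical(out$ui_answer_type, "boolean")

  # with no codes at all there is nothing to bind
  bad <- entry_of(label = "Mystery", answer_type = "boolean",
                  fhir_resource_path = "Condition.code",
                  target_profile_id = "P")
  expect_error(remodel_entry(bad, classify_entry(bad)),
               class = "dak_remodel_error")
})

test_that("passthrough is the identity on the dictionary fields", {
  e <- entry_of(label = "Free text", answer_type = "text",
                fhir_resource_path = "Practitioner.name",
                target_profile_id = "WHO-Core Practitioner")
  out <- remodel_entry(e, classify_entry(e))
  for (f in names(e)) expect_identical(out[[f]], e[[f]], info = f)
})

test_that("revert after remodel reproduces the UI view for every pattern", {
  cases <- list(
    entry_of(label = "Hypertension", answer_type = "boolean",
             fhir_resource_path = "Condition.code", target_profile_id = "P1",
             program = "fp", semantic_code_text = "SNOMED: 38341003"),
    entry_of(label = "Contraceptive method", answer_type = "choice",
             answer_options = "Pill (SNOMED: 123456789) | Implant (SNOMED: 987654321)",
             fhir_resource_path = "Observation.value", target_profile_id = "P2"),
    entry_of(label = "Body Weight", answer_type = "quantity",
             fhir_resource_path = "Observation.value", target_profile_id = "P3"),
    entry_of(label = "Date of delivery", answer_type = "date",
             fhir_resource_path = "Observation.value", target_profile_id = "P4"),
    entry_of(label = "Azithromycin", answer_type = "choice",
             fhir_resource_path = "MedicationStatement.medication",
             target_profile_id = "P5", semantic_code_text = "RxNorm: 18631"),
    entry_of(label = "IUD insertion", answer_type = "boolean",
             fhir_resource_path = "Procedure.code", target_profile_id = "P6",
             semantic_code_text = "SNOMED: 301806003"),
    entry_of(label = "Notes", answer_type = "text",
             fhir_resource_path = "Practitioner.name", target_profile_id = "P7")
  )
  patterns_seen <- character(0)
  for (e in cases) {
    rule <- classify_entry(e)
    patterns_seen <- c(patterns_seen, rule$pattern)
    out <- remodel_entry(e, rule)
    expect_equal(revert_entry(out), ui_projection(e), info = e$label)
  }
  expect_setequal(patterns_seen,
                  c("condition_presence", "coded_observation",
                    "quantity_observation", "date_observation",
                    "medication_statement", "procedure", "passthrough"))
})

test_that("reversibility holds property-style on random dictionaries", {
  for (seed in c(2, 13)) {
    d <- random_dictionary(fixture_spec(seed = seed, n_entries = 30))
    rem <- remodel_dictionary(d)
    for (i in seq_len(nrow(rem))) {
      expect_equal(revert_entry(rem[i, , drop = FALSE]),
                   ui_projection(d$entries[i, , drop = FALSE]))
    }
  }
})

test_that("remodeling never drops terminology codes from the entry", {
  d <- who_fp_sti_dictionary()
  rem <- remodel_dictionary(d)
  for (i in seq_len(nrow(d$entries))) {
    before <- parse_code_text(d$entries$semantic_code_text[i])$codings
    after <- parse_code_text(rem$semantic_code_text[i])$codings
    if (nrow(before)) {
      expect_true(all(paste(before$system, before$code) %in%
                        paste(after$system, after$code)),
                  info = d$entries$element_id[i])
    }
  }
})

test_that("reverting an entry without remodel metadata is an error", {
  e <- entry_of(label = "X", answer_type = "text",
                fhir_resource_path = "Observation.value", target_profile_id = "P")
  expect_error(revert_entry(e), class = "dak_revert_error")
})
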