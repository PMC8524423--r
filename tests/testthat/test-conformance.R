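# Path/attribute parsing, value-set registry and profile building.

test_that("FHIR resource paths parse and unsupported types are rejected", {
  p <- parse_fhir_path("AllergyIntolerance.code")
  expect_equal(p$resource_type, "AllergyIntolerance")
  expect_equal(p$element_path, "code")

  bare <- parse_fhir_path("Observation")
  expect_equal(bare$element_path, "")  # profile-level mapping only

  multi <- parse_fhir_path("Observation.value, Observation.effective")
  expect_equal(nrow(multi), 2L)

  expect_error(parse_fhir_path("Foo.bar"), class = "dak_path_error")
  err <- tryCatch(parse_fhir_path("Basic.code"), dak_path_error = identity)
  expect_match(conditionMessage(err), "Basic")
})

test_that("fixed attributes parse with exactly one equals sign", {
  fx <- parse_fixed_attribute("AllergyIntolerance.category = medication")
  expect_equal(fx$path, "AllergyIntolerance.category")
  expect_equal(fx$value, "medication")
  expect_equal(parse_fixed_attribute("Observation.status = final")$value, "final")
  expect_error(parse_fixed_attribute("Observation.status"),
               class = "dak_attr_error")
  expect_error(parse_fixed_attribute("a = b = c"), class = "dak_attr_error")
})

test_that("value sets reuse registered content instead of duplicating", {
  reg <- dak2fhir:::new_vs_registry()
  cfg <- ig_config()
  gender <- rbind(coding("http://hl7.org/fhir/administrative-gender", "female", "Female"),
                  coding("http://hl7.org/fhir/administrative-gender", "male", "Male"))
  v1 <- build_value_set(gender, "Gender Values", reg, cfg)
  expect_equal(sort(v1$codings$code), c("female", "male"))
  # same content again, even under another name: registry grows by 1 not 2
  v2 <- build_value_set(gender[2:1, ], "Sex Values", reg, cfg)
  expect_identical(v2$id, v1$id)
  expect_length(reg$by_hash, 1L)

  # distinct content with the same display name gets a distinct id
  other <- rbind(gender, coding("http://hl7.org/fhir/administrative-gender",
                                "other", "Other"))
  v3 <- build_value_set(other, "Gender Values", reg, cfg)
  expect_false(identical(v3$id, v1$id))
  expect_length(reg$by_hash, 2L)

  expect_error(build_value_set(dak2fhir:::empty_codings(), "Empty", reg, cfg),
               class = "dak_valueset_error")
})

test_that("duplicate codings deduplicate against a brute-force oracle", {
  set.seed(4)
  for (rep in 1:5) {
    k <- sample(3:10, 1)
    codes <- sprintf("%09d", sample(1e8:(1e8 + 50), k, replace = TRUE))
    cds <- coding("http://snomed.info/sct", codes[1])
    for (c2 in codes[-1]) cds <- rbind(cds, coding("http://snomed.info/sct", c2))
    vs <- build_value_set(cds, sprintf("Random %d", rep))
    expect_equal(nrow(vs$codings), length(unique(codes)))  # oracle: unique()
  }
})

test_that("the drug-allergy group builds a two-constraint profile", {
  d <- make_dict(label = "Drug Allergies", program = "core",
                 answer_type = "text",
                 fhir_resource_path = "AllergyIntolerance.code",
                 additional_fhir_attributes = "AllergyIntolerance.category = medication",
                 target_profile_id = "WHO-Core AllergyIntolerance (Drug Allergies)")
  rem <- remodel_dictionary(d)
  p <- build_profile(rem)
  expect_identical(p$name, "WHO-Core AllergyIntolerance (Drug Allergies)")
  expect_identical(p$id, "who-core-allergyintolerance-drug-allergies")
  expect_length(p$constraints, 2L)
  expect_identical(names(p$constraints), c("category", "code"))  # sorted
  expect_identical(p$constraints$category$fixed$value, "medication")
})

test_that("minimal and binding profiles build as specified", {
  d <- make_dict(label = "Free text", program = "core", answer_type = "text",
                 fhir_resource_path = "Observation.value",
                 target_profile_id = "WHO-Core Observation (Free text)")
  p <- build_profile(remodel_dictionary(d))
  expect_length(p$constraints, 1L)

  db <- make_dict(label = "Not done reason", program = "sti",
                  answer_type = "choice",
                  fhir_resource_path = "Communication.statusReason",
                  value_set_binding = "http://hl7.org/fhir/ValueSet/communication-not-done-reason",
                  target_profile_id = "WHO-STI Communication (Partner)")
  pb <- build_profile(remodel_dictionary(db))
  bind <- pb$constraints$statusReason$binding
  expect_identical(bind$url, "http://hl7.org/fhir/ValueSet/communication-not-done-reason")
  expect_identical(bind$strength, "required")
})

test_that("mixed resource types within one profile id are a grouping error", {
  d <- make_dict(list(label = "A", program = "core", answer_type = "text",
                      fhir_resource_path = "Observation.value",
                      target_profile_id = "P"),
                 list(label = "B", program = "core", answer_type = "text",
                      fhir_resource_path = "Patient.birthDate",
                      target_profile_id = "P"))
  rem <- remodel_dictionary(d)
  expect_error(build_profile(rem), class = "dak_grouping_error")
})

test_that("choice questions with k coded options bind a k-coding value set", {
  set.seed(8)
  for (k in c(2L, 4L, 6L)) {
    codes <- sprintf("%09d", sample(1e8:9e8, k))
    opts <- paste(sprintf("Opt%d (SNOMED: %s)", seq_len(k), codes),
                  collapse = " | ")
    d <- make_dict(label = sprintf("Choice %d", k), program = "core",
                   answer_type = "choice", answer_options = opts,
                   fhir_resource_path = "Observation.value",
                   target_profile_id = sprintf("WHO-Core Observation (Choice %d)", k),
                   semantic_code_text = "SNOMED: 123456789")
    b <- compile_dictionary(d)
    expect_length(b$value_sets, 1L)
    # oracle: direct option -> coding transform
    expect_equal(b$value_sets[[1L]]$codings$code, codes)
    expect_equal(nrow(b$value_sets[[1L]]$codings), k)
  }
})

test_that("StructureDefinition emission is byte-stable and differential-only", {
  b <- bundled_build()
  p <- b$profiles[["who-core-allergyintolerance-drug-allergies"]]
  doc <- emit_structure_definition(p, b$config)
  expect_identical(doc$derivation, "constraint")
  expect_identical(doc$fhirVersion, "4.0.1")
  expect_identical(doc$kind, "resource")
  j1 <- as.character(dak2fhir:::to_stable_json(doc))
  j2 <- as.character(dak2fhir:::to_stable_json(emit_structure_definition(p, b$config)))
  expect_identical(j1, j2)

  # a profile-level mapping yields a root-only differential
  d <- make_dict(label = "Whole resource", program = "core", answer_type = "text",
                 fhir_resource_path = "Observation",
                 target_profile_id = "WHO-Core Observation (Whole)")
  p0 <- build_profile(remodel_dictionary(d))
  doc0 <- emit_structure_definition(p0)
  expect_length(doc0$differential$element, 1L)
  expect_identical(doc0$differential$element[[1L]]$path, "Observation")
})

test_that("the question code is fixed with FHIR-code precedence", {
  d <- make_dict(label = "HIV Status", program = "core", answer_type = "boolean",
                 fhir_resource_path = "Observation.value",
                 fhir_code_system = "http://example.org/fhircs",
                 fhir_code = "hiv-status",
                 semantic_code_text = "LOINC: 55277-8 (maps to HIV status)",
                 target_profile_id = "WHO-Core Observation (HIV Status)")
  p <- build_profile(remodel_dictionary(d))
  expect_identical(p$constraints$code$fixed$system, "http://example.org/fhircs")
  expect_identical(p$constraints$code$fixed$code, "hiv-status")
  # the value element carries the yes/no binding, never a fixation
  expect_null(p$constraints$`value[x]`$fixed)
  expect_false(is.null(p$constraints$`value[x]`$binding))
})

test_that("paths missing from the base resource become generated extensions", {
  d <- make_dict(label = "Tribal affiliation", program = "core",
                 answer_type = "text",
                 fhir_resource_path = "Patient.tribalAffiliation",
                 target_profile_id = "WHO-Core Patient (Extended)")
  b <- compile_dictionary(d)
  p <- b$profiles[[1L]]
  expect_length(p$extensions, 1L)
  expect_true("extension" %in% names(p$constraints))
  expect_equal(nrow(validate_build(b)), 0L)
})
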