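# Fixtures: the bundled WHO FP/STI dictionary reconstruction and a seeded
# random-dictionary generator, so the whole pipeline is exercisable with no
# downloads.
#
# The bundled dictionary realizes the published worked examples (amenorrhea
# with its ICD-10 and SNOMED codes, number of pregnancies with its LOINC
# code, azithromycin with its RxNorm code, the drug-allergy profile with a
# fixed category, the administrative-gender FHIR coding, and the
# communication-not-done-reason binding) plus one row per profile of the
# published Core / FP / STI inventory. Rows behind profiles whose
# element-level content was never published are synthesized minimally (one
# plausible element path per resource type, deterministic synthetic codes)
# and are marked "synthetic skeleton row" in their notes.

CORE_PROFILES <- c(
  "WHO-Core AllergyIntolerance",
  "WHO-Core AllergyIntolerance (Drug Allergies)",
  "WHO-Core Appointment (Return Visit)",
  "WHO-Core Appointment (Visit)",
  "WHO-Core CarePlan (Follow-up)",
  "WHO-Core CarePlan (Intake Contraceptive Method)",
  "WHO-Core CarePlan (Prior Contraceptive Methods)",
  "WHO-Core Coverage (Insurance)",
  "WHO-Core DeviceUseStatement (Intake Contraceptive Method)",
  "WHO-Core DeviceUseStatement (Prior Contraceptive Methods)",
  "WHO-Core MedicationStatement (Current Contraceptive Methods)",
  "WHO-Core MedicationStatement (Current Medication)",
  "WHO-Core MedicationStatement (Prior Contraceptive Methods)",
  "WHO-Core Observation (BMI)",
  "WHO-Core Observation (Body Height)",
  "WHO-Core Observation (Body Weight)",
  "WHO-Core Observation (Breastfeeding)",
  "WHO-Core Observation (Clinical Observations)",
  "WHO-Core Observation (Date of Delivery)",
  "WHO-Core Observation (Days since Unprotected Sex)",
  "WHO-Core Observation (Gender-based Violence Risk Factors)",
  "WHO-Core Observation (Gender-based Violence Victim)",
  "WHO-Core Observation (HIV Care Enrollment)",
  "WHO-Core Observation (HIV Stage)",
  "WHO-Core Observation (HIV Status)",
  "WHO-Core Observation (HIV Test)",
  "WHO-Core Observation (Last Normal Menses)",
  "WHO-Core Observation (Miscarriage or Abortion)",
  "WHO-Core Observation (Never used contraception)",
  "WHO-Core Observation (Number of births)",
  "WHO-Core Observation (Number of Pregnancies)",
  "WHO-Core Observation (Postpartum)",
  "WHO-Core Observation (Pregnancy Status)",
  "WHO-Core Observation (PrEP Status)",
  "WHO-Core Observation (Reason for no contraceptive method at intake)",
  "WHO-Core Observation (Recent Sexual History)",
  "WHO-Core Observation (Sexual History)",
  "WHO-Core Observation (Sexually Active)",
  "WHO-Core Observation (STI Risk Factors)",
  "WHO-Core Observation (Temperature)",
  "WHO-Core Observation (Time Postpartum)",
  "WHO-Core Patient",
  "WHO-Core Practitioner",
  "WHO-Core Procedure (Intake Contraceptive Method)",
  "WHO-Core Procedure (Prior Contraceptive Methods)",
  "WHO-Core ServiceRequest (Referral)"
)

FP_PROFILES <- c(
  "WHO-FP CarePlan (Backup Contraceptive Method)",
  "WHO-FP CarePlan (Exit Contraceptive Method)",
  "WHO-FP CarePlan (Recommendation)",
  "WHO-FP CarePlan (Requested Contraceptive Method)",
  "WHO-FP Condition (Medical Eligibility)",
  "WHO-FP Consent",
  "WHO-FP DeviceUseStatement (Exit Contraceptive Method)",
  "WHO-FP DeviceUseStatement (Requested Contraceptive Method)",
  "WHO-FP Encounter",
  "WHO-FP Encounter (Contraception Issues and Concerns)",
  "WHO-FP HealthcareService",
  "WHO-FP MedicationStatement (Current Medication)",
  "WHO-FP MedicationStatement (Exit Contraceptive Method)",
  "WHO-FP MedicationStatement (Requested Contraceptive Method)",
  "WHO-FP Observation (Breastfeeding Status)",
  "WHO-FP Observation (Days since Last Normal Menses)",
  "WHO-FP Observation (Intercourse since Last Normal Menses)",
  "WHO-FP Observation (Medical eligibility number)",
  "WHO-FP Observation (Medical eligibility text)",
  "WHO-FP Observation (Medical Eligibility)",
  "WHO-FP Observation (Missed or Late Menses)",
  "WHO-FP Observation (Pregnancy Intention)",
  "WHO-FP Observation (Reason for no contraceptive method at exit)",
  "WHO-FP Observation (Reason for Stopping Contraception)",
  "WHO-FP Observation (Smoking Status)",
  "WHO-FP Observation (Test Results)",
  "WHO-FP Procedure (Exit Contraceptive Method)",
  "WHO-FP Procedure (Requested Contraceptive Method)",
  "WHO-FP Procedure (Service Provided)"
)

STI_PROFILES <- c(
  "WHO-STI CarePlan (Recommendation)",
  "WHO-STI Communication (Partner)",
  "WHO-STI Condition (Diagnosis)",
  "WHO-STI Condition (HIV)",
  "WHO-STI Condition (STI History)",
  "WHO-STI Medication",
  "WHO-STI MedicationAdministration",
  "WHO-STI MedicationStatement (Current Medication)",
  "WHO-STI MedicationStatement (Medication History)",
  "WHO-STI Observation (Current STI Treatment)",
  "WHO-STI Observation (Disease Exposure)",
  "WHO-STI Observation (External Genital Examination)",
  "WHO-STI Observation (Increased STI Risk)",
  "WHO-STI Observation (LGV Follow-up)",
  "WHO-STI Observation (Partner HIV Status)",
  "WHO-STI Observation (Partner Symptoms)",
  "WHO-STI Observation (Past STI Treatment)",
  "WHO-STI Observation (Recent Abortion or Miscarriage)",
  "WHO-STI Observation (Recent Syphilis Treatment)",
  "WHO-STI Observation (Reported Symptoms)",
  "WHO-STI Observation (Risk Assessment)",
  "WHO-STI Observation (Signs of Fever)",
  "WHO-STI Observation (Signs of Shock)",
  "WHO-STI Observation (Speculum Examination)",
  "WHO-STI Observation (STI Screening)",
  "WHO-STI Observation (Syphilis Stage)",
  "WHO-STI Observation (Trauma History)",
  "WHO-STI Patient",
  "WHO-STI Procedure (Service Provided)",
  "WHO-STI Specimen"
)

#' Published profile inventory per guide
#'
#' The display names of the profiles in the Core, family-planning and STI
#' implementation guides, as published.
#'
#' @return named list of character vectors (`core`, `fp`, `sti`).
#' @export
profile_inventory <- function() {
  list(core = CORE_PROFILES, fp = FP_PROFILES, sti = STI_PROFILES)
}

profile_parts <- function(name) {
  m <- regmatches(name, regexec("^WHO-(Core|FP|STI) ([A-Za-z]+)(?: \\((.*)\\))?$", name))[[1L]]
  list(program = tolower(m[2L]), resource = m[3L],
       label = if (nzchar(m[4L])) m[4L] else m[3L])
}

# Deterministic synthetic codes for skeleton rows (SNOMED-, RxNorm- and
# LOINC-shaped; syntactically valid, clinically meaningless).
synth_snomed <- function(k) sprintf("%09d", 700000000 + 101 * k)
synth_rxnorm <- function(k) sprintf("%d", 500000 + k)
synth_loinc  <- function(k) sprintf("%05d-%d", 90000 + k, k %% 10)

quantity_label_rx <- "Number|BMI|Height|Weight|Temperature|Days|Time Postpartum|number"

skeleton_row <- function(profile, k) {
  p <- profile_parts(profile)
  e <- list(label = p$label, program = p$program, target_profile_id = profile,
            answer_type = "text", answer_options = "", semantic_code_text = "",
            fhir_resource_path = "", notes = "synthetic skeleton row",
            validation_status = "mapped")
  r <- p$resource
  if (r == "Observation") {
    e$fhir_resource_path <- "Observation.value"
    if (grepl(quantity_label_rx, p$label)) {
      e$answer_type <- "quantity"
      e$semantic_code_text <- sprintf("LOINC: %s (maps to %s)", synth_loinc(k), p$label)
    } else if (grepl("Date", p$label)) {
      e$answer_type <- "date"
      e$semantic_code_text <- sprintf("LOINC: %s (maps to %s)", synth_loinc(k), p$label)
    } else if (grepl("text", p$label)) {
      e$answer_type <- "text"
    } else {
      e$answer_type <- "boolean"
      e$semantic_code_text <- sprintf("SNOMED: %s (maps to %s)", synth_snomed(k), p$label)
    }
  } else if (r == "Condition") {
    e$fhir_resource_path <- "Condition.code"
    e$answer_type <- "boolean"
    e$semantic_code_text <- sprintf("SNOMED: %s (maps to %s)", synth_snomed(k), p$label)
  } else if (r %in% c("MedicationStatement", "MedicationAdministration")) {
    e$fhir_resource_path <- paste0(r, ".medication")
    e$answer_type <- "choice"
    e$semantic_code_text <- sprintf("RxNorm: %s (maps to %s medication)",
                                    synth_rxnorm(k), p$label)
  } else if (r == "Medication") {
    e$fhir_resource_path <- "Medication.code"
    e$answer_type <- "choice"
    e$answer_options <- "Azithromycin (RxNorm: 18,631)"
  } else if (r == "Procedure") {
    e$fhir_resource_path <- "Procedure.code"
    e$answer_type <- "boolean"
    e$semantic_code_text <- sprintf("SNOMED: %s (maps to %s procedure)",
                                    synth_snomed(k), p$label)
  } else if (r %in% c("CarePlan", "Encounter", "HealthcareService",
                      "Coverage", "Specimen", "Consent", "ServiceRequest")) {
    path <- switch(r, CarePlan = "CarePlan.category", Encounter = "Encounter.type",
                   HealthcareService = "HealthcareService.type",
                   Coverage = "Coverage.type", Specimen = "Specimen.type",
                   Consent = "Consent.category", ServiceRequest = "ServiceRequest.code")
    e$fhir_resource_path <- path
    e$answer_type <- "choice"
    e$answer_options <- p$label
  } else if (r == "Appointment") {
    e$fhir_resource_path <- "Appointment.start"
    e$answer_type <- "datetime"
  } else if (r == "DeviceUseStatement") {
    e$fhir_resource_path <- "DeviceUseStatement.device"
  } else if (r == "AllergyIntolerance") {
    e$fhir_resource_path <- "AllergyIntolerance.code"
  } else if (r == "Patient") {
    e$fhir_resource_path <- "Patient.birthDate"
    e$answer_type <- "date"
  } else if (r == "Practitioner") {
    e$fhir_resource_path <- "Practitioner.name"
  }
  e
}

# The six worked mapping rows, keyed by the profile they land in.
worked_rows <- function() {
  list(
    "WHO-FP Condition (Medical Eligibility)" = list(
      label = "Amenorrhea", program = "fp",
      target_profile_id = "WHO-FP Condition (Medical Eligibility)",
      answer_type = "boolean", answer_options = "",
      fhir_resource_path = "Condition.code",
      semantic_code_text = paste("ICD-10: N91.2 (maps to Amenorrhea)",
                                 "SNOMED: 14,302,001 (maps to Amenorrhea)",
                                 sep = "\n"),
      description = "Client has not menstruated for over 6 months",
      validation_status = "validated"),
    "WHO-Core Observation (Number of Pregnancies)" = list(
      label = "Number of Pregnancies", program = "core",
      target_profile_id = "WHO-Core Observation (Number of Pregnancies)",
      answer_type = "quantity", answer_options = "",
      fhir_resource_path = "Observation.value",
      semantic_code_text = "LOINC: 11996–6 (maps to Number of Pregnancies)",
      description = "Total number of pregnancies, including the current one",
      validation_status = "validated"),
    "WHO-STI MedicationStatement (Current Medication)" = list(
      label = "Azithromycin", program = "sti",
      target_profile_id = "WHO-STI MedicationStatement (Current Medication)",
      answer_type = "choice", answer_options = "",
      fhir_resource_path = "MedicationStatement.medication",
      semantic_code_text = "RxNorm: 18,631 (maps to azithromycin)",
      description = "Client currently taking azithromycin",
      validation_status = "validated"),
    "WHO-Core AllergyIntolerance (Drug Allergies)" = list(
      label = "Drug Allergies", program = "core",
      target_profile_id = "WHO-Core AllergyIntolerance (Drug Allergies)",
      answer_type = "text", answer_options = "",
      fhir_resource_path = "AllergyIntolerance.code",
      additional_fhir_attributes = "AllergyIntolerance.category = medication",
      description = "Known allergies to medications",
      validation_status = "validated"),
    "WHO-Core Patient" = list(
      label = "Gender", program = "core",
      target_profile_id = "WHO-Core Patient",
      answer_type = "choice", answer_options = "Female | Male",
      fhir_resource_path = "Patient.gender",
      fhir_code_system = "http://hl7.org/fhir/administrative-gender",
      fhir_code = "female",
      description = "Administrative gender of the client",
      validation_status = "validated"),
    "WHO-STI Communication (Partner)" = list(
      label = "Partner notification not done reason", program = "sti",
      target_profile_id = "WHO-STI Communication (Partner)",
      answer_type = "choice", answer_options = "",
      fhir_resource_path = "Communication.statusReason",
      value_set_binding = "http://hl7.org/fhir/ValueSet/communication-not-done-reason",
      binding_strength = "required",
      description = "Reason partner notification was not performed",
      validation_status = "validated")
  )
}

#' The bundled WHO FP/STI master dictionary
#'
#' Reconstructs a master data dictionary carrying the six published worked
#' mapping rows plus one (synthetic, minimally modelled) row per profile of
#' the published three-guide inventory, with consistent program tags.
#' Compiling it reproduces the Core/FP/STI profile inventory exactly.
#'
#' @return a `data_dictionary`.
#' @export
#' @examples
#' d <- who_fp_sti_dictionary()
#' nrow(d$entries)
who_fp_sti_dictionary <- function() {
  inv <- unlist(profile_inventory(), use.names = FALSE)
  worked <- worked_rows()
  rows <- vector("list", length(inv))
  for (k in seq_along(inv)) {
    prof <- inv[k]
    rows[[k]] <- worked[[prof]] %||% skeleton_row(prof, k)
  }
  entries <- empty_entries(length(rows))
  for (k in seq_along(rows)) {
    for (f in names(rows[[k]])) entries[[f]][k] <- rows[[k]][[f]]
  }
  new_dictionary(entries, source_sheets = "bundled")
}

#' Specification for a random synthetic dictionary
#'
#' @param seed RNG seed.
#' @param n_entries total number of rows (including deliberate duplicates).
#' @param program_mix named proportions over core/fp/sti; must sum to 1.
#' @param fraction_choice,fraction_quantity,fraction_boolean answer-type mix;
#'   the remainder is split between date and text questions.
#' @param codes_per_option integer range `c(min, max)` of inline terminology
#'   codes per answer option (0 yields a generated local code).
#' @param duplicate_rate fraction of rows that are verbatim repeats of
#'   earlier rows (as happens when workflow sheets repeat a concept).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_entries = 50L,
                         program_mix = c(core = 0.4, fp = 0.3, sti = 0.3),
                         fraction_choice = 0.3, fraction_quantity = 0.2,
                         fraction_boolean = 0.3,
                         codes_per_option = c(0L, 1L),
                         duplicate_rate = 0) {
  fr <- c(fraction_choice, fraction_quantity, fraction_boolean, duplicate_rate)
  if (any(fr < 0 | fr > 1) || sum(fr[1:3]) > 1) {
    dak_abort("answer-type fractions must lie in [0,1] and sum to at most 1",
              "dak_spec_error")
  }
  if (abs(sum(program_mix) - 1) > 1e-8 ||
      !all(names(program_mix) %in% PROGRAMS)) {
    dak_abort("program_mix must be proportions over core/fp/sti summing to 1",
              "dak_spec_error")
  }
  if (n_entries == 0L && duplicate_rate > 0) {
    dak_abort("cannot request duplicates in an empty dictionary", "dak_spec_error")
  }
  structure(list(seed = as.integer(seed), n_entries = as.integer(n_entries),
                 program_mix = program_mix,
                 fraction_choice = fraction_choice,
                 fraction_quantity = fraction_quantity,
                 fraction_boolean = fraction_boolean,
                 codes_per_option = as.integer(codes_per_option),
                 duplicate_rate = duplicate_rate),
            class = "fixture_spec")
}

rand_snomed <- function(n) sprintf("%09d", floor(stats::runif(n, 1e8, 1e9)))

#' Generate a random synthetic dictionary
#'
#' Reproducible for equal seeds; respects the spec's proportions up to
#' rounding; every generated code is syntactically valid for its system.
#' The number of deliberate duplicate rows is attached as attribute
#' `"n_duplicates"`.
#'
#' @param spec a [fixture_spec()].
#' @return a `data_dictionary`.
#' @export
random_dictionary <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_dup <- round(spec$n_entries * spec$duplicate_rate)
  n_base <- spec$n_entries - n_dup
  with_seed(spec$seed, {
    prefix <- c(core = "WHO-Core", fp = "WHO-FP", sti = "WHO-STI")
    fr_rest <- max(0, 1 - spec$fraction_choice - spec$fraction_quantity -
                     spec$fraction_boolean)
    types <- if (n_base) sample(
      c("choice", "quantity", "boolean", "date", "text"), n_base, replace = TRUE,
      prob = c(spec$fraction_choice, spec$fraction_quantity,
               spec$fraction_boolean, fr_rest / 2, fr_rest / 2)) else character(0)
    progs <- if (n_base) sample(names(spec$program_mix), n_base, replace = TRUE,
                                prob = spec$program_mix) else character(0)
    entries <- empty_entries(n_base)
    for (i in seq_len(n_base)) {
      lab <- sprintf("Concept %03d", i)
      ty <- types[i]
      rt <- if (ty == "boolean") sample(c("Condition", "Observation"), 1L)
      else "Observation"
      path <- if (rt == "Condition") "Condition.code" else "Observation.value"
      opts <- ""
      sem <- ""
      if (ty == "choice") {
        k <- sample(2:4, 1L)
        opt <- sprintf("%s option %d", lab, seq_len(k))
        ncode <- sample(seq(spec$codes_per_option[1L], spec$codes_per_option[2L]),
                        k, replace = TRUE)
        coded <- ncode > 0
        opt[coded] <- sprintf("%s (SNOMED: %s)", opt[coded],
                              rand_snomed(sum(coded)))
        opts <- join_multi(opt)
        sem <- sprintf("SNOMED: %s (maps to %s)", rand_snomed(1L), lab)
      } else if (ty == "boolean") {
        sem <- sprintf("SNOMED: %s (maps to %s)", rand_snomed(1L), lab)
      } else if (ty %in% c("quantity", "date")) {
        sem <- sprintf("LOINC: %05d-%d (maps to %s)",
                       sample(10000:99999, 1L), sample(0:9, 1L), lab)
      }
      entries$label[i] <- lab
      entries$program[i] <- progs[i]
      entries$answer_type[i] <- ty
      entries$answer_options[i] <- opts
      entries$fhir_resource_path[i] <- path
      entries$semantic_code_text[i] <- sem
      entries$target_profile_id[i] <- sprintf("%s %s (%s)", prefix[progs[i]], rt, lab)
      entries$validation_status[i] <- "mapped"
    }
    if (n_dup > 0L) {
      src <- sample(n_base, n_dup, replace = TRUE)
      dup <- entries[src, , drop = FALSE]
      dup$element_id <- ""
      entries <- rbind(entries, dup)
    }
    d <- new_dictionary(entries)
    attr(d, "n_duplicates") <- n_dup
    d
  })
}
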