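# Dictionary IO, consolidation and the completeness report.

write_sheet <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

test_that("a one-row file reads with the terminology text verbatim", {
  f <- write_sheet(data.frame(
    label = "Amenorrhea",
    fhir_resource_path = "Observation.value",
    target_profile_id = "WHO-FP Observation (Amenorrhea)",
    semantic_code_text = "SNOMED: 14,302,001 (maps to Amenorrhea)",
    check.names = FALSE), tempfile(fileext = ".csv"))
  d <- read_dictionary(f)
  expect_equal(nrow(d$entries), 1L)
  expect_identical(d$entries$semantic_code_text,
                   "SNOMED: 14,302,001 (maps to Amenorrhea)")
  expect_true(nzchar(d$entries$element_id))  # derived deterministically
})

test_that("empty data sections and missing mandatory columns are handled", {
  f <- write_sheet(data.frame(label = character(0),
                              fhir_resource_path = character(0),
                              target_profile_id = character(0)),
                   tempfile(fileext = ".csv"))
  expect_equal(nrow(read_dictionary(f)$entries), 0L)

  f2 <- write_sheet(data.frame(label = "x", fhir_resource_path = "Observation.value"),
                    tempfile(fileext = ".csv"))
  err <- tryCatch(read_dictionary(f2), dak_load_error = identity)
  expect_s3_class(err, "dak_load_error")
  expect_match(conditionMessage(err), "target_profile_id")
})

test_that("duplicate element ids are rejected, unknown columns kept as notes", {
  f <- write_sheet(data.frame(element_id = c("a", "a"), label = c("X", "Y"),
                              fhir_resource_path = "Observation.value",
                              target_profile_id = "P"),
                   tempfile(fileext = ".csv"))
  err <- tryCatch(read_dictionary(f), dak_load_error = identity)
  expect_s3_class(err, "dak_load_error")
  expect_match(conditionMessage(err), "a")

  f2 <- write_sheet(data.frame(label = "X", fhir_resource_path = "Observation.value",
                               target_profile_id = "P", reviewer = "JS"),
                    tempfile(fileext = ".csv"))
  d <- read_dictionary(f2)
  expect_match(d$entries$notes, "\\[reviewer: JS\\]")
})

test_that("dictionaries round-trip through CSV field-by-field", {
  for (d in list(who_fp_sti_dictionary(),
                 random_dictionary(fixture_spec(seed = 11, n_entries = 25)))) {
    f <- tempfile(fileext = ".csv")
    write_dictionary(d, f)
    d2 <- read_dictionary(f, source_sheet = "")
    expect_equal(d2$entries, d$entries)
  }
})

test_that("structural invariants are enforced at construction", {
  expect_error(make_dict(label = "X", fhir_resource_path = "Observation.value",
                         target_profile_id = "P", fhir_code = "female"),
               class = "dak_load_error")  # code without code system
  expect_error(make_dict(label = "X", fhir_resource_path = "Observation.value",
                         target_profile_id = "P", answer_type = "choice"),
               class = "dak_load_error")  # choice without options/binding/codes
  d <- make_dict(label = "X", fhir_resource_path = "Observation.value",
                 target_profile_id = "P", answer_type = "choice",
                 value_set_binding = "http://example.org/vs")
  expect_identical(d$entries$binding_strength, "required")  # default strength
})

test_that("identical rows on two sheets merge into one flagged group", {
  row <- data.frame(label = "Number of Pregnancies",
                    fhir_resource_path = "Observation.value",
                    target_profile_id = "WHO-Core Observation (Number of Pregnancies)",
                    answer_type = "quantity", program = "core")
  m <- consolidate(list(anc = row, visit = row))
  expect_equal(nrow(m$entries), 1L)
  expect_length(m$duplicate_groups, 1L)
  expect_identical(m$duplicate_groups[[1L]]$kind, "merged")
  expect_length(m$duplicate_groups[[1L]]$element_ids, 2L)
  expect_match(m$entries$source_sheet, "anc")
  expect_match(m$entries$source_sheet, "visit")
})

test_that("conflicting mappings are flagged as near-duplicates, never merged", {
  a <- data.frame(label = "Hypertension", fhir_resource_path = "Condition.code",
                  target_profile_id = "WHO-Core Condition (A)",
                  answer_type = "boolean",
                  semantic_code_text = "SNOMED: 38341003")
  b <- a
  b$target_profile_id <- "WHO-Core Condition (B)"
  m <- consolidate(list(s1 = a, s2 = b))
  expect_equal(nrow(m$entries), 2L)
  expect_identical(m$duplicate_groups[[1L]]$kind, "near_duplicate")
  expect_length(m$duplicate_groups[[1L]]$merged, 0L)
})

test_that("disjoint sheets concatenate: entry count matches a brute-force union", {
  set.seed(9)
  mk <- function(labels) data.frame(label = labels,
                                    fhir_resource_path = "Observation.value",
                                    target_profile_id = paste("P", labels),
                                    answer_type = "text")
  n <- c(4L, 7L, 3L)
  sheets <- list(s1 = mk(sprintf("A%02d", 1:n[1])),
                 s2 = mk(sprintf("B%02d", 1:n[2])),
                 s3 = mk(sprintf("C%02d", 1:n[3])))
  m <- consolidate(sheets)
  expect_equal(nrow(m$entries), sum(n))  # oracle: naive concatenation
  expect_length(m$duplicate_groups, 0L)
})

test_that("consolidation matches the brute-force union+grouping oracle", {
  # oracle: exact-duplicate classes under (normalized label, path, mapping)
  oracle_count <- function(raws) {
    all <- do.call(rbind, raws)
    key <- paste(tolower(gsub("\\s+", " ", trimws(all$label))),
                 all$fhir_resource_path, all$target_profile_id,
                 all$answer_type, all$semantic_code_text)
    nrow(all) - sum(table(key) - 1L)
  }
  for (seed in 1:5) {
    set.seed(seed)
    base <- data.frame(
      label = sprintf("Concept %02d", 1:8),
      fhir_resource_path = "Observation.value",
      target_profile_id = sprintf("WHO-Core Observation (Concept %02d)", 1:8),
      answer_type = "text", semantic_code_text = "")
    raws <- lapply(1:3, function(i) base[sample(8, sample(3:6, 1)), , drop = FALSE])
    m <- consolidate(stats::setNames(raws, paste0("s", 1:3)))
    expect_equal(nrow(m$entries), oracle_count(raws), info = seed)
  }
})

test_that("re-consolidating a consolidated dictionary changes nothing", {
  d <- random_dictionary(fixture_spec(seed = 5, n_entries = 40, duplicate_rate = 0.2))
  once <- consolidate(list(master = d))
  twice <- consolidate(list(master = once))
  expect_equal(twice$entries$label, once$entries$label)
  expect_equal(twice$entries$target_profile_id, once$entries$target_profile_id)
  # second pass performs zero merges
  merges <- unlist(lapply(twice$duplicate_groups, `[[`, "merged"))
  expect_length(merges, 0L)
})

test_that("entry count after consolidation equals rows minus duplicate excess", {
  for (seed in c(3, 7)) {
    d <- random_dictionary(fixture_spec(seed = seed, n_entries = 30,
                                        duplicate_rate = 0.2))
    n_dup <- attr(d, "n_duplicates")
    m <- consolidate(list(master = d))
    expect_equal(nrow(m$entries), nrow(d$entries) - n_dup)
  }
})

test_that("completeness report finds full coverage and flags unmapped rows", {
  b <- bundled_build()
  rep <- completeness_report(b$dictionary, b$packages)
  expect_equal(rep$coverage, 1)
  expect_length(rep$uncovered, 0L)

  # a blank-path entry is listed uncovered
  d <- make_dict(list(label = "Mapped", fhir_resource_path = "Observation.value",
                      target_profile_id = "WHO-Core Observation (Mapped)",
                      answer_type = "text", program = "core"),
                 list(label = "Orphan", fhir_resource_path = "",
                      target_profile_id = "", answer_type = "text",
                      program = "core"))
  bb <- compile_dictionary(d)
  expect_identical(bb$coverage$uncovered, "core-orphan")

  # 50-entry fixture with 5 deliberately unmapped: uncovered = set difference
  dd <- random_dictionary(fixture_spec(seed = 21, n_entries = 50))
  unmapped <- dd$entries$element_id[seq(1, 50, by = 10)]
  dd$entries$fhir_resource_path[dd$entries$element_id %in% unmapped] <- ""
  bb2 <- compile_dictionary(dd)
  expect_setequal(bb2$coverage$uncovered, unmapped)
  expect_equal(length(bb2$coverage$uncovered), 5L)
})
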