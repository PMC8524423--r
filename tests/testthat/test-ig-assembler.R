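# Guide partitioning, differential tables and IG tree emission.

fake_profile <- function(id, program, vs_ids = character(0)) {
  structure(list(name = id, id = id, resource_type = "Observation",
                 base = "http://hl7.org/fhir/StructureDefinition/Observation",
                 constraints = list(), program = program,
                 value_set_ids = vs_ids, extensions = list()),
            class = "ProfileDefinition")
}

fake_vs <- function(id) {
  structure(list(name = id, id = id,
                 canonical_url = paste0("http://x/ValueSet/", id),
                 codings = coding("http://snomed.info/sct", "123456"),
                 content_hash = id),
            class = "ValueSetDefinition")
}

test_that("profiles partition into guides and value sets follow usage", {
  profs <- list(fake_profile("p-core", "core", "vs-a"),
                fake_profile("p-fp", "fp", "vs-b"),
                fake_profile("p-sti", "sti", c("vs-b", "vs-c")))
  vss <- list(fake_vs("vs-a"), fake_vs("vs-b"), fake_vs("vs-c"))
  refs <- list(`vs-a` = "p-core", `vs-b` = c("p-fp", "p-sti"), `vs-c` = "p-sti")
  pkgs <- assign_guides(profs, vss, refs)
  expect_identical(vapply(pkgs$core$profiles, `[[`, "", "id"), "p-core")
  expect_identical(vapply(pkgs$fp$profiles, `[[`, "", "id"), "p-fp")
  # vs-b is shared by FP and STI, so it is promoted to Core
  expect_setequal(vapply(pkgs$core$value_sets, `[[`, "", "id"), c("vs-a", "vs-b"))
  expect_identical(vapply(pkgs$sti$value_sets, `[[`, "", "id"), "vs-c")
  expect_identical(pkgs$fp$dependencies, "core")
  expect_identical(pkgs$core$dependencies, character(0))
})

test_that("random assignments match a brute-force rule evaluation", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 30L
    programs <- sample(c("core", "fp", "sti"), n, replace = TRUE)
    profs <- lapply(seq_len(n), function(i) {
      fake_profile(sprintf("p%02d", i), programs[i], sprintf("vs%02d", i %% 7))
    })
    vss <- lapply(0:6, function(k) fake_vs(sprintf("vs%02d", k)))
    refs <- list()
    for (p in profs) refs[[p$value_set_ids]] <-
        c(refs[[p$value_set_ids]], p$id)
    pkgs <- assign_guides(profs, vss, refs)

    # partition property: every profile in exactly one package
    ids_by_pkg <- lapply(pkgs, function(p) vapply(p$profiles, `[[`, "", "id"))
    expect_setequal(unlist(ids_by_pkg), vapply(profs, `[[`, "", "id"))
    expect_equal(sum(lengths(ids_by_pkg)), n)
    # oracle: direct evaluation of the placement rule
    for (g in names(pkgs)) {
      expect_setequal(ids_by_pkg[[g]],
                      vapply(profs, `[[`, "", "id")[programs == g])
    }
    # value sets: single-guide usage stays, mixed usage promotes to core
    for (k in 0:6) {
      vid <- sprintf("vs%02d", k)
      users <- refs[[vid]] %||% character(0)
      gs <- unique(programs[match(users, vapply(profs, `[[`, "", "id"))])
      want <- if (length(gs) == 1L) gs else "core"
      got <- names(Filter(function(p) vid %in% vapply(p$value_sets, `[[`, "", "id"), pkgs))
      expect_identical(got, want, info = vid)
    }
  }
})

test_that("untagged profiles are an assignment error", {
  expect_error(assign_guides(list(fake_profile("p", "")), list(), list()),
               class = "dak_assignment_error")
})

test_that("differential tables list one row per constraint", {
  b <- bundled_build()
  p <- b$profiles[["who-core-allergyintolerance-drug-allergies"]]
  md <- render_differential_table(p)
  expect_match(md[1L], "WHO-Core AllergyIntolerance \\(Drug Allergies\\)")
  rows <- grep("^\\| AllergyIntolerance\\.", md)
  expect_length(rows, length(p$constraints))
  expect_true(any(grepl("category.*medication", md)))

  empty <- fake_profile("empty", "core")
  md0 <- render_differential_table(empty)
  expect_length(grep("^\\| Observation\\.", md0), 0L)  # header-only

  for (p2 in b$profiles[5:15]) {
    md2 <- render_differential_table(p2)
    expect_length(grep(sprintf("^\\| %s\\.", p2$resource_type), md2),
                  length(p2$constraints))
  }
})

test_that("the IG resource enumerates every emitted artifact exactly once", {
  b <- bundled_build()
  out <- withr::local_tempdir()
  write_ig(b, out)
  for (g in c("core", "fp", "sti")) {
    ig <- jsonlite::fromJSON(file.path(out, g, "input",
                                       sprintf("ImplementationGuide-%s.json", g)),
                             simplifyVector = FALSE)
    refs <- vapply(ig$definition$resource, function(r) r$reference$reference, "")
    expect_false(any(duplicated(refs)))
    files <- list.files(file.path(out, g, "input", "resources"))
    expect_setequal(refs, sub("\\.json$", "", sub("-", "/", files)))
  }
})

test_that("an empty package emits an IG resource with zero artifacts", {
  pkgs <- assign_guides(list(fake_profile("p", "fp")), list(), list())
  out <- withr::local_tempdir()
  emit_ig(pkgs$sti, out)
  ig <- jsonlite::fromJSON(file.path(out, "sti", "input",
                                     "ImplementationGuide-sti.json"),
                           simplifyVector = FALSE)
  expect_length(ig$definition$resource, 0L)
  expect_false(dir.exists(file.path(out, "sti", "input", "resources")))
})

test_that("regeneration is byte-identical; one added entry changes only its files", {
  d1 <- random_dictionary(fixture_spec(seed = 17, n_entries = 10))
  b1 <- compile_dictionary(d1)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  write_ig(b1, out1)
  write_ig(b1, out2)
  f1 <- sort(list.files(out1, recursive = TRUE))
  expect_identical(f1, sort(list.files(out2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(out1, f), warn = FALSE),
                     readLines(file.path(out2, f), warn = FALSE), info = f)
  }

  # add one entry and regenerate in place: only the new profile's files and
  # the touched manifests may change (oracle: file-tree diff)
  extra <- make_dict(label = "Added concept", program = "fp",
                     answer_type = "text",
                     fhir_resource_path = "Observation.value",
                     target_profile_id = "WHO-FP Observation (Added concept)")
  d2 <- new_dictionary(rbind(d1$entries, extra$entries))
  b2 <- compile_dictionary(d2)
  write_ig(b2, out2, overwrite = TRUE)
  f2 <- sort(list.files(out2, recursive = TRUE))
  new_files <- setdiff(f2, f1)
  expect_true(all(grepl("who-fp-observation-added-concept", new_files)))
  changed <- Filter(function(f) {
    !identical(readLines(file.path(out1, f), warn = FALSE),
               readLines(file.path(out2, f), warn = FALSE))
  }, f1)
  expect_true(all(grepl("ImplementationGuide-fp|fp/input/pagecontent/index", changed)))
})

test_that("a differing existing file is an emit error unless overwrite is set", {
  b <- compile_dictionary(random_dictionary(fixture_spec(seed = 23, n_entries = 5)))
  out <- withr::local_tempdir()
  write_ig(b, out)
  victim <- list.files(out, pattern = "^StructureDefinition-",
                       recursive = TRUE, full.names = TRUE)[1L]
  writeLines("{}", victim)
  expect_error(write_ig(b, out), class = "dak_emit_error")
  write_ig(b, out, overwrite = TRUE)
  expect_false(identical(readLines(victim, warn = FALSE), "{}"))
})
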