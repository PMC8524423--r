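# IG assembly: partition profiles and value sets into the shared Core guide
# and the per-program guides (FP, STI), and write complete IG source trees.
#
# The output layout follows the de-facto IG-publisher input convention
# (input/resources, input/pagecontent, an npm-style package manifest) but no
# publisher is invoked and no HTML is rendered.

guide_title <- function(guide_id) {
  switch(guide_id,
         core = "WHO Core Implementation Guide",
         fp = "WHO Family Planning Implementation Guide",
         sti = "WHO Sexually Transmitted Infections Implementation Guide",
         paste("WHO", totitle(guide_id), "Implementation Guide"))
}

#' Partition profiles and value sets into implementation-guide packages
#'
#' Profiles tagged `core` (including those promoted because entries from both
#' programs reference them — promotion happens in [build_profile()]) go to
#' the shared Core guide; the rest go to their program's guide. Each value
#' set lands in the lowest common package of its referencing profiles: FP- or
#' STI-only usage stays in that guide, mixed usage is promoted to Core (which
#' both depend on). Generated code systems follow their value sets.
#'
#' @param profiles list of `ProfileDefinition`s (each carries its program tag).
#' @param value_sets list of `ValueSetDefinition`s.
#' @param vs_refs named list: value-set id -> character vector of referencing
#'   profile ids.
#' @param code_systems list of local code-system records.
#' @param config a [ig_config()].
#' @return named list of `ig_package` objects (`core`, `fp`, `sti`, plus any
#'   extra program tags observed).
#' @export
assign_guides <- function(profiles, value_sets, vs_refs = list(),
                          code_systems = list(), config = ig_config()) {
  progs <- vapply(profiles, `[[`, "", "program")
  bad <- !nzchar(progs)
  if (any(bad)) {
    dak_abort(sprintf("profile(s) without a program tag: %s",
                      paste(vapply(profiles[bad], `[[`, "", "id"), collapse = ", ")),
              "dak_assignment_error")
  }
  guide_ids <- unique(c("core", "fp", "sti", progs))
  prof_guide <- stats::setNames(progs, vapply(profiles, `[[`, "", "id"))

  vs_guide <- vapply(value_sets, function(vs) {
    users <- vs_refs[[vs$id]] %||% character(0)
    gs <- unique(unname(prof_guide[users]))
    gs <- gs[!is.na(gs)]
    if (length(gs) == 1L) gs else "core"
  }, "")
  names(vs_guide) <- vapply(value_sets, `[[`, "", "id")

  # a code system follows the value sets that draw on it
  cs_guide <- vapply(code_systems, function(cs) {
    gs <- unique(vs_guide[vapply(value_sets, function(vs) cs$url %in% vs$codings$system, NA)])
    if (length(gs) == 1L) gs else "core"
  }, "")

  pkgs <- lapply(guide_ids, function(g) {
    structure(list(
      guide_id = g,
      title = guide_title(g),
      canonical_base = config$canonical_base,
      profiles = profiles[progs == g],
      value_sets = value_sets[vs_guide == g],
      code_systems = code_systems[cs_guide == g],
      dependencies = if (g == "core") character(0) else "core"
    ), class = "ig_package")
  })
  stats::setNames(pkgs, guide_ids)
}

#' @export
print.ig_package <- function(x, ...) {
  cat(sprintf("<ig_package> %s: %d profile(s), %d value set(s), %d code system(s)\n",
              x$guide_id, length(x$profiles), length(x$value_sets),
              length(x$code_systems)))
  invisible(x)
}

#' Render a profile's differential as a human-readable Markdown table
#'
#' One row per element constraint: path, cardinality, type, fixed value,
#' binding (value-set URL and strength). The header names the profile and
#' its base resource.
#'
#' @param p a `ProfileDefinition`.
#' @return character vector of Markdown lines.
#' @export
render_differential_table <- function(p) {
  lines <- c(
    sprintf("## %s", p$name),
    "",
    sprintf("Differential on base resource `%s` (%s).", p$resource_type, p$base),
    "",
    "| Path | Card. | Type | Fixed | Binding |",
    "|---|---|---|---|---|"
  )
  for (c0 in p$constraints) {
    base_el <- resolve_element(p$resource_type, c0$path)
    base_max <- if (is.null(base_el)) "*" else base_el$meta$max
    card <- paste0(c0$min %||% "", "..", c0$max %||% base_max)
    ty <- if (is.null(c0$type)) "" else
      paste(vapply(c0$type, `[[`, "", "code"), collapse = ", ")
    fx <- if (is.null(c0$fixed)) "" else if (!is.null(c0$fixed$system))
      sprintf("%s (%s)", c0$fixed$code, c0$fixed$system) else c0$fixed$value
    bd <- if (is.null(c0$binding)) "" else
      sprintf("%s (%s)", c0$binding$url, c0$binding$strength)
    lines <- c(lines, sprintf("| %s.%s | %s | %s | %s | %s |",
                              p$resource_type, c0$path, card, ty, fx, bd))
  }
  lines
}

ig_resource_entry <- function(rt, id, name) {
  list(reference = list(reference = paste0(rt, "/", id)),
       name = name, exampleBoolean = FALSE)
}

emit_ig_resource <- function(pkg, config) {
  arts <- list()
  for (p in pkg$profiles) {
    arts[[length(arts) + 1L]] <- ig_resource_entry("StructureDefinition", p$id, p$name)
    for (ext in p$extensions) {
      arts[[length(arts) + 1L]] <- ig_resource_entry("StructureDefinition", ext$id, ext$name)
    }
  }
  for (vs in pkg$value_sets) {
    arts[[length(arts) + 1L]] <- ig_resource_entry("ValueSet", vs$id, vs$name)
  }
  for (cs in pkg$code_systems) {
    arts[[length(arts) + 1L]] <- ig_resource_entry("CodeSystem", cs$id, cs$name)
  }
  ord <- order(vapply(arts, function(a) a$reference$reference, ""))
  doc <- list(
    resourceType = "ImplementationGuide",
    id = pkg$guide_id,
    url = paste0(config$canonical_base, "/ImplementationGuide/", pkg$guide_id),
    version = config$ig_version,
    name = computable_name(pkg$title),
    title = pkg$title,
    status = "draft",
    publisher = config$publisher,
    packageId = paste0("who.dak.", pkg$guide_id),
    fhirVersion = list("4.0.1")
  )
  if (length(pkg$dependencies)) {
    doc$dependsOn <- lapply(pkg$dependencies, function(d) {
      list(uri = paste0(config$canonical_base, "/ImplementationGuide/", d),
           packageId = paste0("who.dak.", d),
           version = config$ig_version)
    })
  }
  doc$definition <- list(resource = arts[ord])
  doc
}

emit_manifest <- function(pkg, config) {
  deps <- list(`hl7.fhir.r4.core` = "4.0.1")
  for (d in pkg$dependencies) deps[[paste0("who.dak.", d)]] <- config$ig_version
  list(
    name = paste0("who.dak.", pkg$guide_id),
    version = config$ig_version,
    title = pkg$title,
    canonical = paste0(config$canonical_base, "/ImplementationGuide/", pkg$guide_id),
    fhirVersions = list("4.0.1"),
    dependencies = deps
  )
}

#' Write one IG package as an implementation-guide source tree
#'
#' Emits, under `<outdir>/<guide_id>/`: the ImplementationGuide R4 resource
#' enumerating every artifact exactly once (`input/ImplementationGuide-*.json`),
#' one JSON file per StructureDefinition / ValueSet / CodeSystem under
#' `input/resources/`, a Markdown differential page per profile plus an index
#' under `input/pagecontent/`, and an npm-style `package.json` manifest.
#' Re-running on unchanged input leaves every byte identical; a collision
#' with a differing existing file is an error unless `overwrite` is set.
#'
#' @param pkg an `ig_package`.
#' @param outdir output root directory.
#' @param config a [ig_config()].
#' @param overwrite permit replacing differing files.
#' @return invisibly, a data.frame of written files and their statuses.
#' @export
emit_ig <- function(pkg, outdir, config = ig_config(), overwrite = config$overwrite) {
  root <- file.path(outdir, pkg$guide_id)
  written <- data.frame(path = character(0), status = character(0),
                        stringsAsFactors = FALSE)
  put <- function(rel, content) {
    p <- file.path(root, rel)
    st <- write_stable(p, content, overwrite = overwrite)
    written <<- rbind(written, data.frame(path = rel, status = st,
                                          stringsAsFactors = FALSE))
  }
  put(file.path("input", sprintf("ImplementationGuide-%s.json", pkg$guide_id)),
      as.character(to_stable_json(emit_ig_resource(pkg, config))))
  for (p in pkg$profiles) {
    put(file.path("input", "resources",
                  sprintf("StructureDefinition-%s.json", p$id)),
        as.character(to_stable_json(emit_structure_definition(p, config))))
    for (ext in p$extensions) {
      put(file.path("input", "resources",
                    sprintf("StructureDefinition-%s.json", ext$id)),
          as.character(to_stable_json(emit_extension_definition(ext, config))))
    }
    put(file.path("input", "pagecontent", paste0(p$id, ".md")),
        render_differential_table(p))
  }
  for (vs in pkg$value_sets) {
    put(file.path("input", "resources", sprintf("ValueSet-%s.json", vs$id)),
        as.character(to_stable_json(emit_value_set(vs, config))))
  }
  for (cs in pkg$code_systems) {
    put(file.path("input", "resources", sprintf("CodeSystem-%s.json", cs$id)),
        as.character(to_stable_json(emit_code_system(cs, config))))
  }
  index <- c(sprintf("# %s", pkg$title), "",
             "Profiles in this guide:", "",
             if (length(pkg$profiles)) {
               sprintf("- [%s](%s.md)",
                       vapply(pkg$profiles, `[[`, "", "name"),
                       vapply(pkg$profiles, `[[`, "", "id"))
             })
  put(file.path("input", "pagecontent", "index.md"), index)
  put("package.json", as.character(to_stable_json(emit_manifest(pkg, config))))
  invisible(written)
}

#' Validate every conformance resource in an emitted IG tree
#'
#' Runs [validate_structuredef()] over each StructureDefinition and the
#' minimal structural checks over ValueSet / CodeSystem / ImplementationGuide
#' files. Generated extensions found in the tree are exempted from the
#' base-path check in the profiles that reference them.
#'
#' @param dir root of one or more emitted guide trees.
#' @return data.frame of issues with a `file` column; zero rows when clean.
#' @export
validate_ig_tree <- function(dir) {
  files <- sort(list.files(
    dir, recursive = TRUE, full.names = TRUE,
    pattern = "^(ImplementationGuide|StructureDefinition|ValueSet|CodeSystem)-.*\\.json$"))
  docs <- lapply(files, function(f) jsonlite::fromJSON(f, simplifyVector = FALSE))
  ext_urls <- unlist(lapply(docs, function(d) {
    if (identical(d$resourceType, "StructureDefinition") &&
        identical(d$type, "Extension")) d$url else NULL
  }))
  out <- cbind(no_issues(), data.frame(file = character(0), stringsAsFactors = FALSE))
  for (i in seq_along(docs)) {
    iss <- if (identical(docs[[i]]$resourceType, "StructureDefinition")) {
      validate_structuredef(docs[[i]], extensions = ext_urls)
    } else {
      validate_conformance_resource(docs[[i]])
    }
    if (nrow(iss)) {
      iss$file <- files[i]
      out <- rbind(out, iss)
    }
  }
  out
}
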