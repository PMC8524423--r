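# The end-to-end compile pipeline: remodel -> profiles -> value sets ->
# guide assignment -> coverage. Fully deterministic: equal dictionaries
# produce byte-identical artifact trees.

#' Compile a master dictionary into implementation-guide packages
#'
#' Runs the whole pipeline in memory: remodels every entry from its
#' user-interface form into the semantic model, groups mapped entries by
#' target profile id and builds one StructureDefinition differential per
#' group, resolves answer concepts into content-deduplicated value sets (and
#' local code systems where options carry no standard code), partitions
#' everything into the shared Core guide plus the FP and STI guides, and
#' cross-checks completeness against the source dictionary.
#'
#' @param dict a `data_dictionary`.
#' @param config a [ig_config()].
#' @return object of class `ig_build`: `dictionary`, `remodeled` (entries
#'   with remodel metadata), `profiles`, `value_sets`, `code_systems`,
#'   `vs_refs` (value-set id -> referencing profile ids), `packages`,
#'   `coverage` (a `coverage_report`), `remodel_log`.
#' @export
compile_dictionary <- function(dict, config = ig_config()) {
  remodeled <- remodel_dictionary(dict, config)
  vs_reg <- new_vs_registry()
  cs_reg <- new_cs_registry()

  mapped <- remodeled[!blank(remodeled$fhir_resource_path) &
                        !blank(remodeled$target_profile_id), , drop = FALSE]
  profiles <- list()
  vs_refs <- list()
  for (pid in unique(mapped$target_profile_id)) {
    group <- mapped[mapped$target_profile_id == pid, , drop = FALSE]
    p <- build_profile(group, config, vs_reg, cs_reg)
    profiles[[p$id]] <- p
    for (vid in p$value_set_ids) {
      vs_refs[[vid]] <- unique(c(vs_refs[[vid]], p$id))
    }
  }
  value_sets <- unname(vs_reg$by_hash)
  value_sets <- value_sets[order(vapply(value_sets, `[[`, "", "id"))]
  code_systems <- unname(cs_reg$systems)
  code_systems <- code_systems[order(vapply(code_systems, `[[`, "", "id"))]

  packages <- assign_guides(unname(profiles), value_sets, vs_refs,
                            code_systems, config)
  coverage <- completeness_report(dict, packages)

  structure(list(
    dictionary = dict,
    remodeled = remodeled,
    profiles = profiles,
    value_sets = value_sets,
    code_systems = code_systems,
    vs_refs = vs_refs,
    packages = packages,
    coverage = coverage,
    remodel_log = attr(remodeled, "remodel_log"),
    config = config
  ), class = "ig_build")
}

#' @export
print.ig_build <- function(x, ...) {
  cat(sprintf("<ig_build> %d entries -> %d profiles, %d value sets, %d code systems\n",
              nrow(x$dictionary$entries), length(x$profiles),
              length(x$value_sets), length(x$code_systems)))
  for (g in names(x$packages)) {
    cat(sprintf("  %-4s %3d profile(s), %2d value set(s)\n", g,
                length(x$packages[[g]]$profiles),
                length(x$packages[[g]]$value_sets)))
  }
  cat(sprintf("  coverage: %.1f%%\n", 100 * x$coverage$coverage))
  invisible(x)
}

#' Write every package of a build as IG source trees
#'
#' @param build an `ig_build`.
#' @param outdir output root; one subdirectory per guide.
#' @param overwrite permit replacing differing files.
#' @return invisibly, a data.frame of all written files and statuses.
#' @export
write_ig <- function(build, outdir, overwrite = build$config$overwrite) {
  out <- NULL
  for (pkg in build$packages) {
    w <- emit_ig(pkg, outdir, build$config, overwrite = overwrite)
    w$path <- file.path(pkg$guide_id, w$path)
    out <- rbind(out, w)
  }
  invisible(out)
}

#' Validate all documents of an in-memory build
#'
#' Emits every StructureDefinition / ValueSet / CodeSystem of the build (in
#' memory, no files) and runs structural validation on each.
#'
#' @param build an `ig_build`.
#' @return issues data.frame (zero rows when clean).
#' @export
validate_build <- function(build) {
  cfg <- build$config
  ext_urls <- unlist(lapply(build$profiles, function(p) {
    vapply(p$extensions, `[[`, "", "url")
  }))
  out <- no_issues()
  out$doc <- character(0)
  for (p in build$profiles) {
    iss <- validate_structuredef(emit_structure_definition(p, cfg),
                                 extensions = ext_urls)
    if (nrow(iss)) { iss$doc <- p$id; out <- rbind(out, iss) }
    for (ext in p$extensions) {
      iss <- validate_structuredef(emit_extension_definition(ext, cfg))
      if (nrow(iss)) { iss$doc <- ext$id; out <- rbind(out, iss) }
    }
  }
  for (vs in build$value_sets) {
    iss <- validate_conformance_resource(emit_value_set(vs, cfg))
    if (nrow(iss)) { iss$doc <- vs$id; out <- rbind(out, iss) }
  }
  for (cs in build$code_systems) {
    iss <- validate_conformance_resource(emit_code_system(cs, cfg))
    if (nrow(iss)) { iss$doc <- cs$id; out <- rbind(out, iss) }
  }
  out
}
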