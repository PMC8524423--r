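# Conformance generation: StructureDefinition differentials, ValueSet and
# CodeSystem resources built from remodeled dictionary entries grouped by
# target profile id.
#
# Answer value sets are registered once by content (the sorted system|code
# multiset) and referenced by every entry that shares them, so the same
# answer list never yields two ValueSet resources. Un-coded options are
# assigned deterministic local codes in a generated CodeSystem.

#' Parse a "FHIR Resource" cell into (resource type, element path) pairs
#'
#' Cells name the target resource type and dotted path(s) to its elements,
#' e.g. `"AllergyIntolerance.code"`; several comma- or semicolon-separated
#' paths may appear and a bare resource type means a profile-level mapping
#' with no element constraint. The resource type is validated against the
#' supported list.
#'
#' @param text cell text, non-empty.
#' @return data.frame with columns `resource_type`, `element_path` (possibly
#'   ""), one row per path.
#' @export
#' @examples
#' parse_fhir_path("AllergyIntolerance.code")
parse_fhir_path <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    dak_abort("empty FHIR resource path", "dak_path_error")
  }
  parts <- trimws(strsplit(text, "[,;]")[[1L]])
  parts <- parts[nzchar(parts)]
  out <- data.frame(resource_type = character(0), element_path = character(0),
                    stringsAsFactors = FALSE)
  for (p in parts) {
    segs <- strsplit(p, ".", fixed = TRUE)[[1L]]
    rt <- segs[1L]
    if (!rt %in% supported_resources()) {
      dak_abort(sprintf("unsupported FHIR resource type: '%s'", rt),
                "dak_path_error", resource_type = rt)
    }
    out <- rbind(out, data.frame(resource_type = rt,
                                 element_path = paste(segs[-1L], collapse = "."),
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Parse an "Additional FHIR Attributes" fixation
#'
#' One fixation per cell segment, written `"Path.to.element = value"` with
#' exactly one `=`, e.g. `"AllergyIntolerance.category = medication"`.
#'
#' @param text fixation text.
#' @return list with `path` (full dotted path) and `value` (token).
#' @export
parse_fixed_attribute <- function(text) {
  parts <- strsplit(text, "=", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !nzchar(trimws(parts[1L])) || !nzchar(trimws(parts[2L]))) {
    dak_abort(sprintf("fixed attribute must contain exactly one '=': '%s'", text),
              "dak_attr_error", text = text)
  }
  list(path = trimws(parts[1L]), value = trimws(parts[2L]))
}

# --- registries (per compile run) -------------------------------------------

new_vs_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$by_hash <- list()   # content hash -> ValueSetDefinition
  e$refs <- list()      # vs id -> character vector of referencing profile ids
  e
}

new_cs_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$systems <- list()   # url -> list(name, id, url, concepts data.frame)
  e
}

register_local_code <- function(cs_reg, url, name, code, display) {
  cs <- cs_reg$systems[[url]]
  if (is.null(cs)) {
    cs <- list(name = name, id = slugify(name), url = url,
               concepts = data.frame(code = character(0), display = character(0),
                                     stringsAsFactors = FALSE))
  }
  if (!code %in% cs$concepts$code) {
    cs$concepts <- rbind(cs$concepts,
                         data.frame(code = code, display = display,
                                    stringsAsFactors = FALSE))
  }
  cs_reg$systems[[url]] <- cs
  invisible(code)
}

content_hash <- function(codings) {
  paste(sort(paste(codings$system, codings$code, sep = "|")), collapse = ";")
}

#' Build (or reuse) a value set from codings or dictionary entries
#'
#' Registers value sets by content: two calls whose code multisets are equal
#' return the same `ValueSetDefinition` and grow the registry by one, not
#' two, so shared answer lists are specified once and referenced everywhere.
#' Duplicate (system, code) pairs are dropped, order otherwise preserved.
#'
#' @param x a data.frame of codings (columns system/code/display) or of
#'   dictionary entries whose options/codes should be resolved first.
#' @param name display name used if a new value set must be created.
#' @param registry a value-set registry (environment) from a compile run;
#'   a fresh one is created when omitted.
#' @param config a [ig_config()].
#' @param cs_registry code-system registry environment for local codes.
#' @return a `ValueSetDefinition`: list(name, id, canonical_url, codings,
#'   content_hash).
#' @export
build_value_set <- function(x, name, registry = new_vs_registry(),
                            config = ig_config(), cs_registry = new_cs_registry()) {
  codings <- if (all(c("system", "code") %in% names(x))) x
  else {
    do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
      entry_codings(x[i, , drop = FALSE], config, cs_registry, vs_name = name)
    }))
  }
  if (is.null(codings) || nrow(codings) == 0L) {
    dak_abort(sprintf("value set '%s' has no resolvable codings", name),
              "dak_valueset_error", name = name)
  }
  codings <- codings[!duplicated(paste(codings$system, codings$code)), , drop = FALSE]
  rownames(codings) <- NULL
  h <- content_hash(codings)
  existing <- registry$by_hash[[h]]
  if (!is.null(existing)) return(existing)
  id <- slugify(name)
  taken <- vapply(registry$by_hash, `[[`, "", "id")
  k <- 1L
  while (id %in% taken) {  # same display name, different content
    k <- k + 1L
    id <- paste0(slugify(name), "-", k)
  }
  vs <- structure(list(
    name = name,
    id = id,
    canonical_url = paste0(config$canonical_base, "/ValueSet/", id),
    codings = codings,
    content_hash = h
  ), class = "ValueSetDefinition")
  registry$by_hash[[h]] <- vs
  vs
}

# Standard yes/no concept codes used when a boolean answer set must become a
# coded value set (SNOMED CT qualifier values).
yes_no_codings <- function() {
  rbind(coding("http://snomed.info/sct", "373066001", "Yes"),
        coding("http://snomed.info/sct", "373067005", "No"))
}

# Resolve one entry's answer concepts to codings. Resolution order per
# option: inline "(System: code)" annotation; then the entry's FHIR code
# system (option label slugified as the code); then a generated local code.
entry_codings <- function(e, config, cs_registry, vs_name = NULL) {
  opts <- split_multi(e$answer_options)
  if (!length(opts) && identical(e$answer_type, "boolean")) return(yes_no_codings())
  if (!length(opts)) {
    parsed <- parse_code_text(e$semantic_code_text, config$registry)$codings
    if (nrow(parsed)) return(parsed)
    if (!blank(e$fhir_code)) return(coding(e$fhir_code_system, e$fhir_code, e$label))
    return(empty_codings())
  }
  vs_name <- vs_name %||% paste(e$label, "Values")
  local_url <- paste0(config$canonical_base, "/CodeSystem/", slugify(vs_name))
  out <- empty_codings()
  rx <- "^(.*?)\\s*\\(([^:()]+)\\s*:\\s*([^() ]+)\\)$"
  for (opt in opts) {
    m <- regmatches(opt, regexec(rx, opt))[[1L]]
    if (length(m)) {
      uri <- resolve_system(m[3L], config$registry)
      out <- rbind(out, coding(uri, normalize_code(uri, m[4L]), m[2L]))
    } else if (!blank(e$fhir_code_system)) {
      out <- rbind(out, coding(e$fhir_code_system, slugify(opt), opt))
    } else {
      code <- slugify(opt)
      register_local_code(cs_registry, local_url, vs_name, code, opt)
      out <- rbind(out, coding(local_url, code, opt))
    }
  }
  out
}

# The question's own code: the FHIR code takes precedence over semantic
# codes for structural fixation; semantic codes then populate value sets.
question_coding <- function(e, config) {
  if (!blank(e$fhir_code)) return(coding(e$fhir_code_system, e$fhir_code, e$label))
  parsed <- parse_code_text(e$semantic_code_text, config$registry)$codings
  if (nrow(parsed)) return(parsed[1L, , drop = FALSE])
  NULL
}

# --- profile building -------------------------------------------------------

new_constraint <- function(path, min = NULL) {
  list(path = path, min = min, max = NULL, type = NULL, fixed = NULL,
       binding = NULL, must_support = TRUE)
}

merge_constraint <- function(a, b, profile, path) {
  conflict <- function(field, eq = identical) {
    !is.null(a[[field]]) && !is.null(b[[field]]) && !eq(a[[field]], b[[field]])
  }
  if (conflict("fixed") || conflict("binding") || conflict("type")) {
    dak_abort(sprintf(
      "profile '%s': conflicting constraints on path '%s'", profile, path),
      "dak_grouping_error", profile = profile, path = path)
  }
  for (f in c("min", "max", "type", "fixed", "binding")) {
    if (is.null(a[[f]])) a[[f]] <- b[[f]]
  }
  if (!is.null(a$fixed) && !is.null(a$binding)) {
    dak_abort(sprintf(
      "profile '%s': path '%s' would carry both a fixed value and a binding",
      profile, path), "dak_grouping_error", profile = profile, path = path)
  }
  a
}

#' Build a profile from the dictionary entries sharing a target profile id
#'
#' One element constraint per mapped path; fixed attributes appended;
#' value-set bindings attached at the entry's strength (default required);
#' question codes fixed on the code element; constraints sorted by path so
#' regeneration is deterministic. All entries in a group must map the same
#' resource type.
#'
#' @param group data.frame of remodeled entries (see [remodel_dictionary()])
#'   sharing one `target_profile_id`.
#' @param config a [ig_config()].
#' @param vs_registry,cs_registry per-run registries (fresh ones by default,
#'   for standalone use).
#' @return a `ProfileDefinition`: list(name, id, resource_type, base,
#'   constraints, program, value_set_ids, extensions), with per-constraint
#'   entry provenance in attribute `"provenance"`.
#' @export
build_profile <- function(group, config = ig_config(),
                          vs_registry = new_vs_registry(),
                          cs_registry = new_cs_registry()) {
  stopifnot(nrow(group) > 0L)
  name <- group$target_profile_id[1L]
  paths <- lapply(seq_len(nrow(group)), function(i) parse_fhir_path(group$fhir_resource_path[i]))
  rts <- unique(unlist(lapply(paths, `[[`, "resource_type")))
  if (length(rts) != 1L) {
    dak_abort(sprintf(
      "profile '%s' mixes resource types (%s) across entries: %s",
      name, paste(rts, collapse = ", "),
      paste(group$element_id, collapse = ", ")),
      "dak_grouping_error", profile = name, entries = group$element_id)
  }
  rt <- rts
  constraints <- list()
  provenance <- list()
  extensions <- list()
  vs_ids <- character(0)

  add <- function(path, patch, eid) {
    res <- resolve_element(rt, path)
    base_min <- if (is.null(res)) 0L else res$meta$min
    mn <- max(config$min_card, base_min)  # never widen below the base minimum
    c0 <- constraints[[path]] %||% new_constraint(path, min = mn)
    cn <- new_constraint(path, min = mn)
    for (f in names(patch)) cn[[f]] <- patch[[f]]
    constraints[[path]] <<- merge_constraint(c0, cn, name, path)
    provenance[[path]] <<- unique(c(provenance[[path]], eid))
  }

  for (i in seq_len(nrow(group))) {
    e <- group[i, , drop = FALSE]
    eid <- e$element_id
    for (j in seq_len(nrow(paths[[i]]))) {
      rel <- paths[[i]]$element_path[j]
      if (!nzchar(rel)) next  # profile-level mapping only
      res <- resolve_element(rt, rel)
      if (is.null(res)) {
        ext <- make_extension(rt, rel, e, config)
        extensions[[ext$id]] <- ext
        add("extension", list(type = list(list(code = "Extension",
                                               profile = ext$url))), eid)
        next
      }
      add(res$path, list(), eid)
    }

    bind_rel <- if (!is.null(e$bind_path) && nzchar(e$bind_path)) e$bind_path
    else if (nrow(paths[[i]]) && nzchar(paths[[i]]$element_path[1L])) paths[[i]]$element_path[1L]
    else ""

    # value-set binding: explicit canonical URL, explicit local name, or a
    # value set generated from the entry's answer concepts
    vs_url <- NULL
    if (!blank(e$value_set_binding)) {
      vsb <- trimws(e$value_set_binding)
      if (grepl("^https?://", vsb)) {
        vs_url <- vsb
      } else {
        vs <- build_value_set(e, vsb, vs_registry, config, cs_registry)
        vs_url <- vs$canonical_url
        vs_ids <- c(vs_ids, vs$id)
      }
    } else {
      needs_vs <- e$remodel_pattern %in% names(concept_set_patterns) ||
        (identical(e$remodel_pattern, "coded_observation")) ||
        nzchar(e$answer_options) ||
        (identical(e$answer_type, "boolean") && nzchar(bind_rel))
      if (needs_vs && nzchar(bind_rel)) {
        bres <- resolve_element(rt, bind_rel)
        if (!is.null(bres) && is_bindable(bres$meta)) {
          codings <- entry_codings(e, config, cs_registry)
          vs_name <- if (identical(e$answer_type, "boolean") &&
                         !nzchar(e$answer_options)) "Yes No Values"
          else paste(e$label, "Values")
          if (nrow(codings)) {
            vs <- build_value_set(codings, vs_name,
                                  vs_registry, config, cs_registry)
            vs_url <- vs$canonical_url
            vs_ids <- c(vs_ids, vs$id)
          }
        }
      }
    }
    if (!is.null(vs_url) && nzchar(bind_rel)) {
      bres <- resolve_element(rt, bind_rel)
      if (!is.null(bres)) {
        add(bres$path, list(binding = list(url = vs_url,
                                           strength = e$binding_strength)), eid)
      }
    }

    # fix the question's own code on the code element (coded observations)
    if (!is.null(e$code_path) && nzchar(e$code_path)) {
      qc <- question_coding(e, config)
      if (!is.null(qc)) {
        cres <- resolve_element(rt, e$code_path)
        if (!is.null(cres)) {
          add(cres$path, list(fixed = list(system = qc$system, code = qc$code,
                                           display = qc$display)), eid)
        }
      }
    }

    # datatype narrowing on the value element
    if (!is.null(e$value_type) && nzchar(e$value_type)) {
      vres <- resolve_element(rt, "value")
      if (!is.null(vres)) {
        add(vres$path, list(type = list(list(code = e$value_type))), eid)
      }
    }

    # additional fixed attributes ("AllergyIntolerance.category = medication")
    for (attr_text in split_multi(e$additional_fhir_attributes)) {
      fx <- parse_fixed_attribute(attr_text)
      fp <- parse_fhir_path(fx$path)
      if (fp$resource_type[1L] != rt) {
        dak_abort(sprintf(
          "profile '%s': fixed attribute '%s' targets %s, not %s",
          name, attr_text, fp$resource_type[1L], rt),
          "dak_grouping_error", profile = name)
      }
      fres <- resolve_element(rt, fp$element_path[1L])
      if (is.null(fres)) {
        dak_abort(sprintf(
          "profile '%s': fixed attribute path '%s' not in the %s base definition",
          name, fx$path, rt), "dak_path_error", profile = name)
      }
      add(fres$path, list(fixed = list(value = fx$value)), eid)
    }
  }

  if (length(constraints)) constraints <- constraints[order(names(constraints))]
  programs <- unique(group$program)
  program <- if ("core" %in% programs || all(c("fp", "sti") %in% programs)) "core"
  else programs[1L]

  structure(list(
    name = name,
    id = slugify(name),
    resource_type = rt,
    base = base_canonical(rt),
    constraints = constraints,
    program = program,
    value_set_ids = unique(vs_ids),
    extensions = extensions
  ), class = "ProfileDefinition", provenance = provenance)
}

make_extension <- function(rt, rel, e, config) {
  id <- slugify(paste(e$target_profile_id, rel))
  list(
    id = id,
    url = paste0(config$canonical_base, "/StructureDefinition/", id),
    context = rt,
    name = paste(e$target_profile_id, rel),
    value_types = switch(e$answer_type,
                         boolean = "boolean", quantity = "Quantity",
                         date = "date", datetime = "dateTime",
                         choice = "CodeableConcept",
                         `multi-choice` = "CodeableConcept",
                         "string")
  )
}

#' @export
print.ProfileDefinition <- function(x, ...) {
  cat(sprintf("<ProfileDefinition> %s [%s, %s]: %d constraint(s)\n",
              x$name, x$resource_type, x$program, length(x$constraints)))
  invisible(x)
}

# --- emission ---------------------------------------------------------------

computable_name <- function(x) gsub("[^A-Za-z0-9]", "", totitle(x))

fixed_element_fields <- function(fixed, base_types, style) {
  key_for <- function(ty) paste0(style, totitle(ty))
  if (!is.null(fixed$system)) {
    cod <- list(system = fixed$system, code = fixed$code)
    if ("CodeableConcept" %in% base_types) {
      return(stats::setNames(list(list(coding = list(cod))),
                             key_for("CodeableConcept")))
    }
    if ("Coding" %in% base_types) return(stats::setNames(list(cod), key_for("Coding")))
    return(stats::setNames(list(fixed$code), key_for(base_types[1L])))
  }
  v <- fixed$value
  if ("CodeableConcept" %in% base_types) {
    return(stats::setNames(list(list(text = v)), key_for("CodeableConcept")))
  }
  ty <- intersect(c("code", "string", "uri", "boolean"), base_types)
  ty <- if (length(ty)) ty[1L] else base_types[1L]
  if (ty == "boolean") v <- identical(tolower(v), "true")
  stats::setNames(list(v), key_for(ty))
}

#' Emit a profile as a FHIR R4 StructureDefinition document
#'
#' Produces a constraint-derivation differential on the base resource:
#' `kind = "resource"`, `derivation = "constraint"`, `fhirVersion = "4.0.1"`,
#' element ids path-based, canonical url under the configured base. Output is
#' byte-stable across runs for equal inputs (no timestamps).
#'
#' @param p a `ProfileDefinition`.
#' @param config a [ig_config()].
#' @return an R list ready for JSON serialisation.
#' @export
emit_structure_definition <- function(p, config = ig_config()) {
  root <- list(id = p$resource_type, path = p$resource_type)
  els <- list(root)
  for (c0 in p$constraints) {
    full <- paste(p$resource_type, c0$path, sep = ".")
    e <- list(id = full, path = full)
    if (!is.null(c0$min)) e$min <- c0$min
    if (!is.null(c0$max)) e$max <- c0$max
    e$mustSupport <- isTRUE(c0$must_support)
    if (!is.null(c0$type)) e$type <- c0$type
    if (!is.null(c0$fixed)) {
      res <- resolve_element(p$resource_type, c0$path)
      base_types <- if (is.null(res)) "string" else unlist(res$meta$types)
      e <- c(e, fixed_element_fields(c0$fixed, base_types, config$fixed_style))
    }
    if (!is.null(c0$binding)) {
      e$binding <- list(strength = c0$binding$strength,
                        valueSet = c0$binding$url)
    }
    els[[length(els) + 1L]] <- e
  }
  list(
    resourceType = "StructureDefinition",
    id = p$id,
    url = paste0(config$canonical_base, "/StructureDefinition/", p$id),
    version = config$ig_version,
    name = computable_name(p$name),
    title = p$name,
    status = "draft",
    publisher = config$publisher,
    fhirVersion = "4.0.1",
    kind = "resource",
    abstract = FALSE,
    type = p$resource_type,
    baseDefinition = p$base,
    derivation = "constraint",
    differential = list(element = els)
  )
}

#' Emit a simple single-value extension StructureDefinition
#'
#' Generated only when a dictionary entry's path is absent from the base
#' resource's element table.
#'
#' @param ext extension record produced during [build_profile()].
#' @param config a [ig_config()].
#' @return an R list ready for JSON serialisation.
#' @export
emit_extension_definition <- function(ext, config = ig_config()) {
  vt <- ext$value_types
  list(
    resourceType = "StructureDefinition",
    id = ext$id,
    url = ext$url,
    version = config$ig_version,
    name = computable_name(ext$name),
    title = ext$name,
    status = "draft",
    publisher = config$publisher,
    fhirVersion = "4.0.1",
    kind = "complex-type",
    abstract = FALSE,
    context = list(list(type = "element", expression = ext$context)),
    type = "Extension",
    baseDefinition = "http://hl7.org/fhir/StructureDefinition/Extension",
    derivation = "constraint",
    differential = list(element = list(
      list(id = "Extension", path = "Extension", min = 0L, max = "1"),
      list(id = "Extension.url", path = "Extension.url", fixedUri = ext$url),
      list(id = "Extension.value[x]", path = "Extension.value[x]",
           type = list(list(code = vt)))
    ))
  )
}

#' Emit a ValueSetDefinition as a FHIR R4 ValueSet document
#'
#' Codings are grouped by system under `compose.include`, systems in sorted
#' order, codes in original order within a system.
#'
#' @param vs a `ValueSetDefinition` from [build_value_set()].
#' @param config a [ig_config()].
#' @return an R list ready for JSON serialisation.
#' @export
emit_value_set <- function(vs, config = ig_config()) {
  include <- lapply(sort(unique(vs$codings$system)), function(sys) {
    rows <- vs$codings[vs$codings$system == sys, , drop = FALSE]
    list(system = sys, concept = lapply(seq_len(nrow(rows)), function(i) {
      cpt <- list(code = rows$code[i])
      if (!is.na(rows$display[i])) cpt$display <- rows$display[i]
      cpt
    }))
  })
  list(
    resourceType = "ValueSet",
    id = vs$id,
    url = vs$canonical_url,
    version = config$ig_version,
    name = computable_name(vs$name),
    title = vs$name,
    status = "draft",
    publisher = config$publisher,
    compose = list(include = include)
  )
}

#' Emit a generated local CodeSystem document
#'
#' @param cs a code-system record from the per-run registry.
#' @param config a [ig_config()].
#' @return an R list ready for JSON serialisation.
#' @export
emit_code_system <- function(cs, config = ig_config()) {
  list(
    resourceType = "CodeSystem",
    id = cs$id,
    url = cs$url,
    version = config$ig_version,
    name = computable_name(cs$name),
    title = cs$name,
    status = "draft",
    publisher = config$publisher,
    caseSensitive = TRUE,
    content = "complete",
    concept = lapply(seq_len(nrow(cs$concepts)), function(i) {
      list(code = cs$concepts$code[i], display = cs$concepts$display[i])
    })
  )
}
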