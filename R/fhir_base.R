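# Base-resource metadata and offline structural validation.
#
# The compiler only targets the nineteen FHIR 4.0.1 resource types that the
# WHO family-planning / STI minimum data set needed. Their element tables
# (path -> types, min, max) are vendored as JSON inside the package
# (inst/extdata/fhir-r4-base.json; regenerated by tools/make-base-meta.R),
# so generation and validation never touch the network. This is not a general
# FHIR validator: no slicing, no terminology expansion, differentials only.

.dak_cache <- new.env(parent = emptyenv())

# Elements every DomainResource inherits; injected at load time.
domain_resource_elements <- function() {
  list(
    id = list(types = list("id"), min = 0L, max = "1"),
    meta = list(types = list("Meta"), min = 0L, max = "1"),
    implicitRules = list(types = list("uri"), min = 0L, max = "1"),
    language = list(types = list("code"), min = 0L, max = "1"),
    text = list(types = list("Narrative"), min = 0L, max = "1"),
    contained = list(types = list("Resource"), min = 0L, max = "*"),
    extension = list(types = list("Extension"), min = 0L, max = "*"),
    modifierExtension = list(types = list("Extension"), min = 0L, max = "*")
  )
}

base_meta <- function() {
  if (is.null(.dak_cache$base)) {
    path <- system.file("extdata", "fhir-r4-base.json", package = "dak2fhir")
    meta <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    common <- domain_resource_elements()
    for (ty in names(meta$resources)) {
      meta$resources[[ty]]$elements <- c(common, meta$resources[[ty]]$elements)
    }
    .dak_cache$base <- meta
  }
  .dak_cache$base
}

#' Resource types supported by the compiler
#'
#' The nineteen FHIR 4.0.1 resource types that were sufficient to model every
#' element of the family-planning and STI data dictionaries; any dictionary
#' row naming a type outside this list is rejected with a structured error.
#'
#' @return sorted character vector of resource-type names.
#' @export
#' @examples
#' supported_resources()
supported_resources <- function() {
  sort(names(base_meta()$resources))
}

#' Base canonical URL of a resource type
#' @param resource_type supported resource-type name.
#' @return canonical URL string.
#' @export
base_canonical <- function(resource_type) {
  r <- base_meta()$resources[[resource_type]]
  if (is.null(r)) {
    dak_abort(sprintf("unsupported FHIR resource type: '%s'", resource_type),
              "dak_path_error", resource_type = resource_type)
  }
  r$canonical
}

# Resolve a dotted element path (without the resource-type head) against the
# base table. Returns list(path = canonical relative path, meta = element
# entry) or NULL. Handles choice elements: "value" and "valueQuantity" both
# resolve to "value[x]" (the latter additionally checks the narrowed type).
resolve_element <- function(resource_type, path) {
  r <- base_meta()$resources[[resource_type]]
  if (is.null(r)) return(NULL)
  els <- r$elements
  if (!nzchar(path)) return(NULL)
  if (!is.null(els[[path]])) return(list(path = path, meta = els[[path]]))
  cand <- paste0(path, "[x]")
  if (!is.null(els[[cand]])) return(list(path = cand, meta = els[[cand]]))
  # typed choice variant, e.g. valueQuantity -> value[x] with type Quantity
  segs <- strsplit(path, ".", fixed = TRUE)[[1L]]
  leaf <- segs[length(segs)]
  prefix <- if (length(segs) > 1L) paste0(paste(segs[-length(segs)], collapse = "."), ".") else ""
  for (nm in names(els)) {
    if (!endsWith(nm, "[x]") || !startsWith(nm, prefix)) next
    stem <- substr(nm, nchar(prefix) + 1L, nchar(nm) - 3L)
    if (startsWith(leaf, stem) && nchar(leaf) > nchar(stem)) {
      ty <- substr(leaf, nchar(stem) + 1L, nchar(leaf))
      types <- unlist(els[[nm]]$types)
      if (tolower(ty) %in% tolower(c(types, vapply(types, totitle, "")))) {
        return(list(path = nm, meta = els[[nm]]))
      }
    }
  }
  NULL
}

totitle <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

# An element is bindable when one of its base types is coded.
is_bindable <- function(meta) {
  any(unlist(meta$types) %in% c("code", "Coding", "CodeableConcept", "Quantity"))
}

sd_issue <- function(severity, code, message) {
  data.frame(severity = severity, code = code, message = message,
             stringsAsFactors = FALSE)
}

no_issues <- function() {
  data.frame(severity = character(0), code = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

max_card_num <- function(x) if (identical(x, "*")) Inf else suppressWarnings(as.numeric(x))

#' Structurally validate a StructureDefinition document
#'
#' Checks an emitted (or externally supplied) StructureDefinition differential
#' against the vendored base-resource metadata: mandatory fields present;
#' known base resource type; every differential path exists in the base
#' element table (unless declared as a generated extension); cardinalities
#' stay within the base bounds; bindings only on coded elements; an element
#' never carries both a fixed/pattern value and a binding. Severities:
#' unknown paths and cardinality violations are errors, stylistic findings
#' are warnings.
#'
#' @param doc an R list (parsed JSON) or a JSON string / file path.
#' @param extensions character vector of canonical URLs of generated
#'   extensions whose paths are exempt from the base-path check.
#' @return data.frame of issues with columns `severity`, `code`, `message`;
#'   zero rows when clean.
#' @export
validate_structuredef <- function(doc, extensions = character(0)) {
  doc <- parse_resource_doc(doc)
  issues <- no_issues()
  req <- c("resourceType", "url", "name", "status", "kind", "abstract",
           "type", "baseDefinition", "derivation", "fhirVersion")
  for (f in req) {
    if (is.null(doc[[f]])) {
      issues <- rbind(issues, sd_issue("error", "missing-field",
                                       sprintf("missing mandatory field '%s'", f)))
    }
  }
  if (!is.null(doc$resourceType) && !identical(doc$resourceType, "StructureDefinition")) {
    issues <- rbind(issues, sd_issue("error", "wrong-resource",
                                     sprintf("resourceType is '%s', expected StructureDefinition",
                                             doc$resourceType)))
    return(issues)
  }
  ty <- doc$type
  if (is.null(ty)) return(issues)
  if (identical(ty, "Extension")) return(issues)  # generated extensions: shape-checked only
  r <- base_meta()$resources[[ty]]
  if (is.null(r)) {
    issues <- rbind(issues, sd_issue("error", "unknown-base",
                                     sprintf("unknown base resource type '%s'", ty)))
    return(issues)
  }
  if (!is.null(doc$baseDefinition) && !identical(doc$baseDefinition, r$canonical)) {
    issues <- rbind(issues, sd_issue("warning", "base-mismatch",
                                     sprintf("baseDefinition '%s' is not the canonical base '%s'",
                                             doc$baseDefinition, r$canonical)))
  }
  if (!is.null(doc$fhirVersion) && !identical(doc$fhirVersion, "4.0.1")) {
    issues <- rbind(issues, sd_issue("error", "fhir-version",
                                     sprintf("fhirVersion '%s', expected 4.0.1", doc$fhirVersion)))
  }
  if (!is.null(doc$derivation) && !identical(doc$derivation, "constraint")) {
    issues <- rbind(issues, sd_issue("error", "derivation",
                                     "derivation must be 'constraint' for a profile differential"))
  }
  els <- doc$differential$element
  if (is.null(els) || !length(els)) {
    issues <- rbind(issues, sd_issue("error", "empty-differential",
                                     "differential has no elements"))
    return(issues)
  }
  for (e in els) {
    p <- e$path
    if (is.null(p)) {
      issues <- rbind(issues, sd_issue("error", "element-no-path",
                                       "differential element without a path"))
      next
    }
    if (identical(p, ty)) next  # root element
    if (!startsWith(p, paste0(ty, "."))) {
      issues <- rbind(issues, sd_issue("error", "path-head",
                                       sprintf("path '%s' does not start with '%s.'", p, ty)))
      next
    }
    rel <- substr(p, nchar(ty) + 2L, nchar(p))
    res <- resolve_element(ty, rel)
    if (is.null(res)) {
      if (is_extension_path(rel, e, extensions)) next
      issues <- rbind(issues, sd_issue("error", "unknown-path",
                                       sprintf("path '%s' not found in the %s base definition", p, ty)))
      next
    }
    bmin <- res$meta$min
    bmax <- max_card_num(res$meta$max)
    if (!is.null(e$min) && (e$min < bmin || e$min > bmax)) {
      issues <- rbind(issues, sd_issue("error", "min-cardinality",
                                       sprintf("path '%s': min %s outside base bounds [%s..%s]",
                                               p, e$min, bmin, res$meta$max)))
    }
    if (!is.null(e$max)) {
      emax <- max_card_num(e$max)
      if (is.na(emax) || emax > bmax) {
        issues <- rbind(issues, sd_issue("error", "max-cardinality",
                                         sprintf("path '%s': max %s exceeds base max %s",
                                                 p, e$max, res$meta$max)))
      } else if (!is.null(e$min) && !is.na(emax) && e$min > emax) {
        issues <- rbind(issues, sd_issue("error", "card-order",
                                         sprintf("path '%s': min %s > max %s", p, e$min, e$max)))
      }
    }
    if (!is.null(e$type)) {
      narrowed <- vapply(e$type, function(t) t$code %||% "", "")
      bad <- setdiff(narrowed, unlist(res$meta$types))
      if (length(bad) && !identical(unlist(res$meta$types), "Extension")) {
        issues <- rbind(issues, sd_issue("error", "type-narrowing",
                                         sprintf("path '%s': type(s) %s not permitted by base",
                                                 p, paste(bad, collapse = ", "))))
      }
    }
    fixed_keys <- grep("^(fixed|pattern)", names(e), value = TRUE)
    if (!is.null(e$binding)) {
      if (!is_bindable(res$meta)) {
        issues <- rbind(issues, sd_issue("error", "binding-not-coded",
                                         sprintf("path '%s' is not a bindable (coded) element", p)))
      }
      if (is.null(e$binding$strength) ||
          !e$binding$strength %in% BINDING_STRENGTHS) {
        issues <- rbind(issues, sd_issue("error", "binding-strength",
                                         sprintf("path '%s': missing or invalid binding strength", p)))
      }
      if (length(fixed_keys)) {
        issues <- rbind(issues, sd_issue("error", "fixed-and-binding",
                                         sprintf("path '%s' carries both a fixed/pattern value and a binding", p)))
      }
    }
  }
  issues
}

is_extension_path <- function(rel, element, extensions) {
  if (!grepl("(^|\\.)extension$", rel)) return(FALSE)
  if (!length(extensions)) return(FALSE)
  profs <- unlist(lapply(element$type, function(t) unlist(t$profile)))
  length(profs) > 0L && all(profs %in% extensions)
}

parse_resource_doc <- function(doc) {
  if (is.character(doc) && length(doc) == 1L) {
    parsed <- tryCatch({
      if (file.exists(doc)) jsonlite::fromJSON(doc, simplifyVector = FALSE)
      else jsonlite::fromJSON(doc, simplifyVector = FALSE)
    }, error = function(e) NULL)
    if (is.null(parsed)) {
      dak_abort("document does not parse as JSON", "dak_parse_error")
    }
    doc <- parsed
  }
  if (!is.list(doc)) dak_abort("document is not a JSON object", "dak_parse_error")
  doc
}

#' Minimal structural checks for ValueSet / CodeSystem / ImplementationGuide
#'
#' Used by the tree validator so every emitted resource file gets at least a
#' mandatory-field check; StructureDefinitions go through the full
#' [validate_structuredef()].
#'
#' @param doc parsed resource document (list, JSON string or path).
#' @return issues data.frame as in [validate_structuredef()].
#' @export
validate_conformance_resource <- function(doc) {
  doc <- parse_resource_doc(doc)
  rt <- doc$resourceType %||% ""
  req <- switch(rt,
    ValueSet = c("url", "name", "status", "compose"),
    CodeSystem = c("url", "name", "status", "content"),
    ImplementationGuide = c("url", "name", "status", "packageId", "fhirVersion"),
    StructureDefinition = return(validate_structuredef(doc)),
    return(sd_issue("error", "unknown-resource",
                    sprintf("unexpected resourceType '%s'", rt)))
  )
  issues <- no_issues()
  for (f in req) {
    if (is.null(doc[[f]])) {
      issues <- rbind(issues, sd_issue("error", "missing-field",
                                       sprintf("%s: missing mandatory field '%s'", rt, f)))
    }
  }
  if (rt == "ValueSet") {
    inc <- doc$compose$include
    if (!length(inc)) {
      issues <- rbind(issues, sd_issue("error", "empty-valueset",
                                       "ValueSet compose has no include"))
    }
  }
  issues
}
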