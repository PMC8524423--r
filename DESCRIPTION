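Package: dak2fhir
Title: Compile WHO Digital Adaptation Kit Data Dictionaries into FHIR R4 Implementation Guides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tooling that turns a WHO Digital Adaptation Kit (DAK) style
    clinical data dictionary, annotated with FHIR resource paths and semantic
    terminology mappings (SNOMED CT, LOINC, ICD-10, RxNorm), into publishable
    FHIR R4 implementation-guide source artifacts: StructureDefinition
    differentials, ValueSet and CodeSystem resources, ImplementationGuide
    manifests and human-readable differential tables, factored into a shared
    Core guide plus per-programme guides (family planning, sexually
    transmitted infections). Includes consolidation of multi-sheet
    workflow-oriented dictionaries into a flat master dictionary with
    duplicate detection, remodeling of user-interface-oriented form questions
    into semantically oriented FHIR elements (with a lossless reverse
    transform), offline structural validation against vendored base-resource
    metadata for the nineteen FHIR 4.0.1 resource types in scope, and a
    command-line pipeline: consolidate, generate, validate, report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
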