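---
title: "From a DAK data dictionary to FHIR implementation guides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a DAK data dictionary to FHIR implementation guides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dak2fhir)
```

## The problem

WHO's Digital Adaptation Kits document a clinical guideline's operational
requirements, including a data dictionary of the minimum data set a
point-of-care system must capture. Those dictionaries are written the way a
clinician meets the data — as form questions with answer lists, repeated
across workflow sheets — while downstream systems need a formal information
model: FHIR resources, profiled element constraints, and value sets carrying
standard terminology codes (SNOMED CT, LOINC, ICD-10, RxNorm). `dak2fhir`
is a compiler between the two representations. Its inputs are rows of a flat
master dictionary annotated with mapping attributes; its outputs are the
source artifacts of three FHIR R4 implementation guides: a shared Core
guide and two program guides (family planning and sexually transmitted
infections), each a set of StructureDefinition differentials, ValueSets,
CodeSystems, an ImplementationGuide manifest, and human-readable
differential tables.

## The compile model and its assumptions

Compilation is a pure function of the dictionary and the run configuration.
The pipeline assumes:

* one row per data element, with a stable `element_id` (derived
  deterministically from program + label when absent);
* the `fhir_resource_path` column names one of the 19 supported FHIR 4.0.1
  resource types; anything else is a structured error, because the scope of
  the supported metadata is exactly those 19 types;
* terminology codes arrive as free text, one `"Label: code (maps to
  Display)"` segment per code, separated by newlines or semicolons. This
  grammar is a declared convention: it matches the way multi-code cells are
  printed in practice, while tolerating a missing display. Parsing is
  conservative — a malformed segment becomes a collected issue, never a
  silently dropped or guessed code.

Code-format validation is deliberately syntactic (per-system regular
expressions: all-digit SNOMED/RxNorm identifiers, `digits-hyphen-digit`
LOINC codes, `A12.3`-shaped ICD-10 codes). The package never consults a
terminology server, so it can verify that a code is well-formed but not that
it exists in a terminology release; code existence and clinical
appropriateness remain human responsibilities.

## Remodeling: UI model to semantic model, reversibly

The central transformation rewrites form-oriented entries into
resource-oriented ones. Rule selection is total and deterministic: an
explicit per-entry override wins, then the (resource type, answer type) rule
table, then `passthrough` with a logged notice. The default table encodes
one specific information-modeling stance among the defensible ones:

* **`condition_presence`** — a yes/no question mapped to `Condition` becomes
  presence semantics: the `code` element is bound (strength `required` by
  default) to a value set holding all of the concept's terminology codes.
  This is chosen over a boolean observation because it scales to any number
  of codes for the concept. The alternative modeling — an observation with
  one fixed code and a yes/no answer — is equally expressible by overriding
  the rule for an entry or by mapping the row to `Observation`; both stances
  are legitimate, which is exactly why the table is configuration rather
  than code.
* **`coded_observation`** — choice or boolean questions on `Observation` fix
  the question's own code on `Observation.code` (the explicit FHIR code
  takes precedence over semantic codes for fixation; semantic codes populate
  value sets) and bind the answer options on `Observation.value[x]`,
  narrowed to `CodeableConcept`. Boolean answers use the standard SNOMED CT
  yes/no qualifier concepts (373066001 / 373067005), because a semantic
  model needs codes, not the strings "yes"/"no".
* **`quantity_observation`** / **`date_observation`** narrow `value[x]` to
  `Quantity` / `dateTime` and fix the question code; no answer value set.
* **`medication_statement`** / **`procedure`** bind the resource's concept
  element (`medication[x]`, `code`) to the entry's code set.

Reversibility is a hard guarantee, tested property-style: the original
question label, answer type and options are carried on the remodeled entry
as metadata, so `revert_entry()` reproduces the UI projection exactly for
every pattern. Storing the UI fields was chosen over inverting the transform
analytically because it makes the guarantee unconditional — any future
pattern stays reversible by construction.

## Value sets, code systems and reuse

Value sets are registered by content: the registry key is the sorted
`system|code` multiset (also exposed as `content_hash`; since the key *is*
the canonical multiset string, equal hashes imply equal content by
construction, with no collision risk). Two entries sharing an answer list
therefore reference one ValueSet resource rather than duplicating it. When
distinct contents would slugify to the same id, a numeric suffix
disambiguates deterministically in build order. Options resolve to codings
in a fixed precedence: an inline `"(System: code)"` annotation on the
option, else the entry's FHIR code system with the slugified option label
as code, else a deterministic local code in a generated CodeSystem under
the guide's canonical base.

## Conformance generation choices

Several points are under-determined by any published convention; the
package's choices, all configurable where marked:

* **Cardinality**: constrained elements get `min = 0` and `mustSupport`
  (a minimum data set says "systems must be able to handle this", not
  "every instance must contain this"); `min_card = 1` switches to mandatory.
  The profile's `min` is never allowed below the base minimum.
* **Fixations** are emitted pattern-style (`patternCode`,
  `patternCodeableConcept`) rather than exact `fixed[x]`, because values
  such as `category = medication` discriminate a profile rather than
  exhaust the element; `fixed_style = "fixed"` switches to exact fixation.
* **Ids** are lowercase-hyphen slugs of the display names
  (`"WHO-Core Observation (HIV Status)"` →
  `who-core-observation-hiv-status`), since FHIR ids forbid the display
  form; the rule is a bijection on the bundled inventory, keeping names
  reconstructible.
* **Extensions** are generated only when an entry's path does not exist in
  the base resource's element table, as a simple single-value extension
  typed from the answer type.
* **Multiple paths** in one cell yield one constraint each, in one profile.
* Constraints are sorted by path and JSON is serialized with fixed options,
  making emission byte-stable; no timestamps are written.

## Guide partitioning

Profiles tagged `core` go to the Core guide; a profile referenced by entries
of both programs is promoted to Core automatically (the promotion rule is a
package convention — partitioning must be total, and the shared guide is
what both programs depend on). Each value set lands in the lowest common
package of its referencing profiles; generated code systems follow their
value sets. The emitted layout follows the de-facto IG-publisher input
convention (`input/resources`, `input/pagecontent`, an npm-style
`package.json`), but no publisher is run and no HTML is rendered.

## Offline validation

The validator checks emitted documents against element metadata for the 19
resource types vendored inside the package (regenerated by
`tools/make-base-meta.R`): mandatory StructureDefinition fields, known base
type, every differential path present in the base table (choice elements
resolve from both `value` and `valueQuantity` spellings), cardinality within
base bounds, bindings only on coded elements, and never a fixed value and a
binding on the same element. The tables cover all top-level elements of each
type plus the nested backbone paths profiles commonly constrain — full R4
snapshots are intentionally not shipped, so the validator is a structural
gate, not a general FHIR validator (no slicing, no terminology expansion,
no FHIRPath invariants).

## The bundled dictionary and the random generator

The bundled dictionary (`who_fp_sti_dictionary()`) carries the six published
worked mapping rows (amenorrhea with ICD-10 `N91.2` and SNOMED
`14,302,001`; number of pregnancies with LOINC `11996–6`; azithromycin with
RxNorm `18,631`; the drug-allergy profile with
`AllergyIntolerance.category = medication`; the administrative-gender FHIR
coding; the `communication-not-done-reason` binding) plus one row per
profile of the published three-guide inventory (46 Core, 29 FP, 30 STI).
Since element-level content behind the other profiles was never published,
those rows are synthesized minimally — one plausible element path per
resource type, deterministic syntactically-valid synthetic codes — and are
marked `"synthetic skeleton row"` in their notes. Compiling the bundle
therefore demonstrates name-level inventory reconstruction and structural
validity; it does not reconstruct the clinical content of the real
dictionaries, and passing tests say nothing about mapping correctness on
real WHO data.

`random_dictionary()` emulates the statistical shape of such dictionaries —
program mix, answer-type mix, per-option coding density, and a configurable
fraction of verbatim duplicate rows (as happens when workflow sheets repeat
a concept). It does not emulate messy real-world phenomena: free-text label
variants of the same concept, conflicting near-duplicate mappings,
multi-resource rows, or ill-formed code text beyond what the parser tests
construct directly.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run at desk scale: the 105-row
bundle, dictionaries of 8–100 rows, 50–100 random seeds for the validity
and fuzz properties. These sizes give each property hundreds of instances
while keeping a full run in tens of seconds; the pipeline itself is linear
in rows and has no tuning that depends on scale. Degenerate inputs are
contractual: empty dictionaries compile to empty guides, a bare resource
type (`"Observation"`) is a profile-level mapping with a root-only
differential, entries with blank paths pass through and surface as
uncovered in the completeness report, and every failure mode raised on the
way is a classed condition mapped to the CLI exit-code contract
(0 success, 1 validation failure, 2 input error).

## Known limitations

* Validation is structural and offline; code existence, display accuracy
  and clinical appropriateness are out of scope.
* No snapshot generation, no profile inheritance beyond the base resources,
  no slicing.
* Duplicate detection keys on normalized label + path + mapping; true
  synonyms with different labels are not detected (that judgement is the
  human review step the near-duplicate flags exist to support).
* The multi-sheet adapter reads one delimited file per sheet; native XLSX
  workbooks should be exported sheet-wise first.
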