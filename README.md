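# dak2fhir

`dak2fhir` compiles a WHO Digital Adaptation Kit (DAK) style clinical data
dictionary into the source artifacts of publishable FHIR R4 implementation
guides. It is written for health-informatics teams who take the semi-structured
"L2" operational layer of a clinical guideline — a data dictionary of core
data elements, organized the way questions appear on a care form — and need
the machine-readable "L3" layer: StructureDefinition profile differentials,
ValueSet and CodeSystem resources, ImplementationGuide manifests and
human-readable differential tables, regenerable at any time from the
dictionary.

## What it does

The input is a flat "master" dictionary (CSV/TSV, one row per data element)
whose mapping columns carry, per element: the target FHIR resource type and
element path(s) (`Observation.value`), additional fixed attributes
(`AllergyIntolerance.category = medication`), a target profile id
(`WHO-Core AllergyIntolerance (Drug Allergies)`), an optional value-set
binding with strength (default `required`), an optional FHIR code system and
code (`http://hl7.org/fhir/administrative-gender` / `female`), and free-text
semantic terminology codes in SNOMED CT, LOINC, ICD-10 and/or RxNorm
(`SNOMED: 14,302,001 (maps to Amenorrhea)`).

The pipeline:

1. **Consolidate** — multiple workflow-oriented sheets are unioned into one
   flat dictionary; rows that repeat a concept with identical mappings are
   merged, rows sharing a label but differing in mapping are flagged as
   near-duplicates for human review, never merged.
2. **Remodel** — user-interface-oriented questions are rewritten into a
   semantically oriented model by deterministic, configurable rules. A
   yes/no question mapped to `Condition` becomes a condition whose `code`
   element is bound to a value set that can hold any number of terminology
   codes for the concept; a coded question on `Observation` fixes the
   question's code on `Observation.code` and binds the answer options on
   `Observation.value[x]`. The original form view is retained as metadata,
   so every remodeled entry reverts exactly to its UI projection.
3. **Generate** — entries grouped by target profile id become
   StructureDefinition differentials (derivation `constraint`, FHIR 4.0.1)
   on the 19 supported base resource types. Answer value sets are registered
   once by code-multiset content and referenced by every element that shares
   them; un-coded options get deterministic local codes in a generated
   CodeSystem.
4. **Assemble** — profiles and value sets are partitioned into a shared
   Core guide plus per-program guides (family planning, STI); value sets
   used by both programs are promoted to Core, which both guides depend on.
5. **Validate & report** — every emitted document is checked offline against
   vendored base-resource element metadata (paths, cardinality bounds,
   bindable elements), and a completeness report confirms each dictionary
   concept is realized by a profile constraint.

Everything is deterministic: the same dictionary always yields a
byte-identical artifact tree.

## Worked example

```r
library(dak2fhir)

d <- who_fp_sti_dictionary()   # bundled FP/STI master dictionary
d
#> <data_dictionary> 105 entries from 1 sheet(s): bundled
#>   programs: core 46, fp 29, sti 30

b <- compile_dictionary(d)
b
#> <ig_build> 105 entries -> 105 profiles, 34 value sets, 14 code systems
#>   core  46 profile(s), 13 value set(s)
#>   fp    29 profile(s), 14 value set(s)
#>   sti   30 profile(s),  7 value set(s)
#>   coverage: 100.0%

write_ig(b, "igs")             # three IG source trees: igs/core, igs/fp, igs/sti

cat(render_differential_table(
  b$profiles[["who-core-allergyintolerance-drug-allergies"]]), sep = "\n")
#> ## WHO-Core AllergyIntolerance (Drug Allergies)
#>
#> Differential on base resource `AllergyIntolerance` (http://hl7.org/fhir/StructureDefinition/AllergyIntolerance).
#>
#> | Path | Card. | Type | Fixed | Binding |
#> |---|---|---|---|---|
#> | AllergyIntolerance.category | 0..* |  | medication |  |
#> | AllergyIntolerance.code | 0..1 |  |  |  |
```

The 105 entries compile into 46 Core, 29 FP and 30 STI profiles — one per
profile of the bundled inventory — with every concept covered. The
drug-allergy profile shows the two generated constraints: the mapped `code`
element and the fixed discriminator `category = medication`.

The same pipeline runs from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","dak2fhir.R",package="dak2fhir"))')" \
    generate master.csv --out igs/
```

Subcommands `consolidate`, `generate`, `validate` and `fixtures` follow the
exit-code contract 0 = success, 1 = validation failure, 2 = input error; a
YAML run config (`--config`) sets the canonical base URL, column dialect,
remodel rules and registry extensions.

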