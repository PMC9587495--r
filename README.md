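# healthfacts

Routine health statistics in many low-resource health systems are produced by
hand: paper consultation registers are tallied at the facility, the tallies
are re-aggregated at district, region and country level, and free-text
diagnoses are matched to standard codes subjectively. The result is data that
are incomplete, late and hard to verify against their source. `healthfacts`
implements the warehouse side of a digitised alternative for analysts and
health-information officers: identity-free digital replicas of consultation
registers flow through terminology mapping into a star-schema fact table
organised along the five-level health pyramid
(country → region → district → facility → service), where they can be rolled
up and drilled down, audited for quality, and compared between systems.

## What it computes

- **Terminology matching.** A local free-text term is scored against each
  dictionary entry (ICD-10/ICPC-2 diagnoses, ATC drugs, LOINC laboratory
  tests) with the token-set Dice coefficient on normalized tokens,
  `s(A, B) = 2|A ∩ B| / (|A| + |B|) ∈ [0, 1]`; an entry's score is the
  maximum over its preferred term and synonyms, and a mapping is accepted
  when `s ≥ t` (default threshold `t = 0.6`). Unmapped terms are kept and
  flagged, never dropped.
- **Fact table.** One row per clinical entry (plus one all-null row per
  entry-less consultation) in the wide retrieval layout: the four geography
  names, `num_examination`, the three code families, examination date,
  patient attributes, and local/standard concept pairs per family.
- **ROLAP measures.** For any grouping of dimensions:
  `consultation_count` (distinct consultations), `entry_count`, and
  `share = group consultations / total consultations in scope`. Drill-down
  re-aggregates at a finer geographic level with exact roll-up conservation.
- **Quality metrics.** Field completeness `100·filled/(records·fields)`;
  reporting completeness `100·|expected ∩ received|/|expected|`; timeliness
  (a monthly report is on time iff submitted by day 5 of the following
  month) with mean submission delay; accuracy as the share of consultations
  whose warehouse values conform to the source register.
- **Paired evaluation.** Yes/no questionnaire matrices (users × criteria,
  per system) are scored as pooled yes-fractions per criterion, per quality
  dimension and overall, and compared with the exact binomial McNemar test
  `p = min(1, 2·P(Bin(b+c, ½) ≥ max(b, c)))` on the discordant pairs; when
  only marginal yes-counts are known, `mcnemar_bound_from_marginals()`
  enumerates every feasible pairing and reports the worst-case p-value.

A seeded generator (`generate_dataset()`, `komo_mondah_fixture()`,
`evaluation_fixture()`) produces register files, pyramid definitions,
dictionary subsets, submission calendars and evaluation matrices with a
ground-truth manifest, so the whole pipeline is testable offline.

## Worked example

A district of 12 facilities with 6054 consultations, 2966 of them carrying
the malaria code B54:

```r
library(healthfacts)

ds   <- komo_mondah_fixture()
pyr  <- load_pyramid(ds$files[["pyramid"]])
reg  <- parse_register(ds$files[["register"]], pyr)
reg  <- attach_mappings(reg, list(load_dictionary(ds$files[["dictionary_icd10"]]),
                                  load_dictionary(ds$files[["dictionary_atc"]]),
                                  load_dictionary(ds$files[["dictionary_loinc"]])))
facts <- build_fact_table(reg, pyr)
cube  <- aggregate_facts(facts, c("health_district_name", "standard_concept_diagnosis"))
cube[cube$standard_concept_diagnosis == "Paludisme",
     c("standard_concept_diagnosis", "consultation_count", "share")]
#>   standard_concept_diagnosis consultation_count     share
#> 7                  Paludisme               2966 0.4899240
```

Malaria accounts for 2966 of 6054 consultations — a 49% share at district
level. Unlike a district tally, the warehouse can split it by facility:

```r
down <- drill_down(cube, facts, "facility")
sum(down$consultation_count[down$standard_concept_diagnosis == "Paludisme"])
#> [1] 2966
```

The per-facility counts sum back to the district total exactly (roll-up
conservation). Scoring the paired 14-user evaluation matrix:

```r
score_evaluation(evaluation_fixture()$matrix)
#> <evaluation_scores>
#>   new          accuracy      100% (28/28)
#>   new          completeness   93% (39/42)
#>   new          timeliness     96% (27/28)
#>   traditional  accuracy       18% (5/28)
#>   traditional  completeness   12% (5/42)
#>   traditional  timeliness     18% (5/28)

mcnemar_bound_from_marginals(39, 5, 42)
#> <mcnemar_bound> max exact p = 1.947e-08 over 4 feasible pairing(s)
```

Whatever the true pairing of the 42 completeness responses, the exact
McNemar p-value is below 2×10⁻⁸ — the difference between the systems is
significant at any conventional level.

A thin command-line front end lives at `inst/cli/healthfacts.R`
(subcommands `simulate`, `ingest`, `map-terms`, `build-facts`, `aggregate`,
`quality`, `evaluate`, `check-access`), enforcing the role-profile
capability matrix: only the service profile can create records; every
profile can analyze and export.

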