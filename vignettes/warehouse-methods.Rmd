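---
title: "From consultation registers to audited health indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From consultation registers to audited health indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthfacts)
```

## The problem and the model

In health systems where the primary data source is a paper consultation
register, routine indicators are produced by manual tallying and manual
semantic matching of free-text diagnoses to standard codes. `healthfacts`
models the digitised alternative as four coupled pieces:

1. a validated **health pyramid** — country, region, district, facility,
   service — in which every node has exactly one parent at the immediately
   superior level, and every consultation is attached to exactly one
   service;
2. **terminology mapping** from local free text to dictionary entries
   (ICD-10/ICPC-2, ATC, LOINC) with an explicit, reviewable score;
3. a materialised **fact table** at the finest available grain, from which
   all aggregation is re-derived rather than pre-tallied;
4. **quality metrics** (completeness, timeliness, accuracy) and paired
   user-evaluation scoring with an exact McNemar comparison.

The pipeline is deterministic end to end: the same register files, pyramid
and dictionaries always produce byte-identical facts, aggregates and
reports. That determinism is what makes the accuracy audit meaningful — a
conformity below 100% can only come from the data, not from the pipeline.

## The match score

Registers record diagnoses the way clinicians write them ("palu",
"paludisme grave"), not the way nomenclatures print them. We normalize both
sides — lowercase, French accent folding by a fixed character table (no
locale-dependent transliteration), punctuation stripped, whitespace
tokenization, no stemming — and score with the token-set Dice coefficient

$$ s(A,B) = \frac{2\,|A \cap B|}{|A| + |B|} \in [0,1], $$

with the conventions \(s = 1\) when both token sets are empty and \(s = 0\)
when exactly one is. Dice is the simplest symmetric statistic that counts
"matches between a local and a standard term" on a [0, 1] scale; we chose it
over character n-gram or edit-distance scores because token-level behaviour
is easy to audit by eye in a mapping report, which matters when the mapping
replaces a manual, subjective step. An entry's score is the maximum over its
preferred term and synonyms — synonyms exist precisely to catch local
phrasing. Ties between entries are broken by code, ascending, so ranking is
total and reproducible.

The acceptance threshold defaults to 0.6: above it, two-token terms must
share at least one token with a one-token target ("paludisme grave" vs
"paludisme" scores 2/3), while token-disjoint pairs are impossible to
accept. It is a parameter, not a constant; mapping reports carry the raw
score so reviewers can audit borderline accepts at any threshold. Terms
with no accepted candidate keep their local wording with a null code and an
`accepted = FALSE` flag — dropping them would silently bias every
completeness denominator downstream.

## The fact grain

The retrieval table keeps the wide, paper-style column list (geography
names, consultation attributes, one code column per family, local/standard
concept pairs) but at the grain of **one row per clinical entry**. A literal
star join of the diagnosis, drug and laboratory dimension tables would
produce the cartesian product of a visit's entries — a consultation with two
diagnoses and three prescriptions would appear six times. The long grain
stores each entry once, leaves the non-applicable concept columns null, and
gives every entry-less consultation exactly one all-null-codes row so that
no visit disappears from the warehouse. Two laws follow and are enforced by
tests: the fact row count equals \(\sum_{\text{consultations}} \max(1,
\text{entries})\), and `consultation_count` (distinct `num_examination`) is
invariant to how many entries a visit has.

Aggregation measures are recomputed from this grain on every query.
`share` divides a group's distinct-consultation count by the total within
the current filter scope; over a partitioning dimension (sex, facility)
shares sum to 1, while over a multi-valued dimension (diagnosis, when
visits can carry several) they legitimately may not. Drill-down keeps all
ancestor name columns in the grouping — names collide across branches in
real hierarchies, node ids are the join keys, and grouping by the full name
path is what makes roll-up conservation exact.

## Quality metrics and their conventions

- **Field completeness** is cell-level: `100 · filled / (records ×
  audited fields)`, where blank and `NA` both count as missing.
- **Reporting completeness** is report-level over an explicit expected
  (facility, month) grid; a report that never arrived is incomplete.
- **Timeliness** declares a report for month *M* on time iff it was
  submitted on or before day 5 (configurable) of month *M*+1, boundary
  inclusive. Delay is counted in days after the period end, floored at
  zero. A missing report is late — absence must be visible to both the
  completeness and the timeliness dimension — but contributes no delay
  value, so the mean delay is always finite and describes the reports that
  actually arrived.
- **Accuracy** is conformity: the share of source-register consultations
  whose warehouse values (date, sex, age, nationality, residence) all match
  the register. On an unmodified pipeline run it is 100 by construction;
  deviations measure transcription corruption, which the generator can
  inject at a known rate.

Percentages for display are rounded half-away-from-zero (92.86 → 93,
17.5 → 18), matching the conventional reporting style; all machine outputs
keep the raw fractions, and tests assert on the raw values.

## Evaluation scoring and the McNemar bound

Questionnaire matrices are binary users × criteria grids per system, with
criteria partitioned into the three quality dimensions. The aggregate score
of a dimension is the pooled yes-fraction over users × criteria — with a
complete grid this equals the user-weighted mean of criterion fractions, an
identity the tests check. Pooling with equal weights is the only choice
that makes the dimension score reproducible from the printed per-criterion
counts alone.

Paired yes/no responses from the same panel are compared with the **exact
binomial McNemar test** on the discordant counts \(b, c\):

$$ p = \min\!\big(1,\; 2\,P(\mathrm{Bin}(b+c, \tfrac12) \ge \max(b,c))\big). $$

With a 14-user panel the large-sample chi-square approximation (with or
without continuity correction) is hard to defend; the exact form is valid
at any count and deterministic. When only the marginal yes-counts per
system are available — the common case when reading published evaluations —
the individual pairings are unknown, but they are constrained:
\(b - c\) is fixed by the marginals and all four cells must be
non-negative. `mcnemar_bound_from_marginals()` enumerates every feasible
\((b, c)\) and reports the **maximum** p-value, a worst-case bound that
holds whatever the true pairing was. For completeness marginals 39/42 vs
5/42 the feasible tables are \((b,c) \in \{(34,0),(35,1),(36,2),(37,3)\}\)
and the bound is about \(1.9 \times 10^{-8}\), comfortably below 0.001.

## The synthetic generator

No consultation-level dataset of this kind is publicly deposited, so the
generator is a first-class module, not a test shim. It emulates: a
configurable pyramid (default 2 regions × 2 districts × 2 facilities × 2
services, 31 nodes); consultations with sociodemographic and economic
fields drawn from small realistic vocabularies; a categorical diagnosis mix
over an ICD-10 subset (default headed by malaria at 0.35, the dominant
cause of visits in the setting emulated); per-visit drug and laboratory
count distributions; register phrasing that uses dictionary synonyms 30% of
the time; a monthly submission calendar with a 1 + Poisson(3)-day delay
beyond the period end; and optional injected missingness (blanked audited
cells) and transcription corruption (perturbed ages, with the clean source
register kept alongside). Every dataset carries a manifest of ground truth
— per-code counts, per-facility totals, injected defects — which tests
recount from the emitted CSVs.

One pseudo-random stream keyed by the seed drives everything, and output
formatting is fixed, so a seed reproduces files byte for byte. Two fixtures
are exact by construction rather than sampled, because they mirror printed
totals: the district worked example (exactly 6054 consultations, exactly
2966 malaria-coded, shuffled as a fixed multiset across 12 facilities — the
real district has 162 facilities, but no per-facility distribution is
published, so only the totals are normative and a smaller facility count
keeps the fixture legible) and the 14-user evaluation matrix with column
sums 14, 12, 13 | 13, 14 | 14, 14 (new) and 2, 1, 2 | 1, 4 | 4, 1
(traditional).

What the generator does **not** emulate: seasonality or epidemic dynamics,
patient trajectories across visits, facility-size heterogeneity beyond the
uniform service assignment, and correlated missingness (cells are blanked
independently). Passing tests therefore demonstrate the pipeline's
bookkeeping and arithmetic on realistic shapes and volumes, not
epidemiological realism of the simulated burden.

## Numerical and interface choices

- Dates are strict ISO 8601 (`YYYY-MM-DD`); no locale parsing, so
  timeliness arithmetic is bit-exact. Weeks are ISO-8601 weeks
  (`2018-W01`), months `YYYY-MM` — unambiguous and sortable.
- Default age bands 0–4, 5–14, 15–49, 50+ (configurable breaks): the usual
  reporting cut for child health, school age, reproductive age, older
  adults.
- Multiple entries per visit are packed into three pipe-separated register
  columns (diagnoses, drugs, labs). How multi-diagnosis visits were
  recorded on paper varies; one row per consultation with packed entries
  keeps register files one-per-service simple and round-trippable.
- Identity columns (name, surname, phone, national_id — configurable)
  abort an entire register file rather than being dropped: a replica that
  ever contained identity data should not enter the warehouse at all.
- Rejected rows are never silently dropped; the rejection report is CSV
  with row numbers and reason codes, because accuracy audits need the
  denominator.
- `admin_category` (public / para-public / private facilities) is carried
  through the pyramid but takes no part in aggregation; whether it should
  partition indicators is a policy question the warehouse does not decide.
- The pilot date window is a generator parameter (default
  2018-01-20..2018-07-12) rather than a constant, since reported pilot
  durations vary by source.
- Profiles: only the service profile (the producer of the data) holds
  `create_record`, `record_clinical_data` and `match_concepts`; all five
  profiles hold `update_data`, `analyze`, `visualize`, `export`. At
  aggregation levels `update_data` means re-running mapping and
  aggregation, never editing service-level register rows — a deliberate
  restriction where the capability table alone would permit more.
- `visualize` is honoured as permission metadata over tabular summaries;
  dashboard rendering is out of scope.

## Problem sizes in the test suite

The suite exercises the worked district example at full size (6054
consultations), property checks on 20 generated datasets of 2000
consultations each (seeds 1–20) for roll-up conservation and the fact-row
law, random 50-entry dictionaries for matcher/brute-force agreement, and
exhaustive \(2^{b+c}\) enumeration of discordance sequences for the McNemar
oracle up to \(b + c = 12\). These sizes were chosen so the full suite runs
comfortably on a laptop while still counting in the thousands where the
conservation laws could plausibly break.

## Known limitations

- The Dice score is token-set based: word order and near-miss spellings
  ("anemie" vs "anemies") do not match; a fuzzier matcher would trade
  auditability for recall.
- Accuracy conformity compares a fixed field set; clinical-entry content is
  audited only through the mapping report.
- The evaluation scorer requires a complete response grid; partially
  answered questionnaires must be handled upstream.
- Aggregation is in-memory over data frames; the CSV contracts are the
  normative interface, and a relational backend could be substituted behind
  them for much larger volumes.
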