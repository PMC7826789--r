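---
title: "Methods: assembling and annotating a kinase chemogenomic set"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembling and annotating a kinase chemogenomic set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinoset)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the defaults it chose where the workflow left a
choice open, and what its synthetic fixtures do and do not demonstrate.

## The problem

Most kinase inhibitors are ATP-competitive and touch more than one kinase.
A chemogenomic set turns that into a feature: assemble inhibitors that are
*potent* (low K_D on at least one kinase) and *narrow* (few kinases hit at
the screening concentration), covering as many kinases as possible with
two or more chemically unrelated scaffolds each. Phenotypes that reproduce
across unrelated inhibitors of a kinase then implicate that kinase.
`kinoset` implements the quantitative steps of that workflow: selectivity
scoring, inclusion filtering, chemotype classification, greedy assembly,
coverage accounting, and annotation of downstream phenotypic screens.

## Selectivity: activity profiles and S₁₀

The primary screen is a binding-displacement panel reporting percent of
control (PoC) per compound × kinase at a fixed concentration (1 µM by
convention): 0 means complete inhibition, 100 no effect, and values above
100 occur. A compound's *activity profile* at cutoff c is the set of
kinases with PoC strictly below c (default c = 10, i.e. ≥ 90 %
inhibition), and its selectivity index is the fraction

$$S_{10} = \frac{\#\{k : \mathrm{PoC}_k < 10\}}{\#\{k\ \text{assayed}\}}.$$

Conventions that matter:

* **All threshold comparisons are strict.** PoC exactly 10, K_D exactly
  100 nM, S₁₀ exactly 0.025 — all fail. This keeps every rule a single
  open inequality and matches the usual "<" phrasing of such criteria.
* **Missing cells leave both numerator and denominator**, with a warning
  per affected compound. An unassayed kinase is not evidence of
  selectivity; S₁₀ is a fraction of *assayed* kinases. A compound with no
  non-missing cells is an error, not S₁₀ = 0.
* **Non-wild-type and non-human assays are excluded** from the
  denominator; the selectivity index is defined over wild-type human
  kinases. Kinase identity is the case-sensitive gene symbol — no alias
  resolution, which is error-prone and out of scope.
* **The panel travels with the matrix.** Compounds profiled on different
  panels (e.g. a 230-assay legacy panel vs. a 401-assay panel) get S₁₀
  denominators from their own panel.

Two cutoffs coexist in practice for the K_D follow-up list: the activity
profile cutoff (PoC < 10) and a more permissive PoC < 20.
`kd_followup_set()` exposes the cutoff as an argument and defaults to 20,
the value usually quoted for the follow-up submission step; both are one
call away.

**Inclusion rule.** `decide_inclusion()` passes a compound iff it has at
least one follow-up K_D < 100 nM *and* S₁₀ < 0.025. "At least one kinase"
is deliberate: a qualifying K_D on *any* kinase counts, because
repurposing a compound's off-target potency is part of the design. An
empty K_D table yields a failed decision, not an error.

## Chemotype binning

Chemotypes are defined by hinge-binder substructures codified as SMARTS
patterns with a total priority order; a compound matching several bins is
assigned to the highest-priority match, and compounds matching none fall
into the `other` bin. Matching is substructure containment with
aromaticity perception and no stereochemistry — bins are scaffolds, not
exact structures. The matching engine is Open Babel (via ChemmineOB); the
test-suite cross-checks assignments against RDKit as a second,
independently implemented engine.

Choices:

* **Priority ties are a hard error.** The priority order must be total;
  breaking ties silently would make assignments depend on row order.
* **The fallback is always present and always last.** A catalog without a
  fallback gets `other` appended after its lowest-priority bin.
* **The catalog is user data.** Real campaigns use curated catalogs of
  ~120 bins; the package ships a 12-bin demonstration catalog covering
  the well-known scaffolds (indazole, oxindole, quinazoline,
  4-anilino-quinazoline, quinoline, pyrimidines, azoles) for examples and
  tests. It makes no claim to reproduce any particular curated catalog's
  membership.

`bin_histogram()` summarizes occupancy into singleton / 2–5 / ≥ 6 strata,
the customary way such catalogs are reported; the strata always sum to
the occupied-bin count.

## Greedy set assembly

The historical curation step — "maximize kinome coverage, aim for two
chemotypes per kinase, prefer under-represented chemotypes among
equivalent compounds" — was expert manual triage. `greedy_assemble()`
commits it to a deterministic algorithm so that selections are auditable
and replayable:

* **Gain.** A candidate's marginal gain is the weighted count of its
  qualifying kinases (kinases with a sub-threshold K_D for that compound)
  that are still below the chemotype depth target `d` (default 2) *and*
  for which the candidate's bin is new. "Coverage" is thus K_D-validated
  potency, not mere PoC activity — coverage claims should rest on the same
  evidence as inclusion.
* **Ties** break by (1) fewer exemplars of the candidate's chemotype
  already selected, (2) lower S₁₀, (3) lexicographic id. Each level
  encodes one of the stated curation preferences; the last makes the
  result total-ordered and reproducible.
* **Stop** when no candidate has positive gain. Every step therefore
  strictly increases $\sum_k \min(d, |\text{chemotypes}(k)|)$; kinases
  beyond the target can still *incidentally* gain depth when a compound is
  added for other kinases, they just never justify an addition.
* **Publication weights** (optional, per-kinase in [0, 1]) linearly
  down-weight well-studied kinases in the gain. No quantitative rule for
  "don't over-represent famous kinases" is established practice, so the
  semantics are documented rather than asserted: weight 0 removes a
  kinase from the objective, weight 1 is neutral.

No optimal set-cover solver is attempted; the greedy surrogate matches
the incremental spirit of the curation it replaces and is exactly
reproducible, which an ILP with solver-dependent tie-breaking would not
be. The full per-step candidate scores and the tie-break level applied
are retained in the result's `audit` table.

## Coverage analytics

`family_coverage()` reports per-family assays, covered counts, and
percentages rounded **half-up** to integers (37.5 → 38), the convention
that reproduces hand-rounded published coverage tables; base R's
round-half-even would not. Families with no assays report `NA` rather
than dividing by zero. The totals row aggregates counts first and
recomputes its percentage from the aggregates. `redundancy_report()`
splits covered kinases by *distinct chemotypes* (not inhibitor count);
`dark_kinase_coverage()` is an exact symbol intersection with a
user-supplied understudied-kinase list — such lists are versioned
externally and are consumed as inputs, never fetched.

## Screen annotation

**Growth rate.** GR corrects endpoint counts for division-time
differences:
$$\mathrm{GR} = 2^{\log_2(x/x_0)/\log_2(x_{ctrl}/x_0)} - 1,$$
the standard normalized growth-rate-inhibition formula from the GR-metrics
literature. GR = 1 at vehicle-like growth, 0 at stasis, < 0 at net loss;
it is scale-invariant and strictly increasing in the treated count. A
non-growing control line makes GR undefined and is a hard error naming the
line (the usual practice is to exclude such lines).

Response classes over a cell-line panel: *inactive* when every line is
within 10 % of vehicle (GR ≥ 0.9); *broad* when at least 75 % of lines
show a > 30 % GR decrease (GR ≤ 0.7); *line-dependent* when some but not
enough lines do. "Most of the lines" is not quantified in common usage;
0.75 is this package's default and is configurable. Lines between the two
bands (e.g. all lines at GR 0.8) classify as inactive — they cross
neither threshold.

**Cytotoxicity.** The normalized healthy-cell fraction partitions into
nontoxic (≥ 0.8), reduced (< 0.8), severe (< 0.5) and extreme (< ⅓, i.e.
a > 67 % decrease). Boundaries are inclusive on the healthier side, so
exactly 0.8 is nontoxic. Per-kinase aggregation restricts to kinases
covered by ≥ 2 distinct chemotypes (single-chemotype kinases cannot
separate kinase pharmacology from compound idiosyncrasy) and averages
their inhibitors' fractions; a kinase is flagged when a one-sided Welch
t-test of its inhibitors' values against the vehicle replicates, BH-
corrected across kinases, is significant at α = 0.05. The flagging test
is this package's documented default — no specific test is canonical for
this step — and with the small per-kinase n typical here it should be
read as a screening flag, not confirmatory inference.

**Autophagic flux.** Reporter time series (GFP/RFP ratio, normalized to
t = 0) are expressed per time point as a percentage of the span between
the paired vehicle series (0 %) and the flux-inducer positive control
(100 %); a degenerate span (control equals vehicle at some time point) is
an error naming the time point. A compound is a hit when |pct| > 20
(strict) at ≥ 5 consecutive time points; the first qualifying run is
reported and its mean sign gives the direction. No smoothing is applied
before hit calling — the rule is defined on the measured series. Hits are
placed in a 2 × 3 category grid: flux direction × cell state
(proliferation reduced; unchanged with abnormal appearance; unchanged
with normal appearance). The six categories are this package's
documented convention for summarizing such screens; `increased`
proliferation is treated as "unchanged" on the proliferation axis, which
only distinguishes reduced from not-reduced.

## Plate logistics

`assay_budget()` is floor(nanomoles in the aliquot / nanomoles per well):
a 1 µL aliquot of 10 mM stock at 1 µM final concentration funds 100
assays at 100 µL working volume and 200 at 50 µL. Floor, because partial
assays have no physical meaning. `build_platemap()` places controls first
(default: column 1, top down — an arbitrary but fixed convention), fills
compounds row- or column-major, errors on overflow with the required
plate count, and is byte-deterministic.

## Synthetic fixtures

The generators in `gen_profiles()`, `gen_growth_screen()` and
`gen_flux_screen()` produce every input the toolkit consumes, with
embedded ground truth, under a single seed; the same spec yields
byte-identical files. Defaults emulate the study conditions of a typical
assembly campaign: a 401-assay wild-type human panel screened at 1 µM; a
compound mixture of 40 % selective (planted active sets of 1–8 kinases,
PoC centred at 5, follow-up K_D 10–80 nM), 30 % promiscuous (30–60 active
kinases) and 30 % inactive (PoC centred at 95); truncated-normal PoC
noise (SD 2) that keeps planted actives below the cutoff and inactives
above it, so ground truth is exact by construction; a 17-line growth
screen with per-line doubling counts of 1.5–4 over the assay window,
planted broad effects at GR 0.5 on all lines and line-selective effects
at GR 0.15 on 3 of 17 lines, log-normal count noise (SD 0.05); and
49-point flux series (0–96 h every 2 h) with planted runs at ±30 %
amplitude of length ≥ 5 for hits and near-miss decoys (length-4 runs at
amplitude, long runs below threshold).

What the fixtures demonstrate: that every pipeline rule recovers exactly
what was planted at zero noise, that recovery degrades gracefully at the
stated noise levels, and that all I/O round-trips (generators emit the
same file formats the readers consume, and tests go through the files).
What they do not demonstrate: performance on real panel data. The noise
models are deliberately simple — truncated normal PoC noise is not the
error structure of a competition binding assay, planted flux runs are
piecewise constant, and the generators plant no correlation structure
across kinases or cell lines. Passing tests certify the *rules*, not
field performance.

## Numerical choices and degenerate inputs

* Percent rounding: half-up via `round_half_up()`; documented above.
* Activity profiles order by ascending PoC, ties by symbol, so output is
  unique.
* Empty inputs: empty K_D table → failed inclusion (not an error); empty
  assignment list → all-zero histogram; empty candidate pool → empty set
  object with intact schema. All-missing PoC rows, unknown kinase
  columns, negative PoC, non-positive K_D, duplicate ids, duplicate bin
  priorities, and non-growing control lines are hard errors.
* Problem sizes in the test-suite (panel sizes 40–401, 1,000-row oracle
  sweeps, 200 random greedy instances within ≤ 8 × 6) were chosen to
  exercise every rule and its boundaries while keeping the default suite
  fast on a single CPU.

## Known limitations

* No conversion between PoC and percent-inhibition conventions; matrices
  are assumed to be PoC. Legacy data reported as inhibition must be
  converted upstream.
* No chemical standardization (salts, tautomers) beyond parse validation;
  bin membership can depend on the drawn tautomer.
* The greedy assembler is a surrogate for manual curation, not a
  reconstruction of any particular historical selection; with the same
  inputs it will generally produce a *defensible* set, not *the* set an
  expert chose.
* The per-kinase toxicity flag and the six-category flux scheme are
  documented defaults where no canonical convention exists.
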