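---
title: "ventalloc: methods, modelling choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ventalloc: methods, modelling choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## 1. What the simulation estimates

`ventalloc` estimates counterfactual outcomes of applying a ventilator
triage protocol during a shortage, using only scarcity-free observables:
each encounter's survival to discharge when everyone gets a bed, and their
comorbidity-adjusted remaining life expectancy. The key identifying
assumptions, inherited from the pair-based simulation literature, are:

* **No bed, no survival.** A patient denied a ventilator dies. This
  overstates mortality among the denied (some would survive on other
  support) and therefore overstates absolute effect sizes, but affects all
  protocols symmetrically.
* **Static allocation.** One decision per encounter at intubation; no
  re-assessment, re-allocation or timed trials, no queueing or arrival
  dynamics, no duration-of-use accounting. Protocol clauses about
  re-assessment are deliberately ignored.
* **Encounters, not patients.** Repeat admissions are treated as
  independent sampling units; within-patient correlation is not modelled.
* **Outcome invariance.** An allocated patient's survival equals their
  observed scarcity-free outcome; triage itself does not change care
  quality.

## 2. The scarcity mechanism

Capacity is expressed as `c = n/20` beds per patient, `n = 1..19`. Each
replicate randomly permutes the cohort and partitions it into blocks of 20
(sampling *without* replacement: every encounter is decided exactly once
per replicate; the alternative with-replacement reading of "randomly
sampling twenty patients" would leave some encounters undecided and is not
used). Within a block the permutation order defines ten pairs, already in
random order, so "first"/"last" pairs are taken literally:

* `n > 10`: pairs `1..n−10` receive two beds; each remaining pair sends
  its higher-priority member.
* `n = 10`: every pair is contested.
* `n < 10`: pairs `1..n` receive one contested bed; the rest none.

Contests compare `(band, tiebreak)` lexicographically, with a fresh uniform
tiebreak per decision — so the lottery protocol (constant band) is decided
entirely by tiebreaks, and any within-band tie in the other protocols
degrades gracefully to a lottery.

**Remainder blocks.** A cohort size not divisible by 20 leaves a final
block of `m < 20` encounters. It forms `⌊m/2⌋` pairs plus, for odd `m`, a
singleton that competes as a pair of one (capacity one bed), and receives
`round(c·m)` beds assigned by the same first-pairs-double /
last-pairs-zero scheme (second beds go to full pairs first). This preserves
the capacity fraction in expectation up to integer rounding. Note the
rounding makes per-encounter allocation probability in the remainder block
`round(c·m)/m` rather than exactly `c`; for cohorts that are multiples of
20 the lottery allocation probability is exactly `c` by symmetry.

**Reproducibility.** All Monte Carlo work uses the L'Ecuyer-CMRG generator:
one master seed spawns an independent stream per capacity level
(`parallel::nextRNGStream`) and an independent substream per replicate
(`nextRNGSubStream`). Results are bit-reproducible for a fixed seed and
independent of replicate execution order, and package code never disturbs
the caller's RNG state.

## 3. Protocols and their tunables

Scoring rules are fixed by their published definitions (tiers, point bands,
the Elixhauser ≥ 12 "severe comorbidity" bonus). Two pieces are
configurable because the sources leave them open:

* **Age-band edges** (`default_age_bands()`): "10-year age bands" is
  operationalised as the reporting bands 18–24, 25–34, …, 75–84, 85+
  (eight bands). Exact edges are configurable; note 18–24 is a 7-year
  band, so e.g. 25 and 34 tie while 31 and 39 do not.
* **Colorado age points** (`default_colorado_table()`): the published
  supplement with the modified-Charlson age points was not available, so
  the defaults use the conventional age-adjusted Charlson increments
  (0 below 50, +1 per decade, capped at 3 from age 70). This is an
  assumption, flagged as such, and the whole table can be replaced from a
  CSV (`read_colorado_table()`). `charlson_points` on the encounter must
  exclude the age contribution, which comes from the table.

## 4. Life expectancy and comorbidity adjustment

Raw remaining life expectancy is a lookup by (age, sex, race) in a period
life table. Comorbidity is applied by the **effective-age method**: the
encounter's comorbidity weight (default: the Elixhauser summary already on
the encounter) is banded into none / low_medium / high (thresholds ≤0 /
1–11 / ≥12, the high cutoff deliberately matching the Maryland severe
threshold) and the band's age offset (defaults 0 / 3 / 7 years) is added to
the age at which the table is re-entered. Offsets are constant in age, so
the rule "under-65s receive the 65-year-old's adjustment" holds by
construction; lookups past the table maximum clamp to the oldest age. The
0/3/7 offsets are placeholders of realistic magnitude — the claims-based
adjustments they stand in for are not published in reusable form — and are
fully configurable (`comorbidity_adjustment()`).

The bundled table (`synthetic_life_table()`, and the small CSV fixture) is
**synthetic**: a monotone schedule linearly interpolated through plausible
US anchor values (≈62 years remaining at 18, ≈19 at 65, ≈6.5 at 85) with
multiplicative sex (±6%) and race scalings. It exists so the package is
self-contained and its invariants testable; any real national life table in
the `age,sex,race,ex` CSV dialect should be supplied for substantive work.

## 5. The synthetic cohort generator

`cohort_spec()` defaults state the world the simulator was developed
against — a 3707-encounter ventilated adult cohort from one US hospital
system in the first pandemic year:

* **Margins**: age-band masses, sex (59/41) and race/ethnicity margins
  taken from that cohort's descriptive table; age is uniform within band.
* **Race-conditional structure** (the driver of the equity findings):
  Black and Hispanic encounters draw age from truncated normals
  (56 ± 17, 53 ± 18; White non-Hispanic mean 64 via the band margins);
  COVID positivity 0.45 / 0.39 / 0.33; mean SOFA 3.46 / 3.14 / 3.69.
* **SOFA**: negative binomial, race-conditional mean, clamped to 0–24.
  The dispersion (`sofa_size = 1.2`) was fixed once so the 1–7 / 8–11 /
  12–24 band masses approximate the observed 86/10/4%.
* **Elixhauser**: a discretised shifted gamma whose scale is solved by
  root finding so that `P(score ≥ 12)` equals a configurable tail mass
  (default 0.1) — the only feature of the distribution any protocol
  consumes. **Charlson condition points**: geometric(0.6) capped at 8, a
  "small non-negative integer" chosen once as plausible for condition
  counts; no source distribution was available.
* **Survival**: Bernoulli from a logistic model with per-unit odds ratios
  0.896 (SOFA), 0.964 (age), 1.054 (Elixhauser). No intercept is
  published, so it is calibrated per generated cohort by one-dimensional
  root finding (`uniroot` on the mean fitted probability over the sampled
  covariates) to hit the 0.72 overall survival target exactly in
  expectation. Note the Elixhauser coefficient is slightly *protective* as
  estimated in the source model; it is reproduced as reported.
* `covid_fraction_override` replaces the race-conditional COVID rates with
  a single overall rate, supporting patient-mix sensitivity analyses.

What a green test on this cohort does **not** establish: the generator has
no within-patient correlation, no hospital-level structure, no correlation
between comorbidity and age or SOFA, and independent Charlson noise — so
synthetic results quantify the *mechanics* of the protocols on a
realistically shaped population, not the study cohort's actual numbers.
Notably, because the generated Charlson points are pure noise, the Colorado
protocol's lives-saved advantage over the age protocol is closer here than
in the source data; the qualitative ordering is preserved on the default
cohort and is asserted by the acceptance suite, but it is a property of the
stated synthetic world, cohort seed included.

## 6. Metrics and intervals

* Replicate-level quantities (survival, allocation, LS, LYS) are
  summarised as mean ± 1.96·SE over replicates: these intervals describe
  Monte Carlo error given the cohort, which is how the simulation's
  headline tables are conventionally reported. They shrink as 1/√R.
* Directly standardized (age-adjusted) rates use the gamma method for
  standardized rates, with the Tiwari modification (mean standardizing
  ratio in the upper bound) as default and Fay–Feuer available. Upper
  bounds are clamped at 1 for proportions. Empirical coverage on binomial
  strata is conservative (the gamma method assumes Poisson counts, which
  over-states binomial variance); the acceptance suite requires ≥93%.
* The standard population for age adjustment defaults to the full cohort's
  own age distribution, which makes crude and adjusted rates coincide
  overall and at baseline — chosen because the source does not name its
  standard; any weight vector can be supplied.
* Subgroups empty in the cohort return an undefined-rate marker rather
  than erroring; age strata empty within a subgroup are dropped with
  renormalized weights and a warning.
* Per-1000 scalings are presentation only; all internal arithmetic is per
  patient.

## 7. Interfaces

Run configuration, and the reproducibility manifest every CLI run writes,
are JSON (`jsonlite`); no YAML parser is part of the supported dependency
set, and JSON round-trips the same structures. The Colorado table and life
table are CSV. The CLI (`exec/ventalloc`, or `vent_main()`) exposes
`generate`, `simulate`, `sweep` and `report`, exits 2 on configuration
errors and 1 on runtime errors, and is deterministic given its manifest.

## 8. Known limitations

Beyond the identifying assumptions of §1: the bundled life table is
synthetic; the comorbidity age offsets and the Colorado age points
are assumptions pending authoritative tables; the generator omits
covariate correlations noted in §5; and the simulation cannot address
re-allocation, DNR adjustment, or hospital-level population bias. These are
scope boundaries, not implementation gaps: all are injectable via the
configurable tables where data exist.
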