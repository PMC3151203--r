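---
title: "Estimating re-identification risk from longitudinal residential trails"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating re-identification risk from longitudinal residential trails}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trailrisk)
```

## The problem

Basic demographics — date of birth (DOB), residential postal code, gender —
are quasi-identifiers: an adversary who knows them for a target person can
match them against a disclosed data set. The standard surrogate for this
re-identification risk is *population uniqueness*: the proportion of people
whose quasi-identifier combination occurs exactly once in the population.
Longitudinal data raise the stakes, because a person's *residential trail*
(their postal code in each of several annual snapshots) is itself close to
a fingerprint, even with the DOB and gender removed.

`trailrisk` implements this analysis as a reusable pipeline over an annual
snapshot registry: quality control and sentinel encoding of births/deaths,
quasi-identifier construction over a generalization lattice, exact and
sample-based uniqueness estimation, a stabilized study-point loop, and a
per-postal-code estimator that works from aggregate counts only. Because
population registries of this kind are confidential, the package also ships
a synthetic registry generator calibrated to the published marginal
statistics of an 11-year urban Canadian registry (1996–2006), so the whole
pipeline is testable end to end.

## The registry model and its quality control

A registry row is one person: id, gender, birth date, optional death date,
and one postal code per window year, taken at the beginning of the year
(within-year moves are invisible at this granularity). Two QC rules remove
defective records, mirroring typical registry practice:

* **all-missing** — no postal code in any window year (removes ~1% under
  the default corruption model);
* **inconsistent** — a postal code strictly before the birth year or
  strictly after the death year (~5%).

`qc_filter()` applies exactly these two rules, in that order of
precedence, and reports the counts; it is idempotent. We did not add a
policy for records with *some* (not all) missing in-life years: the
generator never produces them, and `encode_sentinels()` treats such a
record as a contract violation rather than silently imputing. Real data
with partial missingness should be resolved by the caller before encoding.

After QC, `encode_sentinels()` writes `"UUUUUU"` into years strictly
before birth and `"DDDDDD"` into years strictly after death. This encodes
a *knowledgeable adversary* who knows when the target was born and died;
those facts then participate in key matching. Passing
`sentinel_aware = FALSE` to `build_quasi_identifiers()` blanks the
sentinels instead, emulating an adversary without vital-status knowledge
(uniqueness can only drop).

## Generalization lattice and keys

Keys are assembled per person from three components:

* DOB at one of four granularities: full date, month/year, year,
  suppressed;
* the first *k* characters of each selected year's postal code,
  `k` in 0..6 (0 suppresses the trail; 3 characters is the FSA, a common
  release granularity);
* optionally gender.

Trail years are **year-labelled**: the key stores *which* calendar year
each cropped code belongs to, because the adversary model assumes
knowledge of when the target lived where. Sentinels crop like ordinary
strings and can never collide with real codes (real codes never start with
`U` or `D`). `enumerate_lattice()` produces the full cross product of the
three components and the trail length, excluding the combinations with
both DOB and postal code suppressed; a gender-only level is expressible
directly via `generalization_level()` but is excluded from the lattice as
degenerate (it has at most two classes).

Refinement is the key structural property, and the test suite asserts it:
moving any component toward finer granularity, or adding trail years,
refines the partition of persons and therefore can only raise exact
uniqueness.

## Uniqueness and the Zayatz estimator

All estimators consume the frequency spectrum $c_j$ (number of equivalence
classes of size $j$; $T = \sum_j j\,c_j$ records, $C = \sum_j c_j$
classes). Exact uniqueness is $c_1 / T$.

When only a simple random sample of $n$ from $N$ ($\pi = n/N$) is
available, population uniqueness is estimated with the Zayatz
sample-uniques estimator. The probability that a population class of size
$j$ contributes exactly one record to the sample is hypergeometric,

$$p(j) = \frac{\binom{j}{1}\binom{N-j}{n-1}}{\binom{N}{n}},$$

computed in log-gamma space (`p_sample_unique_given_pop_size()`; a
binomial approximation $j\pi(1-\pi)^{j-1}$ is available for very large
$N$). The estimator plugs the *sample* spectrum in as the prior over
population class sizes:

$$\hat P(\text{pop unique}\mid\text{sample unique}) =
  \frac{p(1)\,c_1/C}{\sum_j p(j)\,c_j/C},\qquad
  \hat N_1 = \frac{c_1 \hat P}{\pi},\qquad
  \hat u = \min\!\left(1, \frac{\hat N_1}{N}\right).$$

At $\pi = 1$ this reduces algebraically to exact uniqueness, which the
suite asserts as an identity. With no sample uniques the estimate is 0.

**Known limitation.** The sample-spectrum plug-in is a crude prior. Our
simulations show the estimator is essentially unbiased when non-unique
population classes are well separated from the singletons (class sizes
around 100: recovery within ±0.05 of truth at $\pi = 0.25$, $N = 50{,}000$,
for true uniqueness 0.05–0.8), but it overestimates substantially — by up
to +0.30 — when the population is dominated by classes of size 2–10,
because such classes shed many sample uniques that the plug-in prior then
misattributes to population uniques. The recovery property in the test
suite therefore uses the well-separated construction; it guards the
implementation, not the estimator's behaviour on adversarial spectra.

## The study-point loop

A *study point* is a generalization level plus a trail length $k$.
`run_study_point()` repeatedly draws a uniform random $k$-subset of window
years (independently across iterations, so subsets may repeat), computes
uniqueness, and updates the cumulative mean. Iteration stops when the
change in the cumulative mean stays below $\delta = 10^{-4}$ for 10
consecutive iterations (counting from the first change available, so a
zero-variance registry stops exactly at the 10-iteration minimum), with a
cap of 1000 iterations. The phrase "change over 10 iterations" is
ambiguous between consecutive differences and a 10-lag difference; we use
consecutive differences by default and expose the lag variant as
`criterion = "lag"`. When $k$ equals the window length there is only one
subset and a single iteration is performed. On moderately sized synthetic
registries the rule typically fires after a few hundred iterations,
consistent with the 100–500 range reported for this design.

Youth/adult stratification uses calendar-year age (`year − birth year`,
matching beginning-of-year snapshots): a person is a *youth* for a trail
if that age is below 20 in **every** selected year. The complementary
"in any year" reading of the rule is obtainable by stratifying per year;
we default to the stricter reading.

`policy_table()` flags each study point against the 5% (strict, untrusted
recipients) and 20% (relaxed, trusted recipients) uniqueness thresholds
used in research-data disclosure precedents; a mean exactly at a threshold
is acceptable, and strict acceptability implies relaxed by construction.
`sensitivity_bounds()` gives the closed-form extreme-case envelope for QC
removals at rate $r$: if every removed record had been corrected and
retained as unique the observed $u$ rises to $(1-r)u + r$; if none were
unique it falls to $(1-r)u$. At $r = 0.06$ these reproduce the familiar
20% → 24.8% and 5% → 10.7% adjustments.

## The synthetic generator: what it emulates, and what it does not

The generator's defaults are the study conditions; they are calibrated
once, to published marginal statistics, and are not tuning knobs:

* **Postal universe** — 6-character codes under FSAs, log-normal
  population shares calibrated so 6-character cells have mean ≈48 and
  median ≈30 residents (large-city profile); ~85% of codes flagged urban.
  Letters D, F, I, O, Q, U never appear, so real codes are disjoint from
  sentinels.
* **Mobility** — move counts drawn from the printed marginal
  48/21/17/8/6% for 0/1/2/3/4+ changes over 11 years; the open 4+
  category becomes a geometric tail (decay 0.5) capped at window−1.
  Change years are placed uniformly among a person's in-life years and
  destinations are drawn by population share (never equal to the current
  code). Persons born or dying mid-window cannot host many moves, so
  infeasible draws are swapped with feasible low-count draws of
  full-window persons: the *population* move-count marginal equals the
  i.i.d. draw exactly, which is also the only statement the source
  statistics make. This implies that short-lived persons move less, which
  is demographically sensible.
* **Demography** — piecewise-uniform age pyramid at the window start with
  band weights 0.32/0.36/0.19/0.13 over ages 0–19/20–44/45–64/65–90
  (chosen once so the youth share lands near the reported ~30%), 51%
  female, 10% of persons born inside the window (uniform over years), and
  a Gompertz annual death hazard $5\times10^{-5} e^{0.09\,\text{age}}$
  (~7% in-window deaths).
* **Corruption** — 1% of persons lose all postal codes; 5% receive one of
  their own codes in an out-of-life year (the two flags mutually
  exclusive). Inconsistency requires an out-of-life year, so targets are
  drawn among eligible persons; a registry without births or deaths
  triggers a configuration warning instead.

What it does **not** emulate: household structure, spatially correlated
moves (movers draw destinations independently of origin), real postal
geography, age- or income-dependent mobility, seasonal birth patterns, or
the repeated-annual-draw construction of the original ~25% sample (we
expose a plain SRS sampling fraction instead and leave the effective-π
judgement to the caller). Passing tests on this generator therefore
demonstrate correctness of the *pipeline* under a realistic marginal
structure, not conclusions about any real city's population.

## Aggregate-counts estimator

When only cell counts (postal code × birth year × gender, with an
urban/rural flag) are available, `aggregate_uniqueness()` estimates
per-code uniqueness on the basic demographics by assigning every person a
uniform day of birth within their birth year, computing exact uniqueness
per postal code against the code's own residents, and averaging over
repetitions (default R = 1000; the two-person closed form
$364/365$ is recovered within Monte-Carlo error). Real calendar lengths
(365/366 days) are used so generated dates stay valid; the effect on
collision probabilities is negligible. At year granularity the birthday
draws cancel and the result is deterministic. Per-code denominators are
the default (the literal reading of per-postal-code uniqueness); a pooled
denominator is available via `pooled = TRUE`. `urban_rural_summary()`
reports stratum medians, which makes the urban/rural contrast visible:
rural codes with much larger populations show markedly lower uniqueness
as soon as the DOB is generalized.

## Numerical and scale choices

Hypergeometric terms use `lchoose()` throughout; spectra are built by
`tabulate(match(...))`, which is exact integer arithmetic. Estimates are
clamped to [0, 1] because sampling noise can push the inflated
$\hat N_1$ above $N$ on pathological spectra. The calibration checks in
the test suite run at 100,000 persons (3 binomial standard errors), the
cross-sectional uniqueness check at 200,000 persons with ~4,200 postal
codes, and the estimator recovery at $N = 50{,}000$ with 20 seeded draws —
sizes at which the binomial tolerances are tight enough to be meaningful
while a full suite run stays around half a minute. All randomness flows
through explicit seeds; `generate_population()` is byte-deterministic
given its config.
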