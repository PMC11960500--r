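---
title: "Methods: disproportionality signal detection in faersignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection in faersignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem and the model

Spontaneous reporting databases have no exposure denominator, so adverse-drug
-event surveillance works on *reporting disproportionality*: for a focal drug
and each adverse-event term, the reports are collapsed to a 2×2 table with
cells `a` (focal drug, target event), `b` (focal drug, other events), `c`
(other drugs, target event) and `d` (the rest), `N = a+b+c+d`, and expected
count under independence `E = (a+b)(a+c)/N`. Because every method has known
failure modes at small counts, four are computed side by side and a term is
declared a signal only when all five joint criteria hold: `a >= 3`, lower
ROR 95% bound `> 1`, `PRR >= 2` with `chi2 >= 4`, `IC - 2SD > 0`,
`EBGM05 > 2`. The comparison operators are applied literally: weak
inequalities for the count, PRR and chi-square thresholds, strict ones for
the three interval bounds, and undefined statistics fail their criterion.
No multiple-testing adjustment is applied — the joint-criteria convention in
this field treats the five simultaneous conditions as the guard against
spurious signals — and this is deliberately left as-is.

### The four statistics

- **ROR** `= ad/(bc)` with Wald interval on the log scale,
  `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. A zero cell leaves the statistic
  undefined (`NA`) rather than raising an error; an optional
  Haldane–Anscombe correction (`continuity = TRUE`) adds 0.5 to all cells of
  affected tables.
- **PRR** `= [a/(a+b)]/[c/(c+d)]` with the Pearson chi-square computed as
  the four-cell `sum((O-E)^2/E)` *without* Yates correction. The
  uncorrected form is the one conventionally paired with the `PRR >= 2`,
  `chi2 >= 4` rule; the corrected variant is available by flag.
- **BCPNN IC**: the point estimate is the observed-to-expected form
  `log2(aN/((a+b)(a+c))) = log2(a/E)`, which is also exactly `log2` of the
  relative reporting ratio `a/E` (the package tests pin this identity). For
  the lower bound `IC - 2SD`, the posterior standard deviation comes from
  the default Monte-Carlo estimator: cell probabilities are drawn from
  `Dirichlet(a+1, b+1, c+1, d+1)` (unit priors), the IC is evaluated per
  draw, and twice the sample SD is subtracted from the point estimate
  (`1e5` draws by default, fully seeded). A closed-form alternative
  (`estimator = "gamma"`) approximates the posterior of `a/E` by
  `Gamma(a+1, E+1)`, giving `SD(IC) = sqrt(trigamma(a+1))/log(2)`. The
  Monte-Carlo route is the default because published IC intervals in this
  field follow several incompatible variance conventions; a sampling-based
  posterior SD under explicit unit priors is reproducible and
  self-documenting, whereas chasing any particular printed convention is
  guesswork. For the same reason the package does not claim to reproduce
  published `IC - 2SD` or `EBGM05` values, only published IC point
  estimates.
- **MGPS / EBGM**: the relative reporting rate `lambda` has a
  two-component gamma mixture prior
  `w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)`, so marginally
  `a` is a mixture of negative binomials. The prior is fitted to all the
  run's `(a, E)` pairs by direct numerical optimisation (`nlminb` over log
  parameters and logit weight) of the marginal likelihood, starting from
  DuMouchel's canonical `(0.2, 0.1, 2, 4, 1/3)`, iteration cap 10,000,
  relative tolerance `1e-8`. The posterior per table is again a
  two-component gamma mixture (`alpha_j + a`, `beta_j + E`, weights from
  the negative-binomial likelihoods); `EBGM = exp(E[log lambda])` via
  digamma, and `EBGM05` inverts the mixture CDF by bisection to `1e-6`
  relative accuracy. Fitting requires at least 10 tables; below that the
  canonical prior is used with a warning.

## Data handling conventions

- **Deduplication** keeps, per case id, the report version with the maximal
  `(FDA receipt date, primary id)` key — the standard practice for FAERS
  quarterly files, where cases recur across quarters as amended versions.
  Output order is sorted by case id and the operation is idempotent.
- **Focal-drug selection** is a case-insensitive substring match of a
  configurable name dictionary against the free-text drug name, restricted
  to role codes (`PS` only by default; FAERS drug names carry trade names,
  biologic suffixes and formulations, which exact matching would miss).
- **Age** is converted to years with fixed factors (decade = 10, month =
  1/12, week = 1/52.18, day = 1/365.25 years) and binned into `<18`,
  `18-44`, `45-64`, `65-74`, `>=75` with inclusive lower bounds, so an age
  of exactly 75 falls in `>=75`. Records with unknown sex or age stay in
  all totals and drop out only of the corresponding stratified analyses.
- **Counting units.** PT-level tables default to event counting (every
  drug–event pair counts once), which is the arithmetic behind published
  event-share percentages such as 141/1,095 = 12.88% for the strongest
  signal. SOC-level tables default to report counting (a case contributes
  at most once per organ class), since one case typically reports several
  terms of the same class; published SOC case counts are smaller than the
  corresponding event counts for exactly this reason. Both units are
  exposed as configuration, and neither is claimed to be "the" correct one.
- **Stratified runs** restrict *both* margins — focal and comparator — to
  the stratum, the standard subgroup-disproportionality convention that
  removes stratum-level confounding. Disjoint exhaustive strata therefore
  partition every term's `a` exactly.
- **Temporal analysis** is cumulative-through-year by default (statistics at
  period `y` use all reports with receipt year `<= y`), matching the notion
  of progressively accumulating signal strength; a per-period mode exists.
  The final cumulative period equals the full-data analysis, which the
  tests assert.
- **Time-to-onset** is event date minus therapy start, for records carrying
  both; negative differences are excluded and counted. Quantiles are type-7
  (linear interpolation) — a convention that has to be pinned for
  reproducibility. Bins are inclusive at both printed endpoints (`31-60`
  means `31 <= d <= 60`; day 0 is in the first bin).
- **Reconstruction from published statistics** inverts the ROR identity:
  given published `(a, ROR)` and the margins, `b = drug_total - a`,
  `c = round(a S/(ROR b + a))` with `S` the background event total, and
  `d = S - c`. Nearest-integer rounding is appropriate because counts are
  integral and published RORs for large signals carry six or more
  significant figures. A background cell that rounds to zero is an
  infeasibility, reported per row.

## The synthetic generator

The generator emulates the FAERS structure end to end: `$`-delimited
DEMO/DRUG/REAC/THER tables, amended duplicate case versions (an earlier
receipt date for a configurable fraction of cases), free-text drug names
with the focal drug as primary suspect, demographics, body weight,
seriousness and outcome codes, and therapy-start/event dates for a subset of
focal reports. Events per report are `1 + Geometric`, truncated at 10, drawn
iid per report; PT co-occurrence correlation is not modelled. Focal PT draws
multiply the background probabilities by the implanted relative risks and
renormalise. A useful property of this multiplicative model: the focal odds
of an implanted PT are `rr p/(1-p)` against background odds `p/(1-p)`, so
the event-level odds ratio equals the implanted multiplier *exactly*, which
is what the parameter-recovery tests exploit.

All randomness flows from one root seed through named per-stage substreams,
so output is byte-identical across runs and platforms and insensitive to
upstream stage changes.

`aducanumab_profile()` freezes the generator at the published 510-report
aducanumab caseload: category probabilities for sex, age group, reporting
year, reporter occupation, country and seriousness equal the published
proportions; weight is normal(71.49, 16.36) truncated to [34.2, 132.0] kg
with the published missingness; events per report average 1,095/510; the
implanted relative risks are the published EBGM values of the 27 signal
PTs, with each signal PT's background probability set to `share/EBGM` so its
rarity is realistic; and the onset distribution is a Weibull fitted by
binned maximum likelihood to the published onset-bin counts (217 onsets).
The background corpus defaults to a desk-scale 10^5 reports rather than
tens of millions; reconstruction work that needs the real database margins
takes them as explicit `grand_total` arguments instead.

### What the generator does and does not show

Passing tests on synthetic data demonstrate that the pipeline's arithmetic,
ordering and conventions are correct and that implanted effects of known
size are recovered — not that real FAERS data are clean. Real extracts add
misspelled free-text drug names, partial dates, country-specific reporting
dynamics, correlated PT clusters (one clinical episode reported as several
terms) and reporting-rate drift, none of which are simulated. Two further
limitations are worth stating plainly:

- The published onset-bin profile is non-monotone (local peaks at 91–120
  and 151–180 days), which no two-parameter Weibull or lognormal can
  reproduce; the binned-MLE Weibull is the best of the supported families
  (the tests verify it dominates an exponential fit) but its bin
  probabilities still deviate from the printed bins by several percentage
  points, and its median sits below the printed 146 days. The fitted family
  is a modelling choice, documented as such, not a claim about the true
  onset law.
- With the realistic (very small) background rates of the hallmark ARIA
  terms, a desk-scale background corpus often yields `c = 0`, leaving the
  ROR undefined — exactly as the statistics define it. Tests that need
  defined RORs for implanted terms therefore use a uniform-probability test
  vocabulary.

## Numerical choices and degenerate inputs

- Zero cells: `NA` statistics plus failed criteria, never exceptions;
  continuity corrections only by explicit flag.
- MGPS: optimisation on transformed parameters keeps the constraint set
  open; a likelihood evaluation that underflows returns a large penalty.
  Component labels are not identifiable (the mixture is exchangeable), so
  recovery tests compare against the matching permutation.
- EBGM05 bisection brackets between the component quantiles, 200 iteration
  cap, `1e-6` relative tolerance.
- Monte-Carlo IC: `rgamma`-based Dirichlet draws; the seed argument
  restores the caller's RNG state afterwards.
- Empty inputs: empty files, empty strata and period edges before the first
  report produce explicit errors, warnings or missing markers as
  documented, never silent drops; malformed rows and fields are repaired to
  `NA` and counted.

## Problem sizes used by the test suite

The suite regenerates everything in code: unit fixtures of a few hundred
records, property checks on 1,000–2,000 random tables, MGPS recovery on
5,000 simulated pairs, coverage of the ROR interval on 2,000 replicates,
and 20-seed implanted-effect recovery plus 10-seed null-calibration runs at
4,000–5,000 background reports. These sizes were chosen so the full suite
and the reproduction script run comfortably on a laptop while keeping every
stochastic assertion's Monte-Carlo error well inside its asserted margin.
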