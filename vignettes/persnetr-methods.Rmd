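---
title: "Methods: egocentric network metrics and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: egocentric network metrics and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persnetr)
```

## The measurement model

A personal-network survey record has three parts: a *name generator*
(the ego lists an unlimited roster of network members), a *name
inter-relater* (presence and strength of ties among the first ten roster
members, coded 0 / 1 / 2 = especially close), and a *name interpreter*
(each alter's sex, race, age, kinship, distance, exercise habits,
perceived health influence, and — for the athlete cohort — football
affiliations). This shape has two consequences that drive the package's
design:

* **Network size is uncapped, tie-based metrics are not.** Size counts
  the whole roster; density, constraint, effective size and degrees are
  computed on the first-ten subnetwork, the only part for which ties
  exist. Records with longer rosters are marked `ties_truncated` in the
  metrics table rather than silently conflated.
* **Structure and composition use different denominators.** Composition
  summarises *all* alters (the interpreter covers the full roster), and
  every composition metric uses a per-metric non-missing denominator, so
  one blank attribute never invalidates a record. This choice — the
  instrument leaves attribute items optional — is why percentages can be
  exactly 0 or 100 with small denominators; the comparison stage reports
  `n_used` so such cells are visible.

## Structural scores

Constraint is the one structural score where tie *strength* enters. We
compute it on the ego-included graph: the ego `e` is a node with unit
weight to each of the first ten alters, alter–alter weights are the raw
strengths, and with symmetrized proportional weights
$p_{ij} = (z_{ij}+z_{ji}) / \sum_q (z_{iq}+z_{qi})$ the reported score is

$$C = 100 \sum_j \Big( p_{ej} + \sum_{q \ne e,j} p_{eq}\,p_{qj} \Big)^2 .$$

The $\times 100$ convention puts typical cohort medians in the 40–60
range and makes the degenerate single-contact network score exactly 100.
Two closed forms pin the implementation down: a star egonet (no
alter–alter ties) gives $C = 100/k$, and a complete binary egonet gives
$C = 100\,(2k-1)^2/k^3$ — every node of $K_{k+1}$ has $p = 1/k$ to each
neighbour, so each dyadic term is $(1/k + (k-1)/k^2)^2$. The test suite
checks both, together with elementwise agreement (to $10^{-9}$) against a
brute-force loop implementation of the published formula and against
`igraph::constraint()` on binary graphs. Whether the original analyses
dichotomized ties before computing constraint is not knowable from the
outside; both variants are exposed (`constraint_weighted`), and the
oracle covers both.

Constraint is *not* monotone in added ties: a new tie redistributes the
proportional weights of its two endpoints and can shrink other alters'
indirect contributions by more than the new dyad adds. Only density and
effective size carry monotonicity properties in the test suite;
constraint is instead pinned by its closed forms and oracles.

Effective size defaults to the binary simplification $k - 2t/k$ (roster
size in the tie section minus mean alter degree): it is the simplest
formula consistent with "number of non-redundant contacts", and it
coincides with Burt's weighted redundancy sum on dichotomized data. The
weighted variant is available (`method = "burt"`) and oracle-checked.

## Composition scores

The index of qualitative variation
$\mathrm{IQV} = \frac{K}{K-1}\big(1 - \sum_k p_k^2\big)$ is used with
$K=2$ (sex) and $K=3$ (race, categories White/Black/Other; finer input
codes are mapped by an explicit dictionary). Two identities double as
tests: for $K=2$, $\mathrm{IQV} = 4p(1-p)$, and with the majority-male
score $M$, $\mathrm{IQV} = 1 - M^2$ on fully observed rosters. The
same-race homogeneity proportion requires a known ego race and at least
two alters (one-alter networks carry no meaningful homogeneity signal
and are excluded, matching the montage convention of the instrument's
published uses).

## Statistical comparison

Univariate contrasts are Mann–Whitney (continuous; tie-corrected normal
approximation without continuity correction, exact enumeration when both
sides have ≤ 8 tie-free observations) and Pearson chi-squared without
Yates correction (a flag restores it). The adjusted contrast is ordinary
least squares of the metric on a group indicator plus six covariates —
age (years), race (non-White indicator), education (ordered 1–5),
employment (three dummies, employed reference), income ($1000s),
domestic status (not-married indicator) — on complete cases. These are
the most conventional minimal codings; the instrument's published uses
state the covariate list but not the codings, so both the list and the
codings are configurable (`covariate_spec()`). Dummy columns that are
constant within an analysis subset (e.g. no students among players in a
stratified contrast) are dropped exactly as `lm()` would drop an unused
factor level; genuinely collinear designs error, naming the columns. No
multiplicity correction is applied to the primary p-values — matching
the reporting convention the package mirrors — and a Benjamini–Hochberg
column is emitted as supplementary output only.

Stratified analyses re-run the same model within the players cohort:
White vs Black/Other (each also against controls), illness count
(0/1/2/3+ vs none), and illness type (sleep apnea / pain /
cardiometabolic vs none, with overlapping membership because one player
can carry several afflictions).

## The synthetic generator

Real records for the athlete cohort are confidential, so the generator
is first-class, tested code, not a fixture. Its distributional forms are
package choices (the sources only print medians and IQRs): roster sizes
are zero-truncated negative binomial, each ego draws a Beta tie
propensity with independent Bernoulli ties given it, incomes are
lognormal, alter race follows the homophily mixture
$h \cdot \text{ego race} + (1-h)\cdot \text{population}$, and all other
alter attributes are conditionally independent Bernoulli given the ego.
The true joint dependence among alter attributes (kin × distance × sex)
is unknown; conditional independence is a documented simplification, so
passing pipeline tests demonstrate *metric and inference correctness*,
not that real networks look like this.

Defaults were calibrated once, before any test was written, against the
published marginal targets (chronic-condition prevalence 42.6% vs 22.7%;
size medians 8 [5, 11] vs 7 [6, 10]; realized density medians 0.75 vs
0.68); `scripts/calibrate_defaults.R` reproduces the scan. The frozen
values: players NB(μ = 8.4, θ = 5) and Beta(1.85, 0.8), controls
NB(μ = 7.6, θ = 8) and Beta(2.0, 1.05). One target is unreachable within
the negative-binomial family: a median-7 size distribution cannot have a
lower quartile of 6 at any plausible dispersion, so the controls'
realized IQR is [5, 10] against the printed [6, 10].

### Presets and their calibration

`planted_effect_presets()` ships three configurations with known ground
truth. `"null"` gives both groups one parameter block, making every
contrast a true null — used to check that per-metric type-I error at
α = 0.05 stays within Monte-Carlo bounds of its nominal level.
`"structure-shift"` moves only size and density. `"paper-like"` encodes
the qualitative signature the package is designed to detect — *structure
parameters identical, composition shifted*: players draw more male
alters, fewer kin, and Black/Other egos a lower race-homophily weight.

Two design decisions in `"paper-like"` deserve explanation. First, the
structure blocks are equalized (both groups use the players'
calibration) rather than keeping the per-group size calibrations: the
generator draws size independently of the covariates given group, so any
size gap would survive covariate adjustment as a true difference,
whereas the signature being emulated is a *structurally null* contrast
(in the real cohorts, the raw 8-vs-7 size gap vanished under
adjustment). Second, the planted composition gaps (male share 0.75 vs
0.55, kin 0.34 vs 0.47) are wider than the published medians imply. The
ego-age distributions differ strongly between groups, so the group
indicator is partially collinear with age and the variance of its
coefficient is inflated; a design-time power calculation showed that
gaps at the published-median scale are detected in only ~70–75% of
replicates at n = 300/group, too unreliable for a preset whose purpose
is to make the signature reproducible. The shipped gaps keep the
published direction and push per-replicate detection near certainty, so
the joint signature rate is limited only by the six structural
true-nulls (≈ 0.95⁶ with strong mutual correlation, ~0.9).

## Problem sizes and numerical choices

Simulation-based tests use n = 300 per group: 200 replicates for null
calibration, 50 for signature recovery, 200 for the engine-recovery
property (fixed nine-alter rosters there, isolating the planted
sex-composition effect from roster-size noise). Oracle equivalence for
the structural scores runs over 1,000 random egonets with k ≤ 10 and
strengths in {0, 1, 2} at a 10⁻⁹ tolerance. Degenerate inputs are mapped
to missing, never to errors, inside the metric layer (size 0 → all tie
metrics `NA`; k < 2 → density `NA`; no known sexes → sex metrics `NA`),
while contract violations (duplicate ids, malformed categories, single
groups) fail fast at the parsing and comparison boundaries. Tie
disagreements between the two stored orientations keep the maximum
(conservative presence coding) and flag the record rather than dropping
it.

## Limitations

Cross-sectional only — no network change over time. The generator's
conditional-independence and distributional assumptions are
simplifications. The education/income/employment codings in the adjusted
model are conventions, config-exposed because the original codings are
unknowable. Constraint values for rosters above ten describe the
first-ten subnetwork only.
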