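---
title: "Water-balance traits, binomial survival models and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-balance traits, binomial survival models and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aridtrait)
```

## The scientific problem

Desiccation is a dominant mortality risk for insects in drying climates.
In a gravimetric desiccation assay, individuals are held under dry
conditions and weighed on a fixed schedule until they die or the assay
ends. From nothing but those repeated wet masses, a final dry mass and the
alive/dead record, four water-balance traits can be derived per individual:

* **Desiccation resistance (DR)** — survival time as a proportion of the
  assay horizon, in (0, 1]. A beetle alive at the final weighing of a 96-h
  assay scores exactly 1 (96 h / 96 h).
* **Water loss rate (WLR)** — the proportion of initial body water lost per
  hour (mg mg^-1 h^-1), estimated as the ordinary-least-squares slope of
  water mass (wet − dry) on time over the alive weighings, sign-flipped and
  divided by the initial water content.
* **Water loss tolerance (WLT)** — the percentage of initial water content
  lost at death: 100 × (initial wet − final wet) / initial water.
* **Fractional water content (fWC)** — initial water content divided by dry
  mass (mg mg^-1), the size-standardized water reserve.

`aridtrait` implements this derivation, the two binomial regression models
used to relate DR to the other traits and to nesting ecology, and the
phylogenetic comparative analyses (independent contrasts, a
contrast-variance signal test, contrast correlations) for the species-level
trait means — plus a mechanistic simulator that generates assay cohorts
with known ground truth, so every stage of the pipeline is testable without
any laboratory data.

## Interval-censored death and the midpoint rule

Weighings happen at 09:00, 12:00, 15:00 and 18:00 each day; with the
origin at the first morning weighing, the schedule is {0, 3, 6, 9} + 24k
hours — 3-h gaps within a day and a 15-h gap overnight. Death is therefore
never observed, only bracketed: an individual is last seen alive at one
weighing and first found dead at the next. `death_time()` takes the
midpoint (the median of the two bracketing times) as the survival time, for
*every* death interval. The midpoint rule is standard for overnight deaths;
we apply it to the 3-h daytime intervals too, for consistency — there the
midpoint is also the interval's least-worst point estimate, and the choice
affects survival times by at most 1.5 h. The final wet mass entering WLT
is likewise the arithmetic mean of the last-alive and first-dead masses.

Survivors are censored at the horizon: DR = 1, and their WLR, WLT and fWC
are left undefined — the physiological traits are measured only on
individuals whose death was observed, and survivors never enter the
regression designs.

Two further derivation rules guard data quality. The WLR regression
requires at least three alive weighings (a two-point slope is dominated by
balance noise); individuals failing this are excluded from the models and
logged in the trait table's `exclusions` attribute. Wet mass marginally
below dry mass is clamped to dry mass: at an *alive* weighing a deficit
above 2 % of dry mass is treated as a data inconsistency and errors, while
post-mortem deficits are clamped silently, because a fully desiccated
carcass legitimately weighs its dry mass plus noise.

## What the simulator emulates — and what it does not

`simulate_assay()` draws, per individual, a dry mass, a fractional water
content, a loss rate and a tolerance from per-species distributions
(truncated-normal by redraw, so all draws are positive and tolerances stay
in (0, 100]); water mass then declines *linearly* — constant mg/h — until
the lost fraction reaches the tolerance, which defines the true death
time `t* = WLT / (100 · WLR)`. Linear decline is the default because the
slope-based WLR estimator is exact under it, which makes the generator a
sharp oracle: on noise-free cohorts the derivation must recover WLR and
fWC to numerical precision, and DR and WLT to within schedule
discretization only (the test suite asserts exactly these bounds; the WLT
bound gains one extra term when a carcass dries out completely before its
first post-mortem weighing, since the recorded mass then floors at the dry
mass). An exponential-decay option (constant proportional loss, death time
`−log(1 − WLT/100)/WLR`) is available but off by default.

The demo species table (`demo_species_params()`, shipped as a CSV config
rather than hard-coded) describes eight dung-beetle species in three
nesting guilds — four tunnelers, three dwellers, one roller — with cohort
sizes of 7–39 individuals and species-level scales typical of temperate
dung beetles: dry mass roughly 8–250 mg, loss rates 0.005–0.018 h^-1,
tolerances 47–70 %. Between-individual coefficients of variation
(0.1–0.45 depending on trait and species) were chosen once to produce
realistic within-species spread and a realistic survivor fraction
(roughly 10–70 % of a species censored at 96 h); the balance noise default
in the demo configuration is 0.1 mg, the resolution of a typical assay
balance, and 0 in oracle tests. The parameter table also determines what
the simulator does *not* emulate: no humidity or temperature physics, no
behaviour or metabolic depression, no separation of cuticular from
respiratory water loss, and no correlation structure between traits beyond
what the species means induce. Passing tests therefore certify the
*estimators* under the stated measurement design, not any biological claim
about real cohorts.

## The two regression models

DR is a proportion, so it is modelled as a binomial response. The assay
does not dictate a trials denominator; we count survival in half-hour
units — 192 trials for a 96-h assay — because every midpoint survival time
(a multiple of 0.5 h on a whole-hour schedule) is then exactly
representable: DR = 64.5/96 becomes exactly 129/192. The choice is
recorded in every run's `fit_meta.json`, since it affects standard errors
(larger units shrink the trials count and inflate SEs proportionally).

The **general-effects model** is a binomial GLMM over the individuals that
died with all traits defined:

    successes/trials ~ log BM × nesting strategy + WLR + WLT + (1 | species)

with the dweller guild as the reference level, natural-log dry body mass,
and a Gaussian random intercept per species to absorb non-independence of
conspecifics. Fractional water content can be added as a candidate term
and is then offered to the pruning step. The **relative-effects model** is
a plain binomial GLM asking whether *relatively* large, slow-losing,
tolerant individuals resist longer consistently across species:

    successes/trials ~ species + scaled BM + scaled WLR + scaled WLT

where `scaled_x = (x − species mean)/species mean`, a dimensionless
within-species deviation (0 at the species mean, 1 at twice it), and the
reference species is configurable.

Both fitters are written in the package. The GLM is maximized by
iteratively reweighted least squares with step-halving, run to a relative
log-likelihood change below 1e-10 (at most 100 iterations) and verified
against the score equations `X'(y − n p̂) = 0`; non-convergence and
separation are errors, never silent results. The GLMM integrates its
single scalar random effect by **adaptive Gauss–Hermite quadrature**
(default 15 nodes): per species the integrand is recentred at its
conditional mode (found by Newton steps) and rescaled by the local
curvature, which makes 15 nodes accurate to well below 1e-6 in
log-likelihood (the suite checks 15 vs 31 nodes). One scalar random effect
makes quadrature cheap and strictly more accurate than a Laplace
approximation. Standard errors come from the numerically differentiated
Hessian of the marginal log-likelihood; a random-SD estimate at the
boundary (≈0) is reported with a warning, being the legitimate degenerate
limit in which the GLMM collapses to the GLM. Inference is by Wald z
throughout, matching the usual published table layout; AIC counts the
fixed effects plus one variance parameter.

"Variance explained" is reported as the squared Pearson correlation
between observed and fitted proportions, labelled as such in every report
(conventions differ, so the metric is always named); a deviance-based
pseudo-R² is reported alongside for the GLM. `prune_nonsignificant()`
implements the customary backward simplification: non-significant
interactions are demoted to additive terms first, then candidate main
effects are dropped largest-p-first at α = 0.05, refitting after every
change and keeping an audit log. Multi-coefficient terms are judged by a
multi-df Wald test.

## Phylogenetic signal and contrast correlations

Species are not independent data points. The comparative layer consumes a
rooted, fully bifurcating tree with strictly positive branch lengths
(polytomies and zero branches are rejected — contrast standardization
divides by √v) and the species-mean traits, with nesting strategy entering
through an ordinal coding (dweller 0 < tunneler 1 < roller 2, by
increasing investment in relocating the brood; the ordering is an
assumption, flagged in all output and reconfigurable).

`independent_contrasts()` implements the classic pruning algorithm:
contrast `(x_i − x_j)/√(v_i + v_j)` at each internal node, ancestral value
the 1/v-weighted mean, parent branch lengthened by `v_i v_j/(v_i + v_j)`.
The test suite verifies it two independent ways: against `ape::pic`, and
against a brute-force GLS identity — the sum of squared standardized
contrasts equals `x'C⁻¹x` minus the phylogenetic-mean term, computed from
the full Brownian covariance matrix — on hundreds of random trees to 1e-8.

**Signal statistic.** The variance of the standardized contrasts: low
variance means close relatives differ less than their branch lengths
predict, i.e. phylogenetic signal. We use the mean-centred population
variance (denominator n); the convention only rescales observed and null
identically, so the randomization p-value is unaffected (tested via affine
invariance). Significance comes from a tip-shuffle null: trait values are
permuted across tips with the topology fixed (999 shuffles by default,
minimum 99), and the one-tailed p-value is the add-one-corrected
proportion of null variances at or below the observed one — so p > 0
always, and under no signal the test is exactly calibrated (the suite
measures type-I error over 500 shuffled-label datasets). A two-tailed
variant is available by flag.

**Contrast correlation.** Contrasts have arbitrary sign and zero
expectation, so trait association uses the correlation through the origin
`r = Σxᵢyᵢ/√(Σxᵢ²Σyᵢ²)`, with a parametric p from `t = r√((n−1)/(1−r²))`
on n−1 degrees of freedom (n = number of contrasts) and, optionally, a
sign-flip randomization p — sign flips being the exchangeable operation
for contrasts. Both are reported because the permutation variant makes no
normality assumption at the small n typical of species-level analyses.

## Numerical and design choices

* **Seeding.** Every generator takes an explicit seed and restores the
  caller's RNG state. The pipeline derives per-stage substreams from the
  single run seed by hashing the stage name, so adding a stage never
  perturbs earlier stages' draws; identical config + seed gives
  byte-identical artifacts (hash-checked in the suite).
* **Degenerate inputs.** Constant traits make the signal test meaningless
  and error; a single contrast has no variance and errors; rank-deficient
  designs error naming the aliased columns; separation is detected by
  diverging IRLS coefficients.
* **Problem sizes in the test suite.** The simulation-based checks use 500
  random trees (≤ 8 tips) for the GLS oracle, 500 datasets × 199 shuffles
  for type-I calibration with 60 × 999 for power, 200 replicates at the
  study-like scale (8 species, 7–39 individuals) for Wald coverage and 100
  at 30 × 50 for bias, and 100 replicates for the pruning rates — sizes
  chosen to keep Monte-Carlo error a few times smaller than the tolerance
  each property is tested at.

## Known limitations

The gravimetric method cannot attribute water loss to cuticular,
respiratory or excretory routes, and the derived WLR assumes loss is
linear in time between weighings. The trials convention for the binomial
response is a modelling choice, not a property of the assay; comparisons
of SEs across studies must account for it. Wald inference at 8 species is
approximate: maximum likelihood underestimates the random-intercept SD
with so few groups, so the intercept's 95 % interval covers at roughly
89–91 % in our simulations while the slope intervals are calibrated
(≈95 %); pooled fixed-effect coverage stays comfortably in the 90–99 %
band. Also and the ordinal coding of nesting strategy imposes an
ordering the data cannot test. With eight tips the signal test has limited
power, so non-significance there is weak evidence of no signal.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(
  list(n_randomizations = 199),
  out_dir = "aridtrait-demo", seed = 11
)
res$manifest
tidy(res$results$fit_general)
res$results$signal$signal
```
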