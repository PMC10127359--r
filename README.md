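# aridtrait

Desiccation-resistance analysis for gravimetric survival assays on
insects: trait derivation from repeated weighings, binomial survival
models, and phylogenetic comparative tests — with a mechanistic simulator
providing ground truth for every stage.

## The problem

In a gravimetric desiccation assay, individuals (here: dung beetles from
three nesting guilds — tunnelers, dwellers, rollers) are held under dry
conditions for 96 h and weighed at 09:00, 12:00, 15:00 and 18:00 each day
until they die or the assay ends. From the weighing record, the final dry
mass and the alive/dead flags, four water-balance traits are derived per
individual:

* **DR**, desiccation resistance = survival time / 96 h ∈ (0, 1], with
  interval-censored deaths placed at the midpoint of the last-alive /
  first-dead weighings (a survivor of the full assay scores exactly
  1 = 96 h/96 h);
* **WLR**, water loss rate (mg mg⁻¹ h⁻¹) = −(OLS slope of water mass on
  time over alive weighings) / initial water content;
* **WLT**, water loss tolerance (%) = 100 × (initial wet − final wet) /
  initial water content, the fatal fraction of body water;
* **fWC**, fractional water content = initial water content / dry mass.

Two binomial regressions relate DR (modelled as successes out of 192
half-hour units) to the other traits:

    general:  DR ~ log BM × nesting strategy + WLR + WLT + (1 | species)
    relative: DR ~ species + scaled BM + scaled WLR + scaled WLT

The GLM is fitted from scratch by iteratively reweighted least squares;
the GLMM integrates its species random intercept by adaptive
Gauss–Hermite quadrature (15 nodes), cross-checked against `lme4` in the
test suite. A phylogenetic layer computes Felsenstein independent
contrasts by the pruning algorithm, measures phylogenetic signal as the
variance of standardized contrasts against a tip-shuffle randomization
null, and reports contrast correlations through the origin.

## Worked example

```r
library(aridtrait)
res <- run_pipeline(list(n_randomizations = 199), out_dir = "demo-run", seed = 11)
```

This simulates an eight-species cohort (7–39 individuals per species,
demo parameters shipped as `inst/extdata/demo_species_params.csv`) plus a
pure-birth tree, derives the traits, runs the comparative screen and fits
both models, writing 12 hash-manifested artifacts. The general-model
report (`demo-run/general_fit.tsv`) from that exact call prints:

```
# AIC = 1005.56 | pseudo-R2 (sq. obs-fitted correlation) = 0.902 | n = 99 | groups = 8
term                                    estimate_se        z        p_value    stars
(Intercept)                             -0.438 ± 0.183     -2.395   1.66e-02   *
log_body_mass                           0.218 ± 0.055      3.944    8.03e-05   ***
nesting_strategyroller                  12.689 ± 6.049     2.098    3.59e-02   *
nesting_strategytunneler                0.238 ± 0.172      1.382    1.67e-01   NS
water_loss_rate                         -216.004 ± 5.169   -41.786  0.00e+00   ***
water_loss_tolerance                    0.047 ± 0.002      24.491   1.85e-132  ***
fractional_water_content                0.075 ± 0.020      3.707    2.10e-04   ***
log_body_mass:nesting_strategyroller    -4.050 ± 1.900     -2.132   3.30e-02   *
log_body_mass:nesting_strategytunneler  -0.190 ± 0.058     -3.274   1.06e-03   **
```

Read: on the logit scale of survival proportion, individuals with faster
water loss die much sooner (the WLR coefficient is per unit rate, hence
its magnitude), higher tolerance buys survival, and the body-mass slope
differs by guild (the interaction rows). The signal screen
(`demo-run/signal.tsv`) from the same run:

```
trait  var_contr   p_value  n_randomizations
dr     3.514       0.725    199
wlr    0.00259     0.965    199
wlt    1386.685    0.155    199
fwc    2.560       0.110    199
bm     1562755.767 0.835    199
ns     38.371      0.775    199
```

— no signal, as expected: the demo tree is simulated independently of the
species parameters, so species means are random labels on the tips. Low
contrast variance relative to the tip-shuffle null (small p) would
indicate related species resembling each other.

Individual stages are plain functions on data frames and pipe together:

```r
sim    <- simulate_assay(assay_config(demo_species_params(), 10, seed = 1))
traits <- derive_traits(sim$individuals, sim$weighings)
fit    <- traits |> build_general_design(include_fwc = TRUE) |> fit_glmm()
tidy(fit); glance(fit); autoplot(fit)
```

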