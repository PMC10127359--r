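# Shared fixtures and independent oracles, all built in code.

# Brute-force Brownian GLS sum of squares: x'C^-1 x minus the
# phylogenetic-mean term, computed from the full Brownian covariance matrix
# C (C_ij = shared path length from the root). Under Brownian motion this
# equals the sum of squared standardized contrasts; it shares no code with
# the pruning algorithm it checks.
gls_contrast_ss <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  Cinv <- solve(C)
  one <- rep(1, length(x))
  mu <- drop(t(one) %*% Cinv %*% x) / drop(t(one) %*% Cinv %*% one)
  drop(t(x) %*% Cinv %*% x) - mu^2 * drop(t(one) %*% Cinv %*% one)
}

# Single-individual measurement series.
make_series <- function(time_h, wet_mass_mg, alive) {
  tibble::tibble(time_h = time_h, wet_mass_mg = wet_mass_mg, alive = alive)
}

# Deterministic (zero-CV, noise-free) assay configuration: every individual
# of a species shares its parameters exactly.
noise_free_config <- function(wlr = c(0.01, 0.008), wlt = c(64, 50),
                              dry = c(40, 120), fwc = c(1.5, 2.5),
                              n = 4, seed = 1) {
  k <- length(wlr)
  assay_config(
    tibble::tibble(
      species = paste0("sp", seq_len(k)),
      nesting_strategy = rep(c("tunneler", "dweller", "roller"), length.out = k),
      mean_dry_mass_mg = rep_len(dry, k), cv_dry_mass = 0,
      mean_fwc = rep_len(fwc, k), mean_wlr_per_h = wlr, cv_wlr = 0,
      mean_wlt_pct = rep_len(wlt, k)
    ),
    n_individuals = n, measurement_noise_sd_mg = 0, seed = seed
  )
}

# Memoized demo-scale trait table shared by several tests.
derive_traits_demo_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_assay(assay_config(
        demo_species_params(),
        n_individuals = demo_species_params()$n_individuals,
        measurement_noise_sd_mg = 0.1, seed = 20260101
      ))
      cache <<- derive_traits(sim$individuals, sim$weighings)
    }
    cache
  }
})

# Negative binomial log-likelihood for a design matrix, used by the
# generic-optimizer oracle for the IRLS fitter.
neg_binom_loglik <- function(beta, X, y, n) {
  -sum(dbinom(y, n, plogis(drop(X %*% beta)), log = TRUE))
}
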