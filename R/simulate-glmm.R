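#' Simulate a binomial dataset with a group random intercept
#'
#' Ground-truth generator for the mixed-model fitter: covariates are drawn
#' i.i.d. standard normal, group (species) intercept deviations are
#' `Normal(0, sigma_species^2)`, and the response is
#' `Binomial(trials, logistic(X beta + u[species]))`. With
#' `sigma_species = 0` the data satisfy a plain GLM, the degenerate limit
#' against which the GLMM fitter is checked.
#'
#' @param beta Coefficient vector; the first element is the intercept, the
#'   rest belong to covariates `x1, x2, ...`.
#' @param sigma_species Random-intercept SD (>= 0).
#' @param n_species Number of groups.
#' @param n_per_species Individuals per group (single value or vector of
#'   length `n_species`).
#' @param trials Binomial trials per individual (>= 1).
#' @param seed Integer seed.
#' @return Tibble with `species`, covariates, `successes`, `trials`, and the
#'   true group deviation `u_true`.
#' @export
simulate_glmm_dataset <- function(beta, sigma_species, n_species, n_per_species,
                                  trials, seed = 1) {
  stopifnot(is.numeric(beta), length(beta) >= 1)
  check_scalar(sigma_species, "sigma_species", lower = 0)
  check_scalar(n_species, "n_species", lower = 2, integer = TRUE)
  check_scalar(trials, "trials", lower = 1, integer = TRUE)
  n_per <- as.integer(rep_len(n_per_species, n_species))
  stopifnot(all(n_per >= 1))
  p_cov <- length(beta) - 1
  with_seed(seed, {
    u <- rnorm(n_species, 0, sigma_species)
    sp <- factor(rep(paste0("sp", seq_len(n_species)), times = n_per),
      levels = paste0("sp", seq_len(n_species))
    )
    N <- length(sp)
    X <- cbind(1, matrix(rnorm(N * p_cov), N, p_cov))
    eta <- drop(X %*% beta) + u[as.integer(sp)]
    out <- tibble::tibble(
      species = sp,
      successes = rbinom(N, trials, plogis(eta)),
      trials = as.integer(trials),
      u_true = u[as.integer(sp)]
    )
    if (p_cov > 0) {
      covs <- tibble::as_tibble(as.data.frame(X[, -1, drop = FALSE]))
      names(covs) <- paste0("x", seq_len(p_cov))
      out <- dplyr::bind_cols(out[, "species"], covs, out[, c("successes", "trials", "u_true")])
    }
    out
  })
}
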