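# Binomial logistic regression fitted from scratch by iteratively reweighted
# least squares (IRLS). Each IRLS step solves the weighted normal equations
# X'WX beta = X'Wz with W = n p (1-p) and working response
# z = eta + (y - n p) / W; at convergence the score equations
# X'(y - n p) = 0 hold and the inverse of X'WX is the Wald covariance.

binom_loglik <- function(y, n, eta) {
  sum(dbinom(y, n, plogis(eta), log = TRUE))
}

#' Fit a binomial GLM by iteratively reweighted least squares
#'
#' Logit-link binomial regression maximized by IRLS until the relative
#' log-likelihood change falls below `tol` and the score norm below
#' `grad_tol`. Standard errors come from the observed information
#' `(X'WX)^{-1}`; Wald z and two-sided normal p-values follow. Diverging
#' coefficients (complete separation) and non-convergence raise errors
#' rather than returning a silent result.
#'
#' @param design A [design_spec()].
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-10).
#' @param grad_tol Score (gradient) norm required at the optimum.
#' @return Object of class `c("wb_glm", "wb_fit")` with coefficients,
#'   standard errors, Wald table, log-likelihood, AIC, two pseudo-R^2
#'   statistics (squared Pearson correlation between observed and fitted
#'   proportions, and the deviance-based 1 - D/D_null) and the design (kept
#'   for refits during pruning).
#' @examples
#' d <- tibble::tibble(x = rnorm(50), successes = rbinom(50, 20, 0.4), trials = 20)
#' fit <- fit_glm(design_spec(d, ~x))
#' tidy(fit)
#' @export
fit_glm <- function(design, max_iter = 100, tol = 1e-10, grad_tol = 1e-8) {
  stopifnot(inherits(design, "design_spec"))
  X <- design$X
  y <- design$y
  n <- design$n
  beta <- rep(0, ncol(X))
  ll_old <- binom_loglik(y, n, drop(X %*% beta))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(n * p * (1 - p), 1e-12)
    z <- eta + (y - n * p) / w
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new) || any(abs(beta_new) > 1e8)) {
      abort("IRLS diverged: complete separation or rank problem")
    }
    ll_new <- binom_loglik(y, n, drop(X %*% beta_new))
    step_ok <- is.finite(ll_new)
    # step-halve if the full IRLS step overshoots the likelihood
    half <- 0
    while ((!step_ok || ll_new < ll_old - 1e-8) && half < 30) {
      beta_new <- (beta + beta_new) / 2
      ll_new <- binom_loglik(y, n, drop(X %*% beta_new))
      step_ok <- is.finite(ll_new)
      half <- half + 1
    }
    delta <- abs(ll_new - ll_old) / (abs(ll_old) + 1e-10)
    beta <- beta_new
    ll_old <- ll_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  score <- drop(crossprod(X, y - n * p))
  if (!converged) abort("IRLS failed to converge within `max_iter` iterations")
  if (max(abs(score)) > grad_tol * max(1, sum(n))) {
    abort("IRLS stopped away from the score equations; possible separation")
  }
  w <- n * p * (1 - p)
  info <- crossprod(X * sqrt(w))
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  ll <- binom_loglik(y, n, eta)
  k <- ncol(X)
  # null (intercept-only) deviance for the deviance pseudo-R^2
  p0 <- sum(y) / sum(n)
  ll_null <- binom_loglik(y, n, rep(qlogis(p0), length(y)))
  ll_sat <- binom_loglik(y, n, qlogis(pmin(pmax(y / n, 1e-12), 1 - 1e-12)))
  dev <- 2 * (ll_sat - ll)
  dev_null <- 2 * (ll_sat - ll_null)
  obs_prop <- y / n
  r2_cor <- if (length(obs_prop) < 2 || sd(obs_prop) == 0 || sd(p) == 0) {
    NA_real_
  } else {
    stats::cor(obs_prop, p)^2
  }
  structure(
    list(
      coefficients = setNames(beta, colnames(X)),
      se = setNames(se, colnames(X)),
      vcov = vcov,
      z = beta / se,
      p_values = 2 * pnorm(-abs(beta / se)),
      log_likelihood = ll,
      deviance = dev,
      null_deviance = dev_null,
      aic = -2 * ll + 2 * k,
      pseudo_r2 = r2_cor,
      pseudo_r2_deviance = if (dev_null > 0) 1 - dev / dev_null else NA_real_,
      fitted = p,
      converged = converged,
      iterations = it,
      n_obs = nrow(X),
      n_groups = NA_integer_,
      random_sd = NA_real_,
      design = design
    ),
    class = c("wb_glm", "wb_fit")
  )
}
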