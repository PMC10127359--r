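# Binomial GLMM with a single Gaussian random intercept per group, fitted by
# maximum likelihood with the random effect integrated out by adaptive
# Gauss-Hermite quadrature. The random effect is parameterized as sigma * u
# with u ~ N(0, 1); for each group the integrand
#   h(u) = sum_i log Binom(y_ij | n_ij, logistic(x_ij'beta + sigma u)) + log phi(u)
# is maximized by Newton steps to find the conditional mode, and the
# quadrature grid is recentred and rescaled there:
#   integral exp(h) du ~= sqrt(2) tau sum_k w_k exp(h(u_hat + sqrt(2) tau z_k) + z_k^2)
# with tau = (-h''(u_hat))^{-1/2}. One scalar random effect makes this both
# cheap and considerably more accurate than a Laplace approximation.

group_mode <- function(eta_fix, y, n, sigma, max_iter = 50) {
  u <- 0
  for (it in seq_len(max_iter)) {
    p <- plogis(eta_fix + sigma * u)
    g <- sigma * sum(y - n * p) - u
    hess <- -sigma^2 * sum(n * p * (1 - p)) - 1
    step <- g / hess
    u_new <- u - step
    if (abs(u_new - u) < 1e-10) {
      u <- u_new
      break
    }
    u <- u_new
  }
  p <- plogis(eta_fix + sigma * u)
  list(mode = u, tau = 1 / sqrt(sigma^2 * sum(n * p * (1 - p)) + 1))
}

# Marginal log-likelihood of (beta, sigma) by adaptive Gauss-Hermite.
agq_loglik <- function(beta, sigma, design, gh) {
  eta_fix <- drop(design$X %*% beta)
  idx <- split(seq_along(design$y), design$group)
  total <- 0
  for (ii in idx) {
    y <- design$y[ii]
    n <- design$n[ii]
    ef <- eta_fix[ii]
    if (sigma < 1e-8) {
      total <- total + sum(dbinom(y, n, plogis(ef), log = TRUE))
      next
    }
    m <- group_mode(ef, y, n, sigma)
    uk <- m$mode + sqrt(2) * m$tau * gh$x
    hk <- vapply(uk, function(u) {
      sum(dbinom(y, n, plogis(ef + sigma * u), log = TRUE)) + dnorm(u, log = TRUE)
    }, numeric(1))
    lse <- hk + gh$x^2 + log(gh$w)
    mx <- max(lse)
    total <- total + log(sqrt(2) * m$tau) + mx + log(sum(exp(lse - mx)))
  }
  total
}

#' Fit a binomial GLMM with a species random intercept
#'
#' Maximum-likelihood fit of a logit-link binomial mixed model with one
#' Gaussian random intercept per group (species), the random effect
#' integrated out by adaptive Gauss-Hermite quadrature (default 15 nodes).
#' Fixed effects and the random-intercept SD are optimized jointly; standard
#' errors come from the numerically differentiated Hessian of the marginal
#' log-likelihood at the optimum. A boundary estimate (SD near 0) is
#' reported with a warning, not an error, since it is the legitimate
#' degenerate limit in which the model collapses to [fit_glm()].
#'
#' @param design A [design_spec()] with a grouping factor.
#' @param quadrature_points Number of Gauss-Hermite nodes (default 15).
#' @param start Optional starting values (fixed effects then sigma).
#' @return Object of class `c("wb_glmm", "wb_fit")`; AIC counts the fixed
#'   effects plus one parameter for the random-intercept variance.
#' @examples
#' d <- simulate_glmm_dataset(beta = c(-0.5, 0.8), sigma_species = 0.5,
#'                            n_species = 8, n_per_species = 20, trials = 50, seed = 1)
#' fit <- fit_glmm(design_spec(d, ~x1, group = "species"))
#' glance(fit)
#' @export
fit_glmm <- function(design, quadrature_points = 15, start = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(design$group)) abort("`design` has no grouping factor; use fit_glm()")
  check_scalar(quadrature_points, "quadrature_points", lower = 2, integer = TRUE)
  gh <- pracma::gaussHermite(as.integer(quadrature_points))
  k <- ncol(design$X)
  if (is.null(start)) {
    glm0 <- fit_glm(strip_group(design))
    start <- c(coef(glm0), 0.5)
  }
  stopifnot(length(start) == k + 1)
  negll <- function(par) {
    val <- -agq_loglik(par[seq_len(k)], abs(par[k + 1]), design, gh)
    if (!is.finite(val)) 1e10 else val
  }
  opt <- nlminb(start, negll, control = list(iter.max = 500, eval.max = 1000))
  if (opt$convergence != 0 && !opt$message %in% c("relative convergence (4)", "both X-convergence and relative convergence (5)")) {
    # nlminb convergence codes vary; accept any result whose gradient is flat
    g <- numeric_grad(negll, opt$par)
    if (max(abs(g)) > 1e-2) {
      abort(paste0("GLMM optimization did not converge: ", opt$message))
    }
  }
  par <- unname(opt$par)
  par[k + 1] <- abs(par[k + 1])
  sigma <- par[k + 1]
  boundary <- sigma < 1e-3
  if (boundary) {
    warn("random-intercept SD estimated at the boundary (~0); fit reported")
  }
  H <- optimHess(par, negll)
  vcov_all <- tryCatch(solve(H), error = function(e) {
    matrix(NA_real_, k + 1, k + 1)
  })
  if (boundary && anyNA(vcov_all)) {
    # at the boundary the sigma row of the Hessian can be singular; fall back
    # to the fixed-effect block
    vcov_all <- matrix(NA_real_, k + 1, k + 1)
    vcov_all[seq_len(k), seq_len(k)] <- solve(H[seq_len(k), seq_len(k)])
  }
  beta <- setNames(par[seq_len(k)], colnames(design$X))
  se <- sqrt(pmax(diag(vcov_all)[seq_len(k)], 0))
  ll <- -opt$objective
  eta <- drop(design$X %*% beta)
  # fitted proportions at the conditional modes of the random effects
  idx <- split(seq_along(design$y), design$group)
  u_modes <- vapply(idx, function(ii) {
    if (sigma < 1e-8) 0 else group_mode(eta[ii], design$y[ii], design$n[ii], sigma)$mode
  }, numeric(1))
  u_long <- rep(NA_real_, length(design$y))
  for (j in seq_along(idx)) u_long[idx[[j]]] <- u_modes[j]
  fitted <- plogis(eta + sigma * u_long)
  obs_prop <- design$y / design$n
  r2_cor <- if (length(obs_prop) < 2 || sd(obs_prop) == 0 || sd(fitted) == 0) {
    NA_real_
  } else {
    stats::cor(obs_prop, fitted)^2
  }
  structure(
    list(
      coefficients = beta,
      se = setNames(se, names(beta)),
      vcov = vcov_all[seq_len(k), seq_len(k), drop = FALSE],
      z = beta / se,
      p_values = 2 * pnorm(-abs(beta / se)),
      random_sd = sigma,
      random_effects = setNames(sigma * u_modes, names(idx)),
      log_likelihood = ll,
      aic = -2 * ll + 2 * (k + 1),
      pseudo_r2 = r2_cor,
      pseudo_r2_deviance = NA_real_,
      fitted = fitted,
      converged = TRUE,
      boundary = boundary,
      quadrature_points = as.integer(quadrature_points),
      n_obs = nrow(design$X),
      n_groups = nlevels(design$group),
      design = design
    ),
    class = c("wb_glmm", "wb_fit")
  )
}

strip_group <- function(design) {
  design$group <- NULL
  design$group_name <- NULL
  design
}

numeric_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x
    xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}
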