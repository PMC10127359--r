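test_that("simulated GLMM datasets have the documented structure", {
  d <- simulate_glmm_dataset(
    beta = c(0, 0), sigma_species = 0, n_species = 10,
    n_per_species = 200, trials = 1, seed = 5
  )
  expect_equal(nrow(d), 2000)
  # beta = 0, sigma = 0: overall success proportion near logistic(0) = 0.5
  p_hat <- mean(d$successes / d$trials)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 2000))
  expect_true(all(tapply(d$u_true, d$species, function(u) length(unique(u))) == 1))
  expect_identical(
    simulate_glmm_dataset(c(1, -1), 0.3, 4, 5, 10, seed = 2),
    simulate_glmm_dataset(c(1, -1), 0.3, 4, 5, 10, seed = 2)
  )
})

test_that("zero between-group variance collapses the GLMM to the GLM", {
  d <- simulate_glmm_dataset(
    beta = c(-0.4, 0.7), sigma_species = 0, n_species = 8,
    n_per_species = 25, trials = 50, seed = 8
  )
  des <- design_spec(d, ~x1, group = "species")
  fm <- suppressWarnings(fit_glmm(des))
  fg <- fit_glm(design_spec(d, ~x1))
  expect_lt(fm$random_sd, 0.05)
  expect_equal(coef(fm), coef(fg), tolerance = 1e-3)
  # with sigma at 0 the marginal likelihood equals the GLM likelihood
  expect_equal(fm$log_likelihood, fg$log_likelihood, tolerance = 1e-4)
})

test_that("adaptive quadrature agrees with lme4's nAGQ fit", {
  skip_if_not_installed("lme4")
  d <- simulate_glmm_dataset(
    beta = c(-0.8, 0.5, -1.0), sigma_species = 0.6, n_species = 12,
    n_per_species = 20, trials = 96, seed = 13
  )
  fm <- fit_glmm(design_spec(d, ~ x1 + x2, group = "species"))
  ref <- lme4::glmer(
    cbind(successes, trials - successes) ~ x1 + x2 + (1 | species),
    data = d, family = stats::binomial, nAGQ = 15
  )
  expect_equal(unname(coef(fm)), unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fm$random_sd, sqrt(unlist(lme4::VarCorr(ref))[[1]]), tolerance = 1e-3)
  expect_equal(unname(fm$se), unname(sqrt(diag(as.matrix(vcov(ref))))), tolerance = 5e-3)
})

test_that("the quadrature order is converged at the default node count", {
  d <- simulate_glmm_dataset(
    beta = c(-0.5, 0.6), sigma_species = 0.8, n_species = 8,
    n_per_species = 15, trials = 192, seed = 17
  )
  des <- design_spec(d, ~x1, group = "species")
  f15 <- fit_glmm(des, quadrature_points = 15)
  f31 <- fit_glmm(des, quadrature_points = 31, start = c(coef(f15), f15$random_sd))
  expect_lt(abs(f15$log_likelihood - f31$log_likelihood), 1e-6)
})

test_that("parameters are recovered within Wald error at a generous scale", {
  beta <- c(-0.8, 0.5, -1.0)
  d <- simulate_glmm_dataset(beta, 0.6, 30, 50, trials = 192, seed = 19)
  fm <- fit_glmm(design_spec(d, ~ x1 + x2, group = "species"))
  expect_true(all(abs(coef(fm) - beta) <= 3 * fm$se))
  expect_lt(abs(fm$random_sd - 0.6), 0.25)
  expect_equal(fm$aic, -2 * fm$log_likelihood + 2 * 4)
})

test_that("GLMM input contracts are enforced", {
  d <- simulate_glmm_dataset(c(0, 1), 0.5, 4, 10, 20, seed = 23)
  expect_error(fit_glmm(design_spec(d, ~x1)), "grouping factor")
  d$species <- factor("only_one")
  expect_error(design_spec(d, ~x1, group = "species"), "at least 2 levels")
})
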