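test_that("death time is the midpoint of the bracketing weighings, for every interval", {
  overnight <- make_series(c(48, 51, 54, 57, 72), c(90, 88, 86, 84, 80),
                           c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(death_time(overnight, 96), list(survival_h = 64.5, died = TRUE))
  within_day <- make_series(c(0, 3, 6, 9), c(100, 97, 94, 91),
                            c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(death_time(within_day, 96)$survival_h, 7.5)
  survivor <- make_series(c(0, 48, 96), c(100, 95, 90), rep(TRUE, 3))
  expect_equal(death_time(survivor, 96), list(survival_h = 96, died = FALSE))
  expect_error(death_time(survivor[0, ], 96), "at least one observation")
})

test_that("series invariants are enforced", {
  expect_error(death_time(make_series(c(0, 0), c(1, 1), c(TRUE, TRUE))), "increasing")
  expect_error(death_time(make_series(c(0, 3), c(1, 1), c(FALSE, FALSE))), "alive")
  expect_error(
    death_time(make_series(c(0, 3, 6), c(1, 1, 1), c(TRUE, FALSE, TRUE))),
    "monotone"
  )
})

test_that("desiccation resistance is survival over horizon, capped at 1", {
  expect_equal(desiccation_resistance(48, 96), 0.5)
  expect_equal(desiccation_resistance(96, 96), 1)
  expect_equal(desiccation_resistance(64.5, 96), 0.671875)
  expect_error(desiccation_resistance(100, 96), "exceed")
  expect_error(desiccation_resistance(0, 96), "positive")
})

test_that("water loss rate is the OLS slope normalized by initial water", {
  s <- make_series(c(0, 3, 6), c(100, 97, 94), rep(TRUE, 3))
  expect_equal(water_loss_rate(s, dry_mass_mg = 40), 1 / 60, tolerance = 1e-12)
  flat <- make_series(c(0, 3, 6), c(100, 100, 100), rep(TRUE, 3))
  expect_equal(water_loss_rate(flat, 40), 0)
  two <- make_series(c(0, 3, 6), c(100, 97, 94), c(TRUE, TRUE, FALSE))
  out <- water_loss_rate(two, 40)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "alive observations")
})

test_that("water loss tolerance averages the bracketing masses at death", {
  s <- make_series(c(0, 3, 6), c(100, 80, 74), c(TRUE, TRUE, FALSE))
  # final wet = (80 + 74)/2 = 77; initial water = 60 -> 100*(100-77)/60
  expect_equal(water_loss_tolerance(s, 40), 100 * 23 / 60)
  exact <- make_series(c(0, 3), c(100, 70), c(TRUE, FALSE))
  expect_equal(water_loss_tolerance(exact, 40), 100 * (100 - 85) / 60)
  survivor <- make_series(c(0, 3), c(100, 99), c(TRUE, TRUE))
  expect_error(water_loss_tolerance(survivor, 40), "died")
})

test_that("fractional water content is initial water over dry mass", {
  s <- make_series(c(0, 3), c(100, 95), c(TRUE, FALSE))
  expect_equal(fractional_water_content(s, 40), 1.5)
  dryish <- make_series(c(0, 3), c(40, 39.9), c(TRUE, FALSE))
  expect_warning(out <- fractional_water_content(dryish, 40), "0")
  expect_equal(out, 0)
})

test_that("wet mass marginally below dry mass is clamped; large alive deficits error", {
  s <- make_series(c(0, 3, 6), c(100, 49.8, 49.5), c(TRUE, TRUE, FALSE))
  expect_warning(wlt <- water_loss_tolerance(s, 50), "clamped")
  expect_equal(wlt, 100) # both bracketing masses clamp to dry: all water lost
  s2 <- make_series(c(0, 3, 6), c(100, 45, 44), c(TRUE, TRUE, FALSE))
  expect_error(suppressWarnings(water_loss_tolerance(s2, 50)), "2%")
  # a fully desiccated carcass weighed just under dry mass is not an error
  s3 <- make_series(c(0, 3, 6), c(100, 60, 49.7), c(TRUE, TRUE, FALSE))
  expect_silent(wlt3 <- water_loss_tolerance(s3, 50))
  expect_equal(wlt3, 100 * (100 - 55) / 50)
})

test_that("noise-free simulations round-trip through trait derivation", {
  cfg <- noise_free_config(wlr = c(0.01, 0.008), wlt = c(64, 50), n = 5)
  sim <- simulate_assay(cfg)
  traits <- derive_traits(sim$individuals, sim$weighings, horizon_h = 96)
  truth <- sim$ground_truth
  dead <- traits$died_in_assay
  m <- match(traits$individual_id, truth$individual_id)

  # the rate regression is exact on noise-free linear decline
  expect_equal(traits$water_loss_rate[dead], truth$wlr_true[m][dead], tolerance = 1e-9)
  expect_equal(traits$fractional_water_content[dead], truth$fwc_true[m][dead], tolerance = 1e-9)

  # survival and tolerance carry only schedule-discretization error
  sched <- sim$schedule
  for (i in which(dead)) {
    t_true <- truth$death_time_h[m[i]]
    lo <- max(sched[sched < t_true])
    hi <- min(sched[sched >= t_true])
    half <- (hi - lo) / 2
    expect_lte(abs(traits$survival_h[i] - t_true), half + 1e-9)
    expect_lte(
      abs(traits$desiccation_resistance[i] - t_true / 96), half / 96 + 1e-12
    )
    wlt_bound <- 100 * truth$wlr_true[m[i]] * half # loss accrued over half the interval
    expect_lte(abs(traits$water_loss_tolerance[i] - truth$wlt_true[m[i]]), wlt_bound + 1e-9)
  }
  # survivors carry no physiological traits
  expect_true(all(is.na(traits$water_loss_rate[!dead])))
  expect_true(all(is.na(traits$water_loss_tolerance[!dead])))
})

test_that("derived resistance is monotone in true death time on a fixed schedule", {
  cfg <- noise_free_config(
    wlr = c(0.02, 0.013, 0.009, 0.007), wlt = c(40, 55, 60, 65),
    dry = rep(50, 4), fwc = rep(2, 4), n = 3
  )
  sim <- simulate_assay(cfg)
  traits <- derive_traits(sim$individuals, sim$weighings)
  truth <- sim$ground_truth[match(traits$individual_id, sim$ground_truth$individual_id), ]
  ord <- order(truth$death_time_h)
  expect_true(all(diff(traits$desiccation_resistance[ord]) >= 0))
})

test_that("within-species scaling centres at the species mean", {
  traits <- derive_traits_demo_cache()
  scaled <- scale_within_species(traits)
  per_sp <- dplyr::summarise(
    dplyr::group_by(scaled, species),
    m_bm = mean(scaled_bm, na.rm = TRUE),
    m_wlr = mean(scaled_wlr, na.rm = TRUE)
  )
  expect_true(all(abs(per_sp$m_bm) < 1e-10))
  expect_true(all(abs(per_sp$m_wlr) < 1e-10))
  # an individual at the species mean scores 0; at twice the mean, exactly 1
  toy <- tibble::tibble(
    species = "a", body_mass_mg = c(6, 3, 2, 1),
    water_loss_rate = 1, water_loss_tolerance = 1
  )
  sc <- scale_within_species(toy)
  expect_equal(sc$scaled_bm, c(1, 0, -1 / 3, -2 / 3))
})

test_that("collinearity screen flags perfect correlation and clears independence", {
  tb <- tibble::tibble(
    water_loss_rate = rnorm(1000), water_loss_tolerance = rnorm(1000),
    fractional_water_content = rnorm(1000), body_mass_mg = rnorm(1000, 50)
  )
  set.seed(7)
  res <- collinearity_check(tb)
  expect_lt(res$max_abs_r, 0.12)
  expect_equal(nrow(res$flagged), 0)
  tb2 <- tb
  tb2$water_loss_tolerance <- -tb2$water_loss_rate
  expect_warning(res2 <- collinearity_check(tb2), "collinearity")
  expect_equal(res2$correlations["water_loss_rate", "water_loss_tolerance"], -1)
  tb3 <- tb
  tb3$body_mass_mg <- 5
  res3 <- collinearity_check(tb3)
  expect_true(all(is.na(res3$correlations["body_mass_mg", 1:3])))
})
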