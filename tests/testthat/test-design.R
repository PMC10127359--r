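test_that("resistance converts exactly to half-hour binomial counts", {
  expect_equal(dr_to_binomial(1, 96, 0.5), tibble::tibble(successes = 192L, trials = 192L))
  expect_equal(dr_to_binomial(64.5 / 96)$successes, 129L)
  expect_equal(dr_to_binomial(0.5)$successes, 96L)
  expect_error(dr_to_binomial(0.5, 96, 0.7), "integer multiple")
  expect_error(dr_to_binomial(0), "\\(0, 1\\]")
})

test_that("the general design encodes guilds, interactions and the dweller reference", {
  traits <- tibble::tibble(
    individual_id = sprintf("i%02d", 1:9),
    species = rep(c("s1", "s2", "s3"), each = 3),
    nesting_strategy = rep(c("dweller", "tunneler", "roller"), each = 3),
    body_mass_mg = exp(c(1, 2, 3, 1.5, 2.5, 3.5, 2, 3, 4)),
    log_body_mass = c(1, 2, 3, 1.5, 2.5, 3.5, 2, 3, 4),
    survival_h = 48, died_in_assay = TRUE,
    desiccation_resistance = 0.5,
    water_loss_rate = c(0.005, 0.011, 0.007, 0.013, 0.009, 0.015, 0.012, 0.006, 0.010),
    water_loss_tolerance = c(50, 44, 58, 47, 53, 41, 56, 49, 45),
    fractional_water_content = c(2.1, 1.8, 2.6, 2.0, 1.5, 2.9, 2.3, 1.7, 2.2),
    scaled_bm = 0, scaled_wlr = 0, scaled_wlt = 0
  )
  des <- build_general_design(traits)
  expect_equal(ncol(des$X), 8)
  expect_equal(qr(des$X)$rank, 8)
  dweller_row <- des$X[1, ]
  expect_equal(unname(dweller_row[c("nesting_strategytunneler", "nesting_strategyroller")]), c(0, 0))
  roller_row <- des$X[7, ]
  expect_equal(unname(roller_row["nesting_strategyroller"]), 1)
  expect_equal(
    unname(roller_row["log_body_mass:nesting_strategyroller"]),
    unname(roller_row["log_body_mass"])
  )
  des9 <- build_general_design(traits, include_fwc = TRUE)
  expect_equal(ncol(des9$X), 9)
  expect_s3_class(des$group, "factor")

  # a guild with a single record warns, and (with the guild interaction) the
  # lone indicator is inevitably aliased with its interaction column
  lone <- traits[c(1:6, 7), ]
  expect_warning(try(build_general_design(lone), silent = TRUE), "< 2 records")
  expect_error(suppressWarnings(build_general_design(lone)), "rank deficient")
})

test_that("the relative design uses species indicators and a configurable reference", {
  traits <- derive_traits_demo_cache()
  des <- build_relative_design(traits, reference_species = "C_erraticus")
  expect_equal(sum(startsWith(colnames(des$X), "species")), 7) # 8 species - reference
  ref_rows <- des$data$species == "C_erraticus"
  expect_true(all(des$X[ref_rows, startsWith(colnames(des$X), "species")] == 0))
  expect_error(build_relative_design(traits, reference_species = "nope"), "absent")
  # survivors and incomplete records never enter the design
  expect_true(all(des$data$died_in_assay))
  expect_false(any(is.na(des$data$water_loss_rate)))
})

test_that("pruning drops a null term and keeps active ones", {
  set.seed(31)
  n <- 150
  d <- tibble::tibble(
    x_active = rnorm(n), x_null = rnorm(n), trials = 192L
  )
  d$successes <- rbinom(n, d$trials, plogis(-0.5 + 0.8 * d$x_active))
  fit <- fit_glm(design_spec(d, ~ x_active + x_null))
  pruned <- prune_nonsignificant(fit, candidate_terms = c("x_active", "x_null"))
  expect_equal(pruned$design$term_labels, "x_active")
  audit <- attr(pruned, "audit")
  expect_equal(audit$term, "x_null")
  expect_gte(audit$p_value, 0.05)
  # empty candidate list returns the fit unchanged
  same <- prune_nonsignificant(fit, character(0))
  expect_equal(coef(same), coef(fit))
})

test_that("pruning demotes a non-significant interaction before main effects", {
  set.seed(33)
  n <- 200
  d <- tibble::tibble(g = rep(c("a", "b"), each = n / 2), x = rnorm(n), trials = 96L)
  d$successes <- rbinom(n, d$trials, plogis(0.3 + 0.7 * d$x + 0.5 * (d$g == "b")))
  fit <- fit_glm(design_spec(d, ~ x * g))
  pruned <- prune_nonsignificant(fit, candidate_terms = c("x", "g", "x:g"))
  audit <- attr(pruned, "audit")
  expect_equal(audit$action[1], "interaction demoted to additive")
  expect_setequal(pruned$design$term_labels, c("x", "g"))
})

test_that("fit reports star the conventional thresholds", {
  set.seed(35)
  d <- tibble::tibble(x = rnorm(60), trials = 20L)
  d$successes <- rbinom(60, 20, plogis(0.2 + 0.6 * d$x))
  fit <- fit_glm(design_spec(d, ~x))
  tab <- fit_report(fit)
  expected <- ifelse(tab$p_value < 0.001, "***",
    ifelse(tab$p_value < 0.01, "**", ifelse(tab$p_value < 0.05, "*", "NS"))
  )
  expect_equal(tab$stars, expected)
  tsv <- fit_report(fit, format = "tsv")
  expect_match(tsv, "AIC = ")
  expect_match(tsv, "pseudo-R2")
  md <- fit_report(fit, labels = c(x = "Log BM"), format = "markdown")
  expect_match(md, "Log BM")
})
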