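# Design construction for the binomial survival models: conversion of the
# desiccation-resistance proportion to a successes/trials pair, the general
# (cross-species) design, and the relative (within-species scaled) design.

#' Convert desiccation resistance to binomial counts
#'
#' The resistance proportion is modelled as a binomial response: survival
#' counted in discrete time units out of the whole assay. The default unit of
#' 0.5 h makes every interval-midpoint survival time (multiples of half an
#' hour on a whole-hour schedule) exactly representable: a 96-h assay becomes
#' 192 trials, and a DR of 64.5/96 becomes exactly 129 successes.
#'
#' @param dr Vector of desiccation-resistance proportions in (0, 1].
#' @param horizon_h Assay duration in hours (default 96).
#' @param unit_h Time unit in hours (default 0.5); `horizon_h` must be an
#'   integer multiple of it.
#' @return Tibble with integer columns `successes` and `trials`.
#' @export
dr_to_binomial <- function(dr, horizon_h = 96, unit_h = 0.5) {
  check_scalar(horizon_h, "horizon_h", lower = 0, strict = TRUE)
  check_scalar(unit_h, "unit_h", lower = 0, strict = TRUE)
  trials <- horizon_h / unit_h
  if (abs(trials - round(trials)) > 1e-8) {
    abort("`horizon_h` must be an integer multiple of `unit_h`")
  }
  trials <- as.integer(round(trials))
  if (any(!is.finite(dr)) || any(dr <= 0) || any(dr > 1 + 1e-12)) {
    abort("`dr` must lie in (0, 1]")
  }
  tibble::tibble(
    successes = as.integer(round(dr * trials)),
    trials = trials
  )
}

#' Build a binomial design specification
#'
#' Assembles the pieces the from-scratch fitters need: the model frame, the
#' fixed-effects model matrix (checked for full column rank), the
#' successes/trials response, term assignments for term-level Wald tests, and
#' the optional grouping factor for the random intercept.
#'
#' @param data Data frame holding response and covariates.
#' @param formula RHS formula for the fixed effects, e.g. `~ x1 + x2`.
#' @param successes,trials Column names of the binomial response.
#' @param group Optional column name of the grouping factor (random
#'   intercept).
#' @return List of class `design_spec`.
#' @export
design_spec <- function(data, formula, successes = "successes",
                        trials = "trials", group = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(inherits(formula, "formula"))
  for (col in c(successes, trials, group)) {
    if (!col %in% names(data)) abort(sprintf("column `%s` not found in `data`", col))
  }
  y <- data[[successes]]
  n <- data[[trials]]
  if (any(y < 0) || any(n < 1) || any(y > n)) {
    abort("need 0 <= successes <= trials with trials >= 1 on every record")
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; aliased columns: ",
                 paste(aliased, collapse = ", ")))
  }
  grp <- if (!is.null(group)) factor(data[[group]]) else NULL
  if (!is.null(grp) && nlevels(grp) < 2) {
    abort("the grouping factor needs at least 2 levels")
  }
  structure(
    list(
      data = data, formula = formula, X = X, y = as.numeric(y), n = as.numeric(n),
      assign = attr(X, "assign"),
      term_labels = attr(stats::terms(formula), "term.labels"),
      group = grp, group_name = group
    ),
    class = "design_spec"
  )
}

# Complete records for modelling: individuals that died with every trait
# defined. Survivors never contribute physiological-trait rows.
complete_model_records <- function(traits) {
  traits <- tibble::as_tibble(traits)
  keep <- traits$died_in_assay &
    stats::complete.cases(traits[, c(
      "log_body_mass", "water_loss_rate",
      "water_loss_tolerance", "fractional_water_content"
    )])
  dplyr::filter(traits, keep)
}

#' General-effects design: traits across species
#'
#' Models desiccation resistance against nesting strategy, log dry body mass
#' and their interaction, plus water loss rate and tolerance, on the
#' individuals that died with all traits defined. The dweller guild is the
#' reference level, so the tunneler and roller coefficients are read against
#' it; a species grouping factor is attached for the random intercept. An
#' optional fractional-water-content column supports the pruning step.
#'
#' @param traits Trait table from [derive_traits()].
#' @param horizon_h,unit_h Passed to [dr_to_binomial()].
#' @param reference_guild Reference nesting strategy (default `"dweller"`).
#' @param include_fwc Add fractional water content as a candidate term.
#' @return A `design_spec` with `group = "species"`.
#' @export
build_general_design <- function(traits, horizon_h = 96, unit_h = 0.5,
                                 reference_guild = "dweller", include_fwc = FALSE) {
  d <- complete_model_records(traits)
  if (nrow(d) == 0) abort("no complete records to model")
  guild_n <- table(d$nesting_strategy)
  if (any(guild_n < 2)) {
    warn(paste0("nesting guild(s) with < 2 records: ",
                paste(names(guild_n)[guild_n < 2], collapse = ", ")))
  }
  if (!reference_guild %in% d$nesting_strategy) {
    abort(sprintf("reference guild `%s` absent from the data", reference_guild))
  }
  d$nesting_strategy <- stats::relevel(factor(d$nesting_strategy), ref = reference_guild)
  d <- dplyr::bind_cols(d, dr_to_binomial(d$desiccation_resistance, horizon_h, unit_h))
  f <- if (include_fwc) {
    ~ log_body_mass * nesting_strategy + water_loss_rate +
      water_loss_tolerance + fractional_water_content
  } else {
    ~ log_body_mass * nesting_strategy + water_loss_rate + water_loss_tolerance
  }
  design_spec(d, f, group = "species")
}

#' Relative-effects design: within-species scaled traits
#'
#' Models desiccation resistance against species identity plus the
#' within-species scaled covariates (body mass, water loss rate, water loss
#' tolerance expressed as deviations from the species mean), asking whether
#' relatively large / slow-losing / tolerant individuals of each species
#' resist longer, consistently across species.
#'
#' @inheritParams build_general_design
#' @param reference_species Reference level for the species factor; default
#'   the first level alphabetically.
#' @return A `design_spec` (no grouping factor: a plain GLM design).
#' @export
build_relative_design <- function(traits, horizon_h = 96, unit_h = 0.5,
                                  reference_species = NULL) {
  d <- complete_model_records(traits)
  if (nrow(d) == 0) abort("no complete records to model")
  d <- dplyr::filter(d, !is.na(.data$scaled_bm) & !is.na(.data$scaled_wlr) & !is.na(.data$scaled_wlt))
  d$species <- factor(d$species)
  if (!is.null(reference_species)) {
    if (!reference_species %in% levels(d$species)) {
      abort(sprintf("reference species `%s` absent from the data", reference_species))
    }
    d$species <- stats::relevel(d$species, ref = reference_species)
  }
  d <- dplyr::bind_cols(d, dr_to_binomial(d$desiccation_resistance, horizon_h, unit_h))
  design_spec(d, ~ species + scaled_bm + scaled_wlr + scaled_wlt)
}
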