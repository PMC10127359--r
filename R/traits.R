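# Trait derivation from raw weighings: survival time with the
# interval-midpoint death rule, desiccation resistance, water loss rate,
# water loss tolerance and fractional water content, plus per-species
# summaries and within-species scaling.

# Validate and order a single individual's measurement series.
# `series` is a data frame with columns time_h, wet_mass_mg, alive.
check_series <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0) {
    abort("a measurement series needs at least one observation")
  }
  needed <- c("time_h", "wet_mass_mg", "alive")
  if (!all(needed %in% names(series))) {
    abort("series must have columns time_h, wet_mass_mg, alive")
  }
  series <- dplyr::arrange(tibble::as_tibble(series), .data$time_h)
  if (any(diff(series$time_h) <= 0)) abort("observation times must be strictly increasing")
  alive <- as.logical(series$alive)
  if (!alive[1]) abort("the first observation must be alive")
  if (any(diff(alive) > 0)) abort("an individual cannot return to life: alive flags must be monotone")
  series$alive <- alive
  series
}

# Wet mass can dip marginally below dry mass through balance noise; clamp
# small deficits (< 2% of dry mass) with a warning and refuse larger ones.
# The 2% integrity bound applies to *alive* weighings: a dead carcass can
# legitimately be weighed at (or, with noise, just under) its dry mass once
# fully desiccated, so post-mortem deficits are clamped silently.
clamp_wet_mass <- function(wet, dry_mass_mg, alive = rep(TRUE, length(wet))) {
  deficit <- dry_mass_mg - wet
  if (any(alive & deficit > 0.02 * dry_mass_mg)) {
    abort("wet mass is more than 2% below dry mass at an alive weighing: inconsistent weighings")
  }
  if (any(alive & deficit > 0)) {
    warn("wet mass marginally below dry mass; clamped to dry mass")
  }
  pmax(wet, dry_mass_mg)
}

#' Survival time from interval-observed death
#'
#' Death is never observed directly in a weighing schedule: an individual is
#' last seen alive at one weighing and first found dead at the next. The
#' survival time is taken as the midpoint (the median of the two bracketing
#' times), for every death interval including overnight gaps. Individuals
#' alive at every weighing are censored at the horizon.
#'
#' @param series Data frame with columns `time_h`, `wet_mass_mg`, `alive` for
#'   one individual.
#' @param horizon_h Assay duration in hours.
#' @return List with `survival_h` and logical `died`.
#' @examples
#' s <- tibble::tibble(time_h = c(57, 72), wet_mass_mg = c(80, 74), alive = c(TRUE, FALSE))
#' death_time(s, 96) # midpoint 64.5 h
#' @export
death_time <- function(series, horizon_h = 96) {
  check_scalar(horizon_h, "horizon_h", lower = 0, strict = TRUE)
  series <- check_series(series)
  if (any(!series$alive)) {
    first_dead <- which(!series$alive)[1]
    list(
      survival_h = median(series$time_h[c(first_dead - 1L, first_dead)]),
      died = TRUE
    )
  } else {
    list(survival_h = horizon_h, died = FALSE)
  }
}

#' Desiccation resistance
#'
#' Survival time under dry conditions as a proportion of the assay horizon: an
#' individual dying immediately scores near 0, one surviving the whole 96-h
#' assay scores exactly 1 (96 h / 96 h).
#'
#' @param survival_h Survival time in hours, in (0, `horizon_h`].
#' @param horizon_h Assay duration in hours.
#' @return Proportion in (0, 1].
#' @export
desiccation_resistance <- function(survival_h, horizon_h = 96) {
  check_scalar(horizon_h, "horizon_h", lower = 0, strict = TRUE)
  if (any(!is.finite(survival_h)) || any(survival_h <= 0)) {
    abort("`survival_h` must be positive")
  }
  if (any(survival_h > horizon_h + 1e-9)) {
    abort("`survival_h` cannot exceed the assay horizon")
  }
  survival_h / horizon_h
}

# Initial water content: first observed wet mass minus dry mass (animals are
# fully hydrated at the start of the assay).
initial_water <- function(series, dry_mass_mg) {
  w0 <- series$wet_mass_mg[1] - dry_mass_mg
  if (w0 <= 0) abort("initial water content must be positive (first wet mass <= dry mass)")
  w0
}

#' Water loss rate
#'
#' Ordinary least-squares slope of water mass (wet mass minus dry mass) on
#' time over the alive observations, sign-flipped and normalized by the
#' initial water content, giving the proportion of initial body water lost
#' per hour (mg mg^-1 h^-1).
#'
#' @inheritParams death_time
#' @param dry_mass_mg Dry body mass in mg.
#' @param min_obs Minimum number of alive observations required (default 3; a
#'   two-point slope is noise-dominated). Fewer returns `NA` with a
#'   `"reason"` attribute so callers can log the exclusion.
#' @return Rate per hour (positive under net loss), or `NA`.
#' @export
water_loss_rate <- function(series, dry_mass_mg, min_obs = 3) {
  check_scalar(dry_mass_mg, "dry_mass_mg", lower = 0, strict = TRUE)
  series <- check_series(series)
  alive <- series[series$alive, ]
  if (nrow(alive) < min_obs) {
    return(structure(NA_real_, reason = sprintf(
      "only %d alive observations (need >= %d)", nrow(alive), min_obs
    )))
  }
  wet <- clamp_wet_mass(alive$wet_mass_mg, dry_mass_mg)
  water <- wet - dry_mass_mg
  w0 <- initial_water(series, dry_mass_mg)
  slope <- coef(lm(water ~ alive$time_h))[[2]]
  -slope / w0
}

#' Water loss tolerance
#'
#' Percentage of the initial water content lost at death:
#' `100 * (initial wet mass - final wet mass) / initial water content`. The
#' final wet mass at the (interval-observed) death is the arithmetic mean of
#' the wet masses at the last-alive and first-dead weighings.
#'
#' @inheritParams water_loss_rate
#' @return Percent in (0, 100], or an error for survivors (tolerance is
#'   defined only for individuals that died in the assay).
#' @export
water_loss_tolerance <- function(series, dry_mass_mg) {
  check_scalar(dry_mass_mg, "dry_mass_mg", lower = 0, strict = TRUE)
  series <- check_series(series)
  if (all(series$alive)) {
    abort("water loss tolerance is defined only for individuals that died in the assay")
  }
  first_dead <- which(!series$alive)[1]
  wet <- clamp_wet_mass(series$wet_mass_mg, dry_mass_mg, series$alive)
  final_wet <- mean(wet[c(first_dead - 1L, first_dead)])
  w0 <- initial_water(series, dry_mass_mg)
  100 * (wet[1] - final_wet) / w0
}

#' Fractional water content
#'
#' Initial water content divided by dry body mass (mg mg^-1), the maximum
#' water an individual can store relative to its size.
#'
#' @inheritParams water_loss_rate
#' @return Ratio >= 0; exactly 0 (initial wet mass equal to dry mass) is
#'   flagged with a warning as physiologically suspicious.
#' @export
fractional_water_content <- function(series, dry_mass_mg) {
  check_scalar(dry_mass_mg, "dry_mass_mg", lower = 0, strict = TRUE)
  series <- check_series(series)
  if (series$wet_mass_mg[1] < dry_mass_mg) {
    abort("initial wet mass below dry mass")
  }
  fwc <- (series$wet_mass_mg[1] - dry_mass_mg) / dry_mass_mg
  if (fwc == 0) warn("fractional water content is exactly 0; check the weighings")
  fwc
}

#' Derive per-individual water-balance traits from raw weighings
#'
#' The main trait-derivation entry point: joins the individual metadata with
#' the long weighing records and computes, per individual, survival time
#' (interval-midpoint rule), desiccation resistance, and -- for individuals
#' that died -- water loss rate, water loss tolerance and fractional water
#' content. Survivors keep `NA` physiological traits and never enter the
#' regression models' trait columns. Within-species scaled covariates are
#' appended via [scale_within_species()].
#'
#' @param individuals Data frame: `individual_id`, `species`,
#'   `nesting_strategy`, `dry_mass_mg`.
#' @param weighings Data frame: `individual_id`, `time_h`, `wet_mass_mg`,
#'   `alive` (logical or 0/1).
#' @param horizon_h Assay duration in hours (default 96).
#' @param min_alive_obs Minimum alive observations for the rate regression.
#' @return Tibble of class `trait_table`, one row per individual, with an
#'   `"exclusions"` attribute logging individuals whose rate could not be
#'   estimated.
#' @examples
#' sim <- simulate_assay(assay_config(demo_species_params(), 5, seed = 1))
#' traits <- derive_traits(sim$individuals, sim$weighings)
#' @export
derive_traits <- function(individuals, weighings, horizon_h = 96, min_alive_obs = 3) {
  individuals <- tibble::as_tibble(individuals)
  weighings <- tibble::as_tibble(weighings)
  stopifnot(
    all(c("individual_id", "species", "nesting_strategy", "dry_mass_mg") %in% names(individuals)),
    all(c("individual_id", "time_h", "wet_mass_mg", "alive") %in% names(weighings))
  )
  orphan <- setdiff(weighings$individual_id, individuals$individual_id)
  if (length(orphan) > 0) {
    abort(paste0("weighings reference unknown individuals: ", paste(head(orphan, 5), collapse = ", ")))
  }
  exclusions <- list()
  rows <- purrr::map_dfr(seq_len(nrow(individuals)), function(i) {
    ind <- individuals[i, ]
    series <- weighings[weighings$individual_id == ind$individual_id, ]
    series <- check_series(series)
    dt <- death_time(series, horizon_h)
    dr <- desiccation_resistance(dt$survival_h, horizon_h)
    wlr <- NA_real_
    wlt <- NA_real_
    fwc <- NA_real_
    if (dt$died) {
      wlr <- water_loss_rate(series, ind$dry_mass_mg, min_obs = min_alive_obs)
      if (is.na(wlr)) {
        exclusions[[ind$individual_id]] <<- attr(wlr, "reason")
        wlr <- NA_real_
      }
      wlt <- water_loss_tolerance(series, ind$dry_mass_mg)
      fwc <- fractional_water_content(series, ind$dry_mass_mg)
    }
    tibble::tibble(
      individual_id = ind$individual_id,
      species = ind$species,
      nesting_strategy = ind$nesting_strategy,
      body_mass_mg = ind$dry_mass_mg,
      log_body_mass = log(ind$dry_mass_mg),
      survival_h = dt$survival_h,
      died_in_assay = dt$died,
      desiccation_resistance = dr,
      water_loss_rate = as.numeric(wlr),
      water_loss_tolerance = wlt,
      fractional_water_content = fwc
    )
  })
  out <- scale_within_species(rows)
  attr(out, "exclusions") <- exclusions
  attr(out, "horizon_h") <- horizon_h
  class(out) <- c("trait_table", class(out))
  out
}

#' Within-species scaled covariates
#'
#' Expresses body mass, water loss rate and water loss tolerance relative to
#' the species average: `scaled_x = (x - species_mean) / species_mean`, a
#' dimensionless deviation (an individual at twice its species mean scores
#' 1). Species means are taken over individuals with the trait defined.
#'
#' @param traits Trait table as produced by [derive_traits()].
#' @return The table with `scaled_bm`, `scaled_wlr`, `scaled_wlt` columns
#'   added or refreshed.
#' @export
scale_within_species <- function(traits) {
  traits <- tibble::as_tibble(traits)
  scale_one <- function(x) {
    m <- mean(x, na.rm = TRUE)
    if (is.nan(m) || m == 0) {
      if (m == 0) abort("species mean is zero; scaled trait undefined")
      return(rep(NA_real_, length(x)))
    }
    (x - m) / m
  }
  dplyr::mutate(
    dplyr::group_by(traits, .data$species),
    scaled_bm = scale_one(.data$body_mass_mg),
    scaled_wlr = scale_one(.data$water_loss_rate),
    scaled_wlt = scale_one(.data$water_loss_tolerance)
  ) |>
    dplyr::ungroup()
}

#' Species-level trait summary
#'
#' One row per species: number dead / total, and mean and SD of body mass,
#' desiccation resistance, water loss rate, water loss tolerance and
#' fractional water content (the layout of a standard species trait table).
#'
#' @param traits Trait table from [derive_traits()].
#' @return Tibble with columns `species`, `nesting_strategy`, `n_dead`,
#'   `n_total`, and `<trait>_mean` / `<trait>_sd` pairs.
#' @export
species_summary <- function(traits) {
  traits <- tibble::as_tibble(traits)
  dplyr::summarise(
    dplyr::group_by(traits, .data$species, .data$nesting_strategy),
    n_dead = sum(.data$died_in_assay),
    n_total = dplyr::n(),
    bm_mean = mean(.data$body_mass_mg),
    bm_sd = sd(.data$body_mass_mg),
    dr_mean = mean(.data$desiccation_resistance),
    dr_sd = sd(.data$desiccation_resistance),
    wlr_mean = mean(.data$water_loss_rate, na.rm = TRUE),
    wlr_sd = sd(.data$water_loss_rate, na.rm = TRUE),
    wlt_mean = mean(.data$water_loss_tolerance, na.rm = TRUE),
    wlt_sd = sd(.data$water_loss_tolerance, na.rm = TRUE),
    fwc_mean = mean(.data$fractional_water_content, na.rm = TRUE),
    fwc_sd = sd(.data$fractional_water_content, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Collinearity screen for model covariates
#'
#' Pairwise Pearson correlations among water loss rate, water loss tolerance,
#' fractional water content and body mass over complete records, with a
#' warning when any |r| exceeds the threshold (covariates that co-vary too
#' strongly cannot be separated in a regression).
#'
#' @param traits Trait table from [derive_traits()].
#' @param threshold Warn when `max |r|` exceeds this (default 0.7).
#' @return List with `correlations` (matrix), `max_abs_r`, and a tibble
#'   `flagged` of pairs above the threshold. Constant columns yield `NA`
#'   correlations, reported as such.
#' @export
collinearity_check <- function(traits, threshold = 0.7) {
  check_scalar(threshold, "threshold", lower = 0, upper = 1)
  cols <- c(
    "water_loss_rate", "water_loss_tolerance",
    "fractional_water_content", "body_mass_mg"
  )
  m <- as.matrix(tibble::as_tibble(traits)[, cols])
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) abort("need at least 3 complete records for the collinearity screen")
  constant <- apply(m, 2, function(x) sd(x) == 0)
  r <- suppressWarnings(stats::cor(m))
  r[constant, ] <- NA
  r[, constant] <- NA
  diag(r) <- 1
  off <- abs(r[upper.tri(r)])
  max_r <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  pairs <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  flagged <- tibble::tibble(
    var1 = colnames(r)[pairs[, 1]],
    var2 = colnames(r)[pairs[, 2]],
    r = r[pairs]
  )
  if (nrow(flagged) > 0) {
    warn(sprintf("collinearity above |r| = %.2f between: %s", threshold,
                 paste(flagged$var1, flagged$var2, sep = "~", collapse = ", ")))
  }
  list(correlations = r, max_abs_r = max_r, flagged = flagged)
}
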