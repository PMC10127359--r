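# Broom-style accessors, term pruning and report formatting for the binomial
# fits.

#' @export
print.wb_fit <- function(x, ...) {
  kind <- if (inherits(x, "wb_glmm")) "Binomial GLMM (adaptive Gauss-Hermite)" else "Binomial GLM (IRLS)"
  cat(kind, "\n")
  cat(sprintf(
    "  n = %d%s, logLik = %.2f, AIC = %.2f\n", x$n_obs,
    if (!is.na(x$n_groups)) sprintf(", groups = %d", x$n_groups) else "",
    x$log_likelihood, x$aic
  ))
  if (inherits(x, "wb_glmm")) {
    cat(sprintf("  random-intercept SD = %.4f\n", x$random_sd))
  }
  print(as.data.frame(tidy(x)), digits = 4)
  invisible(x)
}

#' Tidy coefficient table of a binomial fit
#'
#' @param x A fit from [fit_glm()] or [fit_glmm()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `z`, `p_value` and
#'   significance `stars` (`*` < 0.05, `**` < 0.01, `***` < 0.001, `NS`
#'   otherwise).
#' @method tidy wb_fit
#' @export
tidy.wb_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std_error = unname(x$se),
    z = unname(x$z),
    p_value = unname(x$p_values),
    stars = p_stars(unname(x$p_values))
  )
}

#' One-row model summary of a binomial fit
#'
#' @inheritParams tidy.wb_fit
#' @return Tibble with log-likelihood, AIC, both pseudo-R^2 statistics
#'   (squared observed-fitted correlation, and deviance-based where defined),
#'   random-intercept SD (GLMM), n and groups.
#' @method glance wb_fit
#' @export
glance.wb_fit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    aic = x$aic,
    pseudo_r2 = x$pseudo_r2,
    pseudo_r2_deviance = x$pseudo_r2_deviance,
    random_sd = x$random_sd,
    n_obs = x$n_obs,
    n_groups = x$n_groups,
    converged = x$converged
  )
}

refit <- function(fit, formula) {
  design <- design_spec(fit$design$data, formula,
    successes = "successes", trials = "trials",
    group = fit$design$group_name
  )
  if (inherits(fit, "wb_glmm")) {
    fit_glmm(design, quadrature_points = fit$quadrature_points)
  } else {
    fit_glm(design)
  }
}

# Term-level Wald p: multi-df chi-square for terms spanning several columns.
term_p_values <- function(fit) {
  design <- fit$design
  labels <- design$term_labels
  vapply(seq_along(labels), function(j) {
    cols <- which(design$assign == j)
    if (length(cols) == 1) {
      return(fit$p_values[cols])
    }
    b <- fit$coefficients[cols]
    V <- fit$vcov[cols, cols, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    pchisq(stat, df = length(cols), lower.tail = FALSE)
  }, numeric(1)) |> setNames(labels)
}

#' Backward pruning of non-significant terms
#'
#' Simplifies a fitted model the way the field's survival analyses do:
#' non-significant interactions are demoted to additive terms first, then
#' non-significant candidate main effects are dropped one at a time (largest
#' Wald p first), refitting after every change. Terms not listed in
#' `candidate_terms` are never touched. Multi-coefficient terms (factors,
#' interactions) are judged by a multi-df Wald test.
#'
#' @param fit A fit from [fit_glm()] or [fit_glmm()].
#' @param candidate_terms Character vector of term labels eligible for
#'   removal (empty vector returns the fit unchanged).
#' @param alpha Retention threshold (default 0.05): terms with p >= alpha go.
#' @return The final fit, with an `"audit"` attribute (tibble of drops:
#'   term, p at drop, action).
#' @export
prune_nonsignificant <- function(fit, candidate_terms, alpha = 0.05) {
  stopifnot(inherits(fit, "wb_fit"))
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  audit <- tibble::tibble(term = character(), p_value = numeric(), action = character())
  if (length(candidate_terms) == 0) {
    attr(fit, "audit") <- audit
    return(fit)
  }
  repeat {
    labels <- fit$design$term_labels
    pvals <- term_p_values(fit)
    cand <- intersect(candidate_terms, labels)
    is_inter <- grepl(":", cand, fixed = TRUE)
    # interactions first: a non-significant interaction is demoted before any
    # main effect is considered
    pool <- if (any(is_inter & pvals[cand] >= alpha)) cand[is_inter] else cand[!is_inter]
    pool <- pool[pvals[pool] >= alpha]
    if (length(pool) == 0) break
    victim <- pool[which.max(pvals[pool])]
    keep <- setdiff(labels, victim)
    action <- if (grepl(":", victim, fixed = TRUE)) "interaction demoted to additive" else "term dropped"
    audit <- dplyr::bind_rows(audit, tibble::tibble(
      term = victim, p_value = unname(pvals[victim]), action = action
    ))
    new_formula <- if (length(keep) == 0) ~1 else stats::reformulate(keep)
    fit <- refit(fit, new_formula)
    if (length(keep) == 0) break
  }
  attr(fit, "audit") <- audit
  fit
}

#' Publication-style coefficient report
#'
#' Formats a fit as the customary "Estimate +/- SE / z / p" table with
#' significance stars and the model-level statistics (AIC, pseudo-R^2, n,
#' groups) attached, optionally as markdown or TSV text.
#'
#' @param fit A fit from [fit_glm()] or [fit_glmm()].
#' @param labels Optional named character vector renaming terms for display.
#' @param format `"tibble"` (default), `"markdown"` or `"tsv"`.
#' @return A tibble (with a `"meta"` attribute), or a character string for
#'   the text formats.
#' @export
fit_report <- function(fit, labels = NULL, format = c("tibble", "markdown", "tsv")) {
  format <- match.arg(format)
  if (!isTRUE(fit$converged)) abort("refusing to report a non-converged fit")
  tab <- tidy(fit)
  if (!is.null(labels)) {
    hit <- tab$term %in% names(labels)
    tab$term[hit] <- labels[tab$term[hit]]
  }
  tab <- dplyr::mutate(tab,
    estimate_se = sprintf("%.3f ± %.3f", .data$estimate, .data$std_error),
    z = round(.data$z, 3),
    p_value = signif(.data$p_value, 3)
  )
  meta <- glance(fit)
  attr(tab, "meta") <- meta
  if (format == "tibble") {
    return(tab)
  }
  show <- tab[, c("term", "estimate_se", "z", "p_value", "stars")]
  header <- sprintf(
    "AIC = %.2f | pseudo-R2 (sq. obs-fitted correlation) = %.3f | n = %d%s",
    meta$aic, meta$pseudo_r2, meta$n_obs,
    if (!is.na(meta$n_groups)) sprintf(" | groups = %d", meta$n_groups) else ""
  )
  if (format == "tsv") {
    lines <- c(
      paste0("# ", header),
      paste(names(show), collapse = "\t"),
      apply(show, 1, paste, collapse = "\t")
    )
    return(paste(lines, collapse = "\n"))
  }
  widths <- pmax(nchar(names(show)), apply(show, 2, function(col) max(nchar(col))))
  fmt_row <- function(vals) {
    cells <- mapply(formatC, as.character(unlist(vals)), width = widths, flag = "-")
    paste0("| ", paste(cells, collapse = " | "), " |")
  }
  paste(c(
    header, "",
    fmt_row(names(show)),
    paste0("|", paste(strrep("-", widths + 2), collapse = "|"), "|"),
    apply(show, 1, fmt_row)
  ), collapse = "\n")
}
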