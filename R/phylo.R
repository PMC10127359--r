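# Phylogenetic comparative layer: Felsenstein independent contrasts computed
# by the pruning algorithm, a contrast-variance phylogenetic-signal test with
# a tip-shuffle randomization null, and through-origin contrast correlations.

validate_tree <- function(tree, require_binary = TRUE) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape `phylo` object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) abort("tree has missing branch lengths")
  if (any(tree$edge.length <= 0)) {
    abort("all branch lengths must be > 0 (contrast standardization divides by sqrt(v))")
  }
  if (anyDuplicated(tree$tip.label)) abort("tip labels must be unique")
  if (require_binary) {
    # count children per internal node: an unrooted tree shows up as a basal
    # trifurcation, so this also enforces rootedness
    kids <- tabulate(tree$edge[, 1], nbins = ape::Ntip(tree) + tree$Nnode)
    kids <- kids[(ape::Ntip(tree) + 1):(ape::Ntip(tree) + tree$Nnode)]
    if (any(kids != 2)) {
      abort("tree contains polytomies; only rooted, fully bifurcating trees are supported")
    }
  }
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  invisible(tree)
}

#' Read and validate a Newick tree
#'
#' Parses a strict Newick string or file and checks the invariants the
#' contrast machinery requires: rooted, fully bifurcating, unique tip labels,
#' and strictly positive branch lengths on every non-root edge. Polytomies
#' and missing branch lengths are rejected rather than silently resolved.
#'
#' @param text Newick string, or `NULL` to read from `file`.
#' @param file Path to a Newick file.
#' @return A validated `phylo` object.
#' @examples
#' read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) abort("supply exactly one of `text` or `file`")
  tree <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file = file)
  if (is.null(tree)) abort("could not parse Newick input")
  validate_tree(tree)
  tree
}

# Coerce tip trait values to a named vector aligned with tree tips. Accepts a
# named numeric vector or a two-column data frame (species, value).
as_tip_values <- function(x, tree, trait = NULL) {
  if (is.data.frame(x)) {
    stopifnot(ncol(x) >= 2)
    vals <- x[[2]]
    if (!is.null(trait) && trait %in% names(x)) vals <- x[[trait]]
    x <- setNames(as.numeric(vals), as.character(x[[1]]))
  }
  if (is.null(names(x))) abort("trait values must be named by tip label")
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips) > 0) {
    abort(paste0("missing trait values for tips: ", paste(missing_tips, collapse = ", ")))
  }
  vals <- x[tree$tip.label]
  if (anyNA(vals)) abort("trait values contain NA")
  vals
}

#' Standardized phylogenetic independent contrasts
#'
#' Implements the classic pruning algorithm: at each internal node the
#' contrast between its two daughters is `(x_i - x_j) / sqrt(v_i + v_j)`, the
#' ancestral value is the `1/v`-weighted mean of the daughters, and the
#' node's own branch is lengthened by `v_i v_j / (v_i + v_j)` to carry the
#' uncertainty of the estimate rootward. Under Brownian evolution the
#' resulting `n_tips - 1` contrasts are independent draws from
#' `Normal(0, sigma^2)`.
#'
#' @param tree Rooted, fully bifurcating `phylo` object with positive branch
#'   lengths.
#' @param x Tip trait values: a named numeric vector or a two-column data
#'   frame (tip label, value).
#' @param trait Optional trait name recorded on the result.
#' @return A tibble of class `contrast_set` with columns `node` (internal
#'   node id), `contrast` (standardized) and `expected_variance` (the summed
#'   adjusted branch lengths `v_i + v_j`).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' independent_contrasts(tr, c(A = 2, B = 4, C = 6))
#' @export
independent_contrasts <- function(tree, x, trait = NULL) {
  validate_tree(tree)
  vals <- as_tip_values(x, tree, trait)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  xx <- c(vals, rep(NA_real_, tree$Nnode))
  # working branch length of each node's parent edge (adjusted as we prune)
  vv <- rep(NA_real_, n_node)
  vv[tree$edge[, 2L]] <- tree$edge.length
  contrast <- rep(NA_real_, tree$Nnode)
  evar <- rep(NA_real_, tree$Nnode)
  po <- ape::postorder(tree)
  parents <- tree$edge[po, 1L]
  children <- tree$edge[po, 2L]
  for (anc in unique(parents)) {
    ch <- children[parents == anc]
    stopifnot(length(ch) == 2L) # validated bifurcating
    vi <- vv[ch[1L]]
    vj <- vv[ch[2L]]
    evar[anc - n_tip] <- vi + vj
    contrast[anc - n_tip] <- (xx[ch[1L]] - xx[ch[2L]]) / sqrt(vi + vj)
    xx[anc] <- (xx[ch[1L]] / vi + xx[ch[2L]] / vj) / (1 / vi + 1 / vj)
    if (!is.na(vv[anc])) vv[anc] <- vv[anc] + vi * vj / (vi + vj)
  }
  out <- tibble::tibble(
    node = n_tip + seq_len(tree$Nnode),
    contrast = contrast,
    expected_variance = evar
  )
  structure(out,
    trait = trait %||% "trait", n_tips = n_tip,
    class = c("contrast_set", class(out))
  )
}

#' Variance of standardized contrasts
#'
#' The mean-centred population variance (denominator `n`) of the
#' standardized contrasts: the signal statistic. Low contrast variance means
#' close relatives have similar trait values relative to the divergence the
#' branch lengths predict, i.e. phylogenetic signal. The denominator
#' convention only rescales observed and null identically, so the
#' randomization p-value is unaffected by it.
#'
#' @param contrasts A `contrast_set` from [independent_contrasts()], or a
#'   numeric vector of contrasts.
#' @return The variance (a single number >= 0); at least 2 contrasts are
#'   required (the variance of one value is degenerate).
#' @export
contrast_variance <- function(contrasts) {
  cc <- if (is.data.frame(contrasts)) contrasts$contrast else as.numeric(contrasts)
  if (length(cc) < 2) {
    abort("contrast variance is degenerate with fewer than 2 contrasts")
  }
  mean((cc - mean(cc))^2)
}

#' Contrast-variance phylogenetic-signal test
#'
#' Tests whether related species resemble each other more than species drawn
#' at random from the same tree. The statistic is the variance of the
#' standardized contrasts ([contrast_variance()]); the null distribution
#' comes from shuffling the trait values across the tips with the topology
#' and branch lengths fixed. Signal pulls the contrast variance *down*, so
#' the default one-tailed p-value is the (add-one corrected) proportion of
#' null variances at or below the observed one.
#'
#' @inheritParams independent_contrasts
#' @param n_randomizations Number of tip shuffles (default 999; at least 99).
#' @param seed Integer seed for the shuffles.
#' @param alternative `"less"` (default; low variance = signal) or
#'   `"two.sided"`.
#' @return A list of class `signal_test`: `trait`, `observed_variance`,
#'   `null_variances`, `p_value`, `n_randomizations`, `alternative`, `seed`.
#' @examples
#' tr <- simulate_tree(16, seed = 1)
#' x <- simulate_bm_traits(tr, sigma2 = 1, seed = 2)
#' signal_test(tr, x, n_randomizations = 199, seed = 3)
#' @export
signal_test <- function(tree, x, n_randomizations = 999, seed = 1,
                        alternative = c("less", "two.sided"), trait = NULL) {
  alternative <- match.arg(alternative)
  check_scalar(n_randomizations, "n_randomizations", lower = 99, integer = TRUE)
  validate_tree(tree)
  vals <- as_tip_values(x, tree, trait)
  if (sd(vals) == 0) {
    abort("trait is constant across tips: the signal test is degenerate")
  }
  observed <- contrast_variance(independent_contrasts(tree, vals))
  null_var <- with_seed(seed, vapply(seq_len(n_randomizations), function(i) {
    shuffled <- setNames(sample(vals), names(vals))
    contrast_variance(independent_contrasts(tree, shuffled))
  }, numeric(1)))
  n_le <- sum(null_var <= observed + 1e-12)
  p_low <- (n_le + 1) / (n_randomizations + 1)
  p <- if (alternative == "less") {
    p_low
  } else {
    n_ge <- sum(null_var >= observed - 1e-12)
    min(1, 2 * min(p_low, (n_ge + 1) / (n_randomizations + 1)))
  }
  structure(
    list(
      trait = trait %||% "trait",
      observed_variance = observed,
      null_variances = null_var,
      p_value = p,
      n_randomizations = n_randomizations,
      alternative = alternative,
      seed = seed
    ),
    class = "signal_test"
  )
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf(
    "Contrast-variance phylogenetic signal test (%s)\n  VarContr = %.4g, p = %.4g (%s, %d tip shuffles)\n",
    x$trait, x$observed_variance, x$p_value, x$alternative, x$n_randomizations
  ))
  invisible(x)
}

#' @method tidy signal_test
#' @export
tidy.signal_test <- function(x, ...) {
  tibble::tibble(
    trait = x$trait,
    var_contr = x$observed_variance,
    p_value = x$p_value,
    n_randomizations = x$n_randomizations,
    alternative = x$alternative
  )
}

#' Correlation of two traits' independent contrasts
#'
#' Contrasts have an arbitrary sign and expectation zero, so their
#' association is measured by the correlation through the origin,
#' `r = sum(x_i y_i) / sqrt(sum(x_i^2) sum(y_i^2))`. A parametric p-value
#' uses `t = r sqrt((n - 1) / (1 - r^2))` on `n - 1` degrees of freedom; an
#' optional randomization p-value flips contrast signs at random, which is
#' the exchangeable operation for contrasts.
#'
#' @param cx,cy `contrast_set` objects from the same tree (same nodes, same
#'   order).
#' @param n_randomizations Number of sign-flip randomizations (0 to skip).
#' @param seed Integer seed for the sign flips.
#' @return Tibble with `trait_x`, `trait_y`, `r`, `df`, `t`, `p_value`
#'   (parametric, two-sided) and `p_randomization` (`NA` when skipped).
#' @export
pic_correlation <- function(cx, cy, n_randomizations = 0, seed = 1) {
  stopifnot(inherits(cx, "contrast_set"), inherits(cy, "contrast_set"))
  if (nrow(cx) != nrow(cy) || any(cx$node != cy$node)) {
    abort("contrast sets come from different trees or node orders")
  }
  x <- cx$contrast
  y <- cy$contrast
  n <- length(x)
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0) abort("all contrasts are zero for one trait; correlation undefined")
  r <- sum(x * y) / denom
  tstat <- r * sqrt((n - 1) / max(1 - r^2, .Machine$double.eps))
  p_par <- 2 * pt(-abs(tstat), df = n - 1)
  p_rand <- NA_real_
  if (n_randomizations > 0) {
    robs <- abs(r)
    exceed <- with_seed(seed, sum(vapply(seq_len(n_randomizations), function(i) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      abs(sum(s * x * y) / denom) >= robs - 1e-12
    }, logical(1))))
    p_rand <- (exceed + 1) / (n_randomizations + 1)
  }
  tibble::tibble(
    trait_x = attr(cx, "trait"), trait_y = attr(cy, "trait"),
    n_contrasts = n, r = r, df = n - 1, t = tstat,
    p_value = p_par, p_randomization = p_rand
  )
}

#' Numeric coding of nesting strategy
#'
#' Maps the dung-beetle nesting guilds to an ordinal numeric trait so they
#' can enter the contrast analyses alongside continuous traits. The default
#' order dweller (0) < tunneler (1) < roller (2) follows increasing
#' investment in relocating the brood away from the dung pat; it is an
#' assumption, flagged as a methodological caveat wherever the coding is
#' reported, and reconfigurable.
#'
#' @param strategy Character vector of guild labels (case-insensitive).
#' @param codes Named numeric vector giving the coding.
#' @return Numeric vector.
#' @examples
#' encode_nesting(c("dweller", "Tunneler", "roller"))
#' @export
encode_nesting <- function(strategy, codes = c(dweller = 0, tunneler = 1, roller = 2)) {
  key <- tolower(trimws(as.character(strategy)))
  unknown <- setdiff(unique(key), names(codes))
  if (length(unknown) > 0) {
    abort(paste0("unknown nesting strategy: ", paste(unknown, collapse = ", ")))
  }
  unname(codes[key])
}

#' Phylogenetic signal and contrast correlations for a species trait table
#'
#' Convenience wrapper for the comparative stage of the pipeline: computes
#' the contrast-variance signal test for each species-mean trait (nesting
#' strategy entering through its ordinal coding) and the through-origin
#' contrast correlation of the first trait against each of the others.
#'
#' @param species_traits Data frame with a `species` column matching the tree
#'   tips and one column per trait.
#' @param tree Validated `phylo` object.
#' @param traits Character vector of trait columns to analyse.
#' @param n_randomizations Tip shuffles per signal test.
#' @param seed Integer seed.
#' @return List with tibbles `signal` (trait, VarContr, p) and `correlations`
#'   (trait pair, r, parametric and randomization p).
#' @export
phylo_screen <- function(species_traits, tree, traits,
                         n_randomizations = 999, seed = 1) {
  validate_tree(tree)
  species_traits <- tibble::as_tibble(species_traits)
  stopifnot("species" %in% names(species_traits), all(traits %in% names(species_traits)))
  sig <- purrr::map_dfr(traits, function(tr) {
    vals <- setNames(species_traits[[tr]], species_traits$species)
    tidy(signal_test(tree, vals,
      n_randomizations = n_randomizations,
      seed = substream_seed(seed, paste0("signal-", tr)), trait = tr
    ))
  })
  csets <- lapply(traits, function(tr) {
    independent_contrasts(tree, setNames(species_traits[[tr]], species_traits$species), trait = tr)
  })
  cors <- purrr::map_dfr(seq_along(traits)[-1], function(i) {
    pic_correlation(csets[[1]], csets[[i]],
      n_randomizations = n_randomizations,
      seed = substream_seed(seed, paste0("picr-", traits[i]))
    )
  })
  list(signal = sig, correlations = cors)
}
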