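#' Simulate a pure-birth phylogeny
#'
#' Draws a rooted, fully bifurcating Yule (pure-birth) tree with `n_tips` tips
#' and positive branch lengths, relabelling tips `sp1 ... spN` so they match
#' the species identifiers used by the assay simulator. Output is
#' deterministic for a given `seed`.
#'
#' @param n_tips Number of tips (at least 2).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param birth Speciation rate of the pure-birth process (default 1; only
#'   rescales depth).
#' @return An [ape::rphylo()]-style `phylo` object.
#' @examples
#' tr <- simulate_tree(8, seed = 7)
#' ape::Ntip(tr)
#' @export
simulate_tree <- function(n_tips, seed, birth = 1) {
  check_scalar(n_tips, "n_tips", lower = 2, integer = TRUE)
  check_scalar(birth, "birth", lower = 0, strict = TRUE)
  tree <- with_seed(seed, ape::rphylo(as.integer(n_tips), birth = birth, death = 0))
  tree$tip.label <- paste0("sp", seq_len(ape::Ntip(tree)))
  tree
}

#' Simulate Brownian-motion trait values on a tree
#'
#' Evolves a continuous trait from `root_value` along each edge by adding an
#' independent mean-zero normal increment with variance `sigma2 *
#' branch_length`. Under this model standardized independent contrasts are
#' i.i.d. normal with variance `sigma2`, which makes the generator the ground
#' truth for the contrast-based analyses.
#'
#' @param tree A rooted `phylo` object with positive branch lengths.
#' @param sigma2 Brownian rate (variance accrued per unit branch length), > 0.
#' @param root_value Trait value at the root (default 0).
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values (names are tip labels).
#' @examples
#' tr <- simulate_tree(8, seed = 1)
#' simulate_bm_traits(tr, sigma2 = 1, seed = 2)
#' @export
simulate_bm_traits <- function(tree, sigma2, root_value = 0, seed = 1) {
  validate_tree(tree, require_binary = FALSE)
  check_scalar(sigma2, "sigma2", lower = 0, strict = TRUE)
  check_scalar(root_value, "root_value")
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  # preorder walk: parents are assigned before their children
  ord <- rev(ape::postorder(tree))
  val <- rep(NA_real_, n_node)
  val[n_tip + 1L] <- root_value
  incr <- with_seed(seed, rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length)))
  for (e in ord) {
    val[tree$edge[e, 2L]] <- val[tree$edge[e, 1L]] + incr[e]
  }
  setNames(val[seq_len(n_tip)], tree$tip.label)
}
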