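test_that("Newick reader enforces the tree invariants", {
  tr <- read_newick("(A:1,B:1);")
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(tr$Nnode, 1)
  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  depths <- ape::node.depth.edgelength(tr3)[1:3]
  expect_equal(unname(depths), c(2, 2, 2))
  expect_error(read_newick("(A:1,B:1,C:1);"), "polytomies")
  expect_error(read_newick("(A:1,B);"), "branch length")
  expect_error(read_newick("((A:1,B:1):1,A:2);"), "unique")
  expect_error(read_newick("((A:1,B:0):1,C:2);"), "> 0")
})

test_that("contrasts match hand computation and are zero for constant traits", {
  tr2 <- read_newick("(A:1,B:1);")
  cs <- independent_contrasts(tr2, c(A = 3, B = 1))
  expect_equal(nrow(cs), 1)
  expect_equal(abs(cs$contrast), 2 / sqrt(2))
  expect_equal(cs$expected_variance, 2)

  tr3 <- read_newick("((A:1,B:1):1,C:2);")
  cs3 <- independent_contrasts(tr3, c(A = 2, B = 4, C = 6))
  # contrast(A,B) = (2-4)/sqrt(2); ancestor = 3 on a branch lengthened to 1.5;
  # contrast(anc, C) = (3-6)/sqrt(1.5+2)
  expect_setequal(round(cs3$contrast, 5), round(c(-2 / sqrt(2), -3 / sqrt(3.5)), 5))

  const <- independent_contrasts(tr3, c(A = 1, B = 1, C = 1))
  expect_equal(const$contrast, c(0, 0))
  expect_error(independent_contrasts(tr3, c(A = 1, B = 2)), "missing trait values")
})

test_that("contrast count is conserved and values agree with ape::pic", {
  for (s in 1:20) {
    n <- sample(4:16, 1)
    tr <- simulate_tree(n, seed = s)
    x <- simulate_bm_traits(tr, sigma2 = 2, seed = s + 100)
    cs <- independent_contrasts(tr, x)
    expect_equal(nrow(cs), n - 1)
    expect_true(all(cs$expected_variance > 0))
    oracle <- ape::pic(x[tr$tip.label], tr)
    expect_equal(sort(abs(cs$contrast)), sort(abs(unname(oracle))), tolerance = 1e-10)
  }
})

test_that("recursive contrasts agree with brute-force Brownian GLS", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    tr <- simulate_tree(n, seed = 5000 + i)
    x <- simulate_bm_traits(tr, sigma2 = 1, root_value = 2, seed = 6000 + i)
    ss <- sum(independent_contrasts(tr, x)$contrast^2)
    expect_equal(ss, gls_contrast_ss(tr, x), tolerance = 1e-8)
  }
})

test_that("contrast variance follows the population convention", {
  expect_equal(contrast_variance(c(1, -1)), 1)
  expect_equal(contrast_variance(c(0, 0, 0)), 0)
  expect_error(contrast_variance(0.5), "fewer than 2")
})

test_that("standardized contrasts under BM behave like iid Normal(0, sigma2)", {
  tr <- simulate_tree(24, seed = 77)
  cc <- unlist(lapply(1:120, function(s) {
    independent_contrasts(tr, simulate_bm_traits(tr, sigma2 = 1.7, seed = s))$contrast
  }))
  expect_lt(abs(mean(cc)), 3 * sqrt(1.7 / length(cc)))
  expect_lt(abs(var(cc) - 1.7), 3 * sqrt(2 / length(cc)) * 1.7)
})

test_that("signal test is seed-stable, affine-invariant, and rejects degenerate traits", {
  tr <- simulate_tree(16, seed = 9)
  x <- simulate_bm_traits(tr, 1, seed = 10)
  s1 <- signal_test(tr, x, n_randomizations = 199, seed = 4)
  s2 <- signal_test(tr, x, n_randomizations = 199, seed = 4)
  expect_identical(s1$p_value, s2$p_value)
  s3 <- signal_test(tr, 3 * x - 7, n_randomizations = 199, seed = 4)
  expect_identical(s1$p_value, s3$p_value)
  expect_error(
    signal_test(tr, setNames(rep(1, 16), tr$tip.label), n_randomizations = 199),
    "constant"
  )
  expect_error(signal_test(tr, x, n_randomizations = 50), "range")
  # p-value respects the add-one floor
  expect_gte(s1$p_value, 1 / 200)
})

test_that("strong Brownian signal on a deep tree is detected", {
  tr <- simulate_tree(32, seed = 21)
  x <- simulate_bm_traits(tr, sigma2 = 1, seed = 22)
  s <- signal_test(tr, x, n_randomizations = 199, seed = 23)
  expect_lt(s$p_value, 0.05)
})

test_that("contrast correlation through the origin hits its closed forms", {
  tr <- simulate_tree(12, seed = 31)
  x <- simulate_bm_traits(tr, 1, seed = 32)
  cx <- independent_contrasts(tr, x, trait = "x")
  cy <- cx
  cy$contrast <- 2 * cx$contrast
  r <- pic_correlation(cx, cy)
  expect_equal(r$r, 1)
  cy$contrast <- -cx$contrast
  expect_equal(pic_correlation(cx, cy)$r, -1)
  # randomization p agrees in direction with the parametric one
  y <- simulate_bm_traits(tr, 1, seed = 33)
  cz <- independent_contrasts(tr, y, trait = "y")
  both <- pic_correlation(cx, cz, n_randomizations = 499, seed = 34)
  expect_true(both$p_randomization > 0 && both$p_randomization <= 1)
  expect_equal(both$df, 10) # 12 tips -> 11 contrasts -> n - 1 df
  tr2 <- simulate_tree(8, seed = 35)
  cw <- independent_contrasts(tr2, simulate_bm_traits(tr2, 1, seed = 36))
  expect_error(pic_correlation(cx, cw), "different trees")
})

test_that("through-origin correlation matches the regression-through-origin oracle", {
  tr <- simulate_tree(20, seed = 41)
  cx <- independent_contrasts(tr, simulate_bm_traits(tr, 1, seed = 42))
  cy <- independent_contrasts(tr, simulate_bm_traits(tr, 1, seed = 43))
  res <- pic_correlation(cx, cy)
  # lm through the origin on contrasts: identical t statistic on n-1 df
  lmfit <- summary(lm(cy$contrast ~ cx$contrast - 1))
  expect_equal(abs(res$t), abs(lmfit$coefficients[1, "t value"]), tolerance = 1e-9)
  expect_equal(res$p_value, lmfit$coefficients[1, "Pr(>|t|)"], tolerance = 1e-9)
})

test_that("nesting-strategy coding is ordinal, case-insensitive and validated", {
  expect_equal(encode_nesting(c("dweller", "tunneler", "roller")), c(0, 1, 2))
  expect_equal(encode_nesting("Tunneler"), 1)
  expect_error(encode_nesting("burrower"), "unknown nesting strategy")
  expect_equal(
    encode_nesting("roller", codes = c(dweller = 2, tunneler = 1, roller = 0)), 0
  )
})

test_that("phylo_screen runs the full comparative table", {
  tr <- simulate_tree(8, seed = 51)
  sp <- tibble::tibble(
    species = tr$tip.label,
    dr = simulate_bm_traits(tr, 1, seed = 52),
    wlr = simulate_bm_traits(tr, 1, seed = 53)
  )
  scr <- phylo_screen(sp, tr, traits = c("dr", "wlr"), n_randomizations = 199, seed = 54)
  expect_equal(scr$signal$trait, c("dr", "wlr"))
  expect_true(all(scr$signal$p_value > 0 & scr$signal$p_value <= 1))
  expect_equal(nrow(scr$correlations), 1)
})
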