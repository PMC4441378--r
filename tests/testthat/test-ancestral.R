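test_that("GLS estimates match hand-inverted covariances", {
  # star tree: the root estimate is the arithmetic tip mean
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  y <- c(A = 2, B = 4, C = 6, D = 0)
  expect_equal(unname(bm_ancestral_gls(star, y)), mean(y))

  # 3-tip hand oracle: V = [[2,1,0],[1,2,0],[0,0,2]] gives
  # root = (2a + 2b + 3c) / 7; node(AB) = (3a + 3b + c) / 7
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  est <- bm_ancestral_gls(tr, c(A = 0, B = 0, C = 7))
  expect_equal(unname(est["node4"]), 3)
  expect_equal(unname(est["node5"]), 1)
  a <- 1.2; b <- -0.7; c <- 2.5
  est2 <- bm_ancestral_gls(tr, c(A = a, B = b, C = c))
  expect_equal(unname(est2["node4"]), (2 * a + 2 * b + 3 * c) / 7)

  # identical tip values are invariant
  tr6 <- build_reference_tree()
  est3 <- bm_ancestral_gls(tr6, setNames(rep(3.3, 6), tr6$tip.label))
  expect_equal(unname(est3), rep(3.3, 5))

  expect_error(bm_ancestral_gls(tr, c(A = 1, B = 2)), "C")
})

test_that("GLS estimates agree with an independent reconstruction", {
  library(phytools)
  set.seed(51)
  for (i in 1:3) {
    tr <- ape::rcoal(7)
    y <- setNames(rnorm(7, 10, 3), tr$tip.label)
    mine <- bm_ancestral_gls(tr, y)
    oracle <- phytools::fastAnc(tr, y)
    expect_equal(unname(mine), unname(as.numeric(oracle)), tolerance = 1e-6)
  }
})

test_that("estimates are convex in the tips and order-invariant", {
  set.seed(52)
  tr <- build_reference_tree()
  for (i in 1:20) {
    y <- setNames(rnorm(6, 0, 5), tr$tip.label)
    est <- bm_ancestral_gls(tr, y)
    expect_true(all(est >= min(y) - 1e-10 & est <= max(y) + 1e-10))
    expect_equal(bm_ancestral_gls(tr, y[sample(6)]), est)
  }
})

test_that("niche-history reconstruction aggregates PNO draws correctly", {
  tr <- build_reference_tree()
  point_profile <- function(v)
    pno_profile(c(1, 0), c(v, v + 1), n_bins = 2)

  # identical point masses: every node mean is that value, intervals empty
  profs <- setNames(lapply(rep(2.5, 6), point_profile), tr$tip.label)
  h <- ancestral_niche_history(tr, profs, n_samples = 50, seed = 1)
  expect_equal(h$summary$mean, rep(2.75, 11))  # center of the loaded bin
  expect_equal(h$summary$hi - h$summary$lo, rep(0, 11))

  # two-tip symmetry: root mean = (a + b) / 2
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  profs2 <- list(A = point_profile(0), B = point_profile(10))
  h2 <- ancestral_niche_history(tr2, profs2, n_samples = 20, seed = 1)
  root_row <- h2$summary[!h2$summary$is_tip, ]
  expect_equal(root_row$mean,
               mean(c(profs2$A$bin_center[1], profs2$B$bin_center[1])))

  # cloud sizes and reproducibility
  h3 <- ancestral_niche_history(tr, profs, n_samples = 100, seed = 9)
  expect_equal(nrow(h3$samples[[1]]), 100)
  h3b <- ancestral_niche_history(tr, profs, n_samples = 100, seed = 9)
  expect_identical(h3$samples, h3b$samples)

  # intervals contain the mean and hold ~80% of the samples
  set.seed(53)
  profs_r <- setNames(lapply(1:6, function(i)
    pno_profile(runif(50), rnorm(50, i), n_bins = 50)), tr$tip.label)
  h4 <- ancestral_niche_history(tr, profs_r, n_samples = 400, seed = 2)
  s <- h4$summary
  expect_true(all(s$mean >= s$lo - 1e-9 & s$mean <= s$hi + 1e-9))
  cloud <- h4$samples[[1]][, 1]
  inside <- mean(cloud >= s$lo[1] & cloud <= s$hi[1])
  expect_lt(abs(inside - 0.8), 0.05)

  # posterior tree sets are accepted
  trees <- perturb_tree_posterior(tr, 5, 0.05, seed = 3)
  h5 <- ancestral_niche_history(trees, profs_r, n_samples = 50, seed = 4)
  expect_equal(h5$n_samples, 50)

  dropped <- tr$tip.label[6]
  profs_bad <- profs_r[names(profs_r) != dropped]
  expect_error(ancestral_niche_history(tr, profs_bad, n_samples = 10),
               dropped)
})
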