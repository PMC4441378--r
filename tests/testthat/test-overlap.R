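test_that("Schoener's D matches hand evaluation and its identities", {
  # 4-cell hand oracle
  expect_equal(schoener_d(c(0.5, 0.5, 0, 0), c(0, 0.5, 0.5, 0)), 0.5)
  # complete overlap and disjoint supports
  z <- c(0.25, 0.25, 0.5, 0)
  expect_equal(schoener_d(z, z), 1)
  expect_equal(schoener_d(c(1, 0), c(0, 1)), 0)
  # symmetry
  a <- c(0.7, 0.2, 0.1, 0); b <- c(0.1, 0.1, 0.4, 0.4)
  expect_equal(schoener_d(a, b), schoener_d(b, a))
  expect_error(schoener_d(c(1, 0), c(0.3, 0.3, 0.4)), "lattice")
  expect_error(schoener_d(c(2, 0), c(1, 0)), "sum to 1")
})

test_that("density grids are normalized occupancies on an r x r lattice", {
  set.seed(21)
  bg <- uniform_bg(2000)
  occ <- cloud2d(80, c(1, -1), 0.8)
  dg <- density_grid(occ, bg, r = 100)
  expect_equal(dim(dg$z), c(100, 100))
  expect_equal(sum(dg$z), 1)
  expect_true(all(dg$z >= 0))
  expect_error(density_grid(occ[1:4, ], bg), "at least 5")
  expect_error(density_grid(cbind(rep(1, 10), 1:10), bg), "degenerate")

  # occurrences drawn uniformly like the background: occupancy ~ flat
  occ_u <- uniform_bg(1500)
  dg_u <- density_grid(occ_u, bg, r = 30)
  on_support <- dg_u$z[dg_u$z > 0]
  expect_lt(max(on_support) / mean(on_support), 6)

  # tight cluster on a broad background: occupancy mode at the cluster
  dg_c <- density_grid(cloud2d(200, c(3, 3), 0.3), bg, r = 100)
  peak <- which(dg_c$z == max(dg_c$z), arr.ind = TRUE)[1, ]
  expect_lt(abs(dg_c$x[peak[1]] - 3), 1)
  expect_lt(abs(dg_c$y[peak[2]] - 3), 1)
})

test_that("overlap classification reproduces the published bins", {
  expect_equal(as.character(classify_overlap(0.03)), "none")
  expect_equal(as.character(classify_overlap(0.26)), "low")
  expect_equal(as.character(classify_overlap(0.43)), "moderate")
  expect_equal(as.character(classify_overlap(c(0, 0.2, 0.4, 0.6, 0.8, 1))),
               c("none", "low", "moderate", "high", "very high", "very high"))
  expect_error(classify_overlap(1.2), "0, 1")
  expect_error(classify_overlap(-0.1), "0, 1")
})

test_that("equivalency p-value floors at 2/101 for fully divergent niches", {
  set.seed(22)
  occ1 <- cloud2d(60, c(-5, -5), 0.4)
  occ2 <- cloud2d(60, c(5, 5), 0.4)
  bg <- uniform_bg(2000)
  res <- equivalency_test(occ1, occ2, bg, n_reps = 100, seed = 7)
  expect_lt(res$observed, min(res$simulated))
  expect_equal(res$p_value, 2 / 101)
  expect_equal(round(res$p_value, 2), 0.02)
  expect_true(res$rejected)
  expect_length(res$simulated, 100)
  # determinism: same seed, same simulated sequence
  res2 <- equivalency_test(occ1, occ2, bg, n_reps = 100, seed = 7)
  expect_identical(res$simulated, res2$simulated)
})

test_that("equivalency holds when the two sets are one random split", {
  set.seed(23)
  pool <- cloud2d(120, c(0, 0), 1)
  bg <- uniform_bg(2000, -5, 5)
  res <- equivalency_test(pool[1:60, ], pool[61:120, ], bg,
                          n_reps = 60, seed = 11)
  expect_false(res$rejected)
  expect_gt(res$p_value, 0.05)
})

test_that("D declines monotonically as niche centers separate", {
  set.seed(24)
  bg <- uniform_bg(3000, -10, 10)
  occ1 <- cloud2d(120, c(0, 0), 1)
  seps <- c(0, 1.5, 3, 4.5, 6)
  ds <- vapply(seps, function(dx) {
    set.seed(1000 + round(dx * 10))
    occ2 <- cloud2d(120, c(dx, 0), 1)
    schoener_d(density_grid(occ1, bg), density_grid(occ2, bg))
  }, numeric(1))
  expect_lt(cor(seps, ds, method = "spearman"), -0.8)
})

test_that("similarity test detects habitat selection and respects the null", {
  set.seed(25)
  bg <- uniform_bg(2000, -5, 5)
  # both clades tightly clustered at the same spot inside a broad background:
  # observed overlap beats overlaps with random background draws
  occ_f <- cloud2d(80, c(0, 0), 0.5)
  occ_o <- cloud2d(80, c(0, 0), 0.5)
  res <- similarity_test(occ_f, occ_o, bg, n_reps = 100, seed = 3,
                         direction = "1->2")
  expect_gt(res$observed, quantile(res$simulated, 0.975))
  expect_true(res$rejected)
  expect_equal(res$direction, "1->2")

  # both clades spread like the background: the null generative match, so
  # rejections at the 95% level stay rare across replicate seeds
  rejections <- vapply(1:10, function(s) {
    set.seed(400 + s)
    occ_f2 <- uniform_bg(80, -5, 5)
    occ_o2 <- uniform_bg(80, -5, 5)
    similarity_test(occ_f2, occ_o2, bg, n_reps = 50,
                    seed = 500 + s)$rejected
  }, logical(1))
  expect_lte(mean(rejections), 0.3)
})
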