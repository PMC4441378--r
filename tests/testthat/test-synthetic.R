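test_that("stack generation is seed-deterministic and well-formed", {
  s1 <- tiny_stacks(seed = 7)
  s2 <- tiny_stacks(seed = 7)
  expect_identical(s1, s2)
  expect_named(s1, c("MIR", "DTLST", "NTLST", "NDVI", "EVI"))
  expect_equal(sum(vapply(s1, function(s) length(s$grids), 0L)), 60)

  s3 <- tiny_stacks(seed = 8)
  expect_false(identical(s1$MIR$grids[[1]]$values, s3$MIR$grids[[1]]$values))
})

test_that("daytime LST is never below nighttime LST, any cell or month", {
  for (seed in c(1, 2, 3)) {
    s <- tiny_stacks(seed = seed, noise_sd = 2, seasonal_amplitude = 8)
    for (m in 1:12)
      expect_true(all(s$DTLST$grids[[m]]$values >=
                        s$NTLST$grids[[m]]$values, na.rm = TRUE))
  }
})

test_that("zero seasonality and noise collapse the 12 months to one field", {
  s <- tiny_stacks(seed = 1, seasonal_amplitude = 0, noise_sd = 0)
  for (stk in s)
    for (m in 2:12)
      expect_equal(stk$grids[[m]]$values, stk$grids[[1]]$values)
})

test_that("invalid generation parameters are rejected", {
  expect_error(generate_monthly_stacks(extent = c(5, 0, 0, 10)), "extent")
  expect_error(generate_monthly_stacks(resolution = -1), "resolution")
  expect_error(generate_monthly_stacks(seasonal_amplitude = -1), ">= 0")
  expect_error(generate_monthly_stacks(noise_sd = -0.1), ">= 0")
})

test_that("masked cells are shared by all layers", {
  s <- tiny_stacks(seed = 3, mask_fraction = 0.2)
  na1 <- is.na(s$MIR$grids[[1]]$values)
  expect_gt(sum(na1), 0)
  for (stk in s)
    for (m in 1:12)
      expect_identical(is.na(stk$grids[[m]]$values), na1)
})

test_that("reference scenario reproduces the real per-clade record counts", {
  stacks <- tiny_stacks(seed = 11)
  occ <- generate_clade_occurrences(stacks, canonical_scenario("reference"),
                                    seed = 5)
  expect_s3_class(occ, "occurrence_set")
  expect_equal(nrow(occ), 261)
  counts <- table(occ$clade)[c("I", "II", "III", "IV", "V", "VI")]
  expect_equal(as.vector(counts), c(40, 47, 121, 15, 21, 17))
  # same seed, same records
  occ2 <- generate_clade_occurrences(stacks, canonical_scenario("reference"),
                                     seed = 5)
  expect_identical(occ, occ2)
})

test_that("disjoint-niche clades occupy non-overlapping environments", {
  stacks <- tiny_stacks(seed = 13)
  occ <- generate_clade_occurrences(stacks, canonical_scenario("disjoint"),
                                    seed = 9)
  mir_mean <- rowMeans(vapply(stacks$MIR$grids,
                              function(g) as.vector(g$values),
                              numeric(400)))
  ref <- stacks$MIR$grids[[1]]
  env_a <- mir_mean[cell_index_test(ref, occ[occ$clade == "A", ])]
  env_b <- mir_mean[cell_index_test(ref, occ[occ$clade == "B", ])]
  expect_lt(max(env_a), min(env_b))
})

test_that("a clade with no achievable suitability is reported by name", {
  stacks <- tiny_stacks(seed = 13)
  far <- scenario_spec(clades = c("ok", "impossible"),
                       centers = rbind(c(30, 25), c(1e5, 1e5)),
                       breadths = rbind(c(2, 2), c(2, 2)),
                       n_records = c(5, 5))
  expect_error(generate_clade_occurrences(stacks, far, seed = 1),
               "impossible")
})

test_that("reference tree has the published ages and is ultrametric", {
  tr <- build_reference_tree()
  expect_equal(sort(tr$tip.label), sort(c("I", "II", "III", "IV", "V", "VI")))
  ages <- ape::branching.times(tr)
  expect_equal(max(ages), 5.88)
  expect_equal(min(ages), 2.47)
  expect_equal(sort(unname(ages), decreasing = TRUE),
               c(5.88, 4.82, 4.32, 4.14, 2.47))
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(depths, rep(5.88, 6))
  # (II,III) split is the youngest node
  mrca23 <- ape::getMRCA(tr, c("II", "III"))
  expect_equal(unname(ages[as.character(mrca23)]), 2.47)
  # survives a Newick round trip
  tmp <- tempfile(fileext = ".nwk")
  ape::write.tree(tr, tmp)
  expect_equal(ape::branching.times(read_tree(tmp)), ages)
})

test_that("posterior emulation jitters ages but preserves validity", {
  tr <- build_reference_tree()
  same <- perturb_tree_posterior(tr, 3, age_jitter_sd = 0, seed = 1)
  for (t2 in same) expect_equal(t2$edge.length, tr$edge.length)

  trees <- perturb_tree_posterior(tr, 1000, age_jitter_sd = 0.05, seed = 2)
  expect_length(trees, 1000)
  for (t2 in trees[c(1, 500, 1000)]) {
    expect_true(all(t2$edge.length > 0))
    expect_true(ape::is.ultrametric(t2, tol = 1e-8))
    expect_identical(t2$tip.label, tr$tip.label)
  }
  expect_false(identical(trees[[1]]$edge.length, trees[[2]]$edge.length))
  trees_b <- perturb_tree_posterior(tr, 1000, age_jitter_sd = 0.05, seed = 2)
  expect_identical(trees, trees_b)
  expect_error(perturb_tree_posterior(tr, 1, age_jitter_sd = 50, seed = 3,
                                      max_attempts = 3),
               "ordering")
})
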