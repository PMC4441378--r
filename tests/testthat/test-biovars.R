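test_that("single-series summaries match direct evaluation", {
  # constant series: zero seasonality, zero range
  b <- biovars_single(rep(4.2, 12))
  expect_equal(unname(b), c(4.2, 0, 4.2, 4.2, 0, 4.2, 4.2))

  # 1..12: oracle = sample SD and exhaustive window scan
  x <- as.numeric(1:12)
  b <- biovars_single(x)
  expect_equal(b[["BIO1"]], 6.5)
  expect_equal(b[["BIO4"]], sd(x) * 100)
  expect_equal(b[["BIO4"]], 360.56, tolerance = 1e-4)
  expect_equal(b[["BIO5"]], 12)
  expect_equal(b[["BIO6"]], 1)
  expect_equal(b[["BIO7"]], 11)
  expect_equal(b[["BIO10"]], max(oracle_quarters(x)))  # Oct-Dec = 11
  expect_equal(b[["BIO10"]], 11)
  expect_equal(b[["BIO11"]], min(oracle_quarters(x)))  # Jan-Mar = 2
  expect_equal(b[["BIO11"]], 2)

  # wrap-around quarter: extremes straddling the year boundary
  w <- c(8, 0, 0, 0, 0, 0, 0, 0, 0, 0, 7, 9)
  expect_equal(biovars_single(w)[["BIO10"]], 8)   # Nov-Dec-Jan
  expect_equal(biovars_single(w)[["BIO10"]], max(oracle_quarters(w)))

  expect_error(biovars_single(1:11), "length 12")
  expect_true(all(is.na(biovars_single(c(1:11, NA)))))
})

test_that("day/night summaries match direct evaluation", {
  b <- biovars_daynight(rep(30, 12), rep(20, 12))
  expect_equal(unname(b), c(25, 10, 100, 0, 30, 20, 10, 25, 25))

  # degenerate diurnal range: BIO3 defined as 0
  b0 <- biovars_daynight(rep(7, 12), rep(7, 12))
  expect_equal(b0[["BIO2"]], 0)
  expect_equal(b0[["BIO7"]], 0)
  expect_equal(b0[["BIO3"]], 0)

  expect_warning(biovars_daynight(rep(10, 12), rep(11, 12)), "below")
  expect_error(biovars_daynight(1:12, 1:6), "length 12")
})

test_that("seasonal summaries obey their order and shift invariants", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(12, 20, 5)
    b <- biovars_single(x)
    expect_true(b[["BIO6"]] <= b[["BIO11"]] + 1e-12)
    expect_true(b[["BIO11"]] <= b[["BIO1"]] + 1e-12)
    expect_true(b[["BIO1"]] <= b[["BIO10"]] + 1e-12)
    expect_true(b[["BIO10"]] <= b[["BIO5"]] + 1e-12)
    expect_gte(b[["BIO4"]], 0)
    expect_gte(b[["BIO7"]], 0)
    # adding a constant shifts levels, leaves ranges/seasonality alone
    b2 <- biovars_single(x + 3)
    expect_equal(b2[c("BIO1", "BIO5", "BIO6", "BIO10", "BIO11")],
                 b[c("BIO1", "BIO5", "BIO6", "BIO10", "BIO11")] + 3)
    expect_equal(b2[c("BIO4", "BIO7")], b[c("BIO4", "BIO7")])

    d <- x + abs(rnorm(12, 2)); n <- x - abs(rnorm(12, 2))
    bd <- biovars_daynight(d, n)
    bd2 <- biovars_daynight(d + 3, n + 3)
    expect_equal(bd2[c("BIO2", "BIO3", "BIO4", "BIO7")],
                 bd[c("BIO2", "BIO3", "BIO4", "BIO7")])
  }
  # BIO4 and BIO7 vanish iff the series is constant
  expect_equal(unname(biovars_single(rep(1, 12))[c("BIO4", "BIO7")]), c(0, 0))
  b <- biovars_single(c(rep(1, 11), 1.01))
  expect_gt(b[["BIO4"]], 0)
  expect_gt(b[["BIO7"]], 0)
})

test_that("predictor set has 30 correctly named and grouped variables", {
  stacks <- tiny_stacks(seed = 21)
  ps <- build_predictor_set(stacks)
  expect_length(ps$grids, 30)
  expect_equal(ps$manifest$name, paste0("X", 1:30))
  expect_equal(as.vector(table(ps$manifest$source)[c("MIR", "LST", "NDVI",
                                                     "EVI")]),
               c(7, 9, 7, 7))
  # naming contract: X4/X7 = MIR seasonality/annual range, X13 = LST
  # seasonality
  expect_equal(ps$manifest$transformation[c(4, 7, 13)],
               c("BIO4", "BIO7", "BIO4"))
  expect_equal(ps$manifest$source[c(4, 7, 13)], c("MIR", "MIR", "LST"))

  # X4 equals the per-cell single-series BIO4 of the MIR stack
  mir <- stack_rows(stacks$MIR)
  cell <- 17
  expect_equal(as.vector(ps$grids$X4$values)[cell],
               biovars_single(mir[cell, ])[["BIO4"]])
  expect_equal(as.vector(ps$grids$X7$values)[cell],
               biovars_single(mir[cell, ])[["BIO7"]])
  # X13: LST seasonality from the day/night pair
  d <- stack_rows(stacks$DTLST)[cell, ]; n <- stack_rows(stacks$NTLST)[cell, ]
  expect_equal(as.vector(ps$grids$X13$values)[cell],
               biovars_daynight(d, n)[["BIO4"]])
})

test_that("masked input cells are masked in all 30 predictors", {
  stacks <- tiny_stacks(seed = 22, mask_fraction = 0.15)
  ps <- build_predictor_set(stacks)
  na_in <- is.na(stacks$MIR$grids[[1]]$values)
  for (g in ps$grids)
    expect_identical(is.na(g$values), na_in)
})

test_that("stacks on different grids are refused", {
  stacks <- tiny_stacks(seed = 23)
  other <- tiny_stacks(seed = 23, extent = c(0, 5, 0, 5))
  stacks$EVI <- other$EVI
  expect_error(build_predictor_set(stacks), "EVI")
})
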