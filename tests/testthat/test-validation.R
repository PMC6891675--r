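# Kennard-Stone, folds, cross-validation, and validation statistics.

test_that("Kennard-Stone reproduces the hand-traced 1-D example", {
  m <- matrix(c(0, 1, 2, 9, 10), 5, 1)
  sp <- kennardStoneSplit(m, fraction = 0.6)   # select 3 of 5
  expect_equal(sp$calibration, c(1, 3, 5))     # points 0, 2, 10
  expect_equal(sp$validation, c(2, 4))
  expect_equal(sp$method, "kennard_stone")
})

test_that("Kennard-Stone equals the brute-force greedy oracle on small sets", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(3:8, 1)
    d <- sample(1:3, 1)
    m <- matrix(rnorm(n * d), n, d)
    k <- sample(2:(n - 1), 1)
    frac <- (k + 0.2) / n                      # round(frac * n) == k
    sp <- kennardStoneSplit(m, fraction = frac)
    expect_setequal(sp$calibration, bruteForceKS(m, k))
  }
})

test_that("Kennard-Stone split is a sized partition, incl. group-aware mode", {
  set.seed(7)
  m <- matrix(rnorm(60 * 5), 60)
  sp <- kennardStoneSplit(m, fraction = 0.9)
  expect_length(sp$calibration, 54)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), 1:60)

  # near-1 fraction selects every row
  spAll <- kennardStoneSplit(m, fraction = 0.999)
  expect_length(spAll$calibration, 60)

  # group-aware: replicate rows stay together
  groups <- rep(sprintf("g%02d", 1:20), each = 3)
  spg <- kennardStoneSplit(m, fraction = 0.9, groupIds = groups)
  expect_length(spg$calibration, 18 * 3)
  calG <- unique(groups[spg$calibration])
  valG <- unique(groups[spg$validation])
  expect_length(intersect(calG, valG), 0)
  expect_true(spg$groupAware)
  expect_error(kennardStoneSplit(m, fraction = 1.2), "fraction")
})

test_that("leave-five-out folds partition the rows as blocks of five", {
  f <- makeFoldsLeaveFiveOut(567, seed = 9)
  sizes <- tabulate(f)
  expect_length(sizes, 114)
  expect_equal(sort(unique(sizes)), c(2, 5))
  expect_equal(sum(sizes == 5), 113)
  expect_equal(sum(sizes), 567)

  expect_equal(makeFoldsLeaveFiveOut(5, seed = 1), rep(1L, 5))
  expect_identical(makeFoldsLeaveFiveOut(37, seed = 4),
                   makeFoldsLeaveFiveOut(37, seed = 4))
  expect_false(identical(makeFoldsLeaveFiveOut(37, seed = 4),
                         makeFoldsLeaveFiveOut(37, seed = 5)))
  expect_error(makeFoldsLeaveFiveOut(4, seed = 1), "fold size")

  # venetian-blinds scheme: deterministic interleaving, same fold count
  b <- makeFoldsLeaveFiveOut(23, seed = 1, scheme = "blinds")
  expect_equal(b, (seq_len(23) - 1L) %% 5L + 1L)
  expect_identical(b, makeFoldsLeaveFiveOut(23, seed = 99,
                                            scheme = "blinds"))
  expect_true(all(tabulate(b) <= 5))
})

test_that("cross-validation matches the independent Krylov double-loop oracle", {
  set.seed(15)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(15, sd = 0.2)
  seed <- 77
  cv <- crossValidateLV(X, y, recipe = preprocessRecipe("autoscale"),
                        lvMax = 3, seed = seed)
  oracle <- krylovCVOracle(X, y, 3, makeFoldsLeaveFiveOut(15, seed))
  expect_equal(cv$secvPerLV, oracle, tolerance = 1e-10)
  expect_equal(cv$chosenLV, which.min(oracle))
  expect_length(cv$secvPerLV, 3)
})

test_that("noiseless single-factor data select one latent variable", {
  set.seed(16)
  t0 <- rnorm(20)
  p0 <- rnorm(8)
  X <- t0 %o% p0
  y <- 2 + 3 * t0
  cv <- crossValidateLV(X, y, recipe = preprocessRecipe("center"),
                        lvMax = 3, seed = 2)
  expect_lte(cv$secvPerLV[1], 1e-6)
  expect_equal(cv$chosenLV, 1L)

  # stochastic invariant: with vanishing noise, 1 LV wins for every seed
  chosen <- vapply(1:20, function(s) {
    set.seed(100 + s)
    tt <- rnorm(20); pp <- rnorm(8)
    Xs <- tt %o% pp + matrix(rnorm(160, sd = 1e-6), 20)
    ys <- 1 + 2 * tt
    crossValidateLV(Xs, ys, recipe = preprocessRecipe("center"),
                    lvMax = 3, seed = s)$chosenLV
  }, 0L)
  expect_true(all(chosen == 1L))
})

test_that("an infeasible lvMax is reduced with a warning", {
  set.seed(17)
  X <- matrix(rnorm(10 * 3), 10)
  y <- rnorm(10)
  expect_warning(
    cv <- crossValidateLV(X, y, recipe = preprocessRecipe("center"),
                          lvMax = 8, seed = 1),
    "reduced")
  expect_length(cv$secvPerLV, 3)
})

test_that("SEC: hand value, zero at perfection, homogeneity", {
  y <- c(1, 2, 3, 4)
  expect_equal(sec(y, y, 1), 0)
  expect_equal(sec(y, y + c(1, -1, 1, -1), nLV = 1), sqrt(2))
  set.seed(18)
  yh <- y + rnorm(4, sd = 0.3)
  expect_equal(sec(3 * y, 3 * yh, 1), 3 * sec(y, yh, 1))
  expect_error(sec(y, y, 3), "degrees of freedom")
  # SEC charges a constant offset, SEP does not (documented asymmetry)
  expect_gt(sec(y, y + 1, 1), 0)
  expect_equal(sep(y, y + 1), 0)
})

test_that("SEP and bias: hand values and shift invariance", {
  y <- c(0, 0, 0)
  expect_equal(sep(y, y), 0)
  expect_equal(predictionBias(y, y), 0)
  expect_equal(predictionBias(y, y + 1), 1)
  expect_equal(sep(y, y + 1), 0)
  expect_equal(predictionBias(y, y + c(0, 1, 2)), 1)
  expect_equal(sep(y, y + c(0, 1, 2)), 1)
  set.seed(19)
  yy <- rnorm(10); dd <- rnorm(10)
  expect_equal(sep(yy, yy + dd + 5), sep(yy, yy + dd), tolerance = 1e-12)
  expect_error(sep(1, 1), "at least 2")
})

test_that("R-squared: perfection, affine invariance, hand value", {
  y <- c(1, 2, 3)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, 2 * y - 5), 1)
  expect_equal(rSquared(y, c(1, 2, 2)), 0.75)
  set.seed(20)
  yy <- rnorm(12); yh <- yy + rnorm(12, sd = 0.5)
  expect_equal(rSquared(3 * yy - 1, yh), rSquared(yy, yh),
               tolerance = 1e-12)
  expect_equal(rSquared(y, y, method = "explained"), 1)
  expect_error(rSquared(y, c(2, 2, 2)), "variance")
})

test_that("paired t statistic: hand values and band logic", {
  y <- c(5, 6, 7)
  tt <- pairedT(y, y)
  expect_equal(tt$t, 0)
  expect_true(tt$withinBand)
  t2 <- pairedT(y, y + c(1, 2, 3))
  expect_equal(t2$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_false(t2$withinBand)
  expect_equal(t2$df, 2L)
  expect_error(pairedT(y, y + 1), "degenerate")
  t3 <- pairedT(rnorm(10), rnorm(10), tail = "two")
  expect_equal(t3$tCritical, qt(0.975, 9))
})
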