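# NIPALS PLS1: algebraic correctness against independent oracles.

test_that("a constant response yields the degenerate zero model", {
  set.seed(1)
  X <- matrix(rnorm(24), 6)
  m <- fitPLS(X, rep(3.7, 6), nLV = 2)
  expect_equal(nLV(m), 0L)
  expect_equal(coef(m), rep(0, 4))
  expect_equal(predict(m, X), rep(3.7, 6))
})

test_that("full-rank NIPALS equals the least-squares oracle", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    X <- matrix(rnorm(24), 8, 3)
    y <- rnorm(8)
    m <- fitPLS(X, y, nLV = 3)
    ols <- olsFit(X, y)
    expect_equal(predict(m, X), ols$fitted, tolerance = 1e-8)
    # b on the preprocessed scale relates to OLS b via the y scaling
    expect_equal(coef(m) * m@yScale, ols$b, tolerance = 1e-8)
  }
})

test_that("a one-component model matches the explicit formula", {
  set.seed(21)
  X <- matrix(rnorm(24), 6, 4)
  y <- rnorm(6)
  m <- fitPLS(X, y, nLV = 1)
  Xc <- scale(X, scale = FALSE)
  yc <- (y - mean(y)) / sd(y)
  w <- crossprod(Xc, yc)[, 1]; w <- w / sqrt(sum(w^2))
  t <- (Xc %*% w)[, 1]
  q <- sum(yc * t) / sum(t^2)
  expect_equal(predict(m, X), mean(y) + sd(y) * q * t, tolerance = 1e-10)
})

test_that("training RSS is non-increasing and scores are orthogonal", {
  set.seed(31)
  X <- matrix(rnorm(20 * 8), 20)
  y <- X[, 1] - 2 * X[, 3] + rnorm(20, sd = 0.3)
  rss <- vapply(1:6, function(a) {
    m <- fitPLS(X, y, a)
    sum((y - predict(m, X))^2)
  }, 0)
  expect_true(all(diff(rss) <= 1e-10))

  m <- fitPLS(X, y, 6)
  Tm <- m@scores
  for (a in 1:5) for (b in (a + 1):6) {
    expect_lt(abs(sum(Tm[, a] * Tm[, b])),
              1e-8 * sqrt(sum(Tm[, a]^2) * sum(Tm[, b]^2)))
  }
  # stored b reproduces the prediction identity
  expect_equal(predict(m, X),
               m@yMean + m@yScale * ((scale(X, center = m@xMean,
                                            scale = FALSE) %*% coef(m))[, 1]),
               tolerance = 1e-12)
})

test_that("prediction is deterministic, row-local and centered correctly", {
  set.seed(41)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- fitPLS(X, y, 2)
  # a row equal to the training column means predicts the mean response
  expect_equal(predict(m, matrix(m@xMean, 1)), m@yMean)
  # duplicated rows -> duplicated predictions; row order irrelevant
  p1 <- predict(m, X[c(1, 1, 5), ])
  expect_equal(p1[1], p1[2])
  expect_equal(predict(m, X[10:1, ]), rev(predict(m, X)))
  expect_error(predict(m, X[, 1:2]), "columns")
  expect_error(fitPLS(X, y, 12), "exceeds")
  expect_error(fitPLS(X, y[1:5], 2), "length")
})

test_that("a response orthogonal to X raises a rank error naming the component", {
  X <- cbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  y <- c(1, -1, -1, 1)          # orthogonal to both centered columns
  expect_error(fitPLS(X, y, 1), "component 1")
})

test_that("loading spectra peak at the coupled band and regions rank correctly", {
  cfg <- singleBandConfig(property = "moisture", coupling = 0.4,
                          centerIdx = 120, nSamples = 16)
  tab <- generatePropertyTable(cfg)
  sm <- generateSpectra(tab, cfg)
  y <- tab$moisture[match(sampleIds(sm), tab$sample_id)]
  m <- fitPLS(sm, y, 1)
  ld <- loadingsSpectrum(m, 1)
  expect_equal(nrow(ld), 300L)
  expect_equal(ld$wavenumber, wavenumbers(sm))
  expect_lte(abs(which.max(abs(ld$loading)) - 120), 1)
  expect_error(loadingsSpectrum(m, 2), "component")

  # the region containing the band must rank first
  w <- wavenumbers(sm)
  center <- w[120]
  rk <- topLoadingRegions(ld)
  expect_true(rk$lo[1] <= center && center <= rk$hi[1])

  # all-zero loading: regions tie, ordered by start
  zero <- topLoadingRegions(rep(0, 300), w)
  expect_equal(zero$lo, sort(honeyLoadingRegions()$lo))

  # one region covering the whole grid reproduces the global mean
  one <- topLoadingRegions(ld$loading, w,
                           regions = data.frame(lo = 200, hi = 2000))
  expect_equal(one$meanAbsLoading, mean(abs(ld$loading)))
  expect_error(topLoadingRegions(ld$loading, w,
                                 regions = data.frame(lo = 5000, hi = 6000)),
               "no grid point")
})

test_that("models serialize to JSON and back without loss", {
  set.seed(51)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  m <- fitPLS(X, y, 2, wavenumbers = c(400, 500, 600, 700))
  path <- withr::local_tempfile(fileext = ".json")
  writePLSModel(m, path)
  back <- readPLSModel(path)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
  expect_equal(back@xLoadings, m@xLoadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nLV(back), nLV(m))
})
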