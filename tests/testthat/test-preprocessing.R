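# Spectral preprocessing operators and recipe composition.

test_that("snv standardizes rows and is idempotent", {
  expect_equal(snv(matrix(c(1, 2, 3), 1)), matrix(c(-1, 0, 1), 1))
  set.seed(1)
  m <- matrix(rnorm(40, mean = 5, sd = 3), 4)
  s <- snv(m)
  expect_equal(rowMeans(s), rep(0, 4))
  expect_equal(apply(s, 1, sd), rep(1, 4))
  expect_equal(snv(s), s, tolerance = 1e-12)
  expect_error(snv(matrix(c(5, 5, 5), 1)), "constant")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and the published kernel", {
  w <- seq(0, 20, by = 0.5)
  quad <- matrix(2.5 * w^2 - 3 * w + 1, 1)
  expect_equal(smoothSavGol(quad, 11, 2), quad, tolerance = 1e-9)
  const <- matrix(rep(7, 41), 1)
  expect_equal(smoothSavGol(const, 11, 2), const, tolerance = 1e-12)

  # impulse response of the interior filter = SG(5,2) kernel
  imp <- rep(0, 21); imp[11] <- 1
  sm <- smoothSavGol(matrix(imp, 1), 5, 2)
  expect_equal(sm[1, 9:13], c(-3, 12, 17, 12, -3) / 35, tolerance = 1e-12)

  expect_error(smoothSavGol(quad, 10, 2), "odd")
  expect_error(smoothSavGol(quad, 5, 5), "polyorder")
  expect_error(smoothSavGol(matrix(1:3, 1), 5, 2), "exceeds")
})

test_that("Savitzky-Golay derivative is exact on linears and quadratics", {
  grid <- seq(100, 200, by = 2)           # spacing 2 cm-1
  ramp <- matrix(2 * grid, 1)             # slope 2 a.u./cm-1
  d <- derivativeSavGol(ramp, 11, 2, grid)
  expect_equal(d[1, ], rep(2, length(grid)), tolerance = 1e-9)

  expect_equal(derivativeSavGol(matrix(rep(3, 51), 1), 11, 2, grid)[1, ],
               rep(0, 51), tolerance = 1e-10)

  a <- 0.05; b <- -1.5
  quad <- matrix(a * grid^2 + b * grid + 2, 1)
  dq <- derivativeSavGol(quad, 11, 2, grid)
  expect_equal(dq[1, 6:46], (2 * a * grid + b)[6:46], tolerance = 1e-9)

  expect_error(derivativeSavGol(ramp, 11, 2, c(grid[-51], 405)),
               "uniform")
})

test_that("ALS baseline: flat limit, additivity, peak recovery on a ramp", {
  flat <- matrix(rep(4.2, 120), 1)
  bl <- baselineALS(flat)
  expect_true(max(abs(bl$corrected)) <= 1e-6)
  expect_true(max(abs(bl$baseline - 4.2)) <= 1e-6)

  # corrected + baseline recomposes the input (up to one rounding ulp)
  set.seed(2)
  m <- matrix(abs(rnorm(300)), 2)
  bl2 <- baselineALS(m)
  expect_equal(bl2$corrected + bl2$baseline, m, tolerance = 1e-12)

  # Gaussian peak on a linear ramp: apex recovered within 2%
  idx <- seq_len(400)
  ramp <- 0.5 + 0.004 * idx
  peak <- exp(-(idx - 200)^2 / (2 * 12^2))
  bl3 <- baselineALS(matrix(ramp + peak, 1), lambda = 1e5, p = 0.001)
  expect_equal(max(bl3$corrected[1, ]), 1, tolerance = 0.02)

  expect_error(baselineALS(matrix(1:2, 1)), "3 points")
  expect_error(baselineALS(matrix(1:5, 1), lambda = -1), "lambda")
  expect_error(baselineALS(matrix(1:5, 1), p = 1.5), "p must")
})

test_that("row normalization hand cases", {
  expect_equal(normalizeRows(matrix(c(1, 3), 1), "area"),
               matrix(c(0.25, 0.75), 1))
  expect_equal(normalizeRows(matrix(c(2, 2), 1), "max"),
               matrix(c(1, 1), 1))
  expect_equal(normalizeRows(matrix(c(3, 4), 1), "vector"),
               matrix(c(0.6, 0.8), 1))
  expect_error(normalizeRows(matrix(c(0, 0), 1), "vector"), "zero")
  # idempotence
  set.seed(3)
  m <- matrix(abs(rnorm(30)) + 0.1, 3)
  for (mode in c("area", "max", "vector"))
    expect_equal(normalizeRows(normalizeRows(m, mode), mode),
                 normalizeRows(m, mode), tolerance = 1e-12)
})

test_that("log10 transform and its error reporting", {
  expect_equal(log10Transform(matrix(1, 2, 3)), matrix(0, 2, 3))
  expect_equal(log10Transform(matrix(100, 1))[1, 1], 2)
  m <- matrix(c(2, -0.5, 3), 1)
  expect_equal(log10Transform(m, offset = 1)[1, 2], log10(0.5))
  expect_error(log10Transform(m), "row 1, column 2")
})

test_that("alignment estimates and undoes integer shifts", {
  set.seed(4)
  ref <- exp(-(seq_len(200) - 80)^2 / 50) + 0.2
  row <- ref[pmin(pmax(seq_len(200) - 3, 1), 200)]  # ref shifted +3
  al <- alignToReference(matrix(row, 1), ref, shiftMax = 5)
  expect_equal(attr(al, "shifts"), -3L)
  expect_equal(al[1, 10:190], ref[10:190], tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical row: shift 0, unchanged
  al0 <- alignToReference(matrix(ref, 1), ref, shiftMax = 5)
  expect_equal(attr(al0, "shifts"), 0L)
  expect_equal(al0[1, ], ref, ignore_attr = TRUE)

  # shiftMax 0 is the constrained identity even for white noise
  noise <- rnorm(200)
  aln <- alignToReference(matrix(noise, 1), ref, shiftMax = 0)
  expect_equal(aln[1, ], noise, ignore_attr = TRUE)
})

test_that("center/autoscale keep strict fit/apply separation", {
  set.seed(5)
  cal <- matrix(rnorm(60, mean = 3), 10)
  sc <- fitColumnScaler(cal, "autoscale")
  calT <- applyColumnScaler(cal, sc)
  expect_true(max(abs(colMeans(calT))) <= 1e-12)
  expect_equal(apply(calT, 2, sd), rep(1, 6), tolerance = 1e-12)

  # held-out rows are transformed with the calibration statistics
  held <- matrix(rnorm(6, mean = 50), 1)
  heldT <- applyColumnScaler(held, sc)
  expect_equal(heldT[1, ], (held[1, ] - sc$means) / sc$sds)

  scC <- fitColumnScaler(cal, "center")
  expect_equal(scC$sds, rep(1, 6))
  expect_error(fitColumnScaler(cbind(cal, 7), "autoscale"),
               "zero variance")
})

test_that("recipes compose steps with calibration-only state", {
  cal <- randomSpectra(n = 8, p = 40, seed = 6,
                       wavenumbers = seq(300, 1080, by = 20))
  val <- randomSpectra(n = 3, p = 40, seed = 7,
                       wavenumbers = seq(300, 1080, by = 20))
  # shift intensities positive so area normalization is well defined
  cal@intensities <- cal@intensities + 6
  val@intensities <- val@intensities + 6

  # empty recipe is the identity
  id <- fitRecipe(preprocessRecipe(), cal)
  expect_equal(applyRecipe(id, cal), cal)

  # [snv] recipe equals row-wise snv
  r1 <- fitRecipe(preprocessRecipe("snv"), cal)
  expect_equal(intensities(applyRecipe(r1, cal)), snv(intensities(cal)),
               ignore_attr = TRUE)

  # multi-step recipe equals the manual step-by-step chain, with
  # validation rows transformed by calibration-fitted state
  rec <- preprocessRecipe("baseline",
                          list(name = "smooth", window = 7),
                          list(name = "normalize", mode = "area"),
                          "snv", "center")
  fitted <- fitRecipe(rec, cal)
  outCal <- applyRecipe(fitted, cal)
  outVal <- applyRecipe(fitted, val)

  man <- function(m) {
    m <- baselineALS(m)$corrected
    m <- smoothSavGol(m, 7, 2)
    m <- normalizeRows(m, "area")
    snv(m)
  }
  mCal <- man(intensities(cal))
  sc <- fitColumnScaler(mCal, "center")
  expect_equal(intensities(outCal), applyColumnScaler(mCal, sc),
               ignore_attr = TRUE)
  expect_equal(intensities(outVal),
               applyColumnScaler(man(intensities(val)), sc),
               ignore_attr = TRUE)

  expect_error(applyRecipe(rec, cal), "unfitted")
  expect_error(preprocessRecipe("wavelet"), "unknown step")
  expect_error(preprocessRecipe(list(name = "smooth", widnow = 7)),
               "unknown parameter")
})

test_that("operators are row-local, shape-preserving, and linear where claimed", {
  set.seed(8)
  m <- matrix(abs(rnorm(120)) + 1, 4)
  grid <- seq(100, 158, by = 2)
  perm <- c(3, 1, 4, 2)
  ops <- list(
    function(x) snv(x),
    function(x) smoothSavGol(x, 7, 2),
    function(x) derivativeSavGol(x, 7, 2, grid),
    function(x) baselineALS(x)$corrected,
    function(x) normalizeRows(x, "vector"),
    function(x) log10Transform(x)
  )
  for (op in ops) {
    out <- op(m)
    expect_equal(dim(out), dim(m))                 # shape preserved
    expect_equal(op(m[perm, ]), out[perm, ])       # commutes with row perms
  }
  # linearity of the convolution operators
  a <- 2.3; b <- -0.7
  x <- matrix(rnorm(60), 2); y <- matrix(rnorm(60), 2)
  expect_equal(smoothSavGol(a * x + b * y, 7, 2),
               a * smoothSavGol(x, 7, 2) + b * smoothSavGol(y, 7, 2),
               tolerance = 1e-9)
  g2 <- seq(1, 59, by = 2)
  expect_equal(derivativeSavGol(a * x + b * y, 7, 2, g2),
               a * derivativeSavGol(x, 7, 2, g2) +
                 b * derivativeSavGol(y, 7, 2, g2),
               tolerance = 1e-9)
})
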