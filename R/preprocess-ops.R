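# Row-level spectral preprocessing operators. All operators act on plain
# numeric matrices (one spectrum per row) and preserve matrix shape; the
# recipe layer (recipe.R) lifts them onto SpectralMatrix objects and
# handles fitted state.

.asSpectraMat <- function(m) {
  if (is(m, "SpectralMatrix")) m <- m@intensities
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

#' Standard normal variate (SNV) transform
#'
#' Standardizes each spectrum to mean 0 and unit sample standard deviation
#' (denominator `n - 1`), the classic correction for multiplicative
#' scatter/intensity differences between spectra. Idempotent.
#'
#' @param m numeric matrix (rows = spectra) or [SpectralMatrix-class]
#'   intensities
#' @return matrix of the same shape
#' @export
snv <- function(m) {
  m <- .asSpectraMat(m)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  if (any(s == 0))
    .stopf("snv: row(s) %s are constant (zero variance)",
           paste(which(s == 0), collapse = ", "))
  (m - mu) / s
}

.checkSgParams <- function(window, polyorder, npt) {
  if (!.isWholeNumber(window) || window %% 2 == 0)
    .stopf("Savitzky-Golay window must be an odd integer (got %s)",
           format(window))
  if (!.isWholeNumber(polyorder) || polyorder < 0 || polyorder >= window)
    .stopf("Savitzky-Golay polyorder must satisfy 0 <= polyorder < window")
  if (window > npt)
    .stopf("Savitzky-Golay window (%d) exceeds row length (%d)",
           window, npt)
}

#' Savitzky-Golay smoothing
#'
#' Per-row local least-squares polynomial smoothing; rows that are exact
#' polynomials of degree `<= polyorder` pass through unchanged (including
#' the edges, which use one-sided fits).
#'
#' @inheritParams snv
#' @param window odd filter length (points)
#' @param polyorder polynomial degree, `< window`
#' @return smoothed matrix of the same shape
#' @export
smoothSavGol <- function(m, window = 11L, polyorder = 2L) {
  m <- .asSpectraMat(m)
  .checkSgParams(window, polyorder, ncol(m))
  t(apply(m, 1L, signal::sgolayfilt, p = polyorder, n = window))
}

#' Savitzky-Golay first derivative
#'
#' Per-row smoothed first derivative in intensity units per cm-1; the
#' kernel is scaled by the (uniform) grid spacing.
#'
#' @inheritParams smoothSavGol
#' @param grid wavenumber grid (cm-1); must be uniform to 1e-6 relative
#' @return derivative matrix of the same shape
#' @export
derivativeSavGol <- function(m, window = 11L, polyorder = 2L, grid) {
  m <- .asSpectraMat(m)
  .checkSgParams(window, polyorder, ncol(m))
  if (polyorder < 1L)
    .stopf("derivative needs polyorder >= 1")
  d <- diff(grid)
  if (length(grid) != ncol(m))
    .stopf("derivativeSavGol: grid length (%d) != column count (%d)",
           length(grid), ncol(m))
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
    .stopf(paste("derivativeSavGol: grid is not uniform; resample the",
                 "spectra onto a uniform grid first"))
  t(apply(m, 1L, signal::sgolayfilt, p = polyorder, n = window, m = 1L,
          ts = d[1]))
}

#' Asymmetric-least-squares (ALS) baseline estimation
#'
#' Estimates each row's baseline `z` as the minimizer of
#' `sum_i w_i (y_i - z_i)^2 + lambda * sum_i (d2 z)_i^2` with asymmetric
#' weights `w_i = p` where `y > z` (points above the baseline, i.e. peaks)
#' and `1 - p` below, iterated `nIter` times from uniform weights. The
#' corrected spectrum is `y - z`, so `corrected + baseline == input`
#' exactly.
#'
#' @inheritParams snv
#' @param lambda smoothness penalty (> 0); larger = stiffer baseline
#' @param p asymmetry in (0, 1); small values let peaks float above
#' @param nIter number of reweighting iterations
#' @return list with matrices `baseline` and `corrected`
#' @export
baselineALS <- function(m, lambda = 1e5, p = 0.001, nIter = 10L) {
  m <- .asSpectraMat(m)
  if (!(lambda > 0)) .stopf("baselineALS: lambda must be > 0")
  if (!(p > 0 && p < 1)) .stopf("baselineALS: p must be in (0, 1)")
  npt <- ncol(m)
  if (npt < 3L) .stopf("baselineALS: rows need at least 3 points")
  i <- seq_len(npt - 2L)
  D <- Matrix::sparseMatrix(i = c(i, i, i), j = c(i, i + 1L, i + 2L),
                            x = rep(c(1, -2, 1), each = npt - 2L),
                            dims = c(npt - 2L, npt))
  P <- lambda * Matrix::crossprod(D)
  base <- t(apply(m, 1L, function(y) {
    w <- rep(1, npt)
    z <- y
    for (it in seq_len(nIter)) {
      z <- as.numeric(Matrix::solve(Matrix::Diagonal(x = w) + P, w * y))
      w <- ifelse(y > z, p, 1 - p)
    }
    z
  }))
  if (nrow(m) == 1L) base <- matrix(base, 1L)
  list(baseline = base, corrected = m - base)
}

#' Row-wise normalization
#'
#' `area`: each row sums to 1; `max`: row maximum is 1; `vector`: unit
#' Euclidean norm. Idempotent in every mode.
#'
#' @inheritParams snv
#' @param mode normalization mode
#' @return normalized matrix of the same shape
#' @export
normalizeRows <- function(m, mode = c("area", "max", "vector")) {
  mode <- match.arg(mode)
  m <- .asSpectraMat(m)
  nrm <- switch(mode,
                area = rowSums(m),
                max = apply(m, 1L, max),
                vector = sqrt(rowSums(m^2)))
  if (any(nrm == 0))
    .stopf("normalizeRows: row(s) %s have zero %s norm",
           paste(which(nrm == 0), collapse = ", "), mode)
  m / nrm
}

#' Elementwise log10 transform
#'
#' @inheritParams snv
#' @param offset constant added before taking log10; every
#'   `intensity + offset` must be positive
#' @return transformed matrix
#' @export
log10Transform <- function(m, offset = 0) {
  m <- .asSpectraMat(m)
  shifted <- m + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)
    .stopf(paste("log10Transform: nonpositive argument at row %d, column %d",
                 "(value %g + offset %g); raise the offset or drop the",
                 "step"), bad[1, 1], bad[1, 2], m[bad[1, 1], bad[1, 2]],
           offset)
  }
  log10(shifted)
}

# Estimate the integer shift (within +/- shiftMax) that maximizes the
# cosine similarity between `row` shifted back and `reference` over the
# overlap; ties prefer the smaller |shift| (zero shift always admissible).
.estimateShift <- function(row, reference, shiftMax) {
  best <- 0L
  bestScore <- -Inf
  npt <- length(row)
  cand <- seq(-shiftMax, shiftMax)
  cand <- cand[order(abs(cand), cand)]
  for (s in cand) {
    # score the shifted-row candidate out[i] = row[i - s] against the
    # reference over their overlap
    if (s >= 0) {
      a <- row[seq_len(npt - s)]
      b <- reference[seq_len(npt - s) + s]
    } else {
      a <- row[seq_len(npt + s) - s]
      b <- reference[seq_len(npt + s)]
    }
    denom <- sqrt(sum(a^2) * sum(b^2))
    score <- if (denom > 0) sum(a * b) / denom else 0
    if (score > bestScore + 1e-12) {
      bestScore <- score
      best <- s
    }
  }
  best
}

#' Align spectra to a reference by integer grid shifts
#'
#' Each row is shifted by the integer number of grid points (within
#' `+/- shiftMax`) that maximizes its normalized cross-correlation with the
#' reference; vacated edge positions are filled with the nearest retained
#' value. No circular wrap-around. A row already matching the reference
#' gets shift 0 and passes through unchanged.
#'
#' @inheritParams snv
#' @param reference numeric reference spectrum on the same grid
#' @param shiftMax maximum absolute shift in grid points
#' @return aligned matrix; the per-row estimated shifts are attached as
#'   attribute `"shifts"`
#' @export
alignToReference <- function(m, reference, shiftMax = 5L) {
  m <- .asSpectraMat(m)
  if (length(reference) != ncol(m))
    .stopf("alignToReference: reference length (%d) != column count (%d)",
           length(reference), ncol(m))
  shifts <- integer(nrow(m))
  out <- m
  if (shiftMax > 0L) {
    idx <- seq_len(ncol(m))
    for (r in seq_len(nrow(m))) {
      s <- .estimateShift(m[r, ], reference, shiftMax)
      shifts[r] <- s
      if (s != 0L) out[r, ] <- m[r, pmin(pmax(idx - s, 1L), ncol(m))]
    }
  }
  attr(out, "shifts") <- shifts
  out
}

#' Fit / apply column centering or autoscaling
#'
#' `fitColumnScaler` learns column means (and sds for `autoscale`) on the
#' calibration rows; `applyColumnScaler` applies that fixed state to any
#' matrix, so held-out rows are transformed with the calibration
#' statistics, never their own.
#'
#' @inheritParams snv
#' @param type `"center"` (subtract column means) or `"autoscale"`
#'   (additionally divide by column sds)
#' @return `fitColumnScaler`: list with `type`, `means`, `sds`;
#'   `applyColumnScaler`: transformed matrix
#' @export
fitColumnScaler <- function(m, type = c("autoscale", "center")) {
  type <- match.arg(type)
  m <- .asSpectraMat(m)
  means <- colMeans(m)
  sds <- rep(1, ncol(m))
  if (type == "autoscale") {
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0))
      .stopf("autoscale: column(s) %s have zero variance on the fitting set",
             paste(utils::head(which(sds == 0), 5L), collapse = ", "))
  }
  list(type = type, means = means, sds = sds)
}

#' @rdname fitColumnScaler
#' @param scaler fitted state from `fitColumnScaler`
#' @export
applyColumnScaler <- function(m, scaler) {
  m <- .asSpectraMat(m)
  if (length(scaler$means) != ncol(m))
    .stopf("applyColumnScaler: state has %d columns, matrix has %d",
           length(scaler$means), ncol(m))
  sweep(sweep(m, 2L, scaler$means), 2L, scaler$sds, "/")
}
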