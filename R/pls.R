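# NIPALS PLS1: the core calibration model, implemented from scratch.

#' Fit a PLS1 calibration model by NIPALS
#'
#' Computes `nLV` latent variables for a single response: per component
#' `a`, the weight `w_a = X_a' y_a / ||X_a' y_a||`, score `t_a = X_a w_a`,
#' x-loading `p_a = X_a' t_a / (t_a' t_a)`, y-loading
#' `q_a = y_a' t_a / (t_a' t_a)`, followed by deflation
#' `X_{a+1} = X_a - t_a p_a'` and `y_{a+1} = y_a - q_a t_a`. The regression
#' vector is `b = W (P'W)^{-1} q`. `X` is expected to be already
#' recipe-preprocessed; the fit always centers `X` column-wise and centers
#' and scales `y` internally (predictor scaling belongs to the recipe's
#' autoscale step, keeping one source of truth). NIPALS PLS1 is fully
#' deterministic — no random initialization exists anywhere.
#'
#' A constant response is fitted as the degenerate 0-component model
#' (`b = 0`, intercept = the constant); a response orthogonal to `X` at
#' any component raises a rank error naming the component.
#'
#' @param X preprocessed calibration matrix (n x p) or
#'   [SpectralMatrix-class]
#' @param y numeric response vector, length n
#' @param nLV number of latent variables, `1 <= nLV <= min(n - 1, p)`
#' @param wavenumbers optional grid attached for loading interpretation
#'   (taken from `X` automatically when it is a `SpectralMatrix`)
#' @param earlyStop if `TRUE`, a component at which the deflated response
#'   is numerically orthogonal to the predictors truncates the model at
#'   the last informative component instead of raising (used during
#'   cross-validation, where exact low-rank data make large candidate
#'   counts unreachable); the default keeps the strict error contract
#' @return a [PLSModel-class]
#' @export
fitPLS <- function(X, y, nLV, wavenumbers = numeric(), earlyStop = FALSE) {
  if (is(X, "SpectralMatrix")) {
    if (!length(wavenumbers)) wavenumbers <- X@wavenumbers
    X <- X@intensities
  }
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n)
    .stopf("fitPLS: y length (%d) != row count (%d)", length(y), n)
  if (n < 2L) .stopf("fitPLS: need at least 2 calibration rows")
  if (!.isWholeNumber(nLV) || nLV < 1L)
    .stopf("fitPLS: nLV must be a positive integer")
  if (nLV > min(n - 1L, p))
    .stopf("fitPLS: nLV (%d) exceeds min(n - 1, p) = %d",
           nLV, min(n - 1L, p))
  nLV <- as.integer(nLV)

  xMean <- colMeans(X)
  xScale <- rep(1, p)
  Xc <- sweep(X, 2L, xMean)
  yMean <- mean(y)
  yScale <- stats::sd(y)

  if (!is.finite(yScale) || yScale == 0) {
    return(new("PLSModel", nLV = 0L,
               xMean = xMean, xScale = xScale,
               yMean = yMean, yScale = 1,
               weights = matrix(0, p, 0L), xLoadings = matrix(0, p, 0L),
               yLoadings = numeric(), scores = matrix(0, n, 0L),
               coefficients = rep(0, p), intercept = yMean,
               wavenumbers = as.numeric(wavenumbers)))
  }
  yc <- (y - yMean) / yScale

  W <- matrix(0, p, nLV)
  P <- matrix(0, p, nLV)
  Tm <- matrix(0, n, nLV)
  q <- numeric(nLV)
  tol <- 1e-12 * sqrt(sum(Xc^2) / max(1, n * p)) * n

  reached <- 0L
  for (a in seq_len(nLV)) {
    s <- crossprod(Xc, yc)[, 1L]
    ns <- sqrt(sum(s^2))
    if (!is.finite(ns) || ns <= tol) {
      if (earlyStop) break
      .stopf(paste("fitPLS: response is numerically orthogonal to the",
                   "predictors at component %d; reduce nLV"), a)
    }
    w <- s / ns
    t <- (Xc %*% w)[, 1L]
    tt <- sum(t^2)
    if (tt <= tol^2) {
      if (earlyStop) break
      .stopf("fitPLS: degenerate score (zero variance) at component %d", a)
    }
    pa <- crossprod(Xc, t)[, 1L] / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pa)
    yc <- yc - qa * t
    W[, a] <- w
    P[, a] <- pa
    Tm[, a] <- t
    q[a] <- qa
    reached <- a
  }
  if (reached < nLV) {       # only reachable with earlyStop = TRUE
    nLV <- reached
    W <- W[, seq_len(nLV), drop = FALSE]
    P <- P[, seq_len(nLV), drop = FALSE]
    Tm <- Tm[, seq_len(nLV), drop = FALSE]
    q <- q[seq_len(nLV)]
    if (nLV == 0L)
      return(new("PLSModel", nLV = 0L, xMean = xMean, xScale = xScale,
                 yMean = yMean, yScale = yScale,
                 weights = matrix(0, p, 0L), xLoadings = matrix(0, p, 0L),
                 yLoadings = numeric(), scores = matrix(0, n, 0L),
                 coefficients = rep(0, p), intercept = yMean,
                 wavenumbers = as.numeric(wavenumbers)))
  }
  b <- (W %*% solve(crossprod(P, W), q))[, 1L]
  intercept <- yMean - yScale * sum(xMean / xScale * b)

  new("PLSModel", nLV = nLV,
      xMean = xMean, xScale = xScale, yMean = yMean, yScale = yScale,
      weights = W, xLoadings = P, yLoadings = q, scores = Tm,
      coefficients = b, intercept = intercept,
      wavenumbers = as.numeric(wavenumbers))
}

#' Predict a property from spectra with a fitted PLS model
#'
#' Applies the stored centering/scaling and the linear form
#' `yhat = yMean + yScale * ((x - xMean)/xScale %*% b)`; deterministic and
#' row-local (each spectrum is predicted independently).
#'
#' @param object a [PLSModel-class]
#' @param newdata matrix or [SpectralMatrix-class] with the model's
#'   predictor count
#' @param ... ignored
#' @return numeric vector of predictions
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ...) {
  if (is(newdata, "SpectralMatrix")) newdata <- newdata@intensities
  newdata <- as.matrix(newdata)
  p <- length(object@coefficients)
  if (ncol(newdata) != p)
    .stopf("predict: newdata has %d columns; model expects %d",
           ncol(newdata), p)
  Xs <- sweep(sweep(newdata, 2L, object@xMean), 2L, object@xScale, "/")
  as.numeric(object@yMean +
               object@yScale * (Xs %*% object@coefficients))
})

#' Extract one component's loading spectrum
#'
#' Returns the x-loading vector `p_a` of a component paired with the
#' wavenumber grid; large |loading| marks the spectral regions that drive
#' the model.
#'
#' @param model a [PLSModel-class]
#' @param component component index, `1 <= component <= nLV(model)`
#' @return data.frame with columns `wavenumber` (NA-free only when the
#'   model carries a grid) and `loading`
#' @export
loadingsSpectrum <- function(model, component = 1L) {
  stopifnot(is(model, "PLSModel"))
  if (!.isWholeNumber(component) || component < 1L ||
      component > model@nLV)
    .stopf("loadingsSpectrum: component must be in 1..%d", model@nLV)
  w <- model@wavenumbers
  if (!length(w)) w <- rep(NA_real_, nrow(model@xLoadings))
  data.frame(wavenumber = w, loading = model@xLoadings[, component])
}

#' The six informative Raman loading regions of honey
#'
#' The spectral windows (cm-1) in which PLS loadings of honey property
#' models concentrate their chemical information: sugar-skeleton modes,
#' ring modes of HMF/phenolics, sugar C-C/C-H/C-O-H modes, protein and
#' carbohydrate C-O/C-N modes, CH/OH bending, and carbonyl/water modes.
#'
#' @return data.frame with columns `lo` and `hi`
#' @export
honeyLoadingRegions <- function() {
  data.frame(lo = c(200, 630, 870, 1080, 1400, 1750),
             hi = c(600, 790, 1000, 1200, 1570, 1880))
}

#' Rank spectral regions by mean absolute loading
#'
#' Regions are ranked by descending mean |loading| over the grid points
#' they contain; exact ties keep the region with the lower start first
#' (stable tie-break). A region containing no grid point is an error.
#'
#' @param loading numeric loading vector, or the data.frame returned by
#'   [loadingsSpectrum()]
#' @param wavenumbers grid matching `loading` (ignored when `loading` is a
#'   `loadingsSpectrum` data.frame)
#' @param regions data.frame with columns `lo`, `hi`
#'   (default [honeyLoadingRegions()])
#' @return data.frame: `lo`, `hi`, `meanAbsLoading`, `rank`, sorted by rank
#' @export
topLoadingRegions <- function(loading, wavenumbers = NULL,
                              regions = honeyLoadingRegions()) {
  if (is.data.frame(loading)) {
    wavenumbers <- loading$wavenumber
    loading <- loading$loading
  }
  if (is.null(wavenumbers) || length(wavenumbers) != length(loading))
    .stopf("topLoadingRegions: supply a wavenumber grid matching loading")
  regions <- regions[order(regions$lo), , drop = FALSE]
  mal <- vapply(seq_len(nrow(regions)), function(i) {
    inR <- wavenumbers >= regions$lo[i] & wavenumbers <= regions$hi[i]
    if (!any(inR))
      .stopf("topLoadingRegions: region [%g, %g] contains no grid point",
             regions$lo[i], regions$hi[i])
    mean(abs(loading[inR]))
  }, 0)
  ord <- order(-mal, regions$lo)
  out <- data.frame(lo = regions$lo[ord], hi = regions$hi[ord],
                    meanAbsLoading = mal[ord],
                    rank = seq_along(ord))
  rownames(out) <- NULL
  out
}
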