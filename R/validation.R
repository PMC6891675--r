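# Calibration/validation splitting, cross-validation, and the validation
# statistics (SEC, SEP, bias, R2, paired t).

#' Kennard-Stone calibration/validation split
#'
#' Deterministic greedy maximin selection of a representative calibration
#' subset: start from the two points at maximum Euclidean distance, then
#' repeatedly add the point whose minimum distance to the selected set is
#' largest; exact ties are broken by the lowest row index. Remaining rows
#' form the validation set. With `groupIds` (the default pipeline behavior
#' keeps replicate spectra of one sample together), selection operates on
#' per-group mean spectra and whole groups are assigned to one side, so no
#' sample ever straddles the split.
#'
#' @param x numeric matrix or [SpectralMatrix-class]
#' @param fraction calibration share in (0, 1); the calibration size is
#'   `round(fraction * n_units)`
#' @param groupIds optional per-row group labels (e.g. `sampleIds(x)`)
#' @return list with `calibration` and `validation` (row indices into
#'   `x`), `method`, `fraction`, `groupAware`
#' @export
kennardStoneSplit <- function(x, fraction = 0.9, groupIds = NULL) {
  m <- .asSpectraMat(x)
  if (!(fraction > 0 && fraction < 1))
    .stopf("kennardStoneSplit: fraction must be in (0, 1)")
  n <- nrow(m)
  if (n < 2L) .stopf("kennardStoneSplit: need at least 2 rows")

  if (!is.null(groupIds)) {
    if (length(groupIds) != n)
      .stopf("kennardStoneSplit: groupIds must have one entry per row")
    groups <- unique(groupIds)      # first-appearance order
    gm <- t(vapply(groups, function(g)
      colMeans(m[groupIds == g, , drop = FALSE]), numeric(ncol(m))))
    sel <- .ksSelect(gm, round(fraction * length(groups)))
    calGroups <- groups[sel]
    cal <- which(groupIds %in% calGroups)
  } else {
    sel <- .ksSelect(m, round(fraction * n))
    cal <- sort(sel)
  }
  list(calibration = as.integer(unname(cal)),
       validation = as.integer(setdiff(seq_len(n), cal)),
       method = "kennard_stone", fraction = fraction,
       groupAware = !is.null(groupIds))
}

# Greedy maximin selection of k of nrow(m) points; returns indices in
# selection order.
.ksSelect <- function(m, k) {
  n <- nrow(m)
  k <- max(2L, min(n, as.integer(k)))
  if (k < 2L)
    .stopf("kennardStoneSplit: fraction yields fewer than 2 calibration points")
  D <- unname(as.matrix(stats::dist(m)))
  # seed pair at maximum distance, lowest indices on ties
  best <- c(1L, 2L)
  bestD <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- which(D[i, ] == max(D[i, (i + 1L):n])) # candidates in row i
    j <- j[j > i][1L]
    if (D[i, j] > bestD) {
      bestD <- D[i, j]
      best <- c(i, j)
    }
  }
  sel <- best
  minD <- pmin(D[, best[1L]], D[, best[2L]])
  minD[sel] <- -Inf
  while (length(sel) < k) {
    nxt <- which.max(minD)          # first index on ties
    sel <- c(sel, nxt)
    minD <- pmin(minD, D[, nxt])
    minD[nxt] <- -Inf
  }
  sel
}

#' Leave-five-out cross-validation folds
#'
#' Default scheme `"random"`: a seeded random permutation of `1:n` cut
#' into consecutive blocks of `foldSize` (the last block may be smaller).
#' Scheme `"blinds"` (venetian blinds) assigns row `i` to fold
#' `((i - 1) mod nFolds) + 1`, interleaving rows deterministically
#' (the seed is ignored). Every row lands in exactly one fold; identical
#' seeds give identical folds.
#'
#' @param n number of rows (`>= foldSize`)
#' @param seed integer seed (used by the random scheme)
#' @param foldSize rows left out per fold (default 5)
#' @param scheme `"random"` or `"blinds"`
#' @return integer vector of fold ids, length `n`
#' @export
makeFoldsLeaveFiveOut <- function(n, seed, foldSize = 5L,
                                  scheme = c("random", "blinds")) {
  scheme <- match.arg(scheme)
  if (n < foldSize)
    .stopf("makeFoldsLeaveFiveOut: n (%d) < fold size (%d)", n, foldSize)
  nFolds <- ceiling(n / foldSize)
  if (scheme == "blinds")
    return((seq_len(n) - 1L) %% nFolds + 1L)
  perm <- .withSeed(seed, function() sample.int(n))
  folds <- integer(n)
  folds[perm] <- (seq_len(n) - 1L) %/% foldSize + 1L
  folds
}

#' Select the number of latent variables by leave-five-out CV
#'
#' For each candidate component count `A` in `1:lvMax`, held-out
#' predictions are pooled over all folds and summarized as
#' `SECV(A) = sqrt(sum(residual^2) / n)`; the chosen LV count is the first
#' minimum of the SECV curve. Within each fold the trailing
#' centering/autoscaling of the recipe and the PLS model are refit on the
#' retained rows only; the alignment reference and the row-local
#' treatments (baseline, smoothing, normalization, SNV, ...) are fitted
#' once on the full calibration set, since row-local operators are
#' fold-independent by construction.
#'
#' An infeasible `lvMax` (larger than any fold's training rank allows) is
#' reduced with a warning.
#'
#' @param x calibration spectra ([SpectralMatrix-class] or matrix)
#' @param y response vector
#' @param recipe a [PreprocessRecipe-class] (unfitted)
#' @param lvMax largest candidate LV count
#' @param seed fold seed
#' @param foldSize rows per fold (default 5)
#' @param scheme fold scheme, see [makeFoldsLeaveFiveOut()]
#' @return list: `secvPerLV` (length `lvMax`), `chosenLV`, `folds`
#' @export
crossValidateLV <- function(x, y, recipe = defaultRecipe(), lvMax = 10L,
                            seed = 1L, foldSize = 5L,
                            scheme = c("random", "blinds")) {
  scheme <- match.arg(scheme)
  if (!is(x, "SpectralMatrix"))
    x <- SpectralMatrix(.asSpectraMat(x),
                        wavenumbers = seq_len(ncol(as.matrix(x))) + 100)
  n <- nrow(x@intensities)
  if (length(y) != n)
    .stopf("crossValidateLV: y length (%d) != row count (%d)",
           length(y), n)
  if (!.isWholeNumber(lvMax) || lvMax < 1L)
    .stopf("crossValidateLV: lvMax must be >= 1")

  stages <- .splitRecipeForCV(recipe)
  headFitted <- fitRecipe(stages$head, x)
  xh <- applyRecipe(headFitted, x)@intensities

  folds <- makeFoldsLeaveFiveOut(n, seed, foldSize, scheme)
  minTrain <- n - max(tabulate(folds))
  feasible <- min(minTrain - 1L, ncol(xh))
  lvMax <- as.integer(lvMax)
  if (lvMax > feasible) {
    warning(sprintf(
      "crossValidateLV: lvMax reduced from %d to %d (fold training size)",
      lvMax, feasible), call. = FALSE)
    lvMax <- feasible
  }
  if (lvMax < 1L)
    .stopf("crossValidateLV: no feasible latent variable count")

  press <- numeric(lvMax)
  for (f in sort(unique(folds))) {
    out <- folds == f
    Xtr0 <- xh[!out, , drop = FALSE]
    Xte0 <- xh[out, , drop = FALSE]
    Xtr <- Xtr0
    Xte <- Xte0
    for (st in stages$scalerSteps) {
      sc <- fitColumnScaler(Xtr, if (st$name == "center") "center"
                            else "autoscale")
      Xtr <- applyColumnScaler(Xtr, sc)
      Xte <- applyColumnScaler(Xte, sc)
    }
    fit <- fitPLS(Xtr, y[!out], lvMax, earlyStop = TRUE)
    pp <- .pressPerLV(fit, Xte, y[out])
    if (length(pp) < lvMax) {
      # the fold's response was exhausted early: predictions (and thus the
      # held-out error) no longer change beyond the last component
      base <- if (length(pp)) pp[length(pp)]
              else sum((y[out] - mean(y[!out]))^2)
      pp <- c(pp, rep(base, lvMax - length(pp)))
    }
    press <- press + pp
  }
  secv <- sqrt(press / n)
  list(secvPerLV = secv, chosenLV = which.min(secv), folds = folds)
}

# Squared-error contributions of a test block for truncated models with
# 1..nLV components (uses the per-component score/loading recursion, so
# one fit serves every truncation).
.pressPerLV <- function(model, Xte, yte) {
  A <- model@nLV
  Xc <- sweep(Xte, 2L, model@xMean)
  pred <- rep(model@yMean, nrow(Xte))
  out <- numeric(A)
  for (a in seq_len(A)) {
    t <- (Xc %*% model@weights[, a])[, 1L]
    pred <- pred + model@yScale * model@yLoadings[a] * t
    Xc <- Xc - tcrossprod(t, model@xLoadings[, a])
    out[a] <- sum((yte - pred)^2)
  }
  out
}

#' Standard error of calibration (SEC)
#'
#' `sqrt(sum((y - yhat)^2) / (n - nLV - 1))`: the calibration-set residual
#' error with degrees of freedom reduced by the latent variables and the
#' intercept.
#'
#' @param y observed values
#' @param yhat fitted values
#' @param nLV number of latent variables consumed by the model
#' @return non-negative scalar
#' @export
sec <- function(y, yhat, nLV) {
  n <- length(y)
  stopifnot(length(yhat) == n)
  if (n - nLV - 1 <= 0)
    .stopf("sec: non-positive degrees of freedom (n = %d, nLV = %d)",
           n, nLV)
  sqrt(sum((y - yhat)^2) / (n - nLV - 1))
}

#' Mean prediction bias
#'
#' `mean(yhat - y)`; positive values mean systematic over-prediction.
#'
#' @param y observed values
#' @param yhat predicted values
#' @return scalar bias
#' @export
predictionBias <- function(y, yhat) {
  stopifnot(length(yhat) == length(y))
  mean(yhat - y)
}

#' Standard error of prediction (SEP)
#'
#' The bias-corrected spread of the validation residuals:
#' `sqrt(sum((yhat - y - bias)^2) / (n - 1))`. Invariant to adding a
#' constant to all predictions (unlike SEC, which charges offsets to the
#' residuals).
#'
#' @inheritParams predictionBias
#' @return non-negative scalar
#' @export
sep <- function(y, yhat) {
  n <- length(y)
  stopifnot(length(yhat) == n)
  if (n < 2L) .stopf("sep: need at least 2 observations")
  d <- yhat - y
  sqrt(sum((d - mean(d))^2) / (n - 1))
}

#' Squared correlation between observed and predicted values
#'
#' Default: the squared Pearson correlation (invariant under affine
#' transforms of either argument). `method = "explained"` gives the
#' alternative `1 - SSE/SST` definition.
#'
#' @inheritParams predictionBias
#' @param method `"pearson"` (default) or `"explained"`
#' @return scalar in \[0, 1\] (`"explained"` may be negative for models
#'   worse than the mean)
#' @export
rSquared <- function(y, yhat, method = c("pearson", "explained")) {
  method <- match.arg(method)
  stopifnot(length(yhat) == length(y))
  if (method == "pearson") {
    if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
      .stopf("rSquared: zero variance in y or yhat")
    stats::cor(y, yhat)^2
  } else {
    sst <- sum((y - mean(y))^2)
    if (sst == 0) .stopf("rSquared: zero variance in y")
    1 - sum((y - yhat)^2) / sst
  }
}

#' Paired t-test of predictions against reference values
#'
#' Tests whether predictions differ systematically from the reference
#' method: `t = mean(d) * sqrt(n) / sd(d)` with `d = yhat - y`. The
#' acceptance band is `|t| <= t_critical` with `t_critical` the Student-t
#' quantile at `df = n - 1`; the default band (`tail = "one"`,
#' `level = 0.95`) is the 95% one-sided quantile, about 1.65 at large df.
#' Identical predictions give `t = 0`; a constant nonzero difference has
#' no variance to test against and raises an error.
#'
#' @inheritParams predictionBias
#' @param level confidence level of the band
#' @param tail `"one"` (default) or `"two"`: which quantile defines the
#'   band
#' @return list: `t`, `tCritical`, `withinBand`, `df`
#' @export
pairedT <- function(y, yhat, level = 0.95, tail = c("one", "two")) {
  tail <- match.arg(tail)
  n <- length(y)
  stopifnot(length(yhat) == n)
  if (n < 2L) .stopf("pairedT: need at least 2 pairs")
  d <- yhat - y
  sdd <- stats::sd(d)
  tc <- if (sdd == 0) {
    if (abs(mean(d)) > 0)
      .stopf("pairedT: constant nonzero differences (degenerate variance)")
    0
  } else mean(d) * sqrt(n) / sdd
  pQuant <- if (tail == "one") level else 1 - (1 - level) / 2
  tCrit <- stats::qt(pQuant, df = n - 1)
  list(t = tc, tCritical = tCrit, withinBand = abs(tc) <= tCrit,
       df = n - 1L)
}
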