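#' @title S4 classes of the RamanHoney package

#' SpectralMatrix: replicate-expanded Raman intensity matrix
#'
#' Holds spectra as an `n x p` intensity matrix on a shared, strictly
#' increasing wavenumber grid (Raman shift, cm-1), with one row per
#' physical sample x replicate. Intensities are arbitrary units exactly as
#' loaded; no unit conversion is ever applied.
#'
#' @slot wavenumbers numeric, strictly increasing, finite, positive (cm-1).
#' @slot intensities numeric matrix, `length(wavenumbers)` columns.
#' @slot sampleIds character, per-row physical-sample label.
#' @slot replicateIds integer, per-row replicate index.
#'
#' @exportClass SpectralMatrix
setClass("SpectralMatrix",
  slots = c(
    wavenumbers  = "numeric",
    intensities  = "matrix",
    sampleIds    = "character",
    replicateIds = "integer"
  )
)

setValidity("SpectralMatrix", function(object) {
  w <- object@wavenumbers
  m <- object@intensities
  msg <- character()
  if (length(w) < 2L) msg <- c(msg, "wavenumber grid needs length >= 2")
  if (!all(is.finite(w)) || any(w <= 0))
    msg <- c(msg, "wavenumbers must be finite and positive")
  if (length(w) >= 2L && any(diff(w) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (ncol(m) != length(w))
    msg <- c(msg, sprintf("intensity columns (%d) != grid length (%d)",
                          ncol(m), length(w)))
  if (nrow(m) != length(object@sampleIds) ||
      nrow(m) != length(object@replicateIds))
    msg <- c(msg, "sampleIds/replicateIds must have one entry per row")
  if (nrow(m) > 0 && !all(is.finite(m)))
    msg <- c(msg, "intensities must all be finite")
  key <- paste(object@sampleIds, object@replicateIds, sep = "\r")
  if (anyDuplicated(key))
    msg <- c(msg, "(sampleId, replicateId) pairs must be unique")
  if (length(msg)) msg else TRUE
})

#' PreprocessRecipe: an ordered, parameterized chain of spectral treatments
#'
#' Steps are drawn from the closed set `align`, `baseline`, `smooth`,
#' `normalize`, `derivative`, `log10`, `snv`, `center`, `autoscale`.
#' Stateful steps (`align`, `center`, `autoscale`) learn their state on
#' calibration rows only ([fitRecipe()]) and are then applied unchanged to
#' any other rows ([applyRecipe()]), so validation data can never leak into
#' the transformation.
#'
#' @slot steps list of `list(name=, params=)` step descriptors.
#' @slot state list, per-step fitted state (empty until fitted).
#' @slot fitted logical flag.
#'
#' @exportClass PreprocessRecipe
setClass("PreprocessRecipe",
  slots = c(steps = "list", state = "list", fitted = "logical"),
  prototype = list(steps = list(), state = list(), fitted = FALSE)
)

setValidity("PreprocessRecipe", function(object) {
  known <- names(.stepRegistry)
  msg <- character()
  for (i in seq_along(object@steps)) {
    st <- object@steps[[i]]
    if (!is.list(st) || is.null(st$name) || !(st$name %in% known))
      msg <- c(msg, sprintf("step %d: unknown or malformed step", i))
  }
  if (object@fitted && length(object@state) != length(object@steps))
    msg <- c(msg, "fitted recipe must carry one state entry per step")
  if (length(msg)) msg else TRUE
})

#' PLSModel: a fitted NIPALS PLS1 calibration model
#'
#' Stores the factorization computed by [fitPLS()]: weights `W`, x-loadings
#' `P`, y-loadings `q`, scores `T`, the centering/scaling applied
#' internally, and the regression vector `b = W (P'W)^-1 q` expressed on
#' the preprocessed predictor scale. Predictions are
#' `yhat = yMean + yScale * ((x - xMean)/xScale %*% b)`.
#'
#' @slot nLV integer, number of latent variables A (0 for a constant-y fit).
#' @slot xMean,xScale numeric length-p column centering/scaling.
#' @slot yMean,yScale numeric scalars.
#' @slot weights p x A weight matrix W, unit-norm columns.
#' @slot xLoadings p x A loading matrix P.
#' @slot yLoadings length-A y-loading vector q.
#' @slot scores n x A score matrix T (mutually orthogonal columns).
#' @slot coefficients length-p regression vector b.
#' @slot intercept scalar on the original response scale.
#' @slot wavenumbers optional grid for loading interpretation (may be
#'   length 0 when the model was fitted on an anonymous matrix).
#'
#' @exportClass PLSModel
setClass("PLSModel",
  slots = c(
    nLV = "integer",
    xMean = "numeric", xScale = "numeric",
    yMean = "numeric", yScale = "numeric",
    weights = "matrix", xLoadings = "matrix", yLoadings = "numeric",
    scores = "matrix",
    coefficients = "numeric", intercept = "numeric",
    wavenumbers = "numeric"
  )
)

setValidity("PLSModel", function(object) {
  msg <- character()
  A <- object@nLV
  p <- length(object@coefficients)
  if (ncol(object@weights) != A || ncol(object@xLoadings) != A ||
      length(object@yLoadings) != A || ncol(object@scores) != A)
    msg <- c(msg, "W, P, q, T must all have nLV components")
  if (A > 0 && nrow(object@weights) != p)
    msg <- c(msg, "weights rows must match coefficient length")
  if (A > 0) {
    nrm <- sqrt(colSums(object@weights^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "weight columns must have unit Euclidean norm")
  }
  if (length(object@xMean) != p || length(object@xScale) != p)
    msg <- c(msg, "xMean/xScale must have one entry per predictor")
  if (length(object@wavenumbers) && length(object@wavenumbers) != p)
    msg <- c(msg, "wavenumbers, when present, must match predictor count")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: full specification of the synthetic honey dataset
#'
#' Bundles everything [generatePropertyTable()] and [generateSpectra()]
#' need: sample/replicate counts, the wavenumber grid, per-property
#' truncated-normal distributions, the Raman band catalog with
#' band-property couplings, baseline polynomial coefficient ranges, noise
#' levels, replicate jitter, the maximum integer grid misalignment, and the
#' root seed. See [syntheticConfig()] for defaults and units.
#'
#' @slot nSamples,nReplicates integer counts.
#' @slot wavenumbers numeric grid (cm-1).
#' @slot propertyDistributions data.frame: property, mean, sd, min, max.
#' @slot bands data.frame band catalog (center, width, baseAmplitude and
#'   one coupling column per property, a.u. per standardized unit).
#' @slot baselineRanges numeric matrix 2 x k: lower/upper bounds of the
#'   k polynomial coefficients (constant first) of the per-sample baseline.
#' @slot noiseSd,replicateSd numeric, additive noise / replicate offset a.u.
#' @slot shiftMax integer, max grid-point misalignment per replicate.
#' @slot seed integer root seed.
#'
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  slots = c(
    nSamples = "integer", nReplicates = "integer",
    wavenumbers = "numeric",
    propertyDistributions = "data.frame",
    bands = "data.frame",
    baselineRanges = "matrix",
    noiseSd = "numeric", replicateSd = "numeric",
    shiftMax = "integer", seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nSamples < 0L) msg <- c(msg, "nSamples must be >= 0")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  pd <- object@propertyDistributions
  need <- c("property", "mean", "sd", "min", "max")
  if (!all(need %in% names(pd))) {
    msg <- c(msg, "propertyDistributions needs property/mean/sd/min/max")
  } else {
    if (any(pd$sd < 0)) msg <- c(msg, "property sd must be >= 0")
    if (any(pd$min >= pd$max)) msg <- c(msg, "property min must be < max")
  }
  bd <- object@bands
  if (!all(c("center", "width", "baseAmplitude") %in% names(bd))) {
    msg <- c(msg, "bands needs center/width/baseAmplitude")
  } else if (nrow(bd)) {
    w <- object@wavenumbers
    if (any(bd$width <= 0)) msg <- c(msg, "band widths must be > 0")
    if (any(bd$baseAmplitude < 0))
      msg <- c(msg, "base amplitudes must be >= 0")
    if (any(bd$center < min(w) | bd$center > max(w)))
      msg <- c(msg, "band centers must lie inside the grid window")
  }
  if (object@noiseSd < 0 || object@replicateSd < 0)
    msg <- c(msg, "noise and replicate sd must be >= 0")
  if (object@shiftMax < 0L) msg <- c(msg, "shiftMax must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PipelineRun: result of a full calibration/validation pipeline
#'
#' One [runPipeline()] invocation over a set of properties. `results`
#' holds one validation-report row per property (LVs, SEC, R2cal, SEP,
#' R2val, t statistics, bias); `models`, `split`, `cv` and the recipe echo
#' carry full provenance so the run can be reproduced exactly.
#'
#' @slot results data.frame, one row per property.
#' @slot models named list of [PLSModel-class] objects.
#' @slot split list: calibration/validation row indices, method, fraction.
#' @slot cv named list of per-property cross-validation results.
#' @slot recipeSteps list echo of the preprocessing steps used.
#' @slot wavenumbers numeric, the (trimmed) model grid.
#' @slot seed integer root seed of the run.
#'
#' @exportClass PipelineRun
setClass("PipelineRun",
  slots = c(
    results = "data.frame",
    models = "list",
    split = "list",
    cv = "list",
    recipeSteps = "list",
    wavenumbers = "numeric",
    seed = "integer"
  )
)
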