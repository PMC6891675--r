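# Generics and accessors for the package classes.

#' @rdname SpectralMatrix-class
#' @param object,x a `SpectralMatrix`
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname SpectralMatrix-class
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname SpectralMatrix-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname SpectralMatrix-class
#' @export
setGeneric("replicateIds", function(object) standardGeneric("replicateIds"))

#' @rdname SpectralMatrix-class
#' @export
setMethod("wavenumbers", "SpectralMatrix", function(object) object@wavenumbers)

#' @rdname SpectralMatrix-class
#' @export
setMethod("intensities", "SpectralMatrix", function(object) object@intensities)

#' @rdname SpectralMatrix-class
#' @export
setMethod("sampleIds", "SpectralMatrix", function(object) object@sampleIds)

#' @rdname SpectralMatrix-class
#' @export
setMethod("replicateIds", "SpectralMatrix",
          function(object) object@replicateIds)

#' @rdname SpectralMatrix-class
#' @export
setMethod("dim", "SpectralMatrix", function(x) dim(x@intensities))

#' @rdname SpectralMatrix-class
#' @param i integer or logical row index
#' @param j,drop,... ignored (column subsetting is done by
#'   [trimToWindow()], which keeps the grid consistent)
#' @export
setMethod("[", "SpectralMatrix", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) .stopf("subset columns with trimToWindow(), not `[`")
  new("SpectralMatrix",
      wavenumbers  = x@wavenumbers,
      intensities  = x@intensities[i, , drop = FALSE],
      sampleIds    = x@sampleIds[i],
      replicateIds = x@replicateIds[i])
})

setMethod("show", "SpectralMatrix", function(object) {
  w <- object@wavenumbers
  cat(sprintf(
    "SpectralMatrix: %d spectra x %d points, %.1f-%.1f cm-1 (%d samples)\n",
    nrow(object@intensities), length(w), min(w), max(w),
    length(unique(object@sampleIds))))
})

setMethod("show", "PreprocessRecipe", function(object) {
  cat(sprintf("PreprocessRecipe (%s): %s\n",
              if (object@fitted) "fitted" else "unfitted",
              if (length(object@steps))
                paste(vapply(object@steps, `[[`, "", "name"),
                      collapse = " -> ")
              else "<identity>"))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variable(s), %d predictors\n",
              object@nLV, length(object@coefficients)))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d samples x %d replicates, %d-point grid, %d bands, seed %d\n",
    object@nSamples, object@nReplicates, length(object@wavenumbers),
    nrow(object@bands), object@seed))
})

setMethod("show", "PipelineRun", function(object) {
  cat(sprintf("PipelineRun: %d property model(s), seed %d\n",
              nrow(object@results), object@seed))
  if (nrow(object@results)) {
    df <- object@results
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) round(v, 3))
    print(df, row.names = FALSE)
  }
})

#' Number of latent variables of a fitted PLS model
#' @param object a [PLSModel-class]
#' @return integer count of latent variables
#' @export
setGeneric("nLV", function(object) standardGeneric("nLV"))

#' @rdname nLV
#' @export
setMethod("nLV", "PLSModel", function(object) object@nLV)

#' Regression coefficients of a fitted PLS model
#'
#' @param object a [PLSModel-class]
#' @param ... ignored
#' @return numeric vector `b` on the preprocessed predictor scale
#' @export
setMethod("coef", "PLSModel", function(object, ...) object@coefficients)
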