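# Text serialization: PLS models as JSON, full-run provenance export.

#' Serialize a PLS model to JSON
#'
#' Writes every model field (dimensions, centering/scaling, W, P, q,
#' scores, coefficients, intercept, grid) as a structured JSON document;
#' [readPLSModel()] restores an equivalent model for reproducible
#' prediction runs.
#'
#' @param model a [PLSModel-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePLSModel <- function(model, path) {
  stopifnot(is(model, "PLSModel"))
  obj <- list(
    class = "PLSModel", nLV = model@nLV,
    xMean = model@xMean, xScale = model@xScale,
    yMean = model@yMean, yScale = model@yScale,
    weights = model@weights, xLoadings = model@xLoadings,
    yLoadings = model@yLoadings, scores = model@scores,
    coefficients = model@coefficients, intercept = model@intercept,
    wavenumbers = model@wavenumbers)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a PLS model serialized by [writePLSModel()]
#'
#' @param path JSON path
#' @return a [PLSModel-class]
#' @export
readPLSModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$class, "PLSModel"))
    .stopf("readPLSModel: %s is not a serialized PLSModel", path)
  asMat <- function(m, nr) {
    m <- as.matrix(m)
    if (length(m) == 0L) m <- matrix(0, nr, 0L)
    storage.mode(m) <- "double"
    m
  }
  p <- length(obj$coefficients)
  n <- if (length(obj$scores)) nrow(as.matrix(obj$scores)) else 0L
  new("PLSModel", nLV = as.integer(obj$nLV),
      xMean = as.numeric(obj$xMean), xScale = as.numeric(obj$xScale),
      yMean = as.numeric(obj$yMean), yScale = as.numeric(obj$yScale),
      weights = asMat(obj$weights, p), xLoadings = asMat(obj$xLoadings, p),
      yLoadings = as.numeric(obj$yLoadings),
      scores = asMat(obj$scores, n),
      coefficients = as.numeric(obj$coefficients),
      intercept = as.numeric(obj$intercept),
      wavenumbers = as.numeric(obj$wavenumbers))
}

#' Export a pipeline run with full provenance
#'
#' Writes, under `dir`: `report.csv` ([reportTable()]), `loadings.csv`
#' ([exportLoadings()]), one serialized model per property
#' (`model_<property>.json`), `split.json` (calibration/validation
#' indices), `folds.json` (per-property CV fold assignments and SECV
#' curves), and `run.json` (recipe echo, seed, package version) — enough
#' to reproduce or audit the run exactly.
#'
#' @param run a [PipelineRun-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
exportRun <- function(run, dir) {
  stopifnot(is(run, "PipelineRun"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reportTable(run, file.path(dir, "report.csv"))
  exportLoadings(run, file.path(dir, "loadings.csv"))
  for (prop in names(run@models))
    writePLSModel(run@models[[prop]],
                  file.path(dir, paste0("model_", prop, ".json")))
  jsonlite::write_json(run@split, file.path(dir, "split.json"),
                       digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    lapply(run@cv, function(cv)
      list(secvPerLV = cv$secvPerLV, chosenLV = cv$chosenLV,
           folds = cv$folds)),
    file.path(dir, "folds.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(seed = run@seed,
         recipe = run@recipeSteps,
         package = "RamanHoney",
         version = as.character(utils::packageVersion("RamanHoney"))),
    file.path(dir, "run.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
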