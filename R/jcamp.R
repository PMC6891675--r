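# Minimal JCAMP-DX reader: uncompressed AFFN ##XYDATA=(X++(Y..Y)) only.
# Vendor ASDF compression (SQZ/DIF/DUP) is deliberately out of scope and is
# rejected with an explicit message.

.jcampLabel <- function(lines, label) {
  rx <- paste0("^##", label, "\\s*=\\s*(.*)$")
  hit <- grep(rx, lines, ignore.case = TRUE, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(rx, "\\1", hit[1], ignore.case = TRUE)
}

#' Read a single spectrum from a minimal JCAMP-DX file
#'
#' Supports the plain-number (AFFN) `##XYDATA=(X++(Y..Y))` dialect: each
#' data line carries an x anchor followed by y values at consecutive grid
#' steps. `x = raw * XFACTOR`, `y = raw * YFACTOR` (factors default to 1).
#' Files stored with a descending x axis are reversed so the returned grid
#' ascends. Compressed ASDF encodings (SQZ/DIF/DUP) raise an "unsupported
#' dialect" error.
#'
#' @param path file path
#' @param sampleId label for the single resulting row
#' @return a one-row [SpectralMatrix-class]
#' @export
readJCAMP <- function(path, sampleId = "jcamp") {
  lines <- readLines(path, warn = FALSE)
  xf <- as.numeric(.jcampLabel(lines, "XFACTOR") %||% "1")
  yf <- as.numeric(.jcampLabel(lines, "YFACTOR") %||% "1")
  start <- grep("^##XYDATA", lines, ignore.case = TRUE)
  if (!length(start))
    .stopf("JCAMP %s: no ##XYDATA record", path)
  form <- .jcampLabel(lines, "XYDATA")
  if (!grepl("X\\+\\+\\(Y\\.\\.Y\\)", form))
    .stopf("JCAMP %s: only ##XYDATA=(X++(Y..Y)) is supported (got %s)",
           path, form)
  end <- grep("^##", lines)
  end <- end[end > start[1]]
  end <- if (length(end)) min(end) - 1L else length(lines)
  dataLines <- lines[(start[1] + 1L):end]
  dataLines <- dataLines[nzchar(trimws(dataLines))]
  if (!length(dataLines)) .stopf("JCAMP %s: empty XYDATA block", path)
  # ASDF-compressed dialects encode digits as letters; reject them.
  if (any(grepl("[A-DF-Za-df-z%@]", dataLines)))
    .stopf(paste("JCAMP %s: compressed (SQZ/DIF/DUP) encodings are an",
                 "unsupported dialect; export as plain AFFN numbers"), path)
  parsed <- lapply(dataLines, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln),
                                              "[\\s,;]+", perl = TRUE)[[1]]))
    if (any(is.na(v)) || length(v) < 2L)
      .stopf("JCAMP %s: cannot parse AFFN data line: %s", path, ln)
    v
  })
  anchors <- vapply(parsed, `[`, 0, 1L)
  ys <- lapply(parsed, `[`, -1L)
  counts <- lengths(ys)
  # grid step: prefer the declared FIRSTX/LASTX/NPOINTS, else infer from
  # consecutive line anchors.
  np <- sum(counts)
  firstx <- as.numeric(.jcampLabel(lines, "FIRSTX") %||% anchors[1])
  lastx <- .jcampLabel(lines, "LASTX")
  if (!is.null(lastx) && np > 1L) {
    dx <- (as.numeric(lastx) - firstx) / (np - 1L)
  } else if (length(anchors) > 1L) {
    dx <- (anchors[2] - anchors[1]) / counts[1]
  } else if (np > 1L) {
    .stopf("JCAMP %s: cannot infer the x step (need ##LASTX or >1 line)",
           path)
  } else dx <- 1
  # per-line anchors are checkpoints on a uniform axis; rebuild globally
  offsets <- c(0, cumsum(counts))[seq_along(counts)]
  drift <- abs(anchors - (firstx + dx * offsets))
  if (any(drift > abs(dx) * 0.5 + 1e-9))
    .stopf("JCAMP %s: x anchors are inconsistent with a uniform axis", path)
  xraw <- firstx + dx * (seq_len(np) - 1L)
  x <- xraw * xf
  y <- unlist(ys, use.names = FALSE) * yf
  if (np > 1L && x[1] > x[np]) {   # stored descending: enforce ascending
    x <- rev(x)
    y <- rev(y)
  }
  SpectralMatrix(matrix(y, nrow = 1L), x, sampleId, 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
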