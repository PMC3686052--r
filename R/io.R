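# Artifact I/O: rate matrices, weights and correlograms as CSV with JSON
# sidecars (<file>.json) for metadata.

#' @importFrom jsonlite write_json read_json toJSON
NULL

sidecarPath <- function(file) paste0(file, ".json")

#' Write / read a motor code
#'
#' Rates are stored in sparse long format (neuron, bin, rate; zero bins
#' omitted); bin width, burst width, rendition spans, kind and generator
#' parameters go to a JSON sidecar next to the CSV.
#'
#' @param code a \linkS4class{MotorCode}.
#' @param file CSV path.
#' @return \code{writeMotorCode}: the file path, invisibly;
#'   \code{readMotorCode}: a \linkS4class{MotorCode}.
#' @export
writeMotorCode <- function(code, file) {
  idx <- which(code@rates != 0, arr.ind = TRUE)
  df <- data.frame(neuron = idx[, 1], bin = idx[, 2],
                   rate = code@rates[idx])
  df <- df[order(df$neuron, df$bin), ]
  write.csv(df, file, row.names = FALSE)
  meta <- list(dt = code@dt, t0 = code@t0, codeKind = code@codeKind,
               nNeurons = nrow(code@rates), nBins = ncol(code@rates),
               renditionStart = start(code@renditions),
               renditionWidth = width(code@renditions),
               params = code@params)
  write_json(meta, sidecarPath(file), auto_unbox = TRUE, digits = NA,
             na = "null")
  invisible(file)
}

#' @rdname writeMotorCode
#' @export
readMotorCode <- function(file) {
  df <- read.csv(file)
  meta <- read_json(sidecarPath(file), simplifyVector = TRUE)
  rates <- matrix(0, meta$nNeurons, meta$nBins)
  rates[cbind(df$neuron, df$bin)] <- df$rate
  params <- meta$params
  if (!is.null(params$onsetsMs)) params$onsetsMs <- as.matrix(params$onsetsMs)
  new("MotorCode", rates = rates, dt = meta$dt, t0 = meta$t0,
      renditions = IRanges(start = meta$renditionStart,
                           width = meta$renditionWidth),
      codeKind = meta$codeKind, params = as.list(params))
}

#' Write / read synaptic weights
#'
#' The weight matrix as plain CSV (motor rows x sensory columns) plus a
#' JSON sidecar with the learning-run metadata.
#'
#' @param weights a \linkS4class{SynapticWeights}.
#' @param file CSV path.
#' @return \code{writeWeights}: the path, invisibly; \code{readWeights}: a
#'   \linkS4class{SynapticWeights}.
#' @export
writeWeights <- function(weights, file) {
  write.csv(weights@V, file, row.names = FALSE)
  write_json(list(learningRate = weights@learningRate,
                  gated = weights@gated,
                  diagnostics = weights@diagnostics),
             sidecarPath(file), auto_unbox = TRUE, digits = NA,
             na = "null")
  invisible(file)
}

#' @rdname writeWeights
#' @export
readWeights <- function(file) {
  V <- as.matrix(read.csv(file))
  dimnames(V) <- NULL
  meta <- read_json(sidecarPath(file), simplifyVector = TRUE)
  w <- new("SynapticWeights", V = V,
           learningRate = meta$learningRate %||% NA_real_,
           gated = isTRUE(meta$gated),
           diagnostics = as.list(meta$diagnostics))
  w
}

#' Write / read a motor-sensory map
#'
#' Q as CSV; the delays in a JSON sidecar.
#'
#' @param map a \linkS4class{MotorSensoryMap}.
#' @param file CSV path.
#' @return \code{writeMap}: the path, invisibly; \code{readMap}: a
#'   \linkS4class{MotorSensoryMap}.
#' @export
writeMap <- function(map, file) {
  write.csv(map@Q, file, row.names = FALSE)
  write_json(list(tauM = map@tauM, tauA = map@tauA), sidecarPath(file),
             auto_unbox = TRUE, digits = NA, na = "null")
  invisible(file)
}

#' @rdname writeMap
#' @export
readMap <- function(file) {
  Q <- as.matrix(read.csv(file))
  dimnames(Q) <- NULL
  meta <- read_json(sidecarPath(file), simplifyVector = TRUE)
  motorSensoryMap(Q, tauM = meta$tauM, tauA = meta$tauA)
}

#' Write a correlogram to CSV
#'
#' Long format: lag_ms, i, j, value.
#'
#' @param cc a \linkS4class{CrossCorrelation}.
#' @param file CSV path.
#' @return the path, invisibly.
#' @export
writeCorrelogram <- function(cc, file) {
  d <- dim(cc@values)
  df <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                    lag_ms = cc@lags, KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(cc@values)
  write.csv(df[, c("lag_ms", "i", "j", "value")], file, row.names = FALSE)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
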