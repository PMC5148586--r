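#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats rnorm runif sd cor quantile fft
#' @importFrom utils read.table write.table head
#' @useDynLib eemdSource, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sifting configuration for EMD/EEMD
#'
#' Holds the tunable parameters of the sifting algorithm and its
#' noise-assisted ensemble variant. \code{stopSD} is the normalized squared
#' difference between consecutive sift iterates,
#' \eqn{\sum_t (h_{prev}-h)^2 / \sum_t h_{prev}^2}; a sift is accepted once
#' this falls below \code{stopSD} while the candidate mode satisfies the two
#' intrinsic-mode conditions (extrema/zero-crossing count, and the RMS of
#' the envelope mean within \code{envTol} times the mode's standard
#' deviation), or after \code{maxSifts} iterations.
#'
#' @slot maxModes maximum number of modes to extract
#' @slot maxSifts maximum sift iterations per mode
#' @slot stopSD sift stopping threshold (relative squared change)
#' @slot envTol envelope-mean RMS tolerance, relative to the mode's SD
#' @slot ensembleSize number of noise realizations (EEMD only)
#' @slot noiseRatio added-noise standard deviation as a fraction of the
#'   signal's standard deviation (EEMD only); 0 degenerates to plain EMD
#' @slot seed master seed for the ensemble noise streams
#' @export
setClass("SiftConfig",
  representation(maxModes = "integer", maxSifts = "integer",
                 stopSD = "numeric", envTol = "numeric",
                 ensembleSize = "integer", noiseRatio = "numeric",
                 seed = "integer"),
  prototype(maxModes = 10L, maxSifts = 100L, stopSD = 0.2, envTol = 0.2,
            ensembleSize = 100L, noiseRatio = 0.2, seed = 1L))

setValidity("SiftConfig", function(object) {
  msg <- character()
  if (object@maxModes < 1L) msg <- c(msg, "maxModes must be >= 1")
  if (object@maxSifts < 1L) msg <- c(msg, "maxSifts must be >= 1")
  if (object@stopSD <= 0) msg <- c(msg, "stopSD must be > 0")
  if (object@envTol <= 0) msg <- c(msg, "envTol must be > 0")
  if (object@ensembleSize < 1L) msg <- c(msg, "ensembleSize must be >= 1")
  if (object@noiseRatio < 0) msg <- c(msg, "noiseRatio must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SiftConfig-class
#' @param maxModes,maxSifts,stopSD,envTol,ensembleSize,noiseRatio,seed see slots
#' @return a \code{SiftConfig}
#' @examples
#' SiftConfig(ensembleSize = 20, noiseRatio = 0.1, seed = 7)
#' @export
SiftConfig <- function(maxModes = 10, maxSifts = 100, stopSD = 0.2,
                       envTol = 0.2, ensembleSize = 100, noiseRatio = 0.2,
                       seed = 1) {
  new("SiftConfig", maxModes = as.integer(maxModes),
      maxSifts = as.integer(maxSifts), stopSD = as.numeric(stopSD),
      envTol = as.numeric(envTol), ensembleSize = as.integer(ensembleSize),
      noiseRatio = as.numeric(noiseRatio), seed = as.integer(seed))
}

#' Intrinsic mode function set
#'
#' Result of decomposing one signal: the ordered modes \eqn{c_j(t)} (columns,
#' fastest oscillation first) and the non-oscillating residual \eqn{r(t)}.
#' For plain EMD the columns plus the residual reproduce the input signal to
#' numerical precision.
#'
#' @slot modes numeric matrix, time x modes (zero columns allowed)
#' @slot residual numeric vector, same length as the input
#' @slot rate sampling rate in samples/second
#' @slot params list of sifting parameters used
#' @export
setClass("IMFSet",
  representation(modes = "matrix", residual = "numeric", rate = "numeric",
                 params = "list"),
  prototype(modes = matrix(numeric(0), 0, 0), residual = numeric(0),
            rate = 1, params = list()))

setValidity("IMFSet", function(object) {
  msg <- character()
  if (ncol(object@modes) > 0 && nrow(object@modes) != length(object@residual))
    msg <- c(msg, "modes and residual must have the same length")
  if (!all(is.finite(object@residual))) msg <- c(msg, "residual must be finite")
  if (length(object@modes) && !all(is.finite(object@modes)))
    msg <- c(msg, "modes must be finite")
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (length(msg)) msg else TRUE
})

#' Electrode montage
#'
#' Channel names and 3D electrode positions (meters) in a head-centered
#' right-handed frame: +z through the vertex, +x through the nasion.
#'
#' @slot channelNames character vector, unique
#' @slot positions numeric matrix, channels x 3 (x, y, z in meters)
#' @export
setClass("Montage",
  representation(channelNames = "character", positions = "matrix"))

setValidity("Montage", function(object) {
  msg <- character()
  n <- length(object@channelNames)
  if (n < 4) msg <- c(msg, "at least 4 electrodes required")
  if (anyDuplicated(object@channelNames)) msg <- c(msg, "channel names must be unique")
  if (nrow(object@positions) != n || ncol(object@positions) != 3)
    msg <- c(msg, "positions must be channels x 3")
  if (n >= 2) {
    d <- as.matrix(stats::dist(object@positions))
    diag(d) <- Inf
    if (any(d < 1e-12)) msg <- c(msg, "coincident electrodes")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Montage-class
#' @param channelNames character vector of unique channel names
#' @param positions channels x 3 position matrix (meters)
#' @return a \code{Montage}
#' @export
Montage <- function(channelNames, positions) {
  positions <- as.matrix(positions)
  dimnames(positions) <- list(channelNames, c("x", "y", "z"))
  new("Montage", channelNames = as.character(channelNames),
      positions = positions)
}

#' Volumetric source grid
#'
#' Regular Cartesian lattice of candidate dipole locations clipped to a ball
#' strictly inside the scalp sphere, with coarse octant/depth region labels
#' standing in for anatomical lobes.
#'
#' @slot positions numeric matrix, nodes x 3 (meters), lexicographic x,y,z order
#' @slot spacing lattice spacing (meters)
#' @slot radius clipping radius (meters)
#' @slot regions character region label per node
#' @export
setClass("SourceGrid",
  representation(positions = "matrix", spacing = "numeric",
                 radius = "numeric", regions = "character"))

setValidity("SourceGrid", function(object) {
  msg <- character()
  if (nrow(object@positions) < 1) msg <- c(msg, "grid must have >= 1 node")
  if (ncol(object@positions) != 3) msg <- c(msg, "positions must be nodes x 3")
  r <- sqrt(rowSums(object@positions^2))
  if (any(r > object@radius + 1e-12))
    msg <- c(msg, "all nodes must lie inside the clipping radius")
  if (length(object@regions) != nrow(object@positions))
    msg <- c(msg, "one region label per node")
  if (length(msg)) msg else TRUE
})

#' Lead field (gain matrix)
#'
#' Linear map from dipole moments at the grid nodes to referenced electrode
#' potentials, in volts per ampere-meter. In free-orientation mode columns
#' come in (x, y, z) blocks per node; in fixed-orientation mode each node has
#' a single column for a radially oriented dipole.
#'
#' @slot gain numeric matrix, electrodes x (3 N_v or N_v)
#' @slot montage the \code{Montage} (electrodes projected onto the sphere)
#' @slot grid the \code{SourceGrid}
#' @slot orientation "free" or "fixed"
#' @slot conductivity volume conductivity (S/m)
#' @slot radius scalp sphere radius (meters)
#' @export
setClass("LeadField",
  representation(gain = "matrix", montage = "Montage", grid = "SourceGrid",
                 orientation = "character", conductivity = "numeric",
                 radius = "numeric"))

setValidity("LeadField", function(object) {
  msg <- character()
  nv <- nrow(object@grid@positions)
  ne <- length(object@montage@channelNames)
  want <- if (identical(object@orientation, "fixed")) nv else 3L * nv
  if (!object@orientation %in% c("free", "fixed"))
    msg <- c(msg, "orientation must be 'free' or 'fixed'")
  if (nrow(object@gain) != ne) msg <- c(msg, "gain rows must match electrodes")
  if (ncol(object@gain) != want) msg <- c(msg, "gain columns inconsistent with grid")
  if (!all(is.finite(object@gain))) msg <- c(msg, "gain must be finite")
  if (object@conductivity <= 0) msg <- c(msg, "conductivity must be > 0")
  if (length(msg)) msg else TRUE
})

#' Standardized dipole-energy map
#'
#' Per-node standardized current dipole energy at one time instant or window,
#' the quantity sLORETA maps.
#'
#' @slot energy nonnegative numeric vector, one value per grid node
#' @slot grid the \code{SourceGrid}
#' @slot label free-text time/window label
#' @export
setClass("SourceMap",
  representation(energy = "numeric", grid = "SourceGrid", label = "character"),
  prototype(label = ""))

setValidity("SourceMap", function(object) {
  msg <- character()
  if (length(object@energy) != nrow(object@grid@positions))
    msg <- c(msg, "one energy value per grid node")
  if (any(!is.finite(object@energy))) msg <- c(msg, "energy must be finite")
  if (any(object@energy < -1e-12)) msg <- c(msg, "energy must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Voxelwise paired-test result
#'
#' Paired t statistics per grid node with permutation-corrected p values
#' (max-statistic family-wise correction) and |t| thresholds at the standard
#' significance levels. Positive t means condition A (CT) larger than B (NCT).
#'
#' @slot t numeric t value per node
#' @slot p corrected p value per node, in [0, 1]
#' @slot thresholds named numeric |t| thresholds for levels 0.05, 0.01, 0.001
#' @slot nPerm number of permutations used (2^S when exhaustive)
#' @slot method "exhaustive" or "sampled"
#' @slot grid the \code{SourceGrid}
#' @export
setClass("StatResult",
  representation(t = "numeric", p = "numeric", thresholds = "numeric",
                 nPerm = "integer", method = "character", grid = "SourceGrid"))

setValidity("StatResult", function(object) {
  msg <- character()
  nv <- nrow(object@grid@positions)
  if (length(object@t) != nv || length(object@p) != nv)
    msg <- c(msg, "t and p must have one value per node")
  if (any(object@p < 0 | object@p > 1)) msg <- c(msg, "p must lie in [0, 1]")
  if (!all(is.finite(object@t))) msg <- c(msg, "t must be finite")
  if (length(msg)) msg else TRUE
})

#' Continuous multichannel EEG recording
#'
#' @slot data numeric matrix, channels x time (microvolts)
#' @slot rate sampling rate (samples/second)
#' @slot channelNames character vector
#' @slot markers data.frame with columns \code{sample} (1-based index) and
#'   \code{condition} (character label)
#' @export
setClass("EEGRecording",
  representation(data = "matrix", rate = "numeric",
                 channelNames = "character", markers = "data.frame"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "one channel name per data row")
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (nrow(object@markers)) {
    if (!all(c("sample", "condition") %in% names(object@markers)))
      msg <- c(msg, "markers need 'sample' and 'condition' columns")
    else if (any(object@markers$sample < 1 | object@markers$sample > ncol(object@data)))
      msg <- c(msg, "marker samples out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Epoched EEG trials
#'
#' @slot data numeric array, channels x time x trials (microvolts)
#' @slot rate sampling rate (samples/second)
#' @slot times numeric vector of sample times (seconds, relative to stimulus)
#' @slot channelNames character vector
#' @export
setClass("EEGEpochs",
  representation(data = "array", rate = "numeric", times = "numeric",
                 channelNames = "character"))

setValidity("EEGEpochs", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3) msg <- c(msg, "data must be channels x time x trials")
  else {
    if (d[1] != length(object@channelNames)) msg <- c(msg, "channel names mismatch")
    if (d[2] != length(object@times)) msg <- c(msg, "time axis mismatch")
  }
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname EEGEpochs-class
#' @param data channels x time x trials array (microvolts)
#' @param rate sampling rate (samples/second)
#' @param times time axis (seconds); computed from rate if missing
#' @param channelNames channel names; generated if missing
#' @return an \code{EEGEpochs}
#' @export
EEGEpochs <- function(data, rate, times = NULL, channelNames = NULL) {
  d <- dim(data)
  if (is.null(times)) times <- seq(0, by = 1 / rate, length.out = d[2])
  if (is.null(channelNames)) channelNames <- sprintf("E%02d", seq_len(d[1]))
  new("EEGEpochs", data = data, rate = rate, times = times,
      channelNames = channelNames)
}
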