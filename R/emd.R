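# Empirical mode decomposition: sifting, its noise-assisted ensemble variant,
# and extraction/selection of event-related modes from epoched EEG.

#' Locate interior extrema of a sampled signal
#'
#' Strict turning points are reported; plateaus contribute a single extremum
#' at their midpoint; the first and last samples are never extrema. A
#' constant signal returns empty index sets, which signals the
#' non-oscillating-trend condition that terminates mode extraction.
#'
#' @param x numeric vector, length >= 3
#' @return list with integer components \code{maxima} and \code{minima}
#'   (1-based indices, interleaved by construction)
#' @examples
#' findExtrema(c(0, 1, 0, -1, 0))
#' @export
findExtrema <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 3, all(is.finite(x)))
  .cpp_find_extrema(as.numeric(x))
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' Fits natural cubic splines through the local maxima (upper envelope) and
#' minima (lower envelope) after mirror-extending two extrema of each kind
#' past both ends, and returns the pointwise envelope mean
#' \eqn{m(t) = [env_{max}(t) + env_{min}(t)]/2}. This is the quantity
#' subtracted at each sift iteration.
#'
#' @param x numeric vector
#' @return numeric vector \code{m(t)} of the same length
#' @examples
#' t <- seq(0, 4, by = 0.01)
#' m <- envelopeMean(sin(2 * pi * t) + 1.5)  # approx 1.5 on the interior
#' @export
envelopeMean <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  res <- .cpp_envelope_mean(as.numeric(x))
  if (!res$ok)
    stop("cannot sift: signal has fewer than one maximum or one minimum")
  res$mean
}

#' Test the intrinsic-mode conditions
#'
#' TRUE iff (i) the numbers of interior extrema and zero crossings differ by
#' at most one and (ii) the RMS of the envelope mean, taken over the
#' interior spanned by the extrema, stays within \code{envTol} times the
#' signal's standard deviation.
#'
#' @param x numeric vector
#' @param envTol relative envelope-mean RMS tolerance (default 0.2)
#' @return logical scalar
#' @examples
#' t <- seq(0, 4, by = 0.01)
#' isIMF(sin(2 * pi * 4 * t))        # TRUE
#' isIMF(t)                          # FALSE: no oscillation
#' @export
isIMF <- function(x, envTol = 0.2) {
  stopifnot(is.numeric(x), all(is.finite(x)), envTol > 0)
  .cpp_is_imf(as.numeric(x), envTol)
}

#' Number of zero crossings (exact zeros skipped)
#' @param x numeric vector
#' @return integer count of sign changes
#' @export
zeroCrossings <- function(x) .cpp_zero_crossings(as.numeric(x))

#' Mean oscillation period in samples
#'
#' Length divided by the number of zero-crossing pairs; the standard summary
#' used to demonstrate the dyadic filter-bank behaviour of EMD on white
#' noise (consecutive modes roughly double their mean period).
#'
#' @param x numeric vector
#' @return mean period in samples (Inf if fewer than 2 zero crossings)
#' @export
meanPeriod <- function(x) {
  zc <- zeroCrossings(x)
  if (zc < 2) return(Inf)
  2 * length(x) / zc
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions by iterative sifting:
#' subtract the spline-envelope mean until the candidate satisfies the
#' intrinsic-mode conditions and the relative change between sift iterates
#' falls below \code{stopSD(cfg)}. Extraction stops when the residual has
#' fewer than two interior extrema (a non-oscillating trend) or
#' \code{maxModes} is reached. The returned modes plus residual reproduce
#' the input to numerical precision (perfect reconstruction).
#'
#' @param x numeric vector, length >= 8
#' @param cfg a \code{\link{SiftConfig}}
#' @param rate sampling rate stored with the result (samples/second)
#' @return an \code{\link{IMFSet}}
#' @examples
#' t <- seq(0, 4, by = 1 / 250)
#' dec <- emd(sin(2 * pi * t) + sin(2 * pi * 8 * t))
#' nModes(dec)
#' @export
emd <- function(x, cfg = SiftConfig(), rate = 1) {
  stopifnot(is.numeric(x), length(x) >= 8, all(is.finite(x)))
  res <- .cpp_emd(as.numeric(x), cfg@maxModes, cfg@maxSifts,
                  cfg@stopSD, cfg@envTol)
  md <- res$modes
  if (is.null(dim(md))) md <- matrix(md, nrow = length(x))
  new("IMFSet", modes = md, residual = as.numeric(res$residual), rate = rate,
      params = list(maxModes = cfg@maxModes, maxSifts = cfg@maxSifts,
                    stopSD = cfg@stopSD, envTol = cfg@envTol,
                    sifts = res$sifts, method = "emd"))
}

# Run fn with a private RNG stream seeded by `seed`, restoring caller state.
withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Ensemble empirical mode decomposition
#'
#' Applies EMD to \code{ensembleSize(cfg)} noise-perturbed copies of the
#' signal (white noise of standard deviation \code{noiseRatio} times the
#' signal's standard deviation) and returns the index-wise ensemble mean of
#' the modes; per-realization mode counts are harmonized by padding with
#' zero modes up to the largest count observed. The added noise
#' self-averages out of the ensemble mean, which suppresses mode mixing.
#' Deterministic given \code{seed(cfg)}: the noise is drawn as a single
#' standard-normal matrix (samples x realizations, column order) from the
#' master seed.
#'
#' @inheritParams emd
#' @param noiseSD absolute standard deviation of the added noise; overrides
#'   the relative \code{noiseRatio(cfg)} scaling when given (used for
#'   multichannel decompositions that share one noise floor across channels)
#' @return an \code{\link{IMFSet}} of ensemble-averaged modes
#' @export
eemd <- function(x, cfg = SiftConfig(), rate = 1, noiseSD = NULL) {
  stopifnot(is.numeric(x), length(x) >= 8, all(is.finite(x)))
  if (is.null(noiseSD) && cfg@noiseRatio == 0) return(emd(x, cfg, rate))
  n <- length(x)
  nens <- cfg@ensembleSize
  eps <- if (is.null(noiseSD)) cfg@noiseRatio * stats::sd(x) else noiseSD
  if (eps == 0) return(emd(x, cfg, rate))
  noise <- withSeed(cfg@seed, function() matrix(rnorm(n * nens), n, nens))
  runs <- vector("list", nens)
  for (k in seq_len(nens))
    runs[[k]] <- .cpp_emd(x + eps * noise[, k], cfg@maxModes, cfg@maxSifts,
                          cfg@stopSD, cfg@envTol)
  jmax <- max(vapply(runs, function(r) ncol(r$modes), integer(1)))
  acc <- matrix(0, n, jmax)
  resid <- numeric(n)
  for (k in seq_len(nens)) {
    mk <- runs[[k]]$modes
    if (ncol(mk) > 0) acc[, seq_len(ncol(mk))] <- acc[, seq_len(ncol(mk))] + mk
    resid <- resid + runs[[k]]$residual
  }
  new("IMFSet", modes = acc / nens, residual = resid / nens, rate = rate,
      params = list(maxModes = cfg@maxModes, maxSifts = cfg@maxSifts,
                    stopSD = cfg@stopSD, envTol = cfg@envTol,
                    ensembleSize = nens, noiseRatio = cfg@noiseRatio,
                    seed = cfg@seed, method = "eemd"))
}

#' Event-related modes from trial epochs
#'
#' Decomposes every trial of every channel with \code{\link{eemd}}, aligns
#' modes by index (zero-padding missing high-index modes) and averages mode
#' j across trials, yielding the channel's event-related modes (ERMs).
#' Channels whose trials are all constant yield an empty mode set and a
#' warning.
#'
#' @param epochs an \code{\link{EEGEpochs}} object
#' @param cfg a \code{\link{SiftConfig}}; per-trial noise seeds are spawned
#'   from \code{seed(cfg)} unless \code{seedPerTrial = "shared"}
#' @param seedPerTrial "distinct" (default) draws an independent noise
#'   stream per channel/trial; "shared" reuses the master seed for every
#'   trial (useful for exact-reproducibility checks)
#' @param noiseScale "channel" scales the ensemble noise to each signal's
#'   own standard deviation (\code{noiseRatio(cfg)} as a fraction of it);
#'   "common" uses one absolute noise amplitude for all channels,
#'   \code{noiseRatio(cfg)} times the largest channel standard deviation.
#'   A common noise floor keeps the band decisions of the sift identical
#'   across channels, so each mode's scalp topography stays proportional to
#'   the underlying signal topography even at weak channels
#' @return list of \code{\link{IMFSet}} objects, one per channel
#' @export
ermsFromTrials <- function(epochs, cfg = SiftConfig(),
                           seedPerTrial = c("distinct", "shared"),
                           noiseScale = c("channel", "common")) {
  stopifnot(is(epochs, "EEGEpochs"))
  seedPerTrial <- match.arg(seedPerTrial)
  noiseScale <- match.arg(noiseScale)
  commonSD <- if (noiseScale == "common")
    cfg@noiseRatio * max(apply(epochs@data, 1, stats::sd)) else NULL
  d <- dim(epochs@data)
  nch <- d[1]; ntr <- d[3]
  stopifnot(ntr >= 1)
  seeds <- if (seedPerTrial == "distinct")
    withSeed(cfg@seed, function()
      matrix(sample.int(.Machine$integer.max, nch * ntr), nch, ntr))
  else matrix(cfg@seed, nch, ntr)
  out <- vector("list", nch)
  names(out) <- epochs@channelNames
  for (ch in seq_len(nch)) {
    trials <- epochs@data[ch, , , drop = FALSE]
    if (all(abs(trials - trials[1, 1, 1]) < .Machine$double.eps * 4)) {
      warning("channel ", epochs@channelNames[ch],
              ": all-constant trials, empty ERM set")
      out[[ch]] <- new("IMFSet", modes = matrix(numeric(0), d[2], 0),
                       residual = trials[1, , 1], rate = epochs@rate,
                       params = list(method = "erm", empty = TRUE))
      next
    }
    decs <- vector("list", ntr)
    for (tr in seq_len(ntr)) {
      ctr <- cfg
      ctr@seed <- as.integer(seeds[ch, tr])
      decs[[tr]] <- eemd(epochs@data[ch, , tr], ctr, rate = epochs@rate,
                         noiseSD = commonSD)
    }
    jmax <- max(vapply(decs, nModes, integer(1)))
    acc <- matrix(0, d[2], jmax)
    resid <- numeric(d[2])
    for (tr in seq_len(ntr)) {
      mk <- modes(decs[[tr]])
      if (ncol(mk) > 0) acc[, seq_len(ncol(mk))] <- acc[, seq_len(ncol(mk))] + mk
      resid <- resid + residualSignal(decs[[tr]])
    }
    out[[ch]] <- new("IMFSet", modes = acc / ntr, residual = resid / ntr,
                     rate = epochs@rate,
                     params = list(method = "erm", nTrials = ntr,
                                   ensembleSize = cfg@ensembleSize,
                                   noiseRatio = cfg@noiseRatio,
                                   seed = cfg@seed))
  }
  out
}

#' Event-related modes from a trial-averaged ERP
#'
#' Decomposes each channel's trial-averaged ERP with \code{\link{eemd}}.
#' Compared to per-trial decomposition (\code{\link{ermsFromTrials}}) this
#' averages the noise away before sifting, so the mode split of the evoked
#' waveform is identical across channels up to gain and the scalp topography
#' of each mode is preserved; it is also far cheaper. Per-channel noise
#' seeds are spawned from \code{seed(cfg)}.
#'
#' @param erp numeric matrix channels x time (e.g. from
#'   \code{\link{averageErp}})
#' @param cfg a \code{\link{SiftConfig}}
#' @param rate sampling rate (samples/second)
#' @inheritParams ermsFromTrials
#' @return list of \code{\link{IMFSet}} objects, one per channel
#' @export
ermsFromErp <- function(erp, cfg = SiftConfig(), rate = 1,
                        noiseScale = c("channel", "common")) {
  stopifnot(is.matrix(erp), nrow(erp) >= 1)
  noiseScale <- match.arg(noiseScale)
  commonSD <- if (noiseScale == "common")
    cfg@noiseRatio * max(apply(erp, 1, stats::sd)) else NULL
  nch <- nrow(erp)
  seeds <- spawnSeeds(cfg@seed, nch)
  out <- vector("list", nch)
  names(out) <- rownames(erp)
  for (ch in seq_len(nch)) {
    cc <- cfg
    cc@seed <- as.integer(seeds[ch])
    out[[ch]] <- eemd(erp[ch, ], cc, rate = rate, noiseSD = commonSD)
  }
  out
}

#' Select the event-related mode that best matches the ERP
#'
#' For each mode index j, computes the absolute Pearson correlation between
#' ERM_j and the channel's trial-averaged ERP, averages across channels, and
#' returns the index with the largest mean correlation (ties broken toward
#' the lower index). Zero-variance modes contribute a correlation of 0.
#'
#' @param erms list of \code{\link{IMFSet}} (one per channel), as returned
#'   by \code{\link{ermsFromTrials}}
#' @param reference numeric matrix channels x time of per-channel ERPs
#' @return integer mode index
#' @export
selectMode <- function(erms, reference) {
  stopifnot(is.list(erms), length(erms) >= 1,
            nrow(reference) == length(erms))
  jmax <- max(vapply(erms, nModes, integer(1)))
  if (jmax < 1) stop("no modes to select from")
  score <- numeric(jmax)
  for (j in seq_len(jmax)) {
    cs <- vapply(seq_along(erms), function(ch) {
      m <- modes(erms[[ch]])
      if (ncol(m) < j) return(0)
      v <- m[, j]
      ref <- reference[ch, ]
      if (stats::sd(v) == 0 || stats::sd(ref) == 0) return(0)
      abs(stats::cor(v, ref))
    }, numeric(1))
    score[j] <- mean(cs)
  }
  which.max(score)  # which.max already takes the first (lowest) maximum
}
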