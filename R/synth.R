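# Synthetic two-condition ERP study generator: dipolar P100/N200 source
# waveforms projected through the forward model into multi-subject,
# multi-trial scalp epochs with white + 1/f sensor noise.

#' Gaussian-windowed cosine ERP component
#'
#' \deqn{a \exp(-(t-\mu)^2/(2 w^2)) \cos(2\pi f (t-\mu))}
#' peaks at exactly the amplitude \code{a} at \code{t = latency}. The
#' carrier frequency controls which decomposition mode the component lands
#' in; the width controls its duration.
#'
#' @param latency peak latency in seconds after stimulus onset
#' @param width Gaussian envelope standard deviation in seconds (> 0)
#' @param frequency carrier frequency in Hz
#' @param amplitude peak amplitude (sign encodes polarity)
#' @param times numeric vector of sample times (seconds)
#' @return numeric waveform over \code{times}
#' @examples
#' t <- seq(-0.2, 0.8, by = 1 / 500)
#' w <- makeComponent(0.1, 0.03, 10, 1, t)
#' max(w)  # 1 at t = 0.1
#' @export
makeComponent <- function(latency, width, frequency, amplitude, times) {
  stopifnot(width > 0)
  amplitude * exp(-(times - latency)^2 / (2 * width^2)) *
    cos(2 * pi * frequency * (times - latency))
}

#' Simulation configuration
#'
#' Defaults mirror the two-condition visual ERP study design this
#' generator emulates: 18 subjects, 62-channel scalp coverage sampled
#' at 500 Hz, epochs from -0.2 to 0.8 s, and an occipital dipole source
#' whose P100 component (latency 0.10 s, width 0.03 s, 10 Hz carrier,
#' positive) is 50% stronger under condition CT than NCT, plus an N200
#' component (0.20 s, 0.04 s, 7 Hz, negative) of equal amplitude across
#' conditions. Amplitudes are in nanoampere-meters.
#'
#' @slot nSubjects number of subjects
#' @slot nTrials trials per condition
#' @slot rate sampling rate (samples/second)
#' @slot epoch numeric length-2, epoch span (seconds relative to stimulus)
#' @slot sources list of source specs: each a list with \code{node} (grid
#'   index), \code{orientation} ("radial" or a length-3 vector) and
#'   \code{components}, a list of lists with \code{latency}, \code{width},
#'   \code{frequency}, \code{ampCT}, \code{ampNCT} (nA m)
#' @slot noiseSD white sensor-noise standard deviation (microvolts/trial)
#' @slot pinkWeight 1/f background standard deviation, as a fraction of
#'   \code{noiseSD} (0 disables)
#' @slot subjectJitter lognormal sigma of the per-subject source amplitude
#'   factor (inter-subject variability; shared across conditions)
#' @slot seed master seed
#' @export
setClass("SimConfig",
  representation(nSubjects = "integer", nTrials = "integer", rate = "numeric",
                 epoch = "numeric", sources = "list", noiseSD = "numeric",
                 pinkWeight = "numeric", subjectJitter = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 1) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nTrials < 1) msg <- c(msg, "nTrials must be >= 1")
  if (object@rate <= 0) msg <- c(msg, "rate must be > 0")
  if (length(object@epoch) != 2 || diff(object@epoch) <= 0)
    msg <- c(msg, "epoch must be (tmin, tmax) with tmax > tmin")
  for (src in object@sources)
    for (cmp in src$components) {
      if (cmp$latency < object@epoch[1] || cmp$latency > object@epoch[2])
        msg <- c(msg, "component latency outside epoch")
      if (!all(is.finite(c(cmp$ampCT, cmp$ampNCT))))
        msg <- c(msg, "amplitudes must be finite")
      if (cmp$width <= 0) msg <- c(msg, "component width must be > 0")
    }
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (object@pinkWeight < 0) msg <- c(msg, "pinkWeight must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subjects x", object@nTrials,
      "trials/condition @", object@rate, "Hz, epoch [",
      object@epoch[1], ",", object@epoch[2], ") s,",
      length(object@sources), "source(s), noiseSD", object@noiseSD,
      "uV, seed", object@seed, "\n")
})

#' Default dipolar sources for a grid
#'
#' An occipital node (closest to the posterior-superior direction at 80%% of
#' the grid radius) carrying a P100 with a 50%% CT amplitude boost and a
#' condition-neutral N200. Optionally adds a frontal source replaying the
#' occipital waveform 70 ms later, emulating the early/late response delay.
#'
#' @param grid a \code{\link{SourceGrid}}
#' @param boost CT/NCT amplitude ratio of the P100 (default 1.5)
#' @param frontalDelay if TRUE, add the delayed frontal copy
#' @return list of source specs for \code{\link{SimConfig}}
#' @export
defaultSources <- function(grid, boost = 1.5, frontalDelay = FALSE) {
  target <- grid@radius * 0.8 * c(0, -0.85, 0.5)
  occ <- which.min(colSums((t(grid@positions) - target)^2))
  p100 <- list(latency = 0.10, width = 0.03, frequency = 10,
               ampCT = 20 * boost / 1.5, ampNCT = 20 / 1.5)
  n200 <- list(latency = 0.20, width = 0.04, frequency = 7,
               ampCT = -25, ampNCT = -25)
  src <- list(list(node = occ, orientation = "radial",
                   components = list(p100, n200)))
  if (frontalDelay) {
    ftarget <- grid@radius * 0.8 * c(0, 0.85, 0.5)
    fro <- which.min(colSums((t(grid@positions) - ftarget)^2))
    d100 <- p100; d100$latency <- p100$latency + 0.07
    d200 <- n200; d200$latency <- n200$latency + 0.07
    src <- c(src, list(list(node = fro, orientation = "radial",
                            components = list(d100, d200))))
  }
  src
}

#' @rdname SimConfig-class
#' @param nSubjects,nTrials,rate,epoch,sources,noiseSD,pinkWeight,subjectJitter,seed
#'   see slots
#' @return a \code{SimConfig}
#' @export
SimConfig <- function(sources, nSubjects = 18, nTrials = 150, rate = 500,
                      epoch = c(-0.2, 0.8), noiseSD = 15, pinkWeight = 0.5,
                      subjectJitter = 0.2, seed = 1) {
  new("SimConfig", nSubjects = as.integer(nSubjects),
      nTrials = as.integer(nTrials), rate = as.numeric(rate),
      epoch = as.numeric(epoch), sources = sources,
      noiseSD = as.numeric(noiseSD), pinkWeight = as.numeric(pinkWeight),
      subjectJitter = as.numeric(subjectJitter), seed = as.integer(seed))
}

# Epoch time axis: half-open [tmin, tmax) sampling.
epochTimes <- function(cfg) {
  n <- round(diff(cfg@epoch) * cfg@rate)
  seq(cfg@epoch[1], by = 1 / cfg@rate, length.out = n)
}

# 1/f-shaped noise: white noise spectrally weighted by f^(-1/2) (power 1/f),
# rescaled to unit standard deviation.
pinkNoise <- function(n) {
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # two-sided frequency index
  sp <- sp * f^(-0.5)
  x <- Re(fft(sp, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x)
}

# Clean per-condition source moment time courses (rows = gain columns used
# by the sources) and their scalp projection in microvolts.
cleanScalp <- function(cfg, leadfield, condition, ampFactor = NULL) {
  times <- epochTimes(cfg)
  ne <- nrow(leadfield@gain)
  phi <- matrix(0, ne, length(times))
  for (si in seq_along(cfg@sources)) {
    src <- cfg@sources[[si]]
    nodes <- leadfield@grid@positions
    if (src$node < 1 || src$node > nrow(nodes))
      stop("source node index out of range: ", src$node)
    wf <- numeric(length(times))
    for (cmp in src$components) {
      a <- if (condition == "CT") cmp$ampCT else cmp$ampNCT
      wf <- wf + makeComponent(cmp$latency, cmp$width, cmp$frequency, a, times)
    }
    if (!is.null(ampFactor)) wf <- wf * ampFactor[si]
    ori <- src$orientation
    if (identical(ori, "radial")) {
      p <- nodes[src$node, ]
      if (sqrt(sum(p^2)) < 1e-12)
        stop("radial orientation undefined at the origin node")
      ori <- p / sqrt(sum(p^2))
    }
    ori <- ori / sqrt(sum(ori^2))
    blk <- if (leadfield@orientation == "fixed")
      leadfield@gain[, src$node, drop = FALSE]
    else
      leadfield@gain[, (3 * src$node - 2):(3 * src$node), drop = FALSE] %*% ori
    # gain V/(A m) x amplitude nA m -> volts * 1e-9; report microvolts (1e6)
    phi <- phi + 1e-3 * (blk %*% matrix(wf, 1))
  }
  phi
}

#' Simulate one subject's two-condition epochs
#'
#' Each trial is the forward-projected sum of the configured dipole sources
#' (condition difference enters only through the per-condition component
#' amplitudes) plus white sensor noise and an optional 1/f background.
#' Inter-subject variability is a lognormal amplitude factor per source,
#' shared across conditions and trials. Deterministic given
#' \code{(config, subjectSeed)}.
#'
#' @param cfg a \code{\link{SimConfig}}
#' @param leadfield a \code{\link{LeadField}} whose grid contains the
#'   configured source nodes
#' @param subjectSeed integer seed for this subject
#' @return list with elements \code{CT}, \code{NCT} (each an
#'   \code{\link{EEGEpochs}}) and \code{truth} (amplitude factors and clean
#'   scalp ERPs per condition, microvolts)
#' @export
simulateSubject <- function(cfg, leadfield, subjectSeed) {
  times <- epochTimes(cfg)
  ne <- nrow(leadfield@gain)
  nt <- length(times)
  withSeed(as.integer(subjectSeed), function() {
    ampFactor <- exp(rnorm(length(cfg@sources), 0, cfg@subjectJitter))
    clean <- list(CT = cleanScalp(cfg, leadfield, "CT", ampFactor),
                  NCT = cleanScalp(cfg, leadfield, "NCT", ampFactor))
    out <- list()
    for (cond in c("CT", "NCT")) {
      cube <- array(0, c(ne, nt, cfg@nTrials))
      for (tr in seq_len(cfg@nTrials)) {
        noise <- matrix(rnorm(ne * nt, 0, cfg@noiseSD), ne, nt)
        if (cfg@pinkWeight > 0 && cfg@noiseSD > 0) {
          pink <- t(vapply(seq_len(ne), function(i) pinkNoise(nt),
                           numeric(nt)))
          noise <- noise + cfg@pinkWeight * cfg@noiseSD * pink
        }
        cube[, , tr] <- clean[[cond]] + noise
      }
      out[[cond]] <- EEGEpochs(cube, cfg@rate, times,
                               leadfield@montage@channelNames)
    }
    out$truth <- list(ampFactor = ampFactor, cleanERP = clean)
    out
  })
}

#' Simulated multi-subject study
#'
#' @slot subjects list (one per subject) of lists with \code{CT} and
#'   \code{NCT} \code{\link{EEGEpochs}}
#' @slot truth ground truth: source nodes, per-condition amplitudes,
#'   per-subject amplitude factors and clean scalp ERPs
#' @slot config the generating \code{\link{SimConfig}}
#' @export
setClass("SimStudy",
  representation(subjects = "list", truth = "list", config = "SimConfig"))

setMethod("show", "SimStudy", function(object) {
  cat("SimStudy:", length(object@subjects), "subjects,",
      object@config@nTrials, "trials/condition, seed",
      object@config@seed, "\n")
})

#' Simulate a full two-condition study
#'
#' Spawns independent subject seeds from the master seed and simulates each
#' subject with \code{\link{simulateSubject}}. The ground truth (active
#' nodes, per-condition component amplitudes, per-subject factors) is
#' carried in the returned object and can be written to a structured text
#' sidecar with \code{\link{writeGroundTruth}}.
#'
#' @param cfg a \code{\link{SimConfig}}
#' @param leadfield a \code{\link{LeadField}}
#' @return a \code{\link{SimStudy}}
#' @export
simulateStudy <- function(cfg, leadfield) {
  seeds <- spawnSeeds(cfg@seed, cfg@nSubjects)
  subjects <- vector("list", cfg@nSubjects)
  factors <- matrix(0, cfg@nSubjects, length(cfg@sources))
  for (s in seq_len(cfg@nSubjects)) {
    subjects[[s]] <- simulateSubject(cfg, leadfield, seeds[s])
    factors[s, ] <- subjects[[s]]$truth$ampFactor
  }
  truth <- list(
    nodes = vapply(cfg@sources, function(s) as.integer(s$node), integer(1)),
    components = lapply(cfg@sources, function(s) s$components),
    subjectSeeds = seeds,
    ampFactors = factors)
  new("SimStudy", subjects = subjects, truth = truth, config = cfg)
}

#' Write / read the ground-truth sidecar
#'
#' Machine-readable YAML with the active nodes, component parameters,
#' subject seeds and amplitude factors; round-trips exactly.
#'
#' @param study a \code{\link{SimStudy}}
#' @param path output file
#' @export
writeGroundTruth <- function(study, path) {
  tr <- study@truth
  yaml::write_yaml(list(
    nodes = as.integer(tr$nodes),
    components = tr$components,
    subject_seeds = as.integer(tr$subjectSeeds),
    amp_factors = apply(tr$ampFactors, 1, as.list)), path)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @return \code{readGroundTruth}: the truth list
#' @export
readGroundTruth <- function(path) {
  y <- yaml::read_yaml(path)
  list(nodes = as.integer(unlist(y$nodes)),
       components = y$components,
       subjectSeeds = as.integer(unlist(y$subject_seeds)),
       ampFactors = do.call(rbind, lapply(y$amp_factors, unlist)))
}
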