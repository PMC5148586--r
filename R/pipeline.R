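# End-to-end analysis: per-subject ERP and event-related-mode extraction,
# window means, per-subject standardized source maps per condition, group
# paired t with sign-flip randomization, peak tables and provenance.

#' Analysis configuration
#'
#' Drives \code{\link{runPipeline}}. The default windows are the four
#' analysis intervals of the early/late P100 and N200 components. Pooling
#' is off by default (pooling channels before localization trades spatial
#' accuracy for noise reduction); when given, it must be a named list of
#' channel-name groups and both the data and the lead-field rows are
#' averaged per group.
#'
#' @slot windows named list of numeric length-2 windows (seconds,
#'   half-open)
#' @slot conditions length-2 character, condition labels (A, B); positive t
#'   means A > B
#' @slot sift a \code{\link{SiftConfig}} for the mode-decomposition branch
#' @slot alpha regularization parameter; NA uses
#'   \code{\link{alphaHeuristic}} with \code{snr}
#' @slot snr assumed signal-to-noise ratio for the alpha heuristic
#' @slot modeSelection "auto" (correlation with the ERP, aggregated over
#'   subjects), "sum" (all modes + residual, i.e. the reconstruction), or an
#'   integer mode index as a character (e.g. "5")
#' @slot ermSource "trial" decomposes every single trial and averages modes
#'   across trials (decomposition before averaging, the event-related-mode
#'   definition); "erp" decomposes the trial-averaged ERP per channel, which
#'   preserves each mode's scalp topography exactly up to channel gain and
#'   is much cheaper
#' @slot noiseScale ensemble-noise scaling for the decomposition branch:
#'   "channel" (per-signal relative) or "common" (one absolute noise floor
#'   per subject, \code{noiseRatio} times the largest channel SD)
#' @slot mapAverage how a window becomes one map per subject/condition:
#'   "potential" averages the potentials over the window and inverts once
#'   (mean response amplitude); "energy" inverts every sample in the window
#'   and averages the standardized energies, which is robust to phase
#'   cancellation of oscillatory modes
#' @slot pooling named list of channel groups (empty = no pooling)
#' @slot logTransform apply a log transform to energies before the t-test
#' @slot nPerm permutations for the randomization test
#' @slot seed master seed for decomposition noise and permutations
#' @export
setClass("AnalysisConfig",
  representation(windows = "list", conditions = "character",
                 sift = "SiftConfig", alpha = "numeric", snr = "numeric",
                 modeSelection = "character", ermSource = "character",
                 noiseScale = "character", mapAverage = "character",
                 pooling = "list",
                 logTransform = "logical", nPerm = "integer",
                 seed = "integer"))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (length(object@conditions) != 2 ||
      anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must be two distinct labels")
  if (length(object@windows) < 1) msg <- c(msg, "at least one window")
  if (is.null(names(object@windows)) || anyDuplicated(names(object@windows)))
    msg <- c(msg, "windows must have unique names")
  for (w in object@windows)
    if (length(w) != 2 || w[2] <= w[1]) msg <- c(msg, "bad window")
  if (object@nPerm < 100) msg <- c(msg, "nPerm must be >= 100")
  if (!object@ermSource %in% c("trial", "erp"))
    msg <- c(msg, "ermSource must be 'trial' or 'erp'")
  if (!object@mapAverage %in% c("potential", "energy"))
    msg <- c(msg, "mapAverage must be 'potential' or 'energy'")
  if (!object@noiseScale %in% c("channel", "common"))
    msg <- c(msg, "noiseScale must be 'channel' or 'common'")
  if (length(msg)) msg else TRUE
})

#' @rdname AnalysisConfig-class
#' @param windows,conditions,sift,alpha,snr,modeSelection,ermSource,noiseScale,mapAverage,pooling,logTransform,nPerm,seed
#'   see slots
#' @return an \code{AnalysisConfig}
#' @export
AnalysisConfig <- function(windows = list(early_P100 = c(0.060, 0.120),
                                          early_N200 = c(0.150, 0.210),
                                          late_P100 = c(0.120, 0.180),
                                          late_N200 = c(0.200, 0.260)),
                           conditions = c("CT", "NCT"),
                           sift = SiftConfig(), alpha = NA_real_, snr = 3,
                           modeSelection = "auto", ermSource = "trial",
                           noiseScale = "channel", mapAverage = "potential",
                           pooling = list(), logTransform = FALSE,
                           nPerm = 2000, seed = 1) {
  new("AnalysisConfig", windows = windows, conditions = conditions,
      sift = sift, alpha = as.numeric(alpha), snr = as.numeric(snr),
      modeSelection = as.character(modeSelection),
      ermSource = as.character(ermSource),
      noiseScale = as.character(noiseScale),
      mapAverage = as.character(mapAverage), pooling = pooling,
      logTransform = as.logical(logTransform), nPerm = as.integer(nPerm),
      seed = as.integer(seed))
}

#' Read an analysis configuration from YAML
#'
#' Keys mirror the \code{\link{AnalysisConfig}} slots; sifting parameters
#' live under \code{sift:} (keys max_modes, max_sifts, stop_sd, env_tol,
#' ensemble_size, noise_ratio, seed).
#'
#' @param path YAML file
#' @return an \code{\link{AnalysisConfig}}
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sf <- y$sift
  pick <- function(value, default) if (is.null(value)) default else value
  sift <- SiftConfig(
    maxModes = pick(sf$max_modes, 10),
    maxSifts = pick(sf$max_sifts, 100),
    stopSD = pick(sf$stop_sd, 0.2),
    envTol = pick(sf$env_tol, 0.2),
    ensembleSize = pick(sf$ensemble_size, 100),
    noiseRatio = pick(sf$noise_ratio, 0.2),
    seed = pick(sf$seed, 1))
  windows <- if (is.null(y$windows)) formals(AnalysisConfig)$windows
  else lapply(y$windows, unlist)
  if (is.language(windows)) windows <- eval(windows)
  AnalysisConfig(
    windows = windows,
    conditions = if (is.null(y$conditions)) c("CT", "NCT")
                 else unlist(y$conditions),
    sift = sift,
    alpha = if (is.null(y$alpha)) NA_real_ else y$alpha,
    snr = if (is.null(y$snr)) 3 else y$snr,
    modeSelection = if (is.null(y$mode_selection)) "auto" else y$mode_selection,
    ermSource = if (is.null(y$erm_source)) "trial" else y$erm_source,
    noiseScale = if (is.null(y$noise_scale)) "channel" else y$noise_scale,
    mapAverage = if (is.null(y$map_average)) "potential" else y$map_average,
    pooling = if (is.null(y$pooling)) list() else y$pooling,
    logTransform = isTRUE(y$log_transform),
    nPerm = if (is.null(y$n_perm)) 2000 else y$n_perm,
    seed = if (is.null(y$seed)) 1 else y$seed)
}

# Average data rows and lead-field rows over named channel groups.
poolChannels <- function(mat, channelNames, pooling) {
  rows <- lapply(pooling, function(chs) {
    idx <- match(chs, channelNames)
    if (anyNA(idx)) stop("pooling group refers to unknown channel(s)")
    colMeans(mat[idx, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(pooling)
  out
}

# Selected-mode time course per channel (channels x time).
ermTimecourse <- function(erms, modeIndex) {
  t(vapply(erms, function(im) {
    m <- modes(im)
    if (modeIndex == 0) {          # "sum": full reconstruction
      if (ncol(m)) rowSums(m) + residualSignal(im) else residualSignal(im)
    } else if (ncol(m) >= modeIndex) m[, modeIndex]
    else numeric(length(residualSignal(im)))
  }, numeric(length(residualSignal(erms[[1]])))))
}

#' Run the full two-branch analysis
#'
#' For every subject and condition the trial epochs are (i) averaged into an
#' ERP and (ii) decomposed into event-related modes; for every configured
#' window both branches produce a window-averaged scalp topography, a
#' standardized dipole-energy map per subject, and a group sign-flip
#' randomization test comparing the two conditions. Per window and branch
#' the output directory receives a t-map, a corrected p-map and peak tables
#' at the 0.05/0.01/0.001 levels, plus a provenance file (config echo and
#' hash, seeds, package/R versions). Deterministic given the config seed.
#'
#' @param study a \code{\link{SimStudy}} or a list (one element per subject)
#'   of lists holding an \code{\link{EEGEpochs}} per condition label
#' @param leadfield a \code{\link{LeadField}} whose montage matches the
#'   epoch channels
#' @param config an \code{\link{AnalysisConfig}}
#' @param outputDir results directory (created; cleaned up on failure)
#' @return invisibly, a list per window with elements \code{erp} and
#'   \code{erm}, each holding the \code{\link{StatResult}}, the per-subject
#'   energy matrices and the peak tables; plus \code{modeIndex}
#' @export
runPipeline <- function(study, leadfield, config, outputDir) {
  subjects <- if (is(study, "SimStudy")) study@subjects else study
  ns <- length(subjects)
  if (ns < 2) stop("pipeline stage 'input': need at least 2 subjects")
  condA <- config@conditions[1]; condB <- config@conditions[2]
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  cleanup <- function() unlink(file.path(outputDir, "*"))

  res <- tryCatch({
    alpha <- if (is.na(config@alpha)) alphaHeuristic(leadfield, config@snr)
             else config@alpha
    blocks <- resolutionCovariance(leadfield, alpha)
    grid <- leadfield@grid
    seeds <- spawnSeeds(config@seed, ns + length(config@windows))
    needErm <- TRUE

    erp <- vector("list", ns); erm <- vector("list", ns)
    times <- NULL
    for (s in seq_len(ns)) {
      erp[[s]] <- list(); erm[[s]] <- list()
      for (cond in c(condA, condB)) {
        ep <- subjects[[s]][[cond]]
        if (is.null(ep))
          stop("pipeline stage 'input', subject ", s,
               ": missing condition '", cond, "'")
        if (is.null(times)) times <- ep@times
        erp[[s]][[cond]] <- averageErp(ep)
        if (needErm) {
          cfgS <- config@sift
          cfgS@seed <- as.integer(seeds[s])
          erm[[s]][[cond]] <- tryCatch(
            if (config@ermSource == "trial")
              ermsFromTrials(ep, cfgS, noiseScale = config@noiseScale)
            else ermsFromErp(erp[[s]][[cond]], cfgS, rate = ep@rate,
                             noiseScale = config@noiseScale),
            error = function(e) stop("pipeline stage 'decompose', subject ",
                                     s, ": ", conditionMessage(e)))
        }
      }
    }

    modeIndex <- if (config@modeSelection == "sum") 0L
    else if (config@modeSelection == "auto") {
      # Correlate against the grand-average ERP (all subjects, both
      # conditions): a common reference dilutes each subject's own noise
      # residue, which would otherwise bias selection toward the
      # high-frequency modes that share it.
      grand <- Reduce(`+`, lapply(seq_len(ns), function(s)
        erp[[s]][[condA]] + erp[[s]][[condB]])) / (2 * ns)
      stacked <- list(); ref <- NULL
      for (s in seq_len(ns)) for (cond in c(condA, condB)) {
        stacked <- c(stacked, erm[[s]][[cond]])
        ref <- rbind(ref, grand)
      }
      selectMode(stacked, ref)
    } else {
      i <- suppressWarnings(as.integer(config@modeSelection))
      if (is.na(i) || i < 1)
        stop("pipeline stage 'select': bad modeSelection '",
             config@modeSelection, "'")
      i
    }

    usePooling <- length(config@pooling) > 0
    lf <- leadfield
    if (usePooling) {
      pooledGain <- poolChannels(leadfield@gain,
                                 leadfield@montage@channelNames,
                                 config@pooling)
      centroids <- poolChannels(leadfield@montage@positions,
                                leadfield@montage@channelNames,
                                config@pooling)
      lf <- new("LeadField", gain = pooledGain,
                montage = Montage(names(config@pooling), centroids),
                grid = grid, orientation = leadfield@orientation,
                conductivity = leadfield@conductivity,
                radius = leadfield@radius)
      blocks <- resolutionCovariance(lf, alpha)
    }

    out <- list(modeIndex = modeIndex, alpha = alpha)
    for (wi in seq_along(config@windows)) {
      wname <- names(config@windows)[wi]
      win <- config@windows[[wi]]
      wres <- list()
      for (branch in c("erp", "erm")) {
        eA <- matrix(0, ns, nrow(grid@positions))
        eB <- matrix(0, ns, nrow(grid@positions))
        for (s in seq_len(ns)) {
          for (cond in c(condA, condB)) {
            tc <- if (branch == "erp") erp[[s]][[cond]]
                  else ermTimecourse(erm[[s]][[cond]], modeIndex)
            if (usePooling)
              tc <- poolChannels(tc, leadfield@montage@channelNames,
                                 config@pooling)
            phi <- if (config@mapAverage == "potential")
              windowMean(tc, times, win) * 1e-6        # microvolts -> volts
            else
              tc[, times >= win[1] & times < win[2], drop = FALSE] * 1e-6
            map <- sloreta(lf, phi, alpha, blocks,
                           label = paste(branch, wname))
            if (cond == condA) eA[s, ] <- map@energy else eB[s, ] <- map@energy
          }
        }
        tA <- eA; tB <- eB
        if (config@logTransform) {
          eps <- 1e-12 * max(tA, tB, 1e-300)
          tA <- log(tA + eps); tB <- log(tB + eps)
        }
        stat <- permutationNull(tA, tB, nPerm = config@nPerm,
                                seed = seeds[ns + wi], grid = grid)
        peaks <- lapply(c(0.05, 0.01, 0.001), function(lv)
          clusterPeaks(stat, lv))
        names(peaks) <- c("p05", "p01", "p001")
        base <- file.path(outputDir, paste0(branch, "_", wname))
        write.table(data.frame(node = seq_along(stat@t),
                               grid@positions, t = stat@t),
                    paste0(base, "_tmap.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        write.table(data.frame(node = seq_along(stat@p),
                               grid@positions, p = stat@p),
                    paste0(base, "_pmap.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        for (lv in names(peaks))
          writePeakTable(peaks[[lv]],
                         paste0(base, "_peaks_", lv, ".tsv"))
        wres[[branch]] <- list(stat = stat, energyA = eA, energyB = eB,
                               peaks = peaks)
      }
      out[[wname]] <- wres
    }

    cfgFile <- file.path(outputDir, "config.yaml")
    yaml::write_yaml(list(
      windows = lapply(config@windows, as.numeric),
      conditions = config@conditions,
      sift = list(max_modes = config@sift@maxModes,
                  max_sifts = config@sift@maxSifts,
                  stop_sd = config@sift@stopSD,
                  env_tol = config@sift@envTol,
                  ensemble_size = config@sift@ensembleSize,
                  noise_ratio = config@sift@noiseRatio,
                  seed = config@sift@seed),
      alpha = alpha, snr = config@snr,
      mode_selection = config@modeSelection,
      erm_source = config@ermSource,
      noise_scale = config@noiseScale,
      map_average = config@mapAverage,
      selected_mode = modeIndex,
      pooling = config@pooling, log_transform = config@logTransform,
      n_perm = config@nPerm, seed = config@seed), cfgFile)
    yaml::write_yaml(list(
      config_hash = unname(tools::md5sum(cfgFile)),
      master_seed = config@seed,
      subject_seeds = as.integer(seeds[seq_len(ns)]),
      window_seeds = as.integer(seeds[ns + seq_along(config@windows)]),
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("eemdSource"))),
      file.path(outputDir, "provenance.yaml"))
    out
  }, error = function(e) {
    cleanup()
    stop(conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
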