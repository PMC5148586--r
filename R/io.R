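# Delimited-matrix recording I/O, epoching, trial averaging and window means.

#' Write / read a recording as a delimited matrix with a YAML sidecar
#'
#' The data matrix (channels x time, microvolts) goes to a tab-delimited
#' file; sampling rate, channel names and markers go to
#' \code{<path>.meta.yaml}. Lossless (up to text formatting at 15
#' significant digits).
#'
#' @param recording an \code{\link{EEGRecording}}
#' @param path data file path
#' @export
writeRecordingMatrix <- function(recording, path) {
  write.table(format(recording@data, digits = 15, scientific = TRUE,
                     trim = TRUE),
              path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  yaml::write_yaml(list(rate = recording@rate,
                        channel_names = recording@channelNames,
                        markers = list(sample = as.integer(recording@markers$sample),
                                       condition = as.character(recording@markers$condition))),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeRecordingMatrix
#' @return \code{readRecordingMatrix}: an \code{\link{EEGRecording}}
#' @export
readRecordingMatrix <- function(path) {
  data <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  mk <- meta$markers
  markers <- if (length(mk$sample))
    data.frame(sample = as.integer(unlist(mk$sample)),
               condition = as.character(unlist(mk$condition)))
  else data.frame(sample = integer(0), condition = character(0))
  new("EEGRecording", data = data, rate = meta$rate,
      channelNames = as.character(meta$channel_names), markers = markers)
}

#' Cut a recording into stimulus-locked epochs
#'
#' For every marker with the requested condition label, extracts the
#' half-open window \code{[tmin, tmax)} seconds around the marker sample.
#' Markers whose window would cross a recording edge are dropped with a
#' message and counted in the \code{"dropped"} attribute. Baseline
#' correction subtracts each channel/trial's pre-stimulus mean.
#'
#' @param recording an \code{\link{EEGRecording}}
#' @param tmin,tmax epoch span in seconds relative to each marker
#' @param condition condition label to select
#' @param baseline subtract the pre-stimulus (t < 0) mean (default TRUE)
#' @return an \code{\link{EEGEpochs}}
#' @export
epoch <- function(recording, tmin, tmax, condition, baseline = TRUE) {
  stopifnot(tmax > tmin)
  rate <- recording@rate
  n <- round((tmax - tmin) * rate)
  times <- seq(tmin, by = 1 / rate, length.out = n)
  mk <- recording@markers[recording@markers$condition == condition, ,
                          drop = FALSE]
  if (nrow(mk) == 0) stop("no markers with condition '", condition, "'")
  start <- mk$sample + round(tmin * rate)
  ok <- start >= 1 & (start + n - 1) <= ncol(recording@data)
  if (any(!ok))
    message(sum(!ok), " trial(s) dropped: window crosses a recording edge")
  start <- start[ok]
  if (length(start) == 0) stop("no valid trials after edge-dropping")
  cube <- array(0, c(nrow(recording@data), n, length(start)))
  for (k in seq_along(start))
    cube[, , k] <- recording@data[, start[k]:(start[k] + n - 1)]
  if (baseline) {
    pre <- which(times < 0)
    if (length(pre))
      for (k in seq_along(start)) {
        bl <- rowMeans(cube[, pre, k, drop = FALSE])
        cube[, , k] <- cube[, , k] - bl
      }
  }
  out <- EEGEpochs(cube, rate, times, recording@channelNames)
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Trial-averaged event-related potential
#'
#' Arithmetic mean across trials per channel and time point: the ERP.
#'
#' @param epochs an \code{\link{EEGEpochs}}
#' @return numeric matrix channels x time (microvolts)
#' @export
averageErp <- function(epochs) {
  d <- dim(epochs@data)
  stopifnot(d[3] >= 1)
  out <- apply(epochs@data, c(1, 2), mean)
  rownames(out) <- epochs@channelNames
  out
}

#' Mean over a half-open time window
#'
#' Selects samples with \code{window[1] <= t < window[2]} (inclusive start,
#' exclusive end) and averages them: per row for a matrix time course, as a
#' scalar for a vector.
#'
#' @param timecourse numeric vector or rows x time matrix
#' @param times numeric time axis (seconds), length matching the time
#'   dimension
#' @param window numeric length-2 (start, end) in seconds
#' @return scalar or per-row numeric vector
#' @export
windowMean <- function(timecourse, times, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  idx <- which(times >= window[1] & times < window[2])
  if (length(idx) == 0) stop("empty window selection")
  if (is.matrix(timecourse)) rowMeans(timecourse[, idx, drop = FALSE])
  else mean(timecourse[idx])
}
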