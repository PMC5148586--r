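# Minimal EDF(+) support: enough of the European Data Format to round-trip
# this package's recordings (16-bit samples, one data-record group, and a
# light annotation channel for stimulus markers). Physical units are
# microvolts; quantization error is bounded by (physical range)/2^16.

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = -width)
}

# Annotation TAL byte stream for a set of markers (onsets in seconds).
# Each annotation list is NUL-terminated; NUL cannot live in an R string,
# so assembly happens at the raw-byte level.
talBytes <- function(onsets, labels) {
  parts <- "+0\x14\x14"  # record timestamp TAL
  for (i in seq_along(onsets))
    parts <- c(parts, sprintf("+%.6f\x14%s\x14", onsets[i], labels[i]))
  out <- raw(0)
  for (p in parts) out <- c(out, charToRaw(p), as.raw(0))
  if (length(out) %% 2 == 1) out <- c(out, as.raw(0))
  out
}

#' Write a recording as EDF
#'
#' Single data record holding the whole recording; samples quantized to 16
#' bits over a symmetric physical range (integer microvolt bounds). Markers,
#' if any, are stored in an "EDF Annotations" channel as time-stamped
#' annotation lists with the condition label as annotation text.
#'
#' @param recording an \code{\link{EEGRecording}} (microvolts)
#' @param path output file
#' @return the path, invisibly
#' @export
writeEDF <- function(recording, path) {
  x <- recording@data
  nch <- nrow(x); nt <- ncol(x)
  physMax <- max(1, ceiling(max(abs(x))))
  digMin <- -32768; digMax <- 32767
  dig <- round((x + physMax) / (2 * physMax) * (digMax - digMin) + digMin)
  dig[] <- pmin(pmax(dig, digMin), digMax)

  hasAnn <- nrow(recording@markers) > 0
  ann <- raw(0)
  if (hasAnn) {
    onsets <- (recording@markers$sample - 1) / recording@rate
    ann <- talBytes(onsets, as.character(recording@markers$condition))
  }
  ns <- nch + as.integer(hasAnn)
  annSamples <- length(ann) / 2

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(padField(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X", 80); wr("X", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr(if (hasAnn) "EDF+C" else "", 44)
  wr(1, 8)                                   # one data record
  wr(format(nt / recording@rate, digits = 6), 8)
  wr(ns, 8)
  labs <- c(recording@channelNames, if (hasAnn) "EDF Annotations")
  for (l in labs) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)          # transducer
  for (i in seq_len(ns)) wr(if (i <= nch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= nch) -physMax else -1, 8)
  for (i in seq_len(ns)) wr(if (i <= nch) physMax else 1, 8)
  for (i in seq_len(ns)) wr(digMin, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)          # prefiltering
  for (i in seq_len(ns)) wr(if (i <= nch) nt else annSamples, 8)
  for (i in seq_len(ns)) wr("", 32)          # reserved
  for (i in seq_len(nch))
    writeBin(as.integer(dig[i, ]), con, size = 2, endian = "little")
  if (hasAnn) writeBin(ann, con)
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the subset this package writes (and standard continuous EDF with
#' equal per-record layouts): 16-bit samples scaled to physical units,
#' multiple data records, and EDF+ annotation channels mapped to markers.
#'
#' @param path EDF file
#' @return an \code{\link{EEGRecording}} (microvolts)
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rdn <- function(width) as.numeric(rd(width))
  version <- rd(8)
  if (version != "0")
    stop("malformed EDF header at byte 0: version field is not '0'")
  rd(80); rd(80); rd(8); rd(8)
  headerBytes <- rdn(8)
  rd(44)
  nRec <- rdn(8)
  recDur <- rdn(8)
  ns <- rdn(8)
  if (!is.finite(ns) || ns < 1)
    stop("malformed EDF header at byte 252: bad signal count")
  if (headerBytes != 256 * (ns + 1))
    stop("malformed EDF header at byte 184: header size inconsistent ",
         "with signal count")
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), character(1))
  physMin <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  for (i in seq_len(ns)) rd(80)
  nSamp <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  for (i in seq_len(ns)) rd(32)

  isAnn <- labels == "EDF Annotations"
  sig <- vector("list", ns)
  for (i in seq_len(ns)) sig[[i]] <- vector("list", nRec)
  annRaw <- raw(0)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) {
        annRaw <- c(annRaw, readBin(con, "raw", n = 2 * nSamp[i]))
      } else {
        v <- readBin(con, "integer", n = nSamp[i], size = 2, signed = TRUE,
                     endian = "little")
        if (length(v) < nSamp[i])
          stop("truncated EDF data record ", r, " signal ", i)
        sig[[i]][[r]] <- v
      }
    }
  }
  keep <- which(!isAnn)
  data <- do.call(rbind, lapply(keep, function(i) {
    v <- unlist(sig[[i]])
    physMin[i] + (v - digMin[i]) * (physMax[i] - physMin[i]) /
      (digMax[i] - digMin[i])
  }))
  rate <- nSamp[keep[1]] / recDur
  markers <- data.frame(sample = integer(0), condition = character(0))
  if (length(annRaw)) {
    txt <- rawToChar(annRaw[annRaw != as.raw(0)])
    tals <- strsplit(txt, "\x14\\+", fixed = FALSE)[[1]]
    ev <- regmatches(txt, gregexpr("\\+[0-9.]+\x14[^\x14\x15+]+\x14", txt))[[1]]
    if (length(ev)) {
      onset <- as.numeric(sub("^\\+([0-9.]+)\x14.*", "\\1", ev))
      lab <- sub("^\\+[0-9.]+\x14([^\x14]+)\x14$", "\\1", ev)
      markers <- data.frame(sample = as.integer(round(onset * rate)) + 1L,
                            condition = lab)
    }
  }
  new("EEGRecording", data = data, rate = rate,
      channelNames = labels[keep], markers = markers)
}
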