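# sLORETA source estimation: regularized minimum-norm inverse, resolution
# covariance standardization, standardized dipole-energy maps, peak search.

#' Dipole moment estimate
#'
#' Minimum-norm dipole moments on a source grid. Rows come in (x, y, z)
#' blocks per node in free-orientation mode, one row per node in fixed mode.
#' Units follow the inputs: with potentials in volts and gain in
#' V/(ampere-meter), moments are in ampere-meters.
#'
#' @slot moments numeric matrix, (3 N_v or N_v) x T
#' @slot alpha regularization parameter used
#' @slot orientation "free" or "fixed"
#' @slot grid the \code{\link{SourceGrid}}
#' @export
setClass("DipoleEstimate",
  representation(moments = "matrix", alpha = "numeric",
                 orientation = "character", grid = "SourceGrid"))

setValidity("DipoleEstimate", function(object) {
  msg <- character()
  nv <- nrow(object@grid@positions)
  want <- if (identical(object@orientation, "fixed")) nv else 3L * nv
  if (nrow(object@moments) != want)
    msg <- c(msg, "moments rows inconsistent with grid/orientation")
  if (!all(is.finite(object@moments))) msg <- c(msg, "moments must be finite")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DipoleEstimate", function(object) {
  cat("DipoleEstimate:", nrow(object@moments), "rows x",
      ncol(object@moments), "time points |", object@orientation,
      "orientation | alpha", format(object@alpha, digits = 4), "\n")
})

#' Default regularization heuristic
#'
#' \eqn{\alpha = trace(G G^T) / (N_e \cdot SNR^2)} on the centered gain
#' matrix: the regularizer is sized relative to the average signal power the
#' lead field can produce, divided by an assumed squared signal-to-noise
#' ratio.
#'
#' @param leadfield a \code{\link{LeadField}}
#' @param snr assumed amplitude signal-to-noise ratio (default 3)
#' @return regularization parameter \code{alpha}
#' @export
alphaHeuristic <- function(leadfield, snr = 3) {
  G <- leadfield@gain
  Oc <- centeringOperator(nrow(G))
  Gc <- Oc %*% G
  sum(Gc * Gc) / (nrow(G) * snr^2)
}

#' Regularized minimum-norm inverse
#'
#' Computes the Tikhonov-regularized minimum-norm estimate
#' \deqn{D = G_c^T (G_c G_c^T + \alpha O_c)^\dagger O_c \Phi}
#' with \eqn{G_c = O_c G} the average-referenced gain matrix. For
#' \eqn{\alpha > 0} this minimizes
#' \eqn{\|O_c\Phi - G_c D\|^2 + \alpha\|D\|^2}; for \eqn{\alpha = 0} it is
#' the smallest-norm exact solution within the centered subspace.
#'
#' @param leadfield a \code{\link{LeadField}}
#' @param phi numeric matrix or vector of electrode potentials
#'   (N_e x T), channel order matching the lead field montage
#' @param alpha regularization parameter (>= 0); defaults to
#'   \code{\link{alphaHeuristic}}
#' @param rankTol relative singular-value truncation tolerance for the
#'   pseudoinverse (default 1e-10)
#' @return a \code{\link{DipoleEstimate}}
#' @export
mneInverse <- function(leadfield, phi, alpha = alphaHeuristic(leadfield),
                       rankTol = 1e-10) {
  if (alpha < 0) stop("alpha must be >= 0")
  phi <- as.matrix(phi)
  G <- leadfield@gain
  if (nrow(phi) != nrow(G))
    stop("phi rows must match the lead field's electrodes")
  Oc <- centeringOperator(nrow(G))
  Gc <- Oc %*% G
  M <- pinvTol(Gc %*% t(Gc) + alpha * Oc, tol = rankTol)
  D <- t(Gc) %*% (M %*% (Oc %*% phi))
  new("DipoleEstimate", moments = D, alpha = alpha,
      orientation = leadfield@orientation, grid = leadfield@grid)
}

#' Resolution covariance (diagonal blocks)
#'
#' The standardization matrix of sLORETA,
#' \eqn{\Sigma_D = G_c^T (G_c G_c^T + \alpha O_c)^\dagger G_c}, of which only
#' the per-node diagonal blocks are materialized: 3x3 blocks in free
#' orientation, scalars in fixed orientation. Each block is symmetric
#' positive semidefinite by construction.
#'
#' @inheritParams mneInverse
#' @return free orientation: a 3 x 3 x N_v array; fixed: a numeric vector of
#'   length N_v. Carries attributes \code{orientation} and \code{alpha}.
#' @export
resolutionCovariance <- function(leadfield, alpha = alphaHeuristic(leadfield),
                                 rankTol = 1e-10) {
  if (alpha < 0) stop("alpha must be >= 0")
  G <- leadfield@gain
  Oc <- centeringOperator(nrow(G))
  Gc <- Oc %*% G
  M <- pinvTol(Gc %*% t(Gc) + alpha * Oc, tol = rankTol)
  W <- M %*% Gc
  nv <- nrow(leadfield@grid@positions)
  if (leadfield@orientation == "fixed") {
    blocks <- colSums(Gc * W)
    blocks <- pmax(blocks, 0)
  } else {
    blocks <- array(0, c(3, 3, nv))
    for (i in seq_len(nv)) {
      idx <- (3 * i - 2):(3 * i)
      b <- crossprod(Gc[, idx, drop = FALSE], W[, idx, drop = FALSE])
      blocks[, , i] <- (b + t(b)) / 2
    }
  }
  attr(blocks, "orientation") <- leadfield@orientation
  attr(blocks, "alpha") <- alpha
  blocks
}

#' Standardized dipole-energy map
#'
#' Standardizes the minimum-norm moments by the per-node resolution
#' covariance blocks and returns the equivalent standardized current dipole
#' energy \eqn{E_{dip}(r_i) = d_i^T [\Sigma_D]_{ii}^\dagger d_i} at every
#' grid node (in fixed orientation this reduces to
#' \eqn{d_i^2 / [\Sigma_D]_{ii}}). With a multi-column estimate the
#' quadratic form is evaluated per time sample and averaged, which avoids
#' the phase cancellation a window-averaged potential suffers for
#' oscillatory signals. Nodes whose block is numerically zero while the
#' moment is not are flagged with a warning and mapped to zero energy.
#'
#' @param estimate a \code{\link{DipoleEstimate}}; one time column gives an
#'   instantaneous map, several give the window-averaged energy
#' @param blocks result of \code{\link{resolutionCovariance}} for the same
#'   lead field and alpha
#' @param rankTol shared relative pseudo-rank tolerance for the block
#'   pseudoinverses
#' @param label optional time/window label stored with the map
#' @return a \code{\link{SourceMap}}
#' @export
sloretaMap <- function(estimate, blocks, rankTol = 1e-10, label = "") {
  if (!identical(attr(blocks, "orientation"), estimate@orientation))
    stop("blocks and estimate have different orientation modes")
  nv <- nrow(estimate@grid@positions)
  d <- estimate@moments
  nt <- ncol(d)
  energy <- numeric(nv)
  flagged <- 0L
  if (estimate@orientation == "fixed") {
    for (i in seq_len(nv)) {
      s <- blocks[i]
      if (s <= 0) {
        if (any(abs(d[i, ]) > 0)) flagged <- flagged + 1L
        energy[i] <- 0
      } else energy[i] <- mean(d[i, ]^2) / s
    }
  } else {
    for (i in seq_len(nv)) {
      idx <- (3 * i - 2):(3 * i)
      di <- d[idx, , drop = FALSE]
      Bi <- blocks[, , i]
      smax <- max(abs(Bi))
      if (smax == 0) {
        if (any(abs(di) > 0)) flagged <- flagged + 1L
        energy[i] <- 0
      } else {
        q <- pinvTol(Bi, rankTol) %*% di
        energy[i] <- max(0, mean(colSums(di * q)))
      }
    }
  }
  if (flagged > 0)
    warning(flagged, " node(s) had zero resolution blocks with nonzero ",
            "moments; their energy was set to 0")
  new("SourceMap", energy = energy, grid = estimate@grid, label = label)
}

#' One-call sLORETA map from potentials
#'
#' Convenience wrapper chaining \code{\link{mneInverse}},
#' \code{\link{resolutionCovariance}} and \code{\link{sloretaMap}} for a
#' single potential vector (e.g. a window-averaged ERP topography).
#'
#' @inheritParams mneInverse
#' @param blocks optional precomputed resolution blocks (reuse across many
#'   inversions with the same lead field and alpha)
#' @param label map label
#' @return a \code{\link{SourceMap}}
#' @export
sloreta <- function(leadfield, phi, alpha = alphaHeuristic(leadfield),
                    blocks = NULL, rankTol = 1e-10, label = "") {
  est <- mneInverse(leadfield, phi, alpha, rankTol)
  if (is.null(blocks))
    blocks <- resolutionCovariance(leadfield, alpha, rankTol)
  sloretaMap(est, blocks, rankTol, label)
}

#' Locate the peak of a source map
#'
#' Index and coordinates of the maximum standardized energy; ties break
#' toward the lowest node index (deterministic).
#'
#' @param map a \code{\link{SourceMap}}
#' @return list with \code{index} (integer) and \code{position} (length-3
#'   numeric, meters)
#' @export
localizePeak <- function(map) {
  e <- map@energy
  if (length(e) == 0 || max(e) <= 0) stop("no source energy")
  i <- which.max(e)  # first maximum = lowest index on ties
  list(index = i, position = map@grid@positions[i, ])
}

#' Export a source map as a delimited table
#'
#' Columns \code{node_index, x, y, z, energy}, tab-separated.
#'
#' @param map a \code{\link{SourceMap}}
#' @param path output file
#' @export
writeSourceMap <- function(map, path) {
  df <- data.frame(node_index = seq_along(map@energy),
                   map@grid@positions, energy = map@energy)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
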