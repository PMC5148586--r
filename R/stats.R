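# Paired condition comparison of per-subject source maps: voxelwise paired t,
# sign-flip max-statistic randomization, and cluster-peak tabulation.

# Coerce a list of SourceMaps (or a subjects x nodes matrix) to a matrix,
# returning the shared grid (or NULL).
mapsToMatrix <- function(x) {
  if (is.matrix(x)) return(list(m = x, grid = NULL))
  stopifnot(is.list(x), length(x) >= 1)
  g <- x[[1]]@grid
  for (m in x)
    if (!isTRUE(all.equal(m@grid@positions, g@positions)))
      stop("subject maps must share one grid")
  list(m = do.call(rbind, lapply(x, function(m) m@energy)), grid = g)
}

# Minimal placeholder grid for statistics on plain matrices (one node per
# column along the x axis).
indexGrid <- function(n) {
  pos <- cbind(x = seq_len(n), y = 0, z = 0)
  new("SourceGrid", positions = pos, spacing = 1, radius = n + 1,
      regions = rep("node", n))
}

# Vectorized paired t for a subjects x nodes difference matrix under a set of
# sign patterns (rows of `signs`, entries +-1). Returns patterns x nodes.
tUnderSigns <- function(d, signs) {
  s <- nrow(d)
  sumsq <- colSums(d^2)
  m <- (signs %*% d) / s
  v <- sweep(-s * m^2, 2, sumsq, "+") / (s - 1)
  v[v < 0] <- 0
  tt <- m / sqrt(v / s)
  tt[!is.finite(tt)] <- 0
  tt
}

#' Voxelwise paired t statistics
#'
#' Per node, \eqn{t = \bar d / (s_d/\sqrt{S})} with \eqn{d_s = A_s - B_s}
#' the per-subject condition difference and \eqn{s_d} the sample standard
#' deviation (S-1 denominator). Positive t means condition A (CT) larger
#' than condition B (NCT). Zero-variance nodes get t = 0 and are flagged in
#' the \code{"zeroVariance"} attribute.
#'
#' @param condA,condB per-subject maps for the two conditions: either
#'   subjects x nodes matrices or lists of \code{\link{SourceMap}} objects
#'   on a shared grid
#' @return numeric t value per node
#' @examples
#' a <- matrix(c(2, 3, 4), 3, 1); b <- matrix(c(1, 1, 1), 3, 1)
#' pairedT(a, b)  # 2 / (1/sqrt(3)) = 3.4641
#' @export
pairedT <- function(condA, condB) {
  A <- mapsToMatrix(condA); B <- mapsToMatrix(condB)
  if (!is.null(A$grid) && !is.null(B$grid) &&
      !isTRUE(all.equal(A$grid@positions, B$grid@positions)))
    stop("condition maps must share one grid")
  if (!all(dim(A$m) == dim(B$m))) stop("condition dimensions differ")
  if (nrow(A$m) < 2) stop("need at least 2 subjects")
  d <- A$m - B$m
  tt <- as.numeric(tUnderSigns(d, matrix(1, 1, nrow(d))))
  attr(tt, "zeroVariance") <- which(apply(d, 2, function(x) sd(x) == 0))
  tt
}

#' Sign-flip max-statistic randomization test
#'
#' Builds the null distribution of the maximum |t| across nodes by randomly
#' flipping the sign of each subject's condition difference (exchangeable
#' under the null of no condition effect) and returns family-wise corrected
#' p values \eqn{p_i = (1 + \#\{max_{perm} \ge |t_i|\})/(1 + n_{perm})},
#' plus |t| thresholds at the 0.05, 0.01 and 0.001 levels. When the
#' requested number of permutations reaches \eqn{2^S} the test switches to
#' exhaustive enumeration of all sign patterns (p values then k/2^S).
#'
#' @inheritParams pairedT
#' @param nPerm number of random sign flips (>= 100)
#' @param seed RNG seed for the sampled mode
#' @param grid optional \code{\link{SourceGrid}} when matrices are supplied
#' @param method "auto" enumerates all sign patterns when \code{nPerm}
#'   reaches \eqn{2^S}, otherwise samples; "exhaustive" and "sampled" force
#'   the respective mode
#' @return a \code{\link{StatResult}}
#' @export
permutationNull <- function(condA, condB, nPerm = 2000, seed = 1,
                            grid = NULL, method = c("auto", "exhaustive",
                                                    "sampled")) {
  method <- match.arg(method)
  A <- mapsToMatrix(condA); B <- mapsToMatrix(condB)
  if (is.null(grid)) grid <- A$grid
  if (!all(dim(A$m) == dim(B$m))) stop("condition dimensions differ")
  d <- A$m - B$m
  s <- nrow(d)
  if (s < 2) stop("need at least 2 subjects")
  if (nPerm < 100) stop("nPerm must be >= 100")
  if (is.null(grid)) grid <- indexGrid(ncol(d))
  tObs <- as.numeric(tUnderSigns(d, matrix(1, 1, s)))

  exhaustive <- if (method == "auto") (s <= 30) && (2^s <= nPerm)
                else method == "exhaustive"
  if (exhaustive && s > 30) stop("exhaustive enumeration needs S <= 30")
  if (exhaustive) {
    message("nPerm >= 2^S: enumerating all ", 2^s, " sign patterns")
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), s)))
    dimnames(signs) <- NULL
  } else {
    signs <- withSeed(seed, function()
      matrix(sample(c(1, -1), nPerm * s, replace = TRUE), nPerm, s))
  }
  nullMax <- apply(abs(tUnderSigns(d, signs)), 1, max)
  if (exhaustive) {
    p <- vapply(abs(tObs), function(t0)
      sum(nullMax >= t0 - 1e-12) / length(nullMax), numeric(1))
    nP <- as.integer(2^s)
    method <- "exhaustive"
  } else {
    p <- vapply(abs(tObs), function(t0)
      (1 + sum(nullMax >= t0 - 1e-12)) / (1 + nPerm), numeric(1))
    nP <- as.integer(nPerm)
    method <- "sampled"
  }
  thr <- stats::quantile(nullMax, c(0.95, 0.99, 0.999), names = FALSE,
                         type = 1)
  names(thr) <- c("0.05", "0.01", "0.001")
  new("StatResult", t = tObs, p = pmin(p, 1), thresholds = thr,
      nPerm = nP, method = method, grid = grid)
}

#' Cluster supra-threshold nodes and tabulate peaks
#'
#' Nodes with corrected p at or below \code{level} are grouped by lattice
#' adjacency (26-neighbourhood: centers within \eqn{\sqrt{3}} spacings) and
#' one row per cluster reports the peak voxel coordinates, the signed peak
#' t, the cluster's node count and its majority region label, sorted by
#' |peak t| descending. An empty table (0 rows) is a valid result.
#'
#' @param result a \code{\link{StatResult}}
#' @param level significance level, one of 0.05, 0.01, 0.001
#' @return data.frame with columns X, Y, Z, T-value, Voxels-No, Region
#' @export
clusterPeaks <- function(result, level = 0.05) {
  if (!level %in% c(0.05, 0.01, 0.001))
    stop("level must be one of 0.05, 0.01, 0.001")
  grid <- result@grid
  supra <- which(result@p <= level)
  empty <- data.frame(X = numeric(0), Y = numeric(0), Z = numeric(0),
                      `T-value` = numeric(0), `Voxels-No` = integer(0),
                      Region = character(0), check.names = FALSE)
  if (length(supra) == 0) return(empty)
  pos <- grid@positions[supra, , drop = FALSE]
  lim <- sqrt(3) * grid@spacing * (1 + 1e-6)
  dmat <- as.matrix(stats::dist(pos))
  adj <- dmat <= lim & dmat > 0
  gph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gph)$membership
  rows <- lapply(seq_len(max(comp)), function(k) {
    nodes <- supra[comp == k]
    tvals <- result@t[nodes]
    peak <- nodes[which.max(abs(tvals))]
    regs <- grid@regions[nodes]
    maj <- names(sort(table(regs), decreasing = TRUE))[1]
    data.frame(X = grid@positions[peak, 1], Y = grid@positions[peak, 2],
               Z = grid@positions[peak, 3], `T-value` = result@t[peak],
               `Voxels-No` = length(nodes), Region = maj,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out[["T-value"]])), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a peak table as delimited text
#'
#' @param table data.frame from \code{\link{clusterPeaks}}
#' @param path output file
#' @export
writePeakTable <- function(table, path) {
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
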