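# Spherical-head forward model: source grid, electrode handling, closed-form
# dipole lead field and the average-reference centering operator.
#
# The head is a single homogeneous conducting sphere with an insulating
# boundary. The surface potential of a current dipole p at r0 observed at r
# (|r| = R) has the closed form
#
#   phi(r) = 1/(4 pi sigma) * p . [ 2 d/|d|^3
#            + (r/R + d/|d|) / (R^2 - r.r0 + R |d|) ],   d = r - r0,
#
# obtained by summing the Legendre expansion of the no-flux boundary-value
# problem with the generating-function identities
# sum t^n P_n = 1/g and sum t^n P_n / n = log(2/(1 - t u + g)).

#' Average-reference centering operator
#'
#' Returns \eqn{O_c = I - 1 1^T / N_e}, the projector that re-references
#' potentials to their channel average. It is symmetric, idempotent, and
#' annihilates constant channel offsets (\eqn{O_c 1 = 0}), which is what
#' makes the inverse solution independent of the recording reference.
#'
#' @param nElectrodes number of electrodes (>= 2)
#' @return \code{nElectrodes x nElectrodes} matrix
#' @examples
#' centeringOperator(2)
#' @export
centeringOperator <- function(nElectrodes) {
  stopifnot(nElectrodes >= 2)
  diag(nElectrodes) - matrix(1 / nElectrodes, nElectrodes, nElectrodes)
}

# Octant plus depth label for a grid node; stands in for anatomical lobes.
regionLabel <- function(pos, radius) {
  lr <- ifelse(pos[, 1] >= 0, "R", "L")
  ap <- ifelse(pos[, 2] >= 0, "ant", "post")
  si <- ifelse(pos[, 3] >= 0, "sup", "inf")
  depth <- ifelse(sqrt(rowSums(pos^2)) < 0.5 * radius, "deep", "shallow")
  paste(lr, ap, si, depth, sep = "-")
}

#' Build a spherical source grid
#'
#' Regular Cartesian lattice with the given spacing, clipped to the ball of
#' radius \code{fraction * scalpRadius}. Node order is deterministic
#' (lexicographic in x, y, z). Each node carries a coarse octant/depth
#' region label.
#'
#' @param scalpRadius scalp sphere radius in meters (default 0.09)
#' @param fraction source-shell radius as a fraction of the scalp radius,
#'   in (0, 1) (default 0.87)
#' @param spacing lattice spacing in meters
#' @param includeOrigin keep the node at the origin (default TRUE); the
#'   origin has no radial direction and must be excluded for
#'   fixed-orientation lead fields
#' @return a \code{\link{SourceGrid}}
#' @examples
#' g <- buildSphereGrid(spacing = 0.02)
#' nrow(gridPositions(g))
#' @export
buildSphereGrid <- function(scalpRadius = 0.09, fraction = 0.87,
                            spacing = 0.01, includeOrigin = TRUE) {
  stopifnot(fraction > 0, fraction < 1, spacing > 0)
  r <- fraction * scalpRadius
  k <- floor(r / spacing)
  ax <- seq(-k, k) * spacing
  nodes <- as.matrix(expand.grid(z = ax, y = ax, x = ax))[, 3:1, drop = FALSE]
  colnames(nodes) <- c("x", "y", "z")
  keep <- sqrt(rowSums(nodes^2)) <= r + 1e-12
  if (!includeOrigin) keep <- keep & rowSums(abs(nodes)) > 1e-12
  nodes <- nodes[keep, , drop = FALSE]
  # expand.grid varies its first factor fastest; reorder to lexicographic x,y,z
  ord <- order(nodes[, 1], nodes[, 2], nodes[, 3])
  nodes <- nodes[ord, , drop = FALSE]
  if (nrow(nodes) == 0) stop("empty grid: spacing larger than the source ball")
  new("SourceGrid", positions = nodes, spacing = spacing, radius = r,
      regions = regionLabel(nodes, r))
}

#' Project electrode positions onto the model sphere
#'
#' Rescales each electrode position to \code{scalpRadius} while preserving
#' its direction from the head center, so that digitized or template
#' montages can be used with the spherical head model.
#'
#' @param montage a \code{\link{Montage}}
#' @param scalpRadius target sphere radius (meters)
#' @return a \code{\link{Montage}} with all positions at the given radius
#' @export
projectElectrodes <- function(montage, scalpRadius = 0.09) {
  pos <- montage@positions
  nrm <- sqrt(rowSums(pos^2))
  bad <- which(nrm < 1e-12)
  if (length(bad))
    stop("electrode(s) at the head center cannot be projected: ",
         paste(montage@channelNames[bad], collapse = ", "))
  Montage(montage@channelNames, pos * (scalpRadius / nrm))
}

#' Quasi-uniform spherical EEG montage
#'
#' Generates \code{n} electrode positions on the upper portion of the scalp
#' sphere (a Fibonacci spiral over \code{z/R} in \code{[minZ, 1]}),
#' approximating the coverage of an extended 10-10 cap without committing to
#' specific anatomical labels.
#'
#' @param n number of electrodes (default 62, a 10-10 cap's recording count)
#' @param scalpRadius sphere radius (meters)
#' @param minZ lowest electrode height as a fraction of the radius
#' @return a \code{\link{Montage}} on the sphere surface
#' @export
makeSphericalMontage <- function(n = 62, scalpRadius = 0.09, minZ = -0.25) {
  stopifnot(n >= 4, minZ > -1, minZ < 1)
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  z <- minZ + (k - 0.5) / n * (0.999 - minZ)
  phi <- k * golden
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- scalpRadius * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  Montage(sprintf("E%02d", k), pos)
}

# Closed-form surface potential per unit dipole moment: returns the
# electrodes x 3 matrix of potentials for unit moments along x, y, z of a
# dipole at `node`, for electrodes `elec` (rows) on a sphere of radius R.
dipoleGainBlock <- function(elec, node, R, sigma) {
  d <- sweep(elec, 2, node)                  # r - r0
  dd <- sqrt(rowSums(d^2))
  rdot <- as.numeric(elec %*% node)          # r . r0
  denom <- R^2 - rdot + R * dd
  term1 <- 2 * d / dd^3
  term2 <- (elec / R + d / dd) / denom
  (term1 + term2) / (4 * pi * sigma)
}

#' Single-sphere lead field
#'
#' Computes the gain matrix G mapping dipole moments at the grid nodes to
#' average-referenced electrode potentials, using the closed-form potential
#' of a current dipole inside a homogeneous conducting sphere with an
#' insulating boundary. Potentials superpose linearly over sources, so the
#' forward model is \eqn{\Phi = G D} (up to sensor noise). In
#' fixed-orientation mode each node contributes a single column for a dipole
#' along the radial direction \eqn{r_i/|r_i|}.
#'
#' @param montage a \code{\link{Montage}}; all electrodes must lie on the
#'   sphere of radius \code{scalpRadius} (see \code{\link{projectElectrodes}})
#' @param grid a \code{\link{SourceGrid}} strictly inside the sphere
#' @param conductivity volume conductivity in S/m (default 0.33)
#' @param orientation "free" (3 columns/node) or "fixed" (1 column/node,
#'   radial); the origin node, having no radial direction, is rejected in
#'   fixed mode
#' @param scalpRadius sphere radius in meters (default 0.09)
#' @return a \code{\link{LeadField}} (gain in volts per ampere-meter)
#' @examples
#' mon <- makeSphericalMontage(16)
#' g <- buildSphereGrid(fraction = 0.7, spacing = 0.03)
#' lf <- leadfieldSingleSphere(mon, g)
#' dim(gainMatrix(lf))
#' @export
leadfieldSingleSphere <- function(montage, grid, conductivity = 0.33,
                                  orientation = c("free", "fixed"),
                                  scalpRadius = 0.09) {
  orientation <- match.arg(orientation)
  elec <- montage@positions
  enorm <- sqrt(rowSums(elec^2))
  if (any(abs(enorm - scalpRadius) > 1e-6 * scalpRadius))
    stop("electrodes must lie on the sphere surface; use projectElectrodes()")
  nodes <- grid@positions
  surfDist <- scalpRadius - sqrt(rowSums(nodes^2))
  tooClose <- which(surfDist < grid@spacing / 2)
  if (length(tooClose))
    stop("grid node(s) too close to the sphere surface: ",
         paste(head(tooClose, 5), collapse = ", "))
  nv <- nrow(nodes); ne <- nrow(elec)
  if (orientation == "fixed") {
    rn <- sqrt(rowSums(nodes^2))
    if (any(rn < 1e-12))
      stop("origin node has no radial direction; rebuild the grid with ",
           "includeOrigin = FALSE for fixed orientation")
    gain <- matrix(0, ne, nv)
    for (i in seq_len(nv)) {
      blk <- dipoleGainBlock(elec, nodes[i, ], scalpRadius, conductivity)
      gain[, i] <- blk %*% (nodes[i, ] / rn[i])
    }
  } else {
    gain <- matrix(0, ne, 3 * nv)
    for (i in seq_len(nv))
      gain[, (3 * i - 2):(3 * i)] <-
        dipoleGainBlock(elec, nodes[i, ], scalpRadius, conductivity)
  }
  rownames(gain) <- montage@channelNames
  new("LeadField", gain = gain, montage = montage, grid = grid,
      orientation = orientation, conductivity = conductivity,
      radius = scalpRadius)
}

#' Read / write montage files
#'
#' Delimited text with a header row. Cartesian files have columns
#' \code{name,x,y,z}; spherical files have columns \code{name,theta,phi}
#' (degrees; theta measured from +z, phi from +x toward +y) plus an optional
#' \code{radius}. A comment line \code{# units: m|mm|cm} declares length
#' units (default meters).
#'
#' @param path file path
#' @return \code{readMontage}: a \code{\link{Montage}} (positions in meters)
#' @export
readMontage <- function(path) {
  lines <- readLines(path)
  unitLine <- grep("^#\\s*units:", lines, value = TRUE)
  fac <- 1
  if (length(unitLine)) {
    unit <- trimws(sub("^#\\s*units:", "", unitLine[1]))
    fac <- switch(unit, m = 1, cm = 0.01, mm = 0.001,
                  stop("unknown montage units: ", unit))
  }
  df <- read.table(text = lines[!startsWith(trimws(lines), "#")],
                   header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (all(c("x", "y", "z") %in% names(df))) {
    pos <- as.matrix(df[, c("x", "y", "z")]) * fac
  } else if (all(c("theta", "phi") %in% names(df))) {
    r <- if ("radius" %in% names(df)) df$radius * fac else 0.09
    th <- df$theta * pi / 180; ph <- df$phi * pi / 180
    pos <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
  } else stop("montage file needs columns name,x,y,z or name,theta,phi")
  Montage(df$name, pos)
}

#' @rdname readMontage
#' @param montage a \code{\link{Montage}} to write (meters)
#' @export
writeMontage <- function(montage, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: m", con)
  df <- data.frame(name = montage@channelNames, montage@positions)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Doubles serialized as %.17g strings survive a text round trip exactly.
num17 <- function(x) sprintf("%.17g", x)
mat17 <- function(m) apply(m, 1, function(r) as.list(num17(r)))

#' Export / import a lead field
#'
#' The gain matrix is written as a tab-delimited table and all geometry and
#' physics metadata (orientation mode, radii, conductivity, node and
#' electrode coordinates) as a YAML sidecar \code{<path>.meta.yaml}. All
#' numbers are serialized with 17 significant digits, so that inverse runs
#' on the re-imported pair are reproducible bit-for-bit.
#'
#' @param leadfield a \code{\link{LeadField}}
#' @param path path for the gain matrix table
#' @return \code{readLeadField}: the reconstructed \code{\link{LeadField}}
#' @export
writeLeadField <- function(leadfield, path) {
  gtxt <- apply(leadfield@gain, 2, num17)
  write.table(gtxt, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  meta <- list(
    orientation = leadfield@orientation,
    conductivity = num17(leadfield@conductivity),
    scalp_radius = num17(leadfield@radius),
    grid_spacing = num17(leadfield@grid@spacing),
    grid_radius = num17(leadfield@grid@radius),
    grid_regions = leadfield@grid@regions,
    grid_nodes = mat17(leadfield@grid@positions),
    channel_names = leadfield@montage@channelNames,
    electrode_positions = mat17(leadfield@montage@positions))
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname writeLeadField
#' @export
readLeadField <- function(path) {
  gain <- as.matrix(read.table(path, sep = "\t", header = FALSE,
                               colClasses = "character"))
  gain <- matrix(as.numeric(gain), nrow(gain), ncol(gain))
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  num <- function(x) as.numeric(unlist(x))
  nodes <- do.call(rbind, lapply(meta$grid_nodes, num))
  colnames(nodes) <- c("x", "y", "z")
  epos <- do.call(rbind, lapply(meta$electrode_positions, num))
  grid <- new("SourceGrid", positions = nodes, spacing = num(meta$grid_spacing),
              radius = num(meta$grid_radius),
              regions = as.character(meta$grid_regions))
  mon <- Montage(meta$channel_names, epos)
  rownames(gain) <- mon@channelNames
  new("LeadField", gain = gain, montage = mon, grid = grid,
      orientation = meta$orientation, conductivity = num(meta$conductivity),
      radius = num(meta$scalp_radius))
}
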