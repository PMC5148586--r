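# Shared fixtures and independent oracles. Heavy objects are memoised per
# test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

fixtureLeadField <- function(ne = 32, spacing = 0.018, fraction = 0.87,
                             orientation = "free") {
  key <- paste("lf", ne, spacing, fraction, orientation, sep = "_")
  memo(key, function() {
    mon <- makeSphericalMontage(ne)
    grid <- buildSphereGrid(fraction = fraction, spacing = spacing,
                            includeOrigin = orientation == "free")
    leadfieldSingleSphere(mon, grid, orientation = orientation)
  })
}

# Brute-force extrema scan (independent of the package's plateau handling;
# valid for signals without ties).
scanExtrema <- function(x) {
  n <- length(x)
  mx <- integer(0); mn <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx <- c(mx, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn <- c(mn, i)
  }
  list(maxima = mx, minima = mn)
}

# Truncated Legendre-series surface potential of a dipole in a homogeneous
# conducting sphere with insulating boundary: independent evaluation path
# (series + numerical gradient of the monopole kernel).
seriesPotential <- function(elec, node, p, R = 0.09, sigma = 0.33,
                            nmax = 400) {
  pot <- function(r0) {
    b <- sqrt(sum(r0^2)); if (b < 1e-15) b <- 1e-15
    u <- sum(elec * r0) / (sqrt(sum(elec^2)) * b)
    t <- b / R
    legs <- numeric(nmax)
    pm1 <- 1; p0 <- u
    for (k in 1:nmax) {
      legs[k] <- p0
      p1 <- ((2 * k + 1) * u * p0 - k * pm1) / (k + 1)
      pm1 <- p0; p0 <- p1
    }
    nn <- 1:nmax
    sum((2 * nn + 1) / nn * t^nn * legs) / (4 * pi * sigma * R)
  }
  h <- 1e-6
  g <- numeric(3)
  for (a in 1:3) {
    e <- c(0, 0, 0); e[a] <- h
    g[a] <- (pot(node + e) - pot(node - e)) / (2 * h)
  }
  sum(g * p)
}

# Dense pseudoinverse with the same rank rule, written independently (base R
# svd); used by the inverse-oracle checks.
densePinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
}

# Flood-fill clustering oracle: BFS over the 26-neighbourhood.
bfsClusters <- function(pos, spacing) {
  n <- nrow(pos)
  lab <- integer(n)
  lim <- sqrt(3) * spacing * (1 + 1e-6)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      d <- sqrt(colSums((t(pos) - pos[v, ])^2))
      nb <- which(d <= lim & lab == 0L)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

# Study-condition fixtures for the end-to-end experiments: 62-channel cap,
# 57-node grid, one occipital radial source with a Gaussian-windowed 8 Hz
# component boosted by 50% under CT.
recoveryWorld <- function() {
  memo("recoveryWorld", function() {
    mon <- makeSphericalMontage(62)
    grid <- buildSphereGrid(fraction = 0.8, spacing = 0.03)
    lf <- leadfieldSingleSphere(mon, grid)
    node <- defaultSources(grid)[[1]]$node
    src <- list(list(node = node, orientation = "radial", components = list(
      list(latency = 0.10, width = 0.06, frequency = 8,
           ampCT = 30, ampNCT = 20))))
    cfg0 <- SimConfig(src, nSubjects = 1, nTrials = 1, rate = 200,
                      epoch = c(-0.1, 0.4), noiseSD = 0, pinkWeight = 0,
                      subjectJitter = 0, seed = 1)
    clean <- simulateSubject(cfg0, lf, 1)$truth$cleanERP$CT
    cleanRMS <- max(apply(clean, 1, function(x) sqrt(mean(x^2))))
    list(lf = lf, grid = grid, src = src, node = node,
         truePos = gridPositions(grid)[node, ], cleanRMS = cleanRMS)
  })
}

recoveryAnalysisConfig <- function(seed) {
  AnalysisConfig(windows = list(P100 = c(0.06, 0.12)),
                 sift = SiftConfig(ensembleSize = 60, noiseRatio = 2,
                                   maxModes = 10),
                 ermSource = "erp", noiseScale = "common",
                 mapAverage = "energy", nPerm = 1000, seed = seed)
}

recoverySimConfig <- function(world, seed, snr = 1, nTrials = 60) {
  SimConfig(world$src, nSubjects = 12, nTrials = nTrials, rate = 200,
            epoch = c(-0.1, 0.4), noiseSD = world$cleanRMS / snr,
            pinkWeight = 0.5, subjectJitter = 0.1, seed = seed)
}

peakDistance <- function(stat, world) {
  tt <- tValues(stat)
  pk <- which.max(abs(tt))
  sqrt(sum((gridPositions(world$grid)[pk, ] - world$truePos)^2))
}
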