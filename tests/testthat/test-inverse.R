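# Minimum-norm inverse, standardization, energy maps, peak search.

# Hand-built lead field around an arbitrary gain matrix (for algebraic toys).
toyLeadField <- function(gain, orientation = "free") {
  ne <- nrow(gain)
  nv <- if (orientation == "fixed") ncol(gain) else ncol(gain) / 3
  mon <- makeSphericalMontage(ne)
  pos <- cbind(x = seq_len(nv) * 0.005, y = 0, z = 0)
  grid <- new("SourceGrid", positions = pos, spacing = 0.005,
              radius = max(pos[, 1]) + 0.005, regions = rep("toy", nv))
  new("LeadField", gain = gain, montage = mon, grid = grid,
      orientation = orientation, conductivity = 0.33, radius = 0.09)
}

test_that("mneInverse handles zero data and projector gains", {
  set.seed(1)
  lf <- toyLeadField(matrix(rnorm(6 * 9), 6, 9))
  est <- mneInverse(lf, matrix(0, 6, 3), alpha = 0.1)
  expect_equal(est@moments, matrix(0, 9, 3))
  expect_error(mneInverse(lf, matrix(0, 6, 1), alpha = -1), "alpha")

  # gain = centering projector (N_e = N_v, fixed orientation), alpha = 0:
  # the pseudoinverse of a projector is itself, so D reproduces the centered
  # pattern
  oc <- centeringOperator(6)
  lfp <- toyLeadField(oc, orientation = "fixed")
  phi <- oc %*% c(1, 0, 0, 0, 0, 0)
  est <- mneInverse(lfp, phi, alpha = 0)
  expect_equal(est@moments[, 1], as.numeric(phi), tolerance = 1e-10)
})

test_that("mneInverse agrees with a ridge-regression oracle", {
  set.seed(7)
  G <- matrix(rnorm(6 * 9), 6, 9)
  phi <- matrix(rnorm(6 * 4), 6, 4)
  lf <- toyLeadField(G)
  alpha <- 0.1
  est <- mneInverse(lf, phi, alpha = alpha)
  oc <- centeringOperator(6)
  Gc <- oc %*% G
  oracle <- solve(crossprod(Gc) + alpha * diag(9), crossprod(Gc, oc %*% phi))
  expect_lt(max(abs(est@moments - oracle)), 1e-8)

  # gradient of the penalized least-squares objective vanishes
  grad <- -2 * crossprod(Gc, oc %*% phi - Gc %*% est@moments) +
    2 * alpha * est@moments
  expect_lt(max(abs(grad)), 1e-10)
})

test_that("regularization shrinks the estimate monotonically", {
  set.seed(8)
  lf <- toyLeadField(matrix(rnorm(8 * 12), 8, 12))
  phi <- rnorm(8)
  a0 <- alphaHeuristic(lf)
  norms <- vapply(c(0, a0, 10 * a0, 100 * a0), function(a)
    sqrt(sum(mneInverse(lf, phi, alpha = a)@moments^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("resolution covariance blocks are symmetric PSD and match a scalar oracle", {
  set.seed(9)
  lf <- toyLeadField(matrix(rnorm(8 * 12), 8, 12))
  blocks <- resolutionCovariance(lf, alpha = 0.05)
  for (i in seq_len(dim(blocks)[3])) {
    B <- blocks[, , i]
    expect_lt(max(abs(B - t(B))), 1e-12)
    expect_gt(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values),
              -1e-12)
  }

  # 1-node fixed-orientation toy: scalar via an explicit eigen-decomposition
  g <- matrix(rnorm(6), 6, 1)
  lf1 <- toyLeadField(g, orientation = "fixed")
  alpha <- 0.2
  oc <- centeringOperator(6)
  gc <- oc %*% g
  A <- gc %*% t(gc) + alpha * oc
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  Ainv <- e$vectors[, keep] %*% diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep])
  oracle <- as.numeric(t(gc) %*% Ainv %*% gc)
  got <- resolutionCovariance(lf1, alpha = alpha)
  expect_equal(as.numeric(got), oracle, tolerance = 1e-10)
})

test_that("sloretaMap standardizes moments into nonnegative energies", {
  grid <- new("SourceGrid", positions = cbind(x = 1:3 * 0.01, y = 0, z = 0),
              spacing = 0.01, radius = 0.05, regions = rep("toy", 3))
  est0 <- new("DipoleEstimate", moments = matrix(0, 3, 1), alpha = 0,
              orientation = "fixed", grid = grid)
  ones <- rep(1, 3)
  attr(ones, "orientation") <- "fixed"
  attr(ones, "alpha") <- 0
  expect_equal(energyValues(sloretaMap(est0, ones)), rep(0, 3))

  est <- new("DipoleEstimate", moments = matrix(c(-2, 0.5, 3), 3, 1),
             alpha = 0, orientation = "fixed", grid = grid)
  expect_equal(energyValues(sloretaMap(est, ones)), c(4, 0.25, 9))

  # zero block with a nonzero moment: flagged, energy zero
  degenerate <- c(0, 1, 1)
  attr(degenerate, "orientation") <- "fixed"
  attr(degenerate, "alpha") <- 0
  expect_warning(m <- sloretaMap(est, degenerate), "zero resolution")
  expect_equal(energyValues(m)[1], 0)
})

test_that("localizePeak is deterministic and matches a linear scan", {
  grid <- buildSphereGrid(fraction = 0.6, spacing = 0.03)
  nv <- nrow(gridPositions(grid))
  e <- numeric(nv); e[4] <- 2
  m <- new("SourceMap", energy = e, grid = grid, label = "")
  expect_equal(localizePeak(m)$index, 4L)

  e2 <- numeric(nv); e2[3] <- 5; e2[7] <- 5
  expect_equal(localizePeak(new("SourceMap", energy = e2, grid = grid,
                                label = ""))$index, 3L)

  expect_error(localizePeak(new("SourceMap", energy = numeric(nv),
                                grid = grid, label = "")), "no source energy")

  set.seed(10)
  for (k in 1:200) {
    e3 <- abs(rnorm(nv))
    got <- localizePeak(new("SourceMap", energy = e3, grid = grid,
                            label = ""))$index
    best <- 1L
    for (i in seq_len(nv)) if (e3[i] > e3[best]) best <- i  # linear scan
    expect_identical(got, as.integer(best))
  }
})

test_that("the full chain matches an independent dense-pseudoinverse oracle", {
  set.seed(12)
  ne <- 12; nv <- 6
  G <- matrix(rnorm(ne * 3 * nv), ne, 3 * nv)
  lf <- toyLeadField(G)
  phi <- matrix(rnorm(ne), ne, 1)
  alpha <- 0.3
  pkg <- sloreta(lf, phi, alpha = alpha)

  # independent route: dense pinv, full covariance materialized
  oc <- diag(ne) - matrix(1 / ne, ne, ne)
  Gc <- oc %*% G
  M <- densePinv(Gc %*% t(Gc) + alpha * oc)
  D <- t(Gc) %*% M %*% (oc %*% phi)
  S <- t(Gc) %*% M %*% Gc
  eOracle <- vapply(seq_len(nv), function(i) {
    idx <- (3 * i - 2):(3 * i)
    as.numeric(t(D[idx, ]) %*% densePinv(S[idx, idx]) %*% D[idx, ])
  }, numeric(1))
  expect_lt(max(abs(energyValues(pkg) - eOracle)), 1e-8)
})

test_that("noiseless point sources are localized exactly", {
  lf <- fixtureLeadField(32, 0.018, 0.87)
  blocks <- resolutionCovariance(lf, alpha = 0)
  set.seed(14)
  nodes <- sample(nrow(gridPositions(sourceGrid(lf))), 20)
  for (i in nodes) {
    p <- rnorm(3); p <- p / sqrt(sum(p^2)) * 1e-8
    phi <- gainMatrix(lf)[, (3 * i - 2):(3 * i)] %*% p
    map <- sloretaMap(mneInverse(lf, phi, alpha = 0), blocks)
    expect_identical(localizePeak(map)$index, i)
  }
})

test_that("energies ignore the reference and scale quadratically", {
  lf <- fixtureLeadField(32, 0.018, 0.87)
  set.seed(15)
  phi <- gainMatrix(lf)[, 31:33] %*% (rnorm(3) * 1e-8)
  base <- energyValues(sloreta(lf, phi, alpha = 0))
  offset <- 10 * max(abs(phi))
  shifted <- energyValues(sloreta(lf, phi + offset, alpha = 0))
  expect_lt(max(abs(base - shifted)) / max(base), 1e-10)
  scaled <- energyValues(sloreta(lf, 3 * phi, alpha = 0))
  expect_equal(scaled, 9 * base, tolerance = 1e-10)
})
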