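# Spherical head model: grid, electrodes, closed-form lead field, centering.

test_that("buildSphereGrid matches a brute-force lattice enumeration", {
  g <- buildSphereGrid(scalpRadius = 1, fraction = 0.87, spacing = 0.25)
  # triple-loop oracle
  k <- floor(0.87 / 0.25)
  cnt <- 0
  for (i in -k:k) for (j in -k:k) for (l in -k:k)
    if (sqrt(sum((c(i, j, l) * 0.25)^2)) <= 0.87 + 1e-12) cnt <- cnt + 1
  expect_equal(nrow(gridPositions(g)), cnt)
  expect_true(all(sqrt(rowSums(gridPositions(g)^2)) <= 0.87 + 1e-12))
  # deterministic lexicographic order
  pos <- gridPositions(g)
  expect_false(is.unsorted(order(pos[, 1], pos[, 2], pos[, 3])))
  expect_equal(pos, gridPositions(
    buildSphereGrid(scalpRadius = 1, fraction = 0.87, spacing = 0.25)))

  expect_error(buildSphereGrid(scalpRadius = 1, fraction = 0.5, spacing = 2,
                               includeOrigin = FALSE), "empty grid")
})

test_that("projectElectrodes rescales onto the sphere", {
  m <- Montage(c("a", "b", "c", "d"),
               rbind(c(0, 0, 2), c(1, 1, 0), c(0, 1, 0), c(0.3, -0.2, 0.5)))
  p <- projectElectrodes(m, 1)
  expect_equal(unname(electrodePositions(p)["a", ]), c(0, 0, 1))
  expect_true(all(abs(sqrt(rowSums(electrodePositions(p)^2)) - 1) < 1e-12))
  # already on the sphere: unchanged
  expect_equal(electrodePositions(projectElectrodes(p, 1)),
               electrodePositions(p))
  mbad <- Montage(c("a", "b", "c", "zz"),
                  rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0)))
  expect_error(projectElectrodes(mbad, 1), "zz")
})

test_that("centeringOperator is the average-reference projector", {
  expect_equal(centeringOperator(2),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  for (n in c(3, 7, 62)) {
    oc <- centeringOperator(n)
    expect_lt(max(abs(oc %*% rep(4.2, n))), 1e-12)
    expect_lt(max(abs(oc %*% oc - oc)), 1e-14)
    expect_equal(oc, t(oc))
  }
})

test_that("lead field matches the Legendre-series oracle", {
  mon <- makeSphericalMontage(12)
  grid <- buildSphereGrid(fraction = 0.7, spacing = 0.035)
  lf <- leadfieldSingleSphere(mon, grid)
  set.seed(2)
  for (k in 1:5) {
    i <- sample(nrow(gridPositions(grid)), 1)
    p <- rnorm(3) * 1e-8
    analytic <- gainMatrix(lf)[, (3 * i - 2):(3 * i)] %*% p
    oracle <- vapply(seq_len(12), function(e)
      seriesPotential(electrodePositions(mon)[e, ],
                      gridPositions(grid)[i, ], p), numeric(1))
    expect_lt(max(abs(analytic - oracle)) / max(abs(oracle)), 1e-6)
  }
})

test_that("superposition and scaling hold exactly", {
  lf <- fixtureLeadField(12, 0.035, 0.7)
  G <- gainMatrix(lf)
  set.seed(3)
  d1 <- rnorm(ncol(G)); d2 <- rnorm(ncol(G))
  expect_equal(G %*% (d1 + d2), G %*% d1 + G %*% d2)
  expect_equal(G %*% (2 * d1), 2 * (G %*% d1))
})

test_that("a central radial dipole gives an antisymmetric surface pattern", {
  # montage of antipodal pairs
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1)) * 0.09
  mon <- Montage(sprintf("A%d", 1:6), ax)
  grid <- buildSphereGrid(fraction = 0.5, spacing = 0.05)
  origin <- which(rowSums(abs(gridPositions(grid))) < 1e-12)
  lf <- leadfieldSingleSphere(mon, grid)
  phi <- gainMatrix(lf)[, (3 * origin - 2):(3 * origin)] %*% c(0, 0, 1e-8)
  expect_equal(phi[1], -phi[2], tolerance = 1e-10)  # +-x pair
  expect_equal(phi[5], -phi[6], tolerance = 1e-10)  # +-z pair
  expect_lt(abs(phi[1]), 1e-15)                     # equator of a z dipole
  # central dipole in an insulated sphere: 3x the infinite-medium potential
  expect_equal(phi[5], 3 * 1e-8 / (4 * pi * 0.33 * 0.09^2), tolerance = 1e-10)
})

test_that("mirror symmetry: reflected dipole and electrode give the same potential", {
  ax <- expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))
  ax <- as.matrix(ax) / sqrt(3) * 0.09
  mon <- Montage(sprintf("M%d", 1:8), ax)
  grid <- buildSphereGrid(fraction = 0.6, spacing = 0.027)
  lf <- leadfieldSingleSphere(mon, grid)
  pos <- gridPositions(grid)
  i <- which.min(colSums((t(pos) - c(0.027, 0.027, 0.027))^2))
  j <- which.min(colSums((t(pos) - c(0.027, 0.027, -0.027))^2))  # z-mirror
  p <- c(0.3, -0.5, 0.7) * 1e-8
  pm <- p * c(1, 1, -1)
  phi_i <- gainMatrix(lf)[, (3 * i - 2):(3 * i)] %*% p
  phi_j <- gainMatrix(lf)[, (3 * j - 2):(3 * j)] %*% pm
  # electrode rows come in z-mirrored pairs: row for (x,y,z) vs (x,y,-z)
  mirror <- vapply(seq_len(8), function(e) {
    target <- electrodePositions(mon)[e, ] * c(1, 1, -1)
    which.min(colSums((t(electrodePositions(mon)) - target)^2))
  }, integer(1))
  expect_equal(as.numeric(phi_j[mirror]), as.numeric(phi_i), tolerance = 1e-12)
})

test_that("centered gain keeps potential differences and drops one rank", {
  lf <- fixtureLeadField(12, 0.035, 0.7)
  G <- gainMatrix(lf)
  oc <- centeringOperator(nrow(G))
  set.seed(4)
  phi <- G %*% rnorm(ncol(G))
  phic <- oc %*% (phi + 3e-6)
  expect_equal(outer(as.numeric(phic), as.numeric(phic), `-`),
               outer(as.numeric(phi), as.numeric(phi), `-`),
               tolerance = 1e-9)
  expect_equal(qr(oc %*% G)$rank, nrow(G) - 1L)
})

test_that("montage files round-trip in cartesian and spherical form", {
  mon <- makeSphericalMontage(8)
  f <- tempfile(fileext = ".csv")
  writeMontage(mon, f)
  back <- readMontage(f)
  expect_equal(channelNames(back), channelNames(mon))
  expect_equal(electrodePositions(back), electrodePositions(mon),
               tolerance = 1e-6)

  # spherical file: theta from +z, phi from +x toward +y, mm units
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("# units: mm", "name,theta,phi,radius",
               "Cz,0,0,90", "T8,90,0,90", "T7,90,180,90", "Oz,90,270,90"), f2)
  sph <- readMontage(f2)
  expect_equal(unname(electrodePositions(sph)["Cz", ]), c(0, 0, 0.09),
               tolerance = 1e-12)
  expect_equal(unname(electrodePositions(sph)["T8", ]), c(0.09, 0, 0),
               tolerance = 1e-12)
  expect_equal(unname(electrodePositions(sph)["Oz", ]), c(0, -0.09, 0),
               tolerance = 1e-12)
})

test_that("lead-field export/import reproduces inverse runs bit-for-bit", {
  lf <- fixtureLeadField(12, 0.035, 0.7)
  f <- tempfile(fileext = ".tsv")
  writeLeadField(lf, f)
  back <- readLeadField(f)
  expect_identical(gainMatrix(back), gainMatrix(lf))
  expect_identical(gridPositions(sourceGrid(back)), gridPositions(sourceGrid(lf)))
  expect_equal(orientationMode(back), orientationMode(lf))
  set.seed(6)
  phi <- gainMatrix(lf)[, 4:6] %*% rnorm(3) * 1e-8
  m1 <- sloreta(lf, phi, alpha = 0)
  m2 <- sloreta(back, phi, alpha = 0)
  expect_identical(energyValues(m1), energyValues(m2))
})

test_that("nodes too near the surface and fixed-orientation origin are rejected", {
  mon <- makeSphericalMontage(8)
  gridTight <- buildSphereGrid(fraction = 0.87, spacing = 0.045)
  expect_error(leadfieldSingleSphere(mon, gridTight), "too close")
  gridO <- buildSphereGrid(fraction = 0.6, spacing = 0.027)
  expect_error(leadfieldSingleSphere(mon, gridO, orientation = "fixed"),
               "origin")
  gridNoO <- buildSphereGrid(fraction = 0.6, spacing = 0.027,
                             includeOrigin = FALSE)
  lfFixed <- leadfieldSingleSphere(mon, gridNoO, orientation = "fixed")
  expect_equal(ncol(gainMatrix(lfFixed)), nrow(gridPositions(gridNoO)))
  # fixed column = free block times the radial unit vector
  lfFree <- leadfieldSingleSphere(mon, gridNoO, orientation = "free")
  i <- 5
  r <- gridPositions(gridNoO)[i, ]
  expect_equal(unname(gainMatrix(lfFixed)[, i]),
               as.numeric(gainMatrix(lfFree)[, (3 * i - 2):(3 * i)] %*%
                            (r / sqrt(sum(r^2)))))
})
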