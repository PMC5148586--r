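# Sifting building blocks and the EMD/EEMD decompositions.

test_that("findExtrema locates interior turning points", {
  ex <- findExtrema(c(0, 1, 0, -1, 0))
  expect_equal(ex$maxima, 2L)
  expect_equal(ex$minima, 4L)

  ex <- findExtrema(c(5, 5, 5, 5))
  expect_length(ex$maxima, 0)
  expect_length(ex$minima, 0)

  # one period of a sinusoid: exactly one maximum and one minimum, in the
  # positions a brute-force scan of first-difference sign changes finds
  t <- seq(0, 1, length.out = 100)
  x <- sin(2 * pi * t)
  ex <- findExtrema(x)
  ref <- scanExtrema(x)
  expect_equal(ex$maxima, ref$maxima)
  expect_equal(ex$minima, ref$minima)
  expect_length(ex$maxima, 1)
  expect_length(ex$minima, 1)
  expect_lt(ex$maxima, ex$minima)  # interleaved
})

test_that("envelopeMean recovers offsets and slow components", {
  t <- seq(0, 10, by = 0.01)
  interior <- seq(round(0.15 * length(t)), round(0.85 * length(t)))

  m <- envelopeMean(sin(2 * pi * t))
  expect_lt(max(abs(m[interior])), 0.02)

  m <- envelopeMean(sin(2 * pi * t) + 3)
  expect_lt(max(abs(m[interior] - 3)), 0.02 * 1 + 1e-9)

  slow <- sin(2 * pi * 1 * t)
  m <- envelopeMean(sin(2 * pi * 8 * t) + slow)
  expect_gt(cor(m[interior], slow[interior]), 0.95)

  expect_error(envelopeMean(rep(1, 50)), "cannot sift")
})

test_that("isIMF accepts tones and rejects trends and mixtures", {
  t <- seq(0, 4, by = 0.004)
  expect_true(isIMF(sin(2 * pi * 4 * t)))
  expect_false(isIMF(seq(0, 1, length.out = 100)))

  # a two-tone mixture is not an IMF
  x <- sin(2 * pi * 1 * t) + sin(2 * pi * 8 * t)
  expect_false(isIMF(x))
  # with a dominant slow tone the fast oscillation rides without crossing
  # zero, so the extrema and zero-crossing counts disagree outright
  x2 <- 2 * sin(2 * pi * 1 * t) + sin(2 * pi * 8 * t)
  ex <- findExtrema(x2)
  ne <- length(ex$maxima) + length(ex$minima)
  expect_gt(abs(ne - zeroCrossings(x2)), 1)
  expect_false(isIMF(x2))
})

test_that("emd reconstructs exactly and separates tones", {
  t <- seq(0, 4, by = 1 / 250)
  x <- sin(2 * pi * 4 * t)
  dec <- emd(x)
  expect_gt(cor(modes(dec)[, 1], x), 0.99)
  recon <- rowSums(modes(dec)) + residualSignal(dec)
  expect_lt(max(abs(recon - x)), 1e-9 * diff(range(x)))

  x2 <- sin(2 * pi * 1 * t) + sin(2 * pi * 8 * t)
  dec2 <- emd(x2)
  interior <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  expect_gt(cor(modes(dec2)[interior, 1], sin(2 * pi * 8 * t)[interior]), 0.95)
  expect_gt(cor(modes(dec2)[interior, 2], sin(2 * pi * 1 * t)[interior]), 0.95)

  # constant input: no modes, residual is the input
  dec3 <- emd(rep(2.5, 64))
  expect_equal(nModes(dec3), 0L)
  expect_equal(residualSignal(dec3), rep(2.5, 64))
})

test_that("perfect reconstruction and IMF conditions hold for varied signals", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(c(256, 512), 1)
    x <- switch(1 + k %% 3,
      rnorm(n),
      as.numeric(arima.sim(list(ar = 0.9), n)) + cumsum(rnorm(n, 0, 0.05)),
      sin(2 * pi * (1:n) / 50) + 0.4 * sin(2 * pi * (1:n) / 7) + 0.3 * rnorm(n))
    dec <- emd(x)
    recon <- rowSums(modes(dec)) + residualSignal(dec)
    expect_lt(max(abs(recon - x)), 1e-9 * diff(range(x)))
    for (j in seq_len(nModes(dec)))
      expect_true(isIMF(modes(dec)[, j]))
  }
})

test_that("decompositions are bitwise deterministic given the seed", {
  set.seed(99)
  x <- rnorm(300)
  cfg <- SiftConfig(ensembleSize = 10, noiseRatio = 0.2, seed = 42)
  expect_identical(eemd(x, cfg), eemd(x, cfg))
  expect_identical(emd(x), emd(x))
})

test_that("eemd with a single realization equals emd of the perturbed signal", {
  set.seed(5)
  x <- rnorm(200)
  cfg <- SiftConfig(ensembleSize = 1, noiseRatio = 0.3, seed = 17)
  noise <- eemdSource:::withSeed(17, function() matrix(rnorm(200), 200, 1))
  direct <- emd(x + 0.3 * sd(x) * noise[, 1])
  ens <- eemd(x, cfg)
  expect_equal(modes(ens), modes(direct))
  expect_equal(residualSignal(ens), residualSignal(direct))
})

test_that("ensemble averaging reduces mode mixing from an intermittent burst", {
  rate <- 64
  t <- seq(0, 8 - 1 / rate, by = 1 / rate)
  tone <- sin(2 * pi * 2 * t)
  burst <- ifelse(t >= 3.6 & t < 4.4, 0.6 * sin(2 * pi * 10 * t), 0)
  x <- tone + burst

  bandFraction <- function(v) {
    sp <- Mod(fft(v))^2
    f <- seq(0, rate, length.out = length(v) + 1)[seq_along(v)]
    f <- pmin(f, rate - f)
    sum(sp[f >= 2 / sqrt(2) & f <= 2 * sqrt(2)]) / sum(sp)
  }
  mixScore <- function(dec) {
    j <- which.max(apply(modes(dec), 2, function(v) abs(cor(v, tone))))
    1 - bandFraction(modes(dec)[, j])
  }
  plain <- emd(x)
  ens <- eemd(x, SiftConfig(ensembleSize = 50, noiseRatio = 0.2, seed = 3))
  expect_lt(mixScore(ens), mixScore(plain))
})

test_that("ensemble noise self-averages out of a tone-carrying mode", {
  rate <- 100
  t <- seq(0, 5 - 1 / rate, by = 1 / rate)
  tone <- sin(2 * pi * 5 * t)
  residNoise <- function(nens) {
    dec <- eemd(tone, SiftConfig(ensembleSize = nens, noiseRatio = 0.2,
                                 seed = 7))
    j <- which.max(apply(modes(dec), 2, function(v) abs(cor(v, tone))))
    m <- modes(dec)[, j]
    expect_gt(abs(cor(m, tone)), 0.99)
    sum((m - tone * sum(m * tone) / sum(tone^2))^2)
  }
  e <- vapply(c(10, 40, 100), residNoise, numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("ermsFromTrials averages per-trial modes and flags dead channels", {
  rate <- 128
  n <- 128
  t <- seq(0, by = 1 / rate, length.out = n)
  sig <- sin(2 * pi * 6 * t)
  cfg <- SiftConfig(ensembleSize = 4, noiseRatio = 0.2, seed = 21)

  # single trial: ERMs equal that trial's eemd modes (shared seed path)
  ep1 <- EEGEpochs(array(sig, c(1, n, 1)), rate)
  erms <- ermsFromTrials(ep1, cfg, seedPerTrial = "shared")
  expect_equal(modes(erms[[1]]), modes(eemd(sig, cfg)))

  # identical trials with a shared seed: average of identical items
  ep3 <- EEGEpochs(array(rep(sig, 3), c(1, n, 3)), rate)
  erms3 <- ermsFromTrials(ep3, cfg, seedPerTrial = "shared")
  expect_equal(modes(erms3[[1]]), modes(eemd(sig, cfg)))

  # all-constant channel: empty ERM set with a warning
  cube <- array(rnorm(2 * n * 2), c(2, n, 2))
  cube[2, , ] <- 7
  expect_warning(ermsBad <- ermsFromTrials(EEGEpochs(cube, rate), cfg),
                 "all-constant")
  expect_equal(nModes(ermsBad[[2]]), 0L)
})

test_that("trial-averaged modes beat single-trial modes at recovering an ERP", {
  rate <- 128
  n <- 128
  t <- seq(0, by = 1 / rate, length.out = n)
  erp <- makeComponent(0.4, 0.12, 6, 1, t)
  ntr <- 20
  set.seed(31)
  cube <- array(0, c(1, n, ntr))
  for (k in seq_len(ntr)) cube[1, , k] <- erp + rnorm(n, 0, 1)
  cfg <- SiftConfig(ensembleSize = 6, noiseRatio = 0.2, seed = 8)
  erms <- ermsFromTrials(EEGEpochs(cube, rate), cfg)
  bestCor <- function(im) max(apply(modes(im), 2, function(v)
    if (sd(v) == 0) 0 else abs(cor(v, erp))))
  ermCor <- bestCor(erms[[1]])
  singleCors <- vapply(seq_len(ntr), function(k)
    bestCor(eemd(cube[1, , k], cfg)), numeric(1))
  expect_gt(ermCor, median(singleCors))
})

test_that("selectMode picks the ERP-matching mode with deterministic ties", {
  set.seed(13)
  n <- 120
  m <- matrix(rnorm(n * 4), n, 4)
  im <- new("IMFSet", modes = m, residual = numeric(n), rate = 1,
            params = list())
  expect_equal(selectMode(list(im), matrix(m[, 3], 1)), 3L)

  # reference correlated only with mode 1
  ref <- m[, 1] + rnorm(n, 0, 0.1)
  for (j in 2:4) ref <- ref - m[, j] * sum(ref * m[, j]) / sum(m[, j]^2)
  expect_equal(selectMode(list(im), matrix(ref, 1)), 1L)

  # tie between identical columns resolves to the lower index
  imTie <- new("IMFSet", modes = cbind(m[, 2], m[, 2]), residual = numeric(n),
               rate = 1, params = list())
  expect_equal(selectMode(list(imTie), matrix(m[, 2], 1)), 1L)

  # zero-variance mode scores 0 rather than propagating NA
  imZero <- new("IMFSet", modes = cbind(numeric(n), m[, 1]),
                residual = numeric(n), rate = 1, params = list())
  expect_equal(selectMode(list(imZero), matrix(m[, 1], 1)), 2L)
})

test_that("an embedded narrowband oscillation is recovered by selection", {
  rate <- 128
  n <- 256
  t <- seq(0, by = 1 / rate, length.out = n)
  slow <- sin(2 * pi * 3 * t)
  fast <- 0.8 * sin(2 * pi * 24 * t)
  cfg <- SiftConfig(ensembleSize = 10, noiseRatio = 0.2, seed = 4)
  erms <- list(eemd(slow + fast, cfg, rate = rate))
  # oracle: the full correlation table against the slow reference
  tab <- apply(modes(erms[[1]]), 2, function(v)
    if (sd(v) == 0) 0 else abs(cor(v, slow)))
  expect_equal(selectMode(erms, matrix(slow, 1)), which.max(tab))
  expect_gt(max(tab), 0.9)
})
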