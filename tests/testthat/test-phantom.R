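test_that("the layered-sphere phantom matches analytic shell volumes", {
  fx <- phantomFixture()
  vol <- fx$phantom$volume
  radii <- c(92, 85, 81, 78, 65)
  shellVol <- -diff(c(4 / 3 * pi * radii^3, 0))   # skin..white shells
  counts <- tabulate(vol@labels[vol@labels > 0], 5)
  for (i in 1:5)
    expect_equal(counts[i] * vol@voxelSize^3, shellVol[i],
                 tolerance = 0.05)
  ## optodes sit within half a voxel of the scalp sphere
  pr <- fx$phantom$probe
  r <- sqrt(rowSums(rbind(pr@sourcePos, pr@detectorPos)^2))
  expect_true(all(abs(r - 92) <= vol@voxelSize / 2))
  ## deterministic construction
  ph2 <- makePhantom()
  expect_identical(ph2$volume@labels, vol@labels)
  expect_identical(ph2$surface@vertices, fx$phantom$surface@vertices)
  expect_error(makePhantom(radiiMm = c(skin = 60, skull = 65, csf = 50,
                                       gray = 45, white = 30)), "nested")
})

test_that("simulated recordings follow the forward generative model", {
  fx <- phantomFixture()
  sim <- defaultSimulation()
  ## zero amplitudes, zero noise -> constant intensities
  sim0 <- sim
  sim0$ampHbO <- 0; sim0$ampHbR <- 0
  sim0$cardiacAmp <- 0; sim0$respAmp <- 0; sim0$mayerAmp <- 0
  sim0$ar1Amp <- 0; sim0$superficialAmp <- 0; sim0$motionSpikes <- 0
  so0 <- simulateRecording(fx$phantom, fx$forward, sim0, seed = 1)
  expect_equal(diff(range(intensities(so0$recording))), 0)

  ## noise off: channel OD equals A times the true cortical OD
  simC <- sim
  simC$cardiacAmp <- 0; simC$respAmp <- 0; simC$mayerAmp <- 0
  simC$ar1Amp <- 0; simC$superficialAmp <- 0; simC$motionSpikes <- 0
  soC <- simulateRecording(fx$phantom, fx$forward, simC, seed = 1)
  od <- -log10(intensities(soC$recording) / 1e4)
  ch <- channelTable(fx$phantom$probe)
  pairKey <- paste(fx$forward@pairs$source, fx$forward@pairs$detector)
  i <- which(ch$wavelength == 2)[3]
  row <- match(paste(ch$source[i], ch$detector[i]), pairKey)
  want <- as.numeric(fx$forward@A[row, ] %*% soC$truth$jOd[[2]])
  expect_lt(max(abs(od[i, ] - want)), 1e-9)

  ## same seed -> identical realization; different seed differs
  a <- simulateRecording(fx$phantom, fx$forward, sim, seed = 5)
  b <- simulateRecording(fx$phantom, fx$forward, sim, seed = 5)
  expect_identical(intensities(a$recording), intensities(b$recording))
  c3 <- simulateRecording(fx$phantom, fx$forward, sim, seed = 6)
  expect_false(identical(intensities(a$recording),
                         intensities(c3$recording)))
})

test_that("simulated data survive a SNIRF round trip with identical analysis", {
  fx <- phantomFixture()
  so <- simulateRecording(fx$phantom, fx$forward, defaultSimulation(),
                          seed = 2)
  f <- tempfile(fileext = ".snirf")
  writeSnirf(so$recording, f)
  back <- readSnirf(f)
  odA <- toOpticalDensity(so$recording, baselineWindow = c(0, 20))
  odB <- toOpticalDensity(back, baselineWindow = c(0, 20))
  expect_identical(odA@od, odB@od)
  expect_equal(events(back), events(so$recording))
})

test_that("spatial dispersion matches its definition and a brute-force oracle", {
  surf <- icosphere(2, 70)
  truth <- c(5, 12, 40)
  g <- meshGraph(surf)
  ## all energy inside the truth -> zero dispersion
  m0 <- numeric(nrow(surf@vertices)); m0[truth] <- c(1, 2, 3)
  expect_equal(spatialDispersion(m0, truth, surf), 0)
  ## all-zero map -> undefined
  expect_true(is.na(spatialDispersion(numeric(nrow(surf@vertices)),
                                      truth, surf)))
  ## single off-truth vertex at known geodesic distance d -> SD = d
  far <- 100
  d <- min(igraph::distances(g, v = as.character(truth),
                             to = as.character(far)))
  m1 <- numeric(nrow(surf@vertices)); m1[far] <- 2
  expect_equal(spatialDispersion(m1, truth, surf), d, tolerance = 1e-9)
  ## random maps against the double-loop oracle
  set.seed(91)
  for (r in 1:3) {
    m <- abs(rnorm(nrow(surf@vertices)))
    got <- spatialDispersion(m, truth, surf)
    dAll <- apply(igraph::distances(g, v = as.character(truth)), 2, min)
    dAll[truth] <- 0
    oracle <- sqrt(sum(dAll^2 * m^2) / sum(m^2))
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("ROC-AUC is the rank statistic with the right null behavior", {
  ## indicator map of the truth -> perfect score
  truth <- 1:30
  map <- c(rep(1, 30), rep(0, 970))
  expect_equal(rocAuc(map, truth), 1)
  ## random map -> near-chance AUC
  set.seed(92)
  expect_true(abs(rocAuc(rnorm(1000), truth) - 0.5) < 0.1)
  aucs <- replicate(50, rocAuc(rnorm(1000), truth))
  expect_true(mean(aucs) > 0.45 && mean(aucs) < 0.55)
  ## all-pairs comparison oracle
  for (r in 1:3) {
    x <- abs(rnorm(60)); tr <- sample(60, 20)
    pos <- x[tr]; neg <- x[-tr]
    oracle <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(rocAuc(x, tr), oracle, tolerance = 1e-9)
  }
  expect_error(rocAuc(rnorm(10), 1:10), "degenerate")
})

test_that("the end-to-end benchmark is reproducible for a fixed seed", {
  fx <- phantomFixture()
  b1 <- endToEndBenchmark(seed = 7, snr = 5, phantom = fx$phantom,
                          forward = fx$forward)
  b2 <- endToEndBenchmark(seed = 7, snr = 5, phantom = fx$phantom,
                          forward = fx$forward)
  expect_identical(b1, b2)
  expect_true(all(b1$rocAuc > 0.5))
  expect_true(all(b1$spatialDispersion >= 0))
})
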