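test_that("optical density conversion obeys the log10 baseline identities", {
  pr <- smallProbe()
  times <- seq(0, 9.9, 0.1)
  I <- matrix(rep(500, 4 * 100), 4)
  rec <- OpticalRecording(pr, times, I)
  od <- toOpticalDensity(rec)
  expect_true(all(od@od == 0))               # I == I0 -> dOD == 0

  I2 <- I; I2[1, 50] <- 50                    # I0/10 at one sample
  od2 <- toOpticalDensity(OpticalRecording(pr, times, I2),
                          baselineWindow = c(0, 3))
  expect_equal(od2@od[1, 50], 1, tolerance = 1e-12)

  ## global intensity scaling leaves dOD unchanged
  od7 <- toOpticalDensity(OpticalRecording(pr, times, 7 * I2),
                          baselineWindow = c(0, 3))
  expect_equal(od7@od, od2@od, tolerance = 1e-12)

  expect_error(toOpticalDensity(rec, baselineWindow = c(100, 200)),
               "baseline")
  expect_error(toOpticalDensity(OpticalRecording(pr, times, I - 500)),
               "onpositive")
})

test_that("spline correction removes a transient pulse and touches nothing else", {
  fs <- 10; n <- 5000
  x <- rep(0, n); x[1980:2020] <- 5      # transient artifact inside window
  od <- odFromMatrix(rbind(x, x), fs)
  ## empty window list -> identity
  expect_identical(splineMotionCorrect(od, list()), od)
  corr <- splineMotionCorrect(od, list(c(195, 205)))
  expect_lt(diff(range(corr@od[1, 1900:2100])), 0.5)
  out <- setdiff(seq_len(n), which(od@times >= 195 & od@times <= 205))
  expect_identical(corr@od[1, out], od@od[1, out])   # bit-exact outside
  expect_warning(splineMotionCorrect(od, list(c(195, 205), c(200, 210))),
                 "merged")
})

test_that("TDDR matches the published-iteration oracle", {
  set.seed(31)
  fs <- 10; n <- 4000
  x <- cumsum(rnorm(n)) * 0.01 + sin(2 * pi * 0.05 * seq_len(n) / fs)
  od <- odFromMatrix(rbind(x, x), fs)
  got <- tddrMotionCorrect(od)@od[1, ]
  want <- tddrOracle(x, fs)
  expect_lt(max(abs(got - want)), 1e-10)
  expect_lt(abs(mean(got) - mean(x)), 1e-9)
  ## all-zero input -> all-zero output
  z <- tddrMotionCorrect(odFromMatrix(matrix(0, 2, 500), fs))
  expect_true(all(z@od == 0))
  expect_error(tddrMotionCorrect(odFromMatrix(matrix(c(NA, 1:999), 2),
                                              fs)), "finite")
})

test_that("TDDR suppresses derivative outliers but keeps inlier structure", {
  ## fs = 1: no frequency split, the derivative is corrected directly
  set.seed(32)
  n <- 5000
  d <- rnorm(n - 1); d[2500] <- 50          # 50 sigma derivative spike
  x <- cumsum(c(0, d))
  out <- tddrMotionCorrect(odFromMatrix(rbind(x, x), fs = 1))@od[1, ]
  expect_lt(abs(diff(out)[2500]), 3)        # spike derivative below 3 sigma
  expect_identical(out, tddrOracle(x, 1))
  ## no-outlier, zero-drift fixture: the biweight still softly shrinks
  ## inlier derivatives (E[w z^2]/E[z^2] ~ 0.76), so the bound is the
  ## oracle-computed attenuation, not an exact no-op
  d0 <- rnorm(n - 1)
  d0 <- d0 - mean(d0)
  x0 <- cumsum(c(0, d0))
  out0 <- tddrMotionCorrect(odFromMatrix(rbind(x0, x0), fs = 1))@od[1, ]
  expect_lt(sqrt(mean((out0 - x0)^2)) / sd(x0), 0.35)
  expect_gt(cor(out0, x0), 0.95)
})

test_that("bandpass filtering has the specified frequency response", {
  fs <- 5; t <- seq(0, 599.8, by = 1 / fs); n <- length(t)
  core <- seq(500, n - 500)
  for (design in c("iir", "fir")) {
    ord <- if (design == "fir") 200 else NULL
    dc <- bandpassFilter(matrix(3, 1, n), 0.01, 0.5, design, ord, fs = fs)
    expect_lt(sqrt(mean(dc^2)) / 3, 1e-3)
    keep <- bandpassFilter(matrix(sin(2 * pi * 0.1 * t), 1), 0.01, 0.5,
                           design, ord, fs = fs)
    expect_equal(max(abs(keep[core])), 1, tolerance = 0.05)
    kill <- bandpassFilter(matrix(sin(2 * pi * 2 * t), 1), 0.01, 0.5,
                           design, ord, fs = fs)
    expect_lt(20 * log10(max(abs(kill[core]))), -20)
  }
  expect_error(bandpassFilter(matrix(0, 1, n), 0.01, 3, fs = fs),
               "Nyquist")
})

test_that("filters and detrending are strictly linear operators", {
  set.seed(33)
  fs <- 5; n <- 3000
  x1 <- rnorm(n); x2 <- rnorm(n)
  for (f in list(
    function(x) bandpassFilter(matrix(x, 1), 0.01, 0.5, fs = fs),
    function(x) dctDetrend(matrix(x, 1), 200, fs = fs))) {
    lhs <- f(2 * x1 + 3 * x2)
    rhs <- 2 * f(x1) + 3 * f(x2)
    expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
  }
})

test_that("DCT detrending removes slow and keeps fast components", {
  fs <- 5; t <- seq(0, 599.8, by = 1 / fs)
  expect_lt(max(abs(dctDetrend(matrix(2, 1, length(t)), 200, fs = fs))),
            1e-9)
  slow <- cos(2 * pi * t / 400)
  r <- dctDetrend(matrix(slow, 1), 200, fs = fs)
  expect_lt(sqrt(mean(r^2)) / sqrt(mean(slow^2)), 0.05)
  fast <- sin(2 * pi * 0.05 * t)
  r2 <- dctDetrend(matrix(fast, 1), 200, fs = fs)
  expect_lt(sqrt(mean((r2 - fast)^2)) / sqrt(mean(fast^2)), 0.05)
  expect_error(dctDetrend(matrix(0, 1, 100), 200, fs = fs), "longer")
})

test_that("short-channel regression removes superficial, keeps brain", {
  set.seed(34)
  n <- 3000
  sup <- as.numeric(stats::filter(rnorm(n), 0.9, "recursive"))
  brain <- sin(2 * pi * 0.04 * seq_len(n) / 10)
  pr <- Probe(rbind(c(0, 0, 0), c(100, 0, 0)),
              rbind(c(30, 0, 0), c(108, 0, 0)), c(685, 830),
              pairs = data.frame(source = c(1, 2), detector = c(1, 2)))
  ## pair 1 is long (30 mm), pair 2 short (8 mm)
  X <- rbind(0.8 * sup + brain, 0.8 * sup + brain,   # long, both wavelengths
             sup + 0.01 * rnorm(n), sup + 0.01 * rnorm(n))
  od <- odFromMatrix(X, fs = 10, probe = pr)
  out <- shortChannelRegress(od)
  expect_lt(abs(cor(out@od[1, ], sup)), 0.05)
  expect_gt(cor(out@od[1, ], brain), 0.95)
  expect_identical(out@od[3, ], od@od[3, ])   # short channels untouched
  ## zero-variance regressor -> warned identity (once per wavelength)
  X0 <- X; X0[3, ] <- 1; X0[4, ] <- 1
  w <- capture_warnings(out0 <- shortChannelRegress(odFromMatrix(X0, 10,
                                                                 pr)))
  expect_true(length(w) >= 1 && all(grepl("zero variance", w)))
  expect_identical(out0@od[1, ], X0[1, ])
  ## no short channels at all -> error advising skip
  longOnly <- Probe(matrix(c(0, 0, 0), 1), matrix(c(30, 0, 0), 1),
                    c(685, 830))
  expect_error(shortChannelRegress(odFromMatrix(X[1:2, , drop = FALSE],
                                                10, longOnly)),
               "skip")
})

test_that("MBLL inverts the forward Beer-Lambert synthesis exactly", {
  pr <- Probe(matrix(c(0, 0, 0), 1), matrix(c(30, 0, 0), 1), c(685, 830))
  params <- beerLambertParams(c(685, 830))
  times <- seq(0, 4.9, 0.1)
  set.seed(35)
  hbo <- matrix(rnorm(50), 1); hbr <- matrix(rnorm(50), 1)
  od <- hbToOd(hbo, hbr, pr, data.frame(source = 1, detector = 1), times,
               params)
  hb <- mbll(od, params)
  expect_lt(max(abs(hb@hbo - hbo)), 1e-9)
  expect_lt(max(abs(hb@hbr - hbr)), 1e-9)
  expect_identical(hb@hbt, hb@hbo + hb@hbr)   # bit-exact by construction
  ## zero OD -> zero hemoglobin
  od0 <- od; od0@od[] <- 0
  hb0 <- mbll(od0, params)
  expect_true(all(hb0@hbo == 0) && all(hb0@hbt == 0))
  ## singular extinction matrix is refused
  expect_error(beerLambertParams(c(685, 830),
                                 extinction = matrix(1, 2, 2)), "ingular")
})

test_that("effective pathlength follows d * DPF / PVF", {
  expect_equal(effectivePathlength(3, 5, 50), 0.3)
  dpf <- dpfScholkmann(c(685, 830), age = 25)
  expect_true(all(dpf > 4 & dpf < 8))
  de <- effectivePathlength(3, dpf, 50)
  expect_true(all(de >= 0.25 & de <= 0.45))
  expect_true(all(dpfDuncan(c(690, 830), 25) > 4))
})

test_that("epoch averaging extracts, averages and drops correctly", {
  pr <- smallProbe()
  fs <- 10; times <- seq(0, 199.9, by = 1 / fs)
  resp <- c(rep(0, 10), sin(seq(0, pi, length.out = 41)), rep(0, 50))
  X <- matrix(0, 4, length(times))
  on <- c(20, 60, 100, 140)
  for (o in on) X[, o * fs + seq_along(resp)] <- rep(resp, each = 4)
  ev <- data.frame(label = "t", onset = on + 0.1, duration = 4)
  od <- odFromMatrix(X, fs); od@events <- ev

  one <- epochAverage(od, events = ev[1, ], window = c(-1, 9))
  expect_equal(one$t$n, 1)
  i0 <- which.min(abs(times - ev$onset[1]))
  expect_equal(one$t$mean[1, ], X[1, i0 + seq(-10, 90)])

  all4 <- epochAverage(od, window = c(-1, 9))
  expect_equal(all4$t$n, 4)
  expect_true(all(all4$t$sd == 0))            # identical epochs
  expect_equal(all4$t$mean, one$t$mean)

  ## epochs crossing the record edge are dropped and counted
  evEdge <- rbind(ev, data.frame(label = "t", onset = 199, duration = 4))
  dropped <- epochAverage(od, events = evEdge, window = c(-1, 9))
  expect_equal(dropped$t$dropped, 1)
  expect_error(epochAverage(od, events = data.frame(label = "x",
                                                    onset = 199.9,
                                                    duration = 1),
                            window = c(-1, 9)), "usable")
})

test_that("std of the epoch mean shrinks like 1/sqrt(n)", {
  set.seed(36)
  fs <- 10
  times <- seq(0, 2099.9, by = 1 / fs)
  X <- matrix(rnorm(2 * length(times)), 2)
  pr <- smallProbe()
  od <- odFromMatrix(rbind(X, X), fs)
  ev <- data.frame(label = "t", onset = seq(50, 2000, length.out = 20),
                   duration = 1)
  ep <- epochAverage(od, events = ev, window = c(0, 20))$t
  semObserved <- mean(ep$sd) / sqrt(ep$n)
  expect_equal(semObserved, 1 / sqrt(20), tolerance = 0.3)
})
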