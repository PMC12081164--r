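## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## Full layered-sphere phantom + analytic forward model (the expensive
## fixture; ~15 s, reused across inverse and acceptance tests).
phantomFixture <- function() {
  if (is.null(.fixtures$phantom)) {
    .fixtures$phantom <- makePhantom()
    .fixtures$forward <- buildForwardModel(.fixtures$phantom$volume,
                                           .fixtures$phantom$surface,
                                           .fixtures$phantom$probe)
  }
  list(phantom = .fixtures$phantom, forward = .fixtures$forward)
}

## Small two-pair probe (1 source, 1 detector would collapse SCI pairs).
smallProbe <- function(landmarks = FALSE) {
  lm <- if (landmarks)
    rbind(nasion = c(0, 90, 0), lpa = c(-80, 0, 0), rpa = c(80, 0, 0))
  Probe(rbind(c(0, 0, 0), c(40, 0, 0)),
        rbind(c(30, 0, 0), c(70, 0, 0)),
        c(685, 830), landmarks = lm,
        pairs = data.frame(source = c(1, 2), detector = c(1, 2)))
}

## Recording with sinusoidal cardiac content on every channel.
smallRecording <- function(seed = 1, n = 3000, fs = 10) {
  set.seed(seed)
  pr <- smallProbe(landmarks = TRUE)
  times <- seq(0, by = 1 / fs, length.out = n)
  card <- sin(2 * pi * 1.2 * times)
  I <- t(vapply(seq_len(nChannels(pr)), function(i)
    1000 * 10^(-0.01 * card - 0.002 * rnorm(n)), numeric(n)))
  ev <- data.frame(label = "task", onset = c(50, 150), duration = 10)
  OpticalRecording(pr, times, I, events = ev)
}

## Plain OpticalDensity wrapper around a channel x time matrix.
odFromMatrix <- function(X, fs = 10, probe = NULL) {
  if (is.null(probe)) {
    np <- nrow(X) / 2
    probe <- Probe(cbind(40 * (seq_len(np) - 1), 0, 0),
                   cbind(40 * (seq_len(np) - 1) + 30, 0, 0),
                   c(685, 830),
                   pairs = data.frame(source = seq_len(np),
                                      detector = seq_len(np)))
  }
  times <- seq(0, by = 1 / fs, length.out = ncol(X))
  new("OpticalDensity", probe = probe, times = times, od = X,
      events = data.frame(label = character(), onset = numeric(),
                          duration = numeric()),
      baselineWindow = range(times), baselineStat = "mean")
}

## Small synthetic inverse-problem instance on an icosphere cap.
inverseFixture <- function(seed = 8, nChannels = 8, subdiv = 2,
                           capZ = 20) {
  set.seed(seed)
  surf <- icosphere(subdiv, 70)
  fov <- which(surf@vertices[, 3] > capZ)
  A <- matrix(abs(stats::rnorm(nChannels * length(fov))), nChannels)^2
  noiseVar <- stats::runif(nChannels, 0.5, 1.5)
  m <- A[, 30] %*% t(sin(seq(0, 3, length.out = 20))) +
    0.01 * matrix(stats::rnorm(nChannels * 20), nChannels)
  list(surface = surf, fov = fov, A = A, noiseVar = noiseVar, m = m)
}

## Exhaustive-enumeration oracle for the montage placement program.
montageBruteForce <- function(prob) {
  P <- nrow(prob@positions)
  cand <- setdiff(seq_len(P), prob@excluded)
  D <- as.matrix(stats::dist(prob@positions))
  ok <- D >= prob@dMin & D <= prob@dMax
  V <- prob@V; V[!ok] <- 0
  best <- -Inf; bs <- NULL; bd <- NULL
  if (length(cand) >= prob@nSources + prob@nDetectors) {
    for (S in utils::combn(cand, prob@nSources, simplify = FALSE)) {
      for (Dt in utils::combn(setdiff(cand, S), prob@nDetectors,
                              simplify = FALSE)) {
        all <- c(S, Dt)
        dd <- D[all, all]; diag(dd) <- Inf
        if (min(dd) < prob@optMin) next
        if (any(vapply(S, function(s) sum(ok[s, Dt]), 0L) <
                prob@adjacency)) next
        obj <- sum(V[S, Dt, drop = FALSE])
        if (obj > best + 1e-9) { best <- obj; bs <- S; bd <- Dt }
      }
    }
  }
  list(objective = best, sources = bs, detectors = bd)
}

## Independent straight-line implementation of the published TDDR
## iteration (the oracle the package implementation is checked against).
tddrOracle <- function(x, fs) {
  if (fs > 1) {
    flt <- signal::butter(3, 0.5 / (fs / 2), type = "low")
    low <- signal::filtfilt(flt, x - mean(x)) + mean(x)
  } else low <- x
  high <- x - low
  d <- diff(low)
  w <- rep(1, length(d)); mu <- Inf
  for (i in 1:50) {
    mu0 <- mu
    mu <- sum(w * d) / sum(w)
    dev <- abs(d - mu)
    sigma <- 1.4826 * stats::median(dev)
    if (sigma < .Machine$double.eps) { w <- as.numeric(dev == 0); break }
    r <- dev / (sigma * 4.685)
    w <- ((1 - r^2) * (r < 1))^2
    if (is.finite(mu0) && abs(mu - mu0) <= 1e-8 * max(abs(mu), abs(mu0), 1))
      break
  }
  lowC <- cumsum(c(0, w * (d - mu)))
  lowC - mean(lowC) + mean(low) + high
}
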