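test_that("prelocalization scores find a noise-free generator", {
  fx <- inverseFixture()
  A <- fx$A
  ## data generated from a single column, no noise -> that vertex peaks
  mcol <- A[, 30] %*% t(seq(1, 2, length.out = 5))
  sc <- mspScores(mcol, A)
  expect_equal(which.max(sc), 30L)
  expect_true(all(sc >= 0 & sc <= 1))
  ## invariance to global scaling of the data
  expect_equal(mspScores(100 * mcol, A), sc, tolerance = 1e-12)
  expect_warning(s0 <- mspScores(matrix(0, nrow(A), 3), A), "zero data")
  expect_true(all(s0 == 0.5))
})

test_that("region growing partitions the FOV into connected parcels", {
  fx <- inverseFixture()
  set.seed(71)
  scores <- runif(length(fx$fov))
  ## target 1 parcel: everything in one connected piece
  p1 <- parcellate(fx$surface, fx$fov, scores, targetK = 1)
  expect_equal(length(p1@parcels), 1L)
  expect_setequal(p1@parcels[[1]], seq_along(fx$fov))
  ## general partition property + connectedness of each parcel
  pk <- parcellate(fx$surface, fx$fov, scores, targetK = 8)
  expect_equal(sum(lengths(pk@parcels)), length(fx$fov))
  expect_setequal(unlist(pk@parcels), seq_along(fx$fov))
  nb <- nirsdot:::fovNeighbors(fx$surface, fx$fov)
  for (p in pk@parcels) {
    sub <- lapply(p, function(v) intersect(nb[[v]], p))
    names(sub) <- as.character(seq_along(p))
    comp <- nirsdot:::connectedComponents(
      lapply(p, function(v) match(intersect(nb[[v]], p), p)))
    expect_equal(length(comp), 1L)
  }
  ## determinism
  pk2 <- parcellate(fx$surface, fx$fov, scores, targetK = 8)
  expect_identical(pk@assignment, pk2@assignment)
})

test_that("auto-tuned parcel count approaches the channel count target", {
  fx <- phantomFixture()
  set.seed(72)
  scores <- runif(length(fx$forward@fov))
  K <- 50
  parc <- parcellate(fx$phantom$surface, fx$forward@fov, scores,
                     targetK = K)
  expect_gte(length(parc@parcels), 0.8 * K)
  expect_lte(length(parc@parcels), 1.2 * K)
})

test_that("alpha initialization applies the median and the 0.8 rule", {
  parc <- new("Parcellation", assignment = c(1L, 1L, 1L, 2L, 2L, 2L),
              parcels = list(1:3, 4:6), mspScores = rep(0, 6),
              neighborhoodOrder = 1)
  expect_equal(initAlpha(parc, c(0.1, 0.2, 0.3, 0.1, 0.1, 0.1)),
               c(0.2, 0.1))
  ## median 0.85 -> promoted to exactly 1
  expect_equal(initAlpha(parc, c(0.8, 0.85, 0.9, 0, 0, 0)), c(1, 0))
  ## boundary: median exactly 0.8 reaches the threshold
  expect_equal(initAlpha(parc, c(0.8, 0.8, 0.8, 0, 0, 0))[1], 1)
  expect_equal(initAlpha(parc, c(0.79, 0.79, 0.79, 0, 0, 0))[1], 0.79)
})

test_that("parcel covariances have the stated scale, limit and PSD structure", {
  fx <- inverseFixture()
  sc <- mspScores(fx$m, fx$A)
  parc <- parcellate(fx$surface, fx$fov, sc, 8)
  ## unit normalized energy -> eta = 0.05 (5% of unit energy)
  jUnit <- matrix(1, length(fx$fov), 3)
  pr <- initSigmaK(fx$A, jUnit, parc, fx$surface, fx$fov)
  expect_true(all(abs(pr@eta - 0.05) < 1e-12))
  ## sigma -> 0: no smoothing, Sigma_k diagonal
  pr0 <- initSigmaK(fx$A, jUnit, parc, fx$surface, fx$fov, sigma = 0)
  for (Ck in pr0@Ck)
    expect_lt(max(abs(Ck - diag(diag(Ck), nrow(Ck)))), 1e-12)
  ## PSD on a realistic minimum-norm input
  mne <- mneSolve(fx$m, fx$A, kappa = 1, omega = 0.3,
                  noiseVar = rep(1, nrow(fx$A)))
  pr1 <- initSigmaK(fx$A, mne$j, parc, fx$surface, fx$fov)
  for (k in seq_along(pr1@Ck)) {
    ev <- eigen(pr1@Ck[[k]] * pr1@eta[k, 1], symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
  ## empty parcels are unrepresentable: the class validity rejects them
  expect_error(new("Parcellation", assignment = 1L,
                   parcels = list(integer(0)), mspScores = 1,
                   neighborhoodOrder = 1), "partition")
})

test_that("the free energy obeys its closed-form special cases", {
  S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  s <- c(0.3, -0.2, 0.5)
  q <- 0.5 * as.numeric(t(s) %*% S %*% s)
  expect_equal(freeEnergy(s, 0, S), 0)             # inactive parcel
  expect_equal(freeEnergy(numeric(3), 0.4, S), 0)  # s = 0
  expect_equal(freeEnergy(s, 1, S), q)             # fully active: quadratic
  expect_equal(freeEnergy(s, 0.3, S), log(0.7 + 0.3 * exp(q)))
  ## large-argument guard: F ~ q + log(alpha) for big q
  qBig <- 0.5 * as.numeric(t(20 * s) %*% S %*% (20 * s))
  expect_equal(freeEnergy(20 * s, 0.5, S), qBig + log(0.5),
               tolerance = 1e-6)
})

test_that("the dual value, gradient and curvature check out", {
  fx <- inverseFixture()
  sc <- mspScores(fx$m, fx$A)
  parc <- parcellate(fx$surface, fx$fov, sc, 8)
  mne <- mneSolve(fx$m, fx$A, kappa = 1, omega = 0.3,
                  noiseVar = rep(1, nrow(fx$A)))
  pr <- initSigmaK(fx$A, mne$j, parc, fx$surface, fx$fov)
  pr@alpha <- pmin(initAlpha(parc, sc), 0.9)
  nC <- nrow(fx$A)

  ## lambda = 0 -> D = 0 (all three terms vanish)
  expect_equal(dualValueAndGradient(numeric(nC), fx$m[, 3], fx$A, pr,
                                    fx$noiseVar, 3)$D, 0)

  set.seed(73)
  for (r in 1:3) {
    lam <- rnorm(nC) * 0.5
    dg <- dualValueAndGradient(lam, fx$m[, 3], fx$A, pr, fx$noiseVar, 3)
    fd <- vapply(seq_len(nC), function(i) {
      h <- 1e-6; e <- numeric(nC); e[i] <- h
      (dualValueAndGradient(lam + e, fx$m[, 3], fx$A, pr, fx$noiseVar,
                            3)$D -
         dualValueAndGradient(lam - e, fx$m[, 3], fx$A, pr, fx$noiseVar,
                              3)$D) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(dg$grad - fd)) / max(abs(dg$grad)), 1e-5)
  }

  ## concavity along random chords
  for (r in 1:5) {
    l1 <- rnorm(nC); l2 <- rnorm(nC)
    D1 <- dualValueAndGradient(l1, fx$m[, 3], fx$A, pr, fx$noiseVar, 3)$D
    D2 <- dualValueAndGradient(l2, fx$m[, 3], fx$A, pr, fx$noiseVar, 3)$D
    Dm <- dualValueAndGradient((l1 + l2) / 2, fx$m[, 3], fx$A, pr,
                               fx$noiseVar, 3)$D
    expect_gte(Dm, 0.5 * (D1 + D2) - 1e-10)
  }

  ## all alpha = 1: D reduces to the quadratic minimum-norm dual
  pr1 <- pr; pr1@alpha <- rep(1, length(pr@alpha))
  lam <- rnorm(nC) * 0.3
  Sfull <- matrix(0, length(fx$fov), length(fx$fov))
  for (k in seq_along(parc@parcels)) {
    v <- parc@parcels[[k]]
    Sfull[v, v] <- pr@eta[k, 3] * pr@Ck[[k]]
  }
  Dquad <- sum(lam * fx$m[, 3]) -
    0.5 * as.numeric(t(lam) %*% (fx$A %*% Sfull %*% t(fx$A) +
                                   diag(fx$noiseVar, nC)) %*% lam)
  expect_equal(dualValueAndGradient(lam, fx$m[, 3], fx$A, pr1,
                                    fx$noiseVar, 3)$D, Dquad,
               tolerance = 1e-9)
})

test_that("the dual maximizer is unique, exact for alpha = 1, zero for m = 0", {
  fx <- inverseFixture()
  sc <- mspScores(fx$m, fx$A)
  parc <- parcellate(fx$surface, fx$fov, sc, 8)
  mne <- mneSolve(fx$m, fx$A, kappa = 1, omega = 0.3,
                  noiseVar = rep(1, nrow(fx$A)))
  pr <- initSigmaK(fx$A, mne$j, parc, fx$surface, fx$fov)
  pr@alpha <- pmin(initAlpha(parc, sc), 0.9)
  nC <- nrow(fx$A)

  s0 <- solveLambda(numeric(nC), fx$A, pr, fx$noiseVar, 3)
  expect_true(all(s0$lambda == 0))

  ## restart invariance (uniqueness by concavity)
  set.seed(74)
  sA <- solveLambda(fx$m[, 3], fx$A, pr, fx$noiseVar, 3)
  sB <- solveLambda(fx$m[, 3], fx$A, pr, fx$noiseVar, 3,
                    lambda0 = rnorm(nC))
  expect_true(sA$converged && sB$converged)
  expect_lt(max(abs(sA$lambda - sB$lambda)) /
              max(abs(sA$lambda)), 1e-6)

  ## alpha = 1 closed form
  pr1 <- pr; pr1@alpha <- rep(1, length(pr@alpha))
  s1 <- solveLambda(fx$m[, 3], fx$A, pr1, fx$noiseVar, 3)
  Sfull <- matrix(0, length(fx$fov), length(fx$fov))
  for (k in seq_along(parc@parcels)) {
    v <- parc@parcels[[k]]
    Sfull[v, v] <- pr@eta[k, 3] * pr@Ck[[k]]
  }
  lamRef <- solve(fx$A %*% Sfull %*% t(fx$A) + diag(fx$noiseVar, nC),
                  fx$m[, 3])
  expect_lt(max(abs(s1$lambda - lamRef)) / max(abs(lamRef)), 1e-6)
})

test_that("posterior activation follows the tilted-posterior formula", {
  fx <- inverseFixture()
  sc <- mspScores(fx$m, fx$A)
  parc <- parcellate(fx$surface, fx$fov, sc, 8)
  mne <- mneSolve(fx$m, fx$A, kappa = 1, omega = 0.3,
                  noiseVar = rep(1, nrow(fx$A)))
  pr <- initSigmaK(fx$A, mne$j, parc, fx$surface, fx$fov)
  pr@alpha <- seq(0, 1, length.out = length(parc@parcels))
  nC <- nrow(fx$A)
  ## lambda = 0 -> alpha* = alpha; alpha in {0,1} are fixed points
  a0 <- posteriorAlpha(numeric(nC), pr, fx$A, tIndex = 2)
  expect_equal(a0, pr@alpha, tolerance = 1e-12)
  set.seed(75)
  lam <- rnorm(nC)
  aS <- posteriorAlpha(lam, pr, fx$A, tIndex = 2)
  expect_equal(aS[pr@alpha == 0], 0)
  expect_equal(aS[pr@alpha == 1], 1)
  ## evidence only increases activation; monotone in the prior alpha
  expect_true(all(aS >= pr@alpha - 1e-12))
  ## explicit formula check with the -q convention
  G <- nirsdot:::parcelGrams(fx$A, pr)
  k <- which(pr@alpha > 0 & pr@alpha < 1)[1]
  q <- 0.5 * pr@eta[k, 2] * as.numeric(t(lam) %*% G[[k]] %*% lam)
  expect_equal(aS[k], pr@alpha[k] /
                 (pr@alpha[k] + (1 - pr@alpha[k]) * exp(-q)))
})

test_that("the assembled source estimate obeys the per-parcel formula", {
  fx <- inverseFixture()
  sc <- mspScores(fx$m, fx$A)
  parc <- parcellate(fx$surface, fx$fov, sc, 8)
  mne <- mneSolve(fx$m, fx$A, kappa = 1, omega = 0.3,
                  noiseVar = rep(1, nrow(fx$A)))
  pr <- initSigmaK(fx$A, mne$j, parc, fx$surface, fx$fov)
  pr@alpha <- rep(0.5, length(parc@parcels))
  set.seed(76)
  lam <- rnorm(nrow(fx$A))
  aS <- posteriorAlpha(lam, pr, fx$A, tIndex = 1)
  j <- cmemSolution(lam, aS, pr, fx$A, 1)
  ## zero-activation parcels contribute exactly zero
  aS0 <- aS; aS0[2] <- 0
  j0 <- cmemSolution(lam, aS0, pr, fx$A, 1)
  expect_true(all(j0[parc@parcels[[2]]] == 0))
  ## linear in lambda for fixed alpha*
  expect_equal(cmemSolution(2 * lam, aS, pr, fx$A, 1), 2 * j,
               tolerance = 1e-12)
})

test_that("the full solver satisfies stationarity and the data-fit contract", {
  fx <- inverseFixture()
  sol <- cmemSolve(fx$m, fx$A, fx$surface, fx$fov, noiseVar = fx$noiseVar)
  expect_true(all(sol@converged))
  expect_true(all(sol@alphaStar >= 0 & sol@alphaStar <= 1))
  for (t in c(1, 10, 20)) {
    lhs <- fx$A %*% sol@j[, t] + fx$noiseVar * sol@lambda[, t]
    expect_lt(max(abs(lhs - fx$m[, t])), 1e-5 * max(abs(fx$m[, t])))
  }
})

test_that("relative entropy is zero at the prior and negative elsewhere", {
  S <- list(diag(3), diag(2))
  expect_equal(relativeEntropy(c(0.3, 0.7), S, c(0.3, 0.7), S), 0)
  expect_lt(relativeEntropy(c(0.4, 0.7), S, c(0.3, 0.7), S), 0)
  S2 <- list(2 * diag(3), diag(2))
  expect_lt(relativeEntropy(c(0.3, 0.7), S2, c(0.3, 0.7), S), 0)
  ## support mismatch -> -Inf sentinel
  expect_equal(relativeEntropy(c(0.3, 0.5), S, c(0, 0.5), S), -Inf)
  ## Gaussian-only two-parcel case against numeric integration
  s1 <- 1.7; s0 <- 1.0
  klNum <- stats::integrate(function(x) {
    p <- stats::dnorm(x, 0, sqrt(s1))
    p * (stats::dnorm(x, 0, sqrt(s1), log = TRUE) -
           stats::dnorm(x, 0, sqrt(s0), log = TRUE))
  }, -20, 20)$value
  got <- relativeEntropy(c(1, 1), list(matrix(s1), matrix(s1)),
                         c(1, 1), list(matrix(s0), matrix(s0)))
  expect_equal(got, -2 * klNum, tolerance = 1e-4)
})

test_that("surface-level hemoglobin recovery inverts its synthesis", {
  set.seed(77)
  wl <- c(685, 830)
  E <- extinctionCoefficients(wl)
  hbo <- matrix(rnorm(40), 10); hbr <- matrix(rnorm(40), 10)
  j1 <- E[1, "hbo"] * hbo + E[1, "hbr"] * hbr
  j2 <- E[2, "hbo"] * hbo + E[2, "hbr"] * hbr
  out <- surfaceMbll(j1, j2, wavelengths = wl)
  expect_lt(max(abs(out$hbo - hbo)), 1e-9)
  expect_lt(max(abs(out$hbr - hbr)), 1e-9)
  expect_equal(out$hbt, out$hbo + out$hbr)
  z <- surfaceMbll(matrix(0, 3, 2), matrix(0, 3, 2), wavelengths = wl)
  expect_true(all(z$hbo == 0) && all(z$hbt == 0))
  expect_error(surfaceMbll(j1, j2, extinction = matrix(1, 2, 2)),
               "ingular")
})
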