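test_that("the canonical HRF peaks at 5 s and undershoots at 15 s", {
  h <- canonicalHrf(0.01)
  t <- attr(h, "time")
  expect_equal(t[which.max(h)], 5)
  expect_equal(t[which.min(h)], 15)
  expect_equal(h[1], 0)               # zero at the origin
  expect_equal(max(h), 1)             # unit peak normalization
  expect_lt(min(h), 0)                # a true undershoot
  ## grid independence of the tuned extrema (coarser grid containing 5/15)
  h2 <- canonicalHrf(0.05)
  t2 <- attr(h2, "time")
  expect_equal(t2[which.max(h2)], 5)
  expect_equal(t2[which.min(h2)], 15)
})

test_that("design assembly produces the convolution of the event train", {
  fs <- 5; times <- seq(0, 199.8, by = 1 / fs)
  ## no events, constant only -> single all-ones column
  d0 <- buildDesign(data.frame(label = character(), onset = numeric(),
                               duration = numeric()), times,
                    confounds = "constant")
  expect_equal(ncol(d0$X), 1L)
  expect_true(all(d0$X[, 1] == 1))

  ## one 10 s block: task column equals boxcar (*) HRF by direct sum
  ev <- data.frame(label = "task", onset = 50, duration = 10)
  des <- buildDesign(ev, times, confounds = c("constant", "linear"))
  h <- canonicalHrf(1 / fs)
  box <- as.numeric(times >= 50 - 1e-9 & times <= 60 + 1e-9)
  oracle <- numeric(length(times))
  for (i in seq_along(times))      # direct convolution sum
    for (k in seq_len(min(i, length(h))))
      oracle[i] <- oracle[i] + h[k] * box[i - k + 1] / fs
  expect_lt(max(abs(des$X[, 1] - oracle)), 1e-9)

  ## two identical task regressors -> rank warning naming a column
  ev2 <- rbind(ev, data.frame(label = "task2", onset = 50, duration = 10))
  expect_warning(buildDesign(ev2, times, confounds = "constant"),
                 "rank deficient")
})

test_that("noise-free GLM recovers beta exactly; whitening reduces correctly", {
  fs <- 2; times <- seq(0, 299.5, by = 1 / fs)
  ev <- data.frame(label = "task", onset = seq(20, 250, 40), duration = 10)
  des <- buildDesign(ev, times, confounds = c("constant", "linear"))
  b0 <- c(3, 0.5, -1)
  y <- as.numeric(des$X %*% b0)
  fit <- fitGlm(matrix(y, 1), des, serial = "none")
  expect_lt(max(abs(fit@beta[, 1] - b0)), 1e-9)
  expect_equal(fit@dof[1], nrow(des$X) - 3)

  ## beta equals the generic normal-equations oracle on noisy data
  set.seed(41)
  y2 <- y + rnorm(length(y))
  f2 <- fitGlm(matrix(y2, 1), des, serial = "none")
  oracle <- solve(crossprod(des$X), crossprod(des$X, y2))
  expect_lt(max(abs(f2@beta[, 1] - oracle)), 1e-8)

  ## white residuals: prewhitening stays near the plain OLS fit
  f3 <- fitGlm(matrix(y2, 1), des, serial = "prewhiten")
  expect_lt(abs(f3@rho[1]), 0.15)
  expect_equal(f3@beta[, 1], f2@beta[, 1], tolerance = 0.05)
})

test_that("prewhitened estimates are unbiased under AR(1) noise", {
  set.seed(42)
  fs <- 2; times <- seq(0, 299.5, by = 1 / fs); n <- length(times)
  ev <- data.frame(label = "task", onset = seq(20, 250, 40), duration = 10)
  des <- buildDesign(ev, times, confounds = c("constant", "linear"))
  reps <- 200
  bs <- replicate(reps, {
    e <- as.numeric(stats::filter(rnorm(n), 0.6, "recursive"))
    fitGlm(matrix(2 * des$X[, 1] + e, 1), des, serial = "prewhiten")@beta[1, 1]
  })
  expect_lt(abs(mean(bs) - 2), 2 * sd(bs) / sqrt(reps))
})

test_that("precoloring and prewhitening agree with OLS on the identity case", {
  ## rho ~ 0 noise: the prewhitening operator is near-identity
  set.seed(43)
  fs <- 2; times <- seq(0, 149.5, by = 1 / fs)
  ev <- data.frame(label = "task", onset = c(20, 70, 120), duration = 10)
  des <- buildDesign(ev, times, confounds = "constant")
  y <- as.numeric(des$X %*% c(1, 0.2)) + rnorm(length(times))
  fN <- fitGlm(matrix(y, 1), des, serial = "none")
  fW <- fitGlm(matrix(y, 1), des, serial = "prewhiten")
  expect_equal(fW@beta, fN@beta, tolerance = 0.05)
  fC <- fitGlm(matrix(y, 1), des, serial = "precolor", dt = 1 / fs)
  expect_equal(dim(fC@beta), dim(fN@beta))
  expect_equal(fC@beta[1, 1], fN@beta[1, 1], tolerance = 0.3)
})

test_that("contrasts, p-values and corrections behave", {
  set.seed(44)
  fs <- 2; times <- seq(0, 299.5, by = 1 / fs); n <- length(times)
  ev <- data.frame(label = "task", onset = seq(20, 250, 40), duration = 10)
  des <- buildDesign(ev, times, confounds = "constant")
  Y <- matrix(rnorm(8 * n), 8)
  Y[1, ] <- Y[1, ] + 3 * des$X[, 1]
  fit <- fitGlm(Y, des, serial = "none")

  z <- testContrast(fit, c(0, 0))
  expect_true(all(z$effect == 0))
  expect_true(all(z$p == 1))

  res <- testContrast(fit, c(1, 0), correction = "fdr")
  expect_true(res$significant[1])
  expect_true(all(res$pCorrected >= res$p))

  ## BH step-up against the brute-force definition
  p <- c(0.001, 0.01, 0.02, 0.03, 0.5)
  bhBrute <- function(p, alpha) {
    o <- order(p); m <- length(p)
    k <- which(p[o] <= alpha * seq_len(m) / m)
    if (!length(k)) 0L else max(k)
  }
  expect_equal(bhBrute(p, 0.05), 4L)
  expect_equal(sum(stats::p.adjust(p, "BH") < 0.05), 4L)

  ## Bonferroni rejections are a subset of BH rejections
  for (r in 1:20) {
    pp <- runif(20)^2
    expect_true(all(which(stats::p.adjust(pp, "bonferroni") < 0.05) %in%
                    which(stats::p.adjust(pp, "BH") < 0.05)))
  }
  expect_error(testContrast(fit, c(1, 0, 0)), "length")
})

test_that("group-level random effects reduce to the one-sample t test", {
  set.seed(45)
  ## identical subjects, nonzero effect -> guarded large t, tiny p
  same <- matrix(1, 5, 3)
  g <- groupLevel(same)
  expect_true(all(g$t >= 1e6))
  expect_true(all(g$p < 1e-6))
  ## N(1,1) subjects: mean within 2 SE of 1
  M <- matrix(rnorm(20 * 4, mean = 1), 20)
  g2 <- groupLevel(M)
  se <- apply(M, 2, sd) / sqrt(20)
  expect_true(all(abs(g2$effect - 1) <= 2.5 * se))
  expect_equal(g2$t, unname(apply(M, 2, function(x)
    t.test(x)$statistic)), tolerance = 1e-9)
  ## sign-flip antisymmetry
  g3 <- groupLevel(-M)
  expect_equal(g3$t, -g2$t)
  expect_error(groupLevel(M[1, , drop = FALSE]), "2 subjects")
})
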