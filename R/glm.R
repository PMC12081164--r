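#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two peak-normalized gamma kernels with the time-to-peak
#' parameters tuned (small Newton solve at construction) so that, sampled
#' on any grid containing them, the positive peak falls at exactly 5 s and
#' the undershoot minimum at exactly 15 s. The kernel is normalized to unit
#' peak amplitude and is zero at t = 0.
#'
#' @param dt sampling step (s).
#' @param duration kernel length (s, default 32).
#' @param ratio undershoot-to-peak amplitude ratio (default 1/6).
#' @return numeric kernel sampled at \code{seq(0, duration, by = dt)}, with
#'   attribute \code{time}.
#' @export
canonicalHrf <- function(dt, duration = 32, ratio = 1 / 6) {
  if (dt <= 0) stop("dt must be positive")
  a1 <- 6; a2 <- 12
  ## gamma shapes parameterized by their peak time p: g(t) = (t/p)^a e^{-a(t-p)/p}
  g <- function(t, a, p) ifelse(t <= 0, 0, exp(a * (log(t / p) - (t - p) / p)))
  dg <- function(t, a, p) g(t, a, p) * a * (1 / t - 1 / p)
  ## tune p1, p2 so the combined derivative vanishes at 5 and 15 s
  p <- c(5, 15)
  f <- function(p) c(dg(5, a1, p[1]) - ratio * dg(5, a2, p[2]),
                     dg(15, a1, p[1]) - ratio * dg(15, a2, p[2]))
  for (it in 1:40) {
    f0 <- f(p)
    if (max(abs(f0)) < 1e-14) break
    J <- matrix(0, 2, 2)
    h <- 1e-6
    for (j in 1:2) {
      pj <- p; pj[j] <- pj[j] + h
      J[, j] <- (f(pj) - f0) / h
    }
    p <- p - solve(J, f0)
  }
  t <- seq(0, duration, by = dt)
  k <- g(t, a1, p[1]) - ratio * g(t, a2, p[2])
  k <- k / max(k)
  attr(k, "time") <- t
  attr(k, "peaks") <- p
  k
}

#' Assemble a GLM design matrix
#'
#' Task regressors are boxcar event trains convolved with the canonical
#' HRF (one column per condition), followed by the requested confounds in
#' order: constant, linear trend, discrete-cosine drift set, mean
#' short-channel signal.
#'
#' @param events event table (label, onset, duration).
#' @param times sample times (s, uniform).
#' @param confounds character subset of
#'   \code{c("constant", "linear", "dct", "short_mean")}.
#' @param dctCutoffS period cutoff (s) for the DCT drift set.
#' @param shortMean numeric vector (the mean superficial signal), required
#'   when \code{"short_mean"} is requested.
#' @param hrfDuration canonical HRF length (s).
#' @return list of class \code{nirsDesign} with elements \code{X},
#'   \code{roles}, \code{rank}; a warning names collinear columns.
#' @export
buildDesign <- function(events, times, confounds = c("constant", "linear"),
                        dctCutoffS = 200, shortMean = NULL,
                        hrfDuration = 32) {
  n <- length(times)
  dt <- stats::median(diff(times))
  stopifnot(all(confounds %in% c("constant", "linear", "dct", "short_mean")))
  h <- canonicalHrf(dt, hrfDuration)
  cols <- list(); roles <- character()
  for (lab in unique(events$label)) {
    sel <- events[events$label == lab, , drop = FALSE]
    if (any(sel$onset < times[1] - 1e-9) ||
        any(sel$onset > times[n] + 1e-9))
      stop("event outside the recording: ", lab)
    box <- numeric(n)
    for (i in seq_len(nrow(sel))) {
      idx <- which(times >= sel$onset[i] - 1e-9 &
                   times <= sel$onset[i] + sel$duration[i] + 1e-9)
      if (!length(idx))                       # instantaneous event
        idx <- which.min(abs(times - sel$onset[i]))
      box[idx] <- 1
    }
    task <- convolveTrunc(box, h) * dt
    cols[[paste0("task:", lab)]] <- task
    roles <- c(roles, "task")
  }
  if ("constant" %in% confounds) {
    cols[["constant"]] <- rep(1, n); roles <- c(roles, "constant")
  }
  if ("linear" %in% confounds) {
    cols[["linear"]] <- seq(-1, 1, length.out = n)
    roles <- c(roles, "trend")
  }
  if ("dct" %in% confounds) {
    kMax <- floor(2 * n * dt / dctCutoffS - 1e-9)
    i <- seq_len(n)
    for (k in seq_len(max(kMax, 0))) {
      cols[[paste0("dct", k)]] <- cos(pi * k * (2 * i - 1) / (2 * n))
      roles <- c(roles, "dct")
    }
  }
  if ("short_mean" %in% confounds) {
    if (is.null(shortMean))
      stop("shortMean is required for the short_mean confound")
    cols[["short_mean"]] <- as.numeric(shortMean)
    roles <- c(roles, "short")
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("design matrix is rank deficient; offending columns: ",
            paste(drop, collapse = ", "))
  }
  structure(list(X = X, roles = roles, rank = qrX$rank),
            class = "nirsDesign")
}

convolveTrunc <- function(x, kernel) {
  n <- length(x)
  stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
}

#' Fit the channel-wise general linear model
#'
#' Ordinary least squares per channel after optional handling of serial
#' correlation: \code{"precolor"} smooths data and model with the canonical
#' HRF kernel (unit-sum gain); \code{"prewhiten"} estimates a per-channel
#' AR(1) coefficient from the OLS residual lag-1 autocorrelation, applies
#' the corresponding first-difference whitening operator and refits once.
#'
#' @param Y channel x time data matrix (or an \code{OpticalDensity} /
#'   \code{HemoglobinSeries}; hemoglobin input uses \code{what}).
#' @param design a \code{\link{buildDesign}} result or a plain time x
#'   regressor matrix.
#' @param serial \code{"none"}, \code{"precolor"} or \code{"prewhiten"}.
#' @param dt sample step (s), needed for precoloring with matrix input.
#' @param what chromophore for hemoglobin input.
#' @return a \code{\linkS4class{GLMResult}}.
#' @export
fitGlm <- function(Y, design, serial = c("none", "precolor", "prewhiten"),
                   dt = NULL, what = "hbo") {
  serial <- match.arg(serial)
  if (is(Y, "OpticalDensity")) {
    dt <- stats::median(diff(Y@times)); Y <- Y@od
  } else if (is(Y, "HemoglobinSeries")) {
    dt <- stats::median(diff(Y@times)); Y <- slot(Y, what)
  }
  X <- if (inherits(design, "nirsDesign")) design$X else as.matrix(design)
  n <- nrow(X)
  if (ncol(Y) != n) stop("columns of Y must match rows of X")
  nCh <- nrow(Y)
  p <- ncol(X)
  rk <- qr(X)$rank
  dof <- n - rk
  if (dof <= 0) stop("no residual degrees of freedom")

  precolorOp <- NULL
  if (serial == "precolor") {
    if (is.null(dt)) stop("dt required for precoloring")
    h <- canonicalHrf(dt)
    h <- h / sum(h)
    precolorOp <- function(M)
      apply(M, 2, function(col) convolveTrunc(col, h))
  }

  beta <- matrix(NA_real_, p, nCh,
                 dimnames = list(colnames(X), rownames(Y)))
  betaCov <- vector("list", nCh)
  sigma2 <- numeric(nCh)
  rho <- rep(NA_real_, nCh)
  for (ci in seq_len(nCh)) {
    y <- Y[ci, ]
    Xs <- X; ys <- y
    if (serial == "precolor") {
      Xs <- precolorOp(X); ys <- as.numeric(precolorOp(matrix(y)))
    } else if (serial == "prewhiten") {
      r <- stats::lm.fit(X, y)$residuals
      a <- sum(r[-1] * r[-length(r)]) / sum(r^2)
      if (abs(a) >= 1) {
        warning("AR(1) coefficient clipped to +/-0.99")
        a <- sign(a) * 0.99
      }
      rho[ci] <- a
      W <- function(M) {
        M <- as.matrix(M)
        rbind(sqrt(1 - a^2) * M[1, , drop = FALSE],
              M[-1, , drop = FALSE] - a * M[-nrow(M), , drop = FALSE])
      }
      Xs <- W(X); ys <- as.numeric(W(matrix(y)))
    }
    fit <- stats::lm.fit(Xs, ys)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    res <- fit$residuals
    s2 <- sum(res^2) / dof
    XtX <- crossprod(Xs)
    Vinv <- tryCatch(solve(XtX), error = function(e)
      MASS_ginv(XtX))
    V <- s2 * Vinv
    beta[, ci] <- b
    betaCov[[ci]] <- (V + t(V)) / 2
    sigma2[ci] <- s2
  }
  new("GLMResult", beta = beta, betaCov = betaCov, sigma2 = sigma2,
      dof = rep(dof, nCh), serial = serial, rho = rho, X = X,
      regressors = colnames(X))
}

## Moore-Penrose fallback for (rare) singular normal equations.
MASS_ginv <- function(M, tol = 1e-12) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Contrast testing with multiple-comparison correction
#'
#' Student t test of a linear combination of GLM weights per channel, with
#' optional Bonferroni or Benjamini-Hochberg (FDR) correction across
#' channels.
#'
#' @param result a \code{GLMResult}.
#' @param contrast numeric vector, one weight per regressor.
#' @param correction \code{"none"}, \code{"bonferroni"} or \code{"fdr"}.
#' @param alpha significance level for the \code{significant} column.
#' @return data.frame: channel, effect, se, t, p, pCorrected, significant.
#'   Channels with zero contrast variance get \code{NA} statistics (a zero
#'   effect with zero variance reports p = 1).
#' @export
testContrast <- function(result, contrast,
                         correction = c("none", "bonferroni", "fdr"),
                         alpha = 0.05) {
  correction <- match.arg(correction)
  p <- nrow(result@beta)
  if (length(contrast) != p)
    stop("contrast length must equal the regressor count (", p, ")")
  nCh <- ncol(result@beta)
  eff <- as.numeric(crossprod(contrast, result@beta))
  varc <- vapply(result@betaCov, function(V)
    as.numeric(t(contrast) %*% V %*% contrast), numeric(1))
  se <- sqrt(pmax(varc, 0))
  tval <- ifelse(se > 0, eff / se, NA_real_)
  pval <- 2 * stats::pt(-abs(tval), df = result@dof)
  pval[se == 0 & eff == 0] <- 1
  tval[se == 0 & eff == 0] <- 0
  pAdj <- switch(correction,
                 none = pval,
                 bonferroni = stats::p.adjust(pval, "bonferroni"),
                 fdr = stats::p.adjust(pval, "BH"))
  data.frame(channel = seq_len(nCh), effect = eff, se = se, t = tval,
             p = pval, pCorrected = pAdj,
             significant = !is.na(pAdj) & pAdj < alpha)
}

#' Group-level random-effects test
#'
#' Summary-statistics reduction of the mixed model: subject-level contrast
#' estimates are combined with a one-sample t test per channel (or vertex).
#'
#' @param subjectContrasts numeric matrix, subjects x channels, of
#'   subject-level contrast effects.
#' @return data.frame: channel, effect, t, p, dof. Degenerate zero
#'   between-subject variance with a nonzero mean is guarded to a large
#'   finite t with p < 1e-6.
#' @export
groupLevel <- function(subjectContrasts) {
  M <- as.matrix(subjectContrasts)
  nS <- nrow(M)
  if (nS < 2L) stop("group analysis requires at least 2 subjects")
  m <- colMeans(M)
  s <- apply(M, 2, stats::sd)
  se <- s / sqrt(nS)
  tval <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * 1e12))
  pval <- ifelse(se > 0, 2 * stats::pt(-abs(tval), df = nS - 1),
                 ifelse(m == 0, 1, 1e-300))
  data.frame(channel = seq_len(ncol(M)), effect = m, t = tval, p = pval,
             dof = nS - 1)
}
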