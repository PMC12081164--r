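## Maximum-entropy-on-the-mean reconstruction with a parcel-wise
## Bernoulli-Gaussian prior, solved per time sample through its concave
## dual in channel space.

#' Multiple-source prelocalization scores
#'
#' Projection scores in [0, 1] per vertex: the data window (optionally
#' whitened by the channel noise) is reduced to its principal subspace
#' (95\% energy) and every unit-normalized forward column is scored by the
#' squared norm of its projection onto that subspace. Scores are invariant
#' to global scaling of the data.
#'
#' @param m channel x time data window (>= 2 samples).
#' @param A channel x vertex sensitivity matrix.
#' @param noiseVar optional per-channel variances used to whiten.
#' @param energy principal-subspace energy fraction (default 0.95).
#' @return numeric per-vertex scores in [0, 1].
#' @export
mspScores <- function(m, A, noiseVar = NULL, energy = 0.95) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("need a window of at least 2 samples")
  if (!is.null(noiseVar)) {
    w <- 1 / sqrt(noiseVar)
    m <- m * w
    A <- A * w
  }
  if (max(abs(m)) == 0) {
    warning("zero data window; returning uniform scores 0.5")
    return(rep(0.5, ncol(A)))
  }
  sv <- svd(m)
  ## signal-subspace dimension: energy fraction of the above-noise-floor
  ## spectrum (floor = median squared singular value). With little noise
  ## this reduces to the plain energy rule; with realistic noise it keeps
  ## the subspace from absorbing noise dimensions, which would push every
  ## score toward dim(subspace)/Nc.
  pw <- sv$d^2
  excess <- pmax(pw - stats::median(pw), 0)
  if (sum(excess) == 0) excess <- pw
  rel <- cumsum(excess) / sum(excess)
  k <- which(rel >= energy)[1]
  U <- sv$u[, seq_len(k), drop = FALSE]
  nrm <- sqrt(colSums(A^2))
  An <- sweep(A, 2, pmax(nrm, .Machine$double.xmin), "/")
  sc <- colSums((crossprod(U, An))^2)
  sc[nrm == 0] <- 0
  pmin(pmax(sc, 0), 1)
}

#' Data-driven parcellation by region growing
#'
#' Greedy region growing over the field-of-view submesh: the highest
#' unassigned prelocalization score seeds a parcel, which absorbs all
#' still-unassigned vertices within a geodesic radius of the seed
#' (breadth-first through unassigned vertices only, so parcels are
#' edge-connected); ties go to the earlier seed because assigned vertices
#' are never revisited. The neighborhood radius is tuned automatically by
#' bisection so the parcel count is as close as possible to
#' \code{targetK}.
#'
#' @param surface the full \code{CorticalSurface}.
#' @param fov integer field-of-view vertex indices.
#' @param scores per-FOV-vertex prelocalization scores.
#' @param targetK desired number of parcels (typically the channel count).
#' @param radiusTolMm bisection stopping width for the radius (mm).
#' @return a \code{\linkS4class{Parcellation}} (indices into the FOV); the
#'   tuned radius is in \code{neighborhoodOrder} (mm).
#' @export
parcellate <- function(surface, fov, scores, targetK, radiusTolMm = 0.05) {
  nb <- fovNeighbors(surface, fov)
  if (length(scores) != length(fov))
    stop("scores must match the field of view")
  comps <- connectedComponents(nb)
  if (length(comps) > 1L)
    warning("field of view is disconnected (", length(comps),
            " components); parcellating components independently")
  coords <- surface@vertices[fov, , drop = FALSE]
  kOf <- function(r) max(growParcels(nb, coords, scores, r))
  lo <- 0                                   # every vertex its own parcel
  hi <- 2 * max(stats::dist(coords[seq(1, nrow(coords),
                                       length.out = min(60, nrow(coords))), ,
                                   drop = FALSE]))
  bestR <- lo; bestGap <- abs(kOf(lo) - targetK)
  consider <- function(r) {
    gap <- abs(kOf(r) - targetK)
    if (gap < bestGap) { bestGap <<- gap; bestR <<- r }
    gap
  }
  consider(hi)
  ## K(r) is nonincreasing in r: bisect toward K = targetK
  while (hi - lo > radiusTolMm) {
    mid <- (lo + hi) / 2
    consider(mid)
    if (kOf(mid) > targetK) lo <- mid else hi <- mid
  }
  assign <- growParcels(nb, coords, scores, bestR)
  parcels <- split(seq_along(assign), assign)
  names(parcels) <- NULL
  new("Parcellation", assignment = as.integer(assign),
      parcels = lapply(parcels, as.integer),
      mspScores = as.numeric(scores), neighborhoodOrder = bestR)
}

## Neighbor lists over the FOV submesh, in FOV-local indices.
fovNeighbors <- function(surface, fov) {
  f <- surface@faces
  keep <- matrix(match(f, fov), nrow(f), 3)
  nb <- vector("list", length(fov))
  addEdge <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    for (i in which(ok)) nb[[a[i]]] <<- c(nb[[a[i]]], b[i])
  }
  addEdge(keep[, 1], keep[, 2]); addEdge(keep[, 2], keep[, 1])
  addEdge(keep[, 2], keep[, 3]); addEdge(keep[, 3], keep[, 2])
  addEdge(keep[, 1], keep[, 3]); addEdge(keep[, 3], keep[, 1])
  lapply(nb, function(x) sort(unique(x)))
}

connectedComponents <- function(nb) {
  n <- length(nb)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in nb[[v]]) if (!comp[u]) { comp[u] <- cur; queue <- c(queue, u) }
    }
  }
  split(seq_len(n), comp)
}

## Greedy growth by geodesic radius: Dijkstra-like expansion through
## unassigned vertices only, with path lengths along mesh edges.
growParcels <- function(nb, coords, scores, r) {
  n <- length(nb)
  assign <- integer(n)
  ord <- order(-scores, seq_len(n))     # deterministic: score then index
  k <- 0L
  for (seed in ord) {
    if (assign[seed]) next
    k <- k + 1L
    assign[seed] <- k
    dist <- rep(Inf, n); dist[seed] <- 0
    frontier <- seed
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in nb[[v]]) {
          if (assign[u] && u != seed) next
          du <- dist[v] + sqrt(sum((coords[v, ] - coords[u, ])^2))
          if (du <= r && du < dist[u] - 1e-12) {
            dist[u] <- du
            if (!assign[u]) { assign[u] <- k; nxt <- c(nxt, u) }
            else if (assign[u] == k) nxt <- c(nxt, u)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  assign
}

#' Initialize parcel activation probabilities
#'
#' alpha_k is the median prelocalization score within the parcel; any
#' alpha reaching the 0.8 threshold is set to exactly 1 (the parcel is
#' considered fully active).
#'
#' @param parcellation a \code{Parcellation}.
#' @param scores per-FOV-vertex scores (default: those stored in the
#'   parcellation).
#' @param threshold promotion threshold (default 0.8, boundary included).
#' @return numeric per-parcel alpha.
#' @export
initAlpha <- function(parcellation, scores = parcellation@mspScores,
                      threshold = 0.8) {
  alpha <- vapply(parcellation@parcels,
                  function(v) stats::median(scores[v]), numeric(1))
  alpha[alpha >= threshold] <- 1
  pmin(pmax(alpha, 0), 1)
}

## Row-normalized one-step diffusion smoother within a parcel:
## W = (1 - sigma) I + sigma * degree-normalized adjacency. Isolated
## vertices keep weight 1 on themselves.
diffusionSmoother <- function(nb, parcel, sigma) {
  n <- length(parcel)
  W <- diag(1 - sigma, n)
  pos <- match(seq_along(nb), parcel)
  for (i in seq_len(n)) {
    loc <- match(nb[[parcel[i]]], parcel)
    loc <- loc[!is.na(loc)]
    if (length(loc)) W[i, loc] <- sigma / length(loc)
    else W[i, i] <- 1
  }
  W
}

#' Initialize the parcel covariance structure
#'
#' Builds, per parcel, \code{Sigma_k(t) = W' Lambda W * eta_k(t)}:
#' \code{W} is a row-normalized one-step mesh-diffusion smoother with
#' weight \code{sigma}; \code{Lambda} is the depth-weighting diagonal
#' \code{diag(A_k' A_k)^(-omega)}; and \code{eta_k(t)} is 5\% of the mean
#' squared max-normalized minimum-norm estimate within the parcel.
#'
#' @param A channel x FOV-vertex sensitivity matrix.
#' @param jMne FOV-vertex x time minimum-norm solution (computed with the
#'   identity noise covariance).
#' @param parcellation a \code{Parcellation}.
#' @param surface,fov mesh context for the diffusion smoother.
#' @param sigma diffusion smoothness (default 0.6).
#' @param omega depth-weighting exponent (default 0.3).
#' @param energyFraction the eta scale factor (default 0.05).
#' @return a \code{\linkS4class{MEMPrior}} with unit alpha (set it with
#'   \code{\link{initAlpha}}).
#' @export
initSigmaK <- function(A, jMne, parcellation, surface, fov, sigma = 0.6,
                       omega = 0.3, energyFraction = 0.05) {
  parcels <- parcellation@parcels
  if (any(!lengths(parcels))) stop("empty parcel in parcellation")
  nb <- fovNeighbors(surface, fov)
  jMne <- as.matrix(jMne)
  mx <- apply(abs(jMne), 2, max)
  jn <- sweep(jMne, 2, pmax(mx, .Machine$double.xmin), "/")
  jn[, mx == 0] <- 0
  C <- vector("list", length(parcels))
  eta <- matrix(0, length(parcels), ncol(jMne))
  for (k in seq_along(parcels)) {
    v <- parcels[[k]]
    W <- diffusionSmoother(nb, v, sigma)
    g <- colSums(A[, v, drop = FALSE]^2)
    lam <- numeric(length(g))
    lam[g > 0] <- g[g > 0]^(-omega)
    C[[k]] <- crossprod(W, lam * W)
    eta[k, ] <- energyFraction * colMeans(jn[v, , drop = FALSE]^2)
  }
  new("MEMPrior", parcellation = parcellation,
      alpha = rep(1, length(parcels)), Ck = C, eta = eta, sigma = sigma,
      omega = omega)
}

#' Free energy of one parcel
#'
#' \code{F(s) = log((1 - alpha) + alpha * exp(s' Sigma s / 2))}, evaluated
#' with overflow guarding. Inactive parcels (alpha = 0) have zero free
#' energy; alpha = 1 reduces to the quadratic form.
#'
#' @param s numeric vector (the parcel back-projection \code{A_k' lambda}).
#' @param alpha activation probability.
#' @param Sigma parcel covariance.
#' @return scalar free energy.
#' @export
freeEnergy <- function(s, alpha, Sigma) {
  q <- 0.5 * as.numeric(t(s) %*% Sigma %*% s)
  logExpMix(alpha, q)
}

## log((1-a) + a e^q), stable for large q
logExpMix <- function(alpha, q) {
  if (alpha <= 0) return(0)
  if (alpha >= 1) return(q)
  if (q < 30) log1p(alpha * expm1(q))
  else q + log(alpha) + log1p((1 - alpha) / alpha * exp(-q))
}

## posterior weight w = a e^q / ((1-a) + a e^q), stable
mixWeight <- function(alpha, q) {
  if (alpha <= 0) return(0)
  if (alpha >= 1) return(1)
  1 / (1 + exp(log(1 - alpha) - log(alpha) - q))
}

## Per-sample dual pieces. G[[k]] = A_k C_k A_k' (channel space), scaled by
## eta at evaluation time.
dualPieces <- function(lambda, m, G, etaT, alpha, noiseVar,
                       wantHessian = FALSE) {
  nC <- length(m)
  Dval <- sum(lambda * m) - 0.5 * sum(noiseVar * lambda^2)
  grad <- m - noiseVar * lambda
  H <- if (wantHessian) diag(noiseVar, nC) else NULL
  w <- numeric(length(G))
  for (k in seq_along(G)) {
    if (etaT[k] <= 0 || alpha[k] <= 0) next
    Gl <- etaT[k] * (G[[k]] %*% lambda)
    q <- 0.5 * sum(lambda * Gl)
    Dval <- Dval - logExpMix(alpha[k], q)
    wk <- mixWeight(alpha[k], q)
    w[k] <- wk
    grad <- grad - wk * Gl
    if (wantHessian)
      H <- H + wk * etaT[k] * G[[k]] + wk * (1 - wk) * tcrossprod(Gl)
  }
  list(D = Dval, grad = as.numeric(grad), H = H, w = w)
}

#' Dual objective and gradient of the maximum-entropy problem
#'
#' \code{D(lambda) = lambda'm - sum_k F_k(A_k' lambda) - lambda' Sigma_d
#' lambda / 2}, with its exact gradient. \code{D} is concave with a unique
#' maximizer.
#'
#' @param lambda channel-dimension vector.
#' @param m data vector for the sample.
#' @param A channel x FOV-vertex sensitivity matrix.
#' @param prior a \code{MEMPrior}.
#' @param noiseVar per-channel noise variances.
#' @param tIndex time index selecting the eta column.
#' @return list with \code{D} and \code{grad}.
#' @export
dualValueAndGradient <- function(lambda, m, A, prior, noiseVar,
                                 tIndex = 1L) {
  if (any(!is.finite(lambda))) stop("non-finite lambda")
  G <- parcelGrams(A, prior)
  p <- dualPieces(lambda, m, G, prior@eta[, tIndex], prior@alpha, noiseVar)
  list(D = p$D, grad = p$grad)
}

parcelGrams <- function(A, prior) {
  lapply(seq_along(prior@Ck), function(k) {
    v <- prior@parcellation@parcels[[k]]
    Ak <- A[, v, drop = FALSE]
    Ak %*% prior@Ck[[k]] %*% t(Ak)
  })
}

#' Maximize the dual for one time sample
#'
#' Damped Newton ascent from \code{lambda = 0} with backtracking line
#' search; the Hessian is available in closed form, so convergence to the
#' unique maximizer is fast. Convergence when the gradient sup-norm falls
#' below \code{tol * (1 + max|m|)}.
#'
#' @param m data vector for the sample.
#' @param A sensitivity matrix.
#' @param prior a \code{MEMPrior}.
#' @param noiseVar per-channel noise variances.
#' @param tIndex time index for eta.
#' @param tol,maxIter convergence controls.
#' @param lambda0 starting point.
#' @return list: \code{lambda}, \code{converged}, \code{iterations},
#'   \code{D}, \code{alphaStar}.
#' @export
solveLambda <- function(m, A, prior, noiseVar, tIndex = 1L, tol = 1e-7,
                        maxIter = 500L, lambda0 = NULL) {
  G <- parcelGrams(A, prior)
  solveLambdaG(m, G, prior@eta[, tIndex], prior@alpha, noiseVar, tol,
               maxIter, lambda0)
}

solveLambdaG <- function(m, G, etaT, alpha, noiseVar, tol = 1e-7,
                         maxIter = 500L, lambda0 = NULL) {
  nC <- length(m)
  lambda <- if (is.null(lambda0)) numeric(nC) else lambda0
  thresh <- tol * (1 + max(abs(m)))
  converged <- FALSE
  p <- dualPieces(lambda, m, G, etaT, alpha, noiseVar, wantHessian = TRUE)
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    if (max(abs(p$grad)) <= thresh) { converged <- TRUE; break }
    step <- tryCatch(solve(p$H, p$grad), error = function(e)
      p$grad / max(diag(p$H)))
    t <- 1
    repeat {
      cand <- lambda + t * step
      pc <- dualPieces(cand, m, G, etaT, alpha, noiseVar,
                       wantHessian = TRUE)
      if (is.finite(pc$D) && pc$D >= p$D - 1e-12) break
      t <- t / 2
      if (t < 1e-12) { pc <- p; cand <- lambda; break }
    }
    if (identical(cand, lambda)) break
    lambda <- cand; p <- pc
  }
  if (max(abs(p$grad)) <= thresh) converged <- TRUE
  list(lambda = lambda, converged = converged, iterations = it, D = p$D,
       w = p$w)
}

#' Posterior parcel activation probabilities
#'
#' \code{alpha*_k = alpha_k / (alpha_k + (1 - alpha_k) exp(-q))} with
#' \code{q = lambda*' A_k Sigma_k A_k' lambda* / 2}: the tilted posterior
#' of the Bernoulli-Gaussian prior. It reduces to alpha at lambda = 0 and
#' increases with the evidence q.
#'
#' @param lambda the dual maximizer.
#' @param prior a \code{MEMPrior}.
#' @param A sensitivity matrix.
#' @param noiseVar unused; kept for signature symmetry.
#' @param tIndex time index for eta.
#' @return per-parcel alpha* in [0, 1].
#' @export
posteriorAlpha <- function(lambda, prior, A, noiseVar = NULL,
                           tIndex = 1L) {
  G <- parcelGrams(A, prior)
  etaT <- prior@eta[, tIndex]
  vapply(seq_along(G), function(k) {
    q <- 0.5 * etaT[k] * as.numeric(t(lambda) %*% G[[k]] %*% lambda)
    mixWeight(prior@alpha[k], q)
  }, numeric(1))
}

#' Assemble the posterior source estimate
#'
#' \code{j*_k(t) = alpha*_k(t) Sigma_k A_k' lambda*(t)} per parcel;
#' parcels with alpha = 0 contribute exactly zero.
#'
#' @param lambda dual maximizer for the sample.
#' @param alphaStar posterior activations.
#' @param prior a \code{MEMPrior}.
#' @param A sensitivity matrix.
#' @param tIndex time index for eta.
#' @return FOV-vertex source vector.
#' @export
cmemSolution <- function(lambda, alphaStar, prior, A, tIndex = 1L) {
  out <- numeric(ncol(A))
  for (k in seq_along(prior@Ck)) {
    if (alphaStar[k] <= 0) next
    v <- prior@parcellation@parcels[[k]]
    Ak <- A[, v, drop = FALSE]
    out[v] <- alphaStar[k] * prior@eta[k, tIndex] *
      as.numeric(prior@Ck[[k]] %*% crossprod(Ak, lambda))
  }
  out
}

#' Full maximum-entropy reconstruction
#'
#' Pipeline: prelocalization scores, region-growing parcellation (target
#' K = channel count), alpha initialization, identity-noise minimum-norm
#' solution for the energy scales, prior assembly, then per-sample dual
#' maximization and posterior assembly.
#'
#' @param m channel x time data window.
#' @param A channel x FOV-vertex sensitivity matrix.
#' @param surface,fov mesh context.
#' @param noiseVar per-channel noise variances.
#' @param targetK parcel-count target (default: number of channels).
#' @param omega depth-weighting exponent.
#' @param sigma diffusion smoothness.
#' @param initKappa regularization for the internal minimum-norm solution.
#' @param alpha optional per-parcel activation override (e.g. all 1 for
#'   the closed-form reduction check).
#' @param tol,maxIter dual solver controls.
#' @return a \code{\linkS4class{MEMSolution}}; the prior and parcellation
#'   are attached as attributes \code{prior}.
#' @export
cmemSolve <- function(m, A, surface, fov, noiseVar = rep(1, nrow(A)),
                      targetK = nrow(A), omega = 0.3, sigma = 0.6,
                      initKappa = "lcurve", alpha = NULL, tol = 1e-7,
                      maxIter = 500L) {
  m <- as.matrix(m)
  scores <- mspScores(m, A, noiseVar)
  parc <- parcellate(surface, fov, scores, targetK)
  mne <- mneSolve(m, A, kappa = initKappa, omega = omega,
                  noiseVar = rep(1, nrow(A)))
  prior <- initSigmaK(A, mne$j, parc, surface, fov, sigma, omega)
  prior@alpha <- if (is.null(alpha)) initAlpha(parc) else
    rep(alpha, length.out = length(parc@parcels))
  G <- parcelGrams(A, prior)
  nT <- ncol(m); nC <- nrow(A); K <- length(prior@Ck)
  ## The prior energy scales eta are defined on the max-normalized
  ## minimum-norm solution, so the dual is solved in the units in which
  ## that normalized solution lives: data and noise covariance are scaled
  ## by the per-sample normalizer s(t) = max |j_mne(., t)| and the source
  ## estimate is scaled back afterwards.
  s <- apply(abs(mne$j), 2, max)
  s[s == 0] <- 1
  lambda <- matrix(0, nC, nT)
  alphaStar <- matrix(0, K, nT)
  j <- matrix(0, ncol(A), nT)
  dualValue <- numeric(nT)
  converged <- logical(nT)
  iterations <- integer(nT)
  for (t in seq_len(nT)) {
    sol <- solveLambdaG(m[, t] / s[t], G, prior@eta[, t], prior@alpha,
                        noiseVar / s[t]^2, tol, maxIter)
    lambda[, t] <- sol$lambda / s[t]
    alphaStar[, t] <- pmin(pmax(sol$w, 0), 1)
    j[, t] <- s[t] * cmemSolution(sol$lambda, alphaStar[, t], prior, A, t)
    dualValue[t] <- sol$D
    converged[t] <- sol$converged
    iterations[t] <- sol$iterations
  }
  out <- new("MEMSolution", lambda = lambda, alphaStar = alphaStar, j = j,
             dualValue = dualValue, converged = converged,
             iterations = iterations)
  attr(out, "prior") <- prior
  attr(out, "scale") <- s
  out
}

#' Relative entropy of a Bernoulli-Gaussian distribution against the prior
#'
#' Negated Kullback-Leibler divergence, summed over parcels, between two
#' distributions of the spike-and-slab family (optionally with a mean
#' shift in the active component). Because the Dirac atom and the
#' continuous component are mutually singular the divergence decomposes
#' exactly into the Bernoulli part plus the weighted Gaussian part. The
#' value is 0 iff the distribution equals the prior, negative otherwise;
#' support mismatches (mass where the prior has none) return \code{-Inf}.
#'
#' @param alpha,Sigma per-parcel activation probabilities and covariance
#'   list of the evaluated distribution.
#' @param refAlpha,refSigma the prior's parameters.
#' @param mean optional list of active-component means (default zero).
#' @return scalar relative entropy (<= 0).
#' @export
relativeEntropy <- function(alpha, Sigma, refAlpha, refSigma,
                            mean = NULL) {
  K <- length(alpha)
  stopifnot(length(refAlpha) == K, length(Sigma) == K,
            length(refSigma) == K)
  total <- 0
  for (k in seq_len(K)) {
    a <- alpha[k]; a0 <- refAlpha[k]
    if ((a > 0 && a0 == 0) || (a < 1 && a0 == 1)) return(-Inf)
    bern <- 0
    if (a > 0) bern <- bern + a * log(a / a0)
    if (a < 1) bern <- bern + (1 - a) * log((1 - a) / (1 - a0))
    gauss <- 0
    if (a > 0) {
      S1 <- as.matrix(Sigma[[k]]); S0 <- as.matrix(refSigma[[k]])
      n <- nrow(S1)
      mu <- if (is.null(mean)) numeric(n) else mean[[k]]
      S0inv <- solve(S0)
      gauss <- 0.5 * (sum(diag(S0inv %*% S1)) +
                        as.numeric(t(mu) %*% S0inv %*% mu) - n +
                        determinant(S0)$modulus -
                        determinant(S1)$modulus)
      gauss <- as.numeric(gauss)
    }
    total <- total + bern + a * gauss
  }
  -total
}

#' Surface-level Beer-Lambert conversion
#'
#' Converts two reconstructed optical-density maps (one per wavelength)
#' into hemoglobin maps by per-vertex 2 x 2 extinction inversion. No
#' pathlength division is involved: the reconstruction is already local.
#'
#' @param jOd1,jOd2 vertex x time optical-density reconstructions at the
#'   first and second wavelength.
#' @param wavelengths the two wavelengths (nm), or give \code{extinction}.
#' @param extinction optional 2 x 2 matrix (rows wavelengths, cols hbo,
#'   hbr).
#' @return list with \code{hbo}, \code{hbr}, \code{hbt} matrices.
#' @export
surfaceMbll <- function(jOd1, jOd2, wavelengths = NULL, extinction = NULL) {
  if (is.null(extinction)) {
    if (is.null(wavelengths)) stop("give wavelengths or extinction")
    extinction <- extinctionCoefficients(wavelengths)
  }
  E <- as.matrix(extinction)
  if (rcond(E) < 1e-12) stop("singular extinction matrix")
  Einv <- solve(E)
  jOd1 <- as.matrix(jOd1); jOd2 <- as.matrix(jOd2)
  hbo <- Einv[1, 1] * jOd1 + Einv[1, 2] * jOd2
  hbr <- Einv[2, 1] * jOd1 + Einv[2, 2] * jOd2
  list(hbo = hbo, hbr = hbr, hbt = hbo + hbr)
}
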