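#' Candidate scalp search space around a region of interest
#'
#' Scalp vertices within \code{maxDistMm} (Euclidean) of any ROI vertex,
#' minus explicitly excluded positions (e.g. reserved EEG sites).
#'
#' @param scalpSurface a \code{CorticalSurface} mesh of the scalp.
#' @param roiVertices n x 3 matrix of ROI vertex positions (world mm).
#' @param maxDistMm search radius (default 50).
#' @param excluded integer scalp-vertex indices to remove.
#' @return integer indices of candidate scalp vertices.
#' @export
buildSearchSpace <- function(scalpSurface, roiVertices, maxDistMm = 50,
                             excluded = integer(0)) {
  V <- scalpSurface@vertices
  roiVertices <- matrix(roiVertices, ncol = 3)
  d2 <- rep(Inf, nrow(V))
  for (i in seq_len(nrow(roiVertices)))
    d2 <- pmin(d2, rowSums(sweep(V, 2, roiVertices[i, ])^2))
  cand <- setdiff(which(d2 <= maxDistMm^2), excluded)
  if (!length(cand)) stop("empty search space")
  as.integer(cand)
}

#' Construct a MontageProblem
#'
#' @param positions P x 3 candidate positions (mm).
#' @param V P x P nonnegative matrix; \code{V[p, q]} is the ROI sensitivity
#'   of a channel with source at p and detector at q.
#' @param nSources,nDetectors equipment counts.
#' @param dMin,dMax channel distance range (mm).
#' @param optMin minimum distance between any two chosen optodes (mm).
#' @param adjacency minimum channels per source.
#' @param excluded reserved position indices.
#' @return a \code{MontageProblem}.
#' @export
MontageProblem <- function(positions, V, nSources, nDetectors,
                           dMin = 15, dMax = 35, optMin = 10,
                           adjacency = 1L, excluded = integer(0)) {
  new("MontageProblem", positions = asPositionMatrix(positions),
      V = as.matrix(V), nSources = as.integer(nSources),
      nDetectors = as.integer(nDetectors), dMin = dMin, dMax = dMax,
      optMin = optMin, adjacency = as.integer(adjacency),
      excluded = as.integer(excluded))
}

#' Solve the optimal optode placement problem exactly
#'
#' The placement program is the 0-1 linear program: binaries \code{x_p}
#' (source at p), \code{y_p} (detector at p) and \code{z_pq} (channel
#' active), objective max sum V[p,q] z_pq, with z linked to x and y by the
#' usual linearization (z <= x, z <= y, z >= x + y - 1 for pairs within
#' the channel distance window, z = 0 otherwise), equipment counts, at
#' most one optode per position, minimum optode spacing, and a per-source
#' adjacency (minimum channel count) constraint. Since V >= 0 forces every
#' admissible z to 1 at the optimum, the objective is fully determined by
#' the chosen position sets; the solver is an exact depth-first
#' branch-and-bound over source and detector subsets with an admissible
#' top-k bound, so it returns the program's optimum. Ties are broken
#' toward the lexicographically smallest sorted index vector.
#'
#' @param problem a \code{MontageProblem}.
#' @param timeLimitS soft wall-clock limit; hitting it stops the search and
#'   returns the incumbent with status \code{"feasible"}.
#' @return a \code{\linkS4class{MontageSolution}}.
#' @export
solveMontage <- function(problem, timeLimitS = 60) {
  P <- nrow(problem@positions)
  cand <- setdiff(seq_len(P), problem@excluded)
  ns <- problem@nSources; nd <- problem@nDetectors
  if (length(cand) < ns + nd)
    return(new("MontageSolution", sources = integer(0),
               detectors = integer(0),
               channels = emptyChannels(), objective = -Inf,
               status = "infeasible"))
  D <- as.matrix(stats::dist(problem@positions))
  chanOk <- D >= problem@dMin & D <= problem@dMax
  tooClose <- D < problem@optMin
  diag(tooClose) <- FALSE
  V <- problem@V
  V[!chanOk] <- 0

  t0 <- Sys.time()
  best <- new.env(parent = emptyenv())
  best$obj <- -Inf; best$S <- NULL; best$D <- NULL
  best$timedOut <- FALSE

  srcSets <- utils::combn(cand, ns, simplify = FALSE)
  for (S in srcSets) {
    if (as.numeric(Sys.time() - t0) > timeLimitS) {
      best$timedOut <- TRUE; break
    }
    if (ns > 1L && any(tooClose[S, S])) next
    rest <- setdiff(cand, S)
    ## detector gain given this source set
    g <- colSums(V[S, , drop = FALSE])
    rest <- rest[!apply(tooClose[S, rest, drop = FALSE], 2, any)]
    if (length(rest) < nd) next
    rest <- rest[order(-g[rest], rest)]
    detectorSearch(S, rest, g, nd, V, chanOk, tooClose,
                   problem@adjacency, best)
  }
  if (is.null(best$S)) {
    return(new("MontageSolution", sources = integer(0),
               detectors = integer(0), channels = emptyChannels(),
               objective = -Inf, status = "infeasible"))
  }
  S <- sort(best$S); Dt <- sort(best$D)
  ch <- do.call(rbind, lapply(S, function(s) {
    q <- Dt[chanOk[s, Dt]]
    if (!length(q)) return(NULL)
    data.frame(source = s, detector = q, distance = D[s, q],
               value = V[s, q])
  }))
  if (is.null(ch)) ch <- emptyChannels()
  new("MontageSolution", sources = as.integer(S), detectors = as.integer(Dt),
      channels = ch, objective = best$obj,
      status = if (best$timedOut) "feasible" else "optimal")
}

emptyChannels <- function()
  data.frame(source = integer(), detector = integer(),
             distance = numeric(), value = numeric())

## Depth-first search over detector subsets (candidates pre-sorted by
## gain), bound = current + sum of the best remaining gains.
detectorSearch <- function(S, candD, g, nd, V, chanOk, tooClose,
                           adjacency, best) {
  n <- length(candD)
  gSorted <- g[candD]
  recurse <- function(start, chosen, cur) {
    need <- nd - length(chosen)
    if (need == 0L) {
      ## adjacency: every source must form at least `adjacency` channels
      for (s in S)
        if (sum(chanOk[s, chosen]) < adjacency) return(invisible())
      better <- cur > best$obj + 1e-9 ||
        (abs(cur - best$obj) <= 1e-9 &&
           lexLess(c(sort(S), sort(chosen)), c(sort(best$S), sort(best$D))))
      if (better) { best$obj <- cur; best$S <- S; best$D <- chosen }
      return(invisible())
    }
    if (n - start + 1L < need) return(invisible())
    ub <- cur + sum(sort(gSorted[start:n], decreasing = TRUE)[seq_len(need)])
    if (ub < best$obj - 1e-9) return(invisible())
    for (i in start:n) {
      if (n - i + 1L < need) break
      d <- candD[i]
      if (length(chosen) && any(tooClose[d, chosen])) next
      recurse(i + 1L, c(chosen, d), cur + g[d])
    }
    invisible()
  }
  recurse(1L, integer(0), 0)
}

lexLess <- function(a, b) {
  if (is.null(b)) return(TRUE)
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Export a montage solution
#'
#' \code{format = "tsv"} writes labeled optode coordinates (S1..Sn,
#' D1..Dm) followed by the channel list; \code{format = "snirf"} writes a
#' SNIRF file whose probe block holds the chosen positions with the full
#' channel list at the given wavelengths (data block is a two-sample
#' placeholder).
#'
#' @param solution a feasible \code{MontageSolution}.
#' @param problem the originating \code{MontageProblem}.
#' @param path output path.
#' @param format "tsv" or "snirf".
#' @param wavelengths wavelengths (nm) recorded in the SNIRF probe.
#' @return \code{path}, invisibly.
#' @export
exportMontage <- function(solution, problem, path,
                          format = c("tsv", "snirf"),
                          wavelengths = c(685, 830)) {
  format <- match.arg(format)
  if (solution@status == "infeasible")
    stop("cannot export an infeasible solution")
  sp <- problem@positions[solution@sources, , drop = FALSE]
  dp <- problem@positions[solution@detectors, , drop = FALSE]
  if (format == "tsv") {
    opt <- data.frame(
      label = c(sprintf("S%d", seq_len(nrow(sp))),
                sprintf("D%d", seq_len(nrow(dp)))),
      x = c(sp[, 1], dp[, 1]), y = c(sp[, 2], dp[, 2]),
      z = c(sp[, 3], dp[, 3]))
    con <- file(path, "w"); on.exit(close(con))
    utils::write.table(opt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ch <- solution@channels
    ch$source <- sprintf("S%d", match(ch$source, solution@sources))
    ch$detector <- sprintf("D%d", match(ch$detector, solution@detectors))
    writeLines("", con)
    utils::write.table(ch, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  pairs <- data.frame(
    source = match(solution@channels$source, solution@sources),
    detector = match(solution@channels$detector, solution@detectors))
  pr <- Probe(sp, dp, wavelengths, pairs = pairs)
  rec <- OpticalRecording(pr, times = c(0, 1),
                          intensities = matrix(1, nrow(pr@channels), 2))
  writeSnirf(rec, path)
}
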