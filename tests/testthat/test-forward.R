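## small phantom for geometric checks
tinyPhantom <- function() {
  makePhantom(radiiMm = c(skin = 20, skull = 17, csf = 15, gray = 13,
                          white = 8),
              voxelSizeMm = 2, meshSubdivisions = 2L)
}

test_that("synthetic fluence is 1 at the optode and decays monotonically", {
  ph <- tinyPhantom()
  vol <- ph$volume
  opt <- c(0, 0, 19)
  fl <- syntheticFluence(vol, opt)
  expect_true(all(fl >= 0))
  expect_true(all(fl[vol@labels == 0] == 0))       # zero outside the head
  ## fluence at (near) the optode voxel is ~1 (zero path)
  ijk <- round(nirsdot:::worldToVoxel(vol, matrix(opt, 1)))
  near <- fl[ijk[1] + dim(vol@labels)[1] * (ijk[2] + dim(vol@labels)[2] *
                                              ijk[3]) + 1]
  expect_gt(near, 0.5)
  ## monotone nonincreasing along the inward ray through the tissue
  ray <- vapply(seq(19, 1, by = -2), function(z)
    syntheticFluence(vol, opt, voxels = {
      i <- round(nirsdot:::worldToVoxel(vol, matrix(c(0, 0, z), 1)))
      as.integer(i[1] + dim(vol@labels)[1] * (i[2] + dim(vol@labels)[2] *
                                                i[3]) + 1)
    }), numeric(1))
  expect_true(all(diff(ray) <= 1e-12))
  ## mirror symmetry of two symmetric optodes
  f1 <- syntheticFluence(vol, c(10, 0, 17))
  f2 <- syntheticFluence(vol, c(-10, 0, 17))
  expect_lt(max(abs(f1 - f2[dim(f2)[1]:1, , ])), 1e-6)
  ## optode buried in the interior is refused
  expect_error(syntheticFluence(vol, c(0, 0, 5)), "geometry")
})

test_that("channel sensitivity is reciprocal and banana-shaped", {
  ph <- tinyPhantom()
  vol <- ph$volume
  s <- c(8, 0, 18.4); d <- c(-8, 0, 18.4)
  fs <- syntheticFluence(vol, s)
  fd <- syntheticFluence(vol, d)
  sens1 <- channelSensitivity(fs, fd, volume = vol)
  sens2 <- channelSensitivity(fd, fs, volume = vol)
  expect_identical(as.numeric(sens1), as.numeric(sens2))  # bit-exact
  expect_true(all(sens1[fs == 0] == 0))
  ## peak lies in the slab between the optodes
  gm <- which(vol@labels == TISSUE_LABELS[["gray"]])
  peak <- gm[which.max(sens1[gm])]
  pk <- voxelCenters(vol, arrayInd(peak, dim(vol@labels)) - 1L)
  expect_lt(abs(pk[1]), 8)
  expect_gt(pk[3], 0)
  expect_error(channelSensitivity(fs, fd, normalizer = 0), "zero")
})

test_that("Voronoi assignment matches the brute-force nearest vertex", {
  ph <- tinyPhantom()
  vor <- buildVoronoi(ph$volume, ph$surface, capMm = 6)
  ## partition: every gray voxel is assigned or recorded unassigned
  gm <- which(ph$volume@labels == TISSUE_LABELS[["gray"]])
  expect_setequal(c(vor@voxels, vor@unassigned), gm)
  expect_equal(length(vor@voxels), length(vor@vertex))
  ## exhaustive nearest-vertex oracle
  centers <- voxelCenters(ph$volume,
                          arrayInd(vor@voxels, dim(ph$volume@labels)) - 1L)
  V <- ph$surface@vertices
  for (i in seq(1, length(vor@voxels), by = 17)) {
    d2 <- colSums((t(V) - centers[i, ])^2)
    expect_equal(vor@vertex[i], which.min(d2))
    expect_lte(sqrt(min(d2)), 6)
  }
  expect_error(buildVoronoi(HeadVolume(array(1L, c(3, 3, 3)), 2),
                            ph$surface), "gray")
})

test_that("surface projection is the per-cell mean", {
  ph <- tinyPhantom()
  vor <- buildVoronoi(ph$volume, ph$surface)
  nV <- nrow(ph$surface@vertices)
  ## uniform map -> every nonempty cell gets the constant
  u <- projectToSurface(rep(7, length(vor@voxels)), vor, nV)
  expect_true(all(u[unique(vor@vertex)] == 7))
  expect_true(all(u[setdiff(seq_len(nV), vor@vertex)] == 0))
  ## single nonzero voxel -> its cell mean only
  v1 <- numeric(length(vor@voxels)); v1[5] <- 3
  p1 <- projectToSurface(v1, vor, nV)
  cell <- vor@vertex[5]
  expect_equal(p1[cell], 3 / sum(vor@vertex == cell))
  expect_true(all(p1[-cell] == 0))
  ## independent accumulation oracle + mass conservation
  set.seed(51)
  vals <- runif(length(vor@voxels))
  got <- projectToSurface(vals, vor, nV)
  oracle <- vapply(seq_len(nV), function(v) {
    sel <- vor@vertex == v
    if (!any(sel)) 0 else mean(vals[sel])
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-12)
  cellSize <- tabulate(vor@vertex, nV)
  expect_equal(sum(got * cellSize), sum(vals), tolerance = 1e-9)
})

test_that("log10-decade maps and overlap metrics match their definitions", {
  s <- c(10, 1, 0.1, 5)
  db <- sensitivityDb(s)
  expect_equal(db, c(0, -1, -2, log10(0.5)))
  expect_error(sensitivityDb(rep(0, 3)), "all-zero")

  set.seed(52)
  A <- matrix(runif(30 * 500), 30)
  Adb <- sensitivityDb(A)
  expect_equal(max(Adb), 0)
  ## min sensitivity of the n best channels vs full-sort oracle
  for (n in c(1, 2, 7, 30)) {
    got <- overlapMinSensitivity(Adb, n)
    oracle <- apply(Adb, 2, function(x) sort(x, decreasing = TRUE)[n])
    expect_equal(got, oracle)
  }
  expect_equal(overlapMinSensitivity(Adb, 1), apply(Adb, 2, max))
  expect_equal(overlapMinSensitivity(rbind(c(0, 0), c(-1, -1), c(-2, -2)),
                                     2)[1], -1)
  expect_error(overlapMinSensitivity(Adb, 31), "between")

  ## channel counts above threshold vs exhaustive count
  cnt <- overlapChannelCount(Adb, -1)
  expect_equal(cnt, apply(Adb, 2, function(x) sum(x >= -1)))
  expect_equal(overlapChannelCount(Adb, -Inf),
               apply(Adb, 2, function(x) sum(is.finite(x) | x == -Inf)))
  one <- sensitivityDb(matrix(c(1, 2, 3), 1))
  expect_equal(overlapChannelCount(one, 0), c(0L, 0L, 1L))
})

test_that("field of view matches the brute-force distance filter", {
  ph <- tinyPhantom()
  pr <- ph$probe
  expect_error(fieldOfView(ph$surface, pr, 0), "empty")
  expect_equal(fieldOfView(ph$surface, pr, 1e6),
               seq_len(nrow(ph$surface@vertices)))
  fov <- fieldOfView(ph$surface, pr, 12)
  opt <- rbind(pr@sourcePos, pr@detectorPos)
  oracle <- which(vapply(seq_len(nrow(ph$surface@vertices)), function(v)
    min(sqrt(colSums((t(opt) - ph$surface@vertices[v, ])^2))) <= 12,
    logical(1)))
  expect_equal(fov, oracle)
})

test_that("the assembled forward model is nonnegative with live rows", {
  fx <- phantomFixture()
  A <- fx$forward@A
  expect_true(all(A >= 0))
  expect_true(all(rowSums(A) > 0))
  expect_equal(ncol(A), length(fx$forward@fov))
  expect_true(all(fx$forward@noiseVar > 0))
})
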