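test_that("lorIndex is a symmetric bijection onto the pair range", {
  g <- tinyRing(16L, 1L)
  C <- nCrystals(g)
  pairs <- t(combn(0:(C - 1), 2))
  idx <- lorIndex(pairs[, 1], pairs[, 2], g)
  expect_equal(sort(idx), 0:(C * (C - 1) / 2 - 1))
  expect_equal(length(idx), 120)
  # symmetry
  expect_equal(lorIndex(pairs[, 2], pairs[, 1], g), idx)
  # the first and a known pair under lexicographic enumeration
  expect_equal(lorIndex(0, 1, g), 0)
  expect_equal(lorIndex(2, 3, g), lorIndex(3, 2, g))
  # errors
  expect_error(lorIndex(3, 3, g), "self-pair")
  expect_error(lorIndex(-1, 2, g), "must be in")
  expect_error(lorIndex(0, C, g), "must be in")
})

test_that("lorIndex matches the small-C lexicographic enumeration", {
  # C = 4 worked out by hand: (0,1)->0 (0,2)->1 (0,3)->2 (1,2)->3
  # (1,3)->4 (2,3)->5; checked through the C = 4-prefix of a larger ring
  g <- tinyRing(8L, 1L)
  expect_equal(lorIndex(0, 1, g), 0)
  C <- 8
  expect_equal(lorIndex(2, 3, g), 2 * C - 3 + 0)  # a*C - a(a+1)/2 + b-a-1
})

test_that("crystal boxes sit on the ring with the expected symmetries", {
  g <- tinyRing(16L, 2L)
  b0 <- crystalWorldBox(g, 0)
  expect_equal(b0$center[1], g@ringRadius + g@crystalDepth / 2)
  expect_equal(b0$center[2], 0)
  # opposite crystal: point reflection through the z axis
  bOpp <- crystalWorldBox(g, 8)
  expect_equal(bOpp$center[1:2], -b0$center[1:2], tolerance = 1e-12)
  expect_equal(bOpp$center[3], b0$center[3])
  # all centers share the radial distance
  rads <- vapply(0:(nCrystals(g) - 1), function(i) {
    b <- crystalWorldBox(g, i)
    sqrt(sum(b$center[1:2]^2))
  }, numeric(1))
  expect_lt(max(abs(rads - rads[1])), 1e-9)
  expect_error(crystalWorldBox(g, nCrystals(g)), "crystalId")
})

test_that("rotating a crystal box by one pitch yields the next crystal", {
  g <- tinyRing(16L, 1L)
  dphi <- 2 * pi / g@nCrystalsTransaxial
  R <- matrix(c(cos(dphi), sin(dphi), 0,
                -sin(dphi), cos(dphi), 0,
                0, 0, 1), 3, 3)
  for (i in c(0, 3, 15)) {
    bi <- crystalWorldBox(g, i)
    bj <- crystalWorldBox(g, (i + 1) %% 16)
    expect_equal(as.numeric(R %*% bi$center), bj$center,
                 tolerance = 1e-9)
  }
})

test_that("world/voxel mapping is the exact affine inverse pair", {
  vol <- imageVolume(dims = c(100, 100, 100), voxelSize = 1)
  expect_equal(worldToVoxel(vol, c(0, 0, 0)), c(49.5, 49.5, 49.5))
  # one voxel size along +x shifts the coordinate by exactly 1
  expect_equal(worldToVoxel(vol, c(1, 0, 0)) -
                 worldToVoxel(vol, c(0, 0, 0)), c(1, 0, 0))
  # round trip on random voxels
  set.seed(11)
  q <- matrix(runif(3000, -0.5, 99.5), ncol = 3)
  p <- voxelToWorld(vol, q)
  expect_equal(worldToVoxel(vol, p), q, tolerance = 1e-9)
  # anisotropic + off-center volume
  vol2 <- imageVolume(dims = c(10, 20, 30), voxelSize = c(1, 2, 0.5),
                      center = c(3, -4, 5))
  q2 <- matrix(runif(300, 0, 9), ncol = 3)
  expect_equal(worldToVoxel(vol2, voxelToWorld(vol2, q2)), q2,
               tolerance = 1e-9)
})

test_that("geometry validity rejects broken configurations", {
  expect_error(scannerGeometry(40, 4, 1), "nCrystalsTransaxial")
  expect_error(scannerGeometry(40, 16, 0), "nRings")
  expect_error(scannerGeometry(-1, 16, 1), "positive")
  expect_error(scannerGeometry(40, 64, 8, crystalWidthTransaxial = 50),
               "overlap")
})

test_that("geometry and histogram I/O round-trip", {
  g <- toyRing()
  f <- tempfile(fileext = ".yaml")
  writeGeometry(g, f)
  g2 <- readGeometry(f)
  expect_equal(icsfilter:::geometryHash(g2), icsfilter:::geometryHash(g))
  h <- lorHistogram(seq_len(nLORs(g)) %% 7, g, meta = list(seed = 3))
  fh <- tempfile(fileext = ".lorh")
  writeLORHistogram(h, fh)
  h2 <- readLORHistogram(fh)
  expect_identical(h2@counts, h@counts)
  expect_equal(h2@meta$seed, 3)
})

test_that("volume I/O round-trips through NIfTI and raw+sidecar", {
  set.seed(5)
  vol <- imageVolume(values = array(runif(8 * 6 * 4), dim = c(8, 6, 4)),
                     voxelSize = c(1, 1.5, 2))
  fn <- tempfile(fileext = ".nii.gz")
  writeVolume(vol, fn)
  v2 <- readVolume(fn)
  expect_equal(v2@values, vol@values, tolerance = 1e-6)
  expect_equal(v2@voxelSize, vol@voxelSize)
  fr <- tempfile(fileext = ".f32")
  writeVolume(vol, fr)
  v3 <- readVolume(fr)
  expect_equal(v3@values, vol@values, tolerance = 1e-6)
  expect_equal(v3@center, vol@center)
})
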