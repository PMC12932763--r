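test_that("applyFilter preserves activity and reduces to identity for deltas", {
  tmpl <- smallTemplate(c(12, 12, 8), 1)
  set.seed(81)
  x <- imageVolume(values = array(runif(12 * 12 * 8), dim = c(12, 12, 8)),
                   voxelSize = 1)
  # delta kernels: identity
  kd <- matrix(rep(as.numeric(deltaKernel(11L)@values), 12 * 12 * 8),
               nrow = 12 * 12 * 8, byrow = TRUE)
  std <- kernelStore(kd, tmpl)
  expect_equal(applyFilter(x, std)@values, x@values)
  # random valid kernels: activity preserved despite border truncation
  K <- matrix(runif(12 * 12 * 8 * 1331), 12 * 12 * 8, 1331)
  K <- K / rowSums(K)
  str <- kernelStore(K, tmpl)
  xf <- applyFilter(x, str)
  expect_equal(sum(xf@values), sum(x@values),
               tolerance = 1e-6)
  expect_error(applyFilter(imageVolume(dims = c(4, 4, 4)), str),
               "template")
})

test_that("applyFilter equals a dense matrix-vector oracle", {
  tmpl <- smallTemplate(c(9, 9, 9), 1)
  nv <- 9^3
  set.seed(82)
  K <- matrix(runif(nv * 27), nv, 27)  # 3x3x3 kernels for a dense oracle
  K <- K / rowSums(K)
  str <- kernelStore(K, tmpl)
  x <- array(runif(nv), dim = c(9, 9, 9))
  got <- applyFilter(imageVolume(values = x, voxelSize = 1), str)@values
  # explicit summation oracle
  want <- array(0, dim = c(9, 9, 9))
  off <- -1:1
  for (iz in 1:9) for (iy in 1:9) for (ix in 1:9) {
    row <- (ix - 1) + 9 * ((iy - 1) + 9 * (iz - 1)) + 1
    k <- array(K[row, ], dim = c(3, 3, 3))
    w <- 0
    for (oz in off) for (oy in off) for (ox in off) {
      tx <- ix + ox; ty <- iy + oy; tz <- iz + oz
      if (tx >= 1 && tx <= 9 && ty >= 1 && ty <= 9 && tz >= 1 && tz <= 9)
        w <- w + k[ox + 2, oy + 2, oz + 2]
    }
    for (oz in off) for (oy in off) for (ox in off) {
      tx <- ix + ox; ty <- iy + oy; tz <- iz + oz
      if (tx >= 1 && tx <= 9 && ty >= 1 && ty <= 9 && tz >= 1 && tz <= 9)
        want[tx, ty, tz] <- want[tx, ty, tz] +
          x[ix, iy, iz] * k[ox + 2, oy + 2, oz + 2] / w
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("octant stores mirror consistently and match dense on symmetric nets", {
  tmpl <- smallTemplate(c(8, 8, 8), 2)
  net <- icsNet("direct", inputScale = 8)
  dense <- precomputeKernels(net, tmpl, mode = "dense")
  oct <- precomputeKernels(net, tmpl, mode = "octant")
  octAvg <- precomputeKernels(net, tmpl, mode = "octant", average = TRUE)
  set.seed(83)
  x <- imageVolume(values = array(runif(512), dim = c(8, 8, 8)),
                   voxelSize = 2)
  expect_equal(applyFilter(x, oct)@values, applyFilter(x, dense)@values)
  expect_equal(applyFilter(x, octAvg)@values, applyFilter(x, dense)@values)
  # read-back kernels are normalized and mirror-related
  k1 <- storedKernel(oct, c(1, 2, 3))
  expect_equal(sum(k1@values), 1, tolerance = 1e-9)
  k2 <- storedKernel(oct, c(6, 2, 3))  # x mirror mate of voxel 1
  expect_equal(k2@values, mirrorKernel(k1, c(TRUE, FALSE, FALSE))@values)
  # store size guard
  expect_error(precomputeKernels(net, tmpl, mode = "dense",
                                 maxBytes = 1000), "octant")
  expect_error(precomputeKernels(net, smallTemplate(c(7, 8, 8), 2),
                                 mode = "octant"), "even")
})

test_that("OS-EM keeps the noiseless solution as a fixed point", {
  g <- toyRing()
  tmpl <- smallTemplate(c(12, 12, 8), 2)
  view <- systemMatrixView(g, tmpl)
  set.seed(84)
  xs <- array(0, dim = c(12, 12, 8))
  xs[4:9, 4:9, 3:6] <- runif(6 * 6 * 4) + 0.5
  xTrue <- imageVolume(values = xs, voxelSize = 2)
  y <- forwardProject(xTrue, view)
  # EM multiplier at the true image (exactly as the update computes it)
  # is 1 on every voxel of the support: all LORs crossing a voxel with
  # x* > 0 have y > 0, so their ratios are exactly 1
  gl <- icsfilter:::viewGeom(view)
  sens <- icsfilter:::cppBackProject(rep(1, nLORs(g)), view@dims,
                                     view@voxelSize, view@center, gl,
                                     integer(0), 1L)
  yhat <- forwardProject(xTrue, view)@counts
  ratio <- y@counts / pmax(yhat, 1e-12)
  corr <- icsfilter:::cppBackProject(ratio, view@dims, view@voxelSize,
                                     view@center, gl, integer(0), 1L)
  mult <- corr / pmax(as.numeric(sens), 1e-12)
  support <- as.numeric(xs) > 0 & as.numeric(sens) > 1e-9
  expect_lt(max(abs(mult[support] - 1)), 1e-6)
  # and the iteration stays non-negative and finite from a cold start
  rec <- osemReconstruct(y, view, osemConfig(4, 2))
  expect_true(all(is.finite(rec@values)) && all(rec@values >= 0))
})

test_that("MLEM increases the Poisson likelihood monotonically", {
  g <- toyRing()
  tmpl <- smallTemplate(c(12, 12, 8), 2)
  view <- systemMatrixView(g, tmpl)
  set.seed(85)
  xs <- array(0, dim = c(12, 12, 8))
  xs[4:9, 4:9, 3:6] <- runif(144) + 0.5
  y0 <- forwardProject(imageVolume(values = xs, voxelSize = 2), view)
  y <- lorHistogram(rpois(nLORs(g), 3 * y0@counts), g)
  ll <- numeric(20)
  for (it in 1:20) {
    rec <- osemReconstruct(y, view, osemConfig(1, it))
    yh <- forwardProject(rec, view)@counts
    keep <- y@counts > 0
    ll[it] <- sum(y@counts[keep] * log(pmax(yh[keep], 1e-12))) - sum(yh)
  }
  expect_true(all(diff(ll) > -1e-6))
})

test_that("osemReconstruct handles degenerate inputs", {
  g <- toyRing()
  tmpl <- smallTemplate(c(12, 12, 8), 2)
  view <- systemMatrixView(g, tmpl)
  expect_warning(z <- osemReconstruct(lorHistogram(0, g), view),
                 "all-zero")
  expect_true(all(z@values == 0))
  expect_error(osemConfig(0, 1), ">= 1")
})

test_that("the LOR blur operator preserves counts and has a working adjoint", {
  g <- toyRing()
  tab <- defaultAttenuation()
  blur <- estimateLorBlur(g, tab, nPhotons = 5e4, seed = 9)
  B <- lorBlurMatrix(blur, g)
  expect_equal(range(Matrix::rowSums(B)), c(1, 1), tolerance = 1e-12)
  set.seed(86)
  y <- runif(nLORs(g))
  expect_equal(sum(as.numeric(Matrix::crossprod(B, y))), sum(y),
               tolerance = 1e-9)
  # composite forward model (B A) against its adjoint (At Bt)
  tmpl <- smallTemplate(c(12, 12, 8), 2)
  view <- systemMatrixView(g, tmpl)
  x <- array(runif(12 * 12 * 8), dim = c(12, 12, 8))
  r <- runif(nLORs(g))
  BAx <- as.numeric(Matrix::crossprod(
    B, forwardProject(imageVolume(values = x, voxelSize = 2),
                      view)@counts))
  Btr <- as.numeric(B %*% r)
  AtBtr <- icsfilter:::cppBackProject(Btr, view@dims, view@voxelSize,
                                      view@center,
                                      icsfilter:::viewGeom(view),
                                      integer(0), 1L)
  expect_lt(abs(sum(BAx * r) - sum(x * AtBtr)) / abs(sum(BAx * r)), 1e-6)
})

test_that("a delta blur makes the LOR-space method coincide with plain OS-EM", {
  g <- toyRing()
  tmpl <- smallTemplate(c(12, 12, 8), 2)
  view <- systemMatrixView(g, tmpl)
  set.seed(87)
  xs <- array(0, dim = c(12, 12, 8))
  xs[5:8, 5:8, 4:5] <- 1
  y0 <- forwardProject(imageVolume(values = xs, voxelSize = 2), view)
  y <- lorHistogram(rpois(nLORs(g), y0@counts), g)
  deltaBlur <- list(prob = matrix(c(0, 0, 1, 0, 0), 5, 1),
                    offsetsT = -2:2, offsetsZ = 0L, nRegistered = 1e5)
  r1 <- lorSpaceCorrectedReconstruct(y, view, osemConfig(2, 2), deltaBlur)
  r2 <- osemReconstruct(y, view, osemConfig(2, 2))
  expect_equal(r1@values, r2@values, tolerance = 1e-9)
})

test_that("evaluateExperiment delegates to nrmse and preserves labels", {
  tmpl <- smallTemplate(c(6, 6, 6), 1)
  set.seed(88)
  ref <- imageVolume(values = array(runif(216, 0.5, 1), dim = c(6, 6, 6)),
                     voxelSize = 1)
  a <- imageVolume(values = ref@values * 1.1, voxelSize = 1)
  rep <- evaluateExperiment(list(first = a, second = ref), ref)
  expect_equal(rep$method, c("first", "second"))
  expect_equal(rep$nrmse_percent[2], 0)
  expect_equal(rep$nrmse_percent[1], nrmse(a, ref, asPercent = TRUE))
  expect_error(evaluateExperiment(list(a), ref), "named")
})

test_that("the filter and its adjoint satisfy the inner-product identity", {
  tmpl <- smallTemplate(c(10, 10, 8), 1)
  nv <- prod(c(10, 10, 8))
  set.seed(90)
  K <- matrix(runif(nv * 27), nv, 27)
  K <- K / rowSums(K)
  str <- kernelStore(K, tmpl)
  x <- runif(nv)
  y <- runif(nv)
  Fx <- icsfilter:::cppApplyFilter(x, str@kernels, FALSE, str@dims,
                                   str@norms)
  Fty <- icsfilter:::cppApplyFilterAdjoint(y, str@kernels, FALSE,
                                           str@dims, str@norms)
  expect_equal(sum(Fx * y), sum(x * Fty), tolerance = 1e-12)
  # invariant store: same kernel at every voxel, same identity
  ki <- matrix(K[1, ], 1)
  sti <- kernelStore(ki, tmpl, mode = "invariant")
  Fxi <- icsfilter:::cppApplyFilter(x, sti@kernels, FALSE, sti@dims,
                                    sti@norms)
  Ftyi <- icsfilter:::cppApplyFilterAdjoint(y, sti@kernels, FALSE,
                                            sti@dims, sti@norms)
  expect_equal(sum(Fxi * y), sum(x * Ftyi), tolerance = 1e-12)
  expect_equal(sum(Fxi), sum(x), tolerance = 1e-9)
  # invariant store matches a dense store of the repeated kernel
  std <- kernelStore(matrix(rep(K[1, ], each = nv), nv), tmpl)
  Fxd <- icsfilter:::cppApplyFilter(x, std@kernels, FALSE, std@dims,
                                    std@norms)
  expect_equal(Fxi, Fxd, tolerance = 1e-12)
})

test_that("the scatter-free response kernel is centered and compact", {
  g <- toyRing()
  tmpl <- imageVolume(dims = c(12, 12, 8), voxelSize = c(2, 2, 1.25))
  view <- systemMatrixView(g, tmpl)
  G <- estimateResponseKernel(view, nPairs = 2e5, seed = 12,
                              steps = 600)
  expect_equal(sum(G@values), 1, tolerance = 1e-9)
  grid <- icsfilter:::kernelGrid(11L)
  com <- colSums(grid * as.numeric(G@values))
  # scatter-free response at the center: no systematic displacement
  expect_lt(max(abs(com)), 0.6)
  # most mass within the central 5^3 (tube width, not long tails)
  central <- abs(grid[, 1]) <= 2 & abs(grid[, 2]) <= 2 &
    abs(grid[, 3]) <= 2
  expect_gt(sum(as.numeric(G@values)[central]), 0.7)
})
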