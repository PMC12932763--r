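test_that("smoothL1 matches its piecewise closed form", {
  # quadratic branch, knee continuity, linear branch (pre-normalized)
  expect_equal(smoothL1(0.5, 0, normalize = FALSE)$total, 0.125)
  expect_equal(smoothL1(1, 0, normalize = FALSE)$total, 0.5)
  expect_equal(smoothL1(-3, 0, normalize = FALSE)$total, 2.5)
  y1 <- c(0.2, 0.5, 0.3)
  y2 <- c(0.1, 0.6, 0.3)
  out <- smoothL1(y1, y2, normalize = FALSE)
  expect_equal(out$perLor, c(0.005, 0.005, 0))
  expect_equal(out$total, 0.01)
  # normalization: scaling either input changes nothing
  expect_equal(smoothL1(10 * y1, y2)$total, smoothL1(y1, y2)$total)
  expect_error(smoothL1(c(0, 0), c(1, 1)), "zero LOR image")
})

test_that("training samples are deterministic, in-box and complete", {
  g <- toyRing()
  tmpl <- imageVolume(dims = c(12, 12, 8), voxelSize = c(2, 2, 1.25))
  tab <- defaultAttenuation()
  cfg <- trainConfig(nSamples = 6, nPairs = 5e3, epochs = 1, folds = 2,
                     seed = 77)
  s1 <- generateTrainingSet(cfg, g, tmpl, tab)
  s2 <- generateTrainingSet(cfg, g, tmpl, tab)
  expect_equal(length(s1), 6)
  expect_identical(s1, s2)
  pos <- do.call(rbind, lapply(s1, `[[`, "position"))
  half <- dim(tmpl@values) * tmpl@voxelSize / 2
  expect_true(all(abs(pos) <= matrix(half, 6, 3, byrow = TRUE)))
  expect_true(all(vapply(s1, function(s) sum(s$counts), 1) > 0))
  expect_true(all(vapply(s1, function(s) sum(s$counts), 1) <= 5e3))
  # incremental serialization round-trips
  dir <- tempfile()
  s3 <- generateTrainingSet(cfg, g, tmpl, tab, outDir = dir)
  expect_equal(length(list.files(dir, pattern = "^sample_")), 6)
  s4 <- generateTrainingSet(cfg, g, tmpl, tab, outDir = dir)  # resumed
  expect_identical(s3, s4)
})

test_that("kernelGradient matches finite differences of the full loss", {
  g <- tinyRing(8L, 1L)
  tmpl <- imageVolume(dims = c(9, 9, 9), voxelSize = 2)
  view <- systemMatrixView(g, tmpl)
  pos <- c(1.2, -0.8, 0.5)
  idx <- icsfilter:::containingVoxel(tmpl, pos)
  P <- patchProjector(view, idx - 5L, 11L)
  set.seed(71)
  ytrue <- runif(nLORs(g))
  ytn <- ytrue / sum(ytrue)
  k0 <- icsfilter:::gaussianKernelValues(7 / 6, 11)
  y <- as.numeric(P %*% k0)
  suppressWarnings(gk <- kernelGradient(y, ytrue, view, pos))
  lossOf <- function(k) {
    yy <- as.numeric(P %*% k)
    yn <- yy / sum(yy)
    d <- yn - ytn
    sum(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5))
  }
  entries <- sample(1331, 20)
  for (e in entries) {
    ep <- 1e-6
    kp <- k0; kp[e] <- kp[e] + ep
    km <- k0; km[e] <- km[e] - ep
    fd <- (lossOf(kp) - lossOf(km)) / (2 * ep)
    expect_lt(abs(as.numeric(gk)[e] - fd) / max(abs(fd), 1e-10), 1e-3)
  }
  # minimum: zero gradient at y_pred = y_true
  suppressWarnings(gz <- kernelGradient(y, y, view, pos))
  expect_equal(max(abs(gz)), 0)
  # L1 normalization removes the target scale
  suppressWarnings(g10 <- kernelGradient(y, 10 * ytrue, view, pos))
  expect_equal(g10, gk, tolerance = 1e-12)
})

test_that("one training epoch decreases the loss on a tiny problem", {
  g <- toyRing()
  tab <- defaultAttenuation()
  tmpl <- imageVolume(dims = c(12, 12, 8), voxelSize = c(2, 2, 1.25))
  ok <- 0
  for (seed in 1:5) {
    cfg <- trainConfig(nSamples = 8, nPairs = 2e4, epochs = 2, folds = 2,
                       seed = seed, learningRate = 1e-3, refit = TRUE)
    samples <- generateTrainingSet(cfg, g, tmpl, tab)
    net <- icsNet("direct", inputScale = 12, seed = seed)
    tr <- trainICSNet(net, samples, cfg, systemMatrixView(g, tmpl))
    drop <- vapply(tr$folds, function(f) f$train[1] - f$train[2],
                   numeric(1))
    if (all(drop >= 0)) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("fold assignment partitions the samples", {
  g <- toyRing()
  tmpl <- imageVolume(dims = c(12, 12, 8), voxelSize = c(2, 2, 1.25))
  tab <- defaultAttenuation()
  cfg <- trainConfig(nSamples = 10, nPairs = 5e3, epochs = 1, folds = 5,
                     seed = 3)
  samples <- generateTrainingSet(cfg, g, tmpl, tab)
  tr <- trainICSNet(icsNet("skewnorm", inputScale = 12), samples, cfg,
                    systemMatrixView(g, tmpl))
  expect_equal(sort(unique(tr$foldAssignment)), 1:5)
  expect_equal(length(tr$foldAssignment), 10)
  expect_equal(as.numeric(table(tr$foldAssignment)), rep(2, 5))
})

test_that("head-only training reaches the kernel-space optimal loss", {
  # single repeated sample whose target is the projection of a known
  # blur: head training should approach the optimum found by direct
  # gradient descent on the kernel itself. On this small ring the patch
  # has fewer LORs than kernel entries, so only the loss (not the
  # kernel itself) is identified; kernel recovery on an overdetermined
  # ring is checked in the acceptance suite.
  g <- toyRing()
  tmpl <- smallTemplate(c(12, 12, 8), 2)
  view <- systemMatrixView(g, tmpl)
  pos <- c(0.5, 0.5, 0.5)
  idx <- icsfilter:::containingVoxel(tmpl, pos)
  P <- patchProjector(view, idx - 5L, 11L)
  # target: geometric projection of a known kernel
  kTarget <- evaluateKernel(skewNormParams(mu = c(1, -0.5, 0),
                                           sigma = c(1.5, 1.2, 1),
                                           alpha = c(1, 0, 0)))
  ytrue <- as.numeric(P %*% as.numeric(kTarget@values))
  fitRef <- fitKernelDirect(P, ytrue, steps = 600, lr = 0.1)
  samples <- list(list(position = pos, counts = ytrue, nPairs = 0,
                       seed = 0))
  cfg <- trainConfig(nSamples = 2, nPairs = 0, epochs = 300, folds = 2,
                     seed = 1, learningRate = 1e-2, batchSize = 1,
                     headOnly = TRUE, refit = TRUE)
  # folds need >= 2 samples; bypass CV by duplicating the sample
  samples <- c(samples, samples)
  net <- icsNet("direct", inputScale = 12, seed = 2)
  tr <- trainICSNet(net, samples, cfg, view)
  preps <- icsfilter:::prepareSamples(samples, view, 11L)
  lossInit <- icsfilter:::evalLoss(net, preps[1])
  lossNet <- icsfilter:::evalLoss(tr$network, preps[1])
  # orders of magnitude of the optimality gap closed
  expect_lt(lossNet - fitRef$loss, 0.01 * (lossInit - fitRef$loss))
})
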