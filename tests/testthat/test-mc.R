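test_that("direction sampling is uniform on the sphere", {
  d <- sampleDirection(1e5, seed = 17)
  expect_lt(max(abs(sqrt(rowSums(d^2)) - 1)), 1e-12)
  expect_lt(max(abs(colMeans(d))), 4 * sqrt(1 / 3 / 1e5))
  # Archimedes: z is Uniform(-1, 1)
  ks <- suppressWarnings(ks.test(d[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("free paths follow the Beer-Lambert law", {
  s <- sampleFreePath(1e5, 0.5, seed = 3)
  expect_lt(abs(mean(s) - 2), 3 * 2 / sqrt(1e5))
  expect_lt(abs(mean(s > 4) - exp(-2)), 4 * sqrt(exp(-2) / 1e5))
  expect_true(all(is.infinite(sampleFreePath(10, 0, seed = 1))))
  expect_error(sampleFreePath(10, -1), "non-negative")
})

test_that("Compton sampling matches the Klein-Nishina closed forms and CDF", {
  # closed form: theta = 0 keeps E; 180 deg at 511 keV gives 511/3
  expect_equal(511 / (1 + (511 / 511) * (1 - cos(pi))), 511 / 3)
  cs <- sampleCompton(1e5, 511, seed = 19)
  # energy consistent with the angle for every sample
  expect_equal(cs[, "energy"],
               511 / (1 + (511 / 511) * (1 - cos(cs[, "theta"]))),
               tolerance = 1e-9)
  # empirical angle distribution vs the quadrature CDF oracle
  ks <- suppressWarnings(ks.test(cs[, "theta"],
                                 function(q) kleinNishinaCdf(q, 511)))
  expect_gt(ks$p.value, 0.01)
  # lower energy: softer spectrum, same consistency
  cs2 <- sampleCompton(2e4, 140, seed = 20)
  ks2 <- suppressWarnings(ks.test(cs2[, "theta"],
                                  function(q) kleinNishinaCdf(q, 140)))
  expect_gt(ks2$p.value, 0.01)
})

test_that("Rayleigh angles follow the Thomson law, symmetric and elastic", {
  th <- sampleRayleigh(1e5, seed = 23)
  ks <- suppressWarnings(ks.test(cos(th), thomsonCdf))
  expect_gt(ks$p.value, 0.01)
  # symmetry P(theta) = P(pi - theta) via mirrored histogram chi-square
  h1 <- hist(th, breaks = seq(0, pi, length.out = 21), plot = FALSE)$counts
  cs <- suppressWarnings(chisq.test(cbind(h1, rev(h1))))
  expect_gt(cs$p.value, 0.01)
})

test_that("photon tracing conserves energy and respects the control cases", {
  g <- toyRing()
  tab <- defaultAttenuation()
  # a ray missing the ring entirely
  miss <- tracePhoton(c(0, 0, 0), c(0, 0, 1), g, tab)
  expect_equal(nrow(miss$deposits), 0)
  expect_equal(miss$escape, 511)
  # photoelectric-only: every registered photon deposits all 511 keV once
  pe <- photoelectricOnlyTable(0.2)
  nDep <- 0
  for (s in 1:200) {
    dirv <- c(cos(s), sin(s), 0)
    tr <- tracePhoton(c(0, 0, 0), dirv / sqrt(sum(dirv^2)), g, pe, seed = s)
    if (nrow(tr$deposits) > 0) {
      nDep <- nDep + 1
      expect_equal(nrow(tr$deposits), 1)
      expect_equal(tr$deposits$energy, 511)
      expect_equal(tr$escape, 0)
    } else {
      expect_equal(tr$escape, 511)
    }
  }
  expect_gt(nDep, 50)
  # full physics: deposits + escape always sum to 511 keV
  for (s in 1:300) {
    dirv <- sampleDirection(1, seed = 1000 + s)[1, ]
    tr <- tracePhoton(c(5, -3, 2), dirv, g, tab, seed = s)
    expect_lt(abs(sum(tr$deposits$energy) + tr$escape - 511), 1e-9)
  }
})

test_that("registerHit picks the max-energy crystal with order tie-break", {
  dep <- data.frame(crystal = c(3L, 7L), energy = c(400, 111),
                    order = c(0L, 1L))
  expect_equal(registerHit(dep), 3L)
  expect_equal(registerHit(dep[2, ]), 7L)
  tie <- data.frame(crystal = c(5L, 9L), energy = c(255.5, 255.5),
                    order = c(1L, 0L))
  expect_equal(registerHit(tie), 9L)
  expect_true(is.na(registerHit(dep[0, ])))
  # summed deposits across repeated crystals
  multi <- data.frame(crystal = c(2L, 4L, 2L), energy = c(100, 150, 100),
                      order = 0:2)
  expect_equal(registerHit(multi), 2L)
})

test_that("point-source simulation is reproducible and counts are bounded", {
  g <- toyRing()
  tab <- defaultAttenuation()
  h0 <- simulatePointSource(c(0, 0, 0), 0, g, tab, seed = 1)
  expect_equal(sum(h0@counts), 0)
  h1 <- simulatePointSource(c(0, 0, 0), 2e4, g, tab, seed = 5)
  h2 <- simulatePointSource(c(0, 0, 0), 2e4, g, tab, seed = 5)
  expect_identical(h1@counts, h2@counts)
  expect_lte(sum(h1@counts), 2e4)
  expect_gt(sum(h1@counts), 0)
  # sensitivity reproducible across seeds within binomial 3 sigma
  h3 <- simulatePointSource(c(0, 0, 0), 2e4, g, tab, seed = 99)
  p <- h1@meta$nCoincidences / 2e4
  expect_lt(abs(h3@meta$nCoincidences / 2e4 - p),
            3 * sqrt(p * (1 - p) / 2e4) + 1e-9)
})

test_that("photoelectric-only coincidences are geometrically collinear", {
  g <- toyRing()
  pe <- photoelectricOnlyTable(0.2)
  src <- c(4, 2, 0)
  h <- simulatePointSource(src, 2e4, g, pe, seed = 8)
  hit <- which(h@counts > 0) - 1
  C <- nCrystals(g)
  a <- floor(C - 0.5 - sqrt((C - 0.5)^2 - 2 * hit) + 1e-9)
  b <- hit - (a * C - a * (a + 1) / 2) + a + 1
  for (i in seq_along(hit)) {
    ba <- crystalWorldBox(g, a[i])
    bb <- crystalWorldBox(g, b[i])
    # distance from source to the chord between front-face centers
    p1 <- ba$center - ba$axes[1, ] * g@crystalDepth / 2
    p2 <- bb$center - bb$axes[1, ] * g@crystalDepth / 2
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    v <- src - p1
    dist <- sqrt(sum((v - sum(v * u) * u)^2))
    expect_lt(dist, g@crystalPitchTransaxial + g@crystalPitchAxial)
  }
})

test_that("ICS mislocation exists with Compton enabled and the tracer is a geometric projector without it", {
  g <- toyRing()
  tab <- defaultAttenuation()
  h <- simulatePointSource(c(0, 0, 0), 5e4, g, tab, seed = 31)
  expect_gt(h@meta$nIcsMismatch, 0)
  # cosine similarity of the scatter-free histogram with the analytic
  # geometric (tube-model) projection of the same point source, placed
  # at a voxel center so the two sources coincide
  pe <- photoelectricOnlyTable(0.2)
  src <- c(0.75, 0.75, 0.75)
  hg <- simulatePointSource(src, 1e6, g, pe, seed = 32)
  tmpl <- smallTemplate(c(16, 16, 8), 1.5)
  view <- systemMatrixView(g, tmpl, raysPerLor = 4L)
  ps <- makePointSource(src, tmpl)
  yg <- forwardProject(ps, view)
  cosSim <- sum(hg@counts * yg@counts) /
    sqrt(sum(hg@counts^2) * sum(yg@counts^2))
  expect_gt(cosSim, 0.95)
})

test_that("the pruned ring search agrees with exhaustive box intersection", {
  for (g in list(tinyRing(8L, 1L), toyRing(), defaultGeometry())) {
    set.seed(47)
    n <- 2000
    orig <- cbind(runif(n, -55, 55), runif(n, -55, 55), runif(n, -30, 30))
    d <- sampleDirection(n, seed = 48)
    ok <- icsfilter:::cppNearestEntryCompare(orig, d,
                                             icsfilter:::geomList(g))
    expect_equal(mean(ok), 1)
  }
})

test_that("estimateLorBlur normalizes and reacts to the physics", {
  g <- toyRing()
  pe <- photoelectricOnlyTable(0.2)
  b0 <- estimateLorBlur(g, pe, nPhotons = 2e4, seed = 3)
  expect_equal(sum(b0$prob), 1)
  expect_equal(b0$prob[b0$offsetsT == 0, b0$offsetsZ == 0], 1)
  tab <- defaultAttenuation()
  b1 <- estimateLorBlur(g, tab, nPhotons = 4e4, seed = 3)
  expect_equal(sum(b1$prob), 1)
  # enabling Compton strictly moves mass off the origin
  expect_lt(b1$prob[b1$offsetsT == 0, b1$offsetsZ == 0], 1)
  expect_warning(estimateLorBlur(g, tab, nPhotons = 300, seed = 4),
                 "increase nPhotons")
})
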