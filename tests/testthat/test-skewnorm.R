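test_that("snPdf reduces to the normal density at alpha = 0 and integrates to 1", {
  expect_equal(snPdf(0, 0, 1, 0), 1 / sqrt(2 * pi))
  x <- seq(-4, 4, by = 0.37)
  expect_equal(snPdf(x, 1.2, 0.8, 0), dnorm(x, 1.2, 0.8))
  # unit mass by adaptive quadrature for a skewed case
  q <- integrate(function(x) snPdf(x, 1.3, 0.7, -2.5), -Inf, Inf,
                 rel.tol = 1e-10)
  expect_lt(abs(q$value - 1), 1e-8)
  # reflection symmetry in alpha
  set.seed(21)
  xs <- runif(50, -4, 4)
  as <- runif(50, -5, 5)
  expect_equal(snPdf(xs, 0, 1, as), snPdf(-xs, 0, 1, -as))
  expect_error(snPdf(0, 0, -1, 0), "sigma")
})

test_that("snPdf agrees with an independent erf-based evaluation", {
  skip_if_not_installed("pracma")
  x <- seq(-3, 5, by = 0.21)
  mu <- 0.7; sigma <- 1.3; alpha <- 2.2
  t <- (x - mu) / sigma
  oracle <- 2 / sigma * exp(-t^2 / 2) / sqrt(2 * pi) *
    0.5 * (1 + pracma::erf(alpha * t / sqrt(2)))
  expect_equal(snPdf(x, mu, sigma, alpha), oracle, tolerance = 1e-12)
})

test_that("the xy rotation matrix acts as printed and spares the z axis", {
  # R(90 deg) (1,0,0) = (0,-1,0)
  p <- skewNormParams(mu = c(0.3, -0.7, 1.1), sigma = c(1, 2, 0.5),
                      alpha = c(1, -2, 0), theta = 90)
  p0 <- skewNormParams(mu = p@mu, sigma = p@sigma, alpha = p@alpha,
                       theta = 0)
  expect_equal(sn3d(c(1, 0, 0), p), sn3d(c(0, -1, 0), p0))
  # theta = 0 is the plain product of axis densities
  x <- c(0.4, -1.2, 2)
  expect_equal(sn3d(x, p0),
               snPdf(x[1], 0.3, 1, 1) * snPdf(x[2], -0.7, 2, -2) *
                 snPdf(x[3], 1.1, 0.5, 0))
  # z factor unaffected by any rotation
  for (th in c(33, 90, 211, 316)) {
    pth <- skewNormParams(p@mu, p@sigma, p@alpha, th)
    f1 <- sn3d(rbind(c(0, 0, -3), c(0, 0, 3)), pth)
    f2 <- sn3d(rbind(c(0, 0, -3), c(0, 0, 3)), p0)
    expect_equal(f1, f2)
  }
})

test_that("evaluateKernel is normalized, non-negative and symmetric when isotropic", {
  k <- evaluateKernel(skewNormParams(sigma = c(2, 2, 2)))
  expect_equal(sum(k@values), 1, tolerance = 1e-12)
  expect_true(all(k@values >= 0))
  expect_equal(which.max(k@values),
               cumprod(c(1, 11, 11))[3] * 5 + 11 * 5 + 6)  # center voxel
  # all axis flips and permutations leave the isotropic kernel unchanged
  v <- k@values
  expect_equal(v, v[11:1, , ]); expect_equal(v, v[, 11:1, ])
  expect_equal(v, v[, , 11:1]); expect_equal(v, aperm(v, c(2, 1, 3)))
  expect_equal(v, aperm(v, c(3, 2, 1)))
})

test_that("a drop-shaped parameter set yields an off-origin kernel matching dense re-evaluation", {
  p <- skewNormParams(mu = c(3, 3, 0), sigma = c(1.5, 5, 1.5),
                      alpha = c(0.5, -4, 0.5), theta = 316)
  k <- evaluateKernel(p)
  expect_equal(sum(k@values), 1, tolerance = 1e-12)
  g <- icsfilter:::kernelGrid(11L)
  com <- colSums(g * as.numeric(k@values))
  # elongated, clearly off-origin in the xy plane (drop-like)
  expect_gt(sqrt(sum(com[1:2]^2)), 1)
  expect_lt(abs(com[3]), 1)
  # independent dense evaluation through sn3d on the rotated grid
  f <- sn3d(g, p)
  expect_equal(as.numeric(k@values), f / sum(f), tolerance = 1e-12)
})

test_that("kernel parameter gradients match central finite differences", {
  set.seed(33)
  worst <- 0
  for (rep in 1:20) {
    raw <- c(runif(3, -3, 3), runif(3, 0.3, 4), runif(3, -3, 3),
             runif(1, 10, 350))
    ek <- evaluateKernel(clampParams(raw), gradient = TRUE)
    j <- sample(10, 3)
    for (jj in j) {
      e <- rep(0, 10); e[jj] <- 1e-4
      kp <- evaluateKernel(clampParams(raw + e))
      km <- evaluateKernel(clampParams(raw - e))
      fd <- (as.numeric(kp@values) - as.numeric(km@values)) / 2e-4
      denom <- max(abs(fd), 1e-8)
      worst <- max(worst, max(abs(ek$jacobian[, jj] - fd)) / denom)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("normalization and non-negativity hold across the clamp box", {
  set.seed(34)
  for (rep in 1:40) {
    raw <- c(runif(3, -8, 8), runif(3, -1, 12), runif(3, -8, 8),
             runif(1, -40, 420))
    k <- evaluateKernel(clampParams(raw))
    expect_equal(sum(k@values), 1, tolerance = 1e-6)
    expect_gte(min(k@values), 0)
  }
})

test_that("clampParams clamps to the printed ranges", {
  raw <- c(0, -7, 7, 0, 11, 5, -6, 6, 0, 400)
  p <- clampParams(raw)
  expect_equal(p@mu, c(0, -5, 5))
  expect_equal(p@sigma, c(0.01, 10, 5))
  expect_equal(p@alpha, c(-5, 5, 0))
  expect_equal(p@theta, 360)
  inRange <- c(1, -2, 3, 0.5, 2, 9, -4, 0, 4, 180)
  p2 <- clampParams(inRange)
  expect_equal(c(p2@mu, p2@sigma, p2@alpha, p2@theta), inRange)
})

test_that("mirrorKernel is an involution matching mirrored parameters", {
  p <- skewNormParams(mu = c(3, 0, 0), sigma = c(1.5, 2, 1), alpha = c(0, 0, 0))
  k <- evaluateKernel(p)
  m <- mirrorKernel(k, c(TRUE, FALSE, FALSE))
  expect_equal(sum(m@values), 1)
  expect_equal(mirrorKernel(m, c(TRUE, FALSE, FALSE))@values, k@values)
  pneg <- skewNormParams(mu = c(-3, 0, 0), sigma = c(1.5, 2, 1))
  expect_equal(m@values, evaluateKernel(pneg)@values, tolerance = 1e-12)
  # with skewness the mirrored kernel equals negated mu AND alpha
  ps <- skewNormParams(mu = c(2, 0, 0), sigma = c(1.5, 2, 1),
                       alpha = c(3, 0, 0))
  psm <- skewNormParams(mu = c(-2, 0, 0), sigma = c(1.5, 2, 1),
                        alpha = c(-3, 0, 0))
  expect_equal(mirrorKernel(evaluateKernel(ps), c(TRUE, FALSE, FALSE))@values,
               evaluateKernel(psm)@values, tolerance = 1e-12)
})
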