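# The rotated 3D skew normal and its discretization into filter kernels.
# The univariate density is (2/sigma) phi(t) Phi(alpha t), t = (x - mu) /
# sigma, with phi/Phi the exact standard normal PDF/CDF; the 3D form is
# the product of independent axis densities evaluated at xy-rotated grid
# points. Discretized on the integer grid [-5, 5]^3 and normalized to sum
# to one. All evaluation is done in log space so narrow kernels do not
# underflow, and the 10 parameter gradients are analytic.

#' Univariate skew normal density
#'
#' `(2 / sigma) * dnorm((x - mu) / sigma) * pnorm(alpha * (x - mu) / sigma)`.
#' `alpha = 0` recovers the normal density; negating `alpha` mirrors the
#' density about `mu`.
#'
#' @param x evaluation points (vectorized).
#' @param mu location.
#' @param sigma scale, > 0.
#' @param alpha skewness.
#' @return density values.
#' @export
snPdf <- function(x, mu = 0, sigma = 1, alpha = 0) {
  stopIfNot(sigma > 0, "sigma must be positive")
  t <- (x - mu) / sigma
  2 / sigma * stats::dnorm(t) * stats::pnorm(alpha * t)
}

#' Construct skew-normal kernel parameters
#'
#' @param mu,sigma,alpha per-axis location / scale / skewness (length 3;
#'   kernel-grid units).
#' @param theta xy-plane rotation, degrees.
#' @return a [SkewNormParams-class].
#' @export
skewNormParams <- function(mu = c(0, 0, 0), sigma = c(1, 1, 1),
                           alpha = c(0, 0, 0), theta = 0) {
  new("SkewNormParams", mu = as.numeric(mu), sigma = as.numeric(sigma),
      alpha = as.numeric(alpha), theta = as.numeric(theta))
}

# xy-plane rotation applied to grid points before evaluation:
# x' = R(theta) x, R = [cos sin 0; -sin cos 0; 0 0 1], theta in degrees.
rotateGrid <- function(points, thetaDeg) {
  th <- thetaDeg * pi / 180
  c0 <- cos(th); s0 <- sin(th)
  cbind(c0 * points[, 1] + s0 * points[, 2],
        -s0 * points[, 1] + c0 * points[, 2],
        points[, 3])
}

#' Rotated 3D skew normal density
#'
#' Product of the three axis densities evaluated at the rotated point
#' `x' = R(theta) x`; the rotation acts only in the xy plane (cylindrical
#' scanner symmetry), leaving the z factor untouched.
#'
#' @param x length-3 point or n x 3 matrix.
#' @param params a [SkewNormParams-class].
#' @return density values.
#' @export
sn3d <- function(x, params) {
  validObject(params)
  p <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  xp <- rotateGrid(p, params@theta)
  out <- rep(1, nrow(xp))
  for (d in 1:3)
    out <- out * snPdf(xp[, d], params@mu[d], params@sigma[d],
                       params@alpha[d])
  if (is.matrix(x)) out else drop(out)
}

# integer kernel grid in R array order (x fastest), side k
kernelGrid <- function(k = 11L) {
  h <- (k - 1L) %/% 2L
  g <- seq(-h, h)
  cbind(rep(g, times = k * k),
        rep(rep(g, each = k), times = k),
        rep(g, each = k * k))
}

#' Discretize the rotated skew normal into a filter kernel
#'
#' Evaluates the density on the integer grid `[-5, 5]^3` (side
#' `kernelSize`) and normalizes to sum one. With `gradient = TRUE` the
#' analytic Jacobian of the normalized kernel with respect to the 10
#' parameters (mu1..3, sigma1..3, alpha1..3, theta) is attached; it
#' matches central finite differences to better than 1e-4 relative.
#'
#' @param params a [SkewNormParams-class] (already clamped).
#' @param kernelSize kernel side length (odd).
#' @param gradient also return the `kernelSize^3 x 10` Jacobian.
#' @return a [FilterKernel-class]; with `gradient = TRUE` a list
#'   `list(kernel, jacobian)`.
#' @export
evaluateKernel <- function(params, kernelSize = 11L, gradient = FALSE) {
  validObject(params)
  G <- kernelGrid(kernelSize)
  xp <- rotateGrid(G, params@theta)
  n <- nrow(G)
  logf <- rep(0, n)
  dlog <- if (gradient) matrix(0, n, 10) else NULL
  thRad <- params@theta * pi / 180
  for (d in 1:3) {
    t <- (xp[, d] - params@mu[d]) / params@sigma[d]
    at <- params@alpha[d] * t
    lPhi <- stats::pnorm(at, log.p = TRUE)
    logf <- logf + log(2) - log(params@sigma[d]) +
      stats::dnorm(t, log = TRUE) + lPhi
    if (gradient) {
      # hazard of the CDF factor: phi(at) / Phi(at), stable in logs
      h <- exp(stats::dnorm(at, log = TRUE) - lPhi)
      dldt <- -t + params@alpha[d] * h          # d log f / d t_d
      dlog[, 3 + d] <- (-1 - t * dldt) / params@sigma[d]  # sigma_d
      dlog[, d] <- -dldt / params@sigma[d]                # mu_d
      dlog[, 6 + d] <- t * h                              # alpha_d
      if (d == 1) dlog[, 10] <- dlog[, 10] + dldt * xp[, 2] /
          params@sigma[1]
      if (d == 2) dlog[, 10] <- dlog[, 10] - dldt * xp[, 1] /
          params@sigma[2]
    }
  }
  if (gradient) dlog[, 10] <- dlog[, 10] * pi / 180  # theta in degrees
  m <- max(logf)
  if (!is.finite(m))
    stop("kernel underflowed to zero everywhere; widen sigma", call. = FALSE)
  f <- exp(logf - m)
  S <- sum(f)
  k <- f / S
  kern <- new("FilterKernel",
              values = array(k, dim = rep(kernelSize, 3)))
  if (!gradient) return(kern)
  # d k_i / d p = k_i (g_i - sum_j k_j g_j) for g = d log f / d p
  jac <- k * sweep(dlog, 2, colSums(k * dlog), "-")
  list(kernel = kern, jacobian = jac)
}

# Vectorized kernel evaluation for many (already clamped) parameter
# rows at once: same log-space math as evaluateKernel, chunked to bound
# memory. Returns an n x kernelSize^3 matrix of normalized kernels.
evaluateKernelBatch <- function(params, kernelSize = 11L,
                                chunk = 1024L) {
  n <- nrow(params)
  G <- kernelGrid(kernelSize)
  out <- matrix(0, n, kernelSize^3)
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    idx <- lo:hi
    th <- params[idx, 10] * pi / 180
    # rotated grid coordinates per row: m x 1331
    x1 <- outer(cos(th), G[, 1]) + outer(sin(th), G[, 2])
    x2 <- outer(-sin(th), G[, 1]) + outer(cos(th), G[, 2])
    x3 <- matrix(G[, 3], length(idx), nrow(G), byrow = TRUE)
    logf <- 0
    for (d in 1:3) {
      xp <- list(x1, x2, x3)[[d]]
      t <- (xp - params[idx, d]) / params[idx, 3 + d]
      at <- params[idx, 6 + d] * t
      logf <- logf + log(2) - log(params[idx, 3 + d]) +
        stats::dnorm(t, log = TRUE) + stats::pnorm(at, log.p = TRUE)
    }
    m <- apply(logf, 1, max)
    f <- exp(logf - m)
    out[idx, ] <- f / rowSums(f)
  }
  out
}

#' Clamp a raw 10-parameter vector to the valid ranges
#'
#' Components outside their valid range are clamped to the closest valid
#' value: `mu` to [-5, 5], `sigma` to [0.01, 10], `alpha` to [-5, 5],
#' `theta` to [0, 360] degrees (a hard clamp, not a modular wrap).
#'
#' @param raw numeric vector `(mu1..3, sigma1..3, alpha1..3, theta)`.
#' @return a [SkewNormParams-class].
#' @export
clampParams <- function(raw) {
  stopIfNot(length(raw) == 10L, "raw parameter vector must have length 10")
  skewNormParams(mu = pmin(pmax(raw[1:3], -5), 5),
                 sigma = pmin(pmax(raw[4:6], 0.01), 10),
                 alpha = pmin(pmax(raw[7:9], -5), 5),
                 theta = min(max(raw[10], 0), 360))
}

# gradient mask of the hard clamp (1 inside the range, 0 at/outside the
# bounds unless straightThrough)
clampMask <- function(raw, straightThrough = FALSE) {
  if (straightThrough) return(rep(1, 10))
  lo <- c(rep(-5, 3), rep(0.01, 3), rep(-5, 3), 0)
  hi <- c(rep(5, 3), rep(10, 3), rep(5, 3), 360)
  as.numeric(raw > lo & raw < hi)
}

#' Mirror a filter kernel across axes
#'
#' Reverses the kernel array along the flipped axes; the kernel stays
#' normalized. Mirroring realizes the octant symmetry used to reduce
#' kernel storage: the kernel at a reflected voxel position equals the
#' reflected kernel.
#'
#' @param kernel a [FilterKernel-class].
#' @param flips logical length 3: flip x / y / z.
#' @return a [FilterKernel-class].
#' @export
mirrorKernel <- function(kernel, flips = c(FALSE, FALSE, FALSE)) {
  v <- kernel@values
  k <- dim(v)[1]
  ix <- if (flips[1]) k:1 else 1:k
  iy <- if (flips[2]) k:1 else 1:k
  iz <- if (flips[3]) k:1 else 1:k
  new("FilterKernel", values = v[ix, iy, iz, drop = FALSE])
}

#' Construct a filter kernel from raw values
#'
#' Normalizes a non-negative array to sum one.
#'
#' @param values cubic odd-sized non-negative array.
#' @return a [FilterKernel-class].
#' @export
filterKernel <- function(values) {
  s <- sum(values)
  stopIfNot(s > 0, "kernel values sum to zero")
  new("FilterKernel", values = values / s)
}

#' The centered delta kernel
#'
#' @param kernelSize side length.
#' @return a [FilterKernel-class] with all mass at the center.
#' @export
deltaKernel <- function(kernelSize = 11L) {
  v <- array(0, dim = rep(kernelSize, 3))
  c0 <- (kernelSize + 1) / 2
  v[c0, c0, c0] <- 1
  new("FilterKernel", values = v)
}
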