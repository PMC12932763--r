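# Shared fixtures: small scanners and templates, built in code.

tinyRing <- function(nCrystals = 8L, nRings = 1L) {
  scannerGeometry(ringRadius = 20, nCrystalsTransaxial = nCrystals,
                  nRings = nRings, crystalPitchAxial = 6, crystalDepth = 8)
}

toyRing <- function() {
  # 16 x 2 crystals: big enough for meaningful sinograms, small enough
  # for exhaustive checks
  scannerGeometry(ringRadius = 24, nCrystalsTransaxial = 16, nRings = 2,
                  crystalPitchAxial = 6, crystalDepth = 8)
}

smallTemplate <- function(dims = c(16, 16, 8), voxelSize = 1.5) {
  imageVolume(dims = dims, voxelSize = voxelSize)
}

# analytic CDF of the Thomson angular distribution in mu = cos(theta)
thomsonCdf <- function(mu) {
  ((mu + mu^3 / 3) + 4 / 3) / (8 / 3)
}

# numerically integrated Klein-Nishina CDF of the scattering angle at a
# given photon energy: independent quadrature oracle (dense trapezoid
# grid, interpolated; grid error ~1e-9, far below KS resolution)
kleinNishinaCdf <- function(theta, energyKeV) {
  k <- energyKeV / 511
  grid <- seq(0, pi, length.out = 8192)
  eps <- 1 / (1 + k * (1 - cos(grid)))
  f <- 0.5 * eps^2 * (eps + 1 / eps - sin(grid)^2) * sin(grid)
  cdf <- cumsum(c(0, diff(grid) * (head(f, -1) + tail(f, -1)) / 2))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(grid, cdf, xout = theta, rule = 2)$y
}
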