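# Monte Carlo detector model. Photon pairs are launched back-to-back in a
# direction uniform on the sphere; inside crystal material free paths
# follow the Beer-Lambert law for the energy-dependent total attenuation,
# interaction types are chosen proportionally to the partial coefficients
# (photoelectric absorbs, Compton samples angle/energy from Klein-Nishina,
# Rayleigh samples the Thomson angle elastically). Space between crystal
# boxes is vacuum. Photons below 10 keV are terminated, depositing the
# remainder locally; a photon traversing the ring without interacting is
# discarded. A hit registers at the crystal with the maximum summed energy
# deposit (ties: earliest interaction). All randomness is counter-based:
# one sub-stream per photon-pair index, so a (seed, pair) combination is
# reproducible regardless of batching.

#' Sample directions uniformly on the unit sphere
#'
#' @param n number of samples.
#' @param seed integer seed (counter-based stream).
#' @return n x 3 matrix of unit vectors.
#' @export
sampleDirection <- function(n, seed = 1L) {
  cppSampleDirection(as.integer(n), as.integer(seed))
}

#' Sample Beer-Lambert free path lengths
#'
#' Exponential with rate `mu`; `mu = 0` yields `Inf` (the photon escapes).
#'
#' @param n number of samples.
#' @param mu total linear attenuation coefficient, 1/mm (>= 0).
#' @param seed integer seed.
#' @return path lengths in mm.
#' @export
sampleFreePath <- function(n, mu, seed = 1L) {
  stopIfNot(mu >= 0, "mu must be non-negative")
  cppSampleFreePath(as.integer(n), mu, as.integer(seed))
}

#' Sample Compton scattering from the Klein-Nishina distribution
#'
#' Scattering angles follow the differential Klein-Nishina cross-section
#' at the given photon energy; the scattered energy is the Compton
#' closed form `E' = E / (1 + (E/511)(1 - cos theta))`.
#'
#' @param n number of samples.
#' @param energy photon energy in keV (> 0).
#' @param seed integer seed.
#' @return matrix with columns `theta` (radians) and `energy` (keV).
#' @export
sampleCompton <- function(n, energy, seed = 1L) {
  stopIfNot(energy > 0, "energy must be positive")
  out <- cppSampleCompton(as.integer(n), energy, as.integer(seed))
  colnames(out) <- c("theta", "energy")
  out
}

#' Sample Rayleigh (Thomson) scattering angles
#'
#' Angles distributed proportionally to `(1 + cos^2 theta) sin theta`;
#' the photon energy is unchanged (elastic).
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @return angles in radians.
#' @export
sampleRayleigh <- function(n, seed = 1L) {
  cppSampleRayleigh(as.integer(n), as.integer(seed))
}

#' Trace a single photon through the detector ring
#'
#' @param position world start point (mm), outside the crystals.
#' @param direction unit direction.
#' @param geometry the scanner.
#' @param table attenuation matrix (see [defaultAttenuation()]).
#' @param energy start energy, keV.
#' @param seed integer seed.
#' @param cutoff termination energy, keV.
#' @return list with a deposit data frame (`crystal`, `energy`, `order`)
#'   and the escaping energy `escape` (0 when fully absorbed); the
#'   deposit list is empty if the photon crossed without interacting.
#' @export
tracePhoton <- function(position, direction, geometry,
                        table = defaultAttenuation(), energy = 511,
                        seed = 1L, cutoff = 10) {
  stopIfNot(abs(sqrt(sum(direction^2)) - 1) < 1e-9,
            "direction must be a unit vector")
  res <- cppTracePhoton(as.numeric(position), as.numeric(direction),
                        energy, geomList(geometry), table,
                        as.integer(seed), cutoff)
  list(deposits = data.frame(crystal = res$crystal, energy = res$energy,
                             order = res$order),
       escape = res$escape)
}

#' Registered crystal of a deposit list
#'
#' The crystal with the maximum summed deposited energy; exact ties go to
#' the crystal of the earliest interaction. An empty list registers
#' nothing (`NA`).
#'
#' @param deposits data frame with `crystal`, `energy`, `order` columns.
#' @return the crystal id, or `NA` for no hit.
#' @export
registerHit <- function(deposits) {
  if (nrow(deposits) == 0L) return(NA_integer_)
  res <- cppRegisterHit(as.integer(deposits$crystal),
                        as.numeric(deposits$energy),
                        as.integer(deposits$order))
  res[1]
}

#' Simulate a point-source acquisition
#'
#' Launches `nPairs` back-to-back 511 keV photon pairs from `position`,
#' traces both photons through the ring and records a coincidence when
#' both register in distinct crystals. Object attenuation and scatter are
#' not modelled (detector-only transport).
#'
#' @param position source point, mm.
#' @param nPairs number of photon pairs.
#' @param geometry the scanner.
#' @param table attenuation matrix.
#' @param seed integer seed; fixed seed gives a bit-identical histogram.
#' @return a [LORHistogram-class]; `meta` holds `nPairs`,
#'   `nCoincidences`, `nRegistered` (single photons registered) and
#'   `nIcsMismatch` (registered photons whose max-energy crystal is not
#'   their first-interaction crystal).
#' @export
simulatePointSource <- function(position, nPairs, geometry,
                                table = defaultAttenuation(), seed = 1L) {
  stopIfNot(nPairs >= 0, "nPairs must be non-negative")
  res <- cppSimulatePointSource(as.numeric(position), as.numeric(nPairs),
                                geomList(geometry), table,
                                as.integer(seed))
  lorHistogram(res$counts, geometry,
               meta = list(kind = "point", position = as.numeric(position),
                           nPairs = nPairs, seed = seed,
                           nCoincidences = res$nCoincidences,
                           nRegistered = res$nRegistered,
                           nIcsMismatch = res$nIcsMismatch))
}

#' Simulate an acquisition of a voxelized activity distribution
#'
#' Annihilation points are drawn proportionally to voxel activity
#' (uniform within each voxel); each point emits one back-to-back pair.
#'
#' @param volume an [ImageVolume-class] activity distribution.
#' @param nPairs number of photon pairs.
#' @param geometry the scanner.
#' @param table attenuation matrix.
#' @param seed integer seed.
#' @return a [LORHistogram-class].
#' @export
simulateEmission <- function(volume, nPairs, geometry,
                             table = defaultAttenuation(), seed = 1L) {
  v <- as.numeric(volume@values)
  nz <- which(v > 0)
  stopIfNot(length(nz) > 0, "volume has no activity")
  centers <- voxelCenters(volume)[nz, , drop = FALSE]
  cum <- cumsum(v[nz]) / sum(v[nz])
  res <- cppSimulateEmission(centers, cum, volume@voxelSize,
                             as.numeric(nPairs), geomList(geometry), table,
                             as.integer(seed))
  lorHistogram(res$counts, geometry,
               meta = list(kind = "emission", nPairs = nPairs, seed = seed,
                           nCoincidences = res$nCoincidences,
                           nIcsMismatch = res$nIcsMismatch))
}

#' Estimate the LOR-domain endpoint mislocation blur
#'
#' High-sample Monte Carlo estimate of the distribution of
#' `registered crystal - entry crystal` offsets (transaxial and axial
#' index units) for perpendicular-incidence photons on random crystal
#' front faces. Used as the spatially invariant LOR-domain blur of the
#' reference correction.
#'
#' @param geometry the scanner.
#' @param table attenuation matrix.
#' @param nPhotons number of photons.
#' @param seed integer seed.
#' @param kt,kz maximum transaxial / axial offsets kept.
#' @return list with the normalized offset matrix `prob`
#'   (`(2*kt+1) x (2*kz+1)`, rows = transaxial offsets), `offsetsT`,
#'   `offsetsZ`, and the registered-photon count `nRegistered`. Warns if
#'   any bin has expected count below 10.
#' @export
estimateLorBlur <- function(geometry, table = defaultAttenuation(),
                            nPhotons = 2e5, seed = 1L, kt = 5L, kz = 2L) {
  res <- cppEstimateLorBlur(geomList(geometry), table,
                            as.numeric(nPhotons), as.integer(seed),
                            as.integer(kt), as.integer(kz))
  tot <- sum(res$hist)
  stopIfNot(tot > 0, "no photon registered; blur estimate is degenerate")
  if (tot / length(res$hist) < 10)
    warning("fewer than 10 expected counts per offset bin; ",
            "increase nPhotons")
  list(prob = res$hist / tot,
       offsetsT = -kt:kt, offsetsZ = -kz:kz,
       nRegistered = res$nRegistered)
}
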