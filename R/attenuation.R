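# Attenuation model of the scintillator. The shipped table
# (inst/extdata/lyso_synthetic_attenuation.csv) is synthetic: it is
# computed from an analytic model (Klein-Nishina total cross-section for
# Compton on an LYSO-like electron density, E^-3-scaled photoelectric
# pinned to a realistic 511 keV photofraction, small E^-2 Rayleigh term)
# rather than taken from a measured compilation. tools/
# make_attenuation_table.R regenerates it.

validateAttenuation <- function(tab) {
  stopIfNot(is.matrix(tab) && ncol(tab) == 4L,
            "attenuation table must have 4 columns")
  stopIfNot(all(diff(tab[, 1]) > 0),
            "attenuation energy grid must be strictly increasing")
  stopIfNot(tab[1, 1] <= 50 && tab[nrow(tab), 1] >= 600,
            "attenuation grid must cover at least [50, 600] keV")
  stopIfNot(all(tab[, 2:4] >= 0),
            "attenuation coefficients must be non-negative")
  colnames(tab) <- c("energy_keV", "mu_photo", "mu_compton", "mu_rayleigh")
  tab
}

#' Read an attenuation table (CSV)
#'
#' Expects columns `energy_keV, mu_photo, mu_compton, mu_rayleigh` with
#' linear attenuation coefficients in 1/mm; the grid must be strictly
#' increasing and cover at least 50-600 keV.
#'
#' @param path CSV file path.
#' @return numeric matrix with the four validated columns.
#' @export
readAttenuationTable <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  validateAttenuation(as.matrix(df[, c("energy_keV", "mu_photo",
                                       "mu_compton", "mu_rayleigh")]))
}

#' Klein-Nishina total cross-section per electron
#'
#' Integrated Klein-Nishina cross-section at reduced photon energy
#' `k = E / 511 keV`, in cm^2 per electron.
#'
#' @param k reduced photon energy (vectorized).
#' @return cross-sections in cm^2.
#' @export
kleinNishinaTotal <- function(k) {
  re2 <- 2.8179403262e-13^2   # classical electron radius squared, cm^2
  l <- log(1 + 2 * k)
  2 * pi * re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - l / k) +
                    l / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

#' Analytic attenuation model (LYSO-like)
#'
#' Pluggable analytic fallback: Compton from the integrated Klein-Nishina
#' cross-section times the material electron density; photoelectric scaled
#' as `E^-3` and pinned at 511 keV; Rayleigh a small `E^-2` term.
#'
#' @param energies keV grid (strictly increasing, covering 50-600 keV).
#' @param electronDensity electrons per cm^3.
#' @param muPhoto511,muRayleigh511 pinned coefficients at 511 keV, 1/mm.
#' @return attenuation matrix as in [readAttenuationTable()].
#' @export
analyticAttenuation <- function(energies = exp(seq(log(50), log(650),
                                                   length.out = 41)),
                                electronDensity = 1.826e24,
                                muPhoto511 = 0.028,
                                muRayleigh511 = 0.004) {
  muC <- electronDensity * kleinNishinaTotal(energies / 511) / 10  # 1/mm
  muP <- muPhoto511 * (511 / energies)^3
  muR <- muRayleigh511 * (511 / energies)^2
  validateAttenuation(cbind(energies, muP, muC, muR))
}

.attenCache <- new.env(parent = emptyenv())

#' The shipped synthetic LYSO-like attenuation table
#'
#' @return attenuation matrix as in [readAttenuationTable()].
#' @export
defaultAttenuation <- function() {
  if (is.null(.attenCache$lyso)) {
    path <- system.file("extdata", "lyso_synthetic_attenuation.csv",
                        package = "icsfilter")
    .attenCache$lyso <- readAttenuationTable(path)
  }
  .attenCache$lyso
}

#' Photoelectric-only table (diagnostics)
#'
#' A table with Compton and Rayleigh switched off; every detected photon
#' is absorbed at its first interaction, so no inter-crystal scattering
#' can occur. Used as a control in tests and blur estimation.
#'
#' @param mu constant photoelectric coefficient, 1/mm.
#' @return attenuation matrix.
#' @export
photoelectricOnlyTable <- function(mu = 0.083) {
  validateAttenuation(cbind(c(50, 600), rep(mu, 2), c(0, 0), c(0, 0)))
}

#' Interpolate attenuation coefficients
#'
#' Log-log interpolation (clamped at the grid ends), matching the lookup
#' the Monte Carlo tracer uses.
#'
#' @param table attenuation matrix.
#' @param energy photon energy in keV (vectorized).
#' @return matrix with columns `mu_photo, mu_compton, mu_rayleigh, mu_total`.
#' @export
attenuationLookup <- function(table, energy) {
  le <- pmin(pmax(log(energy), log(table[1, 1])),
             log(table[nrow(table), 1]))
  interp <- function(col) {
    pos <- table[, col] > 0
    if (!any(pos)) return(rep(0, length(le)))
    exp(stats::approx(log(table[, 1]), log(pmax(table[, col], 1e-300)),
                      xout = le, rule = 2)$y)
  }
  mp <- interp(2); mc <- interp(3); mr <- interp(4)
  cbind(mu_photo = mp, mu_compton = mc, mu_rayleigh = mr,
        mu_total = mp + mc + mr)
}
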