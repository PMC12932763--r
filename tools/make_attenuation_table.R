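# Regenerates inst/extdata/lyso_synthetic_attenuation.csv from the
# analytic LYSO-like model (see R/attenuation.R). Run from the package
# root with the package loadable (pkgload) or installed.
pkgload::load_all(".", quiet = TRUE)
tab <- analyticAttenuation()
out <- file.path("inst", "extdata", "lyso_synthetic_attenuation.csv")
con <- file(out, "w")
writeLines(c(
  "# Synthetic LYSO-like linear attenuation coefficients (1/mm).",
  "# Computed analytically: Compton = electron density x integrated",
  "# Klein-Nishina cross-section; photoelectric ~ E^-3 pinned at 511 keV;",
  "# Rayleigh ~ E^-2, small. Not a measured compilation.",
  "# Regenerate with: Rscript tools/make_attenuation_table.R"
), con)
utils::write.csv(as.data.frame(tab), con, row.names = FALSE)
close(con)
cat("wrote", out, "\n")
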