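# Internal helpers: seeded evaluation and a tiny FNV-1a hash used to
# fingerprint geometries and experiment manifests.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# FNV-1a (32-bit) over a character representation; identification only.
fnvHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); h stays a double below 2^32
    low <- h %% 256
    h <- h - low + bitwXor(low, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

geometryHash <- function(geometry) {
  fnvHash(list(geometry@ringRadius, geometry@nCrystalsTransaxial,
               geometry@nRings, geometry@crystalPitchTransaxial,
               geometry@crystalPitchAxial, geometry@crystalDepth,
               geometry@crystalWidthTransaxial, geometry@crystalWidthAxial,
               geometry@axialFov, geometry@material))
}

# list form consumed by the C++ layer
geomList <- function(geometry) {
  list(ringRadius = geometry@ringRadius,
       nCrystalsTransaxial = geometry@nCrystalsTransaxial,
       nRings = geometry@nRings,
       crystalPitchTransaxial = geometry@crystalPitchTransaxial,
       crystalPitchAxial = geometry@crystalPitchAxial,
       crystalDepth = geometry@crystalDepth,
       crystalWidthTransaxial = geometry@crystalWidthTransaxial,
       crystalWidthAxial = geometry@crystalWidthAxial)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
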