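#' Construct a scanner geometry
#'
#' Builds a [ScannerGeometry-class] describing a cylindrical ring of
#' radially oriented rectangular crystals. Crystal widths default to the
#' pitches (transaxially capped at 99.9% of the chord between neighboring
#' box centers so boxes never overlap).
#'
#' @param ringRadius inner (front face) radius in mm.
#' @param nCrystalsTransaxial crystals per ring.
#' @param nRings number of rings.
#' @param crystalPitchTransaxial transaxial pitch in mm; default the inner
#'   arc `2 * pi * ringRadius / nCrystalsTransaxial`.
#' @param crystalPitchAxial axial pitch in mm.
#' @param crystalDepth radial crystal extent in mm.
#' @param crystalWidthTransaxial,crystalWidthAxial crystal face widths in
#'   mm; defaults derived from the pitches.
#' @param material attenuation-table identifier.
#' @return a validated [ScannerGeometry-class].
#' @examples
#' geom <- scannerGeometry(ringRadius = 40, nCrystalsTransaxial = 64,
#'                         nRings = 8)
#' nLORs(geom)
#' @export
scannerGeometry <- function(ringRadius, nCrystalsTransaxial, nRings,
                            crystalPitchTransaxial = NULL,
                            crystalPitchAxial = 4.4,
                            crystalDepth = 10,
                            crystalWidthTransaxial = NULL,
                            crystalWidthAxial = NULL,
                            material = "lyso_synthetic") {
  if (is.null(crystalPitchTransaxial))
    crystalPitchTransaxial <- 2 * pi * ringRadius / nCrystalsTransaxial
  rc <- ringRadius + crystalDepth / 2
  chord <- 2 * rc * sin(pi / nCrystalsTransaxial)
  if (is.null(crystalWidthTransaxial))
    crystalWidthTransaxial <- min(crystalPitchTransaxial, 0.999 * chord)
  if (is.null(crystalWidthAxial))
    crystalWidthAxial <- crystalPitchAxial
  new("ScannerGeometry",
      ringRadius = as.numeric(ringRadius),
      nCrystalsTransaxial = as.integer(nCrystalsTransaxial),
      nRings = as.integer(nRings),
      crystalPitchTransaxial = as.numeric(crystalPitchTransaxial),
      crystalPitchAxial = as.numeric(crystalPitchAxial),
      crystalDepth = as.numeric(crystalDepth),
      crystalWidthTransaxial = as.numeric(crystalWidthTransaxial),
      crystalWidthAxial = as.numeric(crystalWidthAxial),
      axialFov = as.numeric(nRings * crystalPitchAxial),
      material = material)
}

#' The package's stand-in small-animal scanner
#'
#' A desk-scale, fully reproducible ring used throughout the examples and
#' the shipped experiments: 64 transaxial crystals x 8 rings at 40 mm
#' radius, 10 mm crystal depth, 4.4 mm axial pitch (35.2 mm axial FOV),
#' with the synthetic LYSO-like attenuation table.
#'
#' @return a [ScannerGeometry-class].
#' @export
defaultGeometry <- function() {
  scannerGeometry(ringRadius = 40, nCrystalsTransaxial = 64, nRings = 8)
}

#' Construct an image volume
#'
#' @param values 3D array of non-negative activities, or `NULL` for zeros.
#' @param dims volume dimensions (used when `values` is `NULL` or a
#'   scalar).
#' @param voxelSize mm per voxel, scalar or length 3.
#' @param center world coordinate of the volume center (mm); default the
#'   scanner center (origin).
#' @return an [ImageVolume-class].
#' @export
imageVolume <- function(values = NULL, dims = NULL, voxelSize = 1,
                        center = c(0, 0, 0)) {
  if (is.null(values)) {
    stopIfNot(!is.null(dims), "either values or dims must be given")
    values <- array(0, dim = dims)
  }
  if (is.null(dim(values)) && length(values) == 1L && !is.null(dims))
    values <- array(values, dim = dims)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  new("ImageVolume", values = values, voxelSize = voxelSize,
      center = as.numeric(center))
}

#' Construct a LOR histogram
#'
#' @param counts per-LOR counts in canonical order; scalar 0 gives an
#'   empty histogram.
#' @param geometry the [ScannerGeometry-class] the counts are binned on.
#' @param meta optional metadata list.
#' @return a [LORHistogram-class].
#' @export
lorHistogram <- function(counts, geometry, meta = list()) {
  if (length(counts) == 1L) counts <- rep(as.numeric(counts), nLORs(geometry))
  new("LORHistogram", counts = as.numeric(counts), geometry = geometry,
      meta = meta)
}

#' Canonical LOR index of an unordered crystal pair
#'
#' Bijection from unordered pairs of distinct crystal ids (0-based) onto
#' `0 .. C*(C-1)/2 - 1`, by lexicographic pair enumeration; symmetric in
#' its arguments.
#'
#' @param crystalA,crystalB 0-based crystal ids (vectorized).
#' @param geometry the scanner.
#' @return 0-based LOR indices.
#' @examples
#' geom <- scannerGeometry(40, 8, 1)
#' lorIndex(0, 1, geom)  # 0
#' @export
lorIndex <- function(crystalA, crystalB, geometry) {
  C <- nCrystals(geometry)
  a <- as.numeric(crystalA)
  b <- as.numeric(crystalB)
  stopIfNot(all(a == floor(a)) && all(b == floor(b)),
            "crystal ids must be integers")
  stopIfNot(all(a >= 0) && all(b >= 0) && all(a < C) && all(b < C),
            sprintf("crystal ids must be in [0, %d)", C))
  stopIfNot(all(a != b), "self-pairs do not form a LOR")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  lo * C - lo * (lo + 1) / 2 + (hi - lo - 1)
}

#' Crystal box in world coordinates
#'
#' Center, local axes (radial, tangential, axial) and half-extents of a
#' crystal's oriented box. Box centers lie at radial distance
#' `ringRadius + crystalDepth / 2` from the z-axis.
#'
#' @param geometry the scanner.
#' @param crystalId 0-based crystal id.
#' @return list with `center` (mm), `axes` (3x3, rows = radial,
#'   tangential, axial unit vectors) and `halfExtents` (mm, in that
#'   order).
#' @export
crystalWorldBox <- function(geometry, crystalId) {
  C <- nCrystals(geometry)
  stopIfNot(length(crystalId) == 1L && crystalId == floor(crystalId) &&
              crystalId >= 0 && crystalId < C,
            sprintf("crystalId must be a single integer in [0, %d)", C))
  it <- crystalId %% geometry@nCrystalsTransaxial
  ring <- crystalId %/% geometry@nCrystalsTransaxial
  phi <- 2 * pi * it / geometry@nCrystalsTransaxial
  rc <- geometry@ringRadius + geometry@crystalDepth / 2
  z0 <- -0.5 * (geometry@nRings - 1) * geometry@crystalPitchAxial
  center <- c(rc * cos(phi), rc * sin(phi), z0 + ring * geometry@crystalPitchAxial)
  axes <- rbind(radial = c(cos(phi), sin(phi), 0),
                tangential = c(-sin(phi), cos(phi), 0),
                axial = c(0, 0, 1))
  list(center = center, axes = axes,
       halfExtents = c(geometry@crystalDepth, geometry@crystalWidthTransaxial,
                       geometry@crystalWidthAxial) / 2)
}

#' World/voxel coordinate mapping
#'
#' `worldToVoxel` maps world points (mm) to continuous voxel coordinates
#' in which the center of voxel `(i, j, k)` (0-based) has coordinate
#' `(i, j, k)`; `voxelToWorld` is its exact inverse. Points outside the
#' volume are allowed and simply map outside `[-0.5, dims - 0.5]`.
#'
#' @param volume an [ImageVolume-class] (the template supplies dims,
#'   voxel size and world center).
#' @param points numeric length-3 vector or n x 3 matrix of world points
#'   (mm) / voxel coordinates.
#' @return matrix (or vector) of the mapped coordinates.
#' @export
worldToVoxel <- function(volume, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  d <- dim(volume@values)
  corner <- volume@center - d * volume@voxelSize / 2
  out <- sweep(sweep(p, 2, corner), 2, volume@voxelSize, "/") - 0.5
  if (is.matrix(points)) out else drop(out)
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(volume, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  d <- dim(volume@values)
  corner <- volume@center - d * volume@voxelSize / 2
  out <- sweep(sweep(p + 0.5, 2, volume@voxelSize, "*"), 2, corner, "+")
  if (is.matrix(points)) out else drop(out)
}

# 0-based index triple of the voxel containing a world point (half-open
# convention: voxel i covers continuous coordinate [i - 0.5, i + 0.5)).
containingVoxel <- function(volume, point) {
  q <- worldToVoxel(volume, point)
  floor(q + 0.5)
}

#' World coordinates of all voxel centers
#'
#' @param volume an [ImageVolume-class].
#' @return `prod(dims) x 3` matrix in R array order (x fastest).
#' @export
voxelCenters <- function(volume) {
  d <- dim(volume@values)
  idx <- cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
               rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
               rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxelToWorld(volume, idx)
}
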