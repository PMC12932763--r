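#' Construct a system-matrix view
#'
#' Pairs a scanner with an image-volume template and a ray model. The
#' resulting operator `A` has `A[L, V]` = intersection length (mm) of LOR
#' `L`'s chord (between the two crystal front-face centers; averaged over
#' an optional deterministic sub-ray grid) with voxel `V`, computed by
#' exact Siddon grid traversal. [forwardProject()] and [backProject()]
#' share these coefficients, so they form an exact adjoint pair.
#'
#' @param geometry the scanner.
#' @param volumeTemplate an [ImageVolume-class] template (dims, voxel
#'   size, world center).
#' @param raysPerLor sub-rays per face axis (1 = center chords; `m > 1`
#'   traces all pairings of `m x m` face grids - the full tube of
#'   response - at `m^4` chords per LOR).
#' @param endpointDepth endpoint depth behind the crystal front face,
#'   mm. `NULL` uses the mean interaction depth of a 511 keV photon in
#'   the shipped scintillator model (see [meanInteractionDepth()]),
#'   which removes the first-order radial parallax bias that pure
#'   front-face chords exhibit for off-center sources; `0` gives
#'   front-face chords.
#' @return a [SystemMatrixView-class].
#' @export
systemMatrixView <- function(geometry, volumeTemplate, raysPerLor = 1L,
                             endpointDepth = NULL) {
  if (is.null(endpointDepth))
    endpointDepth <- meanInteractionDepth(defaultAttenuation(), 511,
                                          geometry@crystalDepth)
  new("SystemMatrixView", geometry = geometry,
      dims = as.integer(dim(volumeTemplate@values)),
      voxelSize = volumeTemplate@voxelSize,
      center = volumeTemplate@center,
      raysPerLor = as.integer(raysPerLor),
      endpointDepth = as.numeric(endpointDepth))
}

#' Mean interaction depth of a photon in the crystal
#'
#' Expected depth of the first interaction for normal incidence on a
#' crystal of the given radial depth, conditional on interacting:
#' `1/mu - D exp(-mu D) / (1 - exp(-mu D))`.
#'
#' @param table attenuation matrix.
#' @param energy photon energy, keV.
#' @param depth crystal depth, mm.
#' @return depth in mm.
#' @export
meanInteractionDepth <- function(table, energy = 511, depth) {
  mu <- attenuationLookup(table, energy)[, "mu_total"]
  1 / mu - depth * exp(-mu * depth) / (1 - exp(-mu * depth))
}

# geometry list for the C++ layer including the view's endpoint model
viewGeom <- function(view) {
  c(geomList(view@geometry), list(endpointDepth = view@endpointDepth))
}

checkViewVolume <- function(view, volume) {
  stopIfNot(identical(as.integer(dim(volume@values)), view@dims) &&
              all(abs(volume@voxelSize - view@voxelSize) < 1e-12) &&
              all(abs(volume@center - view@center) < 1e-12),
            "volume does not match the view's template")
}

#' Geometric forward projection
#'
#' `y[L] = sum_V A[L, V] x[V]`: line integrals of the image along every
#' (or a subset of) LOR chords.
#'
#' @param x an [ImageVolume-class] matching the view's template.
#' @param view a [SystemMatrixView-class].
#' @param subset optional 0-based LOR indices; other LORs stay zero.
#' @return a [LORHistogram-class] of projection values.
#' @export
forwardProject <- function(x, view, subset = integer(0)) {
  checkViewVolume(view, x)
  y <- cppForwardProject(as.numeric(x@values), view@dims, view@voxelSize,
                         view@center, viewGeom(view),
                         as.integer(subset), view@raysPerLor)
  lorHistogram(y, view@geometry, meta = list(kind = "projection"))
}

#' Geometric backprojection (adjoint of [forwardProject()])
#'
#' `x[V] = sum_L A[L, V] y[L]` with the same coefficients as the forward
#' projection; the exact adjoint makes backprojection usable as the loss
#' gradient map during training.
#'
#' @param y a [LORHistogram-class] on the view's geometry.
#' @param view a [SystemMatrixView-class].
#' @param subset optional 0-based LOR indices to restrict the sum to.
#' @return an [ImageVolume-class].
#' @export
backProject <- function(y, view, subset = integer(0)) {
  stopIfNot(identical(geometryHash(y@geometry),
                      geometryHash(view@geometry)),
            "histogram geometry does not match the view")
  x <- cppBackProject(y@counts, view@dims, view@voxelSize, view@center,
                      viewGeom(view), as.integer(subset),
                      view@raysPerLor)
  imageVolume(values = array(pmax(x, 0), dim = view@dims),
              voxelSize = view@voxelSize, center = view@center)
}

#' Sparse system-matrix block over a kernel patch
#'
#' The columns of `A` restricted to an axis-aligned cubic patch of voxels
#' (the 11^3 footprint of a kernel placed at a voxel), as a sparse
#' `nLORs x patchSize^3` matrix. Patch voxels outside the volume give
#' zero columns. Used to make repeated projections of a kernel cheap
#' during training.
#'
#' @param view a [SystemMatrixView-class].
#' @param patchOrigin 0-based voxel index of the patch corner (length 3).
#' @param patchSize patch side length.
#' @return a `dgCMatrix`.
#' @export
patchProjector <- function(view, patchOrigin, patchSize = 11L) {
  tr <- cppPatchProjector(view@dims, view@voxelSize, view@center,
                          viewGeom(view),
                          as.integer(patchOrigin), as.integer(patchSize),
                          view@raysPerLor)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(tr$nLors, tr$nVox))
}

# Interleaved subset partition. The transaxial view index of a crystal
# pair is (iA + iB) mod Ct; views of consecutive indices differ by half
# a crystal pitch and alternate parity, and odd-parity views contain no
# chord through the scanner axis (the closest odd-separation chord
# passes ~R cos(pi (Ct/2 - 1) / Ct) off-center). Subsets therefore
# group PAIRS of adjacent views - floor(view / 2) mod nSubsets - so
# every subset contains both parities and covers the full field of
# view.
subsetPartition <- function(geometry, nSubsets) {
  C <- nCrystals(geometry)
  Ct <- geometry@nCrystalsTransaxial
  # canonical order is lexicographic in (a, b); build it directly
  a <- rep(0:(C - 2), times = (C - 1):1)
  b <- unlist(lapply(0:(C - 2), function(i) (i + 1):(C - 1)))
  view <- ((a %% Ct) + (b %% Ct)) %% Ct
  ang <- (view %/% 2) %% nSubsets
  lapply(0:(nSubsets - 1), function(s) which(ang == s) - 1L)
}
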