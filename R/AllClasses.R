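#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib icsfilter, .registration = TRUE
NULL

#' Scanner geometry: a cylindrical ring of scintillator crystals
#'
#' Describes the detector as `nRings` rings of `nCrystalsTransaxial`
#' radially oriented rectangular crystals on a cylinder of radius
#' `ringRadius` (front faces at that radius, radial extent `crystalDepth`).
#' Crystal boxes are `crystalWidthTransaxial` x `crystalWidthAxial` across
#' the front face; pitches give the center-to-center spacing. The world
#' origin is the scanner center; all lengths are millimeters.
#'
#' Crystal ids are `ring * nCrystalsTransaxial + transaxialIndex`
#' (0-based); unordered crystal pairs index the lines of response (LORs),
#' of which there are `C * (C - 1) / 2` for `C` crystals.
#'
#' @slot ringRadius inner (front face) radius in mm.
#' @slot nCrystalsTransaxial crystals per ring (>= 8).
#' @slot nRings number of rings (>= 1).
#' @slot crystalPitchTransaxial transaxial center spacing (arc) in mm.
#' @slot crystalPitchAxial axial center spacing in mm.
#' @slot crystalDepth radial crystal extent in mm.
#' @slot crystalWidthTransaxial tangential crystal width in mm.
#' @slot crystalWidthAxial axial crystal width in mm.
#' @slot axialFov axial field of view in mm.
#' @slot material attenuation-table identifier.
#' @export
setClass("ScannerGeometry", representation(
  ringRadius = "numeric",
  nCrystalsTransaxial = "integer",
  nRings = "integer",
  crystalPitchTransaxial = "numeric",
  crystalPitchAxial = "numeric",
  crystalDepth = "numeric",
  crystalWidthTransaxial = "numeric",
  crystalWidthAxial = "numeric",
  axialFov = "numeric",
  material = "character"
))

setValidity("ScannerGeometry", function(object) {
  msg <- character()
  if (object@nCrystalsTransaxial < 8L)
    msg <- c(msg, "nCrystalsTransaxial must be >= 8")
  if (object@nRings < 1L)
    msg <- c(msg, "nRings must be >= 1")
  lens <- c(object@ringRadius, object@crystalPitchTransaxial,
            object@crystalPitchAxial, object@crystalDepth,
            object@crystalWidthTransaxial, object@crystalWidthAxial,
            object@axialFov)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "all lengths must be positive and finite")
  # non-overlap: tangential width must not exceed the chord between
  # neighboring box centers at the crystal center radius
  rc <- object@ringRadius + object@crystalDepth / 2
  chord <- 2 * rc * sin(pi / object@nCrystalsTransaxial)
  if (object@crystalWidthTransaxial > chord + 1e-9)
    msg <- c(msg, "crystal boxes overlap: transaxial width exceeds the center chord")
  if (object@crystalWidthAxial > object@crystalPitchAxial + 1e-9)
    msg <- c(msg, "crystal boxes overlap axially")
  if (length(msg)) msg else TRUE
})

#' 3D image volume with world-coordinate mapping
#'
#' A voxelized non-negative activity distribution. The world origin is the
#' scanner center; `center` is the world coordinate of the volume center
#' (default the origin). Voxel `(0,0,0)` sits at the most-negative corner
#' and voxel centers are at `corner + (i + 0.5) * voxelSize`.
#'
#' @slot values 3D numeric array of non-negative voxel activities.
#' @slot voxelSize mm per voxel along each axis (length 3).
#' @slot center world coordinate (mm) of the volume center (length 3).
#' @export
setClass("ImageVolume", representation(
  values = "array",
  voxelSize = "numeric",
  center = "numeric"
))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive numbers")
  if (length(object@center) != 3L)
    msg <- c(msg, "center must have length 3")
  if (any(object@values < 0))
    msg <- c(msg, "voxel values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Per-LOR event histogram
#'
#' Counts (or expected counts) per unordered crystal pair, in the canonical
#' lexicographic pair order of [lorIndex()]. Carries the geometry it was
#' binned on.
#'
#' @slot counts numeric vector of length `nLORs(geometry)`, non-negative.
#' @slot geometry the [ScannerGeometry-class] the histogram refers to.
#' @slot meta list of creation metadata (seed, pair count, ...).
#' @export
setClass("LORHistogram", representation(
  counts = "numeric",
  geometry = "ScannerGeometry",
  meta = "list"
))

setValidity("LORHistogram", function(object) {
  C <- as.numeric(object@geometry@nCrystalsTransaxial) * object@geometry@nRings
  if (length(object@counts) != C * (C - 1) / 2)
    return("counts length must equal the geometry's LOR count")
  if (any(object@counts < 0) || any(!is.finite(object@counts)))
    return("counts must be finite and non-negative")
  TRUE
})

#' Normalized image-space filter kernel
#'
#' An `11 x 11 x 11` (generally odd-sized cubic) non-negative array over
#' integer voxel offsets `[-5, 5]^3`, normalized to sum to one so that
#' filtering preserves the total activity.
#'
#' @slot values cubic odd-sized 3D array, non-negative, sum 1 (1e-6).
#' @export
setClass("FilterKernel", representation(values = "array"))

setValidity("FilterKernel", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L || length(unique(d)) != 1L || d[1] %% 2L == 0L)
    return("kernel must be a cubic array with odd side length")
  if (any(object@values < 0))
    return("kernel values must be non-negative")
  if (abs(sum(object@values) - 1) > 1e-6)
    return("kernel must sum to 1 (within 1e-6)")
  TRUE
})

#' Parameters of the rotated 3D skew-normal kernel model
#'
#' Ten parameters: per-axis location `mu`, scale `sigma` and skewness
#' `alpha` (kernel-grid units / dimensionless), plus an xy-plane rotation
#' `theta` in degrees. Valid (clamped) ranges: `mu` in [-5, 5], `sigma` in
#' [0.01, 10], `alpha` in [-5, 5], `theta` in [0, 360].
#'
#' @slot mu numeric length 3, location.
#' @slot sigma numeric length 3, scale (> 0).
#' @slot alpha numeric length 3, skewness.
#' @slot theta rotation angle, degrees.
#' @export
setClass("SkewNormParams", representation(
  mu = "numeric", sigma = "numeric", alpha = "numeric", theta = "numeric"
))

setValidity("SkewNormParams", function(object) {
  msg <- character()
  if (length(object@mu) != 3L || any(abs(object@mu) > 5 + 1e-9))
    msg <- c(msg, "mu must be 3 values in [-5, 5]")
  if (length(object@sigma) != 3L ||
      any(object@sigma < 0.01 - 1e-9) || any(object@sigma > 10 + 1e-9))
    msg <- c(msg, "sigma must be 3 values in [0.01, 10]")
  if (length(object@alpha) != 3L || any(abs(object@alpha) > 5 + 1e-9))
    msg <- c(msg, "alpha must be 3 values in [-5, 5]")
  if (length(object@theta) != 1L || object@theta < -1e-9 ||
      object@theta > 360 + 1e-9)
    msg <- c(msg, "theta must be a single angle in [0, 360] degrees")
  if (length(msg)) msg else TRUE
})

#' Kernel-prediction multilayer perceptron
#'
#' A fully connected trunk (64, 128, 256, 512 units, Mish activations) fed
#' with a 3D world position, with one of two output heads: `"direct"`
#' (1331 units, rectified and renormalized into an 11^3 kernel) or
#' `"skewnorm"` (10 units parameterizing the rotated 3D skew normal).
#'
#' @slot head `"direct"` or `"skewnorm"`.
#' @slot weights list of layer weight matrices `W` (in x out) and bias
#'   vectors `b`.
#' @slot inputScale positions are divided by this half-extent (mm) before
#'   the first layer.
#' @slot kernelSize kernel side length (11).
#' @slot seed trunk initialization seed.
#' @slot history training-history log (loss curves).
#' @export
setClass("ICSNet", representation(
  head = "character",
  weights = "list",
  inputScale = "numeric",
  kernelSize = "integer",
  seed = "integer",
  history = "list"
))

setValidity("ICSNet", function(object) {
  if (!object@head %in% c("direct", "skewnorm"))
    return("head must be 'direct' or 'skewnorm'")
  TRUE
})

#' Per-voxel filter-kernel bank
#'
#' Holds one normalized kernel per voxel center of a volume template,
#' either densely or for a single spatial octant (the remaining voxels'
#' kernels are recovered by mirroring, exploiting the reflection symmetry
#' of the ring geometry).
#'
#' @slot kernels matrix, one stored kernel per row (flattened 11^3).
#' @slot mode `"dense"` or `"octant"`.
#' @slot dims volume dimensions the store was built for.
#' @slot voxelSize,center the template's world mapping.
#' @slot norms cached per-voxel in-bounds kernel mass (truncation
#'   renormalization at volume borders).
#' @export
setClass("KernelStore", representation(
  kernels = "matrix",
  mode = "character",
  dims = "integer",
  voxelSize = "numeric",
  center = "numeric",
  norms = "numeric"
))

setValidity("KernelStore", function(object) {
  if (!object@mode %in% c("dense", "octant", "invariant"))
    return("mode must be 'dense', 'octant' or 'invariant'")
  nv <- prod(object@dims)
  expect <- switch(object@mode, dense = nv, octant = nv / 8,
                   invariant = 1)
  if (nrow(object@kernels) != expect)
    return("kernel count does not match the template/mode")
  if (any(object@kernels < 0))
    return("stored kernels must be non-negative")
  s <- rowSums(object@kernels)
  if (any(abs(s - 1) > 1e-6))
    return("every stored kernel must sum to 1 (within 1e-6)")
  TRUE
})

#' Matched forward/backprojection operator pair
#'
#' Describes the geometric system matrix `A` realized by Siddon ray
#' traversal between crystal front faces: `forwardProject` computes `A x`,
#' `backProject` computes `t(A) y` with identical coefficients, so the two
#' are an exact adjoint pair.
#'
#' @slot geometry the scanner.
#' @slot dims,voxelSize,center the image-volume template.
#' @slot raysPerLor rays per LOR along each face axis (1 = single
#'   endpoint-to-endpoint chords; `m` traces all pairings of `m x m`
#'   face-point grids, the full tube of response).
#' @slot endpointDepth LOR endpoint depth behind the crystal front face
#'   in mm (the mean interaction depth by default, which removes the
#'   first-order radial parallax bias of front-face chords).
#' @export
setClass("SystemMatrixView", representation(
  geometry = "ScannerGeometry",
  dims = "integer",
  voxelSize = "numeric",
  center = "numeric",
  raysPerLor = "integer",
  endpointDepth = "numeric"
))

setValidity("SystemMatrixView", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be 3 positive integers")
  if (object@raysPerLor < 1L)
    return("raysPerLor must be >= 1")
  if (object@endpointDepth < 0 ||
      object@endpointDepth > object@geometry@crystalDepth)
    return("endpointDepth must lie within the crystal depth")
  TRUE
})

setMethod("show", "ScannerGeometry", function(object) {
  C <- nCrystals(object)
  cat("ScannerGeometry:", object@nCrystalsTransaxial, "crystals x",
      object@nRings, "rings (", C, "crystals,", format(nLORs(object)),
      "LORs)\n")
  cat("  ring radius", object@ringRadius, "mm, crystal depth",
      object@crystalDepth, "mm, axial FOV", object@axialFov, "mm\n")
  cat("  material:", object@material, "\n")
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@values)
  cat("ImageVolume:", paste(d, collapse = " x "), "voxels of",
      paste(object@voxelSize, collapse = " x "), "mm\n")
  cat("  total activity", format(sum(object@values)),
      ", center (", paste(object@center, collapse = ", "), ") mm\n")
})

setMethod("show", "LORHistogram", function(object) {
  cat("LORHistogram:", format(length(object@counts)), "LORs,",
      format(sum(object@counts)), "total counts\n")
})

setMethod("show", "FilterKernel", function(object) {
  d <- dim(object@values)[1]
  cat("FilterKernel:", d, "x", d, "x", d,
      ", max", format(max(object@values)), "\n")
})

setMethod("show", "SkewNormParams", function(object) {
  cat("SkewNormParams: mu = (", paste(signif(object@mu, 4), collapse = ", "),
      "), sigma = (", paste(signif(object@sigma, 4), collapse = ", "),
      "), alpha = (", paste(signif(object@alpha, 4), collapse = ", "),
      "), theta =", signif(object@theta, 5), "deg\n")
})

setMethod("show", "ICSNet", function(object) {
  cat("ICSNet (", object@head, "head ):",
      paste(vapply(object@weights, function(l) ncol(l$W), 1L),
            collapse = "-"),
      "units,", countParameters(object), "parameters\n")
})

setMethod("show", "KernelStore", function(object) {
  cat("KernelStore (", object@mode, "):", nrow(object@kernels),
      "stored kernels for a", paste(object@dims, collapse = " x "),
      "volume\n")
})
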