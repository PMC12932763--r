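#' Number of crystals in a scanner
#' @param geometry a [ScannerGeometry-class].
#' @return integer crystal count.
#' @export
nCrystals <- function(geometry) {
  geometry@nCrystalsTransaxial * geometry@nRings
}

#' Number of lines of response (unordered crystal pairs)
#' @param geometry a [ScannerGeometry-class].
#' @return numeric LOR count `C * (C - 1) / 2`.
#' @export
nLORs <- function(geometry) {
  C <- as.numeric(nCrystals(geometry))
  C * (C - 1) / 2
}

#' Voxel values of an image volume
#' @param volume an [ImageVolume-class].
#' @return the 3D activity array.
#' @export
voxelValues <- function(volume) volume@values

#' Per-LOR counts of a histogram
#' @param histogram a [LORHistogram-class].
#' @return numeric count vector in canonical LOR order.
#' @export
lorCounts <- function(histogram) histogram@counts

#' Kernel values
#' @param kernel a [FilterKernel-class].
#' @return the kernel array.
#' @export
kernelValues <- function(kernel) kernel@values
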