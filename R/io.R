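# File formats: geometry configs as YAML (versioned schema), image
# volumes as NIfTI or raw float32 + JSON sidecar, LOR histograms as a
# single-file binary container (length-prefixed JSON header + float64
# payload) carrying the geometry hash and creation metadata.

GEOMETRY_SCHEMA <- "icsfilter-geometry-1"
LORH_SCHEMA <- "icsfilter-lorhistogram-1"

#' Read and write scanner-geometry configs (YAML)
#'
#' @param geometry a [ScannerGeometry-class].
#' @param path file path.
#' @return `readGeometry` returns a [ScannerGeometry-class];
#'   `writeGeometry` returns `path` invisibly.
#' @export
writeGeometry <- function(geometry, path) {
  cfg <- c(list(schema = GEOMETRY_SCHEMA), geomList(geometry),
           list(axialFov = geometry@axialFov, material = geometry@material))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' @rdname writeGeometry
#' @export
readGeometry <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopIfNot(identical(cfg$schema, GEOMETRY_SCHEMA),
            sprintf("unrecognized geometry schema '%s'", cfg$schema))
  scannerGeometry(ringRadius = cfg$ringRadius,
                  nCrystalsTransaxial = cfg$nCrystalsTransaxial,
                  nRings = cfg$nRings,
                  crystalPitchTransaxial = cfg$crystalPitchTransaxial,
                  crystalPitchAxial = cfg$crystalPitchAxial,
                  crystalDepth = cfg$crystalDepth,
                  crystalWidthTransaxial = cfg$crystalWidthTransaxial,
                  crystalWidthAxial = cfg$crystalWidthAxial,
                  material = cfg$material)
}

#' Read and write image volumes
#'
#' NIfTI (`.nii` / `.nii.gz`, voxel size in the header) or raw
#' little-endian float32 with a JSON sidecar (`<path>.json` holding shape,
#' voxel size and world center).
#'
#' @param volume an [ImageVolume-class].
#' @param path output path; format chosen by extension (`.nii`/`.nii.gz`
#'   vs anything else = raw + sidecar).
#' @return `readVolume` returns an [ImageVolume-class]; `writeVolume`
#'   returns `path` invisibly.
#' @export
writeVolume <- function(volume, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume@values)
    RNifti::pixdim(img) <- volume@voxelSize
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(volume@values), con, size = 4, endian = "little")
    jsonlite::write_json(
      list(schema = "icsfilter-volume-1", shape = dim(volume@values),
           voxel_size = volume@voxelSize, center = volume@center,
           dtype = "float32le"),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    vs <- attr(img, "pixdim")[seq_len(3)]
    imageVolume(values = array(as.numeric(img), dim = dim(img)),
                voxelSize = vs)
  } else {
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    n <- prod(side$shape)
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    imageVolume(values = array(v, dim = side$shape),
                voxelSize = side$voxel_size, center = side$center)
  }
}

#' Read and write LOR histograms
#'
#' Single-file container: an 8-byte little-endian length prefix, a JSON
#' header (schema, geometry fields and hash, creation metadata), then the
#' count array as float64. On read the stored geometry is reconstructed
#' and its hash verified.
#'
#' @param histogram a [LORHistogram-class].
#' @param path file path.
#' @return `readLORHistogram` returns a [LORHistogram-class];
#'   `writeLORHistogram` returns `path` invisibly.
#' @export
writeLORHistogram <- function(histogram, path) {
  g <- histogram@geometry
  header <- jsonlite::toJSON(
    list(schema = LORH_SCHEMA,
         geometry = c(geomList(g), list(material = g@material)),
         geometryHash = geometryHash(g),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         meta = histogram@meta,
         n = length(histogram@counts)),
    auto_unbox = TRUE, digits = NA)
  raw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(length(raw)), con, size = 8, endian = "little")
  writeBin(raw, con)
  writeBin(histogram@counts, con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname writeLORHistogram
#' @export
readLORHistogram <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nh <- readBin(con, "numeric", n = 1, size = 8, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = nh)))
  stopIfNot(identical(header$schema, LORH_SCHEMA),
            sprintf("unrecognized histogram schema '%s'", header$schema))
  gf <- header$geometry
  geometry <- scannerGeometry(
    ringRadius = gf$ringRadius, nCrystalsTransaxial = gf$nCrystalsTransaxial,
    nRings = gf$nRings, crystalPitchTransaxial = gf$crystalPitchTransaxial,
    crystalPitchAxial = gf$crystalPitchAxial, crystalDepth = gf$crystalDepth,
    crystalWidthTransaxial = gf$crystalWidthTransaxial,
    crystalWidthAxial = gf$crystalWidthAxial, material = gf$material)
  stopIfNot(identical(geometryHash(geometry), header$geometryHash),
            "geometry hash mismatch in histogram container")
  counts <- readBin(con, "numeric", n = header$n, size = 8,
                    endian = "little")
  lorHistogram(counts, geometry, meta = as.list(header$meta))
}
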