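#' Derenzo phantom specification
#'
#' A resolution phantom of rod sectors with graded rod diameters between
#' two plates: cylindrical rods (axis along z) packed on a triangular
#' lattice with center spacing twice the rod diameter, one diameter per
#' 60-degree sector, plus two solid disks capping the rods axially.
#'
#' Default diameters are the classic 0.8-2.5 mm series scaled twofold to
#' the stand-in scanner: its 3.9 mm crystal pitch is about twice that of
#' the small-animal systems the classic series targets, and rods far
#' below the intrinsic resolution would make any reconstruction of them
#' pure noise.
#'
#' @param sectorRodDiameters rod diameter per sector, mm.
#' @param rodLength axial rod length, mm.
#' @param plateThickness axial thickness of each plate, mm.
#' @param plateRadius plate (and rod region) radius, mm.
#' @param activity activity per mm^3 of material (arbitrary units).
#' @return a spec list consumed by [makeDerenzo()].
#' @export
derenzoSpec <- function(sectorRodDiameters = c(1.6, 2, 2.4, 3, 4, 5),
                        rodLength = 12, plateThickness = 2,
                        plateRadius = 15, activity = 1) {
  stopIfNot(all(sectorRodDiameters > 0), "rod diameters must be positive")
  stopIfNot(rodLength > 0 && plateThickness > 0 && plateRadius > 0,
            "lengths must be positive")
  list(sectorRodDiameters = sectorRodDiameters, rodLength = rodLength,
       plateThickness = plateThickness, plateRadius = plateRadius,
       activity = activity)
}

# Rod centers of one sector: triangular lattice with spacing 2 d, aligned
# with the sector bisector, keeping every rod fully inside the sector
# wedge and the plate radius.
sectorRodCenters <- function(d, sectorIndex, nSectors, plateRadius,
                             innerMargin = NULL) {
  spacing <- 2 * d
  if (is.null(innerMargin)) innerMargin <- 2 * d
  half <- pi / nSectors
  rmax <- plateRadius - d
  centers <- NULL
  nRow <- ceiling(rmax / (spacing * sqrt(3) / 2)) + 1
  for (row in 0:nRow) {
    r0 <- innerMargin + row * spacing * sqrt(3) / 2
    if (r0 > rmax) break
    offs <- (seq_len(row + 1) - 1 - row / 2) * spacing
    for (o in offs) {
      x <- r0
      y <- o
      rr <- sqrt(x^2 + y^2)
      if (rr > rmax || rr < 1e-9) next
      # full rod inside the wedge: angular clearance > asin(d / rr)
      ang <- atan2(y, x)
      if (abs(ang) > half - asin(min(1, d / rr)) + 1e-9) next
      centers <- rbind(centers, c(x, y))
    }
  }
  if (is.null(centers)) return(matrix(numeric(0), ncol = 2))
  rot <- 2 * pi * (sectorIndex - 1) / nSectors + half
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  centers %*% t(R)
}

# Fraction of each voxel inside the material, by nSub^3 subvoxel sampling.
voxelOccupancy <- function(volume, insideFun, nSub = 3) {
  d <- dim(volume@values)
  vs <- volume@voxelSize
  corner <- volume@center - d * vs / 2
  frac <- (seq_len(nSub) - 0.5) / nSub
  occ <- array(0, dim = d)
  xs <- corner[1] + (seq_len(d[1]) - 1) * vs[1]
  ys <- corner[2] + (seq_len(d[2]) - 1) * vs[2]
  zs <- corner[3] + (seq_len(d[3]) - 1) * vs[3]
  for (fz in frac) for (fy in frac) for (fx in frac) {
    px <- xs + fx * vs[1]
    py <- ys + fy * vs[2]
    pz <- zs + fz * vs[3]
    occ <- occ + insideFun(px, py, pz)
  }
  occ / nSub^3
}

#' Voxelize a Derenzo phantom
#'
#' Rasterizes the spec into a volume template with 3x3x3 subvoxel
#' occupancy sampling: each voxel's value is `activity` times the fraction
#' of the voxel inside rod or plate material.
#'
#' @param spec a [derenzoSpec()].
#' @param volumeTemplate an [ImageVolume-class] giving dims, voxel size
#'   and world placement; the phantom must fit inside it.
#' @param nSub subvoxel samples per axis.
#' @return an [ImageVolume-class] with the phantom activity.
#' @export
makeDerenzo <- function(spec, volumeTemplate, nSub = 3) {
  d <- dim(volumeTemplate@values)
  vs <- volumeTemplate@voxelSize
  halfExt <- d * vs / 2
  zTop <- spec$rodLength / 2 + spec$plateThickness
  stopIfNot(spec$plateRadius <= min(halfExt[1:2]) && zTop <= halfExt[3],
            "Derenzo spec exceeds the volume template")
  nS <- length(spec$sectorRodDiameters)
  rods <- NULL
  for (s in seq_len(nS)) {
    cen <- sectorRodCenters(spec$sectorRodDiameters[s], s, nS,
                            spec$plateRadius)
    if (nrow(cen))
      rods <- rbind(rods, cbind(cen, spec$sectorRodDiameters[s] / 2))
  }
  stopIfNot(!is.null(rods) && nrow(rods) > 0,
            "no rods fit the spec; enlarge plateRadius or shrink diameters")
  zRod <- spec$rodLength / 2
  inside <- function(px, py, pz) {
    # outer product grids: px over x, py over y, pz over z
    nx <- length(px); ny <- length(py); nz <- length(pz)
    inPlateZ <- abs(pz) > zRod & abs(pz) <= zTop
    inRodZ <- abs(pz) <= zRod
    r2xy <- outer(px^2, py^2, "+")
    inDisk <- r2xy <= spec$plateRadius^2
    inRod <- matrix(FALSE, nx, ny)
    for (k in seq_len(nrow(rods))) {
      dx2 <- (px - rods[k, 1])^2
      dy2 <- (py - rods[k, 2])^2
      inRod <- inRod | (outer(dx2, dy2, "+") <= rods[k, 3]^2)
    }
    out <- array(0, dim = c(nx, ny, nz))
    for (k in seq_len(nz)) {
      if (inPlateZ[k]) out[, , k] <- inDisk
      else if (inRodZ[k]) out[, , k] <- inRod
    }
    out
  }
  occ <- voxelOccupancy(volumeTemplate, inside, nSub = nSub)
  imageVolume(values = occ * spec$activity, voxelSize = vs,
              center = volumeTemplate@center)
}

#' Point-source phantom
#'
#' All activity (sum 1) in the voxel containing `position` under the
#' half-open voxel convention (consistent with [worldToVoxel()]).
#'
#' @param position world point in mm, inside the volume.
#' @param volumeTemplate an [ImageVolume-class] template.
#' @return an [ImageVolume-class] with a single nonzero voxel.
#' @export
makePointSource <- function(position, volumeTemplate) {
  d <- dim(volumeTemplate@values)
  idx <- containingVoxel(volumeTemplate, position)
  stopIfNot(all(idx >= 0) && all(idx < d),
            "position lies outside the volume")
  v <- array(0, dim = d)
  v[idx[1] + 1, idx[2] + 1, idx[3] + 1] <- 1
  imageVolume(values = v, voxelSize = volumeTemplate@voxelSize,
              center = volumeTemplate@center)
}

#' Uniform cylinder phantom
#'
#' @param radius,length cylinder radius and axial length, mm (axis z,
#'   centered).
#' @param volumeTemplate template volume.
#' @param activity activity per mm^3.
#' @param nSub subvoxel samples per axis.
#' @return an [ImageVolume-class].
#' @export
makeCylinderPhantom <- function(radius, length, volumeTemplate,
                                activity = 1, nSub = 3) {
  d <- dim(volumeTemplate@values)
  vs <- volumeTemplate@voxelSize
  halfExt <- d * vs / 2
  stopIfNot(radius <= min(halfExt[1:2]) && length / 2 <= halfExt[3],
            "cylinder exceeds the volume template")
  inside <- function(px, py, pz) {
    inXY <- outer(px^2, py^2, "+") <= radius^2
    out <- array(0, dim = c(base::length(px), base::length(py),
                            base::length(pz)))
    for (k in seq_along(pz)) if (abs(pz[k]) <= length / 2) out[, , k] <- inXY
    out
  }
  occ <- voxelOccupancy(volumeTemplate, inside, nSub = nSub)
  imageVolume(values = occ * activity, voxelSize = vs,
              center = volumeTemplate@center)
}

#' Normalized root mean square error between two volumes
#'
#' `sqrt(mean((pred - gt)^2)) / mean(gt)`: the root mean square voxel
#' difference over all voxels, normalized by the average ground-truth
#' voxel intensity. Scale-equivariant: `nrmse(a*pred, a*gt)` equals
#' `nrmse(pred, gt)` for `a > 0`.
#'
#' @param pred,gt [ImageVolume-class] objects of identical shape; `gt`
#'   must have positive mean.
#' @param asPercent return the value in percent.
#' @return the NRMSE as a fraction (or percent).
#' @export
nrmse <- function(pred, gt, asPercent = FALSE) {
  stopIfNot(identical(dim(pred@values), dim(gt@values)),
            "pred and gt must have identical shapes")
  m <- mean(gt@values)
  stopIfNot(m > 0, "ground truth must have positive mean intensity")
  v <- sqrt(mean((pred@values - gt@values)^2)) / m
  if (asPercent) 100 * v else v
}
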