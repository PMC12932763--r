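# OS-EM reconstruction with image-space position-dependent filtering.
# The stored per-voxel kernels are applied to the image estimate at the
# beginning of each forward projection step (scatter convention: each
# voxel distributes its activity over its own kernel footprint, with
# truncated border kernels renormalized so the total activity is
# preserved exactly). The LOR-space reference correction convolves the
# geometric projection with the endpoint mislocation blur instead and is
# used as the ground-truth reconstruction for NRMSE comparisons.

#' Precompute per-voxel filter kernels
#'
#' Evaluates the network at every voxel center (world position) of the
#' template, or - in octant mode - at the non-negative-coordinate octant
#' only, recovering the other voxels' kernels by mirroring (exploiting
#' the reflection symmetries of the ring). Octant mode reduces storage
#' eightfold; with `average = TRUE` each stored kernel is the average of
#' the mirrored predictions at all 8 symmetry-mate positions, a more
#' robust estimate under approximate symmetry.
#'
#' @param network a trained [ICSNet-class].
#' @param volumeTemplate the reconstruction template.
#' @param mode `"dense"` or `"octant"` (octant requires even dims).
#' @param average octant mode: average the 8 symmetry-mates.
#' @param maxBytes guard on the dense store size; exceeding it is
#'   rejected with the suggestion to use octant mode.
#' @return a [KernelStore-class].
#' @export
precomputeKernels <- function(network, volumeTemplate,
                              mode = c("octant", "dense"),
                              average = FALSE, maxBytes = 2e9) {
  mode <- match.arg(mode)
  d <- dim(volumeTemplate@values)
  k3 <- network@kernelSize^3
  nStore <- if (mode == "dense") prod(d) else prod(d) / 8
  stopIfNot(nStore * k3 * 8 <= maxBytes,
            paste0("kernel store would exceed maxBytes; use mode = ",
                   "'octant' or a coarser volume"))
  if (mode == "octant")
    stopIfNot(all(d %% 2L == 0L), "octant mode requires even dimensions")
  if (mode == "dense") {
    pos <- voxelCenters(volumeTemplate)
    K <- predictKernelMatrix(network, pos)
  } else {
    h <- d %/% 2L
    # octant voxel indices (non-negative world coordinates), x fastest
    idx <- cbind(rep(h[1]:(d[1] - 1), times = h[2] * h[3]),
                 rep(rep(h[2]:(d[2] - 1), each = h[1]), times = h[3]),
                 rep(h[3]:(d[3] - 1), each = h[1] * h[2]))
    pos <- voxelToWorld(volumeTemplate, idx)
    if (!average) {
      K <- predictKernelMatrix(network, pos)
    } else {
      K <- matrix(0, nrow(pos), k3)
      ks <- network@kernelSize
      for (fx in c(FALSE, TRUE)) for (fy in c(FALSE, TRUE))
        for (fz in c(FALSE, TRUE)) {
          sgn <- c(if (fx) -1 else 1, if (fy) -1 else 1, if (fz) -1 else 1)
          pm <- sweep(pos, 2, sgn, "*")
          Km <- predictKernelMatrix(network, pm)
          # mirror each predicted kernel back into octant orientation
          arr <- array(t(Km), dim = c(ks, ks, ks, nrow(pos)))
          ix <- if (fx) ks:1 else 1:ks
          iy <- if (fy) ks:1 else 1:ks
          iz <- if (fz) ks:1 else 1:ks
          K <- K + t(matrix(arr[ix, iy, iz, , drop = FALSE],
                            ks^3, nrow(pos)))
        }
      K <- K / 8
      K <- K / rowSums(K)
    }
  }
  store <- new("KernelStore", kernels = K, mode = mode,
               dims = as.integer(d), voxelSize = volumeTemplate@voxelSize,
               center = volumeTemplate@center, norms = numeric(0))
  store@norms <- cppFilterNorms(store@kernels, store@mode == "octant",
                                store@dims)
  store
}

#' Build a kernel store from explicit kernels
#'
#' @param kernels matrix with one flattened normalized kernel per row
#'   (`prod(dims)` rows for dense mode, one row for a spatially
#'   invariant kernel).
#' @param volumeTemplate the template the store belongs to.
#' @param mode `"dense"`, `"octant"` or `"invariant"` (one kernel used
#'   at every voxel).
#' @return a [KernelStore-class].
#' @export
kernelStore <- function(kernels, volumeTemplate, mode = "dense") {
  store <- new("KernelStore", kernels = kernels, mode = mode,
               dims = as.integer(dim(volumeTemplate@values)),
               voxelSize = volumeTemplate@voxelSize,
               center = volumeTemplate@center, norms = numeric(0))
  store@norms <- cppFilterNorms(store@kernels, store@mode == "octant",
                                store@dims)
  store
}

#' Read back a single stored kernel
#'
#' @param store a [KernelStore-class].
#' @param voxel 0-based voxel index triple.
#' @return a [FilterKernel-class] (mirrored on the fly in octant mode).
#' @export
storedKernel <- function(store, voxel) {
  d <- store@dims
  stopIfNot(all(voxel >= 0) && all(voxel < d), "voxel index out of range")
  ks <- as.integer(round(ncol(store@kernels)^(1 / 3)))
  if (store@mode == "invariant") {
    row <- 1
    flips <- c(FALSE, FALSE, FALSE)
  } else if (store@mode == "dense") {
    row <- voxel[1] + d[1] * (voxel[2] + d[2] * voxel[3]) + 1
    flips <- c(FALSE, FALSE, FALSE)
  } else {
    h <- d %/% 2L
    j <- ifelse(voxel >= h, voxel - h, h - 1 - voxel)
    flips <- voxel < h
    row <- j[1] + h[1] * (j[2] + h[2] * j[3]) + 1
  }
  k <- new("FilterKernel",
           values = array(store@kernels[row, ], dim = rep(ks, 3)))
  mirrorKernel(k, flips)
}

#' Apply the position-dependent image-space filter
#'
#' Each source voxel's activity is distributed over its own kernel's
#' footprint (scatter convention); kernels truncated at the volume
#' border are renormalized so the global activity sum is preserved
#' exactly.
#'
#' @param x an [ImageVolume-class] matching the store's template.
#' @param store a [KernelStore-class].
#' @return the filtered [ImageVolume-class].
#' @export
applyFilter <- function(x, store) {
  stopIfNot(identical(as.integer(dim(x@values)), store@dims) &&
              all(abs(x@voxelSize - store@voxelSize) < 1e-12),
            "volume does not match the kernel store template")
  out <- cppApplyFilter(as.numeric(x@values), store@kernels,
                        store@mode == "octant", store@dims, store@norms)
  imageVolume(values = array(out, dim = store@dims),
              voxelSize = x@voxelSize, center = x@center)
}

#' OS-EM reconstruction configuration
#'
#' @param nSubsets ordered subsets (LORs interleaved by transaxial angle
#'   index modulo `nSubsets`).
#' @param nIterations full passes over all subsets.
#' @param epsilon guard added to denominators.
#' @return a config list.
#' @export
osemConfig <- function(nSubsets = 8L, nIterations = 8L, epsilon = 1e-12) {
  stopIfNot(nSubsets >= 1 && nIterations >= 1,
            "subsets and iterations must be >= 1")
  list(nSubsets = as.integer(nSubsets),
       nIterations = as.integer(nIterations), epsilon = epsilon)
}

#' OS-EM reconstruction with optional image-space ICS filtering
#'
#' Multiplicative EM updates over interleaved LOR subsets:
#' `x <- x * At_s(y_s / max(A_s F x, eps)) / max(At_s 1, eps)`, where `F`
#' is the position-dependent kernel filter applied to the image estimate
#' at the beginning of each forward projection step (identity when no
#' store is given). The sensitivity denominator uses the plain geometric
#' `At_s 1`. Iterates stay non-negative and finite.
#'
#' @param y measured [LORHistogram-class].
#' @param view the [SystemMatrixView-class].
#' @param config an [osemConfig()].
#' @param store optional [KernelStore-class] (filter mode); `NULL`
#'   reconstructs without ICS correction.
#' @param filterAdjoint also apply the filter's adjoint after
#'   backprojection (symmetric variant; off by default, matching the
#'   forward-side-only placement).
#' @return the reconstructed [ImageVolume-class].
#' @export
osemReconstruct <- function(y, view, config = osemConfig(), store = NULL,
                            filterAdjoint = FALSE) {
  stopIfNot(identical(geometryHash(y@geometry),
                      geometryHash(view@geometry)),
            "histogram geometry does not match the view")
  if (sum(y@counts) == 0) {
    warning("all-zero measurement; returning the zero image")
    return(imageVolume(dims = view@dims, voxelSize = view@voxelSize,
                       center = view@center))
  }
  subsets <- subsetPartition(view@geometry, config$nSubsets)
  stopIfNot(all(lengths(subsets) > 0), "empty LOR subset")
  eps <- config$epsilon
  gl <- viewGeom(view)
  x <- array(1, dim = view@dims)
  template <- imageVolume(values = x, voxelSize = view@voxelSize,
                          center = view@center)
  sens <- lapply(subsets, function(s) {
    ones <- rep(0, length(y@counts))
    ones[s + 1] <- 1
    sv <- as.numeric(cppBackProject(ones, view@dims, view@voxelSize,
                                    view@center, gl,
                                    as.integer(s), view@raysPerLor))
    if (!is.null(store) && filterAdjoint)
      sv <- as.numeric(cppApplyFilterAdjoint(sv, store@kernels,
                                             store@mode == "octant",
                                             store@dims, store@norms))
    sv
  })
  xv <- as.numeric(x)
  for (it in seq_len(config$nIterations)) {
    for (si in seq_along(subsets)) {
      s <- subsets[[si]]
      xt <- xv
      if (!is.null(store)) {
        xt <- as.numeric(cppApplyFilter(xv, store@kernels,
                                        store@mode == "octant",
                                        store@dims, store@norms))
      }
      yhat <- cppForwardProject(xt, view@dims, view@voxelSize,
                                view@center, gl,
                                as.integer(s), view@raysPerLor)
      ratio <- rep(0, length(yhat))
      ratio[s + 1] <- y@counts[s + 1] / pmax(yhat[s + 1], eps)
      corr <- as.numeric(cppBackProject(ratio, view@dims, view@voxelSize,
                                        view@center, gl,
                                        as.integer(s), view@raysPerLor))
      if (!is.null(store) && filterAdjoint) {
        # adjoint of the scatter filter = gather with the same kernels
        corr <- as.numeric(cppApplyFilterAdjoint(corr, store@kernels,
                                                 store@mode == "octant",
                                                 store@dims, store@norms))
      }
      upd <- corr / pmax(sens[[si]], eps)
      upd[sens[[si]] <= eps] <- 1  # voxels this subset cannot see
      xv <- xv * upd
    }
  }
  imageVolume(values = array(pmax(xv, 0), dim = view@dims),
              voxelSize = view@voxelSize, center = view@center)
}

#' OS-EM with the LOR-space reference ICS correction
#'
#' The reference method: the forward model is `B A` with `B` the
#' spatially invariant LOR-domain endpoint-offset blur (from
#' [estimateLorBlur()]) applied after geometric projection, and the
#' matched adjoint `At Bt` is used for backprojection; the sensitivity is
#' `At Bt 1_s`. Produces the reconstruction used as ground truth in
#' NRMSE comparisons.
#'
#' @param y measured [LORHistogram-class].
#' @param view the [SystemMatrixView-class].
#' @param config an [osemConfig()].
#' @param blur result of [estimateLorBlur()] on the same geometry.
#' @param probFloor offsets with probability below this are dropped from
#'   the blur support (kept mass renormalized).
#' @param response optional spatially invariant detector-response
#'   kernel (a [FilterKernel-class], e.g. from
#'   [estimateResponseKernel()]): the scatter-free part of the detector
#'   blur, applied in image space before projection with its matched
#'   adjoint, making the reference a full detector-response model
#'   rather than an ICS-only one.
#' @return the reconstructed [ImageVolume-class].
#' @export
lorSpaceCorrectedReconstruct <- function(y, view, config = osemConfig(),
                                         blur, probFloor = 1e-3,
                                         response = NULL) {
  stopIfNot(is.list(blur) && !is.null(blur$prob),
            "blur must come from estimateLorBlur()")
  if (sum(y@counts) == 0) {
    warning("all-zero measurement; returning the zero image")
    return(imageVolume(dims = view@dims, voxelSize = view@voxelSize,
                       center = view@center))
  }
  B <- lorBlurMatrix(blur, view@geometry, probFloor)
  gl <- viewGeom(view)
  eps <- config$epsilon
  G <- NULL
  if (!is.null(response)) {
    tmplG <- imageVolume(dims = view@dims, voxelSize = view@voxelSize,
                         center = view@center)
    G <- kernelStore(matrix(as.numeric(response@values), 1), tmplG,
                     mode = "invariant")
  }
  applyG <- function(v) {
    if (is.null(G)) return(v)
    as.numeric(cppApplyFilter(v, G@kernels, FALSE, G@dims, G@norms))
  }
  applyGt <- function(v) {
    if (is.null(G)) return(v)
    as.numeric(cppApplyFilterAdjoint(v, G@kernels, FALSE, G@dims,
                                     G@norms))
  }
  subsets <- subsetPartition(view@geometry, config$nSubsets)
  # sensitivity: Gt At Bt 1_s (matched adjoint of the model B A G)
  sens <- lapply(subsets, function(s) {
    ones <- rep(0, length(y@counts))
    ones[s + 1] <- 1
    bt <- as.numeric(B %*% ones)
    applyGt(as.numeric(cppBackProject(bt, view@dims, view@voxelSize,
                                      view@center, gl, integer(0),
                                      view@raysPerLor)))
  })
  xv <- rep(1, prod(view@dims))
  for (it in seq_len(config$nIterations)) {
    for (si in seq_along(subsets)) {
      s <- subsets[[si]]
      yg <- cppForwardProject(applyG(xv), view@dims, view@voxelSize,
                              view@center, gl, integer(0),
                              view@raysPerLor)
      yb <- as.numeric(Matrix::crossprod(B, yg))
      ratio <- rep(0, length(yb))
      ratio[s + 1] <- y@counts[s + 1] / pmax(yb[s + 1], eps)
      rt <- as.numeric(B %*% ratio)
      corr <- applyGt(as.numeric(cppBackProject(rt, view@dims,
                                                view@voxelSize,
                                                view@center, gl,
                                                integer(0),
                                                view@raysPerLor)))
      upd <- corr / pmax(sens[[si]], eps)
      upd[sens[[si]] <= eps] <- 1  # voxels this subset cannot see
      xv <- xv * upd
    }
  }
  imageVolume(values = array(pmax(xv, 0), dim = view@dims),
              voxelSize = view@voxelSize, center = view@center)
}

#' Estimate the scatter-free detector-response kernel
#'
#' Simulates a point source with scattering switched off (the
#' photoelectric coefficient set to the full total attenuation, so the
#' first-interaction statistics match the full model) and fits an
#' image-space kernel to the resulting histogram through the view's
#' projector. The result is the geometric part of the detector blur -
#' tube width and depth-of-interaction spread relative to the ray
#' model - free of inter-crystal scattering. Used to give the
#' LOR-space reference method a full detector-response forward model.
#'
#' @param view the [SystemMatrixView-class] the kernel complements.
#' @param table attenuation matrix of the full model (its total sets
#'   the interaction statistics).
#' @param nPairs photon pairs for the estimate.
#' @param seed integer seed.
#' @param position source point; the volume's center voxel by default.
#' @param steps,lr kernel-fit settings (see [fitKernelDirect()]).
#' @return a [FilterKernel-class].
#' @export
estimateResponseKernel <- function(view, table = defaultAttenuation(),
                                   nPairs = 2e6, seed = 1L,
                                   position = NULL, steps = 2000,
                                   lr = 0.1) {
  tmpl <- imageVolume(dims = view@dims, voxelSize = view@voxelSize,
                      center = view@center)
  if (is.null(position))
    position <- voxelToWorld(tmpl, containingVoxel(tmpl, view@center))
  lk <- attenuationLookup(table, table[, 1])
  tab0 <- validateAttenuation(cbind(table[, 1], lk[, "mu_total"],
                                    0 * lk[, 1], 0 * lk[, 1]))
  h <- simulatePointSource(position, nPairs, view@geometry, tab0,
                           seed = seed)
  idx <- containingVoxel(tmpl, position)
  P <- patchProjector(view, idx - 5L, 11L)
  fit <- fitKernelDirect(P, h@counts, steps = steps, lr = lr)
  new("FilterKernel", values = array(fit$values, dim = rep(11L, 3)))
}

#' Sparse LOR-domain blur operator
#'
#' Materializes the endpoint-offset blur as a sparse `nLORs x nLORs`
#' matrix `B` with `B[src, tgt]` the probability that counts on LOR
#' `src` are recorded on LOR `tgt` (offsets applied independently to
#' both endpoints, invalid/self targets dropped, rows renormalized to
#' sum 1 so counts are preserved). `t(B) %*% y` applies the blur,
#' `B %*% r` its adjoint.
#'
#' @param blur result of [estimateLorBlur()].
#' @param geometry the scanner.
#' @param probFloor offsets below this probability are dropped from the
#'   support (the kept mass is renormalized); bounds the operator's
#'   density.
#' @return a `dgCMatrix`.
#' @export
lorBlurMatrix <- function(blur, geometry, probFloor = 1e-3) {
  q <- blur$prob
  keep <- which(q >= probFloor, arr.ind = TRUE)
  stopIfNot(nrow(keep) > 0, "degenerate blur support")
  dt <- blur$offsetsT[keep[, 1]]
  dz <- blur$offsetsZ[keep[, 2]]
  p <- q[keep]
  p <- p / sum(p)
  tr <- cppLorBlurTriplets(as.integer(dt), as.integer(dz), p,
                           geomList(geometry))
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(tr$n, tr$n))
}

#' NRMSE evaluation of labeled reconstructions
#'
#' Computes the NRMSE of each labeled reconstruction against the
#' reference (by convention the LOR-space-corrected reconstruction) and
#' returns a machine-readable table preserving the input order.
#'
#' @param recons named list of [ImageVolume-class] reconstructions.
#' @param reference the reference [ImageVolume-class].
#' @return data frame with `method` and `nrmse_percent`.
#' @export
evaluateExperiment <- function(recons, reference) {
  stopIfNot(is(reference, "ImageVolume"), "reference volume is required")
  stopIfNot(length(names(recons)) == length(recons) &&
              all(nzchar(names(recons))), "recons must be a named list")
  vals <- vapply(recons, function(r) nrmse(r, reference, asPercent = TRUE),
                 numeric(1))
  data.frame(method = names(recons), nrmse_percent = as.numeric(vals),
             row.names = NULL)
}
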