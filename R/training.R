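# Training pipeline: Monte Carlo point-source samples, the LOR-space
# smooth-L1 loss on L1-normalized LOR images, the backprojection gradient
# approximation, and the cross-validated RAdam loop. The predicted kernel
# is placed at the voxel containing the sample position and forward
# projected geometrically (without ICS), so the kernel is pushed to
# absorb exactly the difference between the geometric model and the
# ICS-affected Monte Carlo data.

#' Training configuration
#'
#' Defaults follow the study protocol (50 epochs, RAdam at learning rate
#' 1e-5, batch size 8, 5-fold cross-validation with an 80/20 split) at
#' desk scale: 50 samples of 1e6 photon pairs each (the full-scale
#' protocol uses 500 samples of 1e8 pairs; fidelity scales with these).
#'
#' @param nSamples number of point-source training samples.
#' @param nPairs photon pairs per sample.
#' @param epochs training epochs per fold.
#' @param learningRate RAdam learning rate.
#' @param batchSize samples per optimizer step.
#' @param folds cross-validation folds (>= 2 for CV; each fold trains on
#'   (folds-1)/folds of the samples).
#' @param seed master seed for sampling, fold assignment and shuffling.
#' @param headOnly freeze the trunk and train only the output layer.
#' @param straightThrough pass gradients through the parameter clamp even
#'   at the bounds (skew-normal head).
#' @param refit after cross-validation, refit a final network on all
#'   samples (the model returned for deployment).
#' @return a config list.
#' @export
trainConfig <- function(nSamples = 50, nPairs = 1e6, epochs = 50,
                        learningRate = 1e-5, batchSize = 8, folds = 5,
                        seed = 1L, headOnly = FALSE,
                        straightThrough = FALSE, refit = TRUE) {
  stopIfNot(folds >= 2, "folds must be >= 2")
  list(nSamples = nSamples, nPairs = nPairs, epochs = epochs,
       learningRate = learningRate, batchSize = batchSize, folds = folds,
       seed = as.integer(seed), headOnly = headOnly,
       straightThrough = straightThrough, refit = refit)
}

#' Generate Monte Carlo training samples
#'
#' Draws `nSamples` positions uniformly from the volume template's world
#' box, simulates each point source with the ICS-enabled detector model
#' and stores the position together with its LOR histogram. Deterministic
#' under the master seed; samples whose histogram came out all-zero are
#' regenerated with a fresh sub-seed (logged). With `outDir` each sample
#' is additionally serialized as it is produced and existing files are
#' reused, making long generations resumable.
#'
#' @param config a [trainConfig()].
#' @param geometry the scanner.
#' @param volumeTemplate the field-of-view box to sample positions from.
#' @param table attenuation matrix.
#' @param outDir optional directory for incremental serialization.
#' @return list of samples, each `list(position, counts, nPairs, seed)`.
#' @export
generateTrainingSet <- function(config, geometry, volumeTemplate,
                                table = defaultAttenuation(),
                                outDir = NULL) {
  d <- dim(volumeTemplate@values)
  half <- d * volumeTemplate@voxelSize / 2
  positions <- withSeed(config$seed, {
    matrix(stats::runif(3 * config$nSamples, -1, 1), ncol = 3) %*%
      diag(half) + matrix(volumeTemplate@center, config$nSamples, 3,
                          byrow = TRUE)
  })
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  samples <- vector("list", config$nSamples)
  for (i in seq_len(config$nSamples)) {
    if (!is.null(outDir)) {
      f <- file.path(outDir, sprintf("sample_%04d.rds", i))
      if (file.exists(f)) { samples[[i]] <- readRDS(f); next }
    }
    seedI <- (config$seed + 7919L * i) %% .Machine$integer.max
    rep <- 0L
    repeat {
      h <- simulatePointSource(positions[i, ], config$nPairs, geometry,
                               table, seed = seedI + rep)
      if (sum(h@counts) > 0) break
      rep <- rep + 1L
      message("sample ", i, ": zero-count histogram, regenerating (",
              rep, ")")
      stopIfNot(rep < 20L, "could not generate a nonzero sample")
    }
    samples[[i]] <- list(position = positions[i, ], counts = h@counts,
                         nPairs = config$nPairs, seed = seedI + rep)
    if (!is.null(outDir)) saveRDS(samples[[i]], f)
  }
  samples
}

#' Smooth L1 loss between LOR images
#'
#' Per-LOR Huber-type loss on L1-normalized LOR images: with difference
#' `d`, the loss is `d^2 / 2` for `|d| < 1` and `|d| - 1/2` otherwise
#' (continuous at the knee); the total is the sum over LORs.
#'
#' @param yPred,yTrue [LORHistogram-class] objects on the same geometry,
#'   or plain numeric vectors.
#' @param normalize divide each input by its L1 norm first (the default;
#'   zero-norm input is rejected).
#' @return list with `perLor` losses and their `total`.
#' @export
smoothL1 <- function(yPred, yTrue, normalize = TRUE) {
  p <- if (is(yPred, "LORHistogram")) yPred@counts else as.numeric(yPred)
  t <- if (is(yTrue, "LORHistogram")) yTrue@counts else as.numeric(yTrue)
  stopIfNot(length(p) == length(t), "LOR images differ in length")
  if (normalize) {
    sp <- sum(abs(p)); st <- sum(abs(t))
    stopIfNot(sp > 0 && st > 0, "cannot L1-normalize a zero LOR image")
    p <- p / sp; t <- t / st
  }
  d <- p - t
  a <- abs(d)
  l <- ifelse(a < 1, 0.5 * d^2, a - 0.5)
  list(perLor = l, total = sum(l))
}

# derivative of the per-LOR smooth L1 w.r.t. the (normalized) prediction
smoothL1Grad <- function(d) ifelse(abs(d) < 1, d, sign(d))

# gradient of the total loss w.r.t. the raw (unnormalized, non-negative)
# prediction, including the L1-normalization Jacobian
lossGradRaw <- function(yRaw, yTrueNorm) {
  s <- sum(yRaw)
  stopIfNot(s > 0, "cannot L1-normalize a zero LOR image")
  yn <- yRaw / s
  gN <- smoothL1Grad(yn - yTrueNorm)
  (gN - sum(gN * yn)) / s
}

#' Loss gradient with respect to a placed kernel (backprojection form)
#'
#' Approximates the gradient of the smooth L1 loss with respect to the
#' 11^3 kernel placed at `position` by backprojecting the per-LOR loss
#' gradient (including the L1-normalization Jacobian) and extracting the
#' kernel-footprint patch. Because forward and backprojection are an
#' exact adjoint pair, this equals the true gradient for kernel entries
#' inside the volume; entries whose voxels fall outside are zero-padded.
#'
#' @param yPred the geometric forward projection of the placed kernel
#'   (raw, unnormalized), as a [LORHistogram-class] or numeric vector.
#' @param yTrue the ICS-affected target histogram.
#' @param view the [SystemMatrixView-class] used for the projection.
#' @param position world position the kernel was placed at, mm.
#' @param kernelSize kernel side length.
#' @return `kernelSize^3` gradient array.
#' @export
kernelGradient <- function(yPred, yTrue, view, position, kernelSize = 11L) {
  p <- if (is(yPred, "LORHistogram")) yPred@counts else as.numeric(yPred)
  t <- if (is(yTrue, "LORHistogram")) yTrue@counts else as.numeric(yTrue)
  st <- sum(abs(t))
  stopIfNot(st > 0, "cannot L1-normalize a zero target")
  gY <- lossGradRaw(p, t / st)
  template <- imageVolume(dims = view@dims, voxelSize = view@voxelSize,
                          center = view@center)
  # raw backprojection (the loss gradient is signed)
  xraw <- cppBackProject(gY, view@dims, view@voxelSize, view@center,
                         viewGeom(view), integer(0),
                         view@raysPerLor)
  h <- (kernelSize - 1L) %/% 2L
  idx <- containingVoxel(template, position)
  out <- array(0, dim = rep(kernelSize, 3))
  lo <- idx - h
  for (ox in 0:(kernelSize - 1)) for (oy in 0:(kernelSize - 1)) {
    gx <- lo[1] + ox; gy <- lo[2] + oy
    if (gx < 0 || gy < 0 || gx >= view@dims[1] || gy >= view@dims[2]) next
    gz <- lo[3] + 0:(kernelSize - 1)
    ok <- gz >= 0 & gz < view@dims[3]
    if (!any(ok)) next
    out[ox + 1, oy + 1, which(ok)] <-
      xraw[gx + 1 + view@dims[1] * (gy + view@dims[2] * gz[ok])]
  }
  if (any(idx < h) || any(idx + h >= view@dims))
    warning("kernel patch exceeds the volume; outside entries zero-padded")
  out
}

# --- RAdam (rectified adaptive moment estimation) -----------------------

radamInit <- function(weights) {
  list(t = 0,
       m = lapply(weights, function(l) list(W = 0 * l$W, b = 0 * l$b)),
       v = lapply(weights, function(l) list(W = 0 * l$W, b = 0 * l$b)))
}

# One RAdam step. Updates happen in place through the compiled kernel;
# the caller must own fresh (unshared) copies of weights and state.
radamStep <- function(weights, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(weights)) {
    for (part in c("W", "b")) {
      g <- grads[[i]][[part]]
      if (is.null(g)) next
      cppRadamUpdate(weights[[i]][[part]], state$m[[i]][[part]],
                     state$v[[i]][[part]], g, lr, beta1, beta2, eps,
                     state$t)
    }
  }
  list(weights = weights, state = state)
}

# force fresh copies so in-place optimizer updates cannot alias the
# caller's network object
deepCopyWeights <- function(weights) {
  lapply(weights, function(l) list(W = l$W + 0, b = l$b + 0))
}

# --- per-sample loss / gradient through a cached patch projector --------

# precompute per-sample patch matrices and normalized targets. The
# patch only projects onto the LORs crossing it ("support"); the loss on
# the remaining LORs is a per-sample constant and the normalization
# coupling only involves support terms, so everything downstream works
# on the support rows alone.
prepareSamples <- function(samples, view, kernelSize) {
  template <- imageVolume(dims = view@dims, voxelSize = view@voxelSize,
                          center = view@center)
  h <- (kernelSize - 1L) %/% 2L
  lapply(samples, function(s) {
    idx <- containingVoxel(template, s$position)
    P <- patchProjector(view, idx - h, kernelSize)
    st <- sum(s$counts)
    ytn <- s$counts / st
    sup <- sort(unique(P@i)) + 1L
    ytnOff <- ytn[-sup]
    offLoss <- sum(ifelse(ytnOff < 1, 0.5 * ytnOff^2, ytnOff - 0.5))
    list(position = s$position, P = P[sup, , drop = FALSE],
         ytn = ytn[sup], offLoss = offLoss)
  })
}

# loss (and optionally the gradient at the linear head output) of one
# prepared sample for a head output vector `out`
sampleLossGrad <- function(net, out, prep, wantGrad = TRUE,
                           straightThrough = FALSE) {
  if (net@head == "direct") {
    r <- pmax(out, 0)
    S <- sum(r)
    if (S <= 0) return(list(loss = NA_real_, gOut = 0 * out))
    k <- r / S
    jac <- NULL
  } else {
    raw <- out
    params <- clampParams(raw)
    ek <- evaluateKernel(params, kernelSize = net@kernelSize,
                         gradient = wantGrad)
    if (wantGrad) { k <- as.numeric(ek$kernel@values); jac <- ek$jacobian }
    else k <- as.numeric(ek@values)
  }
  y <- as.numeric(prep$P %*% k)
  sp <- sum(y)
  if (sp <= 0) return(list(loss = NA_real_, gOut = 0 * out))
  yn <- y / sp
  d <- yn - prep$ytn
  a <- abs(d)
  loss <- sum(0.5 * pmin(a, 1)^2 + pmax(a - 1, 0)) + prep$offLoss
  if (!wantGrad) return(list(loss = loss))
  gN <- pmax(pmin(d, 1), -1)
  gY <- (gN - sum(gN * yn)) / sp
  gK <- as.numeric(Matrix::crossprod(prep$P, gY))
  if (net@head == "direct") {
    gR <- (gK - sum(gK * k)) / S
    gOut <- gR * (out > 0)
  } else {
    gParams <- as.numeric(crossprod(jac, gK))
    gOut <- gParams * clampMask(raw, straightThrough)
  }
  list(loss = loss, gOut = gOut)
}

# mean loss of the network over prepared samples (no gradient)
evalLoss <- function(net, preps) {
  pos <- do.call(rbind, lapply(preps, `[[`, "position"))
  out <- netForward(net, pos)$out
  ls <- vapply(seq_along(preps), function(i)
    sampleLossGrad(net, out[i, ], preps[[i]], wantGrad = FALSE)$loss,
    numeric(1))
  mean(ls, na.rm = TRUE)
}

# one epoch of minibatch RAdam over the given sample indices
trainEpoch <- function(net, preps, idx, config, opt) {
  batches <- split(idx, ceiling(seq_along(idx) / config$batchSize))
  totLoss <- 0
  for (bt in batches) {
    pos <- do.call(rbind, lapply(preps[bt], `[[`, "position"))
    fwd <- netForward(net, pos)
    gOut <- matrix(0, length(bt), ncol(fwd$out))
    for (j in seq_along(bt)) {
      sg <- sampleLossGrad(net, fwd$out[j, ], preps[[bt[j]]],
                           straightThrough = config$straightThrough)
      if (is.finite(sg$loss)) totLoss <- totLoss + sg$loss
      else stop("non-finite loss in batch; offending sample index ",
                bt[j], call. = FALSE)
      gOut[j, ] <- sg$gOut
    }
    grads <- netBackward(net, fwd, gOut)
    if (config$headOnly)
      for (i in seq_len(length(grads) - 1))
        grads[[i]] <- list(W = 0 * grads[[i]]$W, b = 0 * grads[[i]]$b)
    step <- radamStep(net@weights, grads, opt, config$learningRate)
    net@weights <- step$weights
    opt <- step$state
  }
  list(net = net, opt = opt, meanLoss = totLoss / length(idx))
}

#' Train a kernel-prediction network
#'
#' K-fold cross-validation (each fold trains on (folds-1)/folds of the
#' samples and logs the held-out loss per epoch), followed by a refit on
#' all samples which is the returned model. Each optimizer step predicts
#' kernels at the batch positions, places them at the voxel containing
#' each sample position, forward projects geometrically through a cached
#' sparse patch operator, L1-normalizes, evaluates the smooth L1 loss
#' against the normalized Monte Carlo histogram, and backpropagates
#' through the adjoint (backprojection) gradient, the normalization
#' Jacobians and the head (rectifier active set, or the skew-normal
#' kernel's analytic parameter Jacobian through the clamp).
#'
#' @param network an initialized [ICSNet-class].
#' @param samples training samples from [generateTrainingSet()].
#' @param config a [trainConfig()].
#' @param view the [SystemMatrixView-class] defining the projector.
#' @param verbose print per-epoch progress.
#' @return list with `network` (the refit model), `folds` (per-fold
#'   train/test loss curves) and `foldAssignment`.
#' @export
trainICSNet <- function(network, samples, config, view, verbose = FALSE) {
  stopIfNot(length(samples) >= config$folds,
            "need at least as many samples as folds")
  preps <- prepareSamples(samples, view, network@kernelSize)
  n <- length(samples)
  foldOf <- withSeed(config$seed + 1L,
                     sample(rep(seq_len(config$folds), length.out = n)))
  folds <- list()
  for (f in seq_len(config$folds)) {
    trainIdx <- which(foldOf != f)
    testIdx <- which(foldOf == f)
    net <- network
    net@weights <- deepCopyWeights(network@weights)
    opt <- radamInit(net@weights)
    trainCurve <- testCurve <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      idx <- withSeed(config$seed + 100L * f + ep,
                      sample(trainIdx))
      res <- trainEpoch(net, preps, idx, config, opt)
      net <- res$net; opt <- res$opt
      trainCurve[ep] <- res$meanLoss
      testCurve[ep] <- evalLoss(net, preps[testIdx])
      if (verbose)
        message(sprintf("fold %d epoch %d: train %.3e test %.3e",
                        f, ep, trainCurve[ep], testCurve[ep]))
    }
    folds[[f]] <- list(train = trainCurve, test = testCurve)
  }
  finalNet <- network
  finalNet@weights <- deepCopyWeights(network@weights)
  if (config$refit) {
    opt <- radamInit(finalNet@weights)
    refitCurve <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      idx <- withSeed(config$seed + 9000L + ep, sample(n))
      res <- trainEpoch(finalNet, preps, idx, config, opt)
      finalNet <- res$net; opt <- res$opt
      refitCurve[ep] <- res$meanLoss
      if (verbose)
        message(sprintf("refit epoch %d: train %.3e", ep, refitCurve[ep]))
    }
    finalNet@history <- list(folds = folds, refit = refitCurve)
  } else {
    finalNet@history <- list(folds = folds)
  }
  list(network = finalNet, folds = folds, foldAssignment = foldOf)
}

#' Directly fit a kernel in kernel space
#'
#' Projected gradient descent on the kernel values themselves (rectify
#' and renormalize after every step) against a target LOR histogram
#' through a patch projector: the kernel-space optimum used as the
#' reference when assessing what the networks recover.
#'
#' @param P sparse patch projector from [patchProjector()].
#' @param yTrue target histogram counts.
#' @param kernelSize kernel side length.
#' @param steps,lr gradient steps and step size.
#' @param init optional starting kernel values.
#' @return list with the fitted normalized kernel `values` and the final
#'   `loss`.
#' @export
fitKernelDirect <- function(P, yTrue, kernelSize = 11L, steps = 400,
                            lr = 0.05, init = NULL) {
  ytn <- yTrue / sum(yTrue)
  k <- if (is.null(init)) gaussianKernelValues(7 / 6, kernelSize) else
    init / sum(init)
  loss <- NA_real_
  for (s in seq_len(steps)) {
    y <- as.numeric(P %*% k)
    sp <- sum(y)
    yn <- y / sp
    d <- yn - ytn
    loss <- sum(ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5))
    gY <- (smoothL1Grad(d) - sum(smoothL1Grad(d) * yn)) / sp
    gK <- as.numeric(Matrix::crossprod(P, gY))
    gK <- gK - sum(gK * k)  # project onto the simplex tangent
    k <- pmax(k - lr * gK, 0)
    k <- k / sum(k)
  }
  list(values = k, loss = loss)
}
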