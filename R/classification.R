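## Constrained 3D classification from 2D projections. Per-projection
## scores against each class reference are converted to occupancies with
## a softmax standardised by the GLOBAL score statistics (mean/sd over
## the full dataset, never per bundle); per-particle occupancies average
## the projection occupancies with Gaussian tilt weights centred at zero
## tilt, so all projections of a particle share one class distribution.
## Class maps are rebuilt each iteration by occupancy-weighted Fourier
## insertion. Score-based weights are deliberately NOT used in the
## occupancy averaging (they overfit at the low SNR of tilt data).

#' Per-projection class occupancies from scores (softmax)
#'
#' `occ_k` is proportional to `exp((s_k - mean) / max(sd, sdFloor))` with
#' global statistics, making occupancies invariant to a joint affine
#' rescaling of all scores.
#'
#' @param scores n x K matrix of per-projection, per-class scores.
#' @param globalMean,globalSd global score statistics (over all
#'   projections and classes of the full dataset).
#' @param sdFloor lower bound for the softmax temperature.
#' @return n x K matrix of occupancies, rows summing to one.
#' @export
projectionOccupancies <- function(scores, globalMean, globalSd,
                                  sdFloor = 1e-6) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 1) stop("at least one class is required")
  z <- (scores - globalMean) / max(globalSd, sdFloor)
  z <- z - apply(z, 1, max)           # numerical safety only
  e <- exp(z)
  e / rowSums(e)
}

#' Per-particle occupancies by tilt-weighted averaging
#'
#' Projection occupancies of one particle are averaged with Gaussian
#' weights `exp(-beta^2 / (2 sigmaTilt^2))` centred at the zero-degree
#' tilt (default s.d. 6 degrees), renormalised over the particle's
#' tilts; the result is renormalised to sum to one. All projections of a
#' particle thereby share one class distribution.
#'
#' @param projOcc n x K matrix of projection occupancies.
#' @param particleOf length-n particle index (1-based) per projection.
#' @param beta length-n tilt angle (degrees) per projection.
#' @param nParticles total number of particles.
#' @param sigmaTilt Gaussian s.d. in degrees; `Inf` gives a plain mean.
#' @return P x K matrix of particle occupancies.
#' @export
particleOccupancies <- function(projOcc, particleOf, beta, nParticles,
                                sigmaTilt = 6) {
  K <- ncol(projOcc)
  w <- if (is.infinite(sigmaTilt)) rep(1, length(beta)) else
    exp(-beta^2 / (2 * sigmaTilt^2))
  out <- matrix(0, nParticles, K)
  for (k in seq_len(K))
    out[, k] <- groupedSum(w * projOcc[, k], particleOf, nParticles)
  wsum <- groupedSum(w, particleOf, nParticles)
  out <- out / pmax(wsum, .Machine$double.eps)
  out / rowSums(out)
}

groupedSum <- function(x, g, n) {
  out <- numeric(n)
  s <- tapply(x, g, sum)
  out[as.integer(names(s))] <- s
  out
}

## Per-projection cache for classification: crop transforms, projection
## rotations, in-crop residual shifts and defocus scalars, computed once
## (poses fixed in no-alignment mode) and reused by every scoring and
## insertion pass. Projection order is tilt-major and fixed, so
## occupancy rows align across passes. Roughly box^2 * 16 bytes per
## projection of memory.
buildProjectionCache <- function(sim, particles) {
  spec <- sim@spec
  ps <- spec$pixelSize
  box <- spec$boxSize
  geom <- sim@geometry
  nT <- nTilts(geom)
  n <- nParticles(particles)
  dims <- spec$tomogramDims
  imgCtr <- floor(dims[1:2] / 2)
  fts <- vector("list", n * nT)
  rots <- vector("list", n * nT)
  resid <- matrix(0, n * nT, 2)
  dfs <- matrix(0, n * nT, 3)
  particleOf <- integer(n * nT); betaOf <- numeric(n * nT)
  row <- 0L
  for (t in seq_len(nT)) {
    im <- sim@tiltImages[, , t]
    for (p in seq_len(n)) {
      pose <- composeProjectionPose(geom, t, particles@positions[p, ],
                                    particles@angles[p, ], dims)
      cInt <- round(imgCtr + pose$shift)
      if (!boxInside(cInt, box, dims)) next
      row <- row + 1L
      fts[[row]] <- ftCentered(cropBox(im, cInt, box))
      rots[[row]] <- pose$rotation
      resid[row, ] <- imgCtr + pose$shift - cInt
      dfs[row, ] <- projDefocus(geom, t, pose$zDepth, ps)
      particleOf[row] <- p; betaOf[row] <- geom@beta[t]
    }
  }
  o <- sim@optics
  ctfs <- lapply(seq_len(row), function(i)
    ctfMatrixRaw(dfs[i, 1], dfs[i, 2], dfs[i, 3], o@voltage, o@cs,
                 o@amplitudeContrast, o@phaseShift, box, ps))
  list(fts = fts[seq_len(row)], rots = rots[seq_len(row)],
       resid = resid[seq_len(row), , drop = FALSE],
       dfs = dfs[seq_len(row), , drop = FALSE], ctfs = ctfs,
       particleOf = particleOf[seq_len(row)],
       betaOf = betaOf[seq_len(row)], box = box, ps = ps,
       optics = sim@optics, n = row)
}

cacheCtf <- function(cache, i) cache$ctfs[[i]]

## Score every cached projection against K class references.
scoreCachePass <- function(cache, refFTs, bandIdx) {
  K <- length(refFTs)
  scores <- matrix(0, cache$n, K)
  for (i in seq_len(cache$n)) {
    ctfM <- cacheCtf(cache, i)
    scores[i, ] <- vapply(refFTs, function(rf)
      cpp_slice_score(cache$fts[[i]], rf, cache$rots[[i]],
                      cache$resid[i, 1], cache$resid[i, 2], ctfM,
                      bandIdx), 0)
  }
  scores
}

## Occupancy-weighted insertion of every cached projection into K class
## accumulators; returns the K normalised maps.
insertCachePass <- function(cache, projOcc) {
  box <- cache$box
  K <- ncol(projOcc)
  ones <- matrix(1, box, box)
  accs <- vector("list", K)
  chunks <- split(seq_len(cache$n), ceiling(seq_len(cache$n) / 400))
  for (ch in chunks) {
    ctfs <- cache$ctfs[ch]
    imfts <- cache$fts[ch]
    rots <- array(unlist(cache$rots[ch]), c(3, 3, length(ch)))
    shifts <- cache$resid[ch, , drop = FALSE]
    wts <- rep(list(ones), length(ch))
    for (k in seq_len(K)) {
      acc <- cpp_insert_slices(box, imfts, rots, shifts, ctfs, wts,
                               projOcc[ch, k])
      accs[[k]] <- if (is.null(accs[[k]])) acc else
        list(num = accs[[k]]$num + acc$num,
             den = accs[[k]]$den + acc$den)
    }
  }
  lapply(accs, function(a)
    reconstructionMap(new("PartialReconstruction", num = a$num,
                          den = a$den, count = cache$n, halfSet = 0L)))
}

#' Constrained 3D classification from particle projections
#'
#' Starting from a random whole-particle assignment to K classes (the
#' initial references are occupancy-weighted reconstructions of those
#' random groups), iterates: score every projection against every class,
#' convert to occupancies with the global statistics, average per
#' particle with Gaussian tilt weights (constrained mode) or keep the
#' per-projection occupancies independent (unconstrained, for
#' comparison), rebuild class maps by occupancy-weighted insertion over
#' the full tilt range. Deterministic given the seed. Classes whose
#' population falls below `minPopulation` are reseeded from a random
#' half of the largest class.
#'
#' @param sim a \linkS4class{CetSimulation}.
#' @param particles aligned particle poses (fixed in `"no-alignment"`
#'   mode).
#' @param K number of classes.
#' @param nIter maximum iterations.
#' @param mode `"no-alignment"` (poses fixed) or `"with-alignment"`
#'   (a bounded constrained pose refinement against the best class after
#'   each iteration).
#' @param constrained average occupancies per particle (TRUE) or use
#'   per-projection occupancies independently (FALSE).
#' @param focusCenter,focusRadius optional spherical focus mask (centre
#'   in box voxels relative to the box centre; radius in Angstrom):
#'   scoring then uses class references masked to that sphere.
#' @param seed RNG seed for the initial random assignment.
#' @param band scoring band `(low, high)` in Angstrom.
#' @param sigmaTilt Gaussian tilt-weight s.d., degrees.
#' @param minPopulation reseeding floor for class populations.
#' @param tol mean absolute occupancy change for early convergence.
#' @param alignLimits search limits for `"with-alignment"` mode.
#' @param verbose print per-iteration populations.
#' @return a \linkS4class{ClassModel}.
#' @export
classifyConstrained <- function(sim, particles, K, nIter = 20,
                                mode = c("no-alignment", "with-alignment"),
                                constrained = TRUE, focusCenter = NULL,
                                focusRadius = NULL, seed = 1,
                                band = c(Inf, NA), sigmaTilt = 6,
                                minPopulation = 1, tol = 1e-4,
                                alignLimits = list(angle = 2, shift = 1),
                                verbose = FALSE) {
  mode <- match.arg(mode)
  if (K < 1) stop("K must be >= 1")
  spec <- sim@spec
  ps <- spec$pixelSize
  if (is.na(band[2])) band[2] <- 3 * ps
  box <- spec$boxSize
  n <- nParticles(particles)
  nT <- nTilts(sim@geometry)
  bandIdx <- bandIndices(box, ps, band[1], band[2])
  set.seed(seed)
  assign0 <- sample(rep_len(seq_len(K), n))
  occ <- matrix(0, n, K)
  occ[cbind(seq_len(n), assign0)] <- 1

  focusMask <- NULL
  if (!is.null(focusCenter) && !is.null(focusRadius)) {
    ax <- seq_len(box) - 1 - floor(box / 2)
    r2 <- outer(outer((ax - focusCenter[1])^2, (ax - focusCenter[2])^2,
                      `+`), (ax - focusCenter[3])^2, `+`)
    focusMask <- (sqrt(r2) <= focusRadius / ps) * 1
  }

  history <- list()
  refs <- NULL
  gm <- 0; gs <- 1
  cache <- buildProjectionCache(sim, particles)
  perParticleRows <- function(occMat)
    occMat[cache$particleOf, , drop = FALSE]
  projOccRows <- perParticleRows(occ)
  for (it in seq_len(nIter)) {
    ## class references from the current (projection-level) occupancies
    refs <- insertCachePass(cache, projOccRows)
    scoreRefs <- refs
    if (!is.null(focusMask))
      scoreRefs <- lapply(refs, function(v) v * focusMask)
    scores <- scoreCachePass(cache, lapply(scoreRefs, ftCentered),
                             bandIdx)
    ## global statistics over the full dataset (never per bundle): the
    ## softmax temperature is the s.d. of the within-projection class
    ## deviations -- the scale on which classes are discriminated
    gm <- mean(scores)
    dev <- scores - rowMeans(scores)
    gs <- if (K > 1) sd(as.numeric(dev)) else 0
    projOcc <- projectionOccupancies(scores, gm, gs)
    if (constrained) {
      occNew <- particleOccupancies(projOcc, cache$particleOf,
                                    cache$betaOf, n, sigmaTilt)
      projOccRows <- perParticleRows(occNew)
    } else {
      ## unconstrained: projections stay independent; particles are
      ## summarised by the plain mean for reporting/reseeding only
      occNew <- particleOccupancies(projOcc, cache$particleOf,
                                    cache$betaOf, n, Inf)
      projOccRows <- projOcc
    }
    pops <- colSums(occNew)
    for (k in which(pops < minPopulation)) {
      big <- which.max(pops)
      pool <- which(occNew[, big] > 1 / K)
      donors <- sample(pool, size = max(1, floor(length(pool) / 2)))
      occNew[donors, ] <- 0
      occNew[donors, k] <- 1
      pops <- colSums(occNew)
      if (constrained) projOccRows <- perParticleRows(occNew)
      message(sprintf(
        "iteration %d: class %d reseeded from class %d (%d particles)",
        it, k, big, length(donors)))
    }
    delta <- mean(abs(occNew - occ))
    occ <- occNew
    history[[it]] <- list(populations = pops, meanOccChange = delta,
                          globalMean = gm, globalSd = gs,
                          projOcc = projOcc,
                          particleOf = cache$particleOf,
                          betaOf = cache$betaOf)
    if (verbose)
      message(sprintf("iteration %d: populations %s, change %.5f", it,
                      paste(sprintf("%.1f", pops), collapse = "/"), delta))
    if (mode == "with-alignment") {
      best <- max.col(occ, ties.method = "first")
      for (k in seq_len(K)) {
        idx <- which(best == k)
        if (length(idx) == 0) next
        particles <- refineFullyConstrained(sim, particles, refs[[k]],
                                            searchLimits = alignLimits,
                                            bands = list(band), sweeps = 1,
                                            pIdx = idx)
      }
      cache <- buildProjectionCache(sim, particles)  # poses moved
      projOccRows <- if (constrained) perParticleRows(occ) else projOccRows
    }
    if (delta < tol && it > 1) break
  }
  ## final references at the converged occupancies
  finMaps <- insertCachePass(cache, projOccRows)
  new("ClassModel", references = finMaps, occupancies = occ,
      scoreMean = gm, scoreSd = gs, iterations = length(history),
      seed = as.integer(seed), populations = colSums(occ),
      history = history)
}

#' Hard class assignment from a ClassModel
#'
#' @param model a \linkS4class{ClassModel}.
#' @return integer class labels (argmax occupancy per particle).
#' @export
classAssignments <- function(model) {
  max.col(occupancies(model), ties.method = "first")
}
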