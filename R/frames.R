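## Per-particle video-frame trajectory refinement. Raw per-frame shifts
## are estimated by maximising the projection score of running-averaged
## frame crops against the reference, then regularised with temporal
## (second-difference) and spatial (neighbouring-particle) quadratic
## penalties solved in closed form. Per-frame mean scores feed the
## score-driven exposure weighting of the reconstruction.

#' Centered running averages of a frame stack
#'
#' Running mean over a centred window with edge truncation; the output
#' has as many frames as the input. `window = 1` is the identity and
#' `window = n` makes every output the full average.
#'
#' @param frames x-y-F array of frames.
#' @param window window length (1..F).
#' @return x-y-F array of running averages.
#' @export
runningAverages <- function(frames, window) {
  fN <- dim(frames)[3]
  stopifnot(window >= 1, window <= fN)
  out <- array(0, dim(frames))
  for (f in seq_len(fN)) {
    lo <- f - (window - 1) %/% 2
    lo <- max(1, min(lo, fN - window + 1))  # clamp the window at the edges
    hi <- lo + window - 1
    sub <- frames[, , lo:hi, drop = FALSE]
    out[, , f] <- apply(sub, c(1, 2), mean)
  }
  out
}

#' Refine per-particle frame trajectories with regularisation
#'
#' For every particle projection of the selected tilts, per-frame shifts
#' are found by maximising the band-limited projection score of the
#' running-averaged frame crop over a bounded shift range, then the noisy
#' trajectories are smoothed by minimising
#' `sum ||raw - x||^2 + lambdaT sum ||D2 x||^2 + lambdaS sum ||x_p - x_q||^2`
#' over neighbouring particle pairs (within `neighborRadius` voxels in
#' the same tilt). Trajectories are reported relative to the first frame.
#' When the per-frame score is below `snrFloor`, the running window is
#' doubled until the mean score stabilises (self-tuning averaging for
#' very low per-frame doses).
#'
#' @param sim a \linkS4class{CetSimulation} with simulated frames.
#' @param particles current (final) particle poses.
#' @param reference reference volume.
#' @param tilts tilt indices to process (default: all with frames).
#' @param window running-average window (frames); doubled automatically
#'   when scores are unstable below `snrFloor`.
#' @param maxShift shift search half-range, pixels.
#' @param lambdaT temporal smoothness weight.
#' @param lambdaS spatial (neighbour) smoothness weight.
#' @param neighborRadius neighbourhood radius in voxels.
#' @param band scoring band `(low, high)` in Angstrom.
#' @param snrFloor mean per-frame score below which the window doubles.
#' @return list with `trajectories` (per tilt: list per particle of
#'   F x 2 shifts), `raw` (unregularised), `frameScores` (T x F matrix of
#'   mean scores; NA for tilts without frames) and `window` (per tilt).
#' @export
refineTrajectories <- function(sim, particles, reference, tilts = NULL,
                               window = 3, maxShift = 3, lambdaT = 2,
                               lambdaS = 0.5, neighborRadius = 80,
                               band = c(Inf, NA), snrFloor = 0.02) {
  spec <- sim@spec
  ps <- spec$pixelSize
  if (is.na(band[2])) band[2] <- 3 * ps
  box <- spec$boxSize
  if (length(sim@frames) == 0) stop("simulation has no frames")
  if (is.null(tilts))
    tilts <- which(!vapply(sim@frames, is.null, TRUE))
  refFT <- ftCentered(reference)
  bandIdx <- bandIndices(box, ps, band[1], band[2])
  geom <- sim@geometry
  dims <- spec$tomogramDims
  imgCtr <- floor(dims[1:2] / 2)
  n <- nParticles(particles)
  fN <- spec$framesPerTilt
  trajectories <- vector("list", nTilts(geom))
  rawList <- vector("list", nTilts(geom))
  frameScores <- matrix(NA_real_, nTilts(geom), fN)
  usedWindow <- rep(NA_integer_, nTilts(geom))
  for (t in tilts) {
    stack <- sim@frames[[t]]
    if (is.null(stack)) next
    ## per-particle geometry for this tilt
    poses <- lapply(seq_len(n), function(p)
      composeProjectionPose(geom, t, particles@positions[p, ],
                            particles@angles[p, ], dims))
    cInts <- lapply(poses, function(pp) round(imgCtr + pp$shift))
    keep <- vapply(cInts, boxInside, TRUE, box = box, dims = dims)
    ctfs <- lapply(seq_len(n), function(p) {
      ctfP <- particleDefocus(tiltCtfParams(geom, t, sim@optics),
                              poses[[p]]$zDepth, ps)
      ctfMatrix(ctfP, box, ps)
    })
    w <- window
    repeat {
      avg <- runningAverages(stack, w)
      raw <- array(0, c(n, fN, 2))
      sc <- matrix(NA_real_, n, fN)
      for (p in which(keep)) {
        resid <- imgCtr + poses[[p]]$shift - cInts[[p]]
        for (f in seq_len(fN)) {
          ft <- ftCentered(cropBox(avg[, , f], cInts[[p]], box))
          obj <- function(dd)
            cpp_slice_score(ft, refFT, poses[[p]]$rotation,
                            resid[1] + dd[1], resid[2] + dd[2],
                            ctfs[[p]], bandIdx)
          res <- coordinateMaximize(obj, c(0, 0),
                                    rbind(c(-1, 1) * maxShift,
                                          c(-1, 1) * maxShift),
                                    tol = c(0.02, 0.02))
          raw[p, f, ] <- res$par
          sc[p, f] <- res$value
        }
      }
      if (fN == 1) { raw[] <- 0 }
      ms <- mean(sc, na.rm = TRUE)
      if (ms >= snrFloor || w >= fN) break
      w <- min(fN, 2 * w)   # self-tuning: longer averages at low SNR
    }
    usedWindow[t] <- w
    smooth <- regularizeTrajectories(raw, particlePositions(particles),
                                     keep, lambdaT, lambdaS,
                                     neighborRadius)
    ## report relative to frame 1
    traj <- lapply(seq_len(n), function(p) {
      m <- smooth[p, , ] - matrix(smooth[p, 1, ], fN, 2, byrow = TRUE)
      colnames(m) <- c("x", "y"); m
    })
    trajectories[[t]] <- traj
    rawList[[t]] <- raw
    frameScores[t, ] <- colMeans(sc, na.rm = TRUE)
  }
  list(trajectories = trajectories, raw = rawList,
       frameScores = frameScores, window = usedWindow)
}

## Closed-form quadratic smoothing of per-particle trajectories.
## raw: n x F x 2. Returns the same shape.
regularizeTrajectories <- function(raw, positions, keep, lambdaT, lambdaS,
                                   neighborRadius) {
  n <- dim(raw)[1]; fN <- dim(raw)[2]
  act <- which(keep)
  m <- length(act)
  out <- raw
  if (m == 0 || fN < 3) return(out)
  ## second-difference operator on frames
  D2 <- matrix(0, fN - 2, fN)
  for (i in seq_len(fN - 2)) D2[i, i:(i + 2)] <- c(1, -2, 1)
  Tm <- crossprod(D2)
  ## neighbour Laplacian on active particles
  L <- matrix(0, m, m)
  if (lambdaS > 0 && m > 1) {
    d <- as.matrix(stats::dist(positions[act, , drop = FALSE]))
    adj <- d > 0 & d <= neighborRadius
    L <- diag(rowSums(adj)) - adj * 1
  }
  ## system over the m*fN unknowns of one coordinate:
  ## (I + lambdaT I_m (x) Tm + lambdaS L (x) I_F) x = raw
  A <- diag(m * fN) +
    lambdaT * (diag(m) %x% Tm) +
    lambdaS * (L %x% diag(fN))
  for (cc in 1:2) {
    b <- as.vector(t(raw[act, , cc]))    # particle-major blocks of F
    x <- solve(A, b)
    out[act, , cc] <- matrix(x, m, fN, byrow = TRUE)
  }
  out
}
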