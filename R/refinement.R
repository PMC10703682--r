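## The projection-matching score d, reference-based global pose search,
## fully constrained 6-DOF refinement, and region-based constrained
## geometry refinement (objective D). The score is a normalised
## cross-correlation computed in Fourier space over a resolution band
## between the particle crop and the CTF-multiplied central-slice
## reprojection of the reference, so it is invariant to image scaling and
## offset. All per-projection poses are regenerated through the pose
## composition mapping at every optimiser step; no per-projection
## parameter is ever free.

#' Score one particle projection against a reference reprojection
#'
#' Normalised Fourier-band cross-correlation between an image and the
#' CTF-multiplied central slice of the reference at the given projection
#' pose. Lies in \[-1, 1\].
#'
#' @param image real particle crop (n x n).
#' @param referenceFT centred Fourier transform of the reference volume
#'   ([ftCentered()]).
#' @param rotation 3 x 3 projection orientation (from
#'   [composeProjectionPose()]).
#' @param shift length-2 in-crop shift of the particle centre, pixels.
#' @param ctf n x n centred CTF matrix ([ctfMatrix()]).
#' @param pixelSize pixel size in Angstrom.
#' @param band resolution band `(low, high)` in Angstrom.
#' @return the score `d`.
#' @export
scoreProjection <- function(image, referenceFT, rotation, shift, ctf,
                            pixelSize, band = c(Inf, 2 * pixelSize)) {
  n <- nrow(image)
  idx <- bandIndices(n, pixelSize, band[1], band[2])
  cpp_slice_score(ftCentered(image), referenceFT, rotation, shift[1],
                  shift[2], ctf, idx)
}

## ---- shared refinement infrastructure ----------------------------------

## Extract crops (centred FFTs + integer crop centres + per-projection CTF
## matrices) for the given particles across the given tilts, under the
## current geometry (+ optional region corrections). Poses may later move
## by a few pixels; the crop centre stays fixed and the in-crop shift
## absorbs the change.
extractCrops <- function(sim, particles, pIdx = NULL, tilts = NULL,
                         regions = NULL, withCtf = TRUE) {
  if (is.null(pIdx)) pIdx <- seq_len(nParticles(particles))
  geom <- sim@geometry
  if (is.null(tilts)) tilts <- seq_len(nTilts(geom))
  dims <- sim@spec$tomogramDims
  box <- sim@spec$boxSize
  ps <- sim@spec$pixelSize
  imgCtr <- floor(dims[1:2] / 2)
  ridx <- if (is.null(regions)) NULL else particleRegions(particles, regions)
  ## hoist tilt-image slices: subsetting the 3D stack per projection
  ## dominates the runtime otherwise
  ims <- lapply(tilts, function(t) sim@tiltImages[, , t])
  out <- vector("list", length(pIdx))
  for (i in seq_along(pIdx)) {
    p <- pIdx[i]
    perTilt <- vector("list", length(tilts))
    for (j in seq_along(tilts)) {
      t <- tilts[j]
      delta <- if (is.null(regions)) NULL else
        regionDelta(regions, ridx[p], t)
      pose <- composeProjectionPose(geom, t, particles@positions[p, ],
                                    particles@angles[p, ], dims, delta)
      cInt <- round(imgCtr + pose$shift)
      if (!boxInside(cInt, box, dims)) next
      crop <- cropBox(ims[[j]], cInt, box)
      entry <- list(ft = ftCentered(crop), centerInt = cInt, tilt = t)
      if (withCtf) {
        ctfP <- particleDefocus(
          tiltCtfParams(geom, t, sim@optics, regions,
                        if (is.null(ridx)) NULL else ridx[p]),
          pose$zDepth, ps)
        entry$ctf <- ctfMatrix(ctfP, box, ps)
      }
      perTilt[[j]] <- entry
    }
    out[[i]] <- perTilt
  }
  names(out) <- as.character(pIdx)
  out
}

## Aggregate score of one particle over its crops at a candidate pose.
particleScore <- function(sim, crops, refFT, bandIdx, position, angles,
                          regions = NULL, regionIdx = NULL) {
  geom <- sim@geometry
  dims <- sim@spec$tomogramDims
  imgCtr <- floor(dims[1:2] / 2)
  total <- 0
  for (cp in crops) {
    if (is.null(cp)) next
    t <- cp$tilt
    delta <- if (is.null(regions)) NULL else regionDelta(regions, regionIdx, t)
    pose <- composeProjectionPose(geom, t, position, angles, dims, delta)
    resid <- imgCtr + pose$shift - cp$centerInt
    total <- total + cpp_slice_score(cp$ft, refFT, pose$rotation, resid[1],
                                     resid[2], cp$ctf, bandIdx)
  }
  total
}

## Coordinate-wise golden-section maximisation with a keep-best guard:
## the returned value is never below the objective at the start point.
coordinateMaximize <- function(fn, start, limits, tol, active = NULL,
                               sweeps = 2) {
  x <- start
  if (is.null(active)) active <- seq_along(start)
  best <- fn(x)
  for (s in seq_len(sweeps)) {
    for (d in active) {
      lo <- limits[d, 1]; hi <- limits[d, 2]
      if (hi <= lo) next
      f1 <- function(v) { xx <- x; xx[d] <- v; fn(xx) }
      opt <- optimize(f1, c(lo, hi), maximum = TRUE, tol = tol[d])
      if (opt$objective > best) {
        best <- opt$objective
        x[d] <- opt$maximum
      }
    }
  }
  list(par = x, value = best)
}

#' Mean projection score per tilt
#'
#' Average of the projection-matching score over all particles, per
#' tilt. On dose-attenuated data the curve is bell-shaped across the
#' tilt series (strongest at the least-exposed low tilts) and feeds the
#' score-driven exposure weighting.
#'
#' @param sim a \linkS4class{CetSimulation}.
#' @param particles current particle poses.
#' @param reference reference volume.
#' @param band scoring band `(low, high)` in Angstrom.
#' @return numeric vector of per-tilt mean scores.
#' @export
perTiltScores <- function(sim, particles, reference, band = c(Inf, NA)) {
  ps <- sim@spec$pixelSize
  if (is.na(band[2])) band[2] <- 3 * ps
  box <- sim@spec$boxSize
  refFT <- ftCentered(reference)
  bandIdx <- bandIndices(box, ps, band[1], band[2])
  geom <- sim@geometry
  dims <- sim@spec$tomogramDims
  imgCtr <- floor(dims[1:2] / 2)
  crops <- extractCrops(sim, particles)
  out <- numeric(nTilts(geom))
  cnt <- numeric(nTilts(geom))
  for (i in seq_len(nParticles(particles))) {
    for (cp in crops[[i]]) {
      if (is.null(cp)) next
      t <- cp$tilt
      pose <- composeProjectionPose(geom, t, particles@positions[i, ],
                                    particles@angles[i, ], dims)
      resid <- imgCtr + pose$shift - cp$centerInt
      out[t] <- out[t] + cpp_slice_score(cp$ft, refFT, pose$rotation,
                                         resid[1], resid[2], cp$ctf,
                                         bandIdx)
      cnt[t] <- cnt[t] + 1
    }
  }
  out / pmax(cnt, 1)
}

## ---- reference-based global search --------------------------------------

#' Euler-angle grid for the global search
#'
#' @param angularStep grid step in degrees.
#' @param thetaRange,phiRange,psiRange ranges (degrees) searched for each
#'   angle; defaults cover the full sphere.
#' @return matrix with columns theta, phi, psi.
#' @export
eulerGrid <- function(angularStep, thetaRange = c(-180, 180),
                      phiRange = c(0, 180), psiRange = c(-180, 180)) {
  sq <- function(r, closed = FALSE) {
    s <- seq(r[1], r[2], by = angularStep)
    if (!closed && length(s) > 1 && s[length(s)] == r[2] &&
        (r[2] - r[1]) %% 360 == 0)
      s <- s[-length(s)]
    s
  }
  g <- expand.grid(theta = sq(thetaRange), phi = sq(phiRange, closed = TRUE),
                   psi = sq(psiRange))
  as.matrix(g)
}

#' Reference-based global pose search under the tilt-geometry constraint
#'
#' Exhaustive search over an Euler grid (and optionally a shift grid);
#' every candidate pose generates all per-tilt projection poses through
#' the pose composition mapping, and the candidate maximising the summed
#' score over tilts wins (ties: first in grid order). When a surface
#' normal prior is available the search is restricted to orientations
#' whose projection direction matches the normal, leaving a single free
#' in-plane angle.
#'
#' @param sim a \linkS4class{CetSimulation}.
#' @param particles \linkS4class{ParticleSet} with starting positions
#'   (angles are ignored unless ranges are relative).
#' @param reference reference volume.
#' @param angularStep Euler grid step, degrees (>= 1).
#' @param thetaRange,phiRange,psiRange searched ranges, degrees.
#' @param normals optional n x 3 matrix of unit normals (one per
#'   particle); restricts theta/phi to the normal direction and searches
#'   psi only.
#' @param tilts tilt indices used (default all).
#' @param band scoring band `(low, high)` in Angstrom.
#' @param pIdx particle indices to search (default all).
#' @return list with `particles` (poses updated, scores = mean d per
#'   tilt), and `evaluations` (score evaluations per particle).
#' @export
globalSearch <- function(sim, particles, reference, angularStep = 15,
                         thetaRange = c(-180, 180), phiRange = c(0, 180),
                         psiRange = c(-180, 180), normals = NULL,
                         tilts = NULL, band = c(Inf, NA), pIdx = NULL) {
  stopifnot(angularStep >= 1)
  ps <- sim@spec$pixelSize
  if (is.na(band[2])) band[2] <- 3 * ps
  box <- sim@spec$boxSize
  refFT <- ftCentered(reference)
  bandIdx <- bandIndices(box, ps, band[1], band[2])
  if (is.null(pIdx)) pIdx <- seq_len(nParticles(particles))
  crops <- extractCrops(sim, particles, pIdx, tilts)
  evals <- integer(length(pIdx))
  for (i in seq_along(pIdx)) {
    p <- pIdx[i]
    if (is.null(normals)) {
      grid <- eulerGrid(angularStep, thetaRange, phiRange, psiRange)
    } else {
      nv <- normals[p, ]
      ## orientations projecting the reference z-axis onto the normal:
      ## theta/phi from the normal, psi free.
      th <- rad2deg(atan2(nv[2], nv[1]))
      ph <- rad2deg(acos(max(-1, min(1, nv[3]))))
      psiSeq <- seq(psiRange[1], psiRange[2], by = angularStep)
      if (length(psiSeq) > 1 && (psiRange[2] - psiRange[1]) %% 360 == 0)
        psiSeq <- psiSeq[-length(psiSeq)]
      grid <- cbind(theta = th, phi = ph, psi = psiSeq)
    }
    bestVal <- -Inf; bestAng <- particles@angles[p, ]
    for (r in seq_len(nrow(grid))) {
      v <- particleScore(sim, crops[[i]], refFT, bandIdx,
                         particles@positions[p, ], grid[r, ])
      evals[i] <- evals[i] + length(crops[[i]])
      if (v > bestVal) { bestVal <- v; bestAng <- grid[r, ] }
    }
    particles@angles[p, ] <- canonicalEuler(bestAng)
    particles@score[p] <- bestVal / max(1, sum(!vapply(crops[[i]], is.null,
                                                       TRUE)))
  }
  validObject(particles)
  list(particles = particles, evaluations = evals)
}

## ---- fully constrained 6-DOF refinement ---------------------------------

#' Fully constrained per-particle pose refinement
#'
#' Local maximisation of the summed projection score over the six
#' particle parameters (three Euler angles, three translations), with all
#' projection poses regenerated through the pose composition at every
#' step. The aggregate score never decreases (keep-best guard).
#'
#' @param sim a \linkS4class{CetSimulation}.
#' @param particles starting poses.
#' @param reference reference volume.
#' @param searchLimits list with `angle` (degrees) and `shift` (voxels)
#'   half-widths; `shiftZ` optionally bounds z separately (default:
#'   `shift`).
#' @param tilts tilt indices used for refinement (e.g. a low-tilt window);
#'   default all.
#' @param bands band schedule: a list of `(low, high)` resolution bands
#'   in Angstrom, coarse to fine. The low-resolution stage provides a
#'   wide capture basin; the finer stages sharpen the pose.
#' @param sweeps optimiser effort multiplier (iteration budget).
#' @param pIdx particle indices to refine (default all).
#' @return updated \linkS4class{ParticleSet} (scores = mean d per tilt).
#' @export
refineFullyConstrained <- function(sim, particles, reference,
                                   searchLimits = list(angle = 8, shift = 5),
                                   tilts = NULL,
                                   bands = list(c(Inf, 10), c(20, NA)),
                                   sweeps = 2, pIdx = NULL) {
  ps <- sim@spec$pixelSize
  box <- sim@spec$boxSize
  refFT <- ftCentered(reference)
  if (!is.list(bands)) bands <- list(bands)
  bandIdxs <- lapply(bands, function(b) {
    if (is.na(b[2])) b[2] <- 2.25 * ps
    bandIndices(box, ps, b[1], b[2])
  })
  if (is.null(pIdx)) pIdx <- seq_len(nParticles(particles))
  crops <- extractCrops(sim, particles, pIdx, tilts)
  la <- searchLimits$angle
  lsh <- searchLimits$shift
  lz <- if (is.null(searchLimits$shiftZ)) lsh else searchLimits$shiftZ
  lims <- c(rep(la, 3), lsh, lsh, lz)
  for (i in seq_along(pIdx)) {
    p <- pIdx[i]
    if (la == 0 && lsh == 0 && lz == 0) next
    start <- c(particles@angles[p, ], particles@positions[p, ])
    cur <- start
    bad <- FALSE
    value <- NA_real_
    for (bandIdx in bandIdxs) {
      ## offsets from the starting pose; large penalty outside limits
      fn <- function(dx) {
        if (any(abs(dx) > lims + 1e-9)) return(-1e6)
        v <- particleScore(sim, crops[[i]], refFT, bandIdx,
                           start[4:6] + dx[4:6], start[1:3] + dx[1:3])
        if (!is.finite(v)) { bad <<- TRUE; return(-1e6) }
        v
      }
      dx0 <- cur - start
      v0 <- fn(dx0)
      ## Nelder-Mead follows the coupling between Euler coordinates that
      ## a coordinate-wise search cannot
      res <- stats::optim(dx0, fn, method = "Nelder-Mead",
                          control = list(fnscale = -1,
                                         maxit = 250 * sweeps,
                                         reltol = 1e-9,
                                         parscale = pmax(lims, 0.2)))
      if (bad) break
      if (res$value >= v0) {           # keep-best guard per stage
        cur <- start + res$par
        value <- res$value
      } else value <- v0
    }
    if (bad) next                      # flagged: pose unchanged
    particles@angles[p, ] <- canonicalEuler(cur[1:3])
    particles@positions[p, ] <- cur[4:6]
    particles@score[p] <- value /
      max(1, sum(!vapply(crops[[i]], is.null, TRUE)))
  }
  validObject(particles)
  particles
}

## ---- region-based constrained geometry refinement -----------------------

#' Region-based constrained geometry refinement
#'
#' For each region and tilt, maximises the summed score of the region's
#' particle projections over per-region corrections to the tilt geometry
#' (tilt-axis angle, tilt angle, image shifts), keeping all particle 3D
#' poses fixed. Models beam-induced sample deformation. Regions with
#' fewer than `minParticles` particles keep zero corrections.
#'
#' @param sim a \linkS4class{CetSimulation}.
#' @param particles current (fixed) particle poses.
#' @param reference reference volume.
#' @param regions \linkS4class{RegionGrid} carrying the starting
#'   corrections (usually zero).
#' @param searchLimits list with `shift` (pixels) and `angle` (degrees)
#'   half-widths; `angle = 0` refines shifts only.
#' @param minParticles minimum particles per region.
#' @param band scoring band `(low, high)` in Angstrom.
#' @param tilts tilt indices to refine (default all).
#' @param sweeps coordinate sweeps.
#' @return list with `regions` (updated grid), `score`, `score0`.
#' @export
refineRegionGeometry <- function(sim, particles, reference, regions,
                                 searchLimits = list(shift = 5, angle = 0),
                                 minParticles = 5, band = c(Inf, NA),
                                 tilts = NULL, sweeps = 2) {
  ps <- sim@spec$pixelSize
  if (is.na(band[2])) band[2] <- 3 * ps
  box <- sim@spec$boxSize
  refFT <- ftCentered(reference)
  bandIdx <- bandIndices(box, ps, band[1], band[2])
  geom <- sim@geometry
  if (is.null(tilts)) tilts <- seq_len(nTilts(geom))
  ridx <- particleRegions(particles, regions)
  dims <- sim@spec$tomogramDims
  imgCtr <- floor(dims[1:2] / 2)
  score0 <- 0; score1 <- 0
  for (g in seq_len(regionCount(regions))) {
    members <- which(ridx == g)
    if (length(members) < minParticles) {
      if (length(members) > 0)
        warning(sprintf(
          "region %d has %d < %d particles; geometry kept", g,
          length(members), minParticles))
      next
    }
    crops <- extractCrops(sim, particles, members, tilts, regions)
    for (j in seq_along(tilts)) {
      t <- tilts[j]
      objective <- function(dd) {
        total <- 0
        delta <- list(alpha = dd[1], beta = dd[2], shiftX = dd[3],
                      shiftY = dd[4])
        for (m in seq_along(members)) {
          cp <- crops[[m]][[j]]
          if (is.null(cp)) next
          pmi <- members[m]
          pose <- composeProjectionPose(geom, t,
                                        particles@positions[pmi, ],
                                        particles@angles[pmi, ], dims,
                                        delta)
          resid <- imgCtr + pose$shift - cp$centerInt
          total <- total + cpp_slice_score(cp$ft, refFT, pose$rotation,
                                           resid[1], resid[2], cp$ctf,
                                           bandIdx)
        }
        total
      }
      start <- c(regions@deltaAlpha[g, t], regions@deltaBeta[g, t],
                 regions@deltaShiftX[g, t], regions@deltaShiftY[g, t])
      s0 <- objective(start)
      score0 <- score0 + s0
      la <- searchLimits$angle; lsh <- searchLimits$shift
      active <- c(if (la > 0) 1:2, if (lsh > 0) 3:4)
      if (length(active) == 0) { score1 <- score1 + s0; next }
      ## coarse shift capture first: the fine-band objective is
      ## multimodal for deformations beyond ~1 px
      cur <- start
      if (lsh > 0) {
        step <- min(1.5, lsh)
        gsx <- seq(start[3] - lsh, start[3] + lsh, by = step)
        gsy <- seq(start[4] - lsh, start[4] + lsh, by = step)
        bestV <- -Inf
        for (sx in gsx) for (sy in gsy) {
          v <- objective(c(start[1], start[2], sx, sy))
          if (v > bestV) { bestV <- v; cur[3:4] <- c(sx, sy) }
        }
        lsh <- step                     # local polish around the capture
      }
      limits <- rbind(cur[1] + c(-1, 1) * la, cur[2] + c(-1, 1) * la,
                      cur[3] + c(-1, 1) * lsh, cur[4] + c(-1, 1) * lsh)
      res <- coordinateMaximize(objective, cur, limits,
                                tol = c(0.02, 0.02, 0.02, 0.02),
                                active = active, sweeps = sweeps)
      if (res$value >= s0) {
        regions@deltaAlpha[g, t] <- res$par[1]
        regions@deltaBeta[g, t] <- res$par[2]
        regions@deltaShiftX[g, t] <- res$par[3]
        regions@deltaShiftY[g, t] <- res$par[4]
        score1 <- score1 + res$value
      } else score1 <- score1 + s0
    }
  }
  list(regions = regions, score = score1, score0 = score0)
}
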