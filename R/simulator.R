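## Ground-truth synthetic data generator. Emulates the statistical
## structure the refinement modules assume: a multi-sphere phantom,
## particles at known poses, tilted projections with CTF and additive
## white Gaussian noise at a controlled SNR, dose-dependent attenuation
## growing with accumulated exposure (and a cos(beta) thickness factor),
## per-region geometric perturbations, and per-tilt video frames with
## drift.

#' Simulation specification
#'
#' Collects every knob of the synthetic tilt-series generator. The
#' defaults define the standard synthetic benchmark used throughout the
#' package tests: a 64-voxel particle box inside a 448 x 448 x 128
#' tomogram (sized so particle boxes stay essentially disjoint, as in a
#' well-dispersed specimen), 41 tilts from -60 to +60 degrees in
#' 3-degree steps with
#' dose-symmetric exposure order, 50 particles, SNR 0.5 (signal variance
#' over noise variance, measured on the first-exposure tilt inside the
#' particle boxes), 3 e/A^2 per tilt with a B-factor growing 1 A^2 per
#' e/A^2 of accumulated exposure, and 3 um nominal defocus at 300 kV.
#'
#' @param tomogramDims tomogram dimensions in voxels (x, y, z).
#' @param pixelSize pixel size in Angstrom.
#' @param tiltAngles tilt angles beta in degrees.
#' @param tiltAxisAngle tilt-axis angle alpha in degrees.
#' @param exposureOrder acquisition order; default dose-symmetric.
#' @param nParticles number of particles.
#' @param boxSize particle box size in voxels (even).
#' @param phantom phantom descriptor, see [makePhantom()].
#' @param phantomVariant optional second descriptor for two-class
#'   mixtures (default: the same phantom with one appended lobe when
#'   `twoVariants = TRUE`).
#' @param twoVariants simulate a 50/50 mixture of phantom and variant.
#' @param snr signal variance / noise variance in the projections;
#'   `Inf` disables noise.
#' @param dosePerTilt electron exposure per tilt, e/A^2.
#' @param bFactorRate B-factor growth per accumulated e/A^2 (A^2); the
#'   per-tilt envelope is `cos(beta) * exp(-k^2 B/4)`.
#' @param defocus nominal defocus, Angstrom (underfocus positive).
#' @param defocusJitter s.d. of the per-tilt defocus spread, Angstrom.
#' @param voltage,cs,amplitudeContrast optics constants (kV, mm, fraction).
#' @param minSpacing minimum pairwise 3D distance between particle
#'   centres, voxels (limits projection overlap).
#' @param framesPerTilt video frames per tilt (0 disables frames).
#' @param frameDrift per-frame linear drift (dx, dy), pixels/frame.
#' @param frameRandomWalk s.d. of the per-frame random-walk step, pixels.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return a named list of class `SimulationSpec`.
#' @export
simulationSpec <- function(tomogramDims = c(448, 448, 128), pixelSize = 2,
                           tiltAngles = seq(-60, 60, by = 3),
                           tiltAxisAngle = 0, exposureOrder = NULL,
                           nParticles = 50, boxSize = 64,
                           phantom = NULL, phantomVariant = NULL,
                           twoVariants = FALSE, snr = 0.5, dosePerTilt = 3,
                           bFactorRate = 1, defocus = 30000,
                           defocusJitter = 0, voltage = 300, cs = 2.7,
                           amplitudeContrast = 0.07,
                           minSpacing = boxSize / 2, framesPerTilt = 0,
                           frameDrift = c(0, 0), frameRandomWalk = 0,
                           seed = 1) {
  if (boxSize %% 2 != 0) stop("boxSize must be even")
  if (!is.finite(snr) && !is.infinite(snr) || (is.finite(snr) && snr <= 0))
    stop("snr must be positive")
  if (is.null(phantom)) phantom <- defaultPhantomDescriptor(boxSize)
  if (twoVariants && is.null(phantomVariant))
    phantomVariant <- variantPhantomDescriptor(boxSize)
  spec <- list(tomogramDims = tomogramDims, pixelSize = pixelSize,
               tiltAngles = tiltAngles, tiltAxisAngle = tiltAxisAngle,
               exposureOrder = exposureOrder, nParticles = nParticles,
               boxSize = boxSize, phantom = phantom,
               phantomVariant = phantomVariant, snr = snr,
               dosePerTilt = dosePerTilt, bFactorRate = bFactorRate,
               defocus = defocus, defocusJitter = defocusJitter,
               voltage = voltage, cs = cs,
               amplitudeContrast = amplitudeContrast,
               minSpacing = minSpacing,
               framesPerTilt = framesPerTilt, frameDrift = frameDrift,
               frameRandomWalk = frameRandomWalk, seed = seed)
  class(spec) <- "SimulationSpec"
  spec
}

#' Default multi-sphere phantom descriptor
#'
#' An asymmetric composite: a large envelope sphere plus a fixed,
#' asymmetric constellation of small dense lobes that gives the density
#' protein-like granularity (high-frequency content), so orientations
#' are recoverable with sub-degree precision. Scaled to the box.
#'
#' @param box particle box size in voxels.
#' @return a descriptor list for [makePhantom()].
#' @export
defaultPhantomDescriptor <- function(box) {
  lobes <- rbind(                      # fixed asymmetric constellation
    c( 0.00,  0.00,  0.00), c( 0.14,  0.05,  0.01),
    c(-0.05, -0.13,  0.08), c( 0.06, -0.03, -0.13),
    c(-0.12,  0.08, -0.05), c( 0.03,  0.14,  0.09),
    c( 0.10, -0.11,  0.05), c(-0.09, -0.02, -0.10),
    c( 0.16, -0.04, -0.06), c(-0.14, -0.08,  0.02),
    c( 0.01,  0.08, -0.15), c(-0.03, -0.16, -0.04),
    c( 0.08,  0.12, -0.08), c(-0.10,  0.13,  0.06),
    c( 0.13,  0.01,  0.12), c(-0.06,  0.02,  0.15))
  radii <- rep(c(0.055, 0.045, 0.05, 0.04), 4) * box
  amps <- rep(c(1.3, 1.1, 1.2, 1.0), 4)
  comps <- c(
    list(list(center = c(0, 0, 0), radius = 0.2 * box, amplitude = 0.5)),
    lapply(seq_len(nrow(lobes)), function(i)
      list(center = lobes[i, ] * box, radius = radii[i],
           amplitude = amps[i])))
  list(smooth = 0.8, components = comps)
}

#' Variant phantom: the default phantom with one appended lobe
#'
#' @param box particle box size in voxels.
#' @return a descriptor list for [makePhantom()].
#' @export
variantPhantomDescriptor <- function(box) {
  d <- defaultPhantomDescriptor(box)
  d$components <- c(d$components, list(
    list(center = c(0, 0.26, 0) * box, radius = 0.14 * box,
         amplitude = 1.4)))
  d
}

#' Build a phantom volume from a descriptor
#'
#' Spheres (optionally anisotropic via `axes`) are rendered with
#' edge-supersampled coverage so the integral matches the analytic
#' component volumes, then band-limited with a Gaussian of s.d.
#' `descriptor$smooth` voxels (convolution preserves the integral). The
#' background is zero and the density positive.
#'
#' @param descriptor list with `smooth` (voxels) and `components`, each a
#'   list with `center` (voxels relative to the box centre), `radius`
#'   (voxels) and `amplitude`.
#' @param box box size in voxels (even).
#' @param pixelSize pixel size in Angstrom (metadata only).
#' @return a `box^3` array.
#' @export
makePhantom <- function(descriptor, box, pixelSize = 1) {
  if (box %% 2 != 0) stop("box must be even")
  vol <- array(0, c(box, box, box))
  ctr <- floor(c(box, box, box) / 2)
  ax <- seq_len(box) - 1
  for (comp in descriptor$components) {
    if (any(abs(comp$center) + comp$radius + 3 * descriptor$smooth > box / 2))
      stop("phantom component does not fit inside the box")
    cc <- ctr + comp$center
    dx <- ax - cc[1]; dy <- ax - cc[2]; dz <- ax - cc[3]
    r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
    r <- sqrt(r2)
    inside <- r <= comp$radius - 1
    edge <- which(abs(r - comp$radius) < 1, arr.ind = TRUE)
    vol[inside] <- vol[inside] + comp$amplitude
    if (nrow(edge) > 0) {
      ## 3^3 supersampled coverage of edge voxels
      off <- as.matrix(expand.grid(s = c(-1, 0, 1) / 3, t = c(-1, 0, 1) / 3,
                                   u = c(-1, 0, 1) / 3))
      pts <- edge - 1  # 0-based voxel coords
      cov <- numeric(nrow(edge))
      for (o in seq_len(nrow(off))) {
        d2 <- (pts[, 1] + off[o, 1] - cc[1])^2 +
              (pts[, 2] + off[o, 2] - cc[2])^2 +
              (pts[, 3] + off[o, 3] - cc[3])^2
        cov <- cov + (d2 <= comp$radius^2)
      }
      vol[edge] <- vol[edge] + comp$amplitude * cov / nrow(off)
    }
  }
  gaussianFilter(vol, descriptor$smooth)
}

#' One simulated tilt series with full ground truth
#'
#' @slot tiltImages x-y-T array of tilt images (signal + noise).
#' @slot geometry \linkS4class{TiltGeometry} (true values).
#' @slot particles \linkS4class{ParticleSet} (true poses).
#' @slot optics \linkS4class{CTFParams} optics constants.
#' @slot phantom,variant phantom volume(s).
#' @slot regions \linkS4class{RegionGrid} of true deformations, or NULL.
#' @slot spec the `SimulationSpec` used.
#' @slot noiseSd white-noise s.d. actually added.
#' @slot doseB per-tilt B factor (A^2).
#' @slot signal noiseless tilt images (array) or NULL.
#' @slot frames list (per tilt) of x-y-F frame stacks, possibly empty.
#' @slot frameShifts list (per tilt) of true F x 2 drift trajectories.
#' @slot variantLabels integer per-particle class labels (1-based), or
#'   zero-length when a single phantom was used.
#' @export
setClass("CetSimulation",
  representation(tiltImages = "array", geometry = "TiltGeometry",
    particles = "ParticleSet", optics = "CTFParams", phantom = "array",
    variant = "ANY", regions = "ANY", spec = "list", noiseSd = "numeric",
    doseB = "numeric", signal = "ANY", frames = "list",
    frameShifts = "list", variantLabels = "integer"))

setMethod("show", "CetSimulation", function(object) {
  d <- dim(object@tiltImages)
  cat(sprintf(
    "CetSimulation: %d x %d images, %d tilts, %d particles, SNR %s\n",
    d[1], d[2], d[3], nParticles(object@particles),
    format(object@spec$snr)))
})

#' Simulate a tilt series with known ground truth
#'
#' Projects every particle through the tilt geometry (via the same pose
#' composition used by refinement), applies the depth-dependent CTF, a
#' dose envelope `cos(beta) exp(-k^2 B(e)/4)` with `B(e)` linear in the
#' accumulated exposure `e`, and white Gaussian noise calibrated so the
#' requested SNR holds inside the particle boxes of the first-exposure
#' tilt. Optionally applies true per-region geometry perturbations and
#' simulates per-tilt video frames with drift.
#'
#' @param spec a `SimulationSpec` from [simulationSpec()].
#' @param regions optional \linkS4class{RegionGrid} of true per-region
#'   deformations to apply during projection.
#' @param particles optional \linkS4class{ParticleSet} of true poses to
#'   reuse (default: drawn randomly).
#' @param variantLabels optional integer labels (1/2) when two variants
#'   are simulated.
#' @param keepSignal keep the noiseless images in the result.
#' @return a \linkS4class{CetSimulation}.
#' @export
simulateTiltSeries <- function(spec, regions = NULL, particles = NULL,
                               variantLabels = NULL, keepSignal = TRUE) {
  set.seed(spec$seed)
  dims <- spec$tomogramDims
  box <- spec$boxSize
  ps <- spec$pixelSize
  tiltA <- spec$tiltAngles
  nT <- length(tiltA)
  jit <- if (spec$defocusJitter > 0) rnorm(nT, 0, spec$defocusJitter) else 0
  geom <- TiltGeometry(beta = tiltA, alpha = spec$tiltAxisAngle,
                       exposureOrder = spec$exposureOrder,
                       defocus1 = spec$defocus + jit,
                       defocus2 = spec$defocus + jit)
  optics <- CTFParams(df1 = spec$defocus, voltage = spec$voltage,
                      cs = spec$cs,
                      amplitudeContrast = spec$amplitudeContrast)
  phantom <- makePhantom(spec$phantom, box, ps)
  variant <- NULL
  if (!is.null(spec$phantomVariant))
    variant <- makePhantom(spec$phantomVariant, box, ps)
  phFT <- ftCentered(phantom)
  vaFT <- if (is.null(variant)) NULL else ftCentered(variant)

  if (is.null(particles))
    particles <- samplePoses(spec, geom)
  n <- nParticles(particles)
  if (is.null(variantLabels)) {
    variantLabels <- if (is.null(variant)) integer(0) else
      sample(rep(1:2, length.out = n))
  }
  ridx <- if (is.null(regions)) rep(1L, n) else
    particleRegions(particles, regions)
  checkOverlaps(particles, box)

  ord <- geom@exposureOrder
  doseB <- spec$bFactorRate * spec$dosePerTilt * (ord + 0.5)
  imgCtr <- floor(dims[1:2] / 2)
  g2 <- freqGrid2(box, ps)
  signal <- array(0, c(dims[1], dims[2], nT))
  sigPix <- NULL
  for (t in seq_len(nT)) {
    im <- matrix(0, dims[1], dims[2])
    env <- cos(deg2rad(geom@beta[t])) * exp(-g2$k^2 * doseB[t] / 4)
    for (p in seq_len(n)) {
      delta <- if (is.null(regions)) NULL else regionDelta(regions, ridx[p], t)
      pose <- composeProjectionPose(geom, t, particles@positions[p, ],
                                    particles@angles[p, ], dims, delta)
      posImg <- imgCtr + pose$shift
      cInt <- round(posImg)
      if (!boxInside(cInt, box, dims)) next
      resid <- posImg - cInt
      ctfP <- particleDefocus(
        tiltCtfParams(geom, t, optics,
                      if (is.null(regions)) NULL else regions, ridx[p]),
        pose$zDepth, ps)
      ctfM <- ctfEval(ctfP, g2$k, g2$azimuth)
      ft <- if (length(variantLabels) && variantLabels[p] == 2) vaFT else phFT
      sl <- cpp_slice_extract(ft, pose$rotation)
      patch <- iftCentered(sl * ctfM * env * shiftPhase(box, resid))
      im <- pasteBox(im, patch, cInt)
      if (t == which(ord == 0L)[1]) {
        x0 <- cInt[1] - box / 2; y0 <- cInt[2] - box / 2
        sigPix <- c(sigPix, im[(x0 + 1):(x0 + box), (y0 + 1):(y0 + box)])
      }
    }
    signal[, , t] <- im
  }
  noiseSd <- 0
  if (is.finite(spec$snr)) {
    varSig <- var(as.numeric(sigPix))
    noiseSd <- sqrt(varSig / spec$snr)
  }
  tiltImages <- signal
  if (noiseSd > 0)
    tiltImages <- tiltImages +
      array(rnorm(length(signal), 0, noiseSd), dim(signal))

  frames <- list(); frameShifts <- list()
  if (spec$framesPerTilt >= 2) {
    fr <- simulateFrames(spec, signal, noiseSd)
    frames <- fr$frames
    frameShifts <- fr$trajectories
  }
  new("CetSimulation", tiltImages = tiltImages, geometry = geom,
      particles = particles, optics = optics, phantom = phantom,
      variant = variant, regions = regions, spec = unclass(spec),
      noiseSd = noiseSd, doseB = doseB,
      signal = if (keepSignal) signal else NULL, frames = frames,
      frameShifts = frameShifts, variantLabels = as.integer(variantLabels))
}

## Rejection-sample particle poses whose projected centres keep the full
## box inside every tilt image.
samplePoses <- function(spec, geom) {
  dims <- spec$tomogramDims
  box <- spec$boxSize
  imgCtr <- floor(dims[1:2] / 2)
  rts <- lapply(seq_len(nTilts(geom)),
                function(t) tiltRotation(geom@alpha[t], geom@beta[t]))
  ctr3 <- floor(dims / 2)
  pos <- matrix(0, spec$nParticles, 3)
  ang <- matrix(0, spec$nParticles, 3)
  minSp <- if (is.null(spec$minSpacing)) 0 else spec$minSpacing
  for (p in seq_len(spec$nParticles)) {
    for (try in 1:2000) {
      cand <- runif(3, box / 2 + 2, dims - box / 2 - 2)
      ok <- all(vapply(seq_along(rts), function(t) {
        q <- rts[[t]] %*% (cand - ctr3)
        c2 <- round(imgCtr + q[1:2] +
                    c(geom@shiftX[t], geom@shiftY[t]))
        boxInside(c2, box, dims)
      }, TRUE))
      if (ok && minSp > 0 && p > 1) {
        dd <- sqrt(rowSums((pos[seq_len(p - 1), , drop = FALSE] -
                            matrix(cand, p - 1, 3, byrow = TRUE))^2))
        ok <- all(dd >= minSp)
      }
      if (ok) break
    }
    if (!ok) stop("could not place particle inside all tilt images")
    pos[p, ] <- cand
    ang[p, ] <- c(runif(1, -180, 180), rad2deg(acos(runif(1, -1, 1))),
                  runif(1, -180, 180))
  }
  ParticleSet(pos, ang)
}

checkOverlaps <- function(particles, box, maxFraction = 0.5) {
  pos <- particlePositions(particles)
  n <- nrow(pos)
  if (n < 2) return(invisible())
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  frac <- mean(apply(d, 1, min) < box / 2)
  if (frac > maxFraction)
    warning(sprintf("%.0f%% of particles overlap within half a box",
                    100 * frac))
  invisible()
}

#' Simulate per-tilt video frames with drift
#'
#' Each frame holds `1/F` of the tilt signal, shifted by the true
#' per-frame trajectory (linear drift plus a random walk, relative to
#' frame 1) and attenuated by the within-tilt dose accumulated up to
#' that frame (B-factor increments relative to the tilt mean, so the
#' frame average keeps the tilt image statistics), plus white noise
#' scaled so the frame sum matches the tilt image noise.
#'
#' @param spec a `SimulationSpec` with `framesPerTilt >= 2`.
#' @param signalImages noiseless tilt images (x-y-T array).
#' @param noiseSd white-noise s.d. of the integrated tilt image.
#' @return list with `frames` (per tilt, x-y-F arrays) and
#'   `trajectories` (per tilt, F x 2 true shifts in pixels).
#' @export
simulateFrames <- function(spec, signalImages, noiseSd) {
  fN <- spec$framesPerTilt
  if (fN < 2) stop("framesPerTilt must be >= 2")
  nT <- dim(signalImages)[3]
  d <- dim(signalImages)[1:2]
  ## centred |k| grid (1/Angstrom) for the full (possibly non-square)
  ## tilt image
  kx <- matrix((seq_len(d[1]) - d[1] / 2 - 1) / (d[1] * spec$pixelSize),
               d[1], d[2])
  ky <- matrix((seq_len(d[2]) - d[2] / 2 - 1) / (d[2] * spec$pixelSize),
               d[1], d[2], byrow = TRUE)
  k2 <- kx^2 + ky^2
  frames <- vector("list", nT)
  trajectories <- vector("list", nT)
  for (t in seq_len(nT)) {
    traj <- matrix(0, fN, 2)
    for (f in 2:fN)
      traj[f, ] <- traj[f - 1, ] + spec$frameDrift +
        rnorm(2, 0, spec$frameRandomWalk)
    stack <- array(0, c(d[1], d[2], fN))
    sigFT <- ftCentered(signalImages[, , t])
    for (f in seq_len(fN)) {
      ## within-tilt dose: B-factor increment relative to the tilt mean
      dB <- spec$bFactorRate * spec$dosePerTilt * ((f - 0.5) / fN - 0.5)
      ph <- exp(-2i * pi * (kx * traj[f, 1] * spec$pixelSize +
                            ky * traj[f, 2] * spec$pixelSize))
      sf <- iftCentered(sigFT * exp(-k2 * dB / 4) * ph)
      stack[, , f] <- sf / fN +
        if (noiseSd > 0) matrix(rnorm(prod(d), 0, noiseSd / sqrt(fN)),
                                d[1], d[2]) else 0
    }
    frames[[t]] <- stack
    trajectories[[t]] <- traj
  }
  list(frames = frames, trajectories = trajectories)
}

#' Synthetic tomogram for particle-picking tests
#'
#' Dense (dark) spheres at random non-overlapping positions, optional
#' high-density contamination blobs, and white Gaussian noise at a
#' controlled SNR (signal variance inside the sphere regions over noise
#' variance). Density convention: dense objects are negative.
#'
#' @param dims tomogram dimensions in voxels.
#' @param nParticles number of particle spheres.
#' @param radius particle radius in voxels.
#' @param snr signal-to-noise variance ratio; `Inf` disables noise.
#' @param nContamination number of large contamination blobs.
#' @param contaminationRadius blob radius in voxels.
#' @param seed RNG seed.
#' @return list with `tomogram`, `centers` (n x 3, 0-based),
#'   `contamination` (m x 3).
#' @export
simulatePickingTomogram <- function(dims = c(160, 160, 96),
                                    nParticles = 30, radius = 8,
                                    snr = 0.5, nContamination = 2,
                                    contaminationRadius = 18, seed = 1) {
  set.seed(seed)
  vol <- array(0, dims)
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - 1)
  addSphere <- function(vol, c0, r, amp) {
    r2 <- outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, `+`),
                (ax[[3]] - c0[3])^2, `+`)
    vol[r2 <= r^2] <- vol[r2 <= r^2] + amp
    vol
  }
  margin <- 2 * radius + 2
  placed <- matrix(numeric(0), 0, 3)
  blobs <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nContamination)) {
    c0 <- runif(3, contaminationRadius + 2, dims - contaminationRadius - 2)
    blobs <- rbind(blobs, c0)
    vol <- addSphere(vol, c0, contaminationRadius, -3)
  }
  for (i in seq_len(nParticles)) {
    for (try in 1:2000) {
      c0 <- runif(3, margin, dims - margin)
      ok <- TRUE
      if (nrow(placed) > 0)
        ok <- all(sqrt(rowSums((placed - matrix(c0, nrow(placed), 3,
                                                byrow = TRUE))^2)) >
                  2.5 * radius)
      if (ok && nrow(blobs) > 0)
        ok <- all(sqrt(rowSums((blobs - matrix(c0, nrow(blobs), 3,
                                               byrow = TRUE))^2)) >
                  contaminationRadius + 2 * radius)
      if (ok) break
    }
    if (!ok) stop("could not place picking sphere")
    placed <- rbind(placed, c0)
    vol <- addSphere(vol, c0, radius, -1)
  }
  vol <- gaussianFilter(vol, 1)
  if (is.finite(snr)) {
    ## signal variance measured over the particle bounding boxes
    sig <- NULL
    for (i in seq_len(nrow(placed))) {
      c0 <- round(placed[i, ]); hw <- radius + 2
      sig <- c(sig, vol[(c0[1] - hw):(c0[1] + hw) + 1,
                        (c0[2] - hw):(c0[2] + hw) + 1,
                        (c0[3] - hw):(c0[3] + hw) + 1])
    }
    noiseSd <- sqrt(var(as.numeric(sig)) / snr)
    vol <- vol + array(rnorm(length(vol), 0, noiseSd), dims)
  }
  list(tomogram = vol, centers = placed, contamination = blobs)
}
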