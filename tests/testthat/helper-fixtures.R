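## Shared fixtures, built lazily and cached for the whole test run so
## expensive simulations are computed once.

.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureEnv[[name]]))
    .fixtureEnv[[name]] <- builder()
  .fixtureEnv[[name]]
}

## small clean simulation: isolated particles, no noise, no dose
cleanSim <- function() fixture("cleanSim", function() {
  spec <- simulationSpec(tomogramDims = c(160, 160, 80), boxSize = 32,
                         nParticles = 4, snr = Inf, dosePerTilt = 0,
                         bFactorRate = 0, seed = 7,
                         tiltAngles = seq(-60, 60, by = 6))
  simulateTiltSeries(spec)
})

## one isolated particle, no noise, no dose (exact-match tests)
singleSim <- function() fixture("singleSim", function() {
  spec <- simulationSpec(tomogramDims = c(160, 160, 80), boxSize = 32,
                         nParticles = 1, snr = Inf, dosePerTilt = 0,
                         bFactorRate = 0, seed = 3,
                         tiltAngles = seq(-60, 60, by = 6))
  simulateTiltSeries(spec)
})

## small noisy simulation at the standard SNR
noisySim <- function() fixture("noisySim", function() {
  spec <- simulationSpec(tomogramDims = c(160, 160, 80), boxSize = 32,
                         nParticles = 4, snr = 0.5, seed = 8,
                         tiltAngles = seq(-60, 60, by = 6))
  simulateTiltSeries(spec)
})

## geodesic angle between two Euler triplets (degrees)
angularError <- function(a, b) {
  R <- eulerToMatrix(a) %*% t(eulerToMatrix(b))
  tr <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  acos(tr) * 180 / pi
}

## rotate a pose by a random rotation of the given geodesic angle
perturbAngles <- function(angles, degrees) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  a <- degrees * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
              3, 3)
  Rp <- diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  matrixToEuler(Rp %*% eulerToMatrix(angles))
}

perturbParticles <- function(particles, angleDeg, shiftVox, seed = 1) {
  set.seed(seed)
  out <- particles
  for (p in seq_len(nParticles(particles))) {
    out@angles[p, ] <- perturbAngles(particles@angles[p, ], angleDeg)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    out@positions[p, ] <- particles@positions[p, ] + shiftVox * d
  }
  out
}

## the standard pose-recovery benchmark: 64-box phantom, 41 tilts
## -60..60 x 3 deg, SNR 0.5, 50 particles, fixed seed; poses perturbed
## by 5 degrees / 3 voxels and refined under full constraints
poseBenchmark <- function() fixture("poseBenchmark", function() {
  spec <- simulationSpec(nParticles = 50, seed = 101)
  sim <- simulateTiltSeries(spec, keepSignal = FALSE)
  pert <- perturbParticles(sim@particles, 5, 3, seed = 11)
  refined <- refineFullyConstrained(sim, pert, sim@phantom,
                                    searchLimits = list(angle = 8,
                                                        shift = 5),
                                    sweeps = 1)
  ## keep only the pose tables; the raw images are large
  list(true = sim@particles, perturbed = pert, refined = refined)
})

## 40 undeformed particles for region-level (CTF) recovery tests
regionSim <- function() fixture("regionSim", function() {
  spec <- simulationSpec(tomogramDims = c(256, 256, 128),
                         nParticles = 40, snr = 0.5, seed = 31)
  simulateTiltSeries(spec)
})

## CTF benchmark: a 1,000 A defocus error injected on one region's
## starting metadata, recovered by region-based CTF refinement
ctfBenchmark <- function() fixture("ctfBenchmark", function() {
  sim <- regionSim()
  rg <- RegionGrid(c(2, 2, 1), sim@spec$tomogramDims,
                   nTilts(sim@geometry))
  rg@deltaDf1[2] <- 1000; rg@deltaDf2[2] <- 1000
  ref <- reconstruct(sim, sim@particles, halfMaps = FALSE)$map
  res <- refineRegionCtf(sim, sim@particles, ref, rg, tolerance = 2000,
                         minParticles = 5, band = c(20, 5))
  list(injected = 1000, refined = res)
})

## deformation benchmark: injected smooth per-region shift field
## (max 4 px), grid 2 x 2 x 1, recovered by iterated region-based
## refinement with the reference rebuilt between passes
deformBenchmark <- function() fixture("deformBenchmark", function() {
  spec <- simulationSpec(tomogramDims = c(256, 256, 128),
                         nParticles = 40, snr = 0.5, seed = 21)
  grid <- c(2, 2, 1)
  nT <- length(spec$tiltAngles)
  truth <- RegionGrid(grid, spec$tomogramDims, nT)
  set.seed(99)
  tprof <- sin(seq(0, pi, length.out = nT))
  for (g in 1:4) {
    amp <- runif(2, 1.5, 4) * sample(c(-1, 1), 2, replace = TRUE)
    truth@deltaShiftX[g, ] <- amp[1] * tprof
    truth@deltaShiftY[g, ] <- amp[2] * tprof
  }
  sim <- simulateTiltSeries(spec, regions = truth)
  recGlobal <- reconstruct(sim, sim@particles)
  est <- RegionGrid(grid, spec$tomogramDims, nT)
  res <- refineRegionGeometry(sim, sim@particles, recGlobal$map, est,
                              searchLimits = list(shift = 5, angle = 0),
                              minParticles = 5, band = c(20, 6))
  ## iterate with a rebuilt reference until the deltas settle
  for (i in 1:4) {
    prev <- cbind(res$regions@deltaShiftX, res$regions@deltaShiftY)
    ref <- reconstruct(sim, sim@particles, regions = res$regions,
                       halfMaps = FALSE)$map
    res <- refineRegionGeometry(sim, sim@particles, ref, res$regions,
                                searchLimits = list(shift = 5, angle = 0),
                                minParticles = 5, band = c(20, 6))
    move <- sqrt(mean((cbind(res$regions@deltaShiftX,
                             res$regions@deltaShiftY) - prev)^2))
    if (move < 0.1) break
  }
  recRegion <- reconstruct(sim, sim@particles, regions = res$regions)
  list(truth = truth, refined = res,
       fscGlobal = fsc(recGlobal$half1, recGlobal$half2,
                       spec$pixelSize),
       fscRegion = fsc(recRegion$half1, recRegion$half2,
                       spec$pixelSize))
})

## small two-variant mixture for determinism/occupancy tests
classificationSmall <- function() fixture("classificationSmall", function() {
  spec <- simulationSpec(tomogramDims = c(256, 256, 64), boxSize = 32,
                         nParticles = 30, snr = 0.2, seed = 43,
                         tiltAngles = seq(-60, 60, by = 12),
                         twoVariants = TRUE, minSpacing = 16)
  list(sim = simulateTiltSeries(spec))
})

## the standard classification benchmark: 300 + 300 particles of two
## phantom variants at SNR 0.2, full tilt range, no-alignment mode;
## paired constrained / unconstrained runs with the same seeds
classificationBenchmark <- function() fixture("classificationBenchmark",
                                              function() {
  spec <- simulationSpec(tomogramDims = c(1040, 1040, 96), boxSize = 32,
                         nParticles = 600, snr = 0.2, seed = 41,
                         twoVariants = TRUE, minSpacing = 16)
  sim <- simulateTiltSeries(spec, keepSignal = FALSE)
  labels <- sim@variantLabels
  runOne <- function(constrained) {
    m <- classifyConstrained(sim, sim@particles, K = 2, nIter = 30,
                             seed = 5, constrained = constrained)
    lab <- classAssignments(m)
    tab <- table(factor(lab, 1:2), factor(labels, 1:2))
    acc <- max(sum(diag(tab)), tab[1, 2] + tab[2, 1]) / sum(tab)
    h <- m@history[[length(m@history)]]
    projLab <- max.col(h$projOcc, ties.method = "first")
    pa <- mean(projLab == labels[h$particleOf])
    list(acc = acc, projAcc = max(pa, 1 - pa), iters = m@iterations)
  }
  cons <- runOne(TRUE)
  unc <- runOne(FALSE)
  list(accConstrained = cons$acc, itersConstrained = cons$iters,
       projAccConstrained = cons$projAcc,
       accUnconstrained = unc$acc, projAccUnconstrained = unc$projAcc)
})

## frame benchmark: per-tilt videos with linear drift + random walk;
## trajectories refined and exposure weights derived from frame scores
frameBenchmark <- function() fixture("frameBenchmark", function() {
  spec <- simulationSpec(tomogramDims = c(192, 192, 64), boxSize = 32,
                         nParticles = 12, snr = 0.5, seed = 51,
                         tiltAngles = seq(-30, 30, by = 6),
                         framesPerTilt = 8, frameDrift = c(0.2, 0.1),
                         frameRandomWalk = 0.05)
  sim <- simulateTiltSeries(spec)
  fr <- refineTrajectories(sim, sim@particles, sim@phantom, window = 3,
                           maxShift = 3)
  ## per-tilt exposure weights from the mean frame scores
  tiltScores <- rowMeans(fr$frameScores, na.rm = TRUE)
  g <- freqGrid2(spec$boxSize, spec$pixelSize)
  w <- exposureWeights(tiltScores, g$k)
  recU <- reconstruct(sim, sim@particles)
  recW <- reconstruct(sim, sim@particles, weights = w)
  list(sim = sim, fr = fr,
       fscUnweighted = fsc(recU$half1, recU$half2, spec$pixelSize),
       fscWeighted = fsc(recW$half1, recW$half2, spec$pixelSize))
})

## the standard picking benchmark: 30 dense spheres, SNR 0.5, two
## contamination blobs, fixed seed
pickingBenchmark <- function() fixture("pickingBenchmark", function() {
  bm <- simulatePickingTomogram(dims = c(160, 160, 96), nParticles = 30,
                                radius = 8, snr = 0.5,
                                nContamination = 2, seed = 7)
  mask <- contaminationMask(bm$tomogram, dilationRadius = 5)
  picks <- pickSizeBased(bm$tomogram, particleRadius = 16, pixelSize = 2,
                         mask = mask)
  list(bm = bm, mask = mask, picks = picks)
})

pickF1 <- function(picks, centers, tolRadius) {
  pos <- particlePositions(picks)
  if (nrow(pos) == 0) return(0)
  used <- rep(FALSE, nrow(centers))
  tp <- 0
  for (i in seq_len(nrow(pos))) {
    d <- sqrt(rowSums((centers - matrix(pos[i, ], nrow(centers), 3,
                                        byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] <= tolRadius && !used[j]) { tp <- tp + 1; used[j] <- TRUE }
  }
  prec <- tp / nrow(pos); rec <- tp / nrow(centers)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
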