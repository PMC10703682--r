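test_that("phantoms are positive, asymmetric and integral-correct", {
  desc <- defaultPhantomDescriptor(32)
  ph <- makePhantom(desc, 32)
  expect_gt(min(ph), -1e-3 * max(ph))   # non-negative up to FFT ringing
  ## integral equals the analytic component volumes within 1%
  analytic <- sum(vapply(desc$components, function(cc)
    cc$amplitude * 4 / 3 * pi * cc$radius^3, 0))
  expect_lt(abs(sum(ph) - analytic) / analytic, 0.01)
  ## a single centred sphere is radially symmetric about the box centre
  sp <- makePhantom(list(smooth = 1, components = list(
    list(center = c(0, 0, 0), radius = 6, amplitude = 1))), 32)
  com <- colSums(which(sp > 0, arr.ind = TRUE) * sp[sp > 0]) / sum(sp)
  expect_equal(as.numeric(com), rep(17, 3), tolerance = 1e-3)
  expect_equal(sp, aperm(sp, c(2, 1, 3)), tolerance = 1e-10)
  ## oversized component rejected
  expect_error(makePhantom(list(smooth = 1, components = list(
    list(center = c(10, 0, 0), radius = 10, amplitude = 1))), 32),
    "fit")
})

test_that("the two-variant phantom differs only inside the lobe", {
  a <- makePhantom(defaultPhantomDescriptor(32), 32)
  b <- makePhantom(variantPhantomDescriptor(32), 32)
  diff <- b - a
  lobe <- variantPhantomDescriptor(32)$components
  lobe <- lobe[[length(lobe)]]
  ctr <- floor(c(32, 32, 32) / 2) + lobe$center
  ax <- seq_len(32) - 1
  r <- sqrt(outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, `+`),
                  (ax - ctr[3])^2, `+`))
  outside <- r > lobe$radius + 4    # lobe plus smoothing support
  expect_lt(max(abs(diff[outside])), 1e-3 * max(diff))
  expect_gt(max(diff), 0.5)
})

test_that("simulation is deterministic and reaches the requested SNR", {
  spec <- simulationSpec(tomogramDims = c(128, 128, 64), boxSize = 32,
                         nParticles = 2, snr = 0.5, seed = 5,
                         tiltAngles = seq(-30, 30, by = 15))
  s1 <- simulateTiltSeries(spec)
  s2 <- simulateTiltSeries(spec)
  expect_identical(s1@tiltImages, s2@tiltImages)
  expect_identical(s1@particles@positions, s2@particles@positions)
  ## SNR: variance ratio of signal boxes vs pure-noise area on the
  ## first-exposure tilt, averaged over seeds
  ratios <- vapply(1:12, function(sd_) {
    sp <- simulationSpec(tomogramDims = c(128, 128, 64), boxSize = 32,
                         nParticles = 1, snr = 0.5, seed = 100 + sd_,
                         tiltAngles = c(-15, 0, 15))
    sim <- simulateTiltSeries(sp)
    t0 <- which(sim@geometry@exposureOrder == 0)
    sig <- sim@signal[, , t0]
    noisy <- sim@tiltImages[, , t0]
    ## signal measured inside the particle box, noise in an empty area
    box <- 32
    pose <- composeProjectionPose(sim@geometry, t0,
                                  sim@particles@positions[1, ],
                                  sim@particles@angles[1, ],
                                  sp$tomogramDims)
    cInt <- round(floor(sp$tomogramDims[1:2] / 2) + pose$shift)
    bs <- sig[(cInt[1] - 15):(cInt[1] + 16), (cInt[2] - 15):(cInt[2] + 16)]
    emptySel <- abs(sig) == 0
    var(as.numeric(bs)) / var(noisy[emptySel])
  }, 0)
  expect_gt(mean(ratios), 0.42)
  expect_lt(mean(ratios), 0.58)
})

test_that("noiseless image power obeys Parseval across paste/crop", {
  sim <- singleSim()
  spec <- sim@spec
  ## single particle: total image power equals the inserted patch power
  for (t in c(1, 11)) {
    im <- sim@tiltImages[, , t]
    pose <- composeProjectionPose(sim@geometry, t,
                                  sim@particles@positions[1, ],
                                  sim@particles@angles[1, ],
                                  spec$tomogramDims)
    imgCtr <- floor(spec$tomogramDims[1:2] / 2)
    cInt <- round(imgCtr + pose$shift)
    box <- spec$boxSize
    crop <- im[(cInt[1] - box / 2 + 1):(cInt[1] + box / 2),
               (cInt[2] - box / 2 + 1):(cInt[2] + box / 2)]
    expect_equal(sum(im^2), sum(crop^2), tolerance = 1e-6)
  }
})

test_that("dose model attenuates signal monotonically with exposure", {
  ## a spherically symmetric phantom so every view has identical
  ## content and only dose/thickness modulate the amplitude
  spec <- simulationSpec(tomogramDims = c(128, 128, 64), boxSize = 32,
                         nParticles = 1, snr = Inf, seed = 6,
                         dosePerTilt = 3, bFactorRate = 2,
                         phantom = list(smooth = 1, components = list(
                           list(center = c(0, 0, 0), radius = 8,
                                amplitude = 1))),
                         tiltAngles = seq(-60, 60, by = 6))
  ## particle at the tomogram centre so the depth-dependent defocus is
  ## identical across tilts and only the dose envelope varies
  centred <- ParticleSet(matrix(c(64, 64, 32), 1), matrix(0, 1, 3))
  sim <- simulateTiltSeries(spec, particles = centred)
  amp <- vapply(seq_len(dim(sim@signal)[3]),
                function(t) sd(as.numeric(sim@signal[, , t])), 0)
  ord <- order(sim@geometry@exposureOrder)
  expect_true(all(diff(amp[ord]) <= 1e-9))
})

test_that("frames carry the drift trajectory and conserve statistics", {
  spec <- simulationSpec(tomogramDims = c(96, 96, 48), boxSize = 32,
                         nParticles = 1, snr = Inf, seed = 12,
                         dosePerTilt = 0, bFactorRate = 0,
                         tiltAngles = c(0), framesPerTilt = 4,
                         frameDrift = c(0, 0), frameRandomWalk = 0)
  sim <- simulateTiltSeries(spec)
  st <- sim@frames[[1]]
  ## zero drift: all frames share the signal; the frame sum restores
  ## the tilt image
  expect_equal(st[, , 1], st[, , 4], tolerance = 1e-10)
  total <- apply(st, c(1, 2), sum)
  expect_equal(total, sim@signal[, , 1], tolerance = 1e-10)
  ## frame signal power sums to the tilt-image power
  expect_equal(sum(vapply(1:4, function(f) sum(st[, , f]^2), 0)),
               sum(sim@signal[, , 1]^2) / 4, tolerance = 1e-6)
})

test_that("random-walk drift grows like the square root of time", {
  spec <- simulationSpec(tomogramDims = c(64, 64, 32), boxSize = 16,
                         nParticles = 1, snr = Inf, seed = 1,
                         dosePerTilt = 0, bFactorRate = 0,
                         tiltAngles = 0, framesPerTilt = 9,
                         frameDrift = c(0, 0), frameRandomWalk = 0.5)
  ## accumulate the squared displacement over many seeds
  msd <- matrix(0, 100, 9)
  for (s in 1:100) {
    sp <- spec; sp$seed <- s
    sim <- suppressWarnings(simulateTiltSeries(sp))
    tr <- sim@frameShifts[[1]]
    msd[s, ] <- rowSums(tr^2)
  }
  m <- colMeans(msd)
  ## E|x_f|^2 = 2 sigma^2 (f - 1) in 2D
  expected <- 2 * 0.5^2 * (0:8)
  expect_lt(max(abs(m[-1] - expected[-1]) / expected[-1]), 0.35)
  ## sqrt growth: displacement ratio frame 9 vs frame 3 ~ 2
  expect_equal(sqrt(m[9] / m[3]), 2, tolerance = 0.25)
})
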