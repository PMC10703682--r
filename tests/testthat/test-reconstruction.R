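test_that("full-coverage noiseless projections rebuild the phantom", {
  ph <- makePhantom(defaultPhantomDescriptor(32), 32)
  set.seed(1)
  m <- 80
  imgs <- vector("list", m); rots <- vector("list", m)
  for (i in 1:m) {
    a <- c(runif(1, -180, 180), acos(runif(1, -1, 1)) * 180 / pi,
           runif(1, -180, 180))
    rots[[i]] <- eulerToMatrix(a)
    ## ideal contrast (CTF = -1): fidelity limited by gridding only
    imgs[[i]] <- -projectVolume(ph, rotation = rots[[i]])
  }
  pr <- fourierInsert(imgs, rots)
  map <- reconstructionMap(pr)
  expect_gt(cor(as.numeric(map), as.numeric(ph)), 0.99)
})

test_that("the missing wedge stays empty and merging is linear", {
  ## identity orientations: all insertion planes share the tomogram
  ## frame, leaving the classic +-60 degree missing wedge
  spec <- simulationSpec(tomogramDims = c(128, 128, 64), boxSize = 32,
                         nParticles = 2, snr = Inf, seed = 9,
                         dosePerTilt = 0, bFactorRate = 0,
                         tiltAngles = seq(-60, 60, by = 6))
  ident <- ParticleSet(rbind(c(40, 40, 32), c(88, 88, 32)),
                       matrix(0, 2, 3))
  simw <- simulateTiltSeries(spec, particles = ident)
  recw <- reconstruct(simw, ident, halfMaps = FALSE)
  F <- ftCentered(recw$map)
  ## direction of the beam at extreme tilt: the un-sampled wedge around
  ## the z axis beyond the +-60 degree tilt range
  n <- dim(F)[1]
  h <- seq_len(n) - n / 2 - 1
  kx <- array(h, c(n, n, n))
  kz <- aperm(kx, c(3, 2, 1))
  r <- sqrt(kx^2 + aperm(kx, c(2, 1, 3))^2 + kz^2)
  ## distance to the nearest sampled central plane; stay beyond the
  ## trilinear spread of every inserted slice
  dmin <- array(Inf, dim(kx))
  for (b in seq(-60, 60, by = 6) * pi / 180)
    dmin <- pmin(dmin, abs(kx * sin(b) + kz * cos(b)))
  wedge <- dmin > 2 & r < n / 2 - 1
  expect_gt(sum(wedge), 1000)             # the wedge is a real region
  expect_lt(max(Mod(F[wedge])), 1e-6 * max(Mod(F)))
  ## linearity: reconstruct(A united B) == merge(reconstruct parts)
  sim <- cleanSim()
  prA <- partialReconstruction(sim, sim@particles, 1:2)
  prB <- partialReconstruction(sim, sim@particles, 3:4)
  prAll <- partialReconstruction(sim, sim@particles, 1:4)
  merged <- mergeBundles(list(prA, prB))
  expect_equal(merged@num, prAll@num, tolerance = 1e-10)
  expect_equal(merged@den, prAll@den, tolerance = 1e-10)
})

test_that("bundle merging is commutative, associative and normalising", {
  sim <- cleanSim()
  parts <- lapply(1:4, function(p)
    partialReconstruction(sim, sim@particles, p))
  ## merge of one equals its own normalisation
  expect_equal(reconstructionMap(mergeBundles(parts[1])),
               reconstructionMap(parts[[1]]))
  ## any permutation gives the identical map
  m1 <- reconstructionMap(mergeBundles(parts))
  for (perm in list(c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    m2 <- reconstructionMap(mergeBundles(parts[perm]))
    expect_lt(max(abs(m1 - m2)), 1e-10 * max(abs(m1)))
  }
  ## fine vs coarse bundling
  half1 <- mergeBundles(parts[1:2]); half2 <- mergeBundles(parts[3:4])
  expect_equal(reconstructionMap(mergeBundles(list(half1, half2))), m1,
               tolerance = 1e-10)
  expect_error(mergeBundles(list(parts[[1]],
    new("PartialReconstruction", num = array(0 + 0i, c(16, 16, 16)),
        den = array(0, c(16, 16, 16)), count = 0L, halfSet = 0L))),
    "dimensions")
})

test_that("FSC behaves on identical, independent and noisy maps", {
  set.seed(2)
  n <- 32
  v <- array(rnorm(n^3), c(n, n, n))
  f <- fsc(v, v, pixelSize = 2)
  expect_true(all(abs(f$fsc - 1) < 1e-10))
  expect_equal(f$resolution, 4)            # Nyquist at 2 A pixels
  ## independent white noise: |FSC| within the null band almost always
  a <- array(rnorm(n^3), c(n, n, n)); b <- array(rnorm(n^3), c(n, n, n))
  f2 <- fsc(a, b, pixelSize = 2)
  lim <- 3 / sqrt(f2$shellSize / 2)
  expect_gt(mean(abs(f2$fsc) < lim), 0.9)
  ## half maps with known spectrally-flat SNR: FSC ~ SNR / (1 + SNR)
  ph <- makePhantom(defaultPhantomDescriptor(32), 32)
  sig <- sd(as.numeric(ph))
  ratios <- NULL
  for (s in 1:3) {
    na <- ph + array(rnorm(n^3, 0, sig), c(n, n, n))
    nb <- ph + array(rnorm(n^3, 0, sig), c(n, n, n))
    f3 <- fsc(na, nb, pixelSize = 2)
    ## per-shell expectation: SSNR / (1 + SSNR) with the signal spectrum
    ## measured from the phantom and E|F_noise|^2 = sigma^2 N
    pf <- ftCentered(ph)
    h <- seq_len(n) - n / 2 - 1
    shell <- round(sqrt(outer(outer(h^2, h^2, `+`), h^2, `+`)))
    keep <- shell >= 1 & shell <= n / 2 - 1
    psig <- tapply(Mod(pf[keep])^2, shell[keep], mean)
    snrShell <- psig / (sig^2 * n^3)
    expected <- snrShell / (1 + snrShell)
    ratios <- rbind(ratios, f3$fsc - expected)
  }
  expect_lt(mean(abs(ratios)), 0.12)
})

test_that("exposure weights are normalised and score-monotone", {
  k <- seq(0, 0.25, by = 0.005)
  ## equal scores: uniform weights
  w <- exposureWeights(rep(0.4, 5), k)
  for (u in 1:5) expect_equal(w[[u]], rep(0.2, length(k)))
  ## normalisation at every frequency
  s <- c(0.5, 0.42, 0.3, 0.21)
  w2 <- exposureWeights(s, k)
  expect_equal(Reduce(`+`, w2), rep(1, length(k)), tolerance = 1e-12)
  ## better-scoring unit dominates, strictly at high frequency
  expect_true(all(w2[[1]] - w2[[4]] >= -1e-12))
  expect_gt(w2[[1]][length(k)], w2[[4]][length(k)])
  expect_equal(w2[[1]][1], w2[[4]][1], tolerance = 1e-9)  # equal at DC
})

test_that("dose weighting does not hurt resolution on attenuated data", {
  sim <- regionSim()
  ps <- sim@spec$pixelSize
  rec0 <- reconstruct(sim, sim@particles)
  f0 <- fsc(rec0$half1, rec0$half2, ps)
  ## per-tilt weights from the per-tilt mean projection scores
  scores <- perTiltScores(sim, sim@particles, sim@phantom)
  g <- freqGrid2(sim@spec$boxSize, ps)
  w <- exposureWeights(scores, g$k)
  rec1 <- reconstruct(sim, sim@particles, weights = w)
  f1 <- fsc(rec1$half1, rec1$half2, ps)
  expect_lte(f1$resolution, f0$resolution + 1e-9)
})
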