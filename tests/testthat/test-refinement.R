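test_that("the projection score is exact on self-matches and null on noise", {
  sim <- singleSim()
  spec <- sim@spec
  box <- spec$boxSize; ps <- spec$pixelSize
  dims <- spec$tomogramDims
  imgCtr <- floor(dims[1:2] / 2)
  refFT <- ftCentered(sim@phantom)
  for (t in c(1, 11, 21)) {
    pose <- composeProjectionPose(sim@geometry, t,
                                  sim@particles@positions[1, ],
                                  sim@particles@angles[1, ], dims)
    cInt <- round(imgCtr + pose$shift)
    crop <- cropBox(sim@tiltImages[, , t], cInt, box)
    ctfP <- particleDefocus(CTFParams(df1 = sim@geometry@defocus1[t]),
                            pose$zDepth, ps)
    ctfM <- ctfMatrix(ctfP, box, ps)
    d <- scoreProjection(crop, refFT, pose$rotation,
                         imgCtr + pose$shift - cInt, ctfM, ps)
    expect_gt(d, 0.999)
    ## scale and offset invariance
    d2 <- scoreProjection(3.7 * crop + 11, refFT, pose$rotation,
                          imgCtr + pose$shift - cInt, ctfM, ps)
    expect_equal(d2, d, tolerance = 1e-9)
    ## the shift theorem: shifting image and model together is neutral
    sh <- shiftImage(crop, c(5, -3))
    d3 <- scoreProjection(sh, refFT, pose$rotation,
                          imgCtr + pose$shift - cInt + c(5, -3), ctfM,
                          ps)
    expect_equal(d3, d, tolerance = 1e-3)
  }
  ## pure-noise null distribution
  idx <- bandIndices(box, ps, Inf, 2 * ps)
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    noise <- matrix(rnorm(box^2), box, box)
    pose <- composeProjectionPose(sim@geometry, 1,
                                  sim@particles@positions[1, ],
                                  sim@particles@angles[1, ], dims)
    d <- scoreProjection(noise, refFT, pose$rotation, c(0, 0),
                         ctfMatrix(CTFParams(), box, ps), ps)
    abs(d) < 3 / sqrt(nrow(idx))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  expect_error(bandIndices(box, ps, 4.5, 4.6), "empty")
})

test_that("global search recovers grid poses, faster with a normal prior", {
  sim <- cleanSim()
  true <- sim@particles
  ## snap the first particle's angles onto a 10-degree grid
  snapped <- true
  snapped@angles[1, ] <- c(40, 60, -30)
  simg <- simulateTiltSeries(sim@spec, particles = snapped)
  start <- snapped
  start@angles[1, ] <- c(0, 90, 0)       # forget the orientation
  res <- globalSearch(simg, start, simg@phantom, angularStep = 10,
                      thetaRange = c(20, 60), phiRange = c(40, 80),
                      psiRange = c(-50, -10), pIdx = 1)
  expect_equal(res$particles@angles[1, ], c(40, 60, -30),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## normal prior: same pose from a single in-plane sweep, far fewer
  ## evaluations
  nv <- eulerToMatrix(c(40, 60, -30)) %*% c(0, 0, 1)
  resN <- globalSearch(simg, start, simg@phantom, angularStep = 10,
                       psiRange = c(-50, -10), normals = t(nv) [rep(1, 4), ],
                       pIdx = 1)
  expect_lt(angularError(resN$particles@angles[1, ], c(40, 60, -30)), 1e-6)
  expect_gte(res$evaluations[1] / resN$evaluations[1], 10)
})

test_that("constrained refinement recovers perturbed poses at SNR 0.5", {
  bm <- poseBenchmark()
  e0 <- vapply(seq_len(nParticles(bm$true)), function(p)
    angularError(bm$perturbed@angles[p, ], bm$true@angles[p, ]), 0)
  e1 <- vapply(seq_len(nParticles(bm$true)), function(p)
    angularError(bm$refined@angles[p, ], bm$true@angles[p, ]), 0)
  s1 <- sqrt(rowSums((bm$refined@positions - bm$true@positions)^2))
  expect_equal(median(e0), 5, tolerance = 0.01)
  expect_lt(median(e1), 1)
  expect_lt(median(s1), 0.5)
})

test_that("refinement honours degenerate limits and fixed points", {
  sim <- noisySim()
  ## zero search limits: poses unchanged exactly
  out0 <- refineFullyConstrained(sim, sim@particles, sim@phantom,
                                 searchLimits = list(angle = 0,
                                                     shift = 0))
  expect_identical(out0@positions, sim@particles@positions)
  expect_identical(out0@angles, sim@particles@angles)
  ## starting at the truth on clean data: the pose barely moves
  simc <- singleSim()
  out1 <- refineFullyConstrained(simc, simc@particles, simc@phantom,
                                 searchLimits = list(angle = 2,
                                                     shift = 1),
                                 sweeps = 1, pIdx = 1)
  expect_lt(angularError(out1@angles[1, ], simc@particles@angles[1, ]),
            0.5)
  expect_lt(sqrt(sum((out1@positions[1, ] -
                      simc@particles@positions[1, ])^2)), 0.25)
})

test_that("region geometry refinement recovers an injected deformation", {
  bm <- deformBenchmark()
  ex <- bm$refined$regions@deltaShiftX - bm$truth@deltaShiftX
  ey <- bm$refined$regions@deltaShiftY - bm$truth@deltaShiftY
  expect_lt(sqrt(mean(c(ex^2, ey^2))), 0.5)
  expect_gte(bm$refined$score, bm$refined$score0)
  ## region-based refinement improves the FSC resolution over the
  ## global-only reconstruction of the deformed data
  expect_lt(bm$fscRegion$resolution, bm$fscGlobal$resolution)
})

test_that("region refinement guards sparse regions with a warning", {
  sim <- noisySim()   # 4 particles
  rg <- RegionGrid(c(2, 2, 1), sim@spec$tomogramDims,
                   nTilts(sim@geometry))
  w <- capture_warnings(
    res <- refineRegionGeometry(sim, sim@particles, sim@phantom, rg,
                                minParticles = 5,
                                searchLimits = list(shift = 3,
                                                    angle = 0)))
  expect_true(any(grepl("particles", w)))
  expect_equal(res$regions@deltaShiftX, rg@deltaShiftX)
})

test_that("per-tilt mean scores follow the dose bell shape", {
  sim <- regionSim()
  sc <- perTiltScores(sim, sim@particles, sim@phantom)
  ord <- order(abs(sim@geometry@beta))
  ## low tilts (least exposure) score best; extremes worst
  expect_gt(mean(sc[ord[1:5]]), mean(sc[ord[37:41]]))
  expect_gt(cor(-abs(sim@geometry@beta), sc), 0.7)
})
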