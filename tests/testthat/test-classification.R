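test_that("projection occupancies are a standardised softmax", {
  ## degenerate cases
  expect_equal(projectionOccupancies(matrix(rnorm(5), 5, 1), 0, 1),
               matrix(1, 5, 1))
  eq <- projectionOccupancies(matrix(0.3, 4, 3), 0.3, 0.1)
  expect_equal(eq, matrix(1 / 3, 4, 3))
  expect_error(projectionOccupancies(matrix(0, 2, 0), 0, 1), "class")
  ## hand-built 3-class table against an independently coded softmax
  set.seed(7)
  s <- matrix(rnorm(30, 0.2, 0.05), 10, 3)
  gm <- 0.21; gs <- 0.04
  occ <- projectionOccupancies(s, gm, gs)
  oracle <- t(apply(s, 1, function(r) {
    e <- exp((r - gm) / gs)
    e / sum(e)
  }))
  expect_equal(occ, oracle, tolerance = 1e-12)
  expect_equal(rowSums(occ), rep(1, 10))
  ## invariant to a joint affine rescaling (mean/sd transform jointly)
  occ2 <- projectionOccupancies(2 * s + 1, 2 * gm + 1, 2 * gs)
  expect_equal(occ2, occ, tolerance = 1e-12)
})

test_that("particle occupancies follow the Gaussian tilt weighting", {
  ## all projections agree: particle occupancy is a point mass
  po <- matrix(rep(c(0, 1), each = 3), 3, 2)
  out <- particleOccupancies(po, rep(1, 3), c(-3, 0, 3), 1)
  expect_equal(out, matrix(c(0, 1), 1, 2))
  ## conflicting hard assignments: the zero-tilt projection wins by
  ## exp(0) / exp(-60^2 / 72)
  po2 <- rbind(c(1, 0), c(0, 1))
  out2 <- particleOccupancies(po2, c(1, 1), c(0, 60), 1, sigmaTilt = 6)
  expect_gt(out2[1, 1], 1 - 1e-10)
  ## infinite sigma: plain unweighted mean
  out3 <- particleOccupancies(po2, c(1, 1), c(0, 60), 1,
                              sigmaTilt = Inf)
  expect_equal(out3, matrix(0.5, 1, 2))
  ## occupancy conservation across particles
  set.seed(1)
  po4 <- projectionOccupancies(matrix(rnorm(60), 20, 3), 0, 1)
  out4 <- particleOccupancies(po4, rep(1:5, 4), rep(c(-6, 0, 6, 12), 5),
                              5)
  expect_equal(rowSums(out4), rep(1, 5))
})

test_that("single-class classification reproduces the consensus map", {
  sim <- cleanSim()
  model <- classifyConstrained(sim, sim@particles, K = 1, nIter = 1,
                               seed = 3)
  expect_equal(occupancies(model), matrix(1, 4, 1))
  consensus <- reconstruct(sim, sim@particles, halfMaps = FALSE)$map
  expect_equal(classReferences(model)[[1]], consensus,
               tolerance = 1e-10)
})

test_that("classification is reproducible and conserves occupancy", {
  sim <- classificationSmall()$sim
  m1 <- classifyConstrained(sim, sim@particles, K = 2, nIter = 4,
                            seed = 11)
  m2 <- classifyConstrained(sim, sim@particles, K = 2, nIter = 4,
                            seed = 11)
  expect_identical(occupancies(m1), occupancies(m2))
  occ <- occupancies(m1)
  expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-9)
  expect_equal(sum(classPopulations(m1)), nrow(occ), tolerance = 1e-9)
})

test_that("focused masks and with-alignment mode produce valid models", {
  sim <- classificationSmall()$sim
  ## focused scoring restricted to the variant-lobe region
  mf <- classifyConstrained(sim, sim@particles, K = 2, nIter = 3,
                            seed = 11, focusCenter = c(0, 8, 0),
                            focusRadius = 16)
  occ <- occupancies(mf)
  expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-9)
  ## bounded re-alignment between iterations keeps occupancies valid
  ma <- classifyConstrained(sim, sim@particles, K = 2, nIter = 2,
                            seed = 11, mode = "with-alignment",
                            alignLimits = list(angle = 1, shift = 0.5))
  expect_equal(rowSums(occupancies(ma)), rep(1, nrow(occ)),
               tolerance = 1e-9)
  expect_equal(length(classReferences(ma)), 2)
})

test_that("constrained classification separates a two-variant mixture", {
  cb <- classificationBenchmark()
  expect_gte(cb$accConstrained, 0.95)
  expect_lte(cb$itersConstrained, 30)
  ## the unconstrained run assigns projections independently; its
  ## per-projection assignments are strictly worse than the constrained
  ## per-particle (= per-projection, by construction) assignments
  expect_lt(cb$projAccUnconstrained, cb$accConstrained)
})
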