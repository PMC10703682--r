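test_that("contamination masking finds dense blobs and little else", {
  ## all-zero tomogram: empty mask
  expect_false(any(contaminationMask(array(0, c(48, 48, 32)))))
  ## pure Gaussian noise: tiny masked fraction after morphology
  fracs <- vapply(1:3, function(s) {
    set.seed(s)
    m <- contaminationMask(array(rnorm(64 * 64 * 48), c(64, 64, 48)),
                           dilationRadius = 2)
    mean(m)
  }, 0)
  expect_lt(mean(fracs), 0.01)
  ## one dense sphere: mask covers it plus the dilation shell
  dims <- c(64, 64, 48)
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - 1)
  r2 <- outer(outer((ax[[1]] - 32)^2, (ax[[2]] - 30)^2, `+`),
              (ax[[3]] - 24)^2, `+`)
  vol <- array(0, dims)
  vol[r2 <= 10^2] <- -5
  m <- contaminationMask(vol, dilationRadius = 5, minVoxels = 50)
  inside <- r2 <= 10^2
  shell <- r2 <= 14^2 & r2 > 10^2     # within the dilation reach
  expect_true(all(m[inside]))
  expect_gt(mean(m[shell]), 0.9)
})

test_that("size-based picking finds dense spheres and respects the mask", {
  set.seed(2)
  dims <- c(128, 128, 64)
  ax <- lapply(1:3, function(a) seq_len(dims[a]) - 1)
  vol <- array(0, dims)
  centers <- NULL
  for (i in 1:20) {
    repeat {
      c0 <- runif(3, 14, dims - 14)
      if (is.null(centers) ||
          min(sqrt(rowSums((centers - matrix(c0, nrow(centers), 3,
                                             byrow = TRUE))^2))) > 22)
        break
    }
    centers <- rbind(centers, c0)
    r2 <- outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2, `+`),
                (ax[[3]] - c0[3])^2, `+`)
    vol[r2 <= 25] <- -1
  }
  picks <- pickSizeBased(vol, particleRadius = 10, pixelSize = 2)
  pos <- particlePositions(picks)
  expect_equal(nrow(pos), 20)
  for (i in seq_len(nrow(pos))) {
    d <- sqrt(rowSums((centers - matrix(pos[i, ], 20, 3, byrow = TRUE))^2))
    expect_lt(min(d), 2)
  }
  ## a pick inside a contamination mask is excluded
  mask <- array(FALSE, dims)
  c1 <- round(centers[1, ])
  mask[(c1[1] - 8):(c1[1] + 8) + 1, (c1[2] - 8):(c1[2] + 8) + 1,
       (c1[3] - 8):(c1[3] + 8) + 1] <- TRUE
  picks2 <- pickSizeBased(vol, particleRadius = 10, pixelSize = 2,
                          mask = mask)
  expect_equal(nrow(particlePositions(picks2)), 19)
  ## empty tomogram: zero picks
  expect_equal(nrow(particlePositions(
    pickSizeBased(array(0, c(64, 64, 32)), 10, 2))), 0)
})

test_that("the picker meets F1 >= 0.9 on the contaminated benchmark", {
  pb <- pickingBenchmark()
  f1 <- pickF1(pb$picks, pb$bm$centers, tolRadius = 8)
  expect_gte(f1, 0.9)
})

test_that("spherical Hough voting detects shells with correct radii", {
  d <- c(100, 100, 100)
  ax <- lapply(1:3, function(a) seq_len(d[a]) - 1)
  shell <- function(c0, r) {
    rr <- sqrt(outer(outer((ax[[1]] - c0[1])^2, (ax[[2]] - c0[2])^2,
                           `+`), (ax[[3]] - c0[3])^2, `+`))
    v <- array(0, d); v[abs(rr - r) <= 1] <- -1; v
  }
  one <- detectSpheres(shell(c(48, 52, 50), 30), c(20, 40),
                       radiusStep = 2)
  expect_equal(length(one$radii), 1)
  expect_lt(max(abs(one$centers[1, ] - c(48, 52, 50))), 2)
  expect_lte(abs(one$radii[1] - 30), 2)
  two <- detectSpheres(shell(c(35, 35, 40), 25) + shell(c(70, 68, 60), 35),
                       c(20, 40), radiusStep = 2)
  expect_equal(length(two$radii), 2)
  ord <- order(two$centers[, 1])
  expect_lt(two$radii[ord[1]], two$radii[ord[2]])   # radius ordering
  ## pure noise: no detections in most seeds
  hits <- vapply(1:5, function(s) {
    set.seed(s)
    length(detectSpheres(array(rnorm(50^3), c(50, 50, 50)), c(15, 25),
                         radiusStep = 5)$radii)
  }, 0)
  expect_gte(mean(hits == 0), 0.8)
})

test_that("surface sampling is uniform with outward unit normals", {
  ps <- 2
  for (r in c(20, 40)) {
    sp <- 15
    set <- sampleSurface(c(50, 50, 50), r, sp, ps)
    n <- nrow(particlePositions(set))
    expect_lt(abs(n - 4 * pi * (r * ps)^2 / sp^2) /
              (4 * pi * (r * ps)^2 / sp^2), 0.1)
    nor <- pickNormals(set)
    expect_equal(sqrt(rowSums(nor^2)), rep(1, n), tolerance = 1e-6)
    rel <- particlePositions(set) - matrix(c(50, 50, 50), n, 3,
                                           byrow = TRUE)
    expect_true(all(rowSums(nor * rel) > 0))
  }
  ## hemispheric spacing: at most a handful of points
  big <- sampleSurface(c(0, 0, 0), 10, pi * 10 * 2, 2)
  expect_lte(nrow(particlePositions(big)), 4)
})

test_that("particle cleaning thresholds scores and removes duplicates", {
  set.seed(4)
  ## well-separated two-Gaussian score mixture: auto threshold splits it
  scores <- c(rnorm(40, 0.1, 0.02), rnorm(60, 0.5, 0.03))
  pos <- cbind(runif(100, 0, 500), runif(100, 0, 500), runif(100, 0, 100))
  parts <- ParticleSet(pos, score = scores)
  out <- cleanParticles(parts, "auto", minDistance = 0)
  expect_equal(sort(out@particleId), 41:100)
  ## unimodal scores: warning and no filtering
  uni <- ParticleSet(pos, score = rnorm(100, 0.3, 0.03))
  expect_warning(keep <- cleanParticles(uni, "auto"), "bimodal")
  expect_equal(nParticles(keep), 100)
  ## duplicate removal keeps the higher-scoring member
  two <- ParticleSet(rbind(c(10, 10, 10), c(10, 11, 10)),
                     score = c(0.2, 0.9))
  expect_equal(cleanParticles(two, NULL, minDistance = 10)@score, 0.9)
  expect_equal(nParticles(cleanParticles(two, NULL, minDistance = 0)), 2)
  ## idempotence (the survivors are unimodal, so the second auto pass
  ## warns and leaves the set untouched)
  once <- cleanParticles(parts, "auto", minDistance = 25)
  twice <- suppressWarnings(cleanParticles(once, "auto",
                                           minDistance = 25))
  expect_equal(once@particleId, twice@particleId)
})
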