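test_that("Euler matrices are proper rotations and round-trip", {
  set.seed(1)
  maxErr <- 0
  for (i in 1:10000) {
    a <- c(runif(1, -180, 179.99), runif(1, 0, 180),
           runif(1, -180, 179.99))
    R <- eulerToMatrix(a)
    expect_equal(det(R), 1, tolerance = 1e-12)
    b <- matrixToEuler(R)
    maxErr <- max(maxErr, max(abs(eulerToMatrix(b) - R)))
  }
  expect_lt(maxErr, 1e-9 * pi / 180)   # < 1e-9 degrees in matrix terms
})

test_that("gimbal-locked orientations canonicalise with psi = 0", {
  expect_equal(eulerToMatrix(c(0, 0, 0)), diag(3))
  ## at phi = 0 the z-rotations merge: (90,0,0) and (0,0,90) coincide
  expect_equal(eulerToMatrix(c(90, 0, 0)), eulerToMatrix(c(0, 0, 90)))
  a <- matrixToEuler(eulerToMatrix(c(30, 0, 40)))
  expect_equal(a[3], 0)
  expect_equal(a[1], 70)
  b <- matrixToEuler(eulerToMatrix(c(30, 180, 40)))
  expect_equal(b[3], 0)
  expect_equal(eulerToMatrix(b), eulerToMatrix(c(30, 180, 40)),
               tolerance = 1e-12)
})

test_that("zero-tilt pose composition projects positions directly", {
  tg <- TiltGeometry(beta = 0, alpha = 0)
  dims <- c(256, 256, 128)
  pp <- composeProjectionPose(tg, 1, c(138, 124, 71), c(0, 0, 0), dims)
  expect_equal(pp$shift, c(10, -4))
  expect_equal(pp$angles, c(0, 0, 0))
  ## on-axis particle: shift zero for any tilt-axis angle at beta = 0
  for (al in c(0, 37.3, -120)) {
    tg2 <- TiltGeometry(beta = 0, alpha = al)
    for (z in c(-40, 0, 33)) {
      pp2 <- composeProjectionPose(tg2, 1, c(128, 128, 64 + z),
                                   c(0, 0, 0), dims)
      expect_equal(pp2$shift, c(0, 0), tolerance = 1e-12)
    }
  }
})

test_that("pose composition matches a brute-force rotation-matrix oracle", {
  ## independent oracle: explicit matrix products, written against the
  ## documented convention
  oracle <- function(alpha, beta, sx, sy, pos, ang, dims) {
    d2r <- function(x) x * pi / 180
    Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
    Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
    Rt <- Rz(d2r(alpha)) %*% Ry(d2r(beta)) %*% Rz(d2r(-alpha))
    Rp <- Rz(d2r(ang[1])) %*% Ry(d2r(ang[2])) %*% Rz(d2r(ang[3]))
    p <- Rt %*% (pos - floor(dims / 2))
    list(shift = c(p[1] + sx, p[2] + sy), rot = Rt %*% Rp, z = p[3])
  }
  set.seed(42)
  dims <- c(512, 512, 256)
  for (i in 1:10000) {
    alpha <- runif(1, -180, 180 - 1e-9)
    beta <- runif(1, -90, 90 - 1e-9)
    sx <- runif(1, -20, 20); sy <- runif(1, -20, 20)
    pos <- runif(3, 0, dims)
    ang <- c(runif(1, -180, 179.9), runif(1, 0, 180),
             runif(1, -180, 179.9))
    tg <- TiltGeometry(beta = beta, alpha = alpha, shiftX = sx,
                       shiftY = sy)
    pp <- composeProjectionPose(tg, 1, pos, ang, dims)
    oc <- oracle(alpha, beta, sx, sy, pos, ang, dims)
    expect_lt(max(abs(pp$shift - oc$shift)), 1e-10)
    expect_lt(max(abs(pp$rotation - oc$rot)), 1e-10)
    expect_lt(abs(pp$zDepth - oc$z), 1e-10)
  }
  ## the worked case from the module contract
  tg <- TiltGeometry(beta = 30, alpha = 85.3)
  pp <- composeProjectionPose(tg, 1, floor(dims / 2) + c(12, 8, -5),
                              c(20, 40, 60), dims)
  oc <- oracle(85.3, 30, 0, 0, floor(dims / 2) + c(12, 8, -5),
               c(20, 40, 60), dims)
  expect_lt(max(abs(pp$rotation - oc$rot)), 1e-10)
  expect_lt(max(abs(eulerToMatrix(pp$angles) - oc$rot)), 1e-10)
})

test_that("region assignment partitions the tomogram", {
  dims <- c(512, 512, 256)
  grid <- c(4, 4, 2)
  expect_equal(prod(grid), 32)
  ## tomogram centre falls in the upper cell (half-open convention)
  idx <- assignRegions(matrix(dims / 2, 1), grid, dims)
  expect_equal(idx, 1L + 2L + 4L * 2L + 16L * 1L)
  set.seed(3)
  pos <- matrix(runif(3000, 0, rep(dims, each = 1000)), ncol = 3)
  idx <- assignRegions(pos, grid, dims)
  expect_equal(length(idx), 1000)
  expect_true(all(idx >= 1 & idx <= 32))
  counts <- tabulate(idx, 32)
  expect_equal(sum(counts), 1000)
  ## multinomial sampling error: each cell ~ 1000/32 +- 5 sd
  expect_true(all(abs(counts - 1000 / 32) <
                  5 * sqrt(1000 * (1 / 32) * (31 / 32))))
  expect_error(assignRegions(matrix(c(-1, 0, 0), 1), grid, dims),
               "outside")
})

test_that("projection poses reproduce simulated tilt images", {
  sim <- singleSim()
  spec <- sim@spec
  dims <- spec$tomogramDims
  box <- spec$boxSize
  imgCtr <- floor(dims[1:2] / 2)
  for (t in c(1, 6, 11, 21)) {
    p <- 1
    pose <- composeProjectionPose(sim@geometry, t,
                                  sim@particles@positions[p, ],
                                  sim@particles@angles[p, ], dims)
    cInt <- round(imgCtr + pose$shift)
    crop <- sim@tiltImages[(cInt[1] - box / 2 + 1):(cInt[1] + box / 2),
                           (cInt[2] - box / 2 + 1):(cInt[2] + box / 2), t]
    ctfP <- particleDefocus(CTFParams(df1 = sim@geometry@defocus1[t],
                                      df2 = sim@geometry@defocus2[t]),
                            pose$zDepth, spec$pixelSize)
    model <- projectVolume(sim@phantom, rotation = pose$rotation,
                           shift = imgCtr + pose$shift - cInt,
                           ctf = ctfMatrix(ctfP, box, spec$pixelSize))
    expect_gt(cor(as.numeric(crop), as.numeric(model)), 0.999)
  }
})

test_that("an in-plane rotation rotates the zero-tilt projection", {
  ## under the ZYZ convention used here the FIRST Euler angle is the
  ## in-plane (beam-axis) rotation of a zero-tilt projection
  ph <- makePhantom(defaultPhantomDescriptor(32), 32)
  base <- projectVolume(ph, c(25, 70, 10))
  rot90 <- projectVolume(ph, c(115, 70, 10))   # theta + 90 degrees
  n <- 32; c0 <- n / 2          # 0-based centre index
  ## 90-degree rotations map the lattice onto itself: compare interior
  ## pixels through the index map (u, v) -> (-v, u)
  err <- 0
  for (x in 2:(n - 1)) for (y in 2:(n - 1)) {
    u <- x - 1 - c0; v <- y - 1 - c0
    xr <- -v + c0 + 1; yr <- u + c0 + 1
    if (xr >= 1 && xr <= n && yr >= 1 && yr <= n)
      err <- max(err, abs(rot90[xr, yr] - base[x, y]))
  }
  expect_lt(err / max(abs(base)), 1e-3)
})

test_that("tilt geometry validity catches malformed inputs", {
  expect_error(TiltGeometry(beta = c(0, 95)), "beta")
  expect_error(TiltGeometry(beta = c(0, 3), tiltIndex = c(1, 1)),
               "unique")
  expect_error(TiltGeometry(beta = c(0, 3),
                            exposureOrder = c(0L, 2L)),
               "permutation")
  expect_silent(TiltGeometry(beta = seq(-60, 60, 3)))
})
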