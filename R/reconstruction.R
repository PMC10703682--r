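## Direct Fourier-inversion reconstruction from 2D particle projections:
## each projection's CTF-multiplied transform is inserted as a central
## slice (trilinear gridding) into a complex numerator, CTF^2 into a real
## denominator, and the map is numerator / (denominator + Wiener
## constant). Partial (bundle-wise) reconstructions merge by addition, so
## the result is independent of bundle size and processing order.

#' Project a volume at a given orientation (central-slice reprojection)
#'
#' Extracts the central slice of the volume transform at the given
#' orientation, optionally multiplies a CTF/envelope and applies a
#' subpixel shift, and returns the real-space projection image.
#'
#' @param volume real volume array (or its centred transform when
#'   `isFT = TRUE`).
#' @param angles Euler triplet `(theta, phi, psi)` degrees, or supply
#'   `rotation` directly.
#' @param rotation 3 x 3 rotation matrix (overrides `angles`).
#' @param shift length-2 shift in pixels (content moves by `+shift`).
#' @param ctf optional n x n filter (CTF and/or envelope) applied in
#'   Fourier space.
#' @param isFT `volume` is already a centred Fourier transform.
#' @return n x n real projection image.
#' @export
projectVolume <- function(volume, angles = NULL, rotation = NULL,
                          shift = c(0, 0), ctf = NULL, isFT = FALSE) {
  vf <- if (isFT) volume else ftCentered(volume)
  if (is.null(rotation)) rotation <- eulerToMatrix(angles)
  sl <- cpp_slice_extract(vf, rotation)
  if (!is.null(ctf)) sl <- sl * ctf
  n <- nrow(sl)
  if (any(shift != 0)) sl <- sl * shiftPhase(n, shift)
  iftCentered(sl)
}

#' Insert projection images into a Fourier accumulator
#'
#' The projection-level reconstruction primitive: each image's
#' CTF-multiplied transform is gridded (trilinear) as a central slice at
#' its orientation into the numerator and CTF^2 into the denominator.
#'
#' @param images list of n x n real projection images.
#' @param rotations list of 3 x 3 rotation matrices (or a 3 x 3 x m
#'   array).
#' @param shifts m x 2 matrix of in-image particle shifts (pixels);
#'   insertion re-centres the particle.
#' @param ctfs list of n x n CTF matrices (or one matrix recycled).
#' @param weights optional list of n x n frequency-weight matrices (or
#'   one matrix recycled).
#' @param scal optional per-image scalar weights (e.g. occupancies).
#' @param halfSet half-set id recorded in the result.
#' @return a \linkS4class{PartialReconstruction}.
#' @export
fourierInsert <- function(images, rotations, shifts = NULL, ctfs = NULL,
                          weights = NULL, scal = NULL, halfSet = 0L) {
  m <- length(images)
  n <- nrow(images[[1]])
  if (is.array(rotations) && length(dim(rotations)) == 3)
    rotations <- lapply(seq_len(dim(rotations)[3]),
                        function(i) rotations[, , i])
  if (is.null(shifts)) shifts <- matrix(0, m, 2)
  if (is.null(ctfs)) ctfs <- matrix(-1, n, n)
  if (is.matrix(ctfs)) ctfs <- rep(list(ctfs), m)
  if (is.null(weights)) weights <- matrix(1, n, n)
  if (is.matrix(weights)) weights <- rep(list(weights), m)
  if (is.null(scal)) scal <- rep(1, m)
  imfts <- lapply(images, ftCentered)
  rots <- array(unlist(rotations), c(3, 3, m))
  acc <- cpp_insert_slices(n, imfts, rots, as.matrix(shifts), ctfs,
                           weights, scal)
  new("PartialReconstruction", num = acc$num, den = acc$den,
      count = as.integer(m), halfSet = as.integer(halfSet))
}

#' Build a partial reconstruction from a subset of particles
#'
#' @param sim a \linkS4class{CetSimulation}.
#' @param particles \linkS4class{ParticleSet} with current poses.
#' @param pIdx particle indices to insert (default all).
#' @param regions optional \linkS4class{RegionGrid} of geometry/CTF
#'   corrections.
#' @param weights optional per-tilt frequency weights: a list (length =
#'   tilts used) of box x box matrices, e.g. from [exposureWeights()].
#' @param occupancy optional per-particle scalar insertion weights.
#' @param tilts tilt indices to insert (default all).
#' @param halfSet half-set id recorded in the result (0 = combined).
#' @return a \linkS4class{PartialReconstruction}.
#' @export
partialReconstruction <- function(sim, particles, pIdx = NULL,
                                  regions = NULL, weights = NULL,
                                  occupancy = NULL, tilts = NULL,
                                  halfSet = 0L) {
  box <- sim@spec$boxSize
  geom <- sim@geometry
  if (is.null(pIdx)) pIdx <- seq_len(nParticles(particles))
  if (is.null(tilts)) tilts <- seq_len(nTilts(geom))
  if (is.null(occupancy)) occupancy <- rep(1, nParticles(particles))
  dims <- sim@spec$tomogramDims
  imgCtr <- floor(dims[1:2] / 2)
  ridx <- if (is.null(regions)) NULL else particleRegions(particles, regions)
  ones <- matrix(1, box, box)
  num <- NULL; den <- NULL; total <- 0L
  ## particles are processed in chunks so crop transforms never
  ## accumulate in memory
  chunks <- split(pIdx, ceiling(seq_along(pIdx) / 20))
  for (chunk in chunks) {
    crops <- extractCrops(sim, particles, chunk, tilts, regions)
    imfts <- list(); ctfs <- list(); wts <- list(); rotList <- list()
    shifts <- NULL; scal <- NULL
    k <- 0
    for (i in seq_along(chunk)) {
      p <- chunk[i]
      for (j in seq_along(tilts)) {
        cp <- crops[[i]][[j]]
        if (is.null(cp)) next
        t <- cp$tilt
        delta <- if (is.null(regions)) NULL else
          regionDelta(regions, ridx[p], t)
        pose <- composeProjectionPose(geom, t, particles@positions[p, ],
                                      particles@angles[p, ], dims, delta)
        resid <- imgCtr + pose$shift - cp$centerInt
        k <- k + 1
        imfts[[k]] <- cp$ft
        ctfs[[k]] <- cp$ctf
        wts[[k]] <- if (is.null(weights)) ones else weights[[j]]
        rotList[[k]] <- pose$rotation
        shifts <- rbind(shifts, resid)
        scal <- c(scal, occupancy[p])
      }
    }
    if (k == 0) next
    rots <- array(unlist(rotList), c(3, 3, k))
    acc <- cpp_insert_slices(box, imfts, rots, shifts, ctfs, wts, scal)
    if (is.null(num)) { num <- acc$num; den <- acc$den } else {
      num <- num + acc$num; den <- den + acc$den
    }
    total <- total + as.integer(k)
  }
  if (total == 0L) stop("no projections to insert")
  new("PartialReconstruction", num = num, den = den,
      count = total, halfSet = as.integer(halfSet))
}

#' Merge partial reconstructions
#'
#' Voxel-wise sum of numerators and denominators; commutative and
#' associative, so any bundle split or processing order yields the same
#' merged result.
#'
#' @param partials list of \linkS4class{PartialReconstruction} with equal
#'   box sizes.
#' @return a merged \linkS4class{PartialReconstruction}.
#' @export
mergeBundles <- function(partials) {
  stopifnot(length(partials) >= 1)
  d <- dim(partials[[1]]@num)
  num <- array(0 + 0i, d); den <- array(0, d); count <- 0L
  for (pr in partials) {
    if (!all(dim(pr@num) == d)) stop("mismatched reconstruction dimensions")
    num <- num + pr@num
    den <- den + pr@den
    count <- count + pr@count
  }
  new("PartialReconstruction", num = num, den = den, count = count,
      halfSet = 0L)
}

#' Normalise an accumulated reconstruction into a real-space map
#'
#' `map = IFT(num / (den + wiener * mean(den)))`.
#'
#' @param partial a \linkS4class{PartialReconstruction}.
#' @param wiener Wiener constant as a fraction of the mean denominator.
#' @return real volume array.
#' @export
reconstructionMap <- function(partial, wiener = 0.01) {
  w <- wiener * mean(partial@den)
  if (w <= 0) w <- 1e-12
  iftCentered(partial@num / (partial@den + w))
}

#' Reconstruct half maps and a combined map
#'
#' Direct Fourier inversion of all particle projections, with half-sets
#' split by particle-id parity.
#'
#' @inheritParams partialReconstruction
#' @param wiener Wiener constant (fraction of mean denominator).
#' @param halfMaps also return per-half-set maps (requires both parities
#'   present).
#' @return list with `map`, and when `halfMaps` is TRUE `half1`, `half2`
#'   and the merged \linkS4class{PartialReconstruction} `partial`.
#' @export
reconstruct <- function(sim, particles, regions = NULL, weights = NULL,
                        occupancy = NULL, tilts = NULL, wiener = 0.01,
                        halfMaps = TRUE) {
  ids <- particles@particleId
  if (halfMaps) {
    h1 <- which(ids %% 2 == 0)
    h2 <- which(ids %% 2 == 1)
    if (length(h1) == 0 || length(h2) == 0)
      stop("a half-set is empty; cannot split by particle parity")
    p1 <- partialReconstruction(sim, particles, h1, regions, weights,
                                occupancy, tilts, halfSet = 1L)
    p2 <- partialReconstruction(sim, particles, h2, regions, weights,
                                occupancy, tilts, halfSet = 2L)
    merged <- mergeBundles(list(p1, p2))
    list(map = reconstructionMap(merged, wiener),
         half1 = reconstructionMap(p1, wiener),
         half2 = reconstructionMap(p2, wiener), partial = merged)
  } else {
    pr <- partialReconstruction(sim, particles, NULL, regions, weights,
                                occupancy, tilts)
    list(map = reconstructionMap(pr, wiener), partial = pr)
  }
}

#' Fourier shell correlation between two half maps
#'
#' Correlation per integer Fourier shell; the resolution is read at the
#' first crossing of the threshold (linear interpolation between shells).
#' Identical maps give FSC = 1 everywhere and resolution at Nyquist.
#'
#' @param half1,half2 real volumes of equal (even) dimensions.
#' @param pixelSize pixel size in Angstrom.
#' @param threshold FSC threshold (default 0.143).
#' @return list with `freq` (1/Angstrom), `fsc`, `shellSize` (voxels per
#'   shell) and `resolution` (Angstrom at the threshold crossing).
#' @export
fsc <- function(half1, half2, pixelSize, threshold = 0.143) {
  stopifnot(all(dim(half1) == dim(half2)))
  n <- dim(half1)[1]
  f1 <- ftCentered(half1); f2 <- ftCentered(half2)
  h <- seq_len(n) - n / 2 - 1
  r2 <- outer(outer(h^2, h^2, `+`), h^2, `+`)
  shell <- round(sqrt(r2))
  keep <- shell >= 1 & shell <= n / 2 - 1
  sh <- shell[keep]
  cross <- Re(f1[keep] * Conj(f2[keep]))
  p1 <- Mod(f1[keep])^2; p2 <- Mod(f2[keep])^2
  num <- tapply(cross, sh, sum)
  d1 <- tapply(p1, sh, sum); d2 <- tapply(p2, sh, sum)
  curve <- as.numeric(num / sqrt(d1 * d2))
  curve[!is.finite(curve)] <- 0
  radii <- as.numeric(names(num))
  freq <- radii / (n * pixelSize)
  res <- 2 * pixelSize  # Nyquist when never crossing
  below <- which(curve < threshold)
  if (length(below) > 0) {
    i <- below[1]
    if (i == 1) {
      res <- 1 / freq[1]
    } else {
      f0 <- freq[i - 1]; f1x <- freq[i]
      c0 <- curve[i - 1]; c1 <- curve[i]
      fx <- f0 + (c0 - threshold) / (c0 - c1) * (f1x - f0)
      res <- 1 / fx
    }
  }
  list(freq = freq, fsc = curve,
       shellSize = as.numeric(table(sh)), resolution = res)
}

#' Score-driven exposure weights
#'
#' Converts per-unit (frame or tilt) mean scores into frequency-dependent
#' weights `w_u(k) = exp(-k^2 / (4 b_u))`, normalised so the weights sum
#' to one across units at every frequency. The falloff parameter `b_u`
#' increases monotonically with the unit's standardised mean score, so
#' better-scoring units contribute more high-frequency signal. Equal
#' scores give uniform weights.
#'
#' @param scores per-unit mean scores (length = number of units).
#' @param k spatial frequencies in 1/Angstrom (vector or matrix).
#' @param b0 baseline falloff, Angstrom^2.
#' @param gain log-scale gain applied to the standardised score.
#' @return list (one element per unit) of arrays shaped like `k`.
#' @export
exposureWeights <- function(scores, k, b0 = 50, gain = 1) {
  stopifnot(length(scores) >= 1, all(is.finite(scores)))
  s <- sd(scores)
  z <- if (is.na(s) || s == 0) rep(0, length(scores)) else
    (scores - mean(scores)) / s
  b <- b0 * exp(gain * z)
  w <- lapply(b, function(bu) exp(-k^2 / (4 * bu)))
  tot <- Reduce(`+`, w)
  lapply(w, function(wu) wu / tot)
}
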