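## 3D particle detection in tomograms: contamination masking, size-based
## picking at local density extrema, spherical-surface detection by Hough
## voting, quasi-uniform surface sampling, and score/distance-based
## particle cleaning. Density convention: dense objects are dark
## (negative contrast), as in cryo-tomograms; `denseIsDark = FALSE`
## inverts.

#' High-contrast contamination mask
#'
#' High-pass filter, binarise at mean + 3 s.d. of the (contrast-corrected)
#' result, remove small connected components, fill holes, then dilate.
#'
#' @param tomogram 3D array.
#' @param dilationRadius dilation radius in voxels.
#' @param hpSigma Gaussian sigma (voxels) of the low-pass subtracted to
#'   form the high-pass (sets the largest feature scale kept).
#' @param lpSigma small smoothing sigma applied before thresholding
#'   (noise suppression; the pair forms a band-pass).
#' @param minVoxels connected components smaller than this are removed.
#' @param denseIsDark contamination is denser/darker than background.
#' @return logical array of the same dimensions.
#' @export
contaminationMask <- function(tomogram, dilationRadius = 5, hpSigma = 16,
                              lpSigma = 2, minVoxels = 100,
                              denseIsDark = TRUE) {
  hp <- gaussianFilter(tomogram, lpSigma) - gaussianFilter(tomogram, hpSigma)
  contrast <- if (denseIsDark) -hp else hp
  thr <- mean(contrast) + 3 * sd(as.numeric(contrast))
  mask <- contrast > thr
  if (!any(mask)) return(mask)
  labels <- cpp_label_components(mask, dim(mask))
  sizes <- tabulate(labels)
  keep <- which(sizes >= minVoxels)
  mask <- array(labels %in% keep, dim(mask))
  if (any(mask)) {
    ## fill holes: voxels not reachable from the border through background
    bg <- !mask
    lb <- cpp_label_components(bg, dim(bg))
    border <- unique(c(lb[1, , ], lb[dim(lb)[1], , ], lb[, 1, ],
                       lb[, dim(lb)[2], ], lb[, , 1], lb[, , dim(lb)[3]]))
    border <- setdiff(border, 0L)
    mask <- array(mask | (lb != 0 & !(lb %in% border)), dim(mask))
    if (dilationRadius > 0) mask <- dilateMask(mask, dilationRadius)
  }
  mask
}

## Sum over a spherical neighbourhood via FFT convolution.
ballSum <- function(vol, radius) {
  d <- dim(vol)
  ker <- array(0, d)
  ctr <- floor(d / 2)
  rng <- lapply(1:3, function(a) seq_len(d[a]) - 1 - ctr[a])
  r2 <- outer(outer(rng[[1]]^2, rng[[2]]^2, `+`), rng[[3]]^2, `+`)
  ker[r2 <= radius^2] <- 1
  Re(fft(fft(vol) * Conj(fft(fftshiftN(ker))), inverse = TRUE)) / prod(d)
}

## Binary dilation with a spherical structuring element.
dilateMask <- function(mask, radius) {
  array(ballSum(mask * 1, radius) > 0.5, dim(mask))
}

#' Size-based 3D particle picking
#'
#' Low-pass filters the tomogram to the particle size (Gaussian sigma =
#' radius/2 voxels), detects local density extrema (minima for dense
#' particles), discards peaks weaker than mean + `peakSd` s.d. of the
#' filtered contrast and peaks inside the contamination mask, then
#' enforces a minimum separation of one particle diameter (greedy, by
#' decreasing strength; ties broken lexicographically by position).
#' Deterministic given inputs.
#'
#' @param tomogram 3D array.
#' @param particleRadius particle radius in Angstrom.
#' @param pixelSize voxel size in Angstrom.
#' @param mask optional logical contamination mask (TRUE = excluded).
#' @param denseIsDark particles are dark (pick minima) or bright.
#' @param peakSd strength threshold in s.d. above the mean contrast.
#' @return a \linkS4class{PickSet} ordered by decreasing strength.
#' @export
pickSizeBased <- function(tomogram, particleRadius, pixelSize, mask = NULL,
                          denseIsDark = TRUE, peakSd = 2) {
  rvox <- particleRadius / pixelSize
  if (rvox <= 2) stop("particle radius must exceed 2 voxels")
  filt <- gaussianFilter(tomogram, rvox / 2)
  contrast <- if (denseIsDark) -filt else filt
  d <- dim(contrast)
  win <- max(1L, as.integer(round(rvox)))
  mx <- contrast
  for (a in 0:2) mx <- cpp_running_extreme(mx, d, win, a, TRUE)
  ## peak-strength statistics outside the contamination mask
  stat <- if (is.null(mask)) contrast else contrast[!mask]
  thr <- mean(stat) + peakSd * sd(as.numeric(stat))
  isPeak <- contrast == mx & contrast > thr
  ## exclude a border margin and masked voxels
  m <- ceiling(rvox)
  idx <- which(isPeak, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    inside <- idx[, 1] > m & idx[, 1] <= d[1] - m &
              idx[, 2] > m & idx[, 2] <= d[2] - m &
              idx[, 3] > m & idx[, 3] <= d[3] - m
    idx <- idx[inside, , drop = FALSE]
  }
  if (!is.null(mask) && nrow(idx) > 0)
    idx <- idx[!mask[idx], , drop = FALSE]
  if (nrow(idx) == 0)
    return(PickSet(matrix(numeric(0), 0, 3)))
  strength <- contrast[idx]
  ord <- order(-strength, idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]; strength <- strength[ord]
  ## greedy minimum separation of one diameter
  minSep <- 2 * rvox
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt(rowSums((idx[keep, , drop = FALSE] -
                        matrix(idx[i, ], sum(keep), 3,
                               byrow = TRUE))^2))
    keep[i] <- all(dd >= minSep)
  }
  PickSet(idx[keep, , drop = FALSE] - 1, strength[keep])  # 0-based coords
}

#' Sphere detection by 3D Hough voting
#'
#' Gradient-based spherical Hough transform: strong-gradient voxels vote
#' along both gradient directions at each candidate radius; accumulator
#' maxima above `minVotes` (a fraction of the ideal shell surface) are
#' returned with their radius, after non-maximum suppression at half the
#' minimum radius.
#'
#' @param tomogram 3D array.
#' @param radiusRange numeric `(min, max)` radius in voxels.
#' @param radiusStep radius sampling step, voxels.
#' @param gradientSd gradient-magnitude selection threshold (s.d. above
#'   mean).
#' @param minVotes detection threshold as a fraction of `4 pi r^2`.
#' @return list with `centers` (m x 3, 0-based voxels), `radii`, `votes`.
#' @export
detectSpheres <- function(tomogram, radiusRange, radiusStep = 1,
                          gradientSd = 2, minVotes = 0.1) {
  d <- dim(tomogram)
  sm <- gaussianFilter(tomogram, 1)
  gx <- (shiftArr(sm, 1, 1) - shiftArr(sm, -1, 1)) / 2
  gy <- (shiftArr(sm, 1, 2) - shiftArr(sm, -1, 2)) / 2
  gz <- (shiftArr(sm, 1, 3) - shiftArr(sm, -1, 3)) / 2
  gm <- sqrt(gx^2 + gy^2 + gz^2)
  thr <- mean(gm) + gradientSd * sd(as.numeric(gm))
  sel <- which(gm > thr)
  if (length(sel) == 0)
    return(list(centers = matrix(numeric(0), 0, 3), radii = numeric(0),
                votes = numeric(0)))
  pos <- arrayInd(sel, d)
  ghat <- cbind(gx[sel], gy[sel], gz[sel]) / gm[sel]
  radii <- seq(radiusRange[1], radiusRange[2], by = radiusStep)
  best <- NULL
  for (r in radii) {
    acc <- array(0, d)
    for (sgn in c(-1, 1)) {
      cand <- round(pos + sgn * r * ghat)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cc <- cand[ok, , drop = FALSE]
      if (nrow(cc) == 0) next
      lin <- cc[, 1] + d[1] * (cc[, 2] - 1) + d[1] * d[2] * (cc[, 3] - 1)
      tb <- table(lin)
      acc[as.integer(names(tb))] <- acc[as.integer(names(tb))] + as.numeric(tb)
    }
    acc <- ballSum(acc, 2)       # pool votes over a small neighbourhood
    thrV <- minVotes * 4 * pi * r^2
    peaks <- which(acc >= thrV)
    if (length(peaks) > 0) {
      pk <- arrayInd(peaks, d)
      best <- rbind(best, cbind(pk, r, acc[peaks]))
    }
  }
  if (is.null(best))
    return(list(centers = matrix(numeric(0), 0, 3), radii = numeric(0),
                votes = numeric(0)))
  ## non-maximum suppression at half the minimum radius
  ord <- order(-best[, 5])
  best <- best[ord, , drop = FALSE]
  nms <- min(radii) / 2
  keep <- logical(nrow(best))
  for (i in seq_len(nrow(best))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    dd <- sqrt(rowSums((best[keep, 1:3, drop = FALSE] -
                        matrix(best[i, 1:3], sum(keep), 3,
                               byrow = TRUE))^2))
    keep[i] <- all(dd >= nms)
  }
  best <- best[keep, , drop = FALSE]
  list(centers = best[, 1:3, drop = FALSE] - 1, radii = best[, 4],
       votes = best[, 5])
}

## circular shift of a 3D array along one axis (for finite differences)
shiftArr <- function(x, by, axis) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- ((idx[[axis]] - 1 - by) %% d[axis]) + 1
  do.call(`[`, c(list(x), idx))
}

#' Quasi-uniform surface sampling of a sphere with outward normals
#'
#' Fibonacci lattice at an arc spacing of approximately `spacing`
#' Angstrom; the number of points is `round(4 pi r^2 / spacing^2)`.
#'
#' @param center sphere centre, voxels.
#' @param radius sphere radius, voxels.
#' @param spacing target spacing in Angstrom.
#' @param pixelSize voxel size in Angstrom.
#' @return a \linkS4class{PickSet} with outward unit normals.
#' @export
sampleSurface <- function(center, radius, spacing, pixelSize) {
  rA <- radius * pixelSize
  if (spacing >= pi * rA + 1e-9) spacing <- pi * rA  # hemispheric bound
  n <- max(1, round(4 * pi * rA^2 / spacing^2))
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  rr <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(n) - 1)
  normals <- cbind(rr * cos(th), rr * sin(th), z)
  pts <- matrix(center, n, 3, byrow = TRUE) + radius * normals
  PickSet(pts, rep(1, n), normals)
}

#' Otsu threshold of a score distribution
#'
#' @param x numeric scores.
#' @param nBins histogram bins.
#' @return list with `threshold` and `varRatio` (inter-class variance /
#'   total variance, a bimodality measure).
#' @export
otsuThreshold <- function(x, nBins = 64) {
  h <- hist(x, breaks = nBins, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; thr <- mids[1]
  mu <- sum(p * mids)
  for (i in seq_len(length(mids) - 1)) {
    w0 <- sum(p[1:i]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:i] * mids[1:i]) / w0
    m1 <- sum(p[(i + 1):length(mids)] * mids[(i + 1):length(mids)]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- (mids[i] + mids[i + 1]) / 2 }
  }
  list(threshold = thr, varRatio = best / max(var(x) *
         (length(x) - 1) / length(x), .Machine$double.eps))
}

#' Score- and proximity-based particle cleaning
#'
#' Per-particle scores (means over each particle's tilted projections)
#' below the threshold are removed; in `"auto"` mode the threshold is the
#' Otsu split of the score histogram, applied only when the distribution
#' is bimodal (inter-class variance ratio above `bimodalMin`; a single
#' Gaussian already reaches about 0.64, so the default demands clearly
#' separated modes -- otherwise a warning is emitted and no score
#' filtering happens). Then duplicates closer than `minDistance` are
#' removed greedily, keeping the higher-scoring member of each pair.
#' Idempotent.
#'
#' @param particles a \linkS4class{ParticleSet} whose `score` slot holds
#'   per-particle mean scores, or to be computed from `projScores`.
#' @param scoreThreshold numeric threshold, `"auto"`, or `NULL` to skip
#'   score filtering.
#' @param minDistance minimum centre distance in voxels (0 disables
#'   duplicate removal).
#' @param projScores optional P x T matrix of per-projection scores whose
#'   row means replace the particle scores.
#' @param bimodalMin minimum Otsu inter-class variance ratio for the
#'   automatic threshold to be applied.
#' @return the filtered \linkS4class{ParticleSet}.
#' @export
cleanParticles <- function(particles, scoreThreshold = "auto",
                           minDistance = 0, projScores = NULL,
                           bimodalMin = 0.85) {
  if (!is.null(projScores))
    particles@score <- rowMeans(projScores)
  sc <- particleScores(particles)
  stopifnot(all(is.finite(sc)))
  keep <- rep(TRUE, nParticles(particles))
  if (!is.null(scoreThreshold)) {
    if (identical(scoreThreshold, "auto")) {
      ot <- otsuThreshold(sc)
      if (ot$varRatio > bimodalMin) {
        keep <- sc >= ot$threshold
      } else {
        warning("score distribution not bimodal; no score filtering applied")
      }
    } else {
      keep <- sc >= scoreThreshold
    }
  }
  pos <- particlePositions(particles)[keep, , drop = FALSE]
  sc2 <- sc[keep]
  ids <- particles@particleId[keep]
  ang <- particleAngles(particles)[keep, , drop = FALSE]
  if (minDistance > 0 && nrow(pos) > 1) {
    ord <- order(-sc2, pos[, 1], pos[, 2], pos[, 3])
    keep2 <- logical(length(ord))
    for (i in ord) {
      sel <- which(keep2)
      if (length(sel) == 0) { keep2[i] <- TRUE; next }
      dd <- sqrt(rowSums((pos[sel, , drop = FALSE] -
                          matrix(pos[i, ], length(sel), 3,
                                 byrow = TRUE))^2))
      keep2[i] <- all(dd >= minDistance)
    }
    pos <- pos[keep2, , drop = FALSE]; sc2 <- sc2[keep2]
    ids <- ids[keep2]; ang <- ang[keep2, , drop = FALSE]
  }
  ParticleSet(pos, ang, sc2, ids)
}
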