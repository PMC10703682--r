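## Contrast transfer function: evaluation, per-tilt estimation from power
## spectra, depth-dependent per-particle defocus, and region-based CTF
## refinement through the projection-matching objective.

#' Relativistic electron wavelength
#'
#' @param voltage acceleration voltage in kV.
#' @return wavelength in Angstrom.
#' @export
electronWavelength <- function(voltage) {
  u <- voltage * 1000
  12.2643247 / sqrt(u * (1 + u * 0.978466e-6))
}

#' Evaluate the CTF at given spatial frequencies
#'
#' `CTF(k, az) = -(sqrt(1 - A^2) sin(gamma) + A cos(gamma))` with
#' `gamma = pi lambda df(az) k^2 - (pi/2) Cs lambda^3 k^4 + phase`, and
#' azimuth-dependent defocus
#' `df(az) = (df1 + df2)/2 + (df1 - df2)/2 cos(2 (az - astig))`.
#' Underfocus is positive; the result lies in \[-1, 1\].
#'
#' @param params a \linkS4class{CTFParams}.
#' @param k spatial frequency in 1/Angstrom (vector or matrix).
#' @param azimuth azimuth in radians (recycled against `k`).
#' @return the real-valued transfer function, same shape as `k`.
#' @export
ctfEval <- function(params, k, azimuth = 0) {
  lam <- electronWavelength(params@voltage)
  csA <- params@cs * 1e7
  df <- (params@df1 + params@df2) / 2 +
    (params@df1 - params@df2) / 2 *
      cos(2 * (azimuth - deg2rad(params@astigAngle)))
  gamma <- pi * lam * df * k^2 - (pi / 2) * csA * lam^3 * k^4 +
    deg2rad(params@phaseShift)
  a <- params@amplitudeContrast
  -(sqrt(1 - a^2) * sin(gamma) + a * cos(gamma))
}

#' Centred n x n CTF matrix for one projection
#'
#' @param params a \linkS4class{CTFParams}.
#' @param n box size.
#' @param pixelSize pixel size in Angstrom.
#' @return n x n real matrix matching the centred spectrum layout.
#' @export
ctfMatrix <- function(params, n, pixelSize) {
  ctfMatrixRaw(params@df1, params@df2, params@astigAngle, params@voltage,
               params@cs, params@amplitudeContrast, params@phaseShift,
               n, pixelSize)
}

#' Per-projection defocus from the per-tilt estimate and particle depth
#'
#' The particle's depth along the beam after the tilt rotation offsets
#' both defoci: `df -= zDepth * pixelSize` (larger z decreases defocus;
#' the sign convention is fixed package-wide and shared with the
#' simulator). Astigmatism is unchanged.
#'
#' @param tiltCtf \linkS4class{CTFParams} estimated for the tilt image.
#' @param zDepth particle depth along the beam in voxels (the `zDepth`
#'   component of [composeProjectionPose()]).
#' @param pixelSize pixel size in Angstrom.
#' @return a \linkS4class{CTFParams} for the particle projection.
#' @export
particleDefocus <- function(tiltCtf, zDepth, pixelSize) {
  off <- -zDepth * pixelSize
  new("CTFParams", df1 = tiltCtf@df1 + off, df2 = tiltCtf@df2 + off,
      astigAngle = tiltCtf@astigAngle, voltage = tiltCtf@voltage,
      cs = tiltCtf@cs, amplitudeContrast = tiltCtf@amplitudeContrast,
      phaseShift = tiltCtf@phaseShift)
}

## Fast scalar-argument CTF matrix (hot path; avoids S4 construction
## and caches the frequency-dependent factors per optics setting).
ctfMatrixRaw <- function(df1, df2, astigDeg, voltage, cs, ac, phaseDeg,
                         n, pixelSize) {
  key <- paste0("ctfp:", n, ":", pixelSize, ":", voltage, ":", cs, ":",
                phaseDeg)
  pre <- .cetCache[[key]]
  if (is.null(pre)) {
    g <- freqGrid2(n, pixelSize)
    lam <- electronWavelength(voltage)
    pre <- list(A = pi * lam * g$k^2,
                B = -(pi / 2) * cs * 1e7 * lam^3 * g$k^4 +
                  deg2rad(phaseDeg))
    .cetCache[[key]] <- pre
  }
  if (df1 == df2) {
    gamma <- ((df1 + df2) / 2) * pre$A + pre$B
  } else {
    akey <- paste0("ctfz:", n, ":", pixelSize, ":", astigDeg)
    cz <- .cetCache[[akey]]
    if (is.null(cz)) {
      g <- freqGrid2(n, pixelSize)
      cz <- cos(2 * (g$azimuth - deg2rad(astigDeg)))
      ## bounded cache: astigmatism searches sweep many candidate angles
      if (length(ls(.cetCache)) < 500) .cetCache[[akey]] <- cz
    }
    gamma <- ((df1 + df2) / 2 + (df1 - df2) / 2 * cz) * pre$A + pre$B
  }
  -(sqrt(1 - ac^2) * sin(gamma) + ac * cos(gamma))
}

## Per-projection defocus scalars for one (tilt, particle) without S4.
projDefocus <- function(geom, tiltIdx, zDepth, pixelSize, regions = NULL,
                        regionIdx = NULL) {
  d1 <- geom@defocus1[tiltIdx]; d2 <- geom@defocus2[tiltIdx]
  aa <- geom@astigAngle[tiltIdx]
  if (!is.null(regions) && !is.null(regionIdx)) {
    d1 <- d1 + regions@deltaDf1[regionIdx]
    d2 <- d2 + regions@deltaDf2[regionIdx]
    aa <- aa + regions@deltaAstig[regionIdx]
  }
  off <- -zDepth * pixelSize
  c(df1 = max(d1, d2) + off, df2 = min(d1, d2) + off, astig = aa)
}

## CTFParams for one tilt row of a TiltGeometry (optics from `base`),
## with optional per-region defocus corrections.
tiltCtfParams <- function(geom, tiltIdx, optics, regions = NULL,
                          regionIdx = NULL) {
  d1 <- geom@defocus1[tiltIdx]; d2 <- geom@defocus2[tiltIdx]
  aa <- geom@astigAngle[tiltIdx]
  if (!is.null(regions) && !is.null(regionIdx)) {
    d1 <- d1 + regions@deltaDf1[regionIdx]
    d2 <- d2 + regions@deltaDf2[regionIdx]
    aa <- aa + regions@deltaAstig[regionIdx]
  }
  if (d1 < d2) { tmp <- d1; d1 <- d2; d2 <- tmp }
  new("CTFParams", df1 = d1, df2 = d2, astigAngle = aa,
      voltage = optics@voltage, cs = optics@cs,
      amplitudeContrast = optics@amplitudeContrast,
      phaseShift = optics@phaseShift)
}

## Radially averaged power spectrum of an image; returns radius (index
## units) and mean power per integer shell.
radialPowerSpectrum <- function(im) {
  n <- nrow(im)
  ps <- Mod(ftCentered(im))^2
  g <- freqIndexGrid(n)
  r <- round(sqrt(g$kx^2 + g$ky^2))
  keep <- r >= 1 & r <= n / 2 - 1
  prof <- tapply(ps[keep], r[keep], mean)
  list(radius = as.numeric(names(prof)), power = as.numeric(prof), ps = ps)
}

## Smooth background through the local minima of a (log) power spectrum.
spectrumBackground <- function(radius, power) {
  lp <- log(pmax(power, .Machine$double.xmin))
  n <- length(lp)
  isMin <- c(TRUE, diff(sign(diff(lp))) > 0, TRUE)
  idx <- which(isMin)
  if (length(idx) < 4) idx <- seq_len(n)
  fit <- smooth.spline(radius[idx], lp[idx], df = min(6, length(idx)))
  exp(predict(fit, radius)$y)
}

#' Estimate defocus and astigmatism from one tilt image
#'
#' Maximises the correlation between the radially averaged,
#' background-subtracted power spectrum and `|CTF|^2` over a 1D defocus
#' grid, then refines astigmatism by fitting per-sector defocus estimates
#' with a `cos 2(az - angle)` model. A normalised fit score below
#' `scoreThreshold` flags the estimate as unreliable (featureless
#' spectrum) without raising an error.
#'
#' @param image real matrix (at least 256 x 256 pixels).
#' @param pixelSize pixel size in Angstrom.
#' @param optics \linkS4class{CTFParams} carrying the optics constants
#'   (the defocus fields are ignored).
#' @param dfRange numeric length-2 defocus search range in Angstrom.
#' @param dfStep grid step for the 1D search, Angstrom.
#' @param resRange resolutions (Angstrom, low to high) used for fitting.
#' @param nSectors number of azimuthal sectors for astigmatism fitting.
#' @param scoreThreshold minimum normalised fit score.
#' @return list with `params` (\linkS4class{CTFParams}), `score`
#'   (normalised fit correlation) and `flagged` (logical).
#' @export
estimateTiltCtf <- function(image, pixelSize, optics = CTFParams(),
                            dfRange = c(5000, 60000), dfStep = 250,
                            resRange = c(30, 2.5 * pixelSize),
                            nSectors = 12, scoreThreshold = 0.3) {
  n <- nrow(image)
  if (n < 256 || ncol(image) < 256)
    stop("CTF estimation needs an image of at least 256 x 256 pixels")
  rps <- radialPowerSpectrum(image)
  kAng <- rps$radius / (n * pixelSize)
  sel <- kAng >= 1 / resRange[1] & kAng <= 1 / resRange[2]
  bg <- spectrumBackground(rps$radius, rps$power)
  sig <- rps$power - bg
  fitCorr <- function(df, kv, sv) {
    p <- CTFParams(df1 = df, df2 = df, voltage = optics@voltage,
                   cs = optics@cs,
                   amplitudeContrast = optics@amplitudeContrast,
                   phaseShift = optics@phaseShift)
    m <- ctfEval(p, kv)^2
    m <- m - mean(m); s <- sv - mean(sv)
    den <- sqrt(sum(m^2) * sum(s^2))
    if (den == 0) 0 else sum(m * s) / den
  }
  grid <- seq(dfRange[1], dfRange[2], by = dfStep)
  cors <- vapply(grid, fitCorr, 0, kv = kAng[sel], sv = sig[sel])
  best <- grid[which.max(cors)]
  opt <- optimize(fitCorr, c(best - dfStep, best + dfStep), kv = kAng[sel],
                  sv = sig[sel], maximum = TRUE)
  dfMean <- opt$maximum
  score <- opt$objective
  flagged <- score < scoreThreshold
  ## astigmatism: per-sector defocus on the 2D spectrum
  df1 <- df2 <- dfMean; astig <- 0
  if (!flagged && nSectors >= 4) {
    g <- freqIndexGrid(n)
    r <- sqrt(g$kx^2 + g$ky^2)
    az <- atan2(g$ky, g$kx) %% pi
    bgMap <- approxMap(r, rps$radius, bg)
    sig2 <- rps$ps - bgMap
    kMap <- r / (n * pixelSize)
    secDf <- rep(NA_real_, nSectors)
    secGrid <- seq(dfMean - 5000, dfMean + 5000, by = 100)
    for (s in seq_len(nSectors)) {
      lo <- (s - 1) * pi / nSectors; hi <- s * pi / nSectors
      m <- az >= lo & az < hi & kMap >= 1 / resRange[1] &
        kMap <= 1 / resRange[2] & r >= 1
      if (sum(m) < 50) next
      ## grid capture first: the correlation oscillates with defocus
      cg <- vapply(secGrid, fitCorr, 0, kv = kMap[m], sv = sig2[m])
      b <- secGrid[which.max(cg)]
      o <- optimize(fitCorr, c(b - 100, b + 100), kv = kMap[m],
                    sv = sig2[m], maximum = TRUE)
      secDf[s] <- o$maximum
    }
    ok <- is.finite(secDf)
    if (sum(ok) >= 4) {
      mid <- ((seq_len(nSectors) - 0.5) * pi / nSectors)[ok]
      fit <- stats::lm(secDf[ok] ~ cos(2 * mid) + sin(2 * mid))
      co <- coef(fit)
      amp <- sqrt(co[2]^2 + co[3]^2)
      astig <- rad2deg(atan2(co[3], co[2]) / 2)
      df1 <- co[1] + amp; df2 <- co[1] - amp
    }
  }
  params <- CTFParams(df1 = max(df1, df2), df2 = min(df1, df2),
                      astigAngle = astig, voltage = optics@voltage,
                      cs = optics@cs,
                      amplitudeContrast = optics@amplitudeContrast,
                      phaseShift = optics@phaseShift)
  list(params = params, score = as.numeric(score), flagged = flagged)
}

## Map a per-shell profile onto a full 2D radius map.
approxMap <- function(r, radius, values) {
  out <- stats::approx(radius, values, xout = as.vector(r), rule = 2)$y
  matrix(out, nrow = nrow(r))
}

#' Region-based CTF refinement (the mapping h)
#'
#' For each region with enough particles, maximises the summed
#' projection-matching score over a per-region defocus/astigmatism
#' correction `(ddf1, ddf2, dastig)` applied on top of the per-tilt
#' estimates (then combined with the depth-dependent per-particle
#' defocus). The search is a derivative-free coordinate maximisation
#' restricted to `+-tolerance`; the summed score never decreases because
#' the incumbent parameters are kept whenever no improvement is found.
#'
#' @param sim a simulation/dataset object as returned by
#'   [simulateTiltSeries()] (tilt images plus geometry).
#' @param particles \linkS4class{ParticleSet} with current poses.
#' @param reference reference volume (real array).
#' @param regions \linkS4class{RegionGrid}; its `deltaDf*` slots hold the
#'   starting corrections and are updated in the returned grid.
#' @param tolerance defocus search half-width in Angstrom (astigmatism
#'   angle is searched within `+-astigTolerance`).
#' @param astigTolerance astigmatism angle half-width, degrees.
#' @param minParticles regions with fewer particles keep zero corrections.
#' @param band resolution band `(low, high)` in Angstrom for scoring.
#' @param refineAstig also refine the astigmatism correction.
#' @return list with `regions` (updated \linkS4class{RegionGrid}),
#'   `score` (summed objective after refinement) and `score0` (before).
#' @export
refineRegionCtf <- function(sim, particles, reference, regions,
                            tolerance = 2000, astigTolerance = 10,
                            minParticles = 5, band = c(Inf, NA),
                            refineAstig = FALSE) {
  ps <- sim@spec$pixelSize
  box <- sim@spec$boxSize
  if (is.na(band[2])) band[2] <- 2.5 * ps
  refFT <- ftCentered(reference)
  bandIdx <- bandIndices(box, ps, band[1], band[2])
  ridx <- particleRegions(particles, regions)
  score0 <- 0; score1 <- 0
  for (g in seq_len(regionCount(regions))) {
    members <- which(ridx == g)
    if (length(members) < minParticles) {
      if (length(members) > 0)
        warning(sprintf("region %d has %d < %d particles; CTF kept", g,
                        length(members), minParticles))
      next
    }
    crops <- extractCrops(sim, particles, members, tilts = NULL,
                          regions = regions, withCtf = FALSE)
    objective <- function(dd) {
      regTmp <- regions
      regTmp@deltaDf1[g] <- dd[1]
      regTmp@deltaDf2[g] <- dd[2]
      regTmp@deltaAstig[g] <- dd[3]
      regionScoreCtf(sim, particles, refFT, bandIdx, members, g, regTmp,
                     crops)
    }
    start <- c(regions@deltaDf1[g], regions@deltaDf2[g],
               regions@deltaAstig[g])
    s0 <- objective(start)
    score0 <- score0 + s0
    if (tolerance > 0) {
      lims <- rbind(start[1] + c(-1, 1) * tolerance,
                    start[2] + c(-1, 1) * tolerance,
                    start[3] + c(-1, 1) * astigTolerance)
      act <- if (refineAstig) 1:3 else 1:2
      res <- coordinateMaximize(objective, start, lims,
                                tol = c(1, 1, 0.1), active = act)
      if (res$value >= s0) {
        regions@deltaDf1[g] <- res$par[1]
        regions@deltaDf2[g] <- res$par[2]
        regions@deltaAstig[g] <- res$par[3]
        score1 <- score1 + res$value
      } else score1 <- score1 + s0
    } else score1 <- score1 + s0
  }
  list(regions = regions, score = score1, score0 = score0)
}

## Summed score of one region's projections under candidate CTF deltas.
## Geometry (including any region geometry corrections) is fixed here;
## only the CTF corrections of region g vary.
regionScoreCtf <- function(sim, particles, refFT, bandIdx, members, g,
                           regions, crops) {
  geom <- sim@geometry
  dims <- sim@spec$tomogramDims
  ps <- sim@spec$pixelSize
  box <- sim@spec$boxSize
  imgCtr <- floor(dims[1:2] / 2)
  total <- 0
  for (m in seq_along(members)) {
    p <- members[m]
    ang <- particles@angles[p, ]
    pos <- particles@positions[p, ]
    for (j in seq_along(crops[[m]])) {
      cp <- crops[[m]][[j]]
      if (is.null(cp)) next
      t <- cp$tilt
      pp <- composeProjectionPose(geom, t, pos, ang, dims,
                                  regionDelta(regions, g, t))
      resid <- imgCtr + pp$shift - cp$centerInt
      ctfP <- particleDefocus(
        tiltCtfParams(geom, t, sim@optics, regions, g), pp$zDepth, ps)
      ctfM <- ctfMatrix(ctfP, box, ps)
      total <- total + cpp_slice_score(cp$ft, refFT, pp$rotation,
                                       resid[1], resid[2], ctfM, bandIdx)
    }
  }
  total
}
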