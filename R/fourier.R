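## Centred Fourier-transform helpers. All spectra in this package are
## centred: array index i (1-based) carries frequency i - n/2 - 1 cycles
## per box, so DC sits at n/2 + 1. Boxes must be even so fftshift and its
## inverse coincide.

fftshiftN <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- n %/% 2
    c((h + 1):n, 1:h)
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Centred forward Fourier transform of an image or volume
#'
#' Real-space origin and DC are both at index `n/2 + 1` along each axis.
#' Requires even box sizes.
#'
#' @param x real array (2D or 3D), even dimensions.
#' @return complex array of the same shape, centred spectrum.
#' @export
ftCentered <- function(x) {
  stopifnot(all(dim(x) %% 2 == 0))
  fftshiftN(fft(fftshiftN(x)))
}

#' Centred inverse Fourier transform
#'
#' Inverse of [ftCentered()]; returns the real part.
#'
#' @param X complex centred spectrum.
#' @return real array of the same shape.
#' @export
iftCentered <- function(X) {
  fftshiftN(Re(fft(fftshiftN(X), inverse = TRUE))) / length(X)
}

## Centred integer frequency grids for an n x n image: h = -n/2 .. n/2-1.
freqIndexGrid <- function(n) {
  h <- seq_len(n) - n / 2 - 1
  list(kx = matrix(h, n, n), ky = matrix(h, n, n, byrow = TRUE))
}

## Memo cache for frequency grids and band indices (hot path).
.cetCache <- new.env(parent = emptyenv())

#' Spatial-frequency magnitude and azimuth grids for an n x n image
#'
#' Cached per (n, pixelSize).
#'
#' @param n box size (even).
#' @param pixelSize pixel size in Angstrom.
#' @return list with `k` (1/Angstrom), `azimuth` (radians), and the
#'   centred integer index grids `kx`, `ky`.
#' @export
freqGrid2 <- function(n, pixelSize) {
  key <- paste0("fg:", n, ":", pixelSize)
  hit <- .cetCache[[key]]
  if (!is.null(hit)) return(hit)
  g <- freqIndexGrid(n)
  k <- sqrt(g$kx^2 + g$ky^2) / (n * pixelSize)
  out <- list(k = k, azimuth = atan2(g$ky, g$kx), kx = g$kx, ky = g$ky)
  .cetCache[[key]] <- out
  out
}

#' Band indices for band-limited scoring
#'
#' 0-based (i, j) array indices of an n x n centred spectrum whose radius
#' (in cycles per box) corresponds to resolutions between `resLow` and
#' `resHigh` Angstrom. The DC term is always excluded; the band is capped
#' below Nyquist.
#'
#' @param n box size.
#' @param pixelSize pixel size in Angstrom.
#' @param resLow,resHigh low/high resolution limits in Angstrom
#'   (`resLow > resHigh`); `resLow = Inf` starts just above DC.
#' @return integer m x 2 matrix of 0-based indices.
#' @export
bandIndices <- function(n, pixelSize, resLow = Inf, resHigh = 2 * pixelSize) {
  key <- paste0("bi:", n, ":", pixelSize, ":", resLow, ":", resHigh)
  hit <- .cetCache[[key]]
  if (!is.null(hit)) return(hit)
  if (resHigh < 2 * pixelSize) resHigh <- 2 * pixelSize
  rLow <- if (is.finite(resLow)) n * pixelSize / resLow else 0
  rHigh <- min(n * pixelSize / resHigh, n / 2 - 1)
  if (rHigh <= rLow) stop("empty frequency band")
  g <- freqIndexGrid(n)
  r <- sqrt(g$kx^2 + g$ky^2)
  sel <- which(r > max(rLow, 0.5) & r <= rHigh, arr.ind = TRUE)
  storage.mode(sel) <- "integer"
  sel <- sel - 1L
  .cetCache[[key]] <- sel
  sel
}

## Phase ramp applying a real-space shift s (pixels): multiplying a
## centred spectrum by shiftPhase(n, s) shifts the image content by +s.
shiftPhase <- function(n, s) {
  g <- freqIndexGrid(n)
  exp(-2i * pi * (g$kx * s[1] + g$ky * s[2]) / n)
}

#' Shift an image by a (possibly subpixel) translation
#'
#' Fourier-space phase shift with periodic wrap-around.
#'
#' @param im real matrix with even dimensions.
#' @param s length-2 shift in pixels; content moves by `+s`.
#' @return shifted real matrix.
#' @export
shiftImage <- function(im, s) {
  d <- dim(im)
  kx <- matrix(seq_len(d[1]) - d[1] / 2 - 1, d[1], d[2])
  ky <- matrix(seq_len(d[2]) - d[2] / 2 - 1, d[1], d[2], byrow = TRUE)
  ph <- exp(-2i * pi * (kx * s[1] / d[1] + ky * s[2] / d[2]))
  iftCentered(ftCentered(im) * ph)
}

## Crop a box x box window centred at 0-based integer position c from a
## larger image (1-based array arithmetic inside).
cropBox <- function(im, centerInt, box) {
  x0 <- centerInt[1] - box / 2   # 0-based start
  y0 <- centerInt[2] - box / 2
  im[(x0 + 1):(x0 + box), (y0 + 1):(y0 + box), drop = FALSE]
}

## Add a box image into a larger image at 0-based integer centre.
pasteBox <- function(im, patch, centerInt) {
  box <- nrow(patch)
  x0 <- centerInt[1] - box / 2
  y0 <- centerInt[2] - box / 2
  im[(x0 + 1):(x0 + box), (y0 + 1):(y0 + box)] <-
    im[(x0 + 1):(x0 + box), (y0 + 1):(y0 + box)] + patch
  im
}

## TRUE when a 0-based centre keeps the whole box inside dims.
boxInside <- function(centerInt, box, dims) {
  all(centerInt - box / 2 >= 0) && all(centerInt + box / 2 <= dims[1:2])
}

## Separable Gaussian low-pass of a 2D/3D array via FFT (sigma in voxels).
gaussianFilter <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  gs <- lapply(d, function(n) {
    h <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))  # unshifted frequencies
    exp(-2 * pi^2 * sigma^2 * (h / n)^2)
  })
  G <- Reduce(outer, gs)
  dim(G) <- d
  Re(fft(fft(x) * G, inverse = TRUE)) / length(x)
}
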