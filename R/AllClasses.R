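#' @import methods
NULL

#' Per-tilt acquisition geometry and CTF for one tilt series
#'
#' Holds, for each projection image of a tilt series, the tilt-axis angle
#' \eqn{\alpha} (degrees, in the image plane), the stage tilt angle
#' \eqn{\beta} (degrees), the in-plane image shift (pixels at the unbinned
#' pixel size), the acquisition (exposure) order used for dose accounting,
#' and the per-tilt defocus pair / astigmatism estimated from the image
#' (Angstrom / degrees).
#'
#' @slot tiltIndex integer, unique per tilt.
#' @slot alpha numeric, tilt-axis angle in degrees, in \[-180, 180).
#' @slot beta numeric, tilt angle in degrees, in \[-90, 90).
#' @slot shiftX,shiftY numeric, in-plane shifts in pixels.
#' @slot exposureOrder integer, a permutation of \code{0:(T-1)}.
#' @slot defocus1,defocus2 numeric, defocus along the major/minor
#'   astigmatism axes in Angstrom (underfocus positive).
#' @slot astigAngle numeric, astigmatism angle in degrees.
#' @export
setClass("TiltGeometry",
  representation(tiltIndex = "integer", alpha = "numeric", beta = "numeric",
    shiftX = "numeric", shiftY = "numeric", exposureOrder = "integer",
    defocus1 = "numeric", defocus2 = "numeric", astigAngle = "numeric"))

setValidity("TiltGeometry", function(object) {
  n <- length(object@tiltIndex)
  lens <- c(length(object@alpha), length(object@beta), length(object@shiftX),
            length(object@shiftY), length(object@exposureOrder),
            length(object@defocus1), length(object@defocus2),
            length(object@astigAngle))
  if (any(lens != n)) return("all slots must have one entry per tilt")
  if (anyDuplicated(object@tiltIndex)) return("tiltIndex must be unique")
  if (any(object@beta < -90 | object@beta >= 90))
    return("beta must lie in [-90, 90)")
  if (any(object@alpha < -180 | object@alpha >= 180))
    return("alpha must lie in [-180, 180)")
  if (!setequal(object@exposureOrder, seq_len(n) - 1L))
    return("exposureOrder must be a permutation of 0..T-1")
  TRUE
})

#' Construct a TiltGeometry
#'
#' @param beta tilt angles in degrees.
#' @param alpha tilt-axis angle(s) in degrees (recycled).
#' @param shiftX,shiftY in-plane shifts in pixels (recycled).
#' @param exposureOrder acquisition order, permutation of \code{0:(T-1)};
#'   default is dose-symmetric (zero tilt first, then alternating sides).
#' @param defocus1,defocus2 per-tilt defocus in Angstrom (recycled).
#' @param astigAngle per-tilt astigmatism angle in degrees (recycled).
#' @param tiltIndex integer indices, default \code{seq_along(beta) - 1}.
#' @return a \linkS4class{TiltGeometry}.
#' @export
TiltGeometry <- function(beta, alpha = 0, shiftX = 0, shiftY = 0,
                         exposureOrder = NULL, defocus1 = 30000,
                         defocus2 = 30000, astigAngle = 0,
                         tiltIndex = seq_along(beta) - 1L) {
  n <- length(beta)
  if (is.null(exposureOrder)) exposureOrder <- doseSymmetricOrder(beta)
  new("TiltGeometry", tiltIndex = as.integer(tiltIndex),
      alpha = rep_len(as.numeric(alpha), n), beta = as.numeric(beta),
      shiftX = rep_len(as.numeric(shiftX), n),
      shiftY = rep_len(as.numeric(shiftY), n),
      exposureOrder = as.integer(exposureOrder),
      defocus1 = rep_len(as.numeric(defocus1), n),
      defocus2 = rep_len(as.numeric(defocus2), n),
      astigAngle = rep_len(as.numeric(astigAngle), n))
}

#' Dose-symmetric exposure order for a set of tilt angles
#'
#' Ranks tilts by |beta| (ties: positive side first), emulating the
#' standard dose-symmetric acquisition scheme where the zero-degree tilt
#' receives the least accumulated exposure.
#'
#' @param beta tilt angles in degrees.
#' @return integer vector, a permutation of \code{0:(T-1)}.
#' @export
doseSymmetricOrder <- function(beta) {
  ord <- order(abs(beta), -sign(beta), beta)
  out <- integer(length(beta))
  out[ord] <- seq_along(beta) - 1L
  out
}

#' A set of particles with 3D poses inside one tomogram
#'
#' Positions are 0-based voxel coordinates in the tomogram frame; angles
#' are intrinsic ZYZ Euler triplets (theta, phi, psi) in degrees mapping
#' the reference frame to the particle frame, stored in canonical ranges
#' (theta, psi in \[-180, 180), phi in \[0, 180\]).
#'
#' @slot particleId integer ids.
#' @slot positions n x 3 matrix of voxel coordinates.
#' @slot angles n x 3 matrix of Euler angles in degrees.
#' @slot score numeric per-particle alignment quality.
#' @export
setClass("ParticleSet",
  representation(particleId = "integer", positions = "matrix",
    angles = "matrix", score = "numeric"))

setValidity("ParticleSet", function(object) {
  n <- length(object@particleId)
  if (nrow(object@positions) != n || ncol(object@positions) != 3)
    return("positions must be an n x 3 matrix")
  if (nrow(object@angles) != n || ncol(object@angles) != 3)
    return("angles must be an n x 3 matrix")
  if (length(object@score) != n) return("score must have one entry per particle")
  if (anyDuplicated(object@particleId)) return("particleId must be unique")
  a <- object@angles
  if (n > 0 && (any(a[, 1] < -180 | a[, 1] >= 180) ||
                any(a[, 2] < 0 | a[, 2] > 180) ||
                any(a[, 3] < -180 | a[, 3] >= 180)))
    return("angles must be canonical: theta, psi in [-180,180), phi in [0,180]")
  TRUE
})

#' Construct a ParticleSet
#'
#' Angles are canonicalised on construction.
#'
#' @param positions n x 3 matrix of voxel coordinates.
#' @param angles n x 3 matrix of ZYZ Euler angles, degrees.
#' @param score per-particle scores (default 0).
#' @param particleId integer ids (default \code{seq_len(n)}).
#' @return a \linkS4class{ParticleSet}.
#' @export
ParticleSet <- function(positions, angles = NULL, score = NULL,
                        particleId = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(angles)) angles <- matrix(0, n, 3)
  angles <- as.matrix(angles)
  for (i in seq_len(n)) angles[i, ] <- canonicalEuler(angles[i, ])
  if (is.null(score)) score <- rep(0, n)
  if (is.null(particleId)) particleId <- seq_len(n)
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  dimnames(angles) <- list(NULL, c("theta", "phi", "psi"))
  new("ParticleSet", particleId = as.integer(particleId),
      positions = positions, angles = angles, score = as.numeric(score))
}

#' Spatial region grid with per-region geometry and CTF corrections
#'
#' Splits the tomogram bounding box into nx x ny x nz half-open uniform
#' cells. Each region carries per-tilt geometry corrections (tilt-axis
#' angle, tilt angle, image shifts) modelling beam-induced deformation,
#' and a per-region defocus/astigmatism correction shared by all tilts.
#' All corrections are initialised to zero.
#'
#' @slot nx,ny,nz integer region counts per axis.
#' @slot tomogramDims numeric length-3 tomogram dimensions in voxels.
#' @slot deltaAlpha,deltaBeta,deltaShiftX,deltaShiftY G x T matrices of
#'   per-region, per-tilt geometry corrections (degrees / pixels).
#' @slot deltaDf1,deltaDf2,deltaAstig length-G per-region CTF corrections
#'   (Angstrom / degrees).
#' @export
setClass("RegionGrid",
  representation(nx = "integer", ny = "integer", nz = "integer",
    tomogramDims = "numeric", deltaAlpha = "matrix", deltaBeta = "matrix",
    deltaShiftX = "matrix", deltaShiftY = "matrix", deltaDf1 = "numeric",
    deltaDf2 = "numeric", deltaAstig = "numeric"))

setValidity("RegionGrid", function(object) {
  g <- object@nx * object@ny * object@nz
  if (any(c(object@nx, object@ny, object@nz) < 1L))
    return("grid counts must be >= 1")
  if (length(object@tomogramDims) != 3) return("tomogramDims must be length 3")
  for (s in c("deltaAlpha", "deltaBeta", "deltaShiftX", "deltaShiftY"))
    if (nrow(slot(object, s)) != g)
      return(sprintf("%s must have G = nx*ny*nz rows", s))
  if (length(object@deltaDf1) != g || length(object@deltaDf2) != g ||
      length(object@deltaAstig) != g)
    return("per-region CTF corrections must have length G")
  TRUE
})

#' Construct a RegionGrid
#'
#' @param grid integer length-3: region counts (nx, ny, nz).
#' @param tomogramDims tomogram dimensions in voxels.
#' @param nTilts number of tilts (sets the per-tilt correction width).
#' @return a \linkS4class{RegionGrid} with all corrections zero.
#' @export
RegionGrid <- function(grid, tomogramDims, nTilts) {
  g <- prod(grid)
  z <- matrix(0, g, nTilts)
  new("RegionGrid", nx = as.integer(grid[1]), ny = as.integer(grid[2]),
      nz = as.integer(grid[3]), tomogramDims = as.numeric(tomogramDims),
      deltaAlpha = z, deltaBeta = z, deltaShiftX = z, deltaShiftY = z,
      deltaDf1 = numeric(g), deltaDf2 = numeric(g), deltaAstig = numeric(g))
}

#' Contrast transfer function parameters
#'
#' Defocus pair along the major/minor astigmatism axes (Angstrom,
#' underfocus positive, \code{df1 >= df2}), astigmatism angle (degrees),
#' and the optics constants of the microscope.
#'
#' @slot df1,df2 numeric defocus in Angstrom, \code{df1 >= df2}.
#' @slot astigAngle numeric astigmatism angle, degrees.
#' @slot voltage numeric acceleration voltage, kV.
#' @slot cs numeric spherical aberration, mm.
#' @slot amplitudeContrast numeric fraction in \[0, 1\].
#' @slot phaseShift numeric additional phase shift, degrees.
#' @export
setClass("CTFParams",
  representation(df1 = "numeric", df2 = "numeric", astigAngle = "numeric",
    voltage = "numeric", cs = "numeric", amplitudeContrast = "numeric",
    phaseShift = "numeric"))

setValidity("CTFParams", function(object) {
  if (object@df1 < object@df2) return("df1 must be >= df2")
  if (object@voltage <= 0) return("voltage must be positive")
  if (object@amplitudeContrast < 0 || object@amplitudeContrast > 1)
    return("amplitudeContrast must lie in [0, 1]")
  TRUE
})

#' Construct CTFParams
#'
#' @param df1,df2 defocus in Angstrom (underfocus positive).
#' @param astigAngle astigmatism angle in degrees.
#' @param voltage acceleration voltage in kV.
#' @param cs spherical aberration in mm.
#' @param amplitudeContrast amplitude contrast fraction.
#' @param phaseShift additional phase shift in degrees.
#' @return a \linkS4class{CTFParams}.
#' @export
CTFParams <- function(df1 = 30000, df2 = df1, astigAngle = 0, voltage = 300,
                      cs = 2.7, amplitudeContrast = 0.07, phaseShift = 0) {
  new("CTFParams", df1 = df1, df2 = df2, astigAngle = astigAngle,
      voltage = voltage, cs = cs, amplitudeContrast = amplitudeContrast,
      phaseShift = phaseShift)
}

#' A partial (bundle-wise) Fourier reconstruction
#'
#' Numerator (complex Fourier accumulation of CTF-multiplied slices) and
#' denominator (CTF^2 + weight accumulation). Partial reconstructions
#' merge by voxel-wise addition, which is commutative and associative, so
#' the final map is independent of bundle size and processing order.
#'
#' @slot num complex n x n x n array.
#' @slot den numeric n x n x n array, non-negative.
#' @slot count integer, number of projections inserted.
#' @slot halfSet integer, 0 = combined, 1/2 = half-set id.
#' @export
setClass("PartialReconstruction",
  representation(num = "array", den = "array", count = "integer",
    halfSet = "integer"))

setValidity("PartialReconstruction", function(object) {
  if (!all(dim(object@num) == dim(object@den)))
    return("num and den must have equal dimensions")
  if (min(object@den) < -1e-8) return("denominator must be non-negative")
  TRUE
})

#' A K-class model for constrained 3D classification
#'
#' @slot references list of K reference volumes.
#' @slot occupancies P x K matrix, rows sum to one.
#' @slot scoreMean,scoreSd numeric global score statistics used in the
#'   occupancy softmax.
#' @slot iterations integer, iterations run.
#' @slot seed integer RNG seed used for initial random assignment.
#' @slot populations numeric length-K class populations (sum of occupancies).
#' @slot history list of per-iteration diagnostics.
#' @export
setClass("ClassModel",
  representation(references = "list", occupancies = "matrix",
    scoreMean = "numeric", scoreSd = "numeric", iterations = "integer",
    seed = "integer", populations = "numeric", history = "list"))

setValidity("ClassModel", function(object) {
  occ <- object@occupancies
  if (ncol(occ) != length(object@references))
    return("occupancies must have one column per class")
  if (nrow(occ) > 0) {
    if (min(occ) < -1e-9) return("occupancies must be non-negative")
    if (max(abs(rowSums(occ) - 1)) > 1e-6)
      return("occupancies must sum to one per particle")
  }
  TRUE
})

#' A set of 3D picks with detection scores and optional surface normals
#'
#' @slot positions n x 3 matrix of voxel coordinates.
#' @slot scores numeric detection strengths.
#' @slot normals n x 3 matrix of outward unit normals, or a 0-row matrix
#'   when normals are not available.
#' @export
setClass("PickSet",
  representation(positions = "matrix", scores = "numeric",
    normals = "matrix"))

setValidity("PickSet", function(object) {
  n <- nrow(object@positions)
  if (ncol(object@positions) != 3) return("positions must be n x 3")
  if (length(object@scores) != n) return("scores must match positions")
  if (nrow(object@normals) > 0) {
    if (nrow(object@normals) != n) return("normals must match positions")
    len <- sqrt(rowSums(object@normals^2))
    if (any(abs(len - 1) > 1e-6)) return("normals must have unit length")
  }
  TRUE
})

#' Construct a PickSet
#'
#' @param positions n x 3 matrix of voxel coordinates.
#' @param scores detection strengths (default 0).
#' @param normals optional n x 3 matrix of unit normals.
#' @return a \linkS4class{PickSet}.
#' @export
PickSet <- function(positions, scores = NULL, normals = NULL) {
  positions <- matrix(as.numeric(positions), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
  if (is.null(scores)) scores <- rep(0, nrow(positions))
  if (is.null(normals)) normals <- matrix(numeric(0), 0, 3)
  new("PickSet", positions = positions, scores = as.numeric(scores),
      normals = as.matrix(normals))
}
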