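## Tilt geometry: Euler conventions, the pose-composition mapping from
## 3D particle alignments to per-projection 2D alignments, and the
## assignment of particles to spatial regions.
##
## Conventions (fixed package-wide):
##  * Euler angles (theta, phi, psi), degrees, intrinsic ZYZ:
##    R = Rz(theta) %*% Ry(phi) %*% Rz(psi); R maps the reference frame to
##    the particle frame.
##  * Tilt operator: rotate the image coordinate frame so the tilt axis is
##    vertical, tilt about it, rotate back: Rz(alpha) Ry(beta) Rz(-alpha).
##  * Tomogram coordinates are 0-based voxels; the rotation/projection
##    origin is the voxel floor(dims/2).
##  * Per-tilt shifts are applied after the tilt rotation.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rotZ <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rotY <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Euler angles to rotation matrix (intrinsic ZYZ)
#'
#' `R = Rz(theta) Ry(phi) Rz(psi)`, mapping the reference frame to the
#' particle frame. Angles in degrees.
#'
#' @param angles numeric length-3 `(theta, phi, psi)` in degrees.
#' @return a 3 x 3 rotation matrix with determinant +1.
#' @seealso [matrixToEuler()]
#' @export
eulerToMatrix <- function(angles) {
  rotZ(angles[1]) %*% rotY(angles[2]) %*% rotZ(angles[3])
}

#' Rotation matrix to canonical ZYZ Euler angles
#'
#' Inverts [eulerToMatrix()]. Near the gimbal-locked axis (phi close to 0
#' or 180 degrees) the in-plane rotation is degenerate; the convention here
#' sets `psi = 0` and folds the whole in-plane rotation into `theta`.
#'
#' @param R a 3 x 3 rotation matrix.
#' @param tol degeneracy tolerance on `|sin(phi)|`.
#' @return numeric `(theta, phi, psi)` in canonical ranges
#'   (theta, psi in \[-180, 180), phi in \[0, 180\]).
#' @export
matrixToEuler <- function(R, tol = 1e-8) {
  cphi <- max(-1, min(1, R[3, 3]))
  phi <- rad2deg(acos(cphi))
  sphi <- sqrt(max(0, 1 - cphi^2))
  if (sphi > tol) {
    theta <- rad2deg(atan2(R[2, 3], R[1, 3]))
    psi <- rad2deg(atan2(R[3, 2], -R[3, 1]))
  } else if (cphi > 0) {          # phi ~ 0: R ~ Rz(theta + psi)
    theta <- rad2deg(atan2(R[2, 1], R[1, 1]))
    psi <- 0
  } else {                        # phi ~ 180: R ~ Rz(theta - psi) Ry(180)
    theta <- rad2deg(atan2(-R[2, 1], -R[1, 1]))
    psi <- 0
  }
  canonicalEuler(c(theta, phi, psi))
}

#' Canonicalise a ZYZ Euler triplet
#'
#' Wraps theta and psi into \[-180, 180) and folds phi into \[0, 180\]
#' using the identity `(theta, -phi, psi) == (theta + 180, phi, psi + 180)`.
#'
#' @param angles numeric `(theta, phi, psi)` in degrees.
#' @return the equivalent canonical triplet.
#' @export
canonicalEuler <- function(angles) {
  wrap <- function(x) ((x + 180) %% 360) - 180
  theta <- angles[1]; phi <- angles[2] %% 360; psi <- angles[3]
  if (phi > 180) {                     # (theta, 360 - phi, psi) identity
    phi <- 360 - phi; theta <- theta + 180; psi <- psi + 180
  }
  c(wrap(theta), phi, wrap(psi))
}

#' Rotation applied to the specimen by one tilt
#'
#' Rotate the image frame by `-alpha` so the tilt axis is vertical (y),
#' tilt about it by `beta`, rotate back: `Rz(alpha) Ry(beta) Rz(-alpha)`.
#'
#' @param alpha tilt-axis angle, degrees.
#' @param beta tilt angle, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
tiltRotation <- function(alpha, beta) {
  rotZ(alpha) %*% rotY(beta) %*% rotZ(-alpha)
}

#' Compose a particle's 3D pose with the tilt geometry (the mapping g)
#'
#' Derives the 2D alignment of one particle projection from the shared
#' tilt geometry (optionally corrected by per-region deltas) and the
#' particle's rigid transformation, by exact rotation-matrix algebra:
#' the projection orientation is `R_tilt %*% R_particle` and the
#' projection shift is the rotated particle position plus the per-tilt
#' image shift. Projection poses are always derived this way, never
#' stored as free parameters.
#'
#' @param tilt a \linkS4class{TiltGeometry}.
#' @param tiltIdx which tilt (1-based row of `tilt`).
#' @param position particle position, 0-based voxels.
#' @param angles particle Euler angles `(theta, phi, psi)`, degrees.
#' @param center rotation origin in voxels, default `floor(dims/2)` must
#'   be supplied by the caller via `tomogramDims`.
#' @param tomogramDims tomogram dimensions in voxels.
#' @param delta optional list with fields `alpha`, `beta`, `shiftX`,
#'   `shiftY`: per-region geometry corrections (default all zero).
#' @return list with `shift` (x, y in pixels relative to the image centre
#'   of the tilt image), `angles` (canonical Euler triplet of the
#'   projection), `rotation` (the 3 x 3 projection orientation),
#'   `zDepth` (depth along the beam in voxels, for defocus assignment).
#' @export
composeProjectionPose <- function(tilt, tiltIdx, position, angles,
                                  tomogramDims, delta = NULL) {
  if (is.null(delta)) delta <- list(alpha = 0, beta = 0, shiftX = 0, shiftY = 0)
  al <- tilt@alpha[tiltIdx] + delta$alpha
  be <- tilt@beta[tiltIdx] + delta$beta
  rt <- tiltRotation(al, be)
  rp <- eulerToMatrix(angles)
  rtot <- rt %*% rp
  center <- floor(tomogramDims / 2)
  p <- rt %*% (position - center)
  shift <- c(p[1] + tilt@shiftX[tiltIdx] + delta$shiftX,
             p[2] + tilt@shiftY[tiltIdx] + delta$shiftY)
  list(shift = shift, angles = matrixToEuler(rtot), rotation = rtot,
       zDepth = p[3])
}

#' Assign particle positions to regions of a uniform 3D grid
#'
#' The tomogram bounding box is split into half-open uniform cells per
#' axis (`[lo, hi)`; boundary coordinates fall in the upper cell, with the
#' top edge clamped into the last cell). The linear region index is
#' `ix + nx * iy + nx * ny * iz` (0-based cells), returned 1-based.
#'
#' @param positions n x 3 matrix of voxel coordinates.
#' @param grid integer length-3 region counts `(nx, ny, nz)`.
#' @param tomogramDims tomogram dimensions in voxels.
#' @return integer vector of 1-based region indices in `1..prod(grid)`.
#' @export
assignRegions <- function(positions, grid, tomogramDims) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  bad <- which(apply(positions, 1, function(p)
    any(p < 0 | p > tomogramDims)))
  if (length(bad) > 0)
    stop("particle(s) outside the tomogram bounding box: ",
         paste(bad, collapse = ", "))
  idx <- integer(nrow(positions))
  cell <- sapply(1:3, function(a) {
    i <- floor(positions[, a] / tomogramDims[a] * grid[a])
    pmin(i, grid[a] - 1L)                    # clamp the closed top edge
  })
  cell <- matrix(cell, ncol = 3)
  as.integer(cell[, 1] + grid[1] * cell[, 2] +
             grid[1] * grid[2] * cell[, 3]) + 1L
}

#' Region index for each particle of a ParticleSet under a RegionGrid
#'
#' @param particles a \linkS4class{ParticleSet}.
#' @param regions a \linkS4class{RegionGrid}.
#' @return integer vector of 1-based region indices.
#' @export
particleRegions <- function(particles, regions) {
  assignRegions(particlePositions(particles),
                c(regions@nx, regions@ny, regions@nz),
                regions@tomogramDims)
}

regionDelta <- function(regions, regionIdx, tiltIdx) {
  if (is.null(regions)) return(NULL)
  list(alpha = regions@deltaAlpha[regionIdx, tiltIdx],
       beta = regions@deltaBeta[regionIdx, tiltIdx],
       shiftX = regions@deltaShiftX[regionIdx, tiltIdx],
       shiftY = regions@deltaShiftY[regionIdx, tiltIdx])
}
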