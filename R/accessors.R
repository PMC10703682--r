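#' @rdname accessors
#' @name accessors
#' @title Accessors for the core data classes
#' @param object a cetrefine S4 object.
#' @description Small accessor generics so user code never touches slots.
NULL

#' @export
setGeneric("nTilts", function(object) standardGeneric("nTilts"))
#' @rdname accessors
#' @export
setMethod("nTilts", "TiltGeometry", function(object) length(object@beta))

#' @export
setGeneric("tiltAngles", function(object) standardGeneric("tiltAngles"))
#' @rdname accessors
#' @export
setMethod("tiltAngles", "TiltGeometry", function(object) object@beta)

#' @export
setGeneric("exposureOrder", function(object) standardGeneric("exposureOrder"))
#' @rdname accessors
#' @export
setMethod("exposureOrder", "TiltGeometry", function(object) object@exposureOrder)

#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setMethod("nParticles", "ParticleSet", function(object) length(object@particleId))

#' @export
setGeneric("particlePositions", function(object) standardGeneric("particlePositions"))
#' @rdname accessors
#' @export
setMethod("particlePositions", "ParticleSet", function(object) object@positions)
#' @rdname accessors
#' @export
setMethod("particlePositions", "PickSet", function(object) object@positions)

#' @export
setGeneric("particleAngles", function(object) standardGeneric("particleAngles"))
#' @rdname accessors
#' @export
setMethod("particleAngles", "ParticleSet", function(object) object@angles)

#' @export
setGeneric("particleScores", function(object) standardGeneric("particleScores"))
#' @rdname accessors
#' @export
setMethod("particleScores", "ParticleSet", function(object) object@score)
#' @rdname accessors
#' @export
setMethod("particleScores", "PickSet", function(object) object@scores)

#' @export
setGeneric("pickNormals", function(object) standardGeneric("pickNormals"))
#' @rdname accessors
#' @export
setMethod("pickNormals", "PickSet", function(object) {
  if (nrow(object@normals) == 0) NULL else object@normals
})

#' @export
setGeneric("regionCount", function(object) standardGeneric("regionCount"))
#' @rdname accessors
#' @export
setMethod("regionCount", "RegionGrid",
          function(object) object@nx * object@ny * object@nz)

#' @export
setGeneric("occupancies", function(object) standardGeneric("occupancies"))
#' @rdname accessors
#' @export
setMethod("occupancies", "ClassModel", function(object) object@occupancies)

#' @export
setGeneric("classPopulations", function(object) standardGeneric("classPopulations"))
#' @rdname accessors
#' @export
setMethod("classPopulations", "ClassModel", function(object) object@populations)

#' @export
setGeneric("classReferences", function(object) standardGeneric("classReferences"))
#' @rdname accessors
#' @export
setMethod("classReferences", "ClassModel", function(object) object@references)

setMethod("show", "TiltGeometry", function(object) {
  cat(sprintf("TiltGeometry with %d tilts, beta %.1f..%.1f deg, axis %.1f deg\n",
              nTilts(object), min(object@beta), max(object@beta),
              object@alpha[1]))
})

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf("ParticleSet with %d particles (mean score %.4f)\n",
              nParticles(object),
              if (nParticles(object)) mean(object@score) else NA_real_))
})

setMethod("show", "RegionGrid", function(object) {
  cat(sprintf("RegionGrid %d x %d x %d (G = %d regions) on %s tomogram\n",
              object@nx, object@ny, object@nz, regionCount(object),
              paste(object@tomogramDims, collapse = " x ")))
})

setMethod("show", "CTFParams", function(object) {
  cat(sprintf(
    "CTFParams: df1 %.0f A, df2 %.0f A, astig %.1f deg, %g kV, Cs %g mm\n",
    object@df1, object@df2, object@astigAngle, object@voltage, object@cs))
})

setMethod("show", "PartialReconstruction", function(object) {
  cat(sprintf("PartialReconstruction: box %d, %d projections, half-set %d\n",
              dim(object@num)[1], object@count, object@halfSet))
})

setMethod("show", "ClassModel", function(object) {
  cat(sprintf("ClassModel with %d classes, %d particles, %d iterations\n",
              length(object@references), nrow(object@occupancies),
              object@iterations))
  cat("  populations:", paste(sprintf("%.1f", object@populations),
                              collapse = ", "), "\n")
})

setMethod("show", "PickSet", function(object) {
  cat(sprintf("PickSet with %d picks%s\n", nrow(object@positions),
              if (nrow(object@normals) > 0) " (with normals)" else ""))
})
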