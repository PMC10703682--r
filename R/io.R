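## On-disk artifacts: MRC2014 volumes/stacks (mode 2), tab-separated
## geometry/particle tables with '#' headers, the compressed
## per-projection refinement metadata table, minimal .star export/import,
## the bundle-processing driver with temporary-scratch semantics, and the
## storage-footprint calculator.

#' Write a volume or stack in MRC2014 format (mode 2)
#'
#' @param data 3D array (volume or image stack).
#' @param path output path.
#' @param pixelSize pixel size in Angstrom, stored in the header.
#' @param isStack write as an image stack (`ispg = 0`) instead of a
#'   volume (`ispg = 1`).
#' @return the path, invisibly.
#' @export
writeMRC <- function(data, path, pixelSize = 1, isStack = FALSE) {
  d <- dim(data)
  if (length(d) == 2) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4,
                               endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  wInt(d)                    # nx ny nz
  wInt(2)                    # mode 2: 32-bit float
  wInt(c(0, 0, 0))           # nxstart
  wInt(d)                    # mx my mz
  wFlt(d * pixelSize)        # cella
  wFlt(c(90, 90, 90))        # cellb
  wInt(c(1, 2, 3))           # mapc mapr maps
  wFlt(c(min(data), max(data), mean(data)))
  wInt(if (isStack) 0 else 1)  # ispg
  wInt(0)                    # nsymbt
  wInt(rep(0, 25))           # extra
  wFlt(c(0, 0, 0))           # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(sd(as.numeric(data)))
  wInt(0)                    # nlabl
  writeBin(raw(1024 - 224), con)
  wFlt(as.numeric(data))
  invisible(path)
}

#' Read an MRC2014 file (mode 2)
#'
#' @param path input path.
#' @return list with `data` (3D array), `pixelSize` and `isStack`.
#' @export
readMRC <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(n) readBin(con, "integer", n, size = 4,
                              endian = "little")
  rFlt <- function(n) readBin(con, "numeric", n, size = 4,
                              endian = "little")
  d <- rInt(3)
  mode <- rInt(1)
  if (mode != 2)
    stop(sprintf("unsupported MRC mode %d (only mode 2 is supported)",
                 mode))
  rInt(3)                    # nxstart
  mx <- rInt(3)
  cella <- rFlt(3)
  rFlt(3); rInt(3); rFlt(3)
  ispg <- rInt(1)
  nsymbt <- rInt(1)
  seek(con, 1024 + nsymbt)
  data <- rFlt(prod(d))
  if (length(data) < prod(d))
    stop("truncated MRC file: ", path)
  list(data = array(data, d), pixelSize = cella[1] / d[1],
       isStack = ispg == 0)
}

## ---- tab-separated tables -----------------------------------------------

#' Write / read the tilt-geometry table
#'
#' Tab-separated, one row per tilt, with a '#'-prefixed header naming the
#' documented column order: tilt_index, alpha, beta, shift_x, shift_y,
#' defocus1, defocus2, astig_angle, exposure_order.
#'
#' @param geom a \linkS4class{TiltGeometry}.
#' @param path file path.
#' @return `writeTiltTable`: the path, invisibly; `readTiltTable`: a
#'   \linkS4class{TiltGeometry}.
#' @export
writeTiltTable <- function(geom, path) {
  df <- data.frame(tilt_index = geom@tiltIndex, alpha = geom@alpha,
                   beta = geom@beta, shift_x = geom@shiftX,
                   shift_y = geom@shiftY, defocus1 = geom@defocus1,
                   defocus2 = geom@defocus2, astig_angle = geom@astigAngle,
                   exposure_order = geom@exposureOrder)
  writeTableHash(df, path)
}

#' @rdname writeTiltTable
#' @export
readTiltTable <- function(path) {
  df <- readTableHash(path)
  new("TiltGeometry", tiltIndex = as.integer(df$tilt_index),
      alpha = df$alpha, beta = df$beta, shiftX = df$shift_x,
      shiftY = df$shift_y, exposureOrder = as.integer(df$exposure_order),
      defocus1 = df$defocus1, defocus2 = df$defocus2,
      astigAngle = df$astig_angle)
}

#' Write / read the particle table
#'
#' Columns: particle_id, x, y, z, theta, phi, psi, score (0-based voxel
#' coordinates, degrees).
#'
#' @param particles a \linkS4class{ParticleSet}.
#' @param path file path.
#' @return `writeParticleTable`: the path, invisibly;
#'   `readParticleTable`: a \linkS4class{ParticleSet}.
#' @export
writeParticleTable <- function(particles, path) {
  pos <- particlePositions(particles); ang <- particleAngles(particles)
  df <- data.frame(particle_id = particles@particleId, x = pos[, 1],
                   y = pos[, 2], z = pos[, 3], theta = ang[, 1],
                   phi = ang[, 2], psi = ang[, 3],
                   score = particleScores(particles))
  writeTableHash(df, path)
}

#' @rdname writeParticleTable
#' @export
readParticleTable <- function(path) {
  df <- readTableHash(path)
  ParticleSet(cbind(df$x, df$y, df$z), cbind(df$theta, df$phi, df$psi),
              df$score, as.integer(df$particle_id))
}

#' Write / read picks as a tab-separated coordinate file
#'
#' Columns: x y z score, plus nx ny nz when normals are present
#' (0-based voxels).
#'
#' @param picks a \linkS4class{PickSet}.
#' @param path file path.
#' @return `writePickTable`: the path, invisibly; `readPickTable`: a
#'   \linkS4class{PickSet}.
#' @export
writePickTable <- function(picks, path) {
  df <- data.frame(x = picks@positions[, 1], y = picks@positions[, 2],
                   z = picks@positions[, 3], score = picks@scores)
  if (nrow(picks@normals) > 0) {
    df$nx <- picks@normals[, 1]; df$ny <- picks@normals[, 2]
    df$nz <- picks@normals[, 3]
  }
  writeTableHash(df, path)
}

#' @rdname writePickTable
#' @export
readPickTable <- function(path) {
  df <- readTableHash(path)
  normals <- if (!is.null(df$nx)) cbind(df$nx, df$ny, df$nz) else NULL
  PickSet(cbind(df$x, df$y, df$z), df$score, normals)
}

writeTableHash <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

readTableHash <- function(path) {
  header <- sub("^#\\s*", "", readLines(path, n = 1))
  cols <- strsplit(header, "\t")[[1]]
  df <- read.table(path, sep = "\t", comment.char = "#",
                   col.names = cols)
  df
}

## ---- per-projection refinement metadata ---------------------------------

#' Project metadata: geometry, particles and per-projection table
#'
#' @slot tilts \linkS4class{TiltGeometry}.
#' @slot particles \linkS4class{ParticleSet}.
#' @slot projections data.frame, one row per (particle, tilt) with pose,
#'   CTF, score, region id and class occupancies.
#' @slot provenance list (config, seeds, versions).
#' @export
setClass("ProjectMetadata",
  representation(tilts = "TiltGeometry", particles = "ParticleSet",
    projections = "data.frame", provenance = "list"))

setValidity("ProjectMetadata", function(object) {
  pj <- object@projections
  if (nrow(pj) > 0) {
    if (!all(pj$particle_id %in% object@particles@particleId))
      return("projection rows reference unknown particles")
    if (!all(pj$tilt_index %in% object@tilts@tiltIndex))
      return("projection rows reference unknown tilts")
  }
  TRUE
})

#' Build the per-projection refinement metadata table
#'
#' One row per (particle, tilt): derived projection pose (through the
#' pose-composition mapping), per-projection CTF, score, region id and
#' optional class occupancies.
#'
#' @param sim a \linkS4class{CetSimulation}.
#' @param particles current particle poses.
#' @param regions optional \linkS4class{RegionGrid}.
#' @param occupancies optional P x K occupancy matrix.
#' @return a \linkS4class{ProjectMetadata}.
#' @export
projectMetadata <- function(sim, particles, regions = NULL,
                            occupancies = NULL) {
  geom <- sim@geometry
  dims <- sim@spec$tomogramDims
  ps <- sim@spec$pixelSize
  ridx <- if (is.null(regions)) rep(1L, nParticles(particles)) else
    particleRegions(particles, regions)
  rows <- list(); k <- 0
  for (p in seq_len(nParticles(particles))) {
    for (t in seq_len(nTilts(geom))) {
      delta <- if (is.null(regions)) NULL else
        regionDelta(regions, ridx[p], t)
      pose <- composeProjectionPose(geom, t, particles@positions[p, ],
                                    particles@angles[p, ], dims, delta)
      ctfP <- particleDefocus(
        tiltCtfParams(geom, t, sim@optics, regions, ridx[p]),
        pose$zDepth, ps)
      k <- k + 1
      rows[[k]] <- data.frame(
        particle_id = particles@particleId[p],
        tilt_index = geom@tiltIndex[t], shift_x = pose$shift[1],
        shift_y = pose$shift[2], theta = pose$angles[1],
        phi = pose$angles[2], psi = pose$angles[3], df1 = ctfP@df1,
        df2 = ctfP@df2, astig_angle = ctfP@astigAngle,
        score = particles@score[p], region = ridx[p])
    }
  }
  pj <- do.call(rbind, rows)
  if (!is.null(occupancies)) {
    K <- ncol(occupancies)
    rowOf <- match(pj$particle_id, particles@particleId)
    for (kk in seq_len(K))
      pj[[paste0("occ_", kk)]] <- occupancies[rowOf, kk]
  }
  new("ProjectMetadata", tilts = geom, particles = particles,
      projections = pj,
      provenance = list(seed = sim@spec$seed,
                        package = as.character(utils::packageVersion(
                          "cetrefine"))))
}

#' Write / read the compressed projection metadata table
#'
#' Plain tab-separated text, bzip2-compressed; round-trips through
#' [readProjectionTable()] to numerical precision.
#'
#' @param meta a \linkS4class{ProjectMetadata} or plain data.frame.
#' @param path output path (conventionally `.tsv.bz2`).
#' @return `writeProjectionTable`: the path, invisibly;
#'   `readProjectionTable`: a data.frame.
#' @export
writeProjectionTable <- function(meta, path) {
  df <- if (is(meta, "ProjectMetadata")) meta@projections else meta
  con <- bzfile(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeProjectionTable
#' @export
readProjectionTable <- function(path) {
  con <- bzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  cols <- strsplit(sub("^#\\s*", "", lines[1]), "\t")[[1]]
  df <- read.table(text = lines[-1], sep = "\t", col.names = cols)
  df
}

## ---- minimal .star interoperability -------------------------------------

#' Export a projection table to a .star file
#'
#' One `data_projections` block with a `loop_` over the documented
#' columns (`_cet<ColumnName>`). Unknown columns survive a round trip.
#'
#' @param meta \linkS4class{ProjectMetadata} or data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportStar <- function(meta, path) {
  df <- if (is(meta, "ProjectMetadata")) meta@projections else meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("", "data_projections", "", "loop_"), con)
  tags <- paste0("_cet", gsub("(^|_)(\\w)", "\\U\\2",
                              names(df), perl = TRUE))
  writeLines(sprintf("%s #%d", tags, seq_along(tags)), con)
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Import a .star file written by [exportStar()]
#'
#' @param path input path.
#' @param required character vector of mandatory column names; missing
#'   ones raise an error listing them.
#' @return a data.frame with snake_case column names; unknown columns are
#'   preserved.
#' @export
importStar <- function(path, required = c("particle_id", "tilt_index")) {
  lines <- readLines(path)
  loopAt <- which(trimws(lines) == "loop_")[1]
  if (is.na(loopAt)) stop("no loop_ block found in ", path)
  body <- lines[(loopAt + 1):length(lines)]
  tagLines <- grep("^_", trimws(body))
  tags <- sub("\\s+#\\d+$", "", trimws(body[tagLines]))
  cols <- sub("^_cet", "", tags)
  cols <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", cols)
  cols <- tolower(cols)
  dataLines <- body[-tagLines]
  dataLines <- dataLines[nzchar(trimws(dataLines))]
  df <- read.table(text = dataLines, col.names = cols)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing mandatory .star columns: ",
         paste(missing, collapse = ", "))
  df
}

## ---- bundle processing driver -------------------------------------------

#' Process items in bundles with temporary scratch space
#'
#' Splits `items` into bundles of `bundleSize`, runs `stage(bundle,
#' scratchSubdir)` for each, deletes the bundle's scratch directory on
#' completion, and combines the per-bundle results (by default with
#' [mergeBundles()], so the final result is independent of bundle size
#' and processing order). A provenance record (config and seed) is
#' written next to the scratch root.
#'
#' @param items list (or vector) of work items.
#' @param stage function `(bundle, scratchDir) -> result`.
#' @param bundleSize items per bundle.
#' @param scratchDir scratch root; created if needed, removed at the end.
#' @param combine function merging the list of bundle results.
#' @param seed optional seed recorded in the provenance file.
#' @param config optional named list recorded in the provenance file.
#' @return list with `result` (combined), `partials` (per-bundle
#'   results) and `provenance` (path of the record).
#' @export
runBundles <- function(items, stage, bundleSize = 1,
                       scratchDir = tempfile("cet-scratch"),
                       combine = mergeBundles, seed = NULL,
                       config = list()) {
  stopifnot(bundleSize >= 1)
  if (!dir.exists(scratchDir)) dir.create(scratchDir, recursive = TRUE)
  if (!is.list(items)) items <- as.list(items)
  bundles <- split(items, ceiling(seq_along(items) / bundleSize))
  prov <- file.path(dirname(scratchDir),
                    paste0(basename(scratchDir), "-provenance.txt"))
  writeLines(c(
    sprintf("package: cetrefine %s", utils::packageVersion("cetrefine")),
    sprintf("date: %s", format(Sys.time())),
    sprintf("seed: %s", if (is.null(seed)) "NA" else seed),
    sprintf("bundle_size: %d", bundleSize),
    sprintf("n_items: %d", length(items)),
    vapply(names(config), function(k)
      sprintf("config.%s: %s", k, paste(format(config[[k]]),
                                        collapse = " ")), "")), prov)
  partials <- vector("list", length(bundles))
  for (i in seq_along(bundles)) {
    bdir <- file.path(scratchDir, sprintf("bundle-%04d", i))
    dir.create(bdir)
    partials[[i]] <- stage(bundles[[i]], bdir)
    unlink(bdir, recursive = TRUE)   # scratch products never persist
  }
  result <- combine(partials)
  unlink(scratchDir, recursive = TRUE)
  list(result = result, partials = partials, provenance = prov)
}

## ---- storage accounting --------------------------------------------------

#' Storage footprint of sub-volume versus projection-based processing
#'
#' The arithmetic behind processing tilt series without saving
#' sub-volumes or particle stacks: a dataset of `nParticles` particles
#' over `nTilts` tilts yields `nParticles * nTilts` projections; a saved
#' 2D stack would occupy `nProjections * box^2 * 4` bytes and extracted
#' sub-volumes `nParticles * box^3 * 4` bytes, while only one small map
#' per bundle persists. 1 GB = 2^30 bytes, 1 TB = 2^40 bytes.
#'
#' @param nParticles number of particles.
#' @param nTilts tilts per series.
#' @param box box size in pixels/voxels.
#' @param framesPerTilt video frames per tilt (for the exposure-weighting
#'   unit count).
#' @param grid optional region grid `(nx, ny, nz)`.
#' @param metadataBytesPerProjection size of one metadata row (text).
#' @return list with `nProjections`, `stackBytes`, `stackGB`,
#'   `subvolumeBytes`, `subvolumeTB`, `totalFrames`, `regionCount`,
#'   `persistedBytes` and `persistedFraction` (persisted / stack).
#' @export
estimateStorage <- function(nParticles, nTilts, box, framesPerTilt = 0,
                            grid = NULL,
                            metadataBytesPerProjection = 128) {
  nProj <- nParticles * nTilts
  stackBytes <- nProj * box^2 * 4
  subvolBytes <- nParticles * box^3 * 4
  ## partial reconstructions merge on the fly: what persists is the
  ## final half-set accumulator pair plus the per-projection metadata
  persistedBytes <- 2 * 2 * box^3 * 4 +
    nProj * metadataBytesPerProjection
  list(nProjections = nProj,
       stackBytes = stackBytes,
       stackGB = stackBytes / 2^30,
       subvolumeBytes = subvolBytes,
       subvolumeTB = subvolBytes / 2^40,
       totalFrames = framesPerTilt * nTilts,
       regionCount = if (is.null(grid)) NA_integer_ else prod(grid),
       persistedBytes = persistedBytes,
       persistedFraction = persistedBytes / stackBytes)
}
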