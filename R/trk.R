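# TrackVis TRK reader/writer. Points are stored on disk in "voxmm"
# coordinates (0-based voxel index + 0.5, scaled by voxel size); in memory
# all points are world mm (RAS), converted through the header's
# voxel-to-RAS matrix.

trk_scalar_names <- c("fa", "fw")

#' Write a tract as a TrackVis TRK file
#'
#' Per-point FA and FW-fraction scalars are stored in the TRK scalar slots
#' (names `fa`, `fw`). The voxel-to-RAS matrix, dimensions and voxel sizes
#' are taken from `reference`.
#'
#' @param tract a tract.
#' @param path output path.
#' @param reference a [dwi_volume()], [label_map()], or list with `dims` and
#'   `affine` describing the image grid the tract belongs to.
#' @return Invisibly, `path`.
#' @export
write_trk <- function(tract, path, reference) {
  ref <- as_reference_grid(reference)
  vs <- voxel_dims(ref$affine)
  pad_str <- function(s, n) c(charToRaw(s), raw(n - nchar(s)))
  num <- function(x, size) writeBin(as.numeric(x), raw(), size = size,
                                    endian = "little")
  int <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                    endian = "little")
  hdr <- c(
    pad_str("TRACK", 6L),
    int(ref$dims, 2L),
    num(vs, 4L),
    num(c(0, 0, 0), 4L),                              # origin (unused)
    int(2L, 2L),                                      # n_scalars
    unlist(lapply(1:10, function(i)
      pad_str(if (i <= 2L) trk_scalar_names[i] else "", 20L))),
    int(0L, 2L),                                      # n_properties
    raw(200L),                                        # property names
    num(t(ref$affine), 4L),                           # vox_to_ras, row-major
    raw(444L),                                        # reserved
    pad_str("RAS", 4L),                               # voxel_order
    raw(4L),                                          # pad2
    num(rep(0, 6), 4L),                               # image orientation
    raw(2L),                                          # pad1
    raw(6L),                                          # invert/swap flags
    int(length(tract$streamlines), 4L),               # n_count
    int(2L, 4L),                                      # version
    int(1000L, 4L))                                   # hdr_size
  stopifnot(length(hdr) == 1000L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (sl in tract$streamlines) {
    n <- nrow(sl$points)
    ijk <- world_to_voxel(ref$affine, sl$points)
    voxmm <- sweep(ijk + 0.5, 2L, vs, `*`)
    dat <- cbind(voxmm, sl$fa %||% rep(0, n), sl$fw %||% rep(0, n))
    writeBin(n, con, size = 4L, endian = "little")
    writeBin(as.numeric(t(dat)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis TRK file
#'
#' @param path a TRK file (version 2, with a valid voxel-to-RAS matrix).
#' @return A `tract` whose points are world mm; scalars named `fa`/`fw` (or
#'   `scalar1`, `scalar2`, ... when unnamed) are attached per point.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 6L)[1:5])
  if (id != "TRACK") stop("not a TRK file: bad magic '", id, "'")
  dims <- readBin(con, "integer", 3L, size = 2L, endian = "little")
  vs <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
  readBin(con, "numeric", 3L, size = 4L, endian = "little")  # origin
  n_scalars <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  snames <- vapply(1:10, function(i) {
    r <- readBin(con, "raw", 20L)
    rawToChar(r[seq_len(max(0, which(r == 0)[1] - 1))])
  }, "")
  n_props <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  readBin(con, "raw", 200L)
  aff <- matrix(readBin(con, "numeric", 16L, size = 4L, endian = "little"),
                4L, 4L, byrow = TRUE)
  readBin(con, "raw", 444L)
  vorder <- {
    r <- readBin(con, "raw", 4L)
    rawToChar(r[seq_len(max(0, which(r == 0)[1] - 1))])
  }
  readBin(con, "raw", 4L + 24L + 2L + 6L)
  n_count <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("unexpected TRK header size: ", hdr_size)
  if (version >= 2L && abs(det(aff[1:3, 1:3])) > 1e-12) {
    affine <- aff
  } else if (toupper(substr(vorder, 1L, 3L)) %in% c("RAS", "LPS", "LAS")) {
    stop("TRK file lacks a voxel-to-RAS matrix; cannot recover world space")
  } else {
    stop("unknown voxel order '", vorder, "' and no voxel-to-RAS matrix")
  }
  if (n_scalars < 0L || n_scalars > 10L)
    stop("invalid scalar count: ", n_scalars)
  snames <- snames[seq_len(n_scalars)]
  snames[snames == ""] <- paste0("scalar", which(snames == ""))
  streamlines <- list()
  i <- 0L
  repeat {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(n) == 0L) break
    vals <- readBin(con, "numeric", n * (3L + n_scalars), size = 4L,
                    endian = "little")
    if (length(vals) != n * (3L + n_scalars))
      stop("truncated TRK record (scalar-count mismatch?)")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)
    if (n_props > 0L) readBin(con, "numeric", n_props, size = 4L)
    ijk <- sweep(m[, 1:3, drop = FALSE], 2L, vs, `/`) - 0.5
    sl <- list(points = voxel_to_world(affine, ijk))
    for (s in seq_len(n_scalars)) sl[[snames[s]]] <- m[, 3L + s]
    class(sl) <- "streamline"
    i <- i + 1L
    streamlines[[i]] <- sl
  }
  if (n_count > 0L && i != n_count)
    warning("TRK header advertised ", n_count, " tracks but ", i, " read")
  structure(list(streamlines = streamlines,
                 provenance = list(source = path, voxel_order = vorder)),
            class = "tract")
}

#' Write a tract as ASCII VTK polylines
#'
#' @param tract a tract.
#' @param path output path (.vtk).
#' @return Invisibly, `path`.
#' @export
write_vtk_polylines <- function(tract, path) {
  np <- vapply(tract$streamlines, function(sl) nrow(sl$points), 1L)
  total <- sum(np)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fwtract streamlines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", total)), con)
  for (sl in tract$streamlines)
    writeLines(apply(sl$points, 1L, function(p)
      paste(sprintf("%.6f", p), collapse = " ")), con)
  writeLines(sprintf("LINES %d %d", length(np), length(np) + total), con)
  off <- 0L
  for (n in np) {
    writeLines(paste(c(n, off + seq_len(n) - 1L), collapse = " "), con)
    off <- off + n
  }
  invisible(path)
}
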