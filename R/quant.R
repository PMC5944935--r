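#' Construct a label map
#'
#' @param data 3-D integer-like array of non-negative labels.
#' @param affine invertible 4x4 voxel-to-world matrix.
#' @return An object of class `label_map`; its voxel volume (mm^3) is the
#'   absolute determinant of the affine's 3x3 block.
#' @export
label_map <- function(data, affine) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("label map must be 3-D")
  if (min(data) < 0) stop("labels must be non-negative")
  affine <- as.matrix(affine)
  if (abs(det(affine)) < 1e-12) stop("degenerate affine")
  structure(list(data = data, affine = affine,
                 voxel_volume = abs(det(affine[1:3, 1:3]))),
            class = "label_map")
}

# Supersample every segment of every streamline so that consecutive samples
# are no farther apart than `spacing` (mm); returns all samples as one matrix.
supersample_points <- function(tract, spacing) {
  out <- lapply(tract$streamlines, function(sl) {
    p <- sl$points
    n <- nrow(p)
    if (n < 2L) return(p)
    seg <- p[-1L, , drop = FALSE] - p[-n, , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    ns <- pmax(1L, ceiling(len / spacing))
    pieces <- lapply(seq_len(n - 1L), function(i) {
      t <- seq(0, 1, length.out = ns[i] + 1L)[-(ns[i] + 1L)]
      cbind(p[i, 1] + t * seg[i, 1], p[i, 2] + t * seg[i, 2],
            p[i, 3] + t * seg[i, 3])
    })
    rbind(do.call(rbind, pieces), p[n, , drop = FALSE])
  })
  do.call(rbind, out)
}

# voxel index (0-based) containing each world point; voxels are half-open
# boxes around voxel centers at integer grid coordinates
points_to_voxels <- function(affine, pts) {
  ijk <- world_to_voxel(affine, pts)
  floor(ijk + 0.5)
}

#' Voxelize a tract into a binary label map
#'
#' Marks every voxel traversed by any fiber. Each segment is supersampled at
#' spacing at most half the smallest voxel dimension before marking, so
#' voxels crossed between stored points are not skipped.
#'
#' @param tract a tract.
#' @param reference list with `dims` (length-3 grid shape) and `affine`, or a
#'   [dwi_volume()] / [label_map()] to copy the grid from.
#' @param supersample_factor spacing divisor: samples are at most
#'   `min(voxel dims) / supersample_factor` apart. The default 20 matches
#'   the dense verification oracle; coarser spacing can hop over voxels a
#'   segment only clips at a corner.
#' @return A binary [label_map()] on the reference grid.
#' @export
voxelize_tract <- function(tract, reference, supersample_factor = 20) {
  ref <- as_reference_grid(reference)
  out <- array(0L, ref$dims)
  if (length(tract$streamlines)) {
    spacing <- min(voxel_dims(ref$affine)) / supersample_factor
    pts <- supersample_points(tract, spacing)
    ijk <- points_to_voxels(ref$affine, pts)
    keep <- ijk[, 1] >= 0 & ijk[, 2] >= 0 & ijk[, 3] >= 0 &
      ijk[, 1] < ref$dims[1] & ijk[, 2] < ref$dims[2] & ijk[, 3] < ref$dims[3]
    ijk <- ijk[keep, , drop = FALSE]
    out[unique(ijk[, 1] + ref$dims[1] * (ijk[, 2] + ref$dims[2] * ijk[, 3])) + 1L] <- 1L
  }
  label_map(out, ref$affine)
}

as_reference_grid <- function(reference) {
  if (inherits(reference, "dwi_volume"))
    list(dims = dim(reference$data)[1:3], affine = reference$affine)
  else if (inherits(reference, "label_map"))
    list(dims = dim(reference$data), affine = reference$affine)
  else if (is.list(reference) && !is.null(reference$dims))
    list(dims = as.integer(reference$dims), affine = as.matrix(reference$affine))
  else stop("cannot interpret reference grid")
}

#' Volume of a label map (mm^3)
#'
#' @param lm a [label_map()].
#' @return Count of nonzero voxels times the voxel volume.
#' @export
labelmap_volume <- function(lm) {
  sum(lm$data > 0) * lm$voxel_volume
}

#' Overlap volume of a tract label map and a mask (mm^3)
#'
#' The mask is resampled to the label map's grid by nearest neighbor when the
#' grids differ.
#'
#' @param tract_lm a [label_map()].
#' @param mask a [label_map()] / binary 3-D array on the same grid.
#' @return Volume of voxels nonzero in both.
#' @export
intersection_volume <- function(tract_lm, mask) {
  mask <- conform_mask(mask, tract_lm)
  sum(tract_lm$data > 0 & mask > 0) * tract_lm$voxel_volume
}

conform_mask <- function(mask, ref_lm) {
  if (inherits(mask, "label_map")) {
    if (identical(dim(mask$data), dim(ref_lm$data)) &&
        max(abs(mask$affine - ref_lm$affine)) < 1e-6) return(mask$data)
    return(resample_mask_nn(mask, dim(ref_lm$data), ref_lm$affine))
  }
  if (!identical(dim(as.array(mask)), dim(ref_lm$data)))
    stop("mask grid does not match; pass a label_map to enable resampling")
  as.array(mask)
}

# nearest-neighbor resampling of a mask onto a target grid via world space
resample_mask_nn <- function(mask_lm, dims, affine) {
  ijk <- as.matrix(expand.grid(0:(dims[1] - 1), 0:(dims[2] - 1),
                               0:(dims[3] - 1)))
  w <- voxel_to_world(affine, ijk)
  src <- points_to_voxels(mask_lm$affine, w)
  sd <- dim(mask_lm$data)
  ok <- src[, 1] >= 0 & src[, 2] >= 0 & src[, 3] >= 0 &
    src[, 1] < sd[1] & src[, 2] < sd[2] & src[, 3] < sd[3]
  out <- array(0, dims)
  out[ijk[ok, , drop = FALSE] + 1L] <-
    mask_lm$data[src[ok, , drop = FALSE] + 1L]
  out
}

#' Split a tract by mask traversal
#'
#' A fiber traverses the mask iff at least one supersampled point along it
#' falls in a nonzero mask voxel. The two outputs partition the input.
#'
#' @param tract a tract.
#' @param mask a [label_map()] (or 3-D array with attribute grid of the
#'   tract's reference) marking the region (e.g. segmented edema).
#' @param supersample_factor see [voxelize_tract()].
#' @return List with `traversing` and `non_traversing` tracts.
#' @export
split_by_mask <- function(tract, mask, supersample_factor = 20) {
  stopifnot(inherits(mask, "label_map"))
  spacing <- min(voxel_dims(mask$affine)) / supersample_factor
  d <- dim(mask$data)
  hits <- vapply(tract$streamlines, function(sl) {
    ijk <- points_to_voxels(mask$affine,
                            supersample_points(list(streamlines = list(sl)),
                                               spacing))
    ok <- ijk[, 1] >= 0 & ijk[, 2] >= 0 & ijk[, 3] >= 0 &
      ijk[, 1] < d[1] & ijk[, 2] < d[2] & ijk[, 3] < d[3]
    any(mask$data[ijk[ok, , drop = FALSE] + 1L] > 0)
  }, TRUE)
  trav <- tract; trav$streamlines <- tract$streamlines[hits]
  non <- tract; non$streamlines <- tract$streamlines[!hits]
  list(traversing = trav, non_traversing = non)
}

#' Mean per-point scalar of a tract
#'
#' @param tract a tract.
#' @param scalar scalar name (`"fa"` or `"fw"`).
#' @param weighting `"point"` (mean over all points of all fibers, default)
#'   or `"fiber"` (mean of per-fiber means).
#' @return The mean, or `NA` for an empty tract.
#' @export
mean_point_scalar <- function(tract, scalar = c("fw", "fa"),
                              weighting = c("point", "fiber")) {
  scalar <- match.arg(scalar)
  weighting <- match.arg(weighting)
  if (!length(tract$streamlines)) return(NA_real_)
  vals <- lapply(tract$streamlines, function(sl) {
    v <- sl[[scalar]]
    if (is.null(v)) stop("scalar '", scalar, "' missing from streamline")
    v
  })
  if (weighting == "point") mean(unlist(vals))
  else mean(vapply(vals, mean, 1.0))
}

#' Fiber count, length statistics and length histogram
#'
#' @param tract a tract.
#' @param bin_width_mm histogram bin width (mm).
#' @return List with `count`, `mean_length_mm`, `sd_length_mm`, `lengths_mm`,
#'   and `histogram` (`breaks`, `counts`); counts sum to the fiber count.
#' @export
fiber_stats <- function(tract, bin_width_mm = 10) {
  lens <- vapply(tract$streamlines, streamline_length, 1.0)
  n <- length(lens)
  if (n == 0L)
    return(list(count = 0L, mean_length_mm = NA_real_, sd_length_mm = NA_real_,
                lengths_mm = numeric(0),
                histogram = list(breaks = numeric(0), counts = integer(0))))
  breaks <- seq(0, bin_width_mm * ceiling(max(lens) / bin_width_mm + 1e-9),
                by = bin_width_mm)
  if (length(breaks) < 2L) breaks <- c(0, bin_width_mm)
  counts <- as.integer(table(cut(lens, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  list(count = n, mean_length_mm = mean(lens),
       sd_length_mm = if (n > 1L) stats::sd(lens) else NA_real_,
       lengths_mm = lens, histogram = list(breaks = breaks, counts = counts))
}

#' Volume-matched selection of a reduced stopping-FA threshold
#'
#' Given tract volumes produced by a sweep of stopping-FA thresholds, selects
#' the threshold whose volume is closest to a target volume (the free-water
#' arm's volume in the three-arm comparison); ties prefer the larger
#' (more conservative) threshold.
#'
#' @param volumes named numeric vector: names are thresholds, values mm^3.
#' @param target_volume target volume (mm^3).
#' @return The selected threshold (numeric).
#' @export
select_rfa_threshold <- function(volumes, target_volume) {
  if (!length(volumes)) stop("empty threshold/volume map")
  thr <- as.numeric(names(volumes))
  err <- abs(volumes - target_volume)
  best <- which(err == min(err))
  thr[best[which.max(thr[best])]]
}

#' Full quantification report of a tract
#'
#' @param tract a tract.
#' @param reference reference grid (see [voxelize_tract()]).
#' @param masks named list of [label_map()] masks (e.g. `edema = ...`).
#' @param bin_width_mm length-histogram bin width.
#' @return A `quant_report` list: tract voxel volume, per-mask intersection
#'   volumes, fiber count and length statistics, and per-mask traversing /
#'   non-traversing mean FW fractions.
#' @export
quantify_tract <- function(tract, reference, masks = list(),
                           bin_width_mm = 10) {
  lm <- voxelize_tract(tract, reference)
  fs <- fiber_stats(tract, bin_width_mm)
  inter <- lapply(masks, intersection_volume, tract_lm = lm)
  fw_split <- lapply(masks, function(m) {
    sp <- split_by_mask(tract, m)
    list(n_traversing = length(sp$traversing$streamlines),
         n_non_traversing = length(sp$non_traversing$streamlines),
         mean_fw_traversing = mean_point_scalar(sp$traversing, "fw"),
         mean_fw_non_traversing = mean_point_scalar(sp$non_traversing, "fw"))
  })
  structure(list(volume_mm3 = labelmap_volume(lm),
                 intersection_mm3 = inter,
                 fiber_count = fs$count,
                 mean_length_mm = fs$mean_length_mm,
                 sd_length_mm = fs$sd_length_mm,
                 histogram = fs$histogram,
                 fw_by_mask = fw_split,
                 label_map = lm), class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("tract volume: %.1f mm^3, %d fibers, mean length %.1f mm\n",
              x$volume_mm3, x$fiber_count, x$mean_length_mm))
  for (nm in names(x$intersection_mm3))
    cat(sprintf("  %s intersection: %.1f mm^3\n", nm, x$intersection_mm3[[nm]]))
  invisible(x)
}
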