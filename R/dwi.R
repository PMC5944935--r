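#' Construct a 4-D diffusion-weighted volume
#'
#' @param data 4-D numeric array indexed `(i, j, k, gradient)`, intensities
#'   `>= 0`; 4th-dimension length must match the gradient table.
#' @param affine invertible 4x4 matrix mapping 0-based voxel indices (voxel
#'   centers) to world mm (RAS).
#' @param gtab a [gradient_table()].
#' @return An object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, affine, gtab) {
  stopifnot(inherits(gtab, "gradient_table"))
  data <- as.array(data)
  if (length(dim(data)) != 4L) stop("data must be a 4-D array")
  if (dim(data)[4] != length(gtab$bvals))
    stop("4th dimension (", dim(data)[4], ") must equal gradient count (",
         length(gtab$bvals), ")")
  if (min(data) < 0) stop("intensities must be non-negative")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, affine = affine, gtab = gtab),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dwi_volume: %d x %d x %d grid, %d gradient volumes, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(sprintf("%.2f", voxel_dims(x$affine)), collapse = " x ")))
  invisible(x)
}

voxel_dims <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

world_to_voxel <- function(affine, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  t(solve(affine) %*% pts)[, 1:3, drop = FALSE]
}

voxel_to_world <- function(affine, ijk) {
  ijk <- rbind(t(as.matrix(ijk)), 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

#' Read a DWI volume from NIfTI + bval/bvec
#'
#' @param nifti_path a 4-D NIfTI-1 file (.nii or .nii.gz).
#' @param bval_path,bvec_path FSL-style gradient table files.
#' @return A [dwi_volume()]; the affine is taken from the NIfTI header.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nifti_path)
  gtab <- read_bvalbvec(bval_path, bvec_path)
  dwi_volume(as.array(img), matrix(as.numeric(RNifti::xform(img)), 4L, 4L),
             gtab)
}

#' Write a DWI volume as NIfTI + bval/bvec
#'
#' @param dwi a [dwi_volume()].
#' @param nifti_path,bval_path,bvec_path output paths.
#' @return Invisibly, `nifti_path`.
#' @export
write_dwi <- function(dwi, nifti_path, bval_path, bvec_path) {
  write_nifti_array(dwi$data, dwi$affine, nifti_path)
  write_bvalbvec(dwi$gtab, bval_path, bvec_path)
  invisible(nifti_path)
}

write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  vd <- voxel_dims(affine)
  img <- RNifti::asNifti(img, reference = NULL)
  RNifti::pixdim(img) <- c(vd, rep(1, length(dim(arr)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Baseline-normalize a DWI volume voxelwise
#'
#' Divides every gradient volume by the voxelwise mean of the baseline
#' (b = 0) volumes, flooring the baseline at a small positive value.
#'
#' @param dwi a [dwi_volume()].
#' @param floor baseline floor (absolute intensity).
#' @return 4-D array of normalized signals.
#' @export
normalize_dwi <- function(dwi, floor = 1e-8) {
  b0 <- dwi$data[, , , dwi$gtab$b0, drop = FALSE]
  s0 <- apply(b0, 1:3, mean)
  s0[s0 < floor] <- floor
  sweep(dwi$data, 1:3, s0, `/`)
}

#' Voxelwise single-tensor FA map
#'
#' Fits the log-linear single-tensor model in every voxel of `mask` (fully
#' vectorized) and returns the fractional anisotropy map used for seeding.
#'
#' @param dwi a [dwi_volume()].
#' @param mask optional 3-D logical/numeric array; default all voxels.
#' @param clamp_floor signal floor before the log.
#' @return 3-D array of FA values (0 outside the mask).
#' @export
fa_map <- function(dwi, mask = NULL, clamp_floor = 1e-8) {
  d <- dim(dwi$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  idx <- which(mask > 0)
  w <- dwi$gtab$bvals > 0
  B <- tensor_design(dwi$gtab$bvecs[w, , drop = FALSE], dwi$gtab$bvals[w])
  Binv <- solve(crossprod(B), t(B))             # 6 x ngrad
  norm <- normalize_dwi(dwi)
  sig <- matrix(aperm(norm, c(4L, 1L, 2L, 3L)), nrow = d[4])[w, idx,
                                                             drop = FALSE]
  sig <- pmax(sig, clamp_floor)
  Dv <- -Binv %*% log(sig)                      # rows: xx yy zz xy xz yz
  md <- colMeans(Dv[1:3, , drop = FALSE])
  dev2 <- (Dv[1, ] - md)^2 + (Dv[2, ] - md)^2 + (Dv[3, ] - md)^2 +
    2 * (Dv[4, ]^2 + Dv[5, ]^2 + Dv[6, ]^2)
  nf2 <- Dv[1, ]^2 + Dv[2, ]^2 + Dv[3, ]^2 +
    2 * (Dv[4, ]^2 + Dv[5, ]^2 + Dv[6, ]^2)
  fa <- ifelse(nf2 > 0, pmin(1, sqrt(1.5 * dev2 / nf2)), 0)
  out <- array(0, d[1:3])
  out[idx] <- fa
  out
}

#' Interpolate baseline-normalized signals at a world position
#'
#' Trilinear interpolation of every gradient volume at a continuous position,
#' divided by the interpolated baseline mean.
#'
#' @param dwi a [dwi_volume()].
#' @param pos world-mm 3-vector.
#' @param floor baseline floor.
#' @return Normalized signal vector, or all-`NA` when `pos` falls outside the
#'   grid (the out-of-bounds signal; callers stop tracking on it).
#' @export
interpolate_signals <- function(dwi, pos, floor = 1e-8) {
  ijk <- as.numeric(world_to_voxel(dwi$affine, matrix(pos, 1L)))
  raw <- as.numeric(.interp_signals_cpp(dwi$data, dim(dwi$data), ijk))
  if (anyNA(raw)) return(raw)
  s0 <- mean(raw[dwi$gtab$b0])
  raw / max(s0, floor)
}
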