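#' Read a 3-D binary mask or label map from NIfTI
#'
#' @param path NIfTI-1 file.
#' @param binarize if `TRUE` (default), nonzero voxels become 1. Values
#'   strictly between 0 and 1 (probabilistic maps) are rejected.
#' @return A [label_map()].
#' @export
read_mask <- function(path, binarize = TRUE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L)
    stop("mask must be 3-D, got ", length(dim(arr)), "-D")
  frac <- arr[arr > 0 & arr < 1]
  if (length(frac))
    stop("mask contains fractional values in (0,1); threshold it first ",
         "(e.g. mask >= 0.5) to obtain a binary mask")
  if (binarize) arr <- (arr != 0) * 1L
  label_map(arr, matrix(as.numeric(RNifti::xform(img)), 4L, 4L))
}

#' Write a mask or label map as NIfTI
#'
#' @param lm a [label_map()] or 3-D array (with `affine`).
#' @param path output path.
#' @param affine required when `lm` is a bare array.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(lm, path, affine = NULL) {
  if (inherits(lm, "label_map")) {
    arr <- lm$data
    affine <- lm$affine
  } else {
    arr <- as.array(lm)
    if (is.null(affine)) stop("affine required for a bare array")
  }
  write_nifti_array(arr * 1L, affine, path)
  invisible(path)
}

# Short stable digest of a configuration (polynomial rolling hash over its
# serialization); used to tag outputs so runs can be matched to settings.
config_digest <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# JSON sidecar recording provenance for a primary output file.
write_sidecar <- function(path, config, extra = list()) {
  side <- paste0(path, ".json")
  meta <- c(list(software = "fwtract",
                 version = as.character(utils::packageVersion("fwtract")),
                 config_digest = config_digest(config)),
            extra)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}
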