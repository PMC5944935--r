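#' Cylindrically symmetric tensor compartment
#'
#' A tissue compartment is a cylindrically symmetric diffusion tensor with
#' eigenvalues `(lambda1, lambda2, lambda2)` and principal direction `m`.
#'
#' @param m principal direction, a unit 3-vector (sign irrelevant).
#' @param lambda1 axial diffusivity (mm^2/s).
#' @param lambda2 radial diffusivity (mm^2/s), `lambda1 >= lambda2 > 0`.
#' @param lambda_min lower diffusivity bound enforced on both eigenvalues.
#' @return An object of class `tensor_compartment`.
#' @export
tensor_compartment <- function(m, lambda1, lambda2, lambda_min = 1e-4) {
  m <- as.numeric(m)
  if (length(m) != 3L || any(!is.finite(m)))
    stop("invalid compartment: m must be a finite 3-vector")
  nrm <- sqrt(sum(m^2))
  if (abs(nrm - 1) > 1e-8) {
    if (nrm < 1e-12) stop("invalid compartment: zero direction")
    m <- m / nrm
  }
  if (!is.finite(lambda1) || !is.finite(lambda2) ||
      lambda2 < lambda_min || lambda1 < lambda2)
    stop("invalid compartment: need lambda1 >= lambda2 >= ", lambda_min)
  structure(list(m = m, lambda1 = lambda1, lambda2 = lambda2),
            class = "tensor_compartment")
}

#' The 3x3 diffusion tensor implied by a compartment
#'
#' @param c a [tensor_compartment()].
#' @return Symmetric positive-definite 3x3 matrix
#'   `lambda2 * I + (lambda1 - lambda2) * m %o% m` (mm^2/s).
#' @export
compartment_tensor <- function(c) {
  if (!inherits(c, "tensor_compartment")) c <- do.call(tensor_compartment, c)
  diag(3L) * c$lambda2 + (c$lambda1 - c$lambda2) * tcrossprod(c$m)
}

#' Multi-tensor model state
#'
#' The per-step model carried by the tracker: one or two tissue compartments
#' plus, for free-water models, the fractional signal volume of an isotropic
#' free-water compartment with fixed diffusivity.
#'
#' @param compartments list of 1 or 2 [tensor_compartment()] objects.
#' @param fw_fraction free-water signal fraction in `[0, 1]`, or `NULL` for
#'   models without a free-water compartment.
#' @param fw_diffusivity isotropic free-water diffusivity (mm^2/s); fixed,
#'   never estimated. Default 3.0e-3 (free water at body temperature).
#' @return An object of class `model_state`.
#' @export
model_state <- function(compartments, fw_fraction = NULL,
                        fw_diffusivity = 3.0e-3) {
  if (inherits(compartments, "tensor_compartment"))
    compartments <- list(compartments)
  if (!length(compartments) %in% 1:2)
    stop("model state needs 1 or 2 tissue compartments")
  compartments <- lapply(compartments, function(c)
    if (inherits(c, "tensor_compartment")) c else do.call(tensor_compartment, c))
  if (!is.null(fw_fraction)) {
    if (!is.finite(fw_fraction) || fw_fraction < 0 || fw_fraction > 1)
      stop("fw_fraction must lie in [0, 1]")
  }
  structure(list(compartments = compartments, fw_fraction = fw_fraction,
                 fw_diffusivity = fw_diffusivity),
            class = "model_state")
}

# Pack a model_state into the filter's flat state vector.
pack_state <- function(state) {
  x <- unlist(lapply(state$compartments, function(c)
    c(c$m, c$lambda1, c$lambda2)), use.names = FALSE)
  if (!is.null(state$fw_fraction)) x <- c(x, state$fw_fraction)
  x
}

unpack_state <- function(x, nc, has_fw, fw_diffusivity = 3.0e-3) {
  comps <- lapply(seq_len(nc) - 1L, function(c)
    tensor_compartment(x[5 * c + 1:3], x[5 * c + 4], x[5 * c + 5]))
  model_state(comps, fw_fraction = if (has_fw) x[5 * nc + 1] else NULL,
              fw_diffusivity = fw_diffusivity)
}

#' Predict the normalized diffusion signal of a model state
#'
#' Each entry is `(1 - f) * mean_i exp(-b * g' D_i g) + f * exp(-b * d_fw)`,
#' the mean taken over the tissue compartments (equal tissue weights) and `f`
#' the free-water fraction (0 for models without a free-water compartment).
#'
#' @param state a [model_state()].
#' @param gtab a [gradient_table()].
#' @return Numeric vector of normalized signals in `(0, 1]`, one per entry.
#' @export
predict_signal <- function(state, gtab) {
  stopifnot(inherits(state, "model_state"), inherits(gtab, "gradient_table"))
  has_fw <- !is.null(state$fw_fraction)
  as.numeric(.predict_signal_cpp(pack_state(state),
                                 length(state$compartments), has_fw,
                                 0, state$fw_diffusivity,
                                 gtab$bvals, gtab$bvecs))
}

#' Fractional anisotropy of a cylindrically symmetric tensor
#'
#' @param lambda1,lambda2 axial and radial diffusivities,
#'   `lambda1 >= lambda2 >= 0`, not both zero. Vectorized.
#' @return `|lambda1 - lambda2| / sqrt(lambda1^2 + 2 lambda2^2)` in `[0, 1]`.
#' @export
fa_cylindrical <- function(lambda1, lambda2) {
  den <- sqrt(lambda1^2 + 2 * lambda2^2)
  if (any(den == 0)) stop("FA undefined for an all-zero tensor")
  abs(lambda1 - lambda2) / den
}

#' Fractional anisotropy of a general symmetric tensor
#'
#' Uses the rotation-invariant form
#' `FA = sqrt(3/2) * ||D - tr(D)/3 I||_F / ||D||_F`, equal to the standard
#' three-eigenvalue formula.
#'
#' @param D symmetric 3x3 tensor.
#' @return FA in `[0, 1]`.
#' @export
fa_general <- function(D) {
  D <- as.matrix(D)
  if (any(abs(D - t(D)) > 1e-8 * max(abs(D), 1e-30)))
    stop("D must be symmetric")
  nf2 <- sum(D^2)
  if (nf2 == 0) stop("FA undefined for an all-zero tensor")
  md <- sum(diag(D)) / 3
  dev2 <- sum((D - diag(3L) * md)^2)
  min(1, sqrt(1.5 * dev2 / nf2))
}

#' Log-linear least-squares single-tensor fit
#'
#' Fits one diffusion tensor to baseline-normalized signals by ordinary least
#' squares on `log(S_k) = -b g_k' D g_k`. Non-positive signals are clamped to
#' `clamp_floor` (with a warning) before taking logs.
#'
#' @param signals baseline-normalized signal vector, one entry per gradient.
#' @param gtab a [gradient_table()].
#' @param clamp_floor positive floor applied to the signals.
#' @return Symmetric 3x3 tensor (mm^2/s).
#' @export
fit_single_tensor <- function(signals, gtab, clamp_floor = 1e-8) {
  stopifnot(inherits(gtab, "gradient_table"))
  if (length(signals) != length(gtab$bvals))
    stop("signal/gradient count mismatch")
  w <- gtab$bvals > 0
  if (sum(w) < 6L) stop("need at least 6 non-baseline gradients")
  s <- signals[w]
  if (any(s <= clamp_floor)) {
    warning("non-positive or tiny signals clamped to floor before log-fit")
    s <- pmax(s, clamp_floor)
  }
  B <- tensor_design(gtab$bvecs[w, , drop = FALSE], gtab$bvals[w])
  if (qr(B)$rank < 6L) stop("rank-deficient gradient design; fit failed")
  d <- qr.solve(B, -log(s))
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3L, 3L)
}

# Design matrix rows: b * (gx^2, gy^2, gz^2, 2gxgy, 2gxgz, 2gygz)
tensor_design <- function(bvecs, bvals) {
  g <- bvecs
  bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

#' Mean (or summed) normalized signal across gradient directions
#'
#' The tracker's secondary stopping scalar: the average of the
#' baseline-normalized signal over the diffusion-weighted directions, used to
#' separate white/gray matter from CSF-like regions.
#'
#' @param signals baseline-normalized signal vector.
#' @param gtab a [gradient_table()].
#' @param stat `"mean"` (default) or `"sum"` over non-baseline entries.
#' @return A non-negative scalar.
#' @export
mean_normalized_signal <- function(signals, gtab, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  w <- gtab$bvals > 0
  if (!any(w)) stop("no non-baseline gradient entries")
  if (stat == "mean") mean(signals[w]) else sum(signals[w])
}
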