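#' Tracker configuration
#'
#' All tunable parameters of the unscented-Kalman-filter streamline tracker.
#' The threshold defaults reproduce the emulated clinical protocol: seeding
#' where single-tensor FA > 0.18 with 20 seeds per voxel; stopping where the
#' tracked compartment's FA falls below 0.15 or the normalized average signal
#' falls below 0.08.
#'
#' @param model `"2t"` (two-tensor), `"2t-fw"` (two-tensor plus free-water
#'   compartment) or `"1t"` (single tensor).
#' @param seeding_fa single-tensor FA threshold for seed voxels.
#' @param seeds_per_voxel seeds per eligible voxel.
#' @param stopping_fa tracked-compartment FA stopping threshold.
#' @param stopping_signal normalized average signal stopping threshold.
#' @param signal_stat `"mean"` or `"sum"` of the normalized signal across
#'   diffusion directions for the stopping scalar.
#' @param step_size_mm Euler step length (mm).
#' @param max_length_mm,min_length_mm streamline length bounds (mm).
#' @param q_dir,q_diff,q_fw process-noise variances per step for direction
#'   components, diffusivities and FW fraction.
#' @param r_meas measurement-noise standard deviation per gradient.
#' @param p0_dir,p0_diff,p0_fw initial covariance diagonal entries.
#' @param alpha,beta,kappa scaled unscented-transform parameters.
#' @param fw_init initial FW fraction of the filter state.
#' @param pin_fw if `TRUE` (with `model = "2t-fw"`), the FW fraction is held
#'   fixed at `fw_init` instead of being estimated (it is removed from the
#'   state vector, so `pin_fw` with `fw_init = 0` is exactly the 2T model).
#' @param fw_diffusivity fixed free-water diffusivity (mm^2/s).
#' @param lambda_min diffusivity floor (mm^2/s).
#' @param rng_seed integer seed for seed-point jitter.
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(model = c("2t-fw", "2t", "1t"),
                           seeding_fa = 0.18, seeds_per_voxel = 20L,
                           stopping_fa = 0.15, stopping_signal = 0.08,
                           signal_stat = c("mean", "sum"),
                           step_size_mm = 0.9, max_length_mm = 250,
                           min_length_mm = 10,
                           q_dir = 1e-4, q_diff = 1e-9, q_fw = 1e-3,
                           r_meas = 0.02,
                           p0_dir = 1e-2, p0_diff = 1e-7, p0_fw = 2.5e-2,
                           alpha = 1e-3, beta = 2, kappa = 0,
                           fw_init = 0.1, pin_fw = FALSE,
                           fw_diffusivity = 3.0e-3, lambda_min = 1e-4,
                           rng_seed = 1L) {
  model <- match.arg(model)
  signal_stat <- match.arg(signal_stat)
  if (stopping_fa > seeding_fa)
    stop("stopping_fa must not exceed seeding_fa")
  if (stopping_fa < 0 || stopping_signal < 0) stop("thresholds must be >= 0")
  if (step_size_mm <= 0) stop("step_size_mm must be positive")
  if (seeds_per_voxel < 1L) stop("seeds_per_voxel must be >= 1")
  structure(list(model = model, seeding_fa = seeding_fa,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 stopping_fa = stopping_fa, stopping_signal = stopping_signal,
                 signal_stat = signal_stat, step_size_mm = step_size_mm,
                 max_length_mm = max_length_mm, min_length_mm = min_length_mm,
                 q_dir = q_dir, q_diff = q_diff, q_fw = q_fw, r_meas = r_meas,
                 p0_dir = p0_dir, p0_diff = p0_diff, p0_fw = p0_fw,
                 alpha = alpha, beta = beta, kappa = kappa,
                 fw_init = fw_init, pin_fw = pin_fw,
                 fw_diffusivity = fw_diffusivity, lambda_min = lambda_min,
                 rng_seed = as.integer(rng_seed)),
            class = "tracker_config")
}

# filter dimensions implied by the model choice
config_model <- function(config) {
  nc <- if (config$model == "1t") 1L else 2L
  has_fw <- config$model == "2t-fw" && !config$pin_fw
  fw_const <- if (config$model == "2t-fw" && config$pin_fw) config$fw_init else 0
  list(nc = nc, has_fw = has_fw, fw_const = fw_const,
       n = 5L * nc + as.integer(has_fw))
}

config_qdiag <- function(config) {
  cm <- config_model(config)
  q <- rep(c(config$q_dir, config$q_dir, config$q_dir,
             config$q_diff, config$q_diff), cm$nc)
  if (cm$has_fw) q <- c(q, config$q_fw)
  q
}

config_p0 <- function(config) {
  cm <- config_model(config)
  p <- rep(c(config$p0_dir, config$p0_dir, config$p0_dir,
             config$p0_diff, config$p0_diff), cm$nc)
  if (cm$has_fw) p <- c(p, config$p0_fw)
  diag(p)
}

cpp_config <- function(config, gtab) {
  cm <- config_model(config)
  list(nc = cm$nc, has_fw = cm$has_fw, fw_const = cm$fw_const,
       d_fw = config$fw_diffusivity, lambda_min = config$lambda_min,
       q_diag = config_qdiag(config), r_meas = config$r_meas^2,
       alpha = config$alpha, beta = config$beta, kappa = config$kappa,
       bvals = gtab$bvals, dirs = gtab$bvecs,
       step_mm = config$step_size_mm, stopping_fa = config$stopping_fa,
       stopping_signal = config$stopping_signal,
       signal_sum = config$signal_stat == "sum",
       max_steps = as.integer(ceiling(config$max_length_mm /
                                        config$step_size_mm)))
}

#' Initialize the filter state at a seed position
#'
#' Fits a single tensor to the interpolated signals at `pos`; its principal
#' direction and eigenvalues are copied into every tissue compartment, and
#' the FW fraction (when estimated) starts at `fw_init`.
#'
#' @param dwi a [dwi_volume()].
#' @param pos world-mm seed position.
#' @param config a [tracker_config()].
#' @return List with `state` (a [model_state()]), `covariance`, and `dir`
#'   (the principal direction), or `NULL` when the fit fails.
#' @export
init_state <- function(dwi, pos, config) {
  sig <- interpolate_signals(dwi, pos)
  if (anyNA(sig)) return(NULL)
  D <- tryCatch(suppressWarnings(fit_single_tensor(sig, dwi$gtab)),
                error = function(e) NULL)
  if (is.null(D)) return(NULL)
  e <- eigen(D, symmetric = TRUE)
  cm <- config_model(config)
  # the single-tensor fit absorbs the FW signal fraction into inflated
  # eigenvalues; deflate so the initial state predicts the fitted signal
  defl <- if (cm$has_fw && config$fw_init > 0 && config$fw_init < 1)
    log(1 / (1 - config$fw_init)) / max(dwi$gtab$bvals) else 0
  l1 <- max(e$values[1] - defl, config$lambda_min * 2)
  l2 <- min(max(mean(e$values[2:3]) - defl, config$lambda_min), l1)
  comp <- tensor_compartment(e$vectors[, 1], l1, l2,
                             lambda_min = config$lambda_min)
  state <- model_state(rep(list(comp), cm$nc),
                       fw_fraction = if (cm$has_fw) config$fw_init,
                       fw_diffusivity = config$fw_diffusivity)
  list(state = state, covariance = config_p0(config), dir = e$vectors[, 1])
}

#' One unscented Kalman filter predict/update cycle
#'
#' Propagates the state through the identity process model (plus process
#' noise) and updates it against a measured normalized signal vector using
#' the scaled unscented transform, followed by constraint projection
#' (directions renormalized, eigenvalues ordered and floored, FW fraction
#' clamped to `[0, 1]`) and covariance repair (symmetrize, clamp negative
#' eigenvalues).
#'
#' @param state a [model_state()].
#' @param covariance state covariance matrix.
#' @param measured normalized signal vector (one entry per gradient).
#' @param gtab a [gradient_table()].
#' @param config a [tracker_config()].
#' @return List with updated `state` and `covariance`.
#' @export
ukf_update <- function(state, covariance, measured, gtab, config) {
  if (any(!is.finite(measured))) stop("non-finite measurement vector")
  cm <- config_model(config)
  res <- .ukf_update_cpp(pack_state(state), covariance, measured,
                         cm$nc, cm$has_fw, cm$fw_const,
                         config$fw_diffusivity, config$lambda_min,
                         config_qdiag(config), config$r_meas^2,
                         config$alpha, config$beta, config$kappa,
                         gtab$bvals, gtab$bvecs)
  if (!res$ok) stop("covariance repair failed; tracking aborted")
  list(state = unpack_state(res$x, cm$nc, cm$has_fw, config$fw_diffusivity),
       covariance = res$P)
}

#' Select the compartment to follow
#'
#' Returns the tissue compartment whose principal direction is most aligned
#' with the previous tracking direction, sign-oriented along it.
#'
#' @param state a [model_state()].
#' @param prev_dir unit 3-vector previous direction.
#' @return List with `index` and oriented unit `direction`.
#' @export
choose_tracked_compartment <- function(state, prev_dir) {
  res <- .choose_compartment_cpp(pack_state(state),
                                 length(state$compartments),
                                 as.numeric(prev_dir))
  list(index = res$index, direction = as.numeric(res$direction))
}

#' Propagate one streamline from a seed
#'
#' Tracks bidirectionally: each half re-initializes the filter at the seed
#' and takes Euler steps of `step_size_mm` along the tracked compartment's
#' direction after each filter update. A half stops when the tracked
#' compartment's FA falls below `stopping_fa`, the normalized average signal
#' falls below `stopping_signal`, the position leaves the brain mask or grid,
#' or `max_length_mm` is reached. The two halves are joined at the seed.
#'
#' @param dwi a [dwi_volume()].
#' @param seed world-mm seed position.
#' @param config a [tracker_config()].
#' @param brain_mask 3-D array (nonzero = inside); default whole grid.
#' @return A `streamline` (list with `points` matrix and per-point `fa`,
#'   `fw`, `signal` vectors), or `NULL` when rejected (shorter than
#'   `min_length_mm` or failed initialization).
#' @export
propagate_streamline <- function(dwi, seed, config, brain_mask = NULL) {
  if (is.null(brain_mask)) brain_mask <- array(1, dim(dwi$data)[1:3])
  init <- init_state(dwi, seed, config)
  if (is.null(init)) return(NULL)
  run <- list(ccfg = cpp_config(config, dwi$gtab),
              inv_aff = solve(dwi$affine),
              mask = array(as.double(brain_mask), dim(brain_mask)))
  propagate_from_init(dwi, seed, pack_state(init$state), init$covariance,
                      init$dir, run, config)
}

# bidirectional propagation given a packed initial state; `run` carries
# per-run precomputed pieces so whole-volume tracking avoids rebuilding them
propagate_from_init <- function(dwi, seed, x0, P0, dir0, run, config) {
  halves <- lapply(list(dir0, -dir0), function(d0)
    .propagate_half_cpp(dwi$data, dim(dwi$data), run$inv_aff, run$mask,
                        as.numeric(seed), as.numeric(d0), x0, P0, run$ccfg))
  n1 <- nrow(halves[[1]]$points); n2 <- nrow(halves[[2]]$points)
  if (n1 + n2 < 2L) return(NULL)
  rev2 <- if (n2 > 1L) rev(seq_len(n2)[-1L]) else integer(0)
  pts <- rbind(halves[[2]]$points[rev2, , drop = FALSE],
               halves[[1]]$points)
  sl <- structure(list(
    points = pts,
    fa = c(halves[[2]]$fa[rev2], halves[[1]]$fa),
    fw = c(halves[[2]]$fw[rev2], halves[[1]]$fw),
    signal = c(halves[[2]]$signal[rev2], halves[[1]]$signal),
    stop_reasons = c(backward = halves[[2]]$reason,
                     forward = halves[[1]]$reason),
    step_size_mm = config$step_size_mm), class = "streamline")
  if (streamline_length(sl) < config$min_length_mm) return(NULL)
  sl
}

# vectorized filter initialization for many seed positions: one interpolation
# sweep, one log-linear tensor fit, then a per-seed 3x3 eigendecomposition.
# Returns packed state vectors (rows; NA row = failed seed) and directions.
batch_init <- function(dwi, seeds, config) {
  cm <- config_model(config)
  ijk <- world_to_voxel(dwi$affine, seeds)
  raw <- .interp_many_cpp(dwi$data, dim(dwi$data), ijk)
  s0 <- rowMeans(raw[, dwi$gtab$b0, drop = FALSE])
  ok <- !is.na(s0) & s0 > 0
  w <- dwi$gtab$bvals > 0
  B <- tensor_design(dwi$gtab$bvecs[w, , drop = FALSE], dwi$gtab$bvals[w])
  Binv <- solve(crossprod(B), t(B))
  defl <- if (cm$has_fw && config$fw_init > 0 && config$fw_init < 1)
    log(1 / (1 - config$fw_init)) / max(dwi$gtab$bvals) else 0
  n <- nrow(seeds)
  x0 <- matrix(NA_real_, n, cm$n)
  dir0 <- matrix(NA_real_, n, 3L)
  sig <- pmax(raw[, w, drop = FALSE] / pmax(s0, 1e-12), 1e-8)
  Dv <- -log(sig) %*% t(Binv)
  for (i in which(ok)) {
    d <- Dv[i, ]
    e <- eigen(matrix(c(d[1], d[4], d[5], d[4], d[2], d[6],
                        d[5], d[6], d[3]), 3L, 3L), symmetric = TRUE)
    l1 <- max(e$values[1] - defl, config$lambda_min * 2)
    l2 <- min(max(mean(e$values[2:3]) - defl, config$lambda_min), l1)
    x <- rep(c(e$vectors[, 1], l1, l2), cm$nc)
    if (cm$has_fw) x <- c(x, config$fw_init)
    x0[i, ] <- x
    dir0[i, ] <- e$vectors[, 1]
  }
  list(x0 = x0, dir0 = dir0, ok = ok)
}

#' @export
print.streamline <- function(x, ...) {
  cat(sprintf("streamline: %d points, %.1f mm\n", nrow(x$points),
              streamline_length(x)))
  invisible(x)
}

#' Length of a streamline (mm)
#' @param sl a streamline.
#' @return Sum of consecutive point distances.
#' @export
streamline_length <- function(sl) {
  p <- sl$points
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Whole-volume tractography
#'
#' Seeds `seeds_per_voxel` positions, uniformly jittered inside every brain
#' mask voxel whose single-tensor FA exceeds `seeding_fa`, and propagates a
#' streamline from each. Jitter is drawn from `config$rng_seed` in voxel
#' raster order, so results are reproducible and independent of execution
#' order.
#'
#' @param dwi a [dwi_volume()].
#' @param brain_mask 3-D array (nonzero = inside); default whole grid.
#' @param config a [tracker_config()].
#' @return An object of class `tract`: list of streamlines plus provenance.
#' @export
track_whole_volume <- function(dwi, brain_mask = NULL, config = tracker_config()) {
  d <- dim(dwi$data)[1:3]
  if (is.null(brain_mask)) brain_mask <- array(1, d)
  if (!any(brain_mask > 0)) {
    warning("empty brain mask; returning empty tract")
    return(new_tract(list(), config, "empty mask"))
  }
  fa <- fa_map(dwi, brain_mask)
  eligible <- which(fa > config$seeding_fa & brain_mask > 0)  # raster order
  if (!length(eligible)) {
    warning("no voxels exceed the seeding FA threshold; empty tract")
    return(new_tract(list(), config, "no eligible voxels"))
  }
  nseed <- length(eligible) * config$seeds_per_voxel
  jit <- with_seed(config$rng_seed,
                   matrix(stats::runif(3L * nseed) - 0.5, nseed, 3L))
  ijk <- arrayInd(eligible, d) - 1L
  ijk <- ijk[rep(seq_len(nrow(ijk)), each = config$seeds_per_voxel), ,
             drop = FALSE] + jit
  seeds <- voxel_to_world(dwi$affine, ijk)
  run <- list(ccfg = cpp_config(config, dwi$gtab),
              inv_aff = solve(dwi$affine),
              mask = array(as.double(brain_mask), dim(brain_mask)))
  init <- batch_init(dwi, seeds, config)
  streamlines <- vector("list", nseed)
  for (s in which(init$ok)) {
    streamlines[[s]] <- propagate_from_init(dwi, seeds[s, ], init$x0[s, ],
                                            config_p0(config),
                                            init$dir0[s, ], run, config)
  }
  streamlines <- streamlines[!vapply(streamlines, is.null, TRUE)]
  new_tract(streamlines, config,
            sprintf("%d seeds in %d voxels", nseed, length(eligible)))
}

new_tract <- function(streamlines, config, seed_desc) {
  structure(list(streamlines = streamlines,
                 provenance = list(model = config$model,
                                   config = unclass(config),
                                   seeds = seed_desc,
                                   version = as.character(
                                     utils::packageVersion("fwtract")))),
            class = "tract")
}

#' @export
print.tract <- function(x, ...) {
  n <- length(x$streamlines)
  cat(sprintf("tract: %d streamlines (model %s)\n", n,
              x$provenance$model %||% "?"))
  invisible(x)
}

#' Number of streamlines in a tract
#' @param x a tract.
#' @export
length.tract <- function(x) length(x$streamlines)

`%||%` <- function(a, b) if (is.null(a)) b else a
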