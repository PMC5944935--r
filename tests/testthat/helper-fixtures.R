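# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately coded independently of the package internals they check.

protocol_31 <- function() make_protocol(30L, 2000, 1L)

# random valid model states for property sweeps
random_state <- function(nc = 2L, fw = NULL) {
  m <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  comps <- replicate(nc, {
    l <- sort(stats::runif(2, 2e-4, 2.5e-3), decreasing = TRUE)
    tensor_compartment(m(), l[1], l[2])
  }, simplify = FALSE)
  model_state(comps, fw_fraction = fw)
}

# analytic mean of a Rician with true amplitude nu and noise sigma
rician_mean_analytic <- function(nu, sigma) {
  x <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}

# dense-sampling voxelization oracle: sample each segment at `spacing`,
# mark containing voxels (independent reimplementation)
dense_voxel_oracle <- function(streamlines, dims, affine, spacing) {
  inv <- solve(affine)
  seen <- array(FALSE, dims)
  for (sl in streamlines) {
    p <- sl$points
    for (i in seq_len(nrow(p) - 1)) {
      len <- sqrt(sum((p[i + 1, ] - p[i, ])^2))
      nstep <- max(2L, ceiling(len / spacing) + 1L)
      for (t in seq(0, 1, length.out = nstep)) {
        q <- (1 - t) * p[i, ] + t * p[i + 1, ]
        ijk <- floor((inv %*% c(q, 1))[1:3] + 0.5)
        if (all(ijk >= 0) && all(ijk < dims))
          seen[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1] <- TRUE
      }
    }
  }
  seen
}

# smooth random curved fibers inside a given grid, for quantification tests
random_curved_fibers <- function(n, dims, voxel_mm, n_pts = 40) {
  lapply(seq_len(n), function(i) {
    start <- stats::runif(3, 0.2, 0.8) * (dims - 1) * voxel_mm
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pts <- matrix(0, n_pts, 3)
    pts[1, ] <- start
    for (k in 2:n_pts) {
      dir <- dir + stats::rnorm(3, 0, 0.25)
      dir <- dir / sqrt(sum(dir^2))
      pts[k, ] <- pts[k - 1, ] + dir * 1.2
    }
    lim <- (dims - 1) * voxel_mm
    pts[, 1] <- pmin(pmax(pts[, 1], 0), lim[1])
    pts[, 2] <- pmin(pmax(pts[, 2], 0), lim[2])
    pts[, 3] <- pmin(pmax(pts[, 3], 0), lim[3])
    structure(list(points = pts, fa = rep(0.5, n_pts),
                   fw = stats::runif(n_pts)), class = "streamline")
  })
}

as_tract <- function(streamlines) {
  structure(list(streamlines = streamlines, provenance = list()),
            class = "tract")
}

# small noise-free single-bundle phantom shared by tracking tests
tiny_bundle_dwi <- function(snr = Inf, edema = FALSE, rng_seed = 1L) {
  ph <- default_edema_phantom(snr = snr, edema = edema,
                              grid = c(28L, 10L, 10L), bundle_radius_mm = 2.5,
                              rng_seed = rng_seed)
  field <- build_field(ph)
  list(spec = ph, field = field,
       dwi = synthesize_dwi(field, protocol_31(), ph))
}
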