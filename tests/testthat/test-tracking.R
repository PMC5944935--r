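test_that("signal interpolation matches a reference interpolator", {
  fx <- tiny_bundle_dwi(snr = Inf)
  dwi <- fx$dwi
  vox <- fx$spec$voxel_mm
  # voxel center returns that voxel's normalized values exactly
  i <- c(10, 4, 4)
  ref <- dwi$data[i[1] + 1, i[2] + 1, i[3] + 1, ]
  got <- interpolate_signals(dwi, i * vox)
  expect_equal(got, ref / ref[1], tolerance = 1e-12)
  # midway between two centers along x: arithmetic mean of the two
  raw2 <- dwi$data[i[1] + 2, i[2] + 1, i[3] + 1, ]
  mid <- interpolate_signals(dwi, (i + c(0.5, 0, 0)) * vox)
  mref <- (ref + raw2) / 2
  expect_equal(mid, mref / mean(mref[1]), tolerance = 1e-12)
  # random positions against an independent trilinear implementation
  set.seed(4)
  for (k in 1:20) {
    p <- stats::runif(3, 1, c(26, 8, 8)) * vox
    ijk <- p / vox
    f0 <- floor(ijk); fr <- ijk - f0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      acc <- acc + w * dwi$data[f0[1] + dx + 1, f0[2] + dy + 1,
                                f0[3] + dz + 1, ]
    }
    expect_equal(interpolate_signals(dwi, p), acc / mean(acc[1]),
                 tolerance = 1e-10)
  }
  # outside the grid: out-of-bounds signal
  expect_true(all(is.na(interpolate_signals(dwi, c(-50, 0, 0)))))
})

test_that("seed initialization copies the single-tensor fit into the state", {
  fx <- tiny_bundle_dwi(snr = Inf)
  ctr <- (fx$spec$grid - 1) / 2 * fx$spec$voxel_mm
  cfg <- tracker_config(model = "2t-fw")
  init <- init_state(fx$dwi, ctr, cfg)
  expect_length(init$state$compartments, 2L)
  for (c in init$state$compartments) {
    ang <- acos(min(1, abs(c$m[1]))) * 180 / pi
    expect_lt(ang, 5)
  }
  expect_identical(init$state$fw_fraction, cfg$fw_init)
  expect_equal(dim(init$covariance), c(11L, 11L))
  # out-of-volume seed fails gracefully
  expect_null(init_state(fx$dwi, c(-100, 0, 0), cfg))
})

test_that("filter updates converge to a crossing + free-water fixed point", {
  gtab <- protocol_31()
  m1 <- c(1, 0, 0); m2 <- c(cos(pi / 3), sin(pi / 3), 0)
  truth <- model_state(list(tensor_compartment(m1, 1.7e-3, 0.3e-3),
                            tensor_compartment(m2, 1.7e-3, 0.3e-3)),
                       fw_fraction = 0.4)
  z <- predict_signal(truth, gtab)
  cfg <- tracker_config(model = "2t-fw")
  D <- fit_single_tensor(z, gtab)
  e <- eigen(D, symmetric = TRUE)
  defl <- log(1 / (1 - cfg$fw_init)) / 2000
  comp <- tensor_compartment(e$vectors[, 1],
                             max(e$values[1] - defl, 2e-4),
                             max(mean(e$values[2:3]) - defl, 1e-4))
  st <- model_state(list(comp, comp), fw_fraction = cfg$fw_init)
  P <- diag(c(rep(c(1e-2, 1e-2, 1e-2, 1e-7, 1e-7), 2), 2.5e-2))
  for (i in 1:50) {
    up <- ukf_update(st, P, z, gtab, cfg)
    st <- up$state; P <- up$covariance
    # projection contract holds after every update
    for (c in st$compartments) {
      expect_true(c$lambda1 >= c$lambda2 && c$lambda2 >= cfg$lambda_min)
      expect_equal(sum(c$m^2), 1, tolerance = 1e-9)
    }
    expect_true(st$fw_fraction >= 0 && st$fw_fraction <= 1)
  }
  angs <- vapply(st$compartments, function(c) {
    min(acos(min(1, abs(sum(c$m * m1)))), acos(min(1, abs(sum(c$m * m2))))) *
      180 / pi
  }, 1.0)
  expect_lt(max(angs), 10)
  expect_lt(abs(st$fw_fraction - 0.4), 0.1)
  # covariance stays symmetric positive semidefinite
  expect_lt(max(abs(P - t(P))), 1e-10)
  expect_gt(min(eigen(P, symmetric = TRUE)$values), -1e-10)
  expect_error(ukf_update(st, P, c(z[-1], NA), gtab, cfg), "finite")
})

test_that("the tracked compartment maximizes alignment with the previous direction", {
  c0 <- tensor_compartment(c(1, 0, 0), 1.7e-3, 0.3e-3)
  c90 <- tensor_compartment(c(0, 1, 0), 1.7e-3, 0.3e-3)
  st <- model_state(list(c0, c90), fw_fraction = 0.1)
  pick <- choose_tracked_compartment(st, c(1, 0, 0))
  expect_equal(pick$index, 1L)
  # single compartment anti-aligned: same compartment, direction negated
  stn <- model_state(list(tensor_compartment(c(-1, 0, 0), 1.7e-3, 0.3e-3)))
  pickn <- choose_tracked_compartment(stn, c(1, 0, 0))
  expect_equal(pickn$index, 1L)
  expect_gt(sum(pickn$direction * c(1, 0, 0)), 0)
  # brute-force oracle over compartments and signs
  set.seed(12)
  for (i in 1:50) {
    st <- random_state(2L, fw = 0.2)
    prev <- stats::rnorm(3); prev <- prev / sqrt(sum(prev^2))
    got <- choose_tracked_compartment(st, prev)
    dots <- vapply(st$compartments, function(c) abs(sum(c$m * prev)), 1.0)
    expect_equal(got$index, which.max(dots))
    best <- st$compartments[[which.max(dots)]]$m
    if (sum(best * prev) < 0) best <- -best
    expect_equal(got$direction, best, tolerance = 1e-12)
  }
})

test_that("streamlines span a noise-free bundle and respect stopping rules", {
  fx <- tiny_bundle_dwi(snr = Inf)
  ctr <- (fx$spec$grid - 1) / 2 * fx$spec$voxel_mm
  cfg <- tracker_config(model = "2t-fw")
  sl <- propagate_streamline(fx$dwi, ctr, cfg)
  expect_s3_class(sl, "streamline")
  expect_lt(abs(streamline_length(sl) - 60) / 60, 0.1)
  # consecutive spacing equals the step size
  seg <- sqrt(rowSums((sl$points[-1, ] - sl$points[-nrow(sl$points), ])^2))
  expect_equal(seg, rep(cfg$step_size_mm, length(seg)), tolerance = 1e-6)
  expect_true(all(sl$fa >= 0 & sl$fa <= 1))
  expect_true(all(sl$fw >= 0 & sl$fw <= 1))
  # a seed in pure free water stops immediately and is rejected
  phfw <- phantom_spec(grid = c(10L, 10L, 10L), bundles = list(),
                       background = list(diffusivity = 3.0e-3, fw = 1),
                       snr = Inf)
  dfw <- synthesize_dwi(build_field(phfw), protocol_31(), phfw)
  expect_null(propagate_streamline(dfw, c(10, 10, 10),
                                   tracker_config(model = "2t")))
})

test_that("the filter recovers the FW fraction through noise-free edema", {
  ctr <- c(33, 10, 10)
  ph <- phantom_spec(grid = c(29L, 9L, 9L),
                     bundles = list(bundle_straight(ctr, length_mm = 60)),
                     edema = edema_region(ctr, radii = c(8, 8, 8),
                                          peak_fw = 0.6, profile = "flat",
                                          radial_boost = 0),
                     snr = Inf)
  field <- build_field(ph)
  dwi <- synthesize_dwi(field, protocol_31(), ph)
  sl <- propagate_streamline(dwi, ctr + c(-20, 0, 0),
                             tracker_config(model = "2t-fw"))
  xs <- sl$points[, 1] - ctr[1]
  on_axis_inside <- abs(xs) < 8 & abs(sl$points[, 2] - ctr[2]) < 1
  expect_gt(sum(on_axis_inside), 10)
  expect_lt(abs(mean(sl$fw[on_axis_inside]) - 0.6), 0.15)
})

test_that("pinning the FW fraction to zero reproduces plain 2T tracking", {
  fx <- tiny_bundle_dwi(snr = Inf)
  ctr <- (fx$spec$grid - 1) / 2 * fx$spec$voxel_mm
  s2t <- propagate_streamline(fx$dwi, ctr + c(-8, 1, 0),
                              tracker_config(model = "2t"))
  spin <- propagate_streamline(fx$dwi, ctr + c(-8, 1, 0),
                               tracker_config(model = "2t-fw", pin_fw = TRUE,
                                              fw_init = 0))
  expect_equal(nrow(s2t$points), nrow(spin$points))
  expect_lt(max(abs(s2t$points - spin$points)), 1e-6)
})

test_that("whole-volume tracking is seeded per voxel and reproducible", {
  fx <- tiny_bundle_dwi(snr = 20, rng_seed = 2L)
  cfg <- tracker_config(model = "2t", seeds_per_voxel = 2L, rng_seed = 6L)
  tr1 <- track_whole_volume(fx$dwi, NULL, cfg)
  tr2 <- track_whole_volume(fx$dwi, NULL, cfg)
  expect_gt(length(tr1$streamlines), 10)
  expect_identical(lapply(tr1$streamlines, `[[`, "points"),
                   lapply(tr2$streamlines, `[[`, "points"))
  # seeds attempted = seeds_per_voxel x eligible voxels
  fa <- fa_map(fx$dwi)
  expect_match(tr1$provenance$seeds,
               sprintf("^%d seeds in %d voxels",
                       2L * sum(fa > cfg$seeding_fa), sum(fa > cfg$seeding_fa)))
  # all recorded points stay inside the brain mask grid
  lim <- (dim(fx$dwi$data)[1:3] - 0.5) * fx$spec$voxel_mm
  for (sl in tr1$streamlines[seq_len(min(20, length(tr1$streamlines)))])
    expect_true(all(sl$points >= -0.5 * fx$spec$voxel_mm) &&
                  all(sweep(sl$points, 2, lim) <= 0))
  # empty mask yields an empty tract with a warning
  expect_warning(tr0 <- track_whole_volume(fx$dwi,
                                           array(0, dim(fx$dwi$data)[1:3]),
                                           cfg), "empty")
  expect_length(tr0$streamlines, 0L)
})
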