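test_that("the emulated protocol has the right layout and spread", {
  gtab <- make_protocol()
  expect_length(gtab$bvals, 31L)
  expect_equal(sum(gtab$bvals == 0), 1L)
  expect_equal(sum(gtab$bvals == 2000), 30L)
  d <- gtab$bvecs[gtab$bvals > 0, ]
  expect_equal(sqrt(rowSums(d^2)), rep(1, 30), tolerance = 1e-8)
  cc <- abs(d %*% t(d)); cc[cc > 1] <- 1
  ang <- acos(cc) * 180 / pi; diag(ang) <- Inf
  expect_gt(min(ang), 10)
  expect_error(make_protocol(5L), "6")
  # deterministic: same layout on every call
  expect_identical(make_protocol()$bvecs, gtab$bvecs)
})

test_that("ground-truth fields carry tangents, membership and edema FW", {
  ph <- default_edema_phantom(snr = Inf)
  field <- build_field(ph)
  ctr <- (ph$grid - 1) / 2 * ph$voxel_mm
  # on-axis voxel carries the bundle tangent (x axis)
  ictr <- round(ctr / ph$voxel_mm) + 1
  expect_equal(field$n_comp[ictr[1], ictr[2], ictr[3]], 1L)
  expect_equal(abs(field$slots[[1]]$dir[ictr[1], ictr[2], ictr[3], 1]), 1)
  # FW elevated only inside the edema region
  expect_gt(field$fw[ictr[1], ictr[2], ictr[3]], 0.5)
  expect_equal(field$fw[2, 2, 2], ph$background$fw)
  # bundle mask is consistent with an analytic cylinder (radius well above
  # the voxel size so voxel-center discretization error stays small)
  ph5 <- phantom_spec(grid = c(30L, 30L, 30L),
                      bundles = list(bundle_straight(ctr, length_mm = 60,
                                                     radius_mm = 5)),
                      snr = Inf)
  f5 <- build_field(ph5)
  vcount <- sum(ground_truth_bundle_mask(f5, 1L))
  analytic <- pi * 5^2 * 60 / ph$voxel_mm^3
  expect_lt(abs(vcount - analytic) / analytic, 0.15)
  expect_error(ground_truth_bundle_mask(field, 5L), "unknown")
})

test_that("arc-bundle tangents match the analytic circle tangent", {
  ctr <- c(30, 30, 30)
  arc <- bundle_arc(ctr, arc_radius_mm = 18, angles = c(0, pi / 2),
                    radius_mm = 2.5)
  ph <- phantom_spec(grid = c(26L, 26L, 26L), bundles = list(arc), snr = Inf)
  field <- build_field(ph)
  idx <- which(field$slots[[1]]$label == 1L, arr.ind = TRUE)
  expect_gt(nrow(idx), 50)
  for (r in sample(seq_len(nrow(idx)), 25)) {
    w <- (idx[r, ] - 1) * ph$voxel_mm
    theta <- atan2(w[2] - ctr[2], w[1] - ctr[1])
    theta <- min(max(theta, 0), pi / 2)
    tan_ref <- c(-sin(theta), cos(theta), 0)
    m <- field$slots[[1]]$dir[idx[r, 1], idx[r, 2], idx[r, 3], ]
    ang <- acos(min(1, abs(sum(m * tan_ref)))) * 180 / pi
    expect_lt(ang, 2)
  }
})

test_that("crossing bundles occupy two compartment slots", {
  ctr <- c(34, 34, 34) / 2
  ph <- phantom_spec(grid = c(15L, 15L, 15L),
                     bundles = bundles_crossing(ctr, angle_deg = 60,
                                                length_mm = 28,
                                                radius_mm = 2.5),
                     snr = Inf)
  field <- build_field(ph)
  expect_gt(sum(field$n_comp == 2L), 0)
  masks <- lapply(1:2, ground_truth_bundle_mask, field = field)
  expect_true(all((masks[[1]] | masks[[2]]) <= field$brain_mask))
})

test_that("noise-free synthesis inverts voxelwise and is reproducible", {
  fx <- tiny_bundle_dwi(snr = Inf)
  gtab <- protocol_31()
  ctr <- (fx$spec$grid - 1) / 2 * fx$spec$voxel_mm
  i <- round(ctr / fx$spec$voxel_mm) + 1
  sig <- fx$dwi$data[i[1], i[2], i[3], ] / fx$dwi$data[i[1], i[2], i[3], 1]
  D <- fit_single_tensor(sig, gtab)
  ev <- eigen(D, symmetric = TRUE)$values
  l2 <- fx$field$slots[[1]]$l2[i[1], i[2], i[3]]
  l1 <- fx$field$slots[[1]]$l1[i[1], i[2], i[3]]
  # background FW mixes in slightly; recovery still close at fw = 0.05
  expect_equal(ev[1], l1, tolerance = 0.1)
  expect_equal(mean(ev[2:3]), l2, tolerance = 0.15)

  # an fw = 0 voxel inverts exactly
  ph0 <- phantom_spec(grid = c(12L, 12L, 12L),
                      bundles = list(bundle_straight(c(12, 12, 12),
                                                     length_mm = 20,
                                                     radius_mm = 3)),
                      background = list(diffusivity = 0.8e-3, fw = 0),
                      snr = Inf)
  f0 <- build_field(ph0)
  d0 <- synthesize_dwi(f0, gtab, ph0)
  i0 <- round(12 / 2.3) + 1
  s0 <- d0$data[i0, i0, i0, ] / d0$data[i0, i0, i0, 1]
  D0 <- fit_single_tensor(s0, gtab)
  expect_equal(eigen(D0, symmetric = TRUE)$values,
               c(1.4e-3, 0.5e-3, 0.5e-3), tolerance = 1e-8)

  # pure free-water voxel attenuates to exp(-6) on the shell
  phfw <- phantom_spec(grid = c(6L, 6L, 6L), bundles = list(),
                       background = list(diffusivity = 3.0e-3, fw = 1),
                       snr = Inf)
  dfw <- synthesize_dwi(build_field(phfw), gtab, phfw)
  expect_equal(unname(dfw$data[3, 3, 3, -1] / phfw$s0), rep(exp(-6), 30),
               tolerance = 1e-12)

  # same seed gives bit-identical noisy volumes
  fxa <- tiny_bundle_dwi(snr = 20, rng_seed = 9L)
  fxb <- tiny_bundle_dwi(snr = 20, rng_seed = 9L)
  expect_identical(fxa$dwi$data, fxb$dwi$data)
})

test_that("Rician noise matches its analytic mean and edema tapers outward", {
  ph <- phantom_spec(grid = c(25L, 25L, 25L), bundles = list(),
                     background = list(diffusivity = 0.8e-3, fw = 0.05),
                     snr = 20, rng_seed = 21L)
  dwi <- synthesize_dwi(build_field(ph), protocol_31(), ph)
  b0 <- dwi$data[, , , 1]                     # constant S0 + Rician noise
  expect_gt(length(b0), 1e4)
  ref <- rician_mean_analytic(ph$s0, ph$s0 / ph$snr)
  expect_lt(abs(mean(b0) - ref) / ref, 0.02)

  # linear-taper FW is non-increasing with distance from the region center
  ctr <- c(28, 28, 28)
  ph2 <- phantom_spec(grid = c(25L, 25L, 25L), bundles = list(),
                      edema = edema_region(ctr, radii = c(15, 15, 15),
                                           peak_fw = 0.8,
                                           profile = "linear"),
                      snr = Inf)
  f2 <- build_field(ph2)
  ij <- round(28 / 2.3) + 1
  along <- f2$fw[ij:25, ij, ij]
  expect_true(all(diff(along) <= 1e-12))
  expect_equal(max(f2$fw), 0.8, tolerance = 0.05)
})
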