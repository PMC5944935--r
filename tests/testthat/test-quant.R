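ref_grid <- function(dims = c(20L, 20L, 20L), vox = 2.3) {
  aff <- diag(4); diag(aff)[1:3] <- vox
  list(dims = dims, affine = aff)
}

axis_fiber <- function(vox = 2.3) {
  # fiber along x from the center of voxel (0,0,0) to the center of (4,0,0)
  pts <- cbind(seq(0, 4 * vox, length.out = 9), 0, 0)
  as_tract(list(structure(list(points = pts, fa = rep(0.5, 9),
                               fw = rep(0.2, 9)), class = "streamline")))
}

test_that("voxelization marks exactly the traversed voxels", {
  ref <- ref_grid()
  lm <- voxelize_tract(axis_fiber(), ref)
  expect_equal(sum(lm$data), 5L)
  expect_equal(which(lm$data > 0, arr.ind = TRUE)[, 1], 1:5,
               ignore_attr = TRUE)
  expect_equal(labelmap_volume(lm), 5 * 2.3^3)

  # empty tract gives an all-zero map
  lm0 <- voxelize_tract(as_tract(list()), ref)
  expect_equal(sum(lm0$data), 0)
  expect_equal(labelmap_volume(lm0), 0)

  # 100 random curved fibers match the dense-sampling oracle
  set.seed(31)
  fibers <- random_curved_fibers(100, ref$dims, 2.3)
  lm_all <- voxelize_tract(as_tract(fibers), ref)
  oracle <- dense_voxel_oracle(fibers, ref$dims, ref$affine, 2.3 / 20)
  expect_identical(lm_all$data > 0, oracle)

  # invariant to point order reversal and streamline order
  rev_fibers <- rev(lapply(fibers, function(sl) {
    sl$points <- sl$points[rev(seq_len(nrow(sl$points))), ]
    sl
  }))
  expect_identical(voxelize_tract(as_tract(rev_fibers), ref)$data,
                   lm_all$data)
})

test_that("intersection volume counts overlap on the common grid", {
  ref <- ref_grid()
  lm <- voxelize_tract(axis_fiber(), ref)
  all_mask <- label_map(array(1L, ref$dims), ref$affine)
  expect_equal(intersection_volume(lm, all_mask), labelmap_volume(lm))
  none <- label_map(array(0L, ref$dims), ref$affine)
  expect_equal(intersection_volume(lm, none), 0)
  m <- array(0L, ref$dims); m[1:3, 1, 1] <- 1L
  expect_equal(intersection_volume(lm, label_map(m, ref$affine)),
               3 * 2.3^3, tolerance = 1e-12)
  expect_lte(intersection_volume(lm, label_map(m, ref$affine)),
             labelmap_volume(lm))
  # a mask on a different grid is resampled through world space
  aff2 <- diag(4); diag(aff2)[1:3] <- 1.15
  m2 <- array(0L, c(40L, 40L, 40L)); m2[1:6, 1:2, 1:2] <- 1L
  expect_equal(intersection_volume(lm, label_map(m2, aff2)),
               3 * 2.3^3, tolerance = 1e-12)
})

test_that("mask splitting partitions fibers by traversal", {
  ref <- ref_grid()
  set.seed(5)
  fibers <- random_curved_fibers(40, ref$dims, 2.3)
  tract <- as_tract(fibers)
  m <- array(0L, ref$dims); m[8:12, 8:12, 8:12] <- 1L
  mask <- label_map(m, ref$affine)
  sp <- split_by_mask(tract, mask)
  expect_equal(length(sp$traversing$streamlines) +
                 length(sp$non_traversing$streamlines), 40L)
  # against the dense oracle
  oracle_hits <- vapply(fibers, function(sl) {
    any(dense_voxel_oracle(list(sl), ref$dims, ref$affine, 2.3 / 20) &
          m > 0)
  }, TRUE)
  expect_equal(length(sp$traversing$streamlines), sum(oracle_hits))

  # everything / nothing masks
  sp_all <- split_by_mask(tract, label_map(array(1L, ref$dims), ref$affine))
  expect_length(sp_all$non_traversing$streamlines, 0L)
  sp_none <- split_by_mask(tract, label_map(array(0L, ref$dims), ref$affine))
  expect_length(sp_none$traversing$streamlines, 0L)

  # a chord crossing a single masked voxel between stored points is caught
  vox <- 2.3
  chord <- as_tract(list(structure(list(
    points = rbind(c(2 * vox, 10 * vox, 10 * vox),
                   c(8 * vox, 10 * vox, 10 * vox)),
    fa = c(0.5, 0.5), fw = c(0, 0)), class = "streamline")))
  m1 <- array(0L, ref$dims); m1[6, 11, 11] <- 1L
  expect_length(split_by_mask(chord, label_map(m1, ref$affine))$
                  traversing$streamlines, 1L)
})

test_that("per-point scalar means honor the weighting scheme", {
  mk <- function(vals) structure(list(points = cbind(seq_along(vals), 0, 0),
                                      fw = vals, fa = vals),
                                 class = "streamline")
  tr <- as_tract(list(mk(c(0, 0)), mk(c(1, 1))))
  expect_equal(mean_point_scalar(tr, "fw"), 0.5)
  tr2 <- as_tract(list(mk(rep(0.3, 7))))
  expect_equal(mean_point_scalar(tr2, "fw"), 0.3)
  # point- vs fiber-weighting differ for unequal lengths
  tr3 <- as_tract(list(mk(rep(0, 6)), mk(rep(1, 2))))
  expect_equal(mean_point_scalar(tr3, "fw", weighting = "point"), 0.25)
  expect_equal(mean_point_scalar(tr3, "fw", weighting = "fiber"), 0.5)
  expect_true(is.na(mean_point_scalar(as_tract(list()), "fw")))
})

test_that("fiber statistics and histograms are consistent", {
  pts <- cbind(seq(0, 9, by = 0.9), 0, 0)
  one <- as_tract(list(structure(list(points = pts, fa = rep(0.5, 11),
                                      fw = rep(0, 11)),
                                 class = "streamline")))
  fs <- fiber_stats(one)
  expect_equal(fs$count, 1L)
  expect_equal(fs$mean_length_mm, 9)
  expect_equal(sum(fs$histogram$counts), 1L)

  fs0 <- fiber_stats(as_tract(list()))
  expect_equal(fs0$count, 0L)

  set.seed(9)
  fibers <- random_curved_fibers(50, c(20L, 20L, 20L), 2.3)
  fs50 <- fiber_stats(as_tract(fibers), bin_width_mm = 7)
  ref_lens <- vapply(fibers, function(sl) {
    p <- sl$points
    sum(sqrt(rowSums((p[-1, ] - p[-nrow(p), ])^2)))
  }, 1.0)
  expect_equal(fs50$mean_length_mm, mean(ref_lens), tolerance = 1e-10)
  expect_equal(sum(fs50$histogram$counts), 50L)
})

test_that("volume-matched threshold selection is an argmin with upward ties", {
  expect_equal(select_rfa_threshold(c("0.15" = 100, "0.07" = 200), 200), 0.07)
  expect_equal(select_rfa_threshold(c("0.15" = 100, "0.07" = 300), 200), 0.15)
  expect_error(select_rfa_threshold(numeric(0), 1), "empty")
  set.seed(13)
  for (i in 1:50) {
    thr <- sort(stats::runif(6), decreasing = TRUE)
    vols <- stats::runif(6, 0, 1000)
    names(vols) <- thr
    target <- stats::runif(1, 0, 1000)
    got <- select_rfa_threshold(vols, target)
    err <- abs(vols - target)
    best <- thr[err == min(err)]
    expect_equal(got, max(best))
  }
})
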