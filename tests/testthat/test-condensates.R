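test_that("well-separated spots are each detected once", {
  spec <- small_spec(n_spots = 5L)
  gen <- gen_nucleus_stack(spec)
  lab <- segment_nucleus(gen$image)
  det <- detect_condensates(gen$image, lab)
  expect_equal(nrow(det$records), 5L)
  # detected centers match ground truth within a spot radius
  gt <- gen$ground_truth$true_spot_centers
  d <- nucleoscope:::cpp_min_dist(
    as.matrix(det$records[, c("x_um", "y_um", "z_um")]), gt)
  expect_lt(max(d), spec$spot_diameter / 2)
})

test_that("zero spots give an empty result, not an error", {
  spec <- small_spec(n_spots = 0L)
  gen <- gen_nucleus_stack(spec)
  lab <- segment_nucleus(gen$image)
  det <- detect_condensates(gen$image, lab)
  expect_equal(nrow(det$records), 0L)
  expect_error(detect_condensates(gen$image, NULL), "nucleus")
})

test_that("erosion separates two spots joined by a one-voxel neck", {
  # constructed mask oracle at the labeling level: two 5-voxel-radius blobs
  # connected by a single-voxel bridge
  d <- c(15L, 15L, 31L)
  fg <- array(FALSE, d)
  for (ctr_x in c(8, 24)) {
    g <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
    fg <- fg | array((g$z - 8)^2 + (g$y - 8)^2 + (g$x - ctr_x)^2 <= 25, d)
  }
  fg[8, 8, 14:18] <- TRUE  # 1-voxel neck
  eroded <- nucleoscope:::cpp_erode6(fg, d, 2L, rep(TRUE, 2))
  seeds <- nucleoscope:::cpp_label3d(eroded, d, 26L)
  expect_equal(max(seeds), 2L)
  expanded <- nucleoscope:::cpp_expand_labels(seeds, fg, d)
  expect_equal(max(expanded), 2L)
  expect_equal(sum(expanded > 0), sum(fg))   # expansion refills the mask
  # without erosion the neck merges them
  expect_equal(max(nucleoscope:::cpp_label3d(fg, d, 26L)), 1L)
})

test_that("detection count is stable across noise seeds at SNR 10", {
  counts <- vapply(1:5, function(s) {
    gen <- gen_nucleus_stack(small_spec(seed = s))
    nrow(detect_condensates(gen$image, segment_nucleus(gen$image))$records)
  }, 1L)
  expect_true(all(counts == 5L))
})

test_that("periphery shell thickness follows the EDT fraction", {
  sp <- sphere_mask(20)
  shell <- periphery_shell(sp, 0.05)
  edt <- nucleoscope:::cpp_edt3d(sp, dim(sp), c(1, 1, 1))
  expect_lte(max(edt[shell]), 0.05 * max(edt) + 1e-9)
  # thickness ~ 0.05 R: innermost shell voxel lies within ~1 voxel of 0.05 R
  expect_gt(max(edt[shell]), 0.05 * 20 - 1.01)
  expect_equal(sum(periphery_shell(sp, 1)), sum(sp))      # whole object
  surf <- periphery_shell(sp, 1e-9)                       # surface voxels only
  expect_equal(sum(surf), sum(edt[sp] <= min(edt[sp])))
  expect_error(periphery_shell(array(FALSE, c(3, 3, 3)),
                               voxel_size = c(1, 1, 1)), "empty")
})

test_that("radial and peripheral distances follow the scaled geometry", {
  sp <- sphere_mask(20)          # radius 20 um, diameter-equivalent ~ 40 um
  lab <- structure(array(as.integer(sp), dim(sp)), voxel_size = c(1, 1, 1),
                   class = c("label_volume", "array"))
  ctr <- (dim(sp) + 1) / 2 - 1   # 0-based center index = physical um
  morph <- data.frame(major_axis = 40, intermediate_axis = 40, minor_axis = 40)
  rec <- data.frame(id = 1:3, nucleus_id = 1L,
                    x_um = ctr[3] + c(0, 10, 19.5),
                    y_um = ctr[2], z_um = ctr[1],
                    volume_um3 = 1, equivalent_diameter_um = 1,
                    n_voxels = 10L, is_control = FALSE)
  out <- radial_peripheral_distances(rec, lab, morph)
  d_eq <- (6 * sum(sp) / pi)^(1 / 3)       # voxel-based equivalent diameter
  expect_equal(out$radial_r[1], 0)
  expect_equal(out$radial_r[2], 10 / d_eq, tolerance = 0.02)
  expect_lt(out$peripheral_p[3], 0.06)     # touching the shell: p ~ 0
  # condensate outside the nucleus is flagged and excluded
  rec_bad <- rec
  rec_bad$x_um[1] <- ctr[3] + 30
  expect_warning(out2 <- radial_peripheral_distances(rec_bad, lab, morph),
                 "outside")
  expect_equal(nrow(out2), 2L)
})

test_that("zero-radius controls sample uniformly over the nucleus", {
  sp <- sphere_mask(14)
  lab <- structure(array(as.integer(sp), dim(sp)), voxel_size = c(1, 1, 1),
                   class = c("label_volume", "array"))
  morph <- data.frame(major_axis = 28, intermediate_axis = 28, minor_axis = 28)
  n <- 300
  rec <- data.frame(id = seq_len(n), nucleus_id = 1L,
                    x_um = 14, y_um = 14, z_um = 14,
                    volume_um3 = 0, equivalent_diameter_um = 0,
                    n_voxels = 1L, is_control = FALSE)
  ctl <- sample_control_points(lab, rec, morph, seed = 42)
  # uniform-in-ball: E[r] = 3R/4, radial_r = r / 2R -> mean 3/8
  expect_lt(abs(mean(ctl$radial_r) - 3 / 8), 0.02)
  # deterministic per seed, stable under appending condensates
  ctl2 <- sample_control_points(lab, rec[1:10, ], morph, seed = 42)
  expect_equal(ctl$x_um[1:10], ctl2$x_um[1:10])
})

test_that("radius-matched controls respect the eroded sampling region", {
  sp <- sphere_mask(14)
  lab <- structure(array(as.integer(sp), dim(sp)), voxel_size = c(1, 1, 1),
                   class = c("label_volume", "array"))
  morph <- data.frame(major_axis = 28, intermediate_axis = 28, minor_axis = 28)
  n <- 150
  rec <- data.frame(id = seq_len(n), nucleus_id = 1L,
                    x_um = 14, y_um = 14, z_um = 14,
                    volume_um3 = 4 / 3 * pi * 5^3,
                    equivalent_diameter_um = 10,   # radius 5
                    n_voxels = 1L, is_control = FALSE)
  ctl <- sample_control_points(lab, rec, morph, seed = 7)
  edt <- nucleoscope:::cpp_edt3d(sp, dim(sp), c(1, 1, 1))
  # every control sits in the region eroded by the condensate radius
  for (i in seq_len(5)) {
    vox <- round(c(ctl$z_um[i], ctl$y_um[i], ctl$x_um[i])) + 1
    expect_gt(edt[vox[1], vox[2], vox[3]], 5)
  }
  # empirical radial CDF matches a rejection-sampling oracle (KS)
  set.seed(1)
  oracle <- replicate(400, {
    repeat {
      p <- runif(3, -1, 1) * 14
      if (sqrt(sum(p^2)) <= 14 - 5 - 0.5) return(sqrt(sum(p^2)))
    }
  })
  d_eq <- (6 * sum(sp) / pi)^(1 / 3)
  ks <- suppressWarnings(stats::ks.test(ctl$radial_r * d_eq, oracle))
  expect_gt(ks$p.value, 0.01)
  # radius >= max inscribed radius falls back to the EDT argmax
  rec_big <- rec[1, ]; rec_big$equivalent_diameter_um <- 40
  expect_warning(ctl_big <- sample_control_points(lab, rec_big, morph),
                 "inscribed")
  vox <- round(c(ctl_big$z_um, ctl_big$y_um, ctl_big$x_um)) + 1
  expect_equal(edt[vox[1], vox[2], vox[3]], max(edt))
})

test_that("Mander's M1 follows the overlap identities", {
  arr <- array(1, c(4, 4, 4))
  img <- voxel_image(arr, c(1, 1, 1))
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  expect_equal(manders_coefficient(a, img, a)$manders_m1, 1)
  b_disjoint <- array(FALSE, c(4, 4, 4)); b_disjoint[3:4, , ] <- TRUE
  expect_equal(manders_coefficient(a, img, b_disjoint)$manders_m1, 0)
  b_half <- array(FALSE, c(4, 4, 4)); b_half[1, , ] <- TRUE
  expect_equal(manders_coefficient(a, img, b_half)$manders_m1, 0.5)
  expect_error(manders_coefficient(array(FALSE, c(4, 4, 4)), img, a), "empty")
})

test_that("scaled total condensate volume normalizes by nucleus volume", {
  rec <- data.frame(volume_um3 = c(2, 3))
  expect_equal(scaled_condensate_volume(rec, 100), 0.05)
  expect_error(scaled_condensate_volume(rec, 0), "positive")
})
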