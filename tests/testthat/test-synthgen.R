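test_that("phantom spec validates its invariants", {
  expect_error(nucleus_phantom_spec(c(-1, 2, 1)), "positive")
  expect_error(nucleus_phantom_spec(c(4, 3, 1.5), margin_vox = 1L), "margin")
  expect_s3_class(small_spec(), "nucleus_phantom_spec")
})

test_that("noiseless ellipsoid recovers the analytic volume within 2%", {
  spec <- small_spec(n_spots = 0L, snr = Inf, psf_sigma = c(0, 0, 0))
  gen <- gen_nucleus_stack(spec)
  thr <- mean(range(gen$image$data))
  vol <- sum(gen$image$data > thr) * prod(gen$image$voxel_size)
  expect_lt(abs(vol / (4 / 3 * pi * prod(spec$semi_axes)) - 1), 0.02)
})

test_that("ground-truth minor/major ratio matches the flatness anchor", {
  spec <- nucleus_phantom_spec(c(8, 8, 1.4112), n_spots = 0L)
  gt <- gen_nucleus_stack(spec)$ground_truth
  expect_equal(gt$true_axes[3] / gt$true_axes[1], 0.1764)
  expect_equal(1 - sqrt(0.1764), 0.58)
})

test_that("seed controls noise only: identical geometry, different noise", {
  a <- gen_nucleus_stack(small_spec(seed = 1L))
  b <- gen_nucleus_stack(small_spec(seed = 2L))
  expect_identical(a$ground_truth$true_spot_centers,
                   b$ground_truth$true_spot_centers)
  expect_false(identical(a$image$data, b$image$data))
  a2 <- gen_nucleus_stack(small_spec(seed = 1L))
  expect_identical(a$image$data, a2$image$data)  # bit-identical rerun
})

test_that("spots lie strictly inside and respect the separation", {
  spec <- small_spec(geometry_seed = 7L)
  gt <- gen_nucleus_stack(spec)$ground_truth
  ctr <- gt$true_center
  rel <- sweep(gt$true_spot_centers, 2, c(ctr["x"], ctr["y"], ctr["z"]))
  u <- sqrt(rowSums(sweep(rel, 2, spec$semi_axes, "/")^2))
  expect_true(all(u < 1))
  d <- as.matrix(dist(gt$true_spot_centers))
  diag(d) <- Inf
  expect_gte(min(d), spec$min_spot_separation)
})

test_that("impossible packing raises a packing error naming the constraint", {
  expect_error(gen_nucleus_stack(small_spec(n_spots = 60L)),
               "min_spot_separation")
})

test_that("ground truth round-trips through JSON losslessly", {
  gt <- gen_nucleus_stack(small_spec())$ground_truth
  path <- tempfile(fileext = ".json")
  save_ground_truth(gt, path)
  back <- load_ground_truth(path)
  expect_equal(back$true_axes, gt$true_axes)
  expect_equal(back$true_spot_centers, gt$true_spot_centers,
               ignore_attr = TRUE)
  expect_equal(back$true_spot_diameter, gt$true_spot_diameter)
})

test_that("two-channel overlap fraction controls Mander's M1", {
  spec <- small_spec(snr = Inf, n_spots = 10L, min_spot_separation = 1.3)
  expect_error(gen_two_channel(spec, 1.5), "overlap_fraction")
  for (f in c(0, 0.5, 1)) {
    two <- gen_two_channel(spec, f)
    lab <- segment_nucleus(two$image_a)
    da <- detect_condensates(two$image_a, lab)
    db <- detect_condensates(two$image_b, lab)
    if (f == 0) {
      expect_equal(manders_coefficient(da$labels, two$image_a,
                                       db$labels)$manders_m1, 0)
    } else {
      m1 <- manders_coefficient(da$labels, two$image_a, db$labels)$manders_m1
      if (f == 1) expect_gt(m1, 0.99) else expect_lt(abs(m1 - 0.5), 0.05)
    }
  }
})

test_that("fBm tracks have the stated ground truth and limits", {
  tr <- gen_tracks_fbm(50, 0.5, 20, dt_min = 30, step_scale = 0.1, seed = 3)
  gt <- attr(tr, "ground_truth")
  expect_equal(gt$true_alpha, 1)
  # H = 0.5: increments are white; lag-1 autocorrelation ~ 0
  ac <- sapply(split(tr, tr$track_id), function(t1) {
    dx <- diff(t1$x_um)
    cor(dx[-1], dx[-length(dx)])
  })
  expect_lt(abs(mean(ac)), 0.1)
  # stationary limit
  tr0 <- gen_tracks_fbm(5, 0.25, 10, step_scale = 0, seed = 1)
  expect_true(all(tr0$x_um == 0 & tr0$y_um == 0))
  expect_error(gen_tracks_fbm(5, 1.2, 10), "hurst")
})

test_that("fBm ensemble MSD follows alpha = 2H", {
  tr <- gen_tracks_fbm(150, 0.25, 30, dt_min = 30, step_scale = 0.1, seed = 11)
  fa <- fit_alpha(compute_msd(tr), window_hours = 7)
  expect_lt(abs(fa$alpha - 0.5), 0.05)
})

test_that("FRAP curve generator evaluates the printed model", {
  cv <- gen_frap_curve(0.2, 0.9, 2, n_points = 41, dt_s = 0.1)
  expect_equal(cv$intensity[1], 0.2)              # F(0) = F0
  expect_equal(cv$intensity[cv$times == 4], 0.55) # half recovery at 2 t1
  # limit t -> inf
  cv2 <- gen_frap_curve(0.2, 0.9, 0.001, n_points = 10000, dt_s = 1)
  expect_lt(abs(tail(cv2$intensity, 1) - 0.9), 1e-3)
  expect_error(gen_frap_curve(0.8, 0.5, 2), "F0 <= Finf")
  expect_error(gen_frap_curve(0.2, 0.9, -1), "t1")
  # bleaching multiplies by exp(-k t)
  cvb <- gen_frap_curve(0.2, 0.9, 2, n_points = 41, dt_s = 0.1,
                        bleach_rate = 0.1)
  expect_equal(cvb$intensity, cv$intensity * exp(-0.1 * cv$times))
})

test_that("ChIP-like track is blocky, nonnegative, sized per arm", {
  expect_error(gen_chip_track(integer(0)), "empty|>= 1")
  t1 <- gen_chip_track(c(arm = 10L), seed = 2)
  expect_equal(nrow(t1), 10L)
  expect_true(all(t1$value >= 0))
  expect_equal(t1$start, (0:9) * 1e6)
  # default 5-arm config totals 258 bins (the model size)
  t258 <- gen_chip_track(seed = 1)
  expect_equal(nrow(t258), 258L)
  # all-off parameters give an all-zero track
  t0 <- gen_chip_track(c(a = 20L),
                       signal_dist = list(meanlog = 0, sdlog = 0.5,
                                          on_fraction = 0), seed = 1)
  expect_true(all(t0$value == 0))
  # bedGraph round trip
  path <- tempfile(fileext = ".bedgraph")
  write_bedgraph(t258, path)
  back <- read_bedgraph(path)
  expect_equal(back$value, t258$value)
  expect_equal(back$start, t258$start)
})
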