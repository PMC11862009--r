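test_that("a single drifting spot yields one track across all frames", {
  det <- data.frame(frame = 0:9, x = (0:9) * 5, y = 0)
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(nrow(tr), 10L)
  expect_error(link_tracks(det[det$frame == 0, ]), "two frames")
})

test_that("jumps beyond the cost cutoff terminate tracks", {
  # 200 px jump: cost 40000 > 16900 -> track ends, new one begins
  det <- data.frame(frame = c(0, 1, 2, 3), x = c(0, 5, 205, 210), y = 0)
  tr <- link_tracks(det)
  expect_equal(length(unique(tr$track_id)), 2L)
  id1 <- tr$track_id[tr$frame == 0]
  expect_equal(tr$track_id[tr$frame == 1], id1)
  expect_false(tr$track_id[tr$frame == 2] == id1)
})

test_that("assignment equals the brute-force minimum for swaps", {
  # two spots near-swapping: optimal pairing = minimum total squared cost
  p0 <- rbind(c(0, 0), c(10, 0))
  p1 <- rbind(c(4, 1), c(6, -1))
  det <- data.frame(frame = rep(0:1, each = 2),
                    x = c(p0[, 1], p1[, 1]), y = c(p0[, 2], p1[, 2]))
  tr <- link_tracks(det, cost_cutoff = 1e6)
  c_straight <- sum((p0 - p1)^2)
  c_crossed <- sum((p0 - p1[2:1, ])^2)
  best <- if (c_straight <= c_crossed) diag(2)[1:2, ] else diag(2)[2:1, ]
  got <- vapply(1:2, function(i) {
    id <- tr$track_id[tr$frame == 0][i]
    which(tr$x[tr$frame == 1] == tr$x[tr$frame == 1 & tr$track_id == id])
  }, 1L)
  expect_equal(got, apply(best, 1, which.max))
})

test_that("linking is invariant to detection order within a frame", {
  set.seed(3)
  det <- data.frame(frame = rep(0:4, each = 3),
                    x = rnorm(15, rep(c(0, 50, 100), 5), 2),
                    y = rnorm(15, 0, 2))
  tr1 <- link_tracks(det)
  perm <- unlist(lapply(split(seq_len(15), det$frame), sample))
  tr2 <- link_tracks(det[perm, ])
  key <- function(tr) {
    s <- split(paste(tr$frame, round(tr$x, 6), sep = ":"), tr$track_id)
    sort(vapply(s, paste, "", collapse = "|"))
  }
  expect_equal(unname(key(tr1)), unname(key(tr2)))
})

test_that("splitting attaches a new track to a terminated parent nearby", {
  det <- data.frame(frame = c(0, 1, 2), x = c(0, 0, 5), y = 0)
  # parent present at frames 0-1 dies (jump > cutoff with tiny cutoff), the
  # frame-2 detection starts a new track within the split radius
  tr <- link_tracks(det, cost_cutoff = 16, split_cutoff = 100)
  ids <- unique(tr$track_id)
  expect_equal(length(ids), 2L)
  child <- tr[tr$frame == 2, ]
  expect_equal(child$parent_id, tr$track_id[tr$frame == 1])
})

test_that("nucleus-motion correction removes common drift", {
  set.seed(4)
  base <- data.frame(track_id = 1L, frame = 0:9,
                     x = cumsum(rnorm(10)), y = cumsum(rnorm(10)))
  drift <- data.frame(frame = 0:9, x = (0:9) * 3, y = (0:9) * -2)
  shifted <- base
  shifted$x <- base$x + drift$x
  shifted$y <- base$y + drift$y
  corr <- correct_tracks(shifted, drift)
  expect_equal(corr$x, base$x)
  expect_equal(corr$y, base$y)
  expect_error(correct_tracks(shifted, drift[1:5, ]), "missing")
})

test_that("MSD follows the reference-point formula", {
  stat <- data.frame(track_id = rep(1:3, each = 5), frame = rep(0:4, 3),
                     x = 0, y = 0)
  m0 <- compute_msd(stat, dt_min = 30)
  expect_true(all(m0$msd == 0))
  expect_equal(m0$n[1], 3L)
  # constant velocity v: MSD(t) = v^2 t^2 (2D with motion on x only)
  v <- 0.2
  lin <- data.frame(track_id = 1L, frame = 0:10, t_min = (0:10) * 1,
                    x = v * (0:10), y = 0)
  ml <- compute_msd(lin)
  expect_equal(ml$msd, (v * ml$t_min)^2)
  # time-averaged variant agrees for a single linear track
  mta <- compute_msd(lin, time_averaged = TRUE)
  expect_equal(mta$msd, (v * mta$t_min)^2)
})

test_that("alpha fitting recovers exact power laws", {
  t <- 1:20
  msd <- structure(data.frame(t_min = t, msd = 2 * t^0.8, sd = 0, n = 10L),
                   class = c("msd_result", "data.frame"))
  fa <- fit_alpha(msd, window_hours = 7)
  expect_equal(fa$alpha, 0.8, tolerance = 1e-10)
  expect_equal(fa$D, 2, tolerance = 1e-10)
  msd2 <- structure(data.frame(t_min = t, msd = 0.04 * t^2, sd = 0, n = 10L),
                    class = c("msd_result", "data.frame"))
  expect_equal(fit_alpha(msd2)$alpha, 2, tolerance = 1e-10)
  # window restricts the fit and <3 points errors
  expect_error(fit_alpha(msd[1:2, ]), "3")
})

test_that("displacement statistics match hand-computed values", {
  tr <- data.frame(track_id = 1L, frame = 0:14, t_min = (0:14) * 30,
                   x = (0:14) * 0.3, y = 0)
  st <- displacement_stats(tr)
  expect_equal(st$mean_step_um_per_min, 0.01)
  expect_equal(st$lifetime_min, 420)
  expect_equal(st$path_length_um, 14 * 0.3)
  # stationary track
  tr0 <- data.frame(track_id = 1L, frame = 0:5, t_min = (0:5) * 30,
                    x = 1, y = 2)
  expect_equal(displacement_stats(tr0)$mean_step_um_per_min, 0)
  # single-frame track: lifetime 0, displacement undefined
  tr1 <- data.frame(track_id = 1L, frame = 0L, t_min = 0, x = 0, y = 0)
  st1 <- displacement_stats(tr1)
  expect_equal(st1$lifetime_min, 0)
  expect_true(is.na(st1$mean_step_um_per_min))
})

test_that("fBm ensembles across H recover alpha = 2H (parameter recovery)", {
  # single-ensemble estimates scatter by ~0.04; average a few independent
  # ensembles of the standard 200 x 30 size to test the recovery property
  for (H in c(0.125, 0.25, 0.4)) {
    alphas <- vapply(1:3, function(s) {
      tr <- gen_tracks_fbm(200, H, 30, dt_min = 30, step_scale = 0.1,
                           seed = round(100 * H) + s)
      fit_alpha(compute_msd(tr), window_hours = 7)$alpha
    }, 1)
    expect_lt(abs(mean(alphas) - 2 * H), 0.05)
  }
})
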