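
# Accept either x/y or x_um/y_um coordinate column names.
norm_track_cols <- function(tracks) {
  if (!"x" %in% names(tracks) && "x_um" %in% names(tracks)) tracks$x <- tracks$x_um
  if (!"y" %in% names(tracks) && "y_um" %in% names(tracks)) tracks$y <- tracks$y_um
  tracks
}

#' Link per-frame detections into tracks (linear assignment)
#'
#' Frame-to-frame linking minimizing total squared displacement via an exact
#' linear assignment solution with birth/death alternatives: a link costs the
#' squared distance between the two detections, links above `cost_cutoff`
#' (squared distance units; the default 16900 corresponds to a 130-pixel
#' gating radius) are forbidden, and every unmatched detection starts or
#' terminates a track. After linking, a track starting at frame `t` may be
#' assigned a parent: the closest track that terminated at frame `t - 1`
#' within `split_cutoff` (squared distance), recorded as a split event.
#'
#' @param detections data.frame with columns `frame`, `x`, `y` (any
#'   consistent spatial unit; cutoffs are in that unit squared).
#' @param cost_cutoff maximum allowed squared link distance.
#' @param split_cutoff maximum squared distance for split-parent assignment.
#' @return data.frame `track_id, parent_id, frame, x, y`, ordered by track
#'   and frame.
#' @export
link_tracks <- function(detections, cost_cutoff = 16900, split_cutoff = 100) {
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  frames <- sort(unique(detections$frame))
  assert_that(length(frames) >= 2, "need detections in at least two frames")
  det <- detections[order(detections$frame), , drop = FALSE]
  det$.row <- seq_len(nrow(det))
  det$track_id <- NA_integer_
  next_id <- 0L
  # tracks present in the first frame
  first <- det$frame == frames[1]
  det$track_id[first] <- seq_len(sum(first))
  next_id <- sum(first)
  terminated <- list()  # per frame index: data.frame of ended track positions
  for (fi in seq_len(length(frames) - 1)) {
    f0 <- frames[fi]; f1 <- frames[fi + 1]
    i0 <- which(det$frame == f0)
    i1 <- which(det$frame == f1)
    n0 <- length(i0); n1 <- length(i1)
    linked1 <- rep(FALSE, n1)
    linked0 <- rep(FALSE, n0)
    if (n0 > 0 && n1 > 0) {
      cost <- outer(det$x[i0], det$x[i1], "-")^2 +
              outer(det$y[i0], det$y[i1], "-")^2
      BIG <- 1e12
      cost[cost > cost_cutoff] <- BIG
      # pad with death (rows) and birth (cols) alternatives at cutoff cost
      n <- n0 + n1
      M <- matrix(0, n, n)
      M[seq_len(n0), seq_len(n1)] <- cost
      M[seq_len(n0), n1 + seq_len(n0)] <- BIG
      M[n0 + seq_len(n1), seq_len(n1)] <- BIG
      M[cbind(seq_len(n0), n1 + seq_len(n0))] <- cost_cutoff  # death
      M[cbind(n0 + seq_len(n1), seq_len(n1))] <- cost_cutoff  # birth
      assign <- cpp_lap(M)
      for (a in seq_len(n0)) {
        j <- assign[a]
        if (j <= n1 && cost[a, j] < BIG) {
          det$track_id[i1[j]] <- det$track_id[i0[a]]
          linked1[j] <- TRUE
          linked0[a] <- TRUE
        }
      }
    }
    # terminated tracks at f0 (no continuation into f1)
    terminated[[fi]] <- data.frame(
      track_id = det$track_id[i0[!linked0]],
      x = det$x[i0[!linked0]], y = det$y[i0[!linked0]])
    # new tracks at f1
    new1 <- which(!linked1)
    if (length(new1) > 0) {
      det$track_id[i1[new1]] <- next_id + seq_along(new1)
      next_id <- next_id + length(new1)
    }
  }
  # split-parent assignment for tracks born after the first frame
  det$parent_id <- NA_integer_
  for (fi in seq_len(length(frames) - 1)) {
    f1 <- frames[fi + 1]
    ended <- terminated[[fi]]
    if (nrow(ended) == 0) next
    i1 <- which(det$frame == f1)
    births <- i1[!duplicated(det$track_id[i1]) &
                   !det$track_id[i1] %in% det$track_id[det$frame <= frames[fi]]]
    for (b in births) {
      d2 <- (ended$x - det$x[b])^2 + (ended$y - det$y[b])^2
      j <- which.min(d2)
      if (length(j) && d2[j] <= split_cutoff)
        det$parent_id[det$track_id == det$track_id[b]] <- ended$track_id[j]
    }
  }
  out <- det[order(det$track_id, det$frame),
             c("track_id", "parent_id", "frame", "x", "y")]
  rownames(out) <- NULL
  out
}

#' Correct tracks for nucleus motion
#'
#' Subtracts the nucleus center coordinates at each frame from the condensate
#' coordinates at the same frame, removing common drift.
#'
#' @param tracks data.frame with `frame`, `x`, `y`.
#' @param nucleus_centers data.frame with `frame`, `x`, `y` of the nucleus
#'   center per frame.
#' @return `tracks` with corrected `x`, `y` (raw positions kept as
#'   `x_raw`, `y_raw`).
#' @export
correct_tracks <- function(tracks, nucleus_centers) {
  m <- match(tracks$frame, nucleus_centers$frame)
  assert_that(!anyNA(m), "nucleus center missing for some frames")
  tracks$x_raw <- tracks$x
  tracks$y_raw <- tracks$y
  tracks$x <- tracks$x - nucleus_centers$x[m]
  tracks$y <- tracks$y - nucleus_centers$y[m]
  tracks
}

#' Ensemble mean squared displacement
#'
#' The reference-point form: each condensate's squared displacement from its
#' own first position, `MSD(t) = (1/N) * sum_i |r_i(t) - r_i(0)|^2`,
#' averaged across the N condensates present at that lag, with the SD across
#' condensates. A time-averaged variant (averaging over all start points
#' within each track) is available with `time_averaged = TRUE`.
#'
#' @param tracks data.frame `track_id, frame, x, y` plus a time column
#'   `t_min` (or supply `dt_min`).
#' @param dt_min frame interval in minutes if `t_min` is absent.
#' @param time_averaged use the time-averaged estimator instead of the
#'   reference-point form.
#' @return data.frame `t_min, msd, sd, n` (lag 0 included with MSD 0).
#' @export
compute_msd <- function(tracks, dt_min = NULL, time_averaged = FALSE) {
  tracks <- norm_track_cols(tracks)
  stopifnot(all(c("track_id", "frame", "x", "y") %in% names(tracks)))
  if (!"t_min" %in% names(tracks)) {
    assert_that(!is.null(dt_min), "supply t_min column or dt_min")
    tracks$t_min <- tracks$frame * dt_min
  }
  ids <- unique(tracks$track_id)
  per_track <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    tr
  })
  dt <- if (!is.null(dt_min)) dt_min else {
    dts <- unlist(lapply(per_track, function(tr) diff(tr$t_min)))
    if (length(dts) == 0) 1 else min(dts)
  }
  max_lag <- max(vapply(per_track, function(tr) max(tr$frame) - min(tr$frame),
                        1))
  lags <- 0:max_lag
  msd <- sd_ <- rep(NA_real_, length(lags))
  n <- integer(length(lags))
  msd[1] <- 0; n[1] <- length(per_track); sd_[1] <- 0
  for (k in seq_len(max_lag)) {
    vals <- unlist(lapply(per_track, function(tr) {
      f0 <- min(tr$frame)
      if (time_averaged) {
        idx <- match(tr$frame + k, tr$frame)
        ok <- !is.na(idx)
        if (!any(ok)) return(NULL)
        mean((tr$x[idx[ok]] - tr$x[ok])^2 + (tr$y[idx[ok]] - tr$y[ok])^2)
      } else {
        j <- match(f0 + k, tr$frame)
        if (is.na(j)) return(NULL)
        (tr$x[j] - tr$x[1])^2 + (tr$y[j] - tr$y[1])^2
      }
    }))
    n[k + 1] <- length(vals)
    if (length(vals) > 0) {
      msd[k + 1] <- mean(vals)
      sd_[k + 1] <- if (length(vals) > 1) stats::sd(vals) else 0
    }
  }
  keep <- n > 0
  structure(data.frame(t_min = lags[keep] * dt, msd = msd[keep],
                       sd = sd_[keep], n = n[keep]),
            class = c("msd_result", "data.frame"))
}

#' Fit the anomalous diffusion exponent
#'
#' Least-squares line on `(log t, log MSD)` over lags within the fit window
#' (default the first 7 hours, where data abundance is highest):
#' `log MSD = log D + alpha * log t`. The slope is the anomalous exponent
#' alpha and the intercept gives `D` in µm²/min^alpha.
#'
#' @param msd an `msd_result` from [compute_msd()].
#' @param window_hours fit window; lags with `t <= window` are used.
#' @return list `alpha`, `D`, `fit` (the `lm` object), `n_points`.
#' @export
fit_alpha <- function(msd, window_hours = 7) {
  sel <- msd$t_min > 0 & msd$t_min <= window_hours * 60 & !is.na(msd$msd)
  if (any(msd$msd[sel] <= 0)) {
    warning("nonpositive MSD values excluded from the log-log fit")
    sel <- sel & msd$msd > 0
  }
  assert_that(sum(sel) >= 3, "need at least 3 positive-lag points in the window")
  fit <- stats::lm(log(msd$msd[sel]) ~ log(msd$t_min[sel]))
  list(alpha = unname(coef(fit)[2]), D = exp(unname(coef(fit)[1])),
       fit = fit, n_points = sum(sel))
}

#' Per-track displacement statistics
#'
#' Mean per-frame Euclidean step divided by the frame interval (µm/min),
#' track lifetime (minutes), and total path length (µm). Single-frame tracks
#' get lifetime 0 and `NA` displacement.
#'
#' @param tracks data.frame `track_id, frame, x, y` (+ optional `t_min`).
#' @param dt_min frame interval in minutes if `t_min` is absent.
#' @return data.frame, one row per track.
#' @export
displacement_stats <- function(tracks, dt_min = NULL) {
  tracks <- norm_track_cols(tracks)
  if (!"t_min" %in% names(tracks)) {
    assert_that(!is.null(dt_min), "supply t_min column or dt_min")
    tracks$t_min <- tracks$frame * dt_min
  }
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) < 2) {
      return(data.frame(track_id = id, mean_step_um_per_min = NA_real_,
                        lifetime_min = 0, path_length_um = 0,
                        n_frames = nrow(tr)))
    }
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    dts <- diff(tr$t_min)
    data.frame(track_id = id,
               mean_step_um_per_min = mean(steps / dts),
               lifetime_min = max(tr$t_min) - min(tr$t_min),
               path_length_um = sum(steps), n_frames = nrow(tr))
  })
  do.call(rbind, rows)
}
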