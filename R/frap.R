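#' Normalize a FRAP trace (double normalization)
#'
#' Corrects the bleached-ROI trace for acquisition bleaching using a
#' reference trace and normalizes to the pre-bleach level:
#' `F(t) = (ROI(t) / Ref(t)) / (mean(ROI_pre) / mean(Ref_pre))`.
#' Time is zeroed at the first post-bleach frame.
#'
#' @param roi bleached-ROI intensity trace.
#' @param reference reference (whole cell / unbleached region) trace of the
#'   same length.
#' @param prebleach_frames number of leading pre-bleach frames (>= 1).
#' @param dt_s sampling interval, seconds.
#' @param roi_kind `"inside_condensate"` or `"outside_condensate"`.
#' @return a `frap_curve` with times (s) and normalized intensity.
#' @export
normalize_frap <- function(roi, reference, prebleach_frames = 1L,
                           dt_s = 0.002101,
                           roi_kind = c("inside_condensate",
                                        "outside_condensate")) {
  roi_kind <- match.arg(roi_kind)
  assert_that(length(roi) == length(reference),
              "ROI and reference traces must have the same length")
  assert_that(prebleach_frames >= 1, "need at least one pre-bleach frame")
  assert_that(length(roi) > prebleach_frames,
              "no post-bleach data: trace contains only pre-bleach frames")
  assert_that(all(reference > 0), "reference trace contains zero intensity")
  pre <- seq_len(prebleach_frames)
  norm0 <- mean(roi[pre]) / mean(reference[pre])
  f <- (roi / reference) / norm0
  post <- (prebleach_frames + 1):length(roi)
  structure(list(times = (seq_along(post) - 1) * dt_s,
                 intensity = f[post],
                 prebleach = 1, roi_kind = roi_kind),
            class = "frap_curve")
}

# The single-diffusion recovery model.
frap_model <- function(t, F0, Finf, t1) {
  u <- (t / t1) / 2
  (F0 + Finf * u) / (1 + u)
}

#' Fit the single-diffusion FRAP recovery model
#'
#' Nonlinear least squares of
#' `F(t) = (F0 + Finf * (t/t1)/2) / (1 + (t/t1)/2)` with bounded parameters
#' (`0 <= F0 <= Finf <= 1.2`, `t1 > 0`) and multi-start initialization over a
#' logarithmic `t1` grid. Under this model the half-recovery time — where
#' `F = (F0 + Finf)/2` — is analytically `t_half = 2 * t1`; both are
#' reported, together with the immobile fraction `1 - Finf` and the plateau
#' estimated alternatively as the mean of the last 5% of frames.
#'
#' @param curve a `frap_curve`.
#' @return list of class `frap_fit`: `F0`, `Finf`, `t1`, `t_half`,
#'   `immobile_fraction`, `last_frames_level`, `rss`, `fit`.
#' @export
fit_recovery <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  t <- curve$times
  y <- curve$intensity
  assert_that(length(t) >= 10, "need at least 10 post-bleach points")
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  t1_grid <- exp(seq(log(max(dt, 1e-9)), log(max(t[length(t)], dt * 10)),
                     length.out = 7))
  F0_init <- max(min(y[seq_len(max(3, length(y) %/% 50))]), 0)
  Finf_init <- min(max(mean(tail(y, max(3, length(y) %/% 20))), F0_init + 1e-3), 1.2)
  best <- NULL
  for (t1_init in t1_grid) {
    fit <- tryCatch(
      stats::nls(y ~ frap_model(t, F0, Finf, t1),
                 start = list(F0 = F0_init, Finf = Finf_init, t1 = t1_init),
                 lower = c(F0 = 0, Finf = 0, t1 = 1e-9),
                 upper = c(F0 = 1.2, Finf = 1.2, t1 = Inf),
                 algorithm = "port",
                 control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("FRAP fit failed to converge from every start of the multi-start ",
         "grid (t1 grid: ", paste(signif(t1_grid, 3), collapse = ", "), ")",
         call. = FALSE)
  p <- coef(best$fit)
  structure(list(F0 = unname(p["F0"]), Finf = unname(p["Finf"]),
                 t1 = unname(p["t1"]), t_half = 2 * unname(p["t1"]),
                 immobile_fraction = 1 - unname(p["Finf"]),
                 last_frames_level = mean(tail(y, max(1, length(y) %/% 20))),
                 rss = best$rss, fit = best$fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP fit: F0 = %.4f, Finf = %.4f (immobile %.1f%%), t1 = %.4g s, t_half = %.4g s\n",
              x$F0, x$Finf, 100 * x$immobile_fraction, x$t1, x$t_half))
  invisible(x)
}
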