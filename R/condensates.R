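#' Detect condensates by eroded-Otsu labeling
#'
#' Implements threshold -> erode -> label -> constrained re-expansion, the
#' scheme used to split touching bright objects: Gaussian blur, Otsu
#' threshold restricted to the nucleus interior, `n_erosions` binary erosions
#' (6-connected cross element), 26-connected labeling of the eroded mask,
#' then expansion of each label back within the un-eroded mask without label
#' merging. Objects smaller than `min_voxels` (after expansion) are dropped.
#'
#' @param img single-channel [voxel_image()].
#' @param nucleus `label_volume` nucleus mask (from [segment_nucleus()]).
#' @param blur_sigma_um Gaussian blur sigma, µm. The default (0.05) stays
#'   below the PSF width: blurring beyond the optical scale inflates the
#'   threshold-equivalent size of spot-scale objects.
#' @param n_erosions erosion iterations.
#' @param min_voxels minimum object size in voxels.
#' @param interior_margin_um boundary margin (µm) excluded from the
#'   threshold computation: the blurred nucleus edge forms an intensity ramp
#'   that would otherwise dominate the within-nucleus histogram and pull the
#'   Otsu threshold to the edge instead of the nucleoplasm/condensate split.
#' @param min_contrast minimum robust z-score of the Otsu threshold above the
#'   nucleoplasm median (in MAD units). An Otsu split always exists, even on
#'   a featureless noisy nucleoplasm; condensates are accepted only when the
#'   threshold clears the nucleoplasm noise by this margin, otherwise the
#'   result is empty.
#' @param nucleus_id which nucleus label defines the interior.
#' @return list with `labels` (condensate label array) and `records`, a
#'   data.frame of `CondensateRecord`s: id, nucleus_id, center (x,y,z µm),
#'   volume µm³ and `equivalent_diameter = (6 V / pi)^(1/3)` µm.
#' @export
detect_condensates <- function(img, nucleus, blur_sigma_um = 0.05,
                               n_erosions = 2L, min_voxels = 5L,
                               interior_margin_um = 0.3,
                               min_contrast = 4,
                               nucleus_id = 1L) {
  stopifnot(inherits(img, "voxel_image"))
  assert_that(!is.null(nucleus), "a nucleus mask is required")
  vs <- img$voxel_size
  nmask <- if (is.logical(nucleus)) nucleus else label_mask(nucleus, nucleus_id)
  arr <- gaussian_blur3d(img$data, blur_sigma_um / vs)
  inner <- nmask
  if (interior_margin_um > 0 && any(nmask)) {
    edt <- cpp_edt3d(nmask, dim(nmask), vs)
    deep <- nmask & edt > interior_margin_um
    if (sum(deep) > 1000) inner <- deep
  }
  vals <- arr[inner]
  empty <- list(labels = array(0L, dim(arr)),
                records = empty_condensate_records())
  if (length(vals) == 0) return(empty)
  # Iterative Otsu for strongly imbalanced foregrounds: condensates occupy a
  # tiny volume fraction, so a single Otsu split can settle on the
  # nucleoplasm noise. If the threshold fails the contrast guard, re-apply
  # Otsu to the values above it (at most two retries); accept the first
  # threshold that clears the guard, else report no condensates.
  ctr_med <- stats::median(vals)
  noise <- stats::mad(vals)
  thr <- NA_real_
  pool <- vals
  for (stage in 1:3) {
    cand <- tryCatch(otsu_threshold(pool), error = function(e) NA_real_)
    if (is.na(cand)) break
    if (noise == 0 || (cand - ctr_med) / noise >= min_contrast) {
      thr <- cand
      break
    }
    pool <- pool[pool > cand]
    if (length(pool) < 100) break
  }
  if (is.na(thr)) return(empty)
  fg <- arr > thr & nmask
  if (!any(fg)) return(empty)
  eroded <- if (n_erosions > 0) {
    # erosion depth kept approximately isotropic in um: erode along z only in
    # iterations where the accumulated z depth lags the xy depth (z voxels
    # are typically coarser than xy)
    z_total <- max(0L, as.integer(round(n_erosions * min(vs[2:3]) / vs[1])))
    with_z <- rep(FALSE, n_erosions)
    if (z_total > 0) with_z[seq_len(min(z_total, n_erosions))] <- TRUE
    cpp_erode6(fg, dim(fg), as.integer(n_erosions), with_z)
  } else fg
  if (!any(eroded)) return(empty)
  seeds <- cpp_label3d(eroded, dim(eroded), 26L)
  labels <- cpp_expand_labels(seeds, fg, dim(fg))
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_voxels)
  labels <- relabel_components(labels, keep)
  k <- length(keep)
  if (k == 0) return(list(labels = labels, records = empty_condensate_records()))
  rec <- vector("list", k)
  for (id in seq_len(k)) {
    m <- labels == id
    co <- mask_coords_um(m, vs)
    vol <- nrow(co) * prod(vs)
    rec[[id]] <- data.frame(
      id = id, nucleus_id = nucleus_id,
      x_um = mean(co[, "x"]), y_um = mean(co[, "y"]), z_um = mean(co[, "z"]),
      volume_um3 = vol,
      equivalent_diameter_um = (6 * vol / pi)^(1 / 3),
      n_voxels = nrow(co), is_control = FALSE)
  }
  list(labels = structure(labels, voxel_size = vs,
                          class = c("label_volume", "array")),
       records = do.call(rbind, rec))
}

empty_condensate_records <- function() {
  data.frame(id = integer(0), nucleus_id = integer(0),
             x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
             volume_um3 = numeric(0), equivalent_diameter_um = numeric(0),
             n_voxels = integer(0), is_control = logical(0))
}

#' Peripheral shell of a nucleus mask
#'
#' The periphery is the set of mask voxels whose Euclidean distance transform
#' (physical units, distance to background) is at most `fraction` times the
#' maximum EDT — the outer `fraction` thickness shell of the object. As
#' `fraction` approaches 0 the shell reduces to the surface voxels;
#' `fraction = 1` returns the whole object.
#'
#' @param nucleus `label_volume` or logical mask with voxel size attribute.
#' @param fraction shell thickness fraction (default 0.05).
#' @param voxel_size optional (z, y, x) µm override.
#' @param id nucleus label.
#' @return logical mask of the shell.
#' @export
periphery_shell <- function(nucleus, fraction = 0.05, voxel_size = NULL,
                            id = 1L) {
  vs <- voxel_size %||% attr(nucleus, "voxel_size")
  assert_that(!is.null(vs), "voxel_size not available on mask; pass explicitly")
  mask <- if (is.logical(nucleus)) nucleus else label_mask(nucleus, id)
  assert_that(any(mask), "empty nucleus mask")
  edt <- cpp_edt3d(mask, dim(mask), vs)
  inside <- edt[mask]
  thr <- max(fraction * max(inside), min(inside))
  shell <- mask & (edt <= thr)
  dim(shell) <- dim(mask)
  attr(shell, "voxel_size") <- vs
  shell
}

#' Scaled radial and peripheral distances of condensates
#'
#' For each record, `radial_r` is the Euclidean distance from the condensate
#' center to the nucleus center (mean voxel position) divided by the nucleus
#' diameter, and `peripheral_p` is the minimum Euclidean distance to any
#' periphery-shell voxel divided by the nucleus height (minor axis). The
#' nucleus diameter defaults to the volume-equivalent spherical diameter
#' `(6 V / pi)^(1/3)`; the major axis can be used instead via
#' `diameter_reference = "major_axis"`.
#'
#' @param records condensate record data.frame (from [detect_condensates()]).
#' @param nucleus nucleus `label_volume`.
#' @param morph one-row morphometry data.frame (from [measure_nuclei()] or
#'   [shape_metrics()]).
#' @param periphery_fraction shell thickness fraction.
#' @param diameter_reference `"equivalent_sphere"` or `"major_axis"`.
#' @param id nucleus label.
#' @return `records` with `radial_r` and `peripheral_p` columns; condensates
#'   whose center falls outside the nucleus mask are dropped with a warning.
#' @export
radial_peripheral_distances <- function(records, nucleus, morph,
                                        periphery_fraction = 0.05,
                                        diameter_reference = c("equivalent_sphere",
                                                               "major_axis"),
                                        id = 1L) {
  diameter_reference <- match.arg(diameter_reference)
  if (nrow(records) == 0) {
    records$radial_r <- numeric(0)
    records$peripheral_p <- numeric(0)
    return(records)
  }
  vs <- attr(nucleus, "voxel_size")
  mask <- if (is.logical(nucleus)) nucleus else label_mask(nucleus, id)
  co <- mask_coords_um(mask, vs)
  ctr <- c(x = mean(co[, "x"]), y = mean(co[, "y"]), z = mean(co[, "z"]))
  V <- nrow(co) * prod(vs)
  diam <- if (diameter_reference == "equivalent_sphere") (6 * V / pi)^(1 / 3)
          else morph$major_axis
  height <- morph$minor_axis
  shell <- periphery_shell(nucleus, periphery_fraction, voxel_size = vs, id = id)
  shell_xyz <- mask_coords_um(shell, vs)[, c(3, 2, 1), drop = FALSE]
  pts <- as.matrix(records[, c("x_um", "y_um", "z_um")])
  # centers must lie inside the nucleus mask
  vox <- cbind(round(records$z_um / vs[1]), round(records$y_um / vs[2]),
               round(records$x_um / vs[3])) + 1
  d <- dim(mask)
  ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 & vox[, 2] <= d[2] &
    vox[, 3] >= 1 & vox[, 3] <= d[3]
  ok[ok] <- mask[cbind(vox[ok, 1], vox[ok, 2], vox[ok, 3])]
  if (!all(ok)) {
    warning(sum(!ok), " condensate center(s) outside the nucleus mask; excluded")
    records <- records[ok, , drop = FALSE]
    pts <- pts[ok, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    records$radial_r <- numeric(0)
    records$peripheral_p <- numeric(0)
    return(records)
  }
  records$radial_r <- sqrt((pts[, 1] - ctr["x"])^2 + (pts[, 2] - ctr["y"])^2 +
                             (pts[, 3] - ctr["z"])^2) / diam
  records$peripheral_p <- cpp_min_dist(pts, shell_xyz) / height
  records
}

#' Radius-matched random control points
#'
#' For each condensate, the nucleus mask is eroded by that condensate's
#' radius (EDT threshold in physical units) and a single voxel is sampled
#' uniformly from the eroded region; the control point inherits the
#' condensate's size and receives `radial_r` / `peripheral_p` by the same
#' formulas. If the eroded region is empty (condensate radius at least the
#' maximal inscribed radius), the voxel of maximal EDT is used and a warning
#' logged. Each condensate uses an independent sub-seed derived from `seed`,
#' so adding condensates never reshuffles earlier controls.
#'
#' @param nucleus nucleus `label_volume`.
#' @param records condensate records with `equivalent_diameter_um`.
#' @param morph one-row morphometry data.frame.
#' @param seed master seed.
#' @param periphery_fraction shell thickness fraction.
#' @param diameter_reference passed to [radial_peripheral_distances()].
#' @param id nucleus label.
#' @return control records (is_control = TRUE) with scaled distances.
#' @export
sample_control_points <- function(nucleus, records, morph, seed = 1L,
                                  periphery_fraction = 0.05,
                                  diameter_reference = "equivalent_sphere",
                                  id = 1L) {
  if (nrow(records) == 0) return(records)
  vs <- attr(nucleus, "voxel_size")
  mask <- if (is.logical(nucleus)) nucleus else label_mask(nucleus, id)
  edt <- cpp_edt3d(mask, dim(mask), vs)
  co_all <- mask_coords_um(mask, vs)
  edt_in <- edt[mask]
  ctl <- records
  for (i in seq_len(nrow(records))) {
    r <- records$equivalent_diameter_um[i] / 2
    candidates <- which(edt_in > r)
    if (length(candidates) == 0) {
      warning("condensate radius >= max inscribed radius; ",
              "falling back to the EDT argmax voxel")
      pick <- which.max(edt_in)
    } else {
      pick <- with_seed(derive_seed(seed, i),
                        candidates[sample.int(length(candidates), 1)])
    }
    ctl$x_um[i] <- co_all[pick, "x"]
    ctl$y_um[i] <- co_all[pick, "y"]
    ctl$z_um[i] <- co_all[pick, "z"]
  }
  ctl$is_control <- TRUE
  radial_peripheral_distances(ctl, nucleus, morph,
                              periphery_fraction = periphery_fraction,
                              diameter_reference = diameter_reference, id = id)
}

#' Mander's colocalization coefficient M1
#'
#' `M1 = sum(I_A over voxels inside both A- and B-objects) /
#'       sum(I_A over voxels inside A-objects)`: the fraction of channel-A
#' object signal overlapped by channel-B objects.
#'
#' @param labelsA,labelsB label arrays (or logical masks) of the segmented
#'   objects in the two co-registered channels.
#' @param imgA channel-A [voxel_image()] supplying the intensities.
#' @return data.frame with `manders_m1`.
#' @export
manders_coefficient <- function(labelsA, imgA, labelsB) {
  a <- if (is.logical(labelsA)) labelsA else labelsA > 0
  b <- if (is.logical(labelsB)) labelsB else labelsB > 0
  assert_that(any(a), "channel-A object set is empty: M1 undefined")
  ia <- imgA$data
  m1 <- sum(ia[a & b]) / sum(ia[a])
  data.frame(manders_m1 = m1)
}

#' Scaled total condensate volume
#'
#' Sum of condensate volumes divided by the nucleus volume (the per-nucleus
#' statistic used to normalize condensate load across conditions).
#'
#' @param records condensate records.
#' @param nucleus_volume_um3 nucleus volume, µm³.
#' @return scalar fraction.
#' @export
scaled_condensate_volume <- function(records, nucleus_volume_um3) {
  assert_that(nucleus_volume_um3 > 0, "nucleus volume must be positive")
  sum(records$volume_um3) / nucleus_volume_um3
}
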