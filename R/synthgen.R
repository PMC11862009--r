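#' Specification of a synthetic nucleus phantom
#'
#' Describes an ellipsoidal nucleus with bright condensate spots (uniform
#' spheres of the stated diameter, emulating dense condensate bodies),
#' imaged with an anisotropic Gaussian PSF and Poisson-Gaussian noise. All lengths in
#' micrometres. Two seeds are carried: `geometry_seed` determines spot
#' placement (the ground-truth geometry) and `seed` the noise realization, so
#' the same phantom geometry can be imaged under independent noise draws.
#'
#' @param semi_axes ellipsoid semi-axes (a, b, c) in µm, ordered (x, y, z)
#'   extent meaning: first along x, second y, third z.
#' @param orientation Euler angles (rad), intrinsic z-y-x rotation of the
#'   ellipsoid. Default no rotation.
#' @param n_spots number of condensate spots.
#' @param spot_diameter condensate diameter (uniform sphere) before PSF blur, µm.
#' @param spot_placement one of `"uniform"`, `"central"`, `"peripheral"`.
#' @param min_spot_separation minimum pairwise center distance, µm.
#' @param snr (spot peak − local background) / background-noise SD; `Inf`
#'   disables noise.
#' @param psf_sigma Gaussian PSF sigma (z, y, x) in µm.
#' @param voxel_size voxel pitch (z, y, x) in µm; default 0.14 x 0.08 x 0.08.
#' @param seed noise seed.
#' @param geometry_seed spot-placement seed.
#' @param margin_vox empty margin around the ellipsoid, voxels (min 2).
#' @param background,base_intensity camera offset level and nuclear interior
#'   intensity (photon counts).
#' @param read_noise_sd additive Gaussian read noise SD (counts).
#' @return a `nucleus_phantom_spec` list.
#' @export
nucleus_phantom_spec <- function(semi_axes, orientation = c(0, 0, 0),
                                 n_spots = 8L, spot_diameter = 0.78,
                                 spot_placement = c("uniform", "central", "peripheral"),
                                 min_spot_separation = 1.5, snr = 10,
                                 psf_sigma = c(0.15, 0.06, 0.06),
                                 voxel_size = c(0.14, 0.08, 0.08),
                                 seed = 1L, geometry_seed = 1L,
                                 margin_vox = 3L,
                                 background = 10, base_intensity = 100,
                                 read_noise_sd = 2) {
  spot_placement <- match.arg(spot_placement)
  assert_that(length(semi_axes) == 3 && all(semi_axes > 0),
              "semi_axes must be 3 positive lengths")
  assert_that(n_spots >= 0, "n_spots must be nonnegative")
  assert_that(margin_vox >= 2, "ellipsoid needs a >= 2 voxel margin")
  assert_that(all(voxel_size > 0) && all(psf_sigma >= 0),
              "voxel_size must be positive, psf_sigma nonnegative")
  structure(list(semi_axes = as.numeric(semi_axes),
                 orientation = as.numeric(orientation),
                 n_spots = as.integer(n_spots),
                 spot_diameter = spot_diameter,
                 spot_placement = spot_placement,
                 min_spot_separation = min_spot_separation,
                 snr = snr, psf_sigma = as.numeric(psf_sigma),
                 voxel_size = as.numeric(voxel_size),
                 seed = as.integer(seed),
                 geometry_seed = as.integer(geometry_seed),
                 margin_vox = as.integer(margin_vox),
                 background = background, base_intensity = base_intensity,
                 read_noise_sd = read_noise_sd),
            class = "nucleus_phantom_spec")
}

# Rotation matrix from intrinsic z-y-x Euler angles, acting on (x, y, z).
euler_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

# Sample spot centers in (x, y, z) µm relative to ellipsoid center.
sample_spot_centers <- function(spec) {
  n <- spec$n_spots
  if (n == 0) return(matrix(numeric(0), 0, 3))
  r_spot <- spec$spot_diameter / 2
  eff <- spec$semi_axes - r_spot - 1e-9
  assert_that(all(eff > 0), "spot does not fit inside the ellipsoid")
  R <- euler_rotation(spec$orientation)
  lims <- switch(spec$spot_placement,
    uniform = c(0, 1), central = c(0, 0.5), peripheral = c(0.6, 0.95))
  centers <- matrix(NA_real_, n, 3)
  with_seed(spec$geometry_seed, {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(10000L)) {
        q <- (runif(3) * 2 - 1) * eff
        u <- sqrt(sum((q / eff)^2))
        if (u > lims[2] || u < lims[1]) next
        p <- as.numeric(R %*% q)
        if (i > 1) {
          dmin <- min(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                                      matrix(p, i - 1, 3, byrow = TRUE))^2)))
          if (dmin < spec$min_spot_separation) next
        }
        centers[i, ] <- p
        placed <- TRUE
        break
      }
      if (!placed)
        stop("spot packing failed after 10000 attempts: cannot satisfy ",
             "min_spot_separation = ", spec$min_spot_separation,
             " um with n_spots = ", n, " in this ellipsoid", call. = FALSE)
    }
  })
  colnames(centers) <- c("x", "y", "z")
  centers
}

# Grid dimensions (z, y, x) and center so the rotated ellipsoid fits with
# the requested margin.
phantom_grid <- function(spec) {
  R <- euler_rotation(spec$orientation)
  M <- R %*% diag(spec$semi_axes^2) %*% t(R)
  half_xyz <- sqrt(diag(M))           # support of the ellipsoid along x, y, z
  half_zyx <- rev(half_xyz)
  n_half <- ceiling(half_zyx / spec$voxel_size) + spec$margin_vox
  dims <- as.integer(2 * n_half + 1)
  center <- n_half * spec$voxel_size  # physical coordinate of center voxel
  list(dims = dims, center_zyx = center)
}

#' Generate a synthetic nucleus stack with ground truth
#'
#' Renders the phantom described by a [nucleus_phantom_spec()]: background
#' offset, ellipsoid interior at a base intensity, uniform spherical spots
#' of the stated diameter at recorded centers, anisotropic Gaussian PSF
#' blur, then Poisson shot noise plus Gaussian read noise scaled to the
#' stated SNR (spot amplitude sits `snr` background-noise SDs above the
#' nuclear base level). Deterministic for fixed seeds.
#'
#' @param spec a [nucleus_phantom_spec()].
#' @return list with elements `image` (a [voxel_image()]) and `ground_truth`
#'   (axes, spot centers in µm grid coordinates, spot diameter, seeds).
#' @export
gen_nucleus_stack <- function(spec) {
  stopifnot(inherits(spec, "nucleus_phantom_spec"))
  g <- phantom_grid(spec)
  dims <- g$dims
  vs <- spec$voxel_size
  centers_rel <- sample_spot_centers(spec)

  # voxel center coordinates relative to ellipsoid center, per axis
  zc <- (seq_len(dims[1]) - 1) * vs[1] - g$center_zyx[1]
  yc <- (seq_len(dims[2]) - 1) * vs[2] - g$center_zyx[2]
  xc <- (seq_len(dims[3]) - 1) * vs[3] - g$center_zyx[3]
  R <- euler_rotation(spec$orientation)
  A <- R %*% diag(1 / spec$semi_axes^2) %*% t(R)  # x' A x <= 1 inside
  # quadratic form expanded over the separable grid
  X <- array(rep(xc, each = dims[1] * dims[2]), dims)
  Y <- array(rep(rep(yc, each = dims[1]), dims[3]), dims)
  Z <- array(rep(zc, dims[2] * dims[3]), dims)
  q <- A[1, 1] * X^2 + A[2, 2] * Y^2 + A[3, 3] * Z^2 +
    2 * (A[1, 2] * X * Y + A[1, 3] * X * Z + A[2, 3] * Y * Z)
  inside <- q <= 1

  img <- array(spec$background, dims)
  img[inside] <- spec$base_intensity

  noise_sd <- sqrt(spec$base_intensity + spec$read_noise_sd^2)
  if (spec$n_spots > 0) {
    # spot cores sit snr * background-noise SDs above the nuclear base level
    amp <- if (is.finite(spec$snr)) spec$snr * noise_sd
           else 5 * spec$base_intensity
    r_spot <- spec$spot_diameter / 2
    for (i in seq_len(nrow(centers_rel))) {
      ctr <- centers_rel[i, ]  # (x, y, z) relative to center
      zi <- which(abs(zc - ctr[3]) <= r_spot)
      yi <- which(abs(yc - ctr[2]) <= r_spot)
      xi <- which(abs(xc - ctr[1]) <= r_spot)
      d2 <- outer(outer((zc[zi] - ctr[3])^2, (yc[yi] - ctr[2])^2, "+"),
                  (xc[xi] - ctr[1])^2, "+")
      sub <- img[zi, yi, xi]
      sub[d2 <= r_spot^2] <- spec$base_intensity + amp
      img[zi, yi, xi] <- sub
    }
  }

  img <- gaussian_blur3d(img, spec$psf_sigma / vs)

  if (is.finite(spec$snr)) {
    with_seed(spec$seed, {
      img[] <- rpois(length(img), lambda = pmax(img, 0)) +
        rnorm(length(img), sd = spec$read_noise_sd)
    })
    img[img < 0] <- 0
  }

  centers_grid <- centers_rel  # (x, y, z) µm in grid coordinates
  if (nrow(centers_grid) > 0) {
    centers_grid[, 1] <- centers_grid[, 1] + g$center_zyx[3]
    centers_grid[, 2] <- centers_grid[, 2] + g$center_zyx[2]
    centers_grid[, 3] <- centers_grid[, 3] + g$center_zyx[1]
  }
  gt <- ground_truth(
    true_axes = spec$semi_axes,
    true_center = c(x = g$center_zyx[3], y = g$center_zyx[2], z = g$center_zyx[1]),
    true_spot_centers = centers_grid,
    true_spot_diameter = spec$spot_diameter,
    orientation = spec$orientation,
    seed = spec$seed, geometry_seed = spec$geometry_seed)
  list(image = voxel_image(img, vs, channel = "HP1a"), ground_truth = gt)
}

#' Ground-truth record attached to every synthetic artifact
#'
#' @param ... named ground-truth fields (true axes, spot centers, alpha,
#'   FRAP parameters, ...).
#' @return a `ground_truth` list, losslessly serializable via
#'   [save_ground_truth()] / [load_ground_truth()].
#' @export
ground_truth <- function(...) structure(list(...), class = "ground_truth")

#' @rdname ground_truth
#' @param gt a `ground_truth` object.
#' @param path JSON sidecar path.
#' @export
save_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  ser <- lapply(unclass(gt), function(f) {
    if (is.matrix(f)) list(.matrix = TRUE, data = as.numeric(f), dim = dim(f),
                           colnames = colnames(f))
    else f
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname ground_truth
#' @export
load_ground_truth <- function(path) {
  ser <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  out <- lapply(ser, function(f) {
    if (is.list(f) && isTRUE(f$.matrix)) {
      m <- matrix(f$data, f$dim[1], f$dim[2])
      if (!is.null(f$colnames)) colnames(m) <- f$colnames
      m
    } else f
  })
  do.call(ground_truth, out)
}

#' Generate a co-registered two-channel phantom with controlled overlap
#'
#' Channel A is the phantom of `spec`; channel B shares the ellipsoid and a
#' fraction `overlap_fraction` of A's spots, while the remaining B spots are
#' displaced to disjoint positions, so that the expected Mander's M1 of A
#' against B equals `overlap_fraction`.
#'
#' @param spec a [nucleus_phantom_spec()].
#' @param overlap_fraction fraction of A spots shared by B, in \[0, 1\].
#' @return list `image_a`, `image_b`, `ground_truth`.
#' @export
gen_two_channel <- function(spec, overlap_fraction) {
  assert_that(is.numeric(overlap_fraction) && overlap_fraction >= 0 &&
                overlap_fraction <= 1,
              "overlap_fraction must lie in [0, 1]")
  a <- gen_nucleus_stack(spec)
  n <- spec$n_spots
  k <- round(overlap_fraction * n)
  centers_a <- a$ground_truth$true_spot_centers   # (x, y, z) grid µm
  g <- phantom_grid(spec)
  ctr_g <- c(g$center_zyx[3], g$center_zyx[2], g$center_zyx[1])
  shared <- centers_a[seq_len(k), , drop = FALSE]
  n_new <- n - k
  sep <- max(spec$min_spot_separation, 2 * spec$spot_diameter)
  new_centers <- matrix(numeric(0), 0, 3)
  if (n_new > 0) {
    eff <- spec$semi_axes - spec$spot_diameter / 2 - 1e-9
    R <- euler_rotation(spec$orientation)
    taken <- centers_a
    with_seed(derive_seed(spec$geometry_seed, 7919), {
      for (i in seq_len(n_new)) {
        placed <- FALSE
        for (attempt in seq_len(10000L)) {
          q <- (runif(3) * 2 - 1) * eff
          if (sum((q / eff)^2) > 1) next
          p <- as.numeric(R %*% q) + ctr_g
          all_pts <- rbind(taken, new_centers)
          if (nrow(all_pts) > 0) {
            dmin <- min(sqrt(rowSums((all_pts -
                     matrix(p, nrow(all_pts), 3, byrow = TRUE))^2)))
            if (dmin < sep) next
          }
          new_centers <- rbind(new_centers, p)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("spot packing failed for displaced channel-B spots", call. = FALSE)
      }
    })
  }
  centers_b <- rbind(shared, new_centers)
  img_b <- render_channel(spec, centers_b, ctr_g, g,
                          seed = derive_seed(spec$seed, 13))
  gt <- a$ground_truth
  gt$true_spot_centers_b <- centers_b
  gt$overlap_fraction <- overlap_fraction
  list(image_a = a$image,
       image_b = voxel_image(img_b, spec$voxel_size, channel = "H3K9me3"),
       ground_truth = gt)
}

# Render a channel with given spot centers (grid µm, columns x,y,z).
render_channel <- function(spec, centers, ctr_g, g, seed) {
  dims <- g$dims
  vs <- spec$voxel_size
  zc <- (seq_len(dims[1]) - 1) * vs[1] - g$center_zyx[1]
  yc <- (seq_len(dims[2]) - 1) * vs[2] - g$center_zyx[2]
  xc <- (seq_len(dims[3]) - 1) * vs[3] - g$center_zyx[3]
  R <- euler_rotation(spec$orientation)
  A <- R %*% diag(1 / spec$semi_axes^2) %*% t(R)
  X <- array(rep(xc, each = dims[1] * dims[2]), dims)
  Y <- array(rep(rep(yc, each = dims[1]), dims[3]), dims)
  Z <- array(rep(zc, dims[2] * dims[3]), dims)
  q <- A[1, 1] * X^2 + A[2, 2] * Y^2 + A[3, 3] * Z^2 +
    2 * (A[1, 2] * X * Y + A[1, 3] * X * Z + A[2, 3] * Y * Z)
  img <- array(spec$background, dims)
  img[q <= 1] <- spec$base_intensity
  noise_sd <- sqrt(spec$base_intensity + spec$read_noise_sd^2)
  amp <- if (is.finite(spec$snr)) spec$snr * noise_sd
         else 5 * spec$base_intensity
  r_spot <- spec$spot_diameter / 2
  for (i in seq_len(nrow(centers))) {
    ctr <- centers[i, ] - ctr_g
    zi <- which(abs(zc - ctr[3]) <= r_spot)
    yi <- which(abs(yc - ctr[2]) <= r_spot)
    xi <- which(abs(xc - ctr[1]) <= r_spot)
    d2 <- outer(outer((zc[zi] - ctr[3])^2, (yc[yi] - ctr[2])^2, "+"),
                (xc[xi] - ctr[1])^2, "+")
    sub <- img[zi, yi, xi]
    sub[d2 <= r_spot^2] <- spec$base_intensity + amp
    img[zi, yi, xi] <- sub
  }
  img <- gaussian_blur3d(img, spec$psf_sigma / vs)
  if (is.finite(spec$snr)) {
    with_seed(seed, {
      img[] <- rpois(length(img), lambda = pmax(img, 0)) +
        rnorm(length(img), sd = spec$read_noise_sd)
    })
    img[img < 0] <- 0
  }
  img
}

#' Generate 2D fractional-Brownian-motion tracks
#'
#' Exact fractional Gaussian noise synthesis per axis (Cholesky factor of the
#' fGn covariance), independent x and y components, so that the ensemble MSD
#' follows `E[MSD(t)] = 2 * step_scale^2 * (t/dt)^(2H)` and the ground-truth
#' anomalous exponent is `alpha = 2 * hurst`.
#'
#' @param n_tracks number of tracks.
#' @param hurst Hurst exponent in (0, 1).
#' @param n_steps steps per track (track has `n_steps + 1` frames).
#' @param dt_min frame interval, minutes.
#' @param step_scale per-axis SD of a single-step increment, µm.
#' @param seed RNG seed.
#' @return data.frame `track_id, frame, t_min, x_um, y_um` with ground truth
#'   (`alpha`, `hurst`) in `attr(, "ground_truth")`.
#' @export
gen_tracks_fbm <- function(n_tracks, hurst, n_steps, dt_min = 30,
                           step_scale = 0.1, seed = 1L) {
  assert_that(hurst > 0 && hurst < 1, "hurst must lie strictly in (0, 1)")
  assert_that(n_steps >= 1 && n_tracks >= 1, "need at least one track and step")
  h2 <- 2 * hurst
  k <- 0:(n_steps - 1)
  acov <- 0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(pmax(k - 1, -1))^h2)
  acov[1] <- 1
  C <- stats::toeplitz(acov)
  L <- t(chol(C + diag(1e-12, n_steps)))
  out <- vector("list", n_tracks)
  with_seed(seed, {
    for (i in seq_len(n_tracks)) {
      dx <- step_scale * as.numeric(L %*% rnorm(n_steps))
      dy <- step_scale * as.numeric(L %*% rnorm(n_steps))
      out[[i]] <- data.frame(
        track_id = i, frame = 0:n_steps,
        t_min = (0:n_steps) * dt_min,
        x_um = c(0, cumsum(dx)), y_um = c(0, cumsum(dy)))
    }
  })
  df <- do.call(rbind, out)
  attr(df, "ground_truth") <- ground_truth(true_alpha = 2 * hurst,
                                           hurst = hurst,
                                           step_scale = step_scale,
                                           dt_min = dt_min)
  df
}

#' Generate a synthetic FRAP recovery curve
#'
#' Samples the single-diffusion recovery model
#' `F(t) = (F0 + Finf * (t/t1)/2) / (1 + (t/t1)/2)`, multiplied by
#' `exp(-bleach_rate * t)` to emulate acquisition bleaching, plus Gaussian
#' noise. Time zero is the first post-bleach frame.
#'
#' @param F0 post-bleach floor (fraction of pre-bleach).
#' @param Finf recovery plateau; requires `0 <= F0 <= Finf <= 1`.
#' @param t1 model timescale, seconds (half-recovery occurs at `2 * t1`).
#' @param n_points number of post-bleach samples.
#' @param dt_s sampling interval, seconds.
#' @param noise_sd Gaussian noise SD (fraction units).
#' @param bleach_rate acquisition bleaching rate, 1/s.
#' @param seed RNG seed.
#' @return a `frap_curve` (times, normalized intensity, ground truth).
#' @export
gen_frap_curve <- function(F0, Finf, t1, n_points = 600L, dt_s = 0.1,
                           noise_sd = 0, bleach_rate = 0, seed = 1L) {
  assert_that(F0 >= 0 && F0 <= Finf && Finf <= 1,
              "parameters must satisfy 0 <= F0 <= Finf <= 1")
  assert_that(t1 > 0, "t1 must be positive")
  t <- (seq_len(n_points) - 1) * dt_s
  f <- (F0 + Finf * (t / t1) / 2) / (1 + (t / t1) / 2)
  f <- f * exp(-bleach_rate * t)
  if (noise_sd > 0)
    with_seed(seed, f <- f + rnorm(length(f), sd = noise_sd))
  structure(list(times = t, intensity = f, prebleach = 1,
                 roi_kind = "inside_condensate",
                 ground_truth = ground_truth(true_frap_params =
                   c(F0 = F0, Finf = Finf, t1 = t1),
                   bleach_rate = bleach_rate, noise_sd = noise_sd)),
            class = "frap_curve")
}

#' Generate a blocky 1-Mb binned ChIP-like signal track
#'
#' Per-arm two-state Markov chain of on/off domains (geometric domain
#' lengths) with one log-normal intensity per on-domain; off bins carry 0 and
#' mark monomers with no HP1 binding (purely repulsive in the polymer model).
#'
#' @param arm_lengths_mb named integer vector of arm lengths in Mb (= bins).
#' @param domain_mean_len_mb mean on-domain length, Mb.
#' @param signal_dist list with `meanlog`, `sdlog` of the log-normal
#'   on-intensity, and `on_fraction`, the stationary fraction of bound bins.
#' @param seed RNG seed.
#' @return data.frame `chrom, start, end, value` (bedGraph convention:
#'   0-based half-open intervals in bp).
#' @export
gen_chip_track <- function(arm_lengths_mb = c(chr8p = 44L, chr13q = 92L,
                                              chr14q = 84L, chr19p = 22L,
                                              chr22q = 16L),
                           domain_mean_len_mb = 5,
                           signal_dist = list(meanlog = 0, sdlog = 0.5,
                                              on_fraction = 0.4),
                           seed = 1L) {
  assert_that(length(arm_lengths_mb) >= 1, "arm list must not be empty")
  assert_that(all(arm_lengths_mb >= 1), "arm lengths must be >= 1 Mb")
  on_frac <- signal_dist$on_fraction %||% 0.4
  rows <- vector("list", length(arm_lengths_mb))
  with_seed(seed, {
    for (a in seq_along(arm_lengths_mb)) {
      n <- arm_lengths_mb[[a]]
      state <- integer(n)
      value <- numeric(n)
      if (on_frac > 0) {
        p_on_off <- min(1, 1 / domain_mean_len_mb)
        off_mean <- domain_mean_len_mb * (1 - on_frac) / on_frac
        p_off_on <- min(1, 1 / off_mean)
        s <- as.integer(runif(1) < on_frac)
        cur_val <- if (s == 1)
          exp(rnorm(1, signal_dist$meanlog, signal_dist$sdlog)) else 0
        for (i in seq_len(n)) {
          state[i] <- s
          value[i] <- cur_val
          flip <- runif(1) < if (s == 1) p_on_off else p_off_on
          if (flip) {
            s <- 1L - s
            cur_val <- if (s == 1)
              exp(rnorm(1, signal_dist$meanlog, signal_dist$sdlog)) else 0
          }
        }
      }
      nm <- names(arm_lengths_mb)[a] %||% paste0("arm", a)
      rows[[a]] <- data.frame(chrom = nm,
                              start = (seq_len(n) - 1) * 1e6,
                              end = seq_len(n) * 1e6,
                              value = value)
    }
  })
  do.call(rbind, rows)
}

#' Write / read a binned signal track as bedGraph
#'
#' @param track data.frame `chrom, start, end, value` (0-based half-open).
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  lines <- sprintf("%s\t%d\t%d\t%.17g", track$chrom, as.integer(track$start),
                   as.integer(track$end), track$value)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names =
                            c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  df
}
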