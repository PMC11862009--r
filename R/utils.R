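# Internal helpers shared across modules.

# Run code with a temporarily-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic sub-seed derivation: counter scheme below 2^31 so adding
# items never reshuffles earlier ones.
derive_seed <- function(master, index) {
  (as.numeric(master) * 10007 + as.numeric(index)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Separable Gaussian smoothing of a 3D array (axis order z, y, x) with
# per-axis sigma given in voxels. Zero-sigma axes are left untouched.
gaussian_blur3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L, length(sigma_vox) == 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# Convolve along one axis with a symmetric kernel, replicating the border
# (sum of shifted copies; cheap and vectorized).
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  half <- (length(kernel) - 1L) / 2L
  out <- array(0, d)
  for (t in seq_along(kernel)) {
    off <- t - 1L - half
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # clamp = replicate border
    out <- out + kernel[t] * slice_index(arr, axis, idx)
  }
  out
}

slice_index <- function(arr, axis, idx) {
  switch(axis,
    arr[idx, , , drop = FALSE],
    arr[, idx, , drop = FALSE],
    arr[, , idx, drop = FALSE])
}

# Otsu threshold on a numeric vector (maximize between-class variance).
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) <= 0)
    stop("cannot threshold a constant image: no separable foreground", call. = FALSE)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(values, br, rightmost.closed = TRUE,
                                        all.inside = TRUE), nbins = n_bins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  tot_w <- w[n_bins]
  tot_m <- m[n_bins]
  w1 <- w[-n_bins]; m1 <- m[-n_bins]
  w2 <- tot_w - w1
  valid <- w1 > 0 & w2 > 0
  mu1 <- m1 / w1
  mu2 <- (tot_m - m1) / w2
  between <- w1 * w2 * (mu1 - mu2)^2
  between[!valid] <- -Inf
  br[which.max(between) + 1L]
}

# Voxel-center physical coordinates (micrometres) of TRUE voxels in a mask.
# Returns an n x 3 matrix with columns (z, y, x); 0-based indices map to
# index * voxel_size (voxel centers).
mask_coords_um <- function(mask, voxel_size) {
  idx <- which(mask)
  d <- dim(mask)
  i0 <- idx - 1L
  z <- i0 %% d[1]
  y <- (i0 %/% d[1]) %% d[2]
  x <- i0 %/% (d[1] * d[2])
  cbind(z = z * voxel_size[1], y = y * voxel_size[2], x = x * voxel_size[3])
}
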