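# Shared fixture builders; everything is generated in code at test time.

# Small, fast phantom spec for unit tests.
small_spec <- function(...) {
  args <- list(semi_axes = c(4, 3, 1.5), n_spots = 5L, spot_diameter = 0.6,
               min_spot_separation = 1.2, snr = 10,
               seed = 1L, geometry_seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(nucleus_phantom_spec, args)
}

# Voxelized sphere mask of radius r voxels at pitch 1 um.
sphere_mask <- function(r = 20, pitch = c(1, 1, 1)) {
  n <- as.integer(2 * ceiling(r / min(pitch)) + 9)
  ctr <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  m <- array(((g$z - ctr) * pitch[1])^2 + ((g$y - ctr) * pitch[2])^2 +
               ((g$x - ctr) * pitch[3])^2 <= r^2, c(n, n, n))
  attr(m, "voxel_size") <- pitch
  m
}

# Voxelized axis-aligned ellipsoid mask (semi-axes in um, voxel pitch z,y,x).
ellipsoid_mask <- function(semi_xyz, pitch = c(0.25, 0.25, 0.25), margin = 4L) {
  half <- ceiling(rev(semi_xyz) / pitch) + margin
  dims <- as.integer(2 * half + 1)
  zc <- ((seq_len(dims[1]) - 1) - half[1]) * pitch[1]
  yc <- ((seq_len(dims[2]) - 1) - half[2]) * pitch[2]
  xc <- ((seq_len(dims[3]) - 1) - half[3]) * pitch[3]
  Z <- array(rep(zc, dims[2] * dims[3]), dims)
  Y <- array(rep(rep(yc, each = dims[1]), dims[3]), dims)
  X <- array(rep(xc, each = dims[1] * dims[2]), dims)
  m <- (X / semi_xyz[1])^2 + (Y / semi_xyz[2])^2 + (Z / semi_xyz[3])^2 <= 1
  dim(m) <- dims
  attr(m, "voxel_size") <- pitch
  m
}

# Independent single-linkage + exhaustive silhouette-cut oracle (graph
# threshold components; no hclust), for n <= 30.
oracle_silhouette_cut <- function(pts) {
  n <- nrow(pts)
  dm <- as.matrix(dist(pts))
  heights <- sort(unique(dm[upper.tri(dm)]))
  comp_at <- function(h) {
    # union-find over edges with d <= h
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (dm[i, j] <= h) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- parent[rj] <- min(ri, rj)
      }
    labs <- vapply(seq_len(n), find, 1L)
    as.integer(factor(labs))
  }
  sil <- function(labels) {
    k <- max(labels)
    s <- numeric(n)
    for (i in seq_len(n)) {
      own <- labels == labels[i]
      if (sum(own) == 1) { s[i] <- 0; next }
      a <- mean(dm[i, own & seq_len(n) != i])
      b <- min(vapply(setdiff(seq_len(k), labels[i]), function(cl)
        mean(dm[i, labels == cl]), 1))
      s[i] <- (b - a) / max(a, b)
    }
    mean(s)
  }
  best <- list(sil = -Inf, k = 1L, labels = rep(1L, n))
  for (h in heights) {
    labels <- comp_at(h)
    k <- max(labels)
    if (k < 2 || k > n - 1) next
    sc <- sil(labels)
    if (sc > best$sil || (sc == best$sil && k < best$k))
      best <- list(sil = sc, k = k, labels = labels)
  }
  if (best$sil <= 0) best <- list(sil = best$sil, k = 1L, labels = rep(1L, n))
  best
}
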