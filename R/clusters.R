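#' Detect condensates in a simulation frame by silhouette-cut clustering
#'
#' Single-linkage agglomerative clustering on the 3D Euclidean distances of
#' the bound monomers. Candidate cuts are the distinct dendrogram merge
#' heights; for every cut yielding `2 <= k <= n - 1` clusters the mean
#' silhouette coefficient is computed and the cut with the maximal
#' silhouette is selected (ties broken toward fewer clusters). If no cut
#' achieves a positive silhouette, all monomers form a single cluster.
#' Clusters with at least `min_size` monomers count as condensates.
#'
#' @param positions n x 3 matrix of bound-monomer coordinates (sigma units).
#' @param min_size minimum monomers per condensate (default 3; excludes
#'   trivially-linked bonded pairs).
#' @return list of class `cluster_result`: `labels`, `n_clusters`,
#'   `silhouette`, `centroids` (condensates only), `sizes`, `condensate`
#'   (logical per cluster).
#' @export
cluster_condensates <- function(positions, min_size = 3L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) {
    labels <- rep(1L, n)
    cen <- if (n == 1 && min_size <= 1) positions else
      matrix(numeric(0), 0, 3)
    return(structure(list(labels = labels, n_clusters = n,
                          silhouette = NA_real_,
                          centroids = cen, sizes = rep(1L, n),
                          condensate = rep(min_size <= 1, n)),
                     class = "cluster_result"))
  }
  d <- dist(positions)
  hc <- hclust(d, method = "single")
  dm <- as.matrix(d)
  heights <- unique(hc$height)
  cuts <- cutree(hc, h = heights)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1)
  best <- list(sil = -Inf, labels = rep(1L, n), k = 1L)
  for (ci in seq_along(heights)) {
    labels <- cuts[, ci]
    k <- max(labels)
    if (k < 2 || k > n - 1) next
    s <- mean_silhouette(dm, labels)
    # ties resolved toward fewer clusters (heights ascend, k descends)
    if (s > best$sil || (s == best$sil && k < best$k))
      best <- list(sil = s, labels = labels, k = k)
  }
  if (!is.finite(best$sil) || best$sil <= 0)
    best <- list(sil = if (is.finite(best$sil)) best$sil else NA_real_,
                 labels = rep(1L, n), k = 1L)
  sizes <- tabulate(best$labels, nbins = best$k)
  cond <- sizes >= min_size
  centroids <- t(vapply(seq_len(best$k), function(cl)
    colMeans(positions[best$labels == cl, , drop = FALSE]), numeric(3)))
  structure(list(labels = best$labels, n_clusters = best$k,
                 silhouette = best$sil,
                 centroids = centroids[cond, , drop = FALSE],
                 sizes = sizes, condensate = cond),
            class = "cluster_result")
}

# Mean silhouette coefficient over all points given a distance matrix and
# integer labels; singleton clusters contribute 0.
mean_silhouette <- function(dm, labels) {
  n <- nrow(dm)
  k <- max(labels)
  sizes <- tabulate(labels, nbins = k)
  # summed distance of each point to each cluster
  md <- matrix(0, n, k)
  for (cl in seq_len(k))
    md[, cl] <- rowSums(dm[, labels == cl, drop = FALSE])
  own <- cbind(seq_len(n), labels)
  a <- md[own] / (sizes[labels] - 1)          # NaN for singletons (size 1)
  mb <- sweep(md, 2, sizes, "/")
  mb[own] <- Inf
  b <- do.call(pmin, as.data.frame(mb))
  s <- (b - a) / pmax(a, b)
  s[sizes[labels] == 1] <- 0
  mean(s)
}

#' Normalized radial and peripheral positions of condensates
#'
#' Radial position `R = |centroid - shell center| / a` (semi-major axis,
#' default). The `"ray"` alternative normalizes by the shell radius along
#' the centroid's direction instead (R = 1 on the wall for every shape, and
#' identically-distributed material scores identically across shapes); both
#' conventions coincide for spheres. Peripheral
#' position `P = d_surface / c` (semi-minor axis), where `d_surface` is the
#' distance from the centroid to the nearest point on the ellipsoidal shell
#' surface, found numerically. At the shell center of any shape, R = 0 and
#' P = 1.
#'
#' @param result a `cluster_result`.
#' @param shell a `shell_spec`.
#' @param normalization `"ray"` or `"semi_major"`.
#' @return data.frame, one row per condensate: `R`, `P`, `size`.
#' @export
normalized_positions <- function(result, shell,
                                 normalization = c("semi_major", "ray")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(result, "cluster_result"), inherits(shell, "shell_spec"))
  cen <- result$centroids
  if (nrow(cen) == 0)
    return(data.frame(R = numeric(0), P = numeric(0), size = integer(0)))
  a <- shell$semi_axes[["a"]]; cc <- shell$semi_axes[["c"]]
  r_abs <- sqrt(rowSums(cen^2))
  if (normalization == "semi_major") {
    R <- r_abs / a
  } else {
    # shell radius along the centroid's direction: |r| scaled so the wall
    # sits at R = 1 for every shape
    ell <- sqrt(rowSums(sweep(cen, 2, c(a, a, cc), "/")^2))
    R <- ifelse(r_abs > 0, ell, 0)
  }
  P <- vapply(seq_len(nrow(cen)), function(i)
    dist_to_spheroid(cen[i, ], a, cc), numeric(1)) / cc
  inside <- rowSums(sweep(cen, 2, c(a, a, cc), "/")^2) < 1
  if (!all(inside))
    warning(sum(!inside), " condensate centroid(s) outside the shell")
  data.frame(R = R, P = P, size = result$sizes[result$condensate])
}

# Distance from an interior point to the surface of the spheroid
# x^2/a^2 + y^2/a^2 + z^2/c^2 = 1 (axisymmetric: reduce to the (rho, z)
# plane and minimize over the surface parameter).
dist_to_spheroid <- function(p, a, c) {
  rho <- sqrt(p[1]^2 + p[2]^2)
  z <- abs(p[3])
  f <- function(t) (rho - a * cos(t))^2 + (z - c * sin(t))^2
  opt <- optimize(f, c(0, pi / 2), tol = 1e-10)
  sqrt(opt$objective)
}

#' Condensate count and size distributions across an ensemble
#'
#' Per-condition summaries of condensate counts (and sizes) over independent
#' runs, with pairwise Mann-Whitney comparisons between conditions.
#'
#' @param results data.frame with columns `condition`, `run`, `n_condensates`
#'   (one row per run; e.g. built from repeated [cluster_condensates()]
#'   calls).
#' @return list: `summary` (per condition), `comparisons` (pairwise tests).
#' @export
condensate_count_distribution <- function(results) {
  stopifnot(all(c("condition", "run", "n_condensates") %in% names(results)))
  conds <- unique(results$condition)
  counts <- tabulate(factor(results$condition, conds))
  if (length(unique(counts)) > 1)
    warning("unbalanced ensembles across conditions")
  summ <- do.call(rbind, lapply(conds, function(cd) {
    v <- results$n_condensates[results$condition == cd]
    data.frame(condition = cd, n_runs = length(v), median = median(v),
               q25 = quantile(v, 0.25, names = FALSE),
               q75 = quantile(v, 0.75, names = FALSE), mean = mean(v))
  }))
  comparisons <- list()
  if (length(conds) > 1) {
    for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
      va <- results$n_condensates[results$condition == conds[i]]
      vb <- results$n_condensates[results$condition == conds[j]]
      cmp <- mann_whitney(va, vb)
      cmp$group_a <- conds[i]; cmp$group_b <- conds[j]
      comparisons[[paste(conds[i], conds[j], sep = " vs ")]] <- cmp
    }
  }
  list(summary = summ, comparisons = comparisons)
}

#' Cluster condensates across the frames of a trajectory
#'
#' Applies [cluster_condensates()] to the bound monomers of each sampled
#' frame and [normalized_positions()] against the shell, returning a long
#' table ready for KDE/boxplot summaries. By convention the clustered set is
#' the bound monomers only (`eps_i > 0`); set `all_monomers = TRUE` to
#' cluster every monomer.
#'
#' @param traj a `polymer_trajectory`.
#' @param min_size minimum condensate size.
#' @param frames which sampled frames to use (default all).
#' @param all_monomers cluster all monomers instead of bound only.
#' @return data.frame: `frame, cluster, size, R, P, n_condensates,
#'   silhouette`.
#' @export
cluster_trajectory <- function(traj, min_size = 3L, frames = NULL,
                               all_monomers = FALSE) {
  stopifnot(inherits(traj, "polymer_trajectory"))
  shell <- traj$system$shell
  sel <- if (all_monomers) rep(TRUE, length(traj$system$eps$eps))
         else traj$system$eps$eps > 0
  nf <- dim(traj$frames)[3]
  frames <- frames %||% seq_len(nf)
  rows <- lapply(frames, function(f) {
    pos <- traj$frames[sel, , f, drop = FALSE]
    dim(pos) <- c(sum(sel), 3)
    cr <- cluster_condensates(pos, min_size = min_size)
    np <- normalized_positions(cr, shell)
    if (nrow(np) == 0) return(NULL)
    data.frame(frame = f, cluster = seq_len(nrow(np)), size = np$size,
               R = np$R, P = np$P, n_condensates = nrow(np),
               silhouette = cr$silhouette)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(0), cluster = integer(0),
                      size = integer(0), R = numeric(0), P = numeric(0),
                      n_condensates = integer(0), silhouette = numeric(0))
  out
}
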