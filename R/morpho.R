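#' Segment nuclei from a 3D stack
#'
#' Anisotropy-aware Gaussian blur followed by global intensity thresholding
#' (Otsu by default) and 26-connected component labeling. By default only
#' the largest component is kept as the nucleus; `multi = TRUE` keeps every
#' component (multi-nucleus fields of view).
#'
#' @param img a single-channel, single-timepoint [voxel_image()].
#' @param blur_sigma_um Gaussian blur sigma in µm (converted per axis to
#'   voxels).
#' @param method threshold method; only `"otsu"` is provided.
#' @param multi keep all components instead of the largest.
#' @param min_voxels drop components smaller than this (only with `multi`).
#' @return integer label array (`label_volume`): 0 background, labels 1..K.
#' @export
segment_nucleus <- function(img, blur_sigma_um = 0.1, method = "otsu",
                            multi = FALSE, min_voxels = 64L) {
  stopifnot(inherits(img, "voxel_image"))
  assert_that(img$axes == "zyx", "segment_nucleus expects a single timepoint")
  assert_that(identical(method, "otsu"), paste0("unknown threshold method: ", method))
  arr <- gaussian_blur3d(img$data, blur_sigma_um / img$voxel_size)
  thr <- otsu_threshold(as.numeric(arr))
  fg <- arr > thr
  if (!any(fg)) stop("segmentation produced an empty foreground", call. = FALSE)
  labels <- cpp_label3d(fg, dim(fg), 26L)
  if (multi) {
    sizes <- tabulate(labels[labels > 0])
    keep <- which(sizes >= min_voxels)
    labels <- relabel_components(labels, keep)
  } else {
    sizes <- tabulate(labels[labels > 0])
    labels <- relabel_components(labels, which.max(sizes))
  }
  structure(labels, voxel_size = img$voxel_size, class = c("label_volume", "array"))
}

relabel_components <- function(labels, keep) {
  map <- integer(max(labels, 1L))
  map[keep] <- seq_along(keep)
  out <- array(0L, dim(labels))
  nz <- labels > 0
  out[nz] <- map[labels[nz]]
  out
}

label_mask <- function(labels, id = 1L) {
  m <- labels == id
  dim(m) <- dim(labels)
  m
}

#' Principal axis lengths of a nucleus mask
#'
#' Voxel centers are mapped to physical µm coordinates, centered, and rotated
#' into the object's principal frame (eigenvectors of the coordinate
#' covariance). Axis lengths are the extents along the three principal
#' directions plus the voxel footprint projected on each direction. Along the
#' minor direction, `trim_fraction` of voxels is excluded from each extreme
#' (quantile clipping) before taking the extent, to remove boundary
#' irregularities on the confinement axis.
#'
#' @param nucleus a `label_volume` from [segment_nucleus()] (or logical mask
#'   with a `voxel_size` attribute).
#' @param trim_fraction fraction trimmed from each extreme of the minor-axis
#'   coordinate distribution (default 0.001, i.e. 0.1%).
#' @param voxel_size override for the (z, y, x) voxel size in µm.
#' @param id which label to measure.
#' @return named numeric: `major`, `intermediate`, `minor` (µm), plus the
#'   rotation matrix and centroid as attributes.
#' @export
principal_axes <- function(nucleus, trim_fraction = 0.001, voxel_size = NULL,
                           id = 1L) {
  vs <- voxel_size %||% attr(nucleus, "voxel_size")
  assert_that(!is.null(vs), "voxel_size not available on mask; pass explicitly")
  mask <- if (is.logical(nucleus)) nucleus else label_mask(nucleus, id)
  n <- sum(mask)
  assert_that(n >= 4, "degenerate object: fewer than 4 voxels")
  co <- mask_coords_um(mask, vs)          # columns z, y, x
  xyz <- co[, c(3, 2, 1), drop = FALSE]   # to (x, y, z)
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  # principal directions, descending variance: major, intermediate, minor
  dirs <- ev$vectors
  proj <- xc %*% dirs
  vs_xyz <- c(vs[3], vs[2], vs[1])
  lens <- numeric(3)
  for (k in 1:3) {
    w <- proj[, k]
    foot <- sum(abs(dirs[, k]) * vs_xyz)  # voxel footprint along direction
    if (k == 3 && trim_fraction > 0) {
      q <- stats::quantile(w, c(trim_fraction, 1 - trim_fraction),
                           names = FALSE, type = 7)
      lens[k] <- diff(q) + foot
    } else {
      lens[k] <- max(w) - min(w) + foot
    }
  }
  lens <- sort(lens, decreasing = TRUE)  # guard against near-ties
  out <- c(major = lens[1], intermediate = lens[2], minor = lens[3])
  attr(out, "rotation") <- dirs
  attr(out, "centroid_xyz") <- ctr
  out
}

#' Dimensionless nucleus shape metrics
#'
#' `elongation = 1 - sqrt(intermediate / major)`,
#' `flatness = 1 - sqrt(minor / major)`,
#' `sphericity = (36 * pi * V^2)^(1/3) / A`; the reported height is the
#' minor-axis length (the confinement axis). A flatness of 1 indicates a
#' flat plane; a sphericity of 1 a perfect sphere.
#'
#' @param axes named vector from [principal_axes()].
#' @param V volume in µm³.
#' @param A surface area in µm².
#' @return data.frame with one row of `NucleusMorphometry` fields.
#' @export
shape_metrics <- function(axes, V, A) {
  assert_that(all(axes > 0), "axis lengths must be positive")
  assert_that(axes["major"] >= axes["intermediate"] &&
                axes["intermediate"] >= axes["minor"],
              "axes must be ordered major >= intermediate >= minor")
  assert_that(V > 0 && A > 0, "V and A must be positive")
  ctr <- attr(axes, "centroid_xyz") %||% c(NA_real_, NA_real_, NA_real_)
  data.frame(
    major_axis = unname(axes["major"]),
    intermediate_axis = unname(axes["intermediate"]),
    minor_axis = unname(axes["minor"]),
    height = unname(axes["minor"]),
    elongation = unname(1 - sqrt(axes["intermediate"] / axes["major"])),
    flatness = unname(1 - sqrt(axes["minor"] / axes["major"])),
    sphericity = unname((36 * pi * V^2)^(1 / 3) / A),
    volume_um3 = V, area_um2 = A,
    centroid_x = ctr[1], centroid_y = ctr[2], centroid_z = ctr[3])
}

#' Volume and surface area of a nucleus mask
#'
#' Volume is voxel count times voxel volume. Surface area is estimated
#' either from a marching-tetrahedra isosurface of the lightly smoothed mask
#' (`"mesh"`, default; unbiased on smooth bodies) or by summing exposed voxel
#' faces (`"voxel_faces"`, the literal voxel-counting convention, which
#' overestimates curved surfaces by a staircase factor of about 1.5).
#'
#' @param nucleus `label_volume` or logical mask with `voxel_size` attribute.
#' @param area_method `"mesh"` or `"voxel_faces"`.
#' @param voxel_size optional (z, y, x) µm override.
#' @param id label to measure.
#' @return named numeric `c(V = ..., A = ...)` in µm³ / µm².
#' @export
volume_surface <- function(nucleus, area_method = c("mesh", "voxel_faces"),
                           voxel_size = NULL, id = 1L) {
  area_method <- match.arg(area_method)
  vs <- voxel_size %||% attr(nucleus, "voxel_size")
  assert_that(!is.null(vs), "voxel_size not available on mask; pass explicitly")
  mask <- if (is.logical(nucleus)) nucleus else label_mask(nucleus, id)
  n <- sum(mask)
  assert_that(n >= 1, "empty object")
  V <- n * prod(vs)
  if (area_method == "voxel_faces") {
    A <- cpp_voxel_face_area(mask, dim(mask), vs)
  } else {
    vol <- array(0, dim(mask))
    vol[mask] <- 1
    # pad so the isosurface closes at the array border
    vol <- pad_array(vol, 2L)
    vol <- gaussian_blur3d(vol, c(1, 1, 1))
    A <- cpp_march_area(vol, dim(vol), vs, 0.5)
  }
  c(V = V, A = A)
}

pad_array <- function(arr, n) {
  d <- dim(arr)
  out <- array(0, d + 2L * n)
  out[n + seq_len(d[1]), n + seq_len(d[2]), n + seq_len(d[3])] <- arr
  out
}

#' Full morphometry of every nucleus in a stack
#'
#' Convenience wrapper: segment, then per nucleus compute principal axes,
#' volume, area and the shape metrics.
#'
#' @param img a [voxel_image()].
#' @param config configuration list (see [default_config()]), `imaging` block.
#' @param multi measure all nuclei rather than the largest.
#' @return data.frame, one row per nucleus, with `nucleus_id`.
#' @export
measure_nuclei <- function(img, config = default_config(), multi = FALSE) {
  cfg <- config$imaging
  labels <- segment_nucleus(img, blur_sigma_um = cfg$blur_sigma_um,
                            method = cfg$threshold_method, multi = multi)
  k <- max(labels)
  rows <- lapply(seq_len(k), function(id) {
    axes <- principal_axes(labels, trim_fraction = cfg$trim_fraction, id = id)
    va <- volume_surface(labels, area_method = cfg$area_method, id = id)
    cbind(nucleus_id = id, shape_metrics(axes, va["V"], va["A"]))
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}
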