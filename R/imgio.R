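#' Voxel image with physical voxel sizes
#'
#' Container for a 3D (or 3D+time) fluorescence intensity grid. The axis
#' order is fixed as (z, y, x) for single timepoints and (t, z, y, x) for
#' time series; physical positions are voxel centers at
#' `index * voxel_size` (0-based indices, micrometres).
#'
#' @param data numeric array, 3D `(z, y, x)` or 4D `(t, z, y, x)`,
#'   nonnegative intensities.
#' @param voxel_size numeric length-3, voxel pitch in micrometres in order
#'   (z, y, x). Must be strictly positive.
#' @param channel optional channel label.
#' @param dt_min frame interval in minutes (required information for 4D data).
#' @return an object of class `voxel_image`.
#' @export
voxel_image <- function(data, voxel_size, channel = NULL, dt_min = NULL) {
  nd <- length(dim(data))
  assert_that(nd %in% c(3L, 4L), "data must be a 3D (z,y,x) or 4D (t,z,y,x) array")
  assert_that(length(voxel_size) == 3L && all(voxel_size > 0),
              "voxel_size must be 3 strictly positive lengths (z, y, x)")
  assert_that(all(is.finite(data)) && min(data) >= 0,
              "intensities must be finite and nonnegative")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 channel = channel, dt_min = dt_min,
                 axes = if (nd == 3L) "zyx" else "tzyx"),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat("<voxel_image> axes", x$axes, "dim", paste(dim(x$data), collapse = "x"),
      "voxel", paste(signif(x$voxel_size, 4), collapse = "x"), "um\n")
  invisible(x)
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

#' Extract one timepoint of a 4D stack as a 3D voxel image
#'
#' @param img a [voxel_image()].
#' @param t timepoint index (1-based).
#' @return a 3D `voxel_image`.
#' @export
frame_at <- function(img, t) {
  stopifnot(inherits(img, "voxel_image"))
  if (img$axes == "zyx") return(img)
  voxel_image(img$data[t, , , ], img$voxel_size, img$channel, img$dt_min)
}

## ---------------------------------------------------------------------------
## Minimal baseline TIFF codec.
##
## The deployment environment has no R TIFF library, so the package carries a
## small codec for uncompressed little-endian grayscale TIFF: 32-bit float
## samples, one strip per page, voxel metadata as a JSON ImageDescription.
## This is sufficient for lossless round-trips of the package's own stacks
## and for detecting foreign files that lack voxel-size metadata.
## ---------------------------------------------------------------------------

#' Write a voxel image as a multi-page TIFF
#'
#' Pages are z-slices (and, for 4D data, timepoints in t-major order). Voxel
#' sizes, axis layout and frame interval are stored in a JSON
#' `ImageDescription` tag so that [read_stack()] round-trips losslessly.
#'
#' @param img a [voxel_image()].
#' @param path output path.
#' @param metadata write the JSON metadata tag (`TRUE`); disabling this
#'   produces a plain TIFF, used in tests to emulate foreign files.
#' @return `path`, invisibly.
#' @export
write_stack <- function(img, path, metadata = TRUE) {
  stopifnot(inherits(img, "voxel_image"))
  d <- dim(img$data)
  if (img$axes == "zyx") {
    pages <- lapply(seq_len(d[1]), function(z) img$data[z, , ])
    w <- d[3]; h <- d[2]
  } else {
    pages <- list()
    for (t in seq_len(d[1])) for (z in seq_len(d[2]))
      pages[[length(pages) + 1L]] <- img$data[t, z, , ]
    w <- d[4]; h <- d[3]
  }
  desc <- if (metadata) {
    jsonlite::toJSON(list(
      nucleoscope = TRUE, axes = img$axes, shape = d,
      voxel_size_um = img$voxel_size, dt_min = img$dt_min,
      channel = img$channel), auto_unbox = TRUE, digits = NA, null = "null")
  } else NULL

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  n_pages <- length(pages)
  page_bytes <- w * h * 4
  data_start <- 8
  desc_raw <- if (!is.null(desc)) {
    r <- c(charToRaw(as.character(desc)), as.raw(0))
    if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
    r
  } else raw(0)
  desc_off <- data_start + n_pages * page_bytes
  ifd_start <- desc_off + length(desc_raw)
  n_entries <- function(p) if (p == 1 && !is.null(desc)) 11L else 10L
  ifd_sizes <- 2 + 12 * vapply(seq_len(n_pages), n_entries, 1L) + 4
  ifd_offsets <- ifd_start + cumsum(c(0, head(ifd_sizes, -1)))

  writeBin(charToRaw("II"), con)
  w2(42); w4(ifd_offsets[1])
  for (p in seq_len(n_pages)) {
    # page data row-major (y rows of x); matrix is (y, x) so transpose-free
    # writing needs x fastest: t(page) stored column-major gives x fastest
    writeBin(as.numeric(t(pages[[p]])), con, size = 4, endian = "little")
  }
  if (length(desc_raw)) writeBin(desc_raw, con)
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3 && count == 1) { w2(value); w2(0) } else w4(value)
  }
  for (p in seq_len(n_pages)) {
    w2(n_entries(p))
    entry(256, 4, 1, w)                          # ImageWidth
    entry(257, 4, 1, h)                          # ImageLength
    entry(258, 3, 1, 32)                         # BitsPerSample
    entry(259, 3, 1, 1)                          # Compression: none
    entry(262, 3, 1, 1)                          # Photometric: BlackIsZero
    if (p == 1 && !is.null(desc))
      entry(270, 2, length(desc_raw), desc_off)  # ImageDescription
    entry(273, 4, 1, data_start + (p - 1) * page_bytes)  # StripOffsets
    entry(277, 3, 1, 1)                          # SamplesPerPixel
    entry(278, 4, 1, h)                          # RowsPerStrip
    entry(279, 4, 1, page_bytes)                 # StripByteCounts
    entry(339, 3, 1, 3)                          # SampleFormat: IEEE float
    w4(if (p < n_pages) ifd_offsets[p + 1] else 0)
  }
  invisible(path)
}

#' Read a TIFF stack into a voxel image
#'
#' Reads uncompressed little-endian grayscale TIFF (8/16-bit unsigned or
#' 32-bit float). Voxel sizes are taken from the JSON metadata written by
#' [write_stack()]; a file without voxel-size metadata is an error unless
#' `voxel_size` is supplied explicitly (no silent defaults).
#'
#' @param path TIFF file path.
#' @param voxel_size optional explicit (z, y, x) voxel size in micrometres,
#'   overriding (or substituting for) file metadata.
#' @return a [voxel_image()].
#' @export
read_stack <- function(path, voxel_size = NULL) {
  assert_that(file.exists(path), sprintf("file does not exist: %s", path))
  raw_all <- readBin(path, "raw", file.info(path)$size)
  assert_that(length(raw_all) >= 8, "not a TIFF file: truncated header")
  if (rawToChar(raw_all[1:2]) != "II")
    stop("unsupported TIFF: only little-endian ('II') files are read", call. = FALSE)
  u2 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u4 <- function(off) sum(as.numeric(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  assert_that(u2(2) == 42, "not a TIFF file: bad magic number")
  ifd <- u4(4)
  pages <- list()
  desc <- NULL
  while (ifd != 0) {
    n <- u2(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u2(off); type <- u2(off + 2); count <- u4(off + 4)
      val <- if (type == 3 && count == 1) u2(off + 8) else u4(off + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val,
                                        voff = off + 8)
    }
    gt <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    w <- gt(256); h <- gt(257)
    assert_that(!is.null(w) && !is.null(h), "TIFF page missing dimensions")
    assert_that(gt(259, 1) == 1, "unsupported TIFF: compressed data")
    bits <- gt(258, 1)
    fmt <- gt(339, 1)
    if (!is.null(tags[["270"]]) && is.null(desc)) {
      dsc <- tags[["270"]]
      dr <- raw_all[dsc$value + seq_len(dsc$count)]
      dr <- dr[dr != as.raw(0)]
      desc <- tryCatch(jsonlite::fromJSON(rawToChar(dr)), error = function(e) NULL)
    }
    so <- tags[["273"]]; sc <- tags[["279"]]
    assert_that(!is.null(so), "TIFF page missing strip offsets")
    read_strip <- function(offset, nbytes) {
      bytes <- raw_all[offset + seq_len(nbytes)]
      if (bits == 32 && fmt == 3) readBin(bytes, "numeric", nbytes / 4, size = 4,
                                          endian = "little")
      else if (bits == 16) readBin(bytes, "integer", nbytes / 2, size = 2,
                                   signed = FALSE, endian = "little")
      else if (bits == 8) as.integer(bytes)
      else stop("unsupported TIFF sample layout (bits=", bits, ", format=", fmt,
                ")", call. = FALSE)
    }
    if (so$count == 1) {
      px <- read_strip(so$value, sc$value)
    } else {
      offs <- vapply(seq_len(so$count) - 1, function(k) u4(so$value + 4 * k), 1)
      cnts <- vapply(seq_len(sc$count) - 1, function(k) u4(sc$value + 4 * k), 1)
      px <- unlist(lapply(seq_along(offs), function(k) read_strip(offs[k], cnts[k])))
    }
    pages[[length(pages) + 1L]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    ifd <- u4(ifd + 2 + n * 12)
  }
  vs <- voxel_size
  axes <- "zyx"; dt_min <- NULL; channel <- NULL; shape <- NULL
  if (!is.null(desc) && isTRUE(desc$nucleoscope)) {
    if (is.null(vs)) vs <- as.numeric(desc$voxel_size_um)
    axes <- desc$axes %||% "zyx"
    dt_min <- desc$dt_min
    channel <- desc$channel
    shape <- as.integer(desc$shape)
  }
  if (is.null(vs))
    stop("TIFF carries no voxel-size metadata; pass voxel_size explicitly ",
         "(no silent default is applied)", call. = FALSE)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr3 <- array(0, c(length(pages), h, w))
  for (z in seq_along(pages)) arr3[z, , ] <- pages[[z]]
  if (axes == "tzyx") {
    nt <- shape[1]; nz <- shape[2]
    arr <- array(0, c(nt, nz, h, w))
    for (t in seq_len(nt)) for (z in seq_len(nz))
      arr[t, z, , ] <- arr3[(t - 1) * nz + z, , ]
  } else arr <- arr3
  voxel_image(arr, vs, channel = channel, dt_min = dt_min)
}

## ---------------------------------------------------------------------------
## Typed CSV tables
## ---------------------------------------------------------------------------

#' Write / read typed CSV tables
#'
#' CSV round-trip at full double precision (17 significant digits) with a
#' UTF-8 header. `schema`, a named vector of column classes (e.g.
#' `c(id = "integer", x_um = "numeric")`), is validated on both ends; a
#' mismatch is an error naming the offending column.
#'
#' @param records a data.frame.
#' @param path file path.
#' @param schema optional named character vector of column classes.
#' @return `write_table` returns `path` invisibly; `read_table` the data.frame.
#' @export
write_table <- function(records, path, schema = NULL) {
  stopifnot(is.data.frame(records))
  check_schema(records, schema)
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema = NULL) {
  assert_that(file.exists(path), sprintf("file does not exist: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (col in names(schema)) {
      if (!col %in% names(df))
        stop("table is missing column '", col, "'", call. = FALSE)
      df[[col]] <- switch(schema[[col]],
        integer = as.integer(df[[col]]),
        numeric = as.numeric(df[[col]]),
        character = as.character(df[[col]]),
        logical = as.logical(df[[col]]),
        stop("unknown schema class for column '", col, "'", call. = FALSE))
    }
  }
  df
}

check_schema <- function(df, schema) {
  if (is.null(schema)) return(invisible(TRUE))
  for (col in names(schema)) {
    if (!col %in% names(df))
      stop("record set is missing column '", col, "'", call. = FALSE)
    ok <- switch(schema[[col]],
      integer = is.integer(df[[col]]),
      numeric = is.numeric(df[[col]]),
      character = is.character(df[[col]]),
      logical = is.logical(df[[col]]),
      FALSE)
    if (!ok) stop("column '", col, "' is not of class ", schema[[col]],
                  call. = FALSE)
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

#' Default run configuration
#'
#' All tunables of every pipeline stage, with defaults matching the study's
#' printed values where such values exist (periphery fraction 0.05, minor-axis
#' trim fraction 0.001, tracking cost cutoffs 16900/100, MSD fit window 7 h,
#' FENE k = 30, R0 = 1.5, bending constant 1 kBT, monomer volume fraction 0.10,
#' 258 monomers over five chromosome arms). Serializable to JSON via
#' [save_config()] / [load_config()]; every pipeline output embeds the
#' config hash from [config_hash()].
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    imaging = list(
      blur_sigma_um = 0.1,
      condensate_blur_sigma_um = 0.05,
      threshold_method = "otsu",
      periphery_fraction = 0.05,
      trim_fraction = 0.001,
      n_erosions = 2L,
      min_voxels = 5L,
      area_method = "mesh",
      diameter_reference = "equivalent_sphere"
    ),
    tracking = list(
      cost_cutoff = 16900,
      split_cutoff = 100,
      msd_window_hours = 7
    ),
    frap = list(
      dt_s = 0.002101,  # printed acquisition interval ("0,002101 s"), 600 frames
      n_points = 600L
    ),
    polymer = list(
      n_monomers = 258L,
      arm_lengths_mb = c(chr8p = 44L, chr13q = 92L, chr14q = 84L,
                         chr19p = 22L, chr22q = 16L),
      phi = 0.10,
      fene_k = 30, fene_r0 = 1.5, bend_k = 1,
      lj_cut = 2.5,
      level_scales = c(E1 = 0.5, E2 = 1.0, E3 = 1.5, E4 = 2.0),
      dt = 0.01, gamma = 1,
      equil_steps = 2e5, sample_steps = 2e5, sample_every = 1e4
    ),
    clustering = list(min_size = 3L)
  )
}

#' @rdname default_config
#' @param config configuration list.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
load_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file does not exist: %s", path))
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname default_config
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
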