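#' Demo imaging-pipeline configuration
#'
#' Three synthetic conditions emulating non-confined, 3-5 µm and <3 µm
#' confinement: progressively flatter ellipsoids with fewer condensate
#' spots, following the direction of change seen in confined fibroblasts.
#'
#' @param n_per_condition nuclei per condition.
#' @return config list for [run_imaging_pipeline()].
#' @export
imaging_demo_config <- function(n_per_condition = 3L) {
  base <- default_config()
  base$conditions <- list(
    list(name = "non_confined", semi_axes = c(5.5, 4.5, 3.0), n_spots = 16L),
    list(name = "confined_3_5um", semi_axes = c(6.5, 5.5, 1.9), n_spots = 10L),
    list(name = "confined_lt3um", semi_axes = c(8.0, 6.0, 1.285), n_spots = 8L))
  base$n_per_condition <- as.integer(n_per_condition)
  base
}

#' Run the imaging pipeline end to end on synthetic nuclei
#'
#' generate -> segment -> morphometry -> condensate detection -> scaled
#' distances -> radius-matched controls -> condition comparisons. Every
#' output table carries the config hash; per-stage wall-clock times are
#' recorded in the manifest.
#'
#' @param config from [imaging_demo_config()] (or a compatible list).
#' @return list: `manifest`, `nuclei` (morphometry table), `condensates`
#'   (incl. control records), `comparisons`.
#' @export
run_imaging_pipeline <- function(config = imaging_demo_config()) {
  t0 <- proc.time()[["elapsed"]]
  hash <- config_hash(config)
  cfg <- config$imaging
  nuclei <- list(); condensates <- list()
  stage_times <- c()
  run_idx <- 0L
  for (cond in config$conditions) {
    for (rep in seq_len(config$n_per_condition)) {
      run_idx <- run_idx + 1L
      seed_i <- derive_seed(config$seed, run_idx)
      spec <- nucleus_phantom_spec(
        semi_axes = cond$semi_axes, n_spots = cond$n_spots,
        seed = seed_i, geometry_seed = derive_seed(seed_i, 1))
      gen <- gen_nucleus_stack(spec)
      labels <- segment_nucleus(gen$image, blur_sigma_um = cfg$blur_sigma_um)
      axes <- principal_axes(labels, trim_fraction = cfg$trim_fraction)
      va <- volume_surface(labels, area_method = cfg$area_method)
      morph <- shape_metrics(axes, va[["V"]], va[["A"]])
      morph$condition <- cond$name
      morph$nucleus_id <- run_idx
      det <- detect_condensates(gen$image, labels,
                                blur_sigma_um = cfg$condensate_blur_sigma_um %||%
                                  cfg$blur_sigma_um,
                                n_erosions = cfg$n_erosions,
                                min_voxels = cfg$min_voxels)
      rec <- det$records
      if (nrow(rec) > 0) {
        rec <- radial_peripheral_distances(
          rec, labels, morph, periphery_fraction = cfg$periphery_fraction,
          diameter_reference = cfg$diameter_reference)
        ctl <- sample_control_points(
          labels, rec, morph, seed = derive_seed(seed_i, 2),
          periphery_fraction = cfg$periphery_fraction,
          diameter_reference = cfg$diameter_reference)
        rec <- rbind(rec, ctl)
        rec$condition <- cond$name
        rec$nucleus_id <- run_idx
        condensates[[length(condensates) + 1L]] <- rec
      }
      morph$n_condensates <- nrow(det$records)
      morph$scaled_condensate_volume <-
        scaled_condensate_volume(det$records, morph$volume_um3)
      nuclei[[length(nuclei) + 1L]] <- morph
    }
  }
  nuclei <- do.call(rbind, nuclei)
  condensates <- if (length(condensates)) do.call(rbind, condensates) else
    empty_condensate_records()
  conds <- vapply(config$conditions, `[[`, "", "name")
  comparisons <- list()
  for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
    key <- paste(conds[i], conds[j], sep = " vs ")
    comparisons[[key]] <- list(
      n_condensates = mann_whitney(
        nuclei$n_condensates[nuclei$condition == conds[i]],
        nuclei$n_condensates[nuclei$condition == conds[j]]),
      height = mann_whitney(
        nuclei$height[nuclei$condition == conds[i]],
        nuclei$height[nuclei$condition == conds[j]]))
  }
  manifest <- list(pipeline = "imaging", config_hash = hash,
                   seed = config$seed, n_runs = run_idx,
                   package_version = as.character(packageVersion("nucleoscope")),
                   elapsed_s = proc.time()[["elapsed"]] - t0)
  nuclei$config_hash <- hash
  if (nrow(condensates)) condensates$config_hash <- hash
  list(manifest = manifest, nuclei = nuclei, condensates = condensates,
       comparisons = comparisons)
}

#' Run the simulation pipeline over a shape x level x seed grid
#'
#' ChIP-like signal -> per-monomer epsilon -> shell -> initialization ->
#' Langevin dynamics -> per-frame silhouette clustering -> normalized R/P
#' table and per-condition count comparisons.
#'
#' @param config a [default_config()]-style list; the `polymer` block
#'   controls the model, `shapes`, `levels` and `n_seeds` the grid.
#' @param shapes confinement shapes to run.
#' @param levels interaction-strength levels to run.
#' @param n_seeds independent replicate runs per condition.
#' @return list: `manifest`, `clusters` (long table: shape, level, seed,
#'   frame, R, P, ...), `counts` (per run), `count_stats`.
#' @export
run_simulation_pipeline <- function(config = default_config(),
                                    shapes = c("sphere", "oblate_0.33"),
                                    levels = c("E1", "E4"),
                                    n_seeds = 2L) {
  t0 <- proc.time()[["elapsed"]]
  hash <- config_hash(config)
  pc <- config$polymer
  bad <- setdiff(shapes, c("sphere", "oblate_0.5", "oblate_0.33"))
  if (length(bad))
    stop("invalid shape name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(levels, names(pc$level_scales))
  if (length(bad))
    stop("invalid level name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  track <- gen_chip_track(arm_lengths_mb = pc$arm_lengths_mb,
                          seed = derive_seed(config$seed, 900))
  rows <- list(); counts <- list()
  for (shape in shapes) {
    shell <- build_shell(shape, n_monomers = pc$n_monomers, phi = pc$phi)
    for (level in levels) {
      eps <- chip_to_epsilon(track, level = level,
                             scale_map = pc$level_scales)
      for (s in seq_len(n_seeds)) {
        run_seed <- derive_seed(config$seed,
                                1000 * match(shape, shapes) +
                                  100 * match(level, levels) + s)
        sys <- init_system(pc$arm_lengths_mb, eps, shell, seed = run_seed)
        traj <- run_langevin(sys, n_steps = pc$equil_steps + pc$sample_steps,
                             dt = pc$dt, gamma = pc$gamma,
                             sample_every = pc$sample_every,
                             lj_cut = pc$lj_cut,
                             seed = derive_seed(run_seed, 5))
        nf <- dim(traj$frames)[3]
        keep <- which(seq_len(nf) * pc$sample_every > pc$equil_steps)
        cl <- cluster_trajectory(traj, min_size = config$clustering$min_size,
                                 frames = keep)
        if (nrow(cl) > 0) {
          cl$shape <- shape; cl$level <- level; cl$seed_rep <- s
          rows[[length(rows) + 1L]] <- cl
        }
        counts[[length(counts) + 1L]] <- data.frame(
          condition = paste(shape, level, sep = ":"), run = s,
          n_condensates = if (nrow(cl) > 0) mean(cl$n_condensates[
            !duplicated(cl$frame)]) else 0)
      }
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else NULL
  counts <- do.call(rbind, counts)
  count_stats <- if (length(unique(counts$condition)) > 1)
    condensate_count_distribution(counts) else NULL
  manifest <- list(pipeline = "simulation", config_hash = hash,
                   seed = config$seed,
                   grid = list(shapes = shapes, levels = levels,
                               n_seeds = n_seeds),
                   package_version = as.character(packageVersion("nucleoscope")),
                   elapsed_s = proc.time()[["elapsed"]] - t0)
  list(manifest = manifest, clusters = clusters, counts = counts,
       count_stats = count_stats)
}
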