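# Experiment orchestration: paired-dataset simulation across a grid of
# motion levels x shot counts x trajectories, staged reconstruction,
# training, correction and evaluation, with deterministic per-cell
# seeding from one master seed.
#
# On-disk container: one RDS file per experiment cell holding the groups
# (clean images, corrupted k-space, masks, motion parameters, and the
# stage outputs added later) plus a JSON provenance sidecar recording the
# configuration and seeds needed to regenerate it.

#' Simulate a paired clean/corrupted dataset
#'
#' For each image: draw a phantom, draw a per-shot motion trajectory and
#' (for the random trajectory) a sampling scheme from seeds derived from
#' `seed`, corrupt the k-space with the forward motion model, and
#' reconstruct the artifact image with CG-SENSE.
#'
#' @param n_images Number of image pairs.
#' @param size Image side length.
#' @param delta_theta Maximum rotation between shots (degrees).
#' @param n_shots Number of shots.
#' @param scheme_name Encoding trajectory name (see [make_scheme()]).
#' @param n_coils Number of simulated receive coils.
#' @param seed Integer seed; the dataset is deterministic in it.
#' @param schedule Motion schedule (see [make_motion()]).
#' @param max_translation Maximum translation (pixels).
#' @param n_ellipses Phantom complexity.
#' @param keep_kspace Keep the corrupted multi-coil k-space and masks in
#'   the returned object (needed by the staged pipeline; off by default
#'   to keep training datasets small).
#' @param cg Optional [cg_config()] for the reconstruction stage.
#' @return A `paired_dataset`: list with `clean` and `corrupted`
#'   `[size, size, 1, n]` arrays, per-image `motion` parameters, `meta`,
#'   and optionally `kspace`/`schemes`.
#' @export
make_paired_dataset <- function(n_images, size, delta_theta, n_shots,
                                scheme_name = "random", n_coils = 8L,
                                seed = 0L, schedule = "constant_increment",
                                max_translation = 0, n_ellipses = 8L,
                                keep_kspace = FALSE, cg = cg_config()) {
  abort_if(n_images < 1, "`n_images` must be >= 1")
  coils <- simulate_coil_maps(n_coils, size)
  clean <- array(0, c(size, size, 1L, n_images))
  corrupted <- array(0, c(size, size, 1L, n_images))
  motions <- vector("list", n_images)
  kspaces <- if (keep_kspace) vector("list", n_images) else NULL
  schemes <- if (keep_kspace) vector("list", n_images) else NULL
  fixed_scheme <- if (scheme_name != "random")
    make_scheme(scheme_name, n_shots, size) else NULL
  for (i in seq_len(n_images)) {
    ph <- generate_phantom(size, seed = derive_seed(seed, "phantom", i),
                           n_ellipses = n_ellipses)
    motion <- make_motion(schedule, n_shots, delta_theta, max_translation,
                          seed = derive_seed(seed, "motion", i))
    scheme <- if (is.null(fixed_scheme))
      make_scheme("random", n_shots, size,
                  seed = derive_seed(seed, "scheme", i)) else fixed_scheme
    y <- forward_corrupt(ph, motion, scheme, coils)
    rec <- cg_sense_reconstruct(y, coils, cg)
    clean[, , 1L, i] <- ph
    corrupted[, , 1L, i] <- rec$image
    motions[[i]] <- motion
    if (keep_kspace) { kspaces[[i]] <- y$samples; schemes[[i]] <- scheme }
  }
  structure(list(clean = clean, corrupted = corrupted, motion = motions,
                 kspace = kspaces, schemes = schemes,
                 meta = list(n_images = n_images, size = size,
                             delta_theta = delta_theta, n_shots = n_shots,
                             scheme_name = scheme_name, n_coils = n_coils,
                             schedule = schedule,
                             max_translation = max_translation,
                             seed = as.integer(seed))),
            class = "paired_dataset")
}

#' Read or write a paired dataset container
#'
#' One RDS file per dataset plus a `.json` provenance sidecar with the
#' simulation parameters and seed.
#'
#' @param dataset A `paired_dataset`.
#' @param path RDS file path.
#' @return `path` (write) or the dataset (read).
#' @export
write_dataset <- function(dataset, path) {
  abort_if(!inherits(dataset, "paired_dataset"),
           "`dataset` must be a paired_dataset")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset, path)
  jsonlite::write_json(dataset$meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  abort_if(!file.exists(path), sprintf("dataset '%s' does not exist", path))
  ds <- readRDS(path)
  abort_if(!inherits(ds, "paired_dataset"),
           "file does not contain a paired_dataset")
  ds
}

#' Experiment-grid configuration
#'
#' Defaults cover the full study grids (motion levels 2-14 degrees, shot
#' counts 2-128, all four trajectories); scale `n_images`, `image_size`
#' and the training settings down for desk-scale runs.
#'
#' @param delta_thetas Motion levels in degrees.
#' @param shot_counts Numbers of shots.
#' @param trajectories Trajectory names.
#' @param n_images Image pairs per grid cell.
#' @param image_size Image side length.
#' @param n_coils Simulated coil count.
#' @param schedule Motion schedule name.
#' @param cg A [cg_config()].
#' @param train A [train_config()].
#' @param unet A [unet_config()].
#' @param master_seed Master seed fanned out to grid cells.
#' @param output_dir Directory for datasets, checkpoints and reports.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(delta_thetas = c(2, 5, 8, 10, 12, 14),
                              shot_counts = c(2, 4, 8, 16, 32, 64, 128),
                              trajectories = "random",
                              n_images = 32L, image_size = 128L,
                              n_coils = 8L,
                              schedule = "constant_increment",
                              cg = cg_config(), train = train_config(),
                              unet = unet_config(input_size = image_size),
                              master_seed = 0L, output_dir = "experiments") {
  abort_if(any(delta_thetas < 0), "motion levels must be >= 0")
  abort_if(any(shot_counts < 1), "shot counts must be >= 1")
  abort_if(!all(trajectories %in% SCHEME_NAMES),
           "unknown trajectory name in `trajectories`")
  structure(list(delta_thetas = delta_thetas, shot_counts = shot_counts,
                 trajectories = trajectories,
                 n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 n_coils = as.integer(n_coils), schedule = schedule,
                 cg = cg, train = train, unet = unet,
                 master_seed = as.integer(master_seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Top-level keys mirror the [experiment_config()] arguments; `cg`,
#' `train` and `unet` are nested sections passed to their constructors.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  abort_if(!file.exists(path), sprintf("config '%s' does not exist", path))
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("cg", "train", "unet"))]
  if (!is.null(y$cg)) args$cg <- do.call(cg_config, y$cg)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$unet)) args$unet <- do.call(unet_config, y$unet)
  do.call(experiment_config, args)
}

cell_label <- function(dt, S, traj) {
  sprintf("dtheta%s_S%d_%s", format(dt, trim = TRUE), S, traj)
}

cell_path <- function(config, dt, S, traj) {
  file.path(config$output_dir, paste0(cell_label(dt, S, traj), ".rds"))
}

grid_cells <- function(config) {
  expand.grid(delta_theta = config$delta_thetas,
              n_shots = config$shot_counts,
              trajectory = config$trajectories,
              stringsAsFactors = FALSE)
}

#' Simulate every cell of an experiment grid
#'
#' Writes one paired-dataset container per (motion level, shot count,
#' trajectory) cell under `config$output_dir`; each cell's seed is
#' derived from the master seed and the cell label, so cells are
#' independently reproducible.
#'
#' @param config An `experiment_config`.
#' @param keep_kspace Keep corrupted k-space in the containers.
#' @return Data frame of cells and their file paths, invisibly.
#' @export
run_simulate <- function(config, keep_kspace = FALSE) {
  cells <- grid_cells(config)
  cells$path <- NA_character_
  for (i in seq_len(nrow(cells))) {
    dt <- cells$delta_theta[i]; S <- cells$n_shots[i]
    traj <- cells$trajectory[i]
    ds <- make_paired_dataset(
      config$n_images, config$image_size, dt, S, traj, config$n_coils,
      seed = derive_seed(config$master_seed, cell_label(dt, S, traj)),
      schedule = config$schedule, keep_kspace = keep_kspace,
      cg = config$cg)
    path <- cell_path(config, dt, S, traj)
    write_dataset(ds, path)
    cells$path[i] <- path
    message(sprintf("simulated %s (%d pairs)", cell_label(dt, S, traj),
                    config$n_images))
  }
  invisible(cells)
}

#' Re-reconstruct the corrupted k-space of a stored dataset
#'
#' Adds/overwrites the `reconstructed` group of a dataset that was
#' simulated with `keep_kspace = TRUE`, recording CG iteration counts and
#' final residuals.
#'
#' @param path Dataset RDS path.
#' @param cg A [cg_config()].
#' @return The augmented dataset, invisibly.
#' @export
run_reconstruct <- function(path, cg = cg_config()) {
  ds <- read_dataset(path)
  abort_if(is.null(ds$kspace),
           "dataset has no stored k-space; simulate with keep_kspace = TRUE")
  size <- ds$meta$size
  coils <- simulate_coil_maps(ds$meta$n_coils, size)
  n <- ds$meta$n_images
  rec <- array(0, c(size, size, 1L, n))
  iters <- integer(n); resid <- numeric(n)
  for (i in seq_len(n)) {
    r <- cg_sense_reconstruct(ds$kspace[[i]], coils, cg,
                              mask = scheme_union_mask(ds$schemes[[i]]))
    rec[, , 1L, i] <- r$image
    iters[i] <- r$iterations_used
    resid[i] <- r$residual_history[length(r$residual_history)]
  }
  ds$reconstructed <- rec
  ds$cg_info <- data.frame(image = seq_len(n), iterations = iters,
                           final_residual = resid)
  saveRDS(ds, path)
  invisible(ds)
}

#' Train a corrector for one experiment cell
#'
#' @param path Dataset RDS path (clean/corrupted pairs).
#' @param config An `experiment_config` (its `train`/`unet` sections are
#'   used).
#' @param checkpoint Output checkpoint path (default: alongside the
#'   dataset).
#' @param val_dataset Optional held-out `paired_dataset`.
#' @return The `trained_corrector`, invisibly.
#' @export
run_train <- function(path, config, checkpoint = NULL, val_dataset = NULL) {
  ds <- read_dataset(path)
  model <- train(ds, config$train, config$unet, val_dataset = val_dataset)
  if (is.null(checkpoint)) checkpoint <- sub("\\.rds$", "_model.rds", path)
  save_corrector(model, checkpoint)
  invisible(model)
}

#' Apply a trained corrector to a stored dataset
#'
#' Adds the `corrected` group to the dataset container.
#'
#' @param path Dataset RDS path.
#' @param model A `trained_corrector` or checkpoint path.
#' @return The augmented dataset, invisibly.
#' @export
run_correct <- function(path, model) {
  if (is.character(model)) model <- load_corrector(model)
  ds <- read_dataset(path)
  ds$corrected <- correct(model, ds$corrupted)
  saveRDS(ds, path)
  invisible(ds)
}

#' Evaluate a stored dataset: corrupted and corrected vs clean
#'
#' @param path Dataset RDS path.
#' @param report_prefix Optional path prefix; when given, per-comparison
#'   CSV/JSON reports are written as `<prefix>_corrupted.csv` etc.
#' @return Named list of `metrics_report`s (one per available
#'   comparison: `corrupted`, `reconstructed`, `corrected`).
#' @export
run_evaluate <- function(path, report_prefix = NULL) {
  ds <- read_dataset(path)
  refs <- batch_to_list(ds$clean)
  out <- list()
  for (group in c("corrupted", "reconstructed", "corrected")) {
    if (is.null(ds[[group]])) next
    rep <- evaluate_set(refs, batch_to_list(ds[[group]]))
    out[[group]] <- rep
    if (!is.null(report_prefix))
      write_metrics_report(rep,
                           csv_path = sprintf("%s_%s.csv", report_prefix,
                                              group),
                           json_path = sprintf("%s_%s.json", report_prefix,
                                               group))
  }
  abort_if(length(out) == 0, "dataset has no image groups to evaluate")
  out
}

# [H, W, 1, B] array -> list of matrices.
batch_to_list <- function(x) {
  x <- as_image_batch(x)
  lapply(seq_len(dim(x)[4]), function(i) matrix(x[, , 1L, i],
                                                dim(x)[1], dim(x)[2]))
}

#' @export
print.paired_dataset <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<paired_dataset> %d pairs, %dx%d, dtheta=%g deg, S=%d, %s, %d coils\n",
    m$n_images, m$size, m$size, m$delta_theta, m$n_shots, m$scheme_name,
    m$n_coils))
  invisible(x)
}
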