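#' Specification of a simulated pulling dataset
#'
#' Bundles the experiment grid for [generate_dataset()]: which pulling
#' geometries, the velocity ladder, replicates per (mode, velocity) cell,
#' and the simulator settings shared across curves. Defaults reproduce the
#' study conditions: velocities 500-5000 nm/s, ~30 pN/nm cantilever,
#' mode-specific class weights from [default_mode_classes()].
#'
#' @param modes Character vector, subset of `c("HAP", "PAP")`.
#' @param velocities Pulling velocities, nm/s.
#' @param replicates Curves per (mode, velocity) cell.
#' @param n_units Unfoldable units per construct.
#' @param spring_constant Cantilever spring constant, pN/nm.
#' @param sampling_rate Sampling rate, Hz.
#' @param temperature Temperature, K.
#' @param max_piezo Piezo travel, nm.
#' @param force_noise_sd Force noise SD, pN.
#' @param classes Optional named list `list(HAP = , PAP = )` of class tables
#'   overriding [default_mode_classes()].
#' @param initial_contour_length Optional named list overriding the
#'   per-mode initial contour length.
#' @param base_seed Base RNG seed; curve `i` of the grid uses
#'   `base_seed + i`.
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(modes = c("HAP", "PAP"),
                           velocities = c(500, 1000, 2000, 3000, 5000),
                           replicates = 20,
                           n_units = 6,
                           spring_constant = 30,
                           sampling_rate = 1e4,
                           temperature = 298,
                           max_piezo = 300,
                           force_noise_sd = 5,
                           classes = NULL,
                           initial_contour_length = NULL,
                           base_seed = 1L) {
  modes <- match.arg(modes, c("HAP", "PAP"), several.ok = TRUE)
  stopifnot(all(velocities > 0), replicates >= 1, n_units >= 1)
  structure(
    list(modes = modes, velocities = velocities, replicates = replicates,
         n_units = n_units, spring_constant = spring_constant,
         sampling_rate = sampling_rate, temperature = temperature,
         max_piezo = max_piezo, force_noise_sd = force_noise_sd,
         classes = classes, initial_contour_length = initial_contour_length,
         base_seed = as.integer(base_seed)),
    class = "dataset_config"
  )
}

#' Generate a dataset of simulated pulling curves on disk
#'
#' Simulates one curve per (mode, velocity, replicate) cell of the config
#' grid, writes each to a TSV file ([write_force_curve()]) under `out_dir`,
#' and writes `manifest.json` enumerating files with their metadata. Curve
#' `i` (in grid order) is seeded with `base_seed + i`, so the whole dataset
#' is reproducible file-for-file; the random construct of each curve is
#' drawn under the same per-curve seed.
#'
#' @param config A [dataset_config()].
#' @param out_dir Output directory (created if missing).
#' @param overwrite If `FALSE` (default) an existing non-empty `out_dir` is
#'   an error.
#' @return The manifest as a tibble (`path`, `mode`, `velocity_nm_per_s`,
#'   `replicate`, `seed`), invisibly written to `manifest.json`.
#' @export
generate_dataset <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "dataset_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is non-empty; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  grid <- tidyr::expand_grid(
    mode = config$modes,
    velocity = config$velocities,
    replicate = seq_len(config$replicates)
  )
  grid$seed <- config$base_seed + seq_len(nrow(grid))

  rows <- purrr::pmap(grid, function(mode, velocity, replicate, seed) {
    classes <- if (!is.null(config$classes)) config$classes[[mode]] else
      default_mode_classes(mode)
    init_lc <- if (!is.null(config$initial_contour_length))
      config$initial_contour_length[[mode]] else NULL
    # construct draw uses an offset seed so it does not share the start of
    # the simulation RNG stream
    model <- withr::with_seed(seed + 1000003L, sample_construct(
      mode, n_units = config$n_units, classes = classes,
      initial_contour_length = init_lc
    ))
    proto <- pulling_protocol(
      velocity, spring_constant = config$spring_constant,
      sampling_rate = config$sampling_rate, temperature = config$temperature,
      max_piezo = config$max_piezo, force_noise_sd = config$force_noise_sd,
      seed = seed
    )
    curve <- simulate_curve(model, proto)
    fname <- sprintf("curve_%s_v%04d_r%03d.tsv", mode, as.integer(velocity),
                     replicate)
    write_force_curve(curve, file.path(out_dir, fname))
    tibble::tibble(path = fname, mode = mode, velocity_nm_per_s = velocity,
                   replicate = replicate, seed = seed)
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(manifest)
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.json` or to the dataset directory
#'   containing it.
#' @return Manifest tibble with `path` resolved relative to the manifest.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path)) stop("no manifest at ", path, call. = FALSE)
  m <- tibble::as_tibble(jsonlite::fromJSON(path))
  m$path <- file.path(dirname(path), m$path)
  m
}
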