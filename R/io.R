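CONFIG_SCHEMA_VERSION <- "1.0"

# tiny rolling-hash digest over a canonical JSON rendering; identifies the
# config that produced an artifact without external dependencies
config_digest <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Validate and normalise a simulation configuration file
#'
#' Reads a YAML configuration with sections `simulation` (the
#' [tissue_config()] fields) and `potential` (the [potential_params()]
#' fields) plus a `schema_version`. Unknown keys are rejected by name;
#' missing keys take the package defaults; invalid values raise errors
#' naming the offending field.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with `config` (a `tissue_config`), `params`
#'   (`potential_params`), `schema_version`, and `digest`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Configuration file not found: %s", path),
          class = "blastopack_config_error")
  }
  raw <- yaml::read_yaml(path)
  known_top <- c("schema_version", "simulation", "potential")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "blastopack_config_error")
  }
  sim <- raw$simulation %||% list()
  pot <- raw$potential %||% list()
  check_keys <- function(given, allowed, section) {
    extra <- setdiff(names(given), allowed)
    if (length(extra)) {
      abort(sprintf("Unknown key(s) in `%s`: %s", section,
                    paste(extra, collapse = ", ")),
            class = "blastopack_config_error")
    }
  }
  check_keys(sim, names(formals(tissue_config)), "simulation")
  check_keys(pot, names(formals(potential_params)), "potential")
  config <- do.call(tissue_config, sim)
  params <- do.call(potential_params, pot)
  version <- as.character(raw$schema_version %||% CONFIG_SCHEMA_VERSION)
  if (version != CONFIG_SCHEMA_VERSION) {
    abort(sprintf("Unsupported schema_version `%s` (expected %s).",
                  version, CONFIG_SCHEMA_VERSION),
          class = "blastopack_config_error")
  }
  list(config = config, params = params, schema_version = version,
       digest = config_digest(list(simulation = unclass(config),
                                   potential = unclass(params))))
}

#' Write a trajectory to a run directory
#'
#' Emits a run manifest (JSON: schema version, seed, configuration, digest,
#' software version), per-snapshot positions (`positions.csv`: `step`,
#' `cell_id`, `x`, `y`, `fixed`) and the observables table
#' (`observables.csv`). Tables are plain UTF-8 CSV with a header row.
#'
#' @param traj A `trajectory` from [run_simulation()].
#' @param dir Output directory (created if needed).
#' @param prefix Optional file-name prefix (e.g. a condition label).
#' @return The directory path, invisibly.
#' @export
write_trajectory <- function(traj, dir, prefix = "") {
  stopifnot(inherits(traj, "trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tag <- function(name) file.path(dir, paste0(prefix, name))
  pos <- purrr::map2_dfr(
    traj$snapshots, traj$observables$step,
    function(st, step) dplyr::mutate(as_tibble(st), step = step,
                                     .before = 1)
  ) |>
    dplyr::select("step", cell_id = "cell", "x", "y", "fixed")
  write.csv(pos, tag("positions.csv"), row.names = FALSE)
  write.csv(traj$observables, tag("observables.csv"), row.names = FALSE)
  manifest <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    subcommand = "simulate",
    seed = traj$seed,
    config = unclass(traj$config),
    potential = unclass(traj$params),
    digest = config_digest(list(simulation = unclass(traj$config),
                                potential = unclass(traj$params))),
    timestamp = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("blastopack"))
  )
  jsonlite::write_json(manifest, tag("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}

#' Read a trajectory run directory back into tables
#'
#' @param dir Directory written by [write_trajectory()].
#' @param prefix Prefix used at write time.
#' @return List with `manifest` (list), `positions` and `observables`
#'   (tibbles).
#' @export
read_trajectory <- function(dir, prefix = "") {
  tag <- function(name) file.path(dir, paste0(prefix, name))
  list(
    manifest = jsonlite::read_json(tag("manifest.json"), simplifyVector = TRUE),
    positions = as_tibble(read.csv(tag("positions.csv"))),
    observables = as_tibble(read.csv(tag("observables.csv")))
  )
}

#' Run the cavity-expansion experiment with a matched no-growth control
#'
#' Runs [run_simulation()] twice with identical seeds: once as configured
#' (the cavity-growth condition) and once with the growth rate forced to
#' zero (the control). Writes each condition's observables and positions,
#' a `summary.json` with initial/final packing index and mean neighbour
#' degree per condition, and (optionally) a two-panel figure. On failure any
#' partially written output directory created by this call is removed.
#'
#' @param config A [tissue_config()], or the path to a YAML file accepted by
#'   [validate_config()].
#' @param out_dir Output directory.
#' @param params A [potential_params()]; ignored (taken from the file) when
#'   `config` is a path.
#' @param make_figure Write `fig_cavity_expansion.pdf`? Default `TRUE`.
#' @return A tibble with one row per condition (the [glance.trajectory()]
#'   columns plus `condition`), invisibly also carrying the trajectories in
#'   attribute `"trajectories"`.
#' @export
run_fig5d_experiment <- function(config, out_dir,
                                 params = potential_params(),
                                 make_figure = TRUE) {
  if (is.character(config)) {
    v <- validate_config(config)
    config <- v$config
    params <- v$params
  }
  stopifnot(inherits(config, "tissue_config"))
  created <- !dir.exists(out_dir)
  cleanup <- function() if (created && dir.exists(out_dir)) {
    unlink(out_dir, recursive = TRUE)
  }
  tryCatch({
    control_cfg <- config
    control_cfg$cavity_growth_rate <- 0
    growth <- run_simulation(config, params)
    control <- run_simulation(control_cfg, params)
    write_trajectory(growth, out_dir, prefix = "growth_")
    write_trajectory(control, out_dir, prefix = "control_")
    summary_tbl <- dplyr::bind_rows(
      dplyr::mutate(glance(growth), condition = "growth", .before = 1),
      dplyr::mutate(glance(control), condition = "control", .before = 1)
    )
    jsonlite::write_json(summary_tbl, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (make_figure) {
      long <- dplyr::bind_rows(
        dplyr::mutate(growth$observables, condition = "growth"),
        dplyr::mutate(control$observables, condition = "control")
      ) |>
        tidyr::pivot_longer(c("packing_index", "mean_degree"),
                            names_to = "observable", values_to = "value")
      fig <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time,
                                                y = .data$value,
                                                colour = .data$condition)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~observable, scales = "free_y") +
        ggplot2::labs(x = "time", y = NULL) +
        ggplot2::theme_minimal()
      suppressMessages(ggplot2::ggsave(
        file.path(out_dir, "fig_cavity_expansion.pdf"), fig,
        width = 8, height = 4))
    }
    attr(summary_tbl, "trajectories") <- list(growth = growth,
                                              control = control)
    invisible(summary_tbl)
  }, error = function(e) {
    cleanup()
    stop(e)
  })
}

#' Write a labelled image as TIFF files with a JSON sidecar
#'
#' Channels are written as one 32-bit float TIFF each (intensities scaled to
#' \[0, 1\]; the scale factors are recorded in the sidecar), label masks as
#' TIFFs, and ground-truth metadata as JSON. Requires the `tiff` package.
#'
#' @param img A [labeled_image()].
#' @param dir Output directory.
#' @param name Base file name.
#' @return The directory, invisibly.
#' @export
write_labeled_image <- function(img, dir, name = "image") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The `tiff` package is required for TIFF output.")
  }
  stopifnot(inherits(img, "labeled_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_ch <- dim(img$channels)[3]
  scales <- numeric(n_ch)
  offsets <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    m <- img$channels[, , ch]
    offsets[ch] <- min(m, 0)
    scales[ch] <- max(m - offsets[ch], 1e-12)
    tiff::writeTIFF((m - offsets[ch]) / scales[ch],
                    file.path(dir, sprintf("%s_ch%d.tif", name, ch)),
                    bits.per.sample = 32L)
  }
  mask_scales <- list()
  for (mk in c("cell_mask", "nucleus_mask")) {
    if (!is.null(img[[mk]])) {
      s <- max(img[[mk]], 1L)
      mask_scales[[mk]] <- s
      tiff::writeTIFF(img[[mk]] / s,
                      file.path(dir, sprintf("%s_%s.tif", name, mk)),
                      bits.per.sample = 32L)
    }
  }
  sidecar <- list(name = name, n_channels = n_ch, channel_scales = scales,
                  channel_offsets = offsets, mask_scales = mask_scales,
                  pixel_size = img$pixel_size, truth = img$truth)
  jsonlite::write_json(sidecar, file.path(dir, paste0(name, "_truth.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a labelled image written by [write_labeled_image()]
#'
#' @param dir Directory containing the files.
#' @param name Base file name used at write time.
#' @return A [labeled_image()].
#' @export
read_labeled_image <- function(dir, name = "image") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The `tiff` package is required for TIFF input.")
  }
  sidecar <- jsonlite::read_json(file.path(dir, paste0(name, "_truth.json")),
                                 simplifyVector = TRUE)
  chans <- lapply(seq_len(sidecar$n_channels), function(ch) {
    tiff::readTIFF(file.path(dir, sprintf("%s_ch%d.tif", name, ch))) *
      sidecar$channel_scales[ch] + sidecar$channel_offsets[ch]
  })
  read_mask <- function(mk) {
    f <- file.path(dir, sprintf("%s_%s.tif", name, mk))
    if (!file.exists(f)) return(NULL)
    matrix(as.integer(round(tiff::readTIFF(f) * sidecar$mask_scales[[mk]])),
           nrow = nrow(chans[[1]]))
  }
  labeled_image(
    channels = array(unlist(chans),
                     dim = c(dim(chans[[1]]), sidecar$n_channels)),
    cell_mask = read_mask("cell_mask"),
    nucleus_mask = read_mask("nucleus_mask"),
    pixel_size = sidecar$pixel_size,
    truth = sidecar$truth
  )
}
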