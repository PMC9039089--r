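TRAJ_COLS <- c("cell_id", "subpopulation", "well_id", "t_h", "intensity")

#' Read and write trajectory sets
#'
#' Trajectory sets interchange as CSV with header
#' `cell_id,subpopulation,well_id,t_h,intensity`. All cells must share one
#' uniform time grid with no duplicate `(cell_id, t_h)` pairs; violations
#' are rejected naming the offending cell. The write/read round trip is
#' lossless.
#'
#' @param path File path.
#' @return `read_trajectories()` returns a validated trajectory tibble.
#' @export
read_trajectories <- function(path) {
  # missing optional columns are handled below; silence readr's complaint
  x <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      cell_id = readr::col_character(),
                      subpopulation = readr::col_character(),
                      well_id = readr::col_character(),
                      t_h = readr::col_double(),
                      intensity = readr::col_double()
                    ))
  )
  missing <- setdiff(c("cell_id", "t_h", "intensity"), names(x))
  if (length(missing))
    stop("trajectory file lacks column(s): ", paste(missing, collapse = ", "))
  validate_trajectories(x)
  x
}

#' @rdname read_trajectories
#' @param cells Trajectory tibble to write.
#' @export
write_trajectories <- function(cells, path) {
  validate_trajectories(cells)
  out <- cells
  for (col in setdiff(TRAJ_COLS, names(out))) out[[col]] <- NA
  readr::write_csv(out[, TRAJ_COLS], path)
  invisible(path)
}

validate_trajectories <- function(cells) {
  grids <- split(cells$t_h, cells$cell_id)
  ref <- grids[[1]]
  for (id in names(grids)) {
    g <- grids[[id]]
    if (anyDuplicated(g))
      stop("duplicate timepoints for cell ", id)
    if (length(g) != length(ref) || any(sort(g) != sort(ref)))
      stop("cell ", id, " is not on the common time grid")
  }
  invisible(cells)
}

#' Run the full synthesis-to-statistics pipeline
#'
#' Orchestrates the package end to end on synthetic data: generate a
#' two-population mixing experiment, bead-normalize and log-detrend,
#' cluster into giant cells, fit the quorum-sensing and/or contact model
#' ensembles to the cluster averages, extract Hilbert phases and the
#' Kuramoto order parameter, and run the mixing-control statistics.
#' Idempotent under a fixed seed.
#'
#' @param config Named list of stage settings; see Details. Unset entries
#'   take defaults sized for a demonstration run.
#' @param out_dir Optional directory: stage outputs are written as CSV plus
#'   a plain-text run manifest.
#' @details Recognised entries: `seed`, `n_per_pop`, `phase_offset_h`,
#'   `synth` (a [synth_config()]), `fit` (a [fit_config()]), `models`
#'   (subset of `c("quorum", "contact")`), `free_rates`, `window_h`
#'   (clustering window), `detrend_window_h`.
#' @return A list: `trajectories`, `clusters`, `accuracy`, `phases`,
#'   `sync` (Kuramoto K tibble), `fits` (per model), `comparison`
#'   (delta chi-squared tibble when both models ran), `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  t_start <- Sys.time()
  seed <- config$seed %||% 1L
  n_per_pop <- config$n_per_pop %||% 20L
  offset <- config$phase_offset_h %||% 12
  synth <- config$synth %||% synth_config(duration_h = 120, seed = seed)
  synth$seed <- synth$seed %||% seed
  fitcfg <- config$fit %||% fit_config(preset = "desk",
                                       equilibration_sweeps = 200,
                                       accumulation_sweeps = 200,
                                       seed = seed)
  models <- config$models %||% "quorum"
  window_h <- config$window_h %||% c(0, 30)
  detrend_window_h <- config$detrend_window_h %||% 24

  ts <- simulate_mixing(n_per_pop, offset, synth)
  norm <- normalize_by_beads(ts, attr(ts, "beads"))
  det <- detrend_trajectories(norm, window_h = detrend_window_h)

  cl <- cluster_trajectories(det, window_h = window_h)
  acc <- clustering_accuracy(cl, attr(ts, "truth"))

  phases <- det |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$t_h, .by_group = TRUE) |>
    dplyr::reframe(hilbert_phase(.data$intensity, .data$t_h))
  sync <- phases |>
    dplyr::filter(!.data$edge) |>
    dplyr::rename(phase = "F_C") |>
    kuramoto_order(se_boot = 100, seed = seed)

  # cluster averages back on a positive scale for the reporter comparison
  fit_data <- cl$means |>
    dplyr::transmute(cell_id = paste0("c", .data$cluster),
                     t_h = .data$t_h,
                     value = exp(.data$value))
  fits <- list()
  for (m in models) {
    r <- if (m == "quorum") clock_oscillator_rates() else
      contact_oscillator_rates()
    free <- config$free_rates %||% c("D6", "L3")
    fits[[m]] <- run_ensemble(r, fit_data, fitcfg, free_rates = free)
  }
  comparison <- if (all(c("quorum", "contact") %in% names(fits))) {
    df <- abs(n_model_parameters("quorum") - n_model_parameters("contact"))
    compare_models(fits$contact, fits$quorum, df = df)
  }

  manifest <- tibble::tibble(
    stage = c("seed", "n_per_pop", "phase_offset_h", "models",
              "equilibration_sweeps", "accumulation_sweeps", "elapsed_s"),
    value = as.character(c(seed, n_per_pop, offset,
                           paste(models, collapse = "+"),
                           fitcfg$equilibration_sweeps,
                           fitcfg$accumulation_sweeps,
                           round(as.numeric(difftime(Sys.time(), t_start,
                                                     units = "secs")), 1)))
  )

  out <- list(trajectories = ts, clusters = cl, accuracy = acc,
              phases = phases, sync = sync, fits = fits,
              comparison = comparison, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectories(ts, file.path(out_dir, "trajectories.csv"))
    readr::write_csv(cl$labels, file.path(out_dir, "clusters.csv"))
    readr::write_csv(phases, file.path(out_dir, "phases.csv"))
    readr::write_csv(sync, file.path(out_dir, "sync.csv"))
    for (m in names(fits)) {
      readr::write_csv(fits[[m]]$moments,
                       file.path(out_dir, paste0("fit_", m, "_moments.csv")))
      readr::write_csv(tibble::tibble(sweep = seq_along(fits[[m]]$chi2_trace),
                                      chi2 = fits[[m]]$chi2_trace),
                       file.path(out_dir, paste0("fit_", m, "_chi2.csv")))
    }
    if (!is.null(comparison))
      readr::write_csv(comparison, file.path(out_dir, "model_comparison.csv"))
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  }
  out
}
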