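#' Configuration of the synthetic single-cell fluorescence generator
#'
#' Describes the statistical world the generator emulates: microwell
#' single-cell mCherry recordings sampled every 30 min over 10 days, with
#' circadian oscillation near a 21 h period, multiplicative
#' photobleaching-style decay, a bead reference channel, and additive
#' measurement noise. Defaults follow the experimental design where stated
#' (sampling, duration, period) and a documented realistic choice where
#' not (noise, amplitude, trend).
#'
#' @param n_cells Number of cells (>= 1).
#' @param duration_h Record length, hours (default 240 = 10 days).
#' @param dt_h Sampling interval, hours (default 0.5); `duration_h / dt_h`
#'   must be an integer.
#' @param period_mean_h,period_sd_h Per-cell oscillation periods are drawn
#'   from `N(period_mean_h, period_sd_h^2)` (defaults 21 h, 1 h).
#' @param phase_offset_h Phase offset of the whole population, hours
#'   (mixing experiments).
#' @param phase_sd_h Per-cell phase jitter SD, hours.
#' @param amplitude Relative oscillation amplitude (fraction of baseline).
#' @param noise_sd Additive measurement noise SD, intensity units.
#' @param trend_rate Multiplicative exponential decay rate, per hour
#'   (photobleaching proxy).
#' @param bead_level Bead/baseline intensity, intensity units.
#' @param bead_noise_sd Noise SD of the bead reference channel.
#' @param engine `"phase"`: closed-form cosine of a (possibly coupled)
#'   phase oscillator; `"ode"`: trajectories taken from the CCG-2 reporter
#'   of the quorum-sensing clock network ([clock_oscillator_rates()]),
#'   phase-shifted per cell.
#' @param seed Optional RNG seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 100, duration_h = 240, dt_h = 0.5,
                         period_mean_h = 21, period_sd_h = 1,
                         phase_offset_h = 0, phase_sd_h = 1,
                         amplitude = 0.3, noise_sd = 5, trend_rate = 0.003,
                         bead_level = 100, bead_noise_sd = 0,
                         engine = c("phase", "ode"), seed = NULL) {
  engine <- match.arg(engine)
  if (dt_h <= 0 || duration_h <= 0)
    stop("invalid config: duration_h and dt_h must be positive")
  n_samp <- duration_h / dt_h
  if (abs(n_samp - round(n_samp)) > 1e-8)
    stop("invalid config: duration_h / dt_h must be an integer sample count")
  if (n_cells < 1) stop("invalid config: n_cells must be >= 1")
  if (noise_sd < 0 || period_sd_h < 0 || phase_sd_h < 0 || bead_noise_sd < 0)
    stop("invalid config: noise/jitter SDs must be non-negative")
  structure(as.list(environment()), class = "synth_config")
}

#' Microwell density layouts
#'
#' The microwell chamber holds an interlaced `grid_side` x `grid_side`
#' array of 10 um wells, so the well count is `grid_side^2`; the four
#' chamber designs (126, 87, 55, 46) give 15,876 / 7,569 / 3,025 / 2,116
#' wells. `coupling_scale` sets the strength of the phase coupling the
#' generator applies for that density.
#'
#' @param grid_side Wells per chamber side (one or more values).
#' @param coupling_scale Dimensionless coupling strength, recycled.
#' @return A tibble with columns `grid_side`, `wells`, `coupling_scale`.
#' @export
#' @examples
#' density_layout(c(126, 87, 55, 46))$wells
density_layout <- function(grid_side, coupling_scale = 0) {
  if (any(grid_side < 1)) stop("grid_side must be positive")
  tibble::tibble(
    grid_side = as.integer(grid_side),
    wells = as.integer(grid_side^2),
    coupling_scale = rep_len(coupling_scale, length(grid_side))
  )
}

#' Generate a synthetic single-cell trajectory population
#'
#' Each cell's fluorescence is
#' `exp(-trend_rate * t) * bead_level * (1 + amplitude * cos(phi_i(t))) +
#' noise`, where under the `"phase"` engine `phi_i(t) = 2*pi*t/T_i +
#' phi_i(0)` with per-cell periods `T_i ~ N(period_mean_h, period_sd_h^2)`,
#' and under the `"ode"` engine the cosine is replaced by the (normalized,
#' per-cell phase-shifted) CCG-2 reporter of the quorum-sensing clock
#' network. Bit-identical under a fixed seed.
#'
#' @param config A [synth_config()].
#' @param subpopulation Label stored in the `subpopulation` column.
#' @param cell_prefix Prefix for cell ids.
#' @return A trajectory tibble (`cell_id`, `subpopulation`, `well_id`,
#'   `t_h`, `intensity`) with attributes `beads` (bead reference tibble)
#'   and `truth` (per-cell period/phase ground truth).
#' @export
#' @examples
#' ts <- simulate_population(synth_config(n_cells = 5, seed = 1))
simulate_population <- function(config = synth_config(),
                                subpopulation = "A", cell_prefix = "cell") {
  stopifnot(inherits(config, "synth_config"))
  with_seed_if(config$seed, simulate_population_impl(config, subpopulation,
                                                     cell_prefix))
}

simulate_population_impl <- function(config, subpopulation, cell_prefix) {
  t_h <- seq(0, config$duration_h, by = config$dt_h)
  nt <- length(t_h)
  nc <- config$n_cells
  periods <- stats::rnorm(nc, config$period_mean_h, config$period_sd_h)
  periods <- pmax(periods, 1) # guard against absurd draws at large sd
  phase0 <- 2 * pi * (config$phase_offset_h +
                        stats::rnorm(nc, 0, config$phase_sd_h)) / periods

  osc <- if (config$engine == "phase") {
    # nt x nc matrix of cos(phase)
    vapply(seq_len(nc), function(i) {
      cos(2 * pi * t_h / periods[i] + phase0[i])
    }, numeric(nt))
  } else {
    ode_oscillation_matrix(t_h, periods, phase0)
  }

  trend <- exp(-config$trend_rate * t_h)
  noise <- matrix(stats::rnorm(nt * nc, 0, config$noise_sd), nt, nc)
  inten <- trend * config$bead_level * (1 + config$amplitude * osc) + noise

  ids <- sprintf("%s%03d", cell_prefix, seq_len(nc))
  out <- tibble::tibble(
    cell_id = rep(ids, each = nt),
    subpopulation = subpopulation,
    well_id = rep(sprintf("w%05d", seq_len(nc)), each = nt),
    t_h = rep(t_h, nc),
    intensity = as.vector(inten)
  )
  beads <- tibble::tibble(
    t_h = t_h,
    intensity = config$bead_level +
      stats::rnorm(nt, 0, config$bead_noise_sd)
  )
  truth <- tibble::tibble(cell_id = ids, subpopulation = subpopulation,
                          period_h = periods, phase0_rad = phase0)
  attr(out, "beads") <- beads
  attr(out, "truth") <- truth
  attr(out, "config") <- config
  out
}

# ODE engine: one reference limit-cycle solve of the quorum-sensing network,
# per-cell phase shifts realised by sampling the cycle at shifted times and
# rescaling time so each cell runs at its drawn period. The reporter is
# normalized to zero-mean unit-amplitude so it drops into the same
# `1 + amplitude * osc` envelope as the cosine engine.
ode_oscillation_matrix <- function(t_h, periods, phase0) {
  ref <- clock_reference_cycle()
  nt <- length(t_h)
  vapply(seq_along(periods), function(i) {
    tt <- (t_h / periods[i] - phase0[i] / (2 * pi)) * ref$period_h
    tt <- tt %% ref$period_h
    stats::approx(ref$t_h, ref$ccg2, xout = tt, rule = 2)$y
  }, numeric(nt))
}

clock_cycle_cache <- new.env(parent = emptyenv())

# One period of the CCG-2 reporter on the quorum-model limit cycle,
# normalized to mean 0, max |.| 1. Cached per session.
clock_reference_cycle <- function() {
  if (!is.null(clock_cycle_cache$ref)) return(clock_cycle_cache$ref)
  r <- clock_oscillator_rates()
  burn <- integrate_clock(r, clock_state(1, "quorum"), c(0, 400))
  if (sim_failed(burn)) stop("reference clock integration failed")
  y0 <- unlist(burn[nrow(burn), -1])
  names(y0) <- names(burn)[-1]
  grid <- seq(0, 80, by = 0.1)
  sim <- integrate_clock(r, y0, grid)
  v <- sim$CCG2_c1
  ph <- hilbert_phase(v - mean(v), grid, edge_exclude_h = 0)
  per <- 2 * pi * (max(grid)) / (ph$F_C[length(grid)] - ph$F_C[1])
  idx <- grid <= per
  t_cycle <- grid[idx]
  vc <- v[idx]
  vc <- vc - mean(vc)
  vc <- vc / max(abs(vc))
  clock_cycle_cache$ref <- list(t_h = t_cycle, ccg2 = vc, period_h = per)
  clock_cycle_cache$ref
}

#' Generate the two-population mixing experiment
#'
#' Two labelled subpopulations whose oscillation phases differ by
#' `phase_offset_h` at time zero, mimicking the classic experiment in
#' which cells given an extra 12 h of light are mixed with an unshifted
#' population. Ground-truth labels are kept in the `subpopulation` column
#' and the `truth` attribute.
#'
#' @param n_per_pop Cells per subpopulation (>= 1).
#' @param phase_offset_h Offset between the populations, hours (default 12).
#' @param config A [synth_config()]; its own `phase_offset_h` applies to
#'   population A, `+ phase_offset_h` to population B.
#' @return A trajectory tibble of `2 * n_per_pop` cells, attributes as in
#'   [simulate_population()].
#' @export
simulate_mixing <- function(n_per_pop, phase_offset_h = 12,
                            config = synth_config()) {
  if (n_per_pop < 1) stop("n_per_pop must be >= 1")
  cfg_a <- config
  cfg_a$n_cells <- n_per_pop
  cfg_b <- cfg_a
  cfg_b$phase_offset_h <- config$phase_offset_h + phase_offset_h
  build <- function() {
    a <- simulate_population_impl(cfg_a, "A", "A_cell")
    b <- simulate_population_impl(cfg_b, "B", "B_cell")
    out <- dplyr::bind_rows(a, b)
    attr(out, "beads") <- attr(a, "beads")
    attr(out, "truth") <- dplyr::bind_rows(attr(a, "truth"), attr(b, "truth"))
    attr(out, "config") <- config
    out
  }
  with_seed_if(config$seed, build())
}

#' Generate a density series of coupled populations
#'
#' One trajectory set per microwell density layout. Within each layout the
#' cells' phases evolve under the noisy Kuramoto model with coupling
#' `K = coupling_scale` (and a fixed phase noise), so measured Kuramoto
#' order increases with `coupling_scale`: the synthetic analogue of
#' density-dependent quorum-sensing synchronization.
#'
#' @param layouts A [density_layout()] tibble (>= 2 rows).
#' @param config A [synth_config()]; `n_cells` caps the number of tracked
#'   cells per layout (never more than the layout's well count).
#' @param kuramoto_sigma Phase-noise SD of the coupled-phase simulation,
#'   radians/sqrt(h).
#' @return A list of trajectory tibbles, one per layout, each carrying a
#'   `layout` attribute (one row of `layouts`).
#' @export
simulate_density_series <- function(layouts, config = synth_config(),
                                    kuramoto_sigma = 0.15) {
  if (nrow(layouts) < 2) stop("need at least 2 density layouts")
  seeds <- if (is.null(config$seed)) rep(list(NULL), nrow(layouts)) else
    as.list(config$seed + seq_len(nrow(layouts)))
  purrr::map(seq_len(nrow(layouts)), function(i) {
    lay <- layouts[i, ]
    cfg <- config
    cfg$n_cells <- min(config$n_cells, lay$wells)
    cfg$seed <- seeds[[i]]
    ts <- with_seed_if(cfg$seed, simulate_coupled_impl(cfg, lay$coupling_scale,
                                                       kuramoto_sigma))
    attr(ts, "layout") <- lay
    ts
  })
}

simulate_coupled_impl <- function(config, coupling, sigma) {
  t_h <- seq(0, config$duration_h, by = config$dt_h)
  nt <- length(t_h)
  nc <- config$n_cells
  periods <- pmax(stats::rnorm(nc, config$period_mean_h, config$period_sd_h), 1)
  phase0 <- 2 * pi * (config$phase_offset_h +
                        stats::rnorm(nc, 0, config$phase_sd_h)) / periods
  p <- kuramoto_params(omega = 2 * pi / periods, K_couple = coupling,
                       sigma = sigma, phi0 = phase0, dt_h = 0.05,
                       normalize = TRUE)
  sim <- simulate_kuramoto(p, duration_h = config$duration_h,
                           save_dt_h = config$dt_h)
  phi <- attr(sim, "phase_matrix")
  osc <- cos(phi[seq_len(nt), , drop = FALSE])
  trend <- exp(-config$trend_rate * t_h)
  noise <- matrix(stats::rnorm(nt * nc, 0, config$noise_sd), nt, nc)
  inten <- trend * config$bead_level * (1 + config$amplitude * osc) + noise
  ids <- sprintf("cell%03d", seq_len(nc))
  out <- tibble::tibble(
    cell_id = rep(ids, each = nt),
    subpopulation = NA_character_,
    well_id = rep(sprintf("w%05d", seq_len(nc)), each = nt),
    t_h = rep(t_h, nc),
    intensity = as.vector(inten)
  )
  attr(out, "truth") <- tibble::tibble(cell_id = ids, period_h = periods,
                                       phase0_rad = phase0)
  attr(out, "config") <- config
  out
}
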