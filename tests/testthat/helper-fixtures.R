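# Shared fixtures and small utilities for the suite.

# wrapped absolute phase difference in [0, pi]
wrap_diff <- function(x) {
  y <- abs(x) %% (2 * pi)
  pmin(y, 2 * pi - y)
}

# a random positive clock state for RHS property checks
random_clock_state <- function(n_cells, model, seed) {
  withr::with_seed(seed, {
    y <- clock_state(n_cells, model)
    y[] <- stats::runif(length(y), 0, 2)
    y
  })
}

# quick linear-phase tibble for cycle-count checks
linear_phase <- function(period_h, duration_h, dt_h = 0.5) {
  t <- seq(0, duration_h, dt_h)
  tibble::tibble(t_h = t, F_C = 2 * pi * t / period_h)
}

# small mixing experiment at the generator's default ("paper-like") noise
mixing_fixture <- function(n_per_pop = 120, seed = 1, duration_h = 60) {
  simulate_mixing(n_per_pop, 12,
                  synth_config(duration_h = duration_h, seed = seed))
}
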