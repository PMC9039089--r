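#' Parameters of the stochastic Kuramoto phase model
#'
#' The model couples `n` oscillators with intrinsic frequencies `omega_i`
#' through `dphi_i/dt = omega_i + K sum_j sin(phi_j - phi_i) + eps_i`, with
#' `eps_i` white noise of standard deviation `sigma` (radians per sqrt
#' hour). The coupling sum is unnormalized as written; `normalize = TRUE`
#' switches to the textbook `K/n` convention.
#'
#' @param omega Intrinsic frequencies, radians per hour.
#' @param K_couple Coupling constant `K` (>= 0).
#' @param sigma White-noise SD, radians/sqrt(h) (>= 0).
#' @param phi0 Initial phases, radians (recycled to `length(omega)`).
#' @param dt_h Integrator step, hours.
#' @param normalize Divide the coupling sum by `n`?
#' @return A list of class `kuramoto_params`.
#' @export
kuramoto_params <- function(omega, K_couple, sigma = 0, phi0 = 0,
                            dt_h = 0.05, normalize = FALSE) {
  n <- length(omega)
  stopifnot(n >= 1, sigma >= 0, dt_h > 0, K_couple >= 0)
  phi0 <- rep_len(phi0, n)
  structure(list(omega = omega, K_couple = K_couple, sigma = sigma,
                 phi0 = phi0, n = n, dt_h = dt_h, normalize = normalize),
            class = "kuramoto_params")
}

#' Simulate the stochastic Kuramoto phase model
#'
#' Stochastic Heun (predictor-corrector Runge-Kutta) integration with fixed
#' step `dt_h`; noise increments scale with `sqrt(dt)`. Reproducible under
#' `set.seed()` / the `seed` argument.
#'
#' @param params A [kuramoto_params()] object.
#' @param duration_h Simulated duration, hours.
#' @param save_dt_h Output sampling interval (defaults to the integrator
#'   step; must be a multiple of it).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `cell_id`, `t_h`, `phase` (radians,
#'   continuous), carrying the timepoints x oscillators phase matrix as
#'   attribute `phase_matrix`.
#' @export
#' @examples
#' p <- kuramoto_params(omega = rep(2 * pi / 21, 5), K_couple = 1, sigma = 0.1)
#' sim <- simulate_kuramoto(p, duration_h = 48, save_dt_h = 0.5, seed = 1)
simulate_kuramoto <- function(params, duration_h, save_dt_h = NULL,
                              seed = NULL) {
  stopifnot(inherits(params, "kuramoto_params"))
  dt <- params$dt_h
  if (is.null(save_dt_h)) save_dt_h <- dt
  save_every <- round(save_dt_h / dt)
  if (abs(save_every * dt - save_dt_h) > 1e-9)
    stop("save_dt_h must be a multiple of dt_h")
  n_steps <- round(duration_h / dt)
  # explicit-Euler style stability heuristic for the coupling term
  strength <- if (params$normalize) params$K_couple else params$K_couple * params$n
  if (strength * dt > 0.5)
    warning("dt_h is large relative to the coupling strength K*n; ",
            "consider a smaller step", call. = FALSE)
  mat <- with_seed_if(seed, {
    simulate_kuramoto_cpp(params$phi0, params$omega, params$K_couple,
                          params$sigma, dt, n_steps, save_every,
                          params$normalize)
  })
  t_h <- seq(0, by = save_dt_h, length.out = nrow(mat))
  colnames(mat) <- sprintf("osc%03d", seq_len(params$n))
  out <- tibble::as_tibble(as.data.frame(mat)) |>
    tibble::add_column(t_h = t_h, .before = 1) |>
    tidyr::pivot_longer(-"t_h", names_to = "cell_id", values_to = "phase") |>
    dplyr::arrange(.data$cell_id, .data$t_h)
  attr(out, "phase_matrix") <- mat
  attr(out, "params") <- params
  out
}

#' Fit the Kuramoto coupling constant to measured phase trajectories
#'
#' Ensemble Metropolis-Hastings identification of the coupling constant `K`
#' and the initial phases `phi0` of each oscillator against continuized
#' phase trajectories, with the noiseless Kuramoto model as the forward
#' map (the same Heun integrator with `sigma = 0`). Intrinsic frequencies
#' `omega_i` are either supplied or estimated per oscillator from a
#' periodogram of `sin(phase)`.
#'
#' @param phase_data Continuized phase trajectories: a timepoints x
#'   oscillators matrix, or a tidy tibble as produced by
#'   [simulate_kuramoto()]. At least 2 oscillators.
#' @param t_h Time grid of the rows of `phase_data` (matrix input only).
#' @param omega Optional intrinsic frequencies; estimated from the data
#'   when `NULL`.
#' @param config A [fit_config()]; desk-scale sweeps are plenty here.
#' @param error_sd Per-point measurement SD (radians) used in the
#'   chi-squared; estimated from first differences when `NULL`.
#' @param K_init Starting value for the coupling constant.
#' @param dt_h Integrator step for the forward simulations.
#' @param normalize Use the `K/n`-normalized coupling variant?
#' @return A list of class `kuramoto_fit`: `K_mean`, `K_se` (posterior
#'   spread), `phi0`, `chi2`, `n`, `chi2_per_n`, `samples`, `trace`.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
fit_kuramoto <- function(phase_data, t_h = NULL, omega = NULL,
                         config = fit_config(preset = "desk"),
                         error_sd = NULL, K_init = 1, dt_h = 0.01,
                         normalize = FALSE) {
  mat <- attr(phase_data, "phase_matrix") %||% phase_matrix_of(phase_data)
  if (is.null(t_h)) {
    t_h <- if (is.data.frame(phase_data)) sort(unique(phase_data$t_h))
           else stop("t_h required with matrix input")
  }
  n <- ncol(mat)
  if (n < 2) stop("need at least 2 oscillators to fit coupling")
  save_dt <- t_h[2] - t_h[1]
  duration <- max(t_h) - min(t_h)
  if (is.null(omega)) omega <- estimate_omega(mat, save_dt)
  if (is.null(error_sd)) {
    resid <- apply(mat, 2, function(p) p - (t_h - t_h[1]) * mean(diff(p)) / save_dt - p[1])
    error_sd <- max(stats::sd(resid), 1e-3)
  }

  forward <- function(K, phi0) {
    p <- kuramoto_params(omega, K, sigma = 0, phi0 = phi0, dt_h = dt_h,
                         normalize = normalize)
    sim <- simulate_kuramoto_cpp(p$phi0, p$omega, p$K_couple, 0, dt_h,
                                 round(duration / dt_h),
                                 round(save_dt / dt_h), normalize)
    sim
  }
  objective <- function(theta) {
    pred <- forward(theta[1], theta[-1])
    if (nrow(pred) != nrow(mat)) return(Inf)
    sum(((pred - mat) / error_sd)^2)
  }

  init <- c(K = K_init, stats::setNames(mat[1, ], paste0("phi0_", seq_len(n))))
  run <- mh_run(objective, init, config,
                positive = c(TRUE, rep(FALSE, n)))
  samples <- run$samples
  K_samp <- samples[, 1]
  phi0_hat <- colMeans(samples[, -1, drop = FALSE])
  pred <- forward(mean(K_samp), phi0_hat)
  chi2 <- sum(((pred - mat) / error_sd)^2)
  n_pts <- length(mat)
  structure(list(
    K_mean = mean(K_samp), K_se = stats::sd(K_samp),
    phi0 = phi0_hat, omega = omega, error_sd = error_sd,
    chi2 = chi2, n = n_pts, chi2_per_n = chi2 / n_pts,
    samples = samples, trace = run$chi2_trace, accept_rate = run$accept_rate
  ), class = "kuramoto_fit")
}

# Dominant angular frequency of each oscillator from a periodogram of
# sin(phase); falls back to the mean phase slope for near-linear phases.
estimate_omega <- function(mat, dt_h) {
  apply(mat, 2, function(p) {
    if (length(p) >= 8) {
      pg <- periodogram(sin(p), dt_h = dt_h)
      2 * pi / attr(pg, "peak_period_h")
    } else {
      mean(diff(p)) / dt_h
    }
  })
}

#' @export
print.kuramoto_fit <- function(x, ...) {
  cat("<kuramoto_fit>  K =", format(x$K_mean, digits = 5), "+/-",
      format(x$K_se, digits = 3), "  chi2/n =",
      format(x$chi2_per_n, digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.kuramoto_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K", names(x$phi0)),
    estimate = c(x$K_mean, unname(x$phi0)),
    std.error = c(x$K_se, apply(x$samples[, -1, drop = FALSE], 2, stats::sd))
  )
}

#' @export
glance.kuramoto_fit <- function(x, ...) {
  tibble::tibble(K = x$K_mean, K_se = x$K_se, chi2 = x$chi2, n = x$n,
                 chi2_per_n = x$chi2_per_n)
}
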