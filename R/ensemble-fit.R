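#' Configuration of an ensemble Metropolis-Hastings fit
#'
#' The full-scale protocol runs 40,000 equilibration sweeps followed by
#' 40,000 accumulation sweeps (a sweep proposes, on average, one update per
#' free parameter). The `"desk"` preset (2,000/2,000) is the scaled-down
#' setting used in tests and examples.
#'
#' @param equilibration_sweeps,accumulation_sweeps Sweep counts; defaults
#'   come from `preset`.
#' @param temperature Boltzmann temperature of the ensemble (chi-squared
#'   energy scale), default 1.
#' @param proposal_scale Initial relative proposal step, auto-tuned during
#'   equilibration toward 20-40% acceptance and frozen for accumulation.
#' @param seed Optional RNG seed applied by the fitting functions.
#' @param error_sd Per-point measurement SD: a number, `"mad"` (robust
#'   residual scale estimated from the data), or a numeric vector.
#' @param preset `"full"` (40,000/40,000) or `"desk"` (2,000/2,000).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(equilibration_sweeps = NULL,
                       accumulation_sweeps = NULL,
                       temperature = 1, proposal_scale = 0.1, seed = NULL,
                       error_sd = "mad", preset = c("full", "desk")) {
  preset <- match.arg(preset)
  base <- if (preset == "full") 40000L else 2000L
  eq <- as.integer(equilibration_sweeps %||% base)
  acc <- as.integer(accumulation_sweeps %||% base)
  stopifnot(eq >= 1, acc >= 1, temperature > 0, proposal_scale > 0)
  structure(list(equilibration_sweeps = eq, accumulation_sweeps = acc,
                 temperature = temperature, proposal_scale = proposal_scale,
                 seed = seed, error_sd = error_sd, preset = preset),
            class = "fit_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chi-squared agreement between model and data trajectories
#'
#' `chi2 = sum(((model - data) / sigma)^2)` over all shared points, with
#' the per-point count `n` and `chi2/n` reported alongside.
#'
#' @param model_traj,data_traj Numeric vectors/matrices on identical grids,
#'   or tibbles with columns `cell_id`, `t_h` and a value column.
#' @param error_sd Per-point SD sigma (scalar or vector recycled across
#'   points).
#' @return A one-row tibble: `chi2`, `n`, `chi2_per_n`.
#' @export
#' @examples
#' chi_squared(c(1, 2, 3), c(1, 2, 4), error_sd = 1) # chi2 = 1
chi_squared <- function(model_traj, data_traj, error_sd = 1) {
  m <- traj_values(model_traj)
  d <- traj_values(data_traj)
  if (length(m) != length(d))
    stop("model and data trajectories are on different grids")
  if (is.data.frame(model_traj) && is.data.frame(data_traj)) {
    if (!isTRUE(all.equal(sort(unique(model_traj$t_h)),
                          sort(unique(data_traj$t_h)))))
      stop("model and data trajectories are on different grids")
  }
  chi2 <- sum(((m - d) / error_sd)^2)
  n <- length(d)
  tibble::tibble(chi2 = chi2, n = n, chi2_per_n = chi2 / n)
}

traj_values <- function(x) {
  if (is.data.frame(x)) {
    col <- intersect(c("value", "intensity"), names(x))[1]
    if (is.na(col)) stop("trajectory tibble needs a 'value' or 'intensity' column")
    x <- x[order(x$cell_id, x$t_h), ]
    return(x[[col]])
  }
  as.numeric(x)
}

#' Metropolis-Hastings sampler over a chi-squared surface
#'
#' Boltzmann-ensemble sampler with acceptance probability
#' `min(1, exp(-delta_chi2 / (2 * temperature)))`. Each sweep makes
#' `length(init)` single-parameter proposals at indices drawn with
#' replacement, so every parameter is visited once per sweep on average.
#' Positive parameters (rates) take multiplicative log-normal steps with
#' the Hastings correction `theta'/theta`; unconstrained parameters take
#' additive Gaussian steps. Per-parameter step scales are tuned during
#' equilibration toward 20-40% acceptance and frozen for accumulation, so
#' the accumulated chain satisfies detailed balance.
#'
#' @param objective Function mapping a parameter vector to a chi-squared
#'   value; may return `Inf` (e.g. on integration failure) to force
#'   rejection.
#' @param init Named numeric vector of starting values.
#' @param config A [fit_config()].
#' @param positive Logical vector: which parameters are positivity-
#'   constrained (log-normal proposals). Default all.
#' @param scales Optional initial per-parameter proposal scales.
#' @return A list of class `mh_run`: `samples` (accumulation sweeps x
#'   parameters matrix), `chi2_trace` (one entry per sweep, equilibration
#'   then accumulation), `accept_rate` per parameter, frozen `scales`,
#'   `n_eval`, and the final `chi2`.
#' @export
mh_run <- function(objective, init, config = fit_config(preset = "desk"),
                   positive = NULL, scales = NULL) {
  P <- length(init)
  positive <- positive %||% rep(TRUE, P)
  stopifnot(length(positive) == P)
  scales <- scales %||% rep(config$proposal_scale, P)
  theta <- as.numeric(init)
  chi2 <- objective(theta)
  if (!is.finite(chi2)) stop("objective is not finite at the initial point")
  Tmp <- config$temperature
  eq <- config$equilibration_sweeps
  acc <- config$accumulation_sweeps
  n_sweeps <- eq + acc
  chi2_trace <- numeric(n_sweeps)
  samples <- matrix(NA_real_, acc, P,
                    dimnames = list(NULL, names(init)))
  prop_ct <- acc_ct <- numeric(P)
  adapt_block <- 50L

  run_body <- function() {
    for (sw in seq_len(n_sweeps)) {
      idx <- sample.int(P, P, replace = TRUE)
      for (i in idx) {
        old <- theta[i]
        if (positive[i]) {
          step <- stats::rnorm(1, 0, scales[i])
          cand <- old * exp(step)
          log_hastings <- log(cand) - log(old)
        } else {
          cand <- old + stats::rnorm(1, 0, scales[i])
          log_hastings <- 0
        }
        theta[i] <<- cand
        chi2_new <- objective(theta)
        log_alpha <- if (is.finite(chi2_new)) {
          -(chi2_new - chi2) / (2 * Tmp) + log_hastings
        } else {
          -Inf
        }
        prop_ct[i] <<- prop_ct[i] + 1
        if (log(stats::runif(1)) < log_alpha) {
          chi2 <<- chi2_new
          acc_ct[i] <<- acc_ct[i] + 1
        } else {
          theta[i] <<- old
        }
      }
      chi2_trace[sw] <<- chi2
      if (sw <= eq && sw %% adapt_block == 0) {
        rate <- ifelse(prop_ct > 0, acc_ct / prop_ct, 0.3)
        scales <<- scales * ifelse(rate > 0.4, 1.4,
                                   ifelse(rate < 0.2, 1 / 1.4, 1))
        prop_ct[] <<- 0
        acc_ct[] <<- 0
      }
      if (sw == eq) { # freeze adaptation; restart acceptance bookkeeping
        prop_ct[] <<- 0
        acc_ct[] <<- 0
      }
      if (sw > eq) samples[sw - eq, ] <<- theta
    }
  }
  with_seed_if(config$seed, run_body())

  structure(list(
    samples = samples, chi2_trace = chi2_trace,
    accept_rate = ifelse(prop_ct > 0, acc_ct / prop_ct, NA_real_),
    scales = scales, chi2 = chi2,
    n_eval = n_sweeps * P
  ), class = "mh_run")
}

#' Ensemble moments of accumulated MCMC samples
#'
#' Per-parameter ensemble mean and spread. Three uncertainty conventions
#' are emitted: the posterior SD across the ensemble (`sd`), the naive
#' standard error `sd/sqrt(N)` (`se_naive`), and the autocorrelation-
#' corrected standard error `sd/sqrt(ESS)` (`se`), where the effective
#' sample size uses the initial positive sequence of autocorrelations.
#'
#' @param samples An accumulation matrix (sweeps x parameters), an
#'   `mh_run`, or an `ensemble_fit` object. At least 2 samples.
#' @return A tibble: `term`, `mean`, `sd`, `se_naive`, `ess`, `se`.
#' @export
ensemble_moments <- function(samples) {
  if (inherits(samples, "mh_run")) samples <- samples$samples
  if (inherits(samples, "ensemble_fit")) samples <- samples$samples
  samples <- as.matrix(samples)
  if (nrow(samples) < 2) stop("need at least 2 accumulated samples")
  N <- nrow(samples)
  tibble::tibble(
    term = colnames(samples) %||% paste0("p", seq_len(ncol(samples))),
    mean = unname(colMeans(samples)),
    sd = unname(apply(samples, 2, stats::sd)),
    se_naive = .data$sd / sqrt(N),
    ess = unname(apply(samples, 2, effective_sample_size)),
    se = .data$sd / sqrt(.data$ess)
  )
}

#' Effective sample size of an autocorrelated chain
#'
#' `N / (1 + 2 * sum(rho_k))` over the initial positive sequence of lagged
#' autocorrelations (truncated at the first non-positive value).
#'
#' @param x Numeric chain.
#' @return Effective sample size in `[1, length(x)]`.
#' @export
effective_sample_size <- function(x) {
  N <- length(x)
  if (stats::sd(x) == 0) return(N)
  rho <- stats::acf(x, lag.max = min(N - 1, 1000), plot = FALSE)$acf[-1]
  first_neg <- which(rho <= 0)[1]
  if (!is.na(first_neg)) rho <- rho[seq_len(first_neg - 1)]
  max(1, min(N, N / (1 + 2 * sum(rho))))
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test used as a convergence diagnostic on
#' accumulated parameter traces: a converged chain shows no systematic
#' drift with sweep.
#'
#' @param x Numeric series.
#' @return A one-row tibble: `S` statistic, `z`, two-sided `p.value`.
#' @export
mann_kendall <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 points for a trend test")
  S <- sum(vapply(seq_len(n - 1), function(i) {
    sum(sign(x[(i + 1):n] - x[i]))
  }, numeric(1)))
  varS <- n * (n - 1) * (2 * n + 5) / 18
  z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS) else 0
  tibble::tibble(S = S, z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Ensemble fit of a clock-network model to fluorescence trajectories
#'
#' Boltzmann-ensemble Metropolis-Hastings identification of rate constants
#' (and optionally initial conditions) of the quorum-sensing or contact
#' model against cluster-average CCG-2 fluorescence trajectories, one data
#' trajectory per giant cell. Equilibration adapts proposal scales; the
#' accumulation phase collects the model ensemble whose average is the
#' reported prediction.
#'
#' @param rates Starting `clock_rates` (its `model` attribute selects the
#'   communication model).
#' @param data Tibble with columns `cell_id`, `t_h`, `value`: one observed
#'   (cluster-average) trajectory per giant cell, all on one grid.
#' @param config A [fit_config()].
#' @param free_rates Character vector of rate names to sample; defaults to
#'   the estimated set of the chosen model.
#' @param init Initial state vector; defaults to [clock_state()] sized to
#'   the data.
#' @param free_init Character vector of state names to sample as additional
#'   parameters (additive proposals), or `NULL`.
#' @param rtol,atol Integration tolerances for the proposal solves.
#' @param observable_mode Compare on `"raw"` CCG-2 or `"detrended"` scale.
#' @return A list of class `ensemble_fit`: `samples`, `chi2_trace`,
#'   `moments`, `prediction` (ensemble-average trajectory tibble), `chi2`,
#'   `n_points`, `chi2_per_n`, `accept_rate`, `converged` (Mann-Kendall
#'   p-values per free parameter on the accumulation trace), `config`.
#' @export
run_ensemble <- function(rates, data, config = fit_config(preset = "desk"),
                         free_rates = NULL, init = NULL, free_init = NULL,
                         rtol = 1e-6, atol = 1e-9,
                         observable_mode = c("raw", "detrended")) {
  stopifnot(inherits(rates, "clock_rates"))
  observable_mode <- match.arg(observable_mode)
  model <- attr(rates, "model")
  cells <- sort(unique(data$cell_id))
  n_cells <- length(cells)
  t_grid <- sort(unique(data$t_h))
  data <- data[order(data$cell_id, data$t_h), ]
  dmat <- matrix(data$value, nrow = length(t_grid), ncol = n_cells)

  free_rates <- free_rates %||% if (model == "quorum") ESTIMATED_RATES else
    setdiff(ESTIMATED_RATES, c("eta_ext", "D10"))
  bad <- setdiff(free_rates, CLOCK_RATE_NAMES)
  if (length(bad)) stop("unknown rate(s): ", paste(bad, collapse = ", "))
  init <- init %||% clock_state(n_cells, model)

  sig <- config$error_sd
  if (identical(sig, "mad")) {
    sig <- max(apply(dmat, 2, function(v) stats::mad(diff(v)) / sqrt(2)), 1e-8)
  }

  theta0 <- c(unclass(rates)[free_rates],
              if (length(free_init)) init[free_init])
  positive <- c(rep(TRUE, length(free_rates)), rep(FALSE, length(free_init)))

  predict_mat <- function(theta) {
    r <- unclass(rates)
    r[free_rates] <- theta[seq_along(free_rates)]
    y0 <- init
    if (length(free_init)) y0[free_init] <- theta[-seq_along(free_rates)]
    r <- structure(r, class = "clock_rates", model = model)
    sim <- integrate_clock(r, y0, t_grid, rtol = rtol, atol = atol)
    if (sim_failed(sim)) return(NULL)
    obs <- observable_ccg2(sim, mode = observable_mode)
    matrix(obs$value, nrow = length(t_grid), ncol = n_cells)
  }
  objective <- function(theta) {
    pm <- predict_mat(theta)
    if (is.null(pm) || anyNA(pm)) return(Inf)
    sum(((pm - dmat) / sig)^2)
  }

  run <- mh_run(objective, theta0, config, positive = positive)

  # ensemble-average prediction over a thinned subset of accumulated models
  keep <- unique(round(seq(1, nrow(run$samples), length.out = min(50, nrow(run$samples)))))
  preds <- lapply(keep, function(k) predict_mat(run$samples[k, ]))
  preds <- preds[!vapply(preds, is.null, logical(1))]
  pred_mat <- Reduce(`+`, preds) / length(preds)
  prediction <- tibble::tibble(
    cell_id = rep(cells, each = length(t_grid)),
    t_h = rep(t_grid, n_cells),
    value = as.vector(pred_mat)
  )
  chi2 <- sum(((pred_mat - dmat) / sig)^2)
  n_pts <- length(dmat)

  conv <- vapply(seq_len(ncol(run$samples)), function(j) {
    tr <- run$samples[, j]
    if (stats::sd(tr) == 0) return(1)
    # thin long traces: the MK statistic is O(n^2)
    if (length(tr) > 500) tr <- tr[round(seq(1, length(tr), length.out = 500))]
    mann_kendall(tr)$p.value
  }, numeric(1))
  names(conv) <- colnames(run$samples)

  structure(list(
    samples = run$samples, chi2_trace = run$chi2_trace,
    moments = ensemble_moments(run$samples),
    prediction = prediction, chi2 = chi2, n_points = n_pts,
    chi2_per_n = chi2 / n_pts, error_sd = sig,
    accept_rate = run$accept_rate, converged = conv,
    model = model, free_rates = free_rates, free_init = free_init,
    n_cells = n_cells, config = config
  ), class = "ensemble_fit")
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("<ensemble_fit>", x$model, "model,", length(x$free_rates),
      "free rates;", "chi2 =", format(x$chi2, digits = 5),
      "over n =", x$n_points, "points (chi2/n =",
      paste0(format(x$chi2_per_n, digits = 3), ")"), "\n")
  invisible(x)
}

#' @export
tidy.ensemble_fit <- function(x, ...) x$moments

#' @export
glance.ensemble_fit <- function(x, ...) {
  tibble::tibble(model = x$model, chi2 = x$chi2, n = x$n_points,
                 chi2_per_n = x$chi2_per_n,
                 n_free = ncol(x$samples),
                 min_trend_p = min(x$converged))
}

#' Chi-squared comparison of two fitted communication models
#'
#' `delta_chi2 = chi2(a) - chi2(b)` with a chi-squared tail probability at
#' `df` degrees of freedom, the difference in free-parameter counts of the
#' two configured models (computed, not hard-coded, when fits are given).
#'
#' @param fit_a,fit_b `ensemble_fit` objects on the same data, or bare
#'   chi-squared values.
#' @param df Degrees of freedom; computed from the fits when omitted.
#' @return A one-row tibble: `delta_chi2`, `df`, `p.value`.
#' @export
#' @examples
#' compare_models(4373, 2019, df = 3)
compare_models <- function(fit_a, fit_b, df = NULL) {
  chi2_of <- function(f) if (inherits(f, "ensemble_fit")) f$chi2 else as.numeric(f)
  npar_of <- function(f) {
    if (inherits(f, "ensemble_fit"))
      length(f$free_rates) + length(f$free_init)
    else NA_integer_
  }
  if (inherits(fit_a, "ensemble_fit") && inherits(fit_b, "ensemble_fit")) {
    if (fit_a$n_points != fit_b$n_points)
      stop("fits are not on the same data (different point counts)")
    df <- df %||% abs(npar_of(fit_a) - npar_of(fit_b))
  }
  if (is.null(df)) stop("df must be supplied when comparing bare chi-squared values")
  d <- chi2_of(fit_a) - chi2_of(fit_b)
  p <- if (d == 0) 1 else stats::pchisq(abs(d), df = df, lower.tail = FALSE)
  tibble::tibble(delta_chi2 = d, df = df, p.value = p)
}
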