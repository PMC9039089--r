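test_that("chi-squared bookkeeping matches its definition", {
  expect_equal(chi_squared(c(1, 2, 3), c(1, 2, 3))$chi2, 0)
  expect_equal(chi_squared(c(1, 2, 3 + 0.5), c(1, 2, 3), error_sd = 0.5)$chi2, 1)
  out <- chi_squared(rep(0, 442), rep(0, 442))
  expect_identical(out$n, 442L)
  # the published fit quality: chi2 = 2016 over n = 442 points
  expect_equal(round(2016 / 442, 2), 4.56)
  expect_error(chi_squared(1:3, 1:4), "different grids")
})

test_that("the sampler is greedy in the zero-temperature limit", {
  obj <- function(th) (th[1] - 3)^2
  run <- mh_run(obj, c(x = 10),
                fit_config(equilibration_sweeps = 200,
                           accumulation_sweeps = 200,
                           temperature = 1e-9, seed = 1),
                positive = FALSE)
  expect_true(all(diff(run$chi2_trace) <= 1e-12))
})

test_that("MH sampling reproduces the Gaussian stationary distribution", {
  # chi2(x) = (x - 3)^2 at T = 1 has stationary density N(3, 1)
  obj <- function(th) (th[1] - 3)^2
  run <- mh_run(obj, c(x = 0),
                fit_config(equilibration_sweeps = 2000,
                           accumulation_sweeps = 20000, seed = 4),
                positive = FALSE)
  x <- run$samples[, 1]
  se <- sd(x) / sqrt(effective_sample_size(x))
  expect_lt(abs(mean(x) - 3), 3 * se)
  expect_equal(var(x), 1, tolerance = 0.1)
})

test_that("a 2-parameter quadratic surface yields the analytic Gaussian", {
  obj <- function(th) (th[1] - 1)^2 + (th[2] + 2)^2 / 4
  run <- mh_run(obj, c(a = 0, b = 0),
                fit_config(equilibration_sweeps = 2000,
                           accumulation_sweeps = 20000, seed = 9),
                positive = c(FALSE, FALSE))
  m <- colMeans(run$samples)
  expect_equal(unname(m), c(1, -2), tolerance = 0.15)
  # variances 1 and 4; cross-covariance 0
  V <- cov(run$samples)
  expect_equal(unname(diag(V)), c(1, 4), tolerance = 0.2)
  expect_lt(abs(V[1, 2]) / sqrt(V[1, 1] * V[2, 2]), 0.1)
})

test_that("positivity-constrained parameters use valid log-normal proposals", {
  # stationary target exp(-chi2/2) with chi2 = (log x)^2: log-normal posterior
  obj <- function(th) (log(th[1]))^2
  run <- mh_run(obj, c(x = 1),
                fit_config(equilibration_sweeps = 1000,
                           accumulation_sweeps = 15000, seed = 2))
  # in y = log x the target is exp(-y^2/2) e^y, i.e. N(1, 1)
  lx <- log(run$samples[, 1])
  expect_true(all(run$samples[, 1] > 0))
  expect_equal(mean(lx), 1, tolerance = 0.15)
  expect_equal(var(lx), 1, tolerance = 0.15)
})

test_that("ensemble moments follow their conventions", {
  s <- matrix(rep(2, 10), ncol = 1, dimnames = list(NULL, "a"))
  m <- ensemble_moments(s)
  expect_equal(m$se, 0)
  expect_equal(m$sd, 0)
  m2 <- ensemble_moments(matrix(c(1, 3), ncol = 1))
  expect_equal(m2$mean, 2)
  expect_error(ensemble_moments(matrix(1, 1, 1)), "2 accumulated")
  # published decay rates imply the printed lifetimes
  tab <- published_rate_moments()
  mean_of <- function(r) tab$mean[tab$rate == r]
  expect_equal(round(1 / mean_of("D6"), 1), 1.7)
  expect_equal(round(1 / mean_of("D7")), 24)
  expect_equal(round(1 / mean_of("D10"), 2), 0.42)
})

test_that("model comparison reproduces the published bookkeeping", {
  out <- compare_models(4373, 2019, df = 3)
  expect_equal(out$delta_chi2, 2354)
  expect_lt(out$p.value, 1e-4)
  same <- compare_models(100, 100, df = 3)
  expect_equal(same$delta_chi2, 0)
  expect_equal(same$p.value, 1)
  # chi-square CDF oracle: P(X2_3 > 11.34) ~ 0.01
  expect_equal(compare_models(111.34, 100, df = 3)$p.value, 0.01,
               tolerance = 0.01)
})

test_that("the Mann-Kendall test flags trends and passes white noise", {
  x <- withr::with_seed(1, rnorm(200))
  expect_gt(mann_kendall(x)$p.value, 0.01)
  expect_lt(mann_kendall(x + seq(0, 3, length.out = 200))$p.value, 1e-6)
})

test_that("ensemble fitting recovers an identifiable rate on synthetic data", {
  # data generated by the demo oscillator with a perturbed D6 start
  r_true <- clock_oscillator_rates()
  y0 <- clock_limit_cycle_state(c(0, 12))
  t_grid <- seq(0, 96, 2)
  sim <- integrate_clock(r_true, y0, t_grid)
  obs <- observable_ccg2(sim, "raw")
  noise_sd <- 0.05 * sd(obs$value)
  data <- dplyr::mutate(obs,
    value = value + withr::with_seed(5, rnorm(dplyr::n(), 0, noise_sd)))

  r_start <- clock_oscillator_rates(D6 = unclass(r_true)[["D6"]] * 1.15)
  cfg <- fit_config(equilibration_sweeps = 800, accumulation_sweeps = 600,
                    seed = 8, error_sd = noise_sd)
  fit <- run_ensemble(r_start, data, cfg, free_rates = c("D6", "L3"),
                      init = y0)
  mom <- tidy(fit)
  d6 <- mom[mom$term == "D6", ]
  expect_lt(abs(d6$mean - unclass(r_true)[["D6"]]), 3 * d6$sd)
  expect_lt(fit$chi2_per_n, 2) # noise-level fit quality
  # converged identified-parameter trace shows no systematic drift with sweep
  expect_gt(fit$converged[["D6"]], 0.01)
  # the ensemble-average prediction is no worse than the median sampled model
  keep <- round(seq(1, nrow(fit$samples), length.out = 9))
  chi_of <- function(th) {
    r <- clock_oscillator_rates(D6 = unname(th[1]), L3 = unname(th[2]))
    s <- integrate_clock(r, y0, t_grid)
    chi_squared(observable_ccg2(s, "raw"), data, fit$error_sd)$chi2
  }
  sample_chi2 <- apply(fit$samples[keep, , drop = FALSE], 1, chi_of)
  expect_lte(fit$chi2, median(sample_chi2) * 1.05)
})

test_that("a zero-noise self-fit keeps chi-squared at zero", {
  r <- clock_oscillator_rates()
  y0 <- clock_limit_cycle_state(c(0, 12))
  t_grid <- seq(0, 48, 2)
  data <- observable_ccg2(integrate_clock(r, y0, t_grid), "raw")
  cfg <- fit_config(equilibration_sweeps = 5, accumulation_sweeps = 5,
                    seed = 1, error_sd = 1)
  fit <- run_ensemble(r, data, cfg, free_rates = c("D6"), init = y0)
  expect_equal(fit$chi2_trace[1], 0, tolerance = 1e-10)
})

test_that("ensemble fits are reproducible under a fixed seed", {
  r <- clock_oscillator_rates()
  y0 <- clock_limit_cycle_state(c(0, 12))
  t_grid <- seq(0, 48, 4)
  data <- observable_ccg2(integrate_clock(r, y0, t_grid), "raw")
  cfg <- fit_config(equilibration_sweeps = 10, accumulation_sweeps = 10,
                    seed = 31, error_sd = 1e-10)
  f1 <- run_ensemble(r, data, cfg, free_rates = c("D6", "Abar"), init = y0)
  f2 <- run_ensemble(r, data, cfg, free_rates = c("D6", "Abar"), init = y0)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$chi2_trace, f2$chi2_trace)
})
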