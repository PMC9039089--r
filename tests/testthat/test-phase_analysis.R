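test_that("bead normalization divides frame-wise and cancels shared drift", {
  t <- seq(0, 48, 0.5)
  cells <- tibble::tibble(cell_id = "a", t_h = t, intensity = 2 * rep(1, length(t)))
  expect_equal(normalize_by_beads(cells, rep(1, length(t)))$intensity,
               cells$intensity)
  expect_equal(normalize_by_beads(cells, rep(1, length(t)) * cells$intensity)$intensity,
               rep(2, length(t)) / 2 * 1) # cells = 2*beads -> constant
  # shared lamp drift cancels exactly
  drift <- 1 + 0.2 * sin(2 * pi * t / 37)
  sig <- 100 * (1 + 0.3 * cos(2 * pi * t / 21))
  cells2 <- tibble::tibble(cell_id = "a", t_h = t, intensity = sig * drift)
  beads <- tibble::tibble(t_h = t, intensity = 50 * drift)
  out <- normalize_by_beads(cells2, beads)
  expect_equal(out$intensity, sig / 50, tolerance = 1e-12)
  expect_error(normalize_by_beads(cells, rep(0, length(t))), "positive")
})

test_that("moving-average log-detrending removes constants and slow trends", {
  x <- rep(5, 200)
  expect_equal(detrend_series(x, 24, 0.5), rep(0, 200))
  # slow exponential: log is linear, centred mean cancels it in the interior
  lam <- 1e-8
  t <- seq(0, 240, 0.5)
  d <- detrend_series(exp(-lam * t), 24, 0.5)
  expect_lt(max(abs(d)), 1e-6)
  expect_error(detrend_series(c(1, -1, 2), 24, 0.5), "positive")
  expect_error(detrend_series(x, window_h = 0.3, dt_h = 0.5), "multiple")
})

test_that("a 30 h sinusoid detrended with a 30 h window keeps its 30 h peak", {
  t <- seq(0, 239.5, 0.5)
  y <- 100 * (1 + 0.3 * cos(2 * pi * t / 30))
  d <- detrend_series(y, window_h = 30, dt_h = 0.5)
  expect_equal(peak_period(periodogram(d, dt_h = 0.5)), 30)
})

test_that("Hilbert phase advances linearly for a cosine and ignores amplitude", {
  t <- seq(0, 210, 0.5)
  x <- cos(2 * pi * t / 21)
  ph <- hilbert_phase(x, t)
  interior <- !ph$edge
  slope <- mean(diff(ph$F_C[interior])) / 0.5
  expect_equal(slope, 2 * pi / 21, tolerance = 0.01)
  ph2 <- hilbert_phase(2 * x, t)
  expect_equal(ph$F_H, ph2$F_H, tolerance = 1e-10)
  # wrapping count over 210 h at a 21 h period: ten 2*pi wraps in F_H
  wraps <- sum(diff(ph$F_H) < -pi)
  expect_equal(wraps, 10)
  expect_error(hilbert_phase(rep(0, 100)), "zero")
  expect_error(hilbert_phase(c(1, 2)), "4 samples")
})

test_that("continuization minimizes the per-step jump and inverts wrapping", {
  expect_equal(continuize_phase(c(0.9 * pi, -0.9 * pi)),
               c(0.9 * pi, 1.1 * pi))
  # slow monotone phases are shifted by whole turns only
  f <- seq(0.2, 40, 0.11)
  wrapped <- ((f + pi) %% (2 * pi)) - pi
  fc <- continuize_phase(wrapped)
  expect_lt(max(abs(diff(fc) - diff(f))), 1e-9)
  # invariant: F_C == F_H modulo 2*pi, increments bounded by pi
  for (seed in 1:5) {
    fh <- withr::with_seed(seed, runif(300, -pi, pi))
    fc <- continuize_phase(fh)
    turns <- (fc - fh) / (2 * pi)
    expect_lt(max(abs(turns - round(turns))), 1e-9)
    expect_lte(max(abs(diff(fc))), pi + 1e-12)
  }
})

test_that("cycle counts follow the continuized phase", {
  ph <- linear_phase(21, 210)
  expect_equal(count_cycles(ph, 0, 210), 10)
  expect_equal(count_cycles(ph, 12, 12), 0)
  expect_equal(count_cycles(linear_phase(21, 209, 0.5), 0, 209), 209 / 21)
  expect_equal(round(count_cycles(linear_phase(21, 209, 0.5), 0, 209), 2), 9.95)
  expect_error(count_cycles(ph, 0, 1000), "grid")
})

test_that("Kuramoto order parameter hits its calibration points", {
  t <- seq(0, 48, 0.5)
  same <- outer(2 * pi * t / 21, rep(1, 6))
  expect_equal(kuramoto_order(same)$K, 1)
  anti <- cbind(2 * pi * t / 21, 2 * pi * t / 21 + pi)
  expect_equal(kuramoto_order(anti)$K, 0, tolerance = 1e-12)
  # the printed (centred) variant vanishes for constant perfect synchrony
  const <- matrix(1.3, nrow = length(t), ncol = 6)
  expect_equal(kuramoto_order(const, variant = "printed")$K, 0,
               tolerance = 1e-12)
  expect_equal(kuramoto_order(const)$K, 1)
  expect_error(kuramoto_order(same[, 1, drop = FALSE]), "2 oscillators")
})

test_that("uniform random phases give the finite-n resultant sqrt(pi/(4n))", {
  n <- 1000
  Ks <- vapply(1:40, function(s) {
    ph <- withr::with_seed(s, matrix(runif(n, 0, 2 * pi), nrow = 1))
    kuramoto_order(ph)$K
  }, numeric(1))
  expect_equal(mean(Ks), sqrt(pi / (4 * n)), tolerance = 0.1)
})

test_that("phase noise degrades the Kuramoto order parameter monotonically", {
  t <- seq(0, 48, 0.5)
  base <- outer(2 * pi * t / 21, rep(1, 40))
  K_at <- function(sd) {
    mean(vapply(1:5, function(s) {
      jit <- withr::with_seed(s * 100 + round(sd * 10),
                              matrix(rnorm(length(base), 0, sd), nrow(base)))
      kuramoto_order(base + jit)$K
    }, numeric(1)))
  }
  Ks <- vapply(c(0, 0.5, 1, 2), K_at, numeric(1))
  expect_true(all(diff(Ks) < 0))
})

test_that("bootstrap SE of K is reported over oscillators", {
  t <- seq(0, 48, 0.5)
  ph <- outer(2 * pi * t / 21, rep(1, 10)) +
    withr::with_seed(1, matrix(rnorm(10 * length(t), 0, 0.3), length(t)))
  out <- kuramoto_order(ph, se_boot = 100, seed = 2)
  expect_gt(out$se_K, 0)
  out2 <- kuramoto_order(ph, se_boot = 100, seed = 2)
  expect_identical(out$se_K, out2$se_K)
})

test_that("periodogram finds exact and dominant tones and rejects noise peaks", {
  t <- seq(0, 239.5, 0.5)
  expect_equal(peak_period(periodogram(cos(2 * pi * t / 30), 0.5)), 30)
  # both tones on the FFT grid of a 210 h record (420 samples)
  t2 <- seq(0, 209.5, 0.5)
  two <- sqrt(2) * cos(2 * pi * t2 / 21) + cos(2 * pi * t2 / 10.5)
  expect_equal(peak_period(periodogram(two, 0.5)), 21)
  # white noise: observed peak power is typical of its own permutation null
  x <- withr::with_seed(3, rnorm(480))
  obs <- attr(periodogram(x, 0.5), "peak_power")
  null <- vapply(1:200, function(s) {
    attr(periodogram(withr::with_seed(1000 + s, sample(x)), 0.5), "peak_power")
  }, numeric(1))
  expect_lt(obs, quantile(null, 0.99))
  expect_error(periodogram(rnorm(5), 0.5), "8 samples")
})
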