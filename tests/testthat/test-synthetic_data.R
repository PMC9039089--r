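test_that("config invariants are enforced", {
  expect_error(synth_config(dt_h = 0), "positive")
  expect_error(synth_config(duration_h = -1), "positive")
  expect_error(synth_config(duration_h = 10, dt_h = 0.7), "integer")
  expect_error(synth_config(n_cells = 0), "n_cells")
  expect_error(synth_config(noise_sd = -1), "non-negative")
})

test_that("the noiseless trendless limit is an exact sampled cosine", {
  cfg <- synth_config(n_cells = 1, noise_sd = 0, trend_rate = 0,
                      period_sd_h = 0, phase_sd_h = 0, seed = 1)
  ts <- simulate_population(cfg)
  t <- ts$t_h
  expect_equal(ts$intensity, 100 * (1 + 0.3 * cos(2 * pi * t / 21)),
               tolerance = 1e-12)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- simulate_population(synth_config(n_cells = 8, duration_h = 48, seed = 42))
  b <- simulate_population(synth_config(n_cells = 8, duration_h = 48, seed = 42))
  expect_identical(a$intensity, b$intensity)
  c <- simulate_population(synth_config(n_cells = 8, duration_h = 48, seed = 43))
  expect_false(identical(a$intensity, c$intensity))
})

test_that("periodogram peaks recover the generating period distribution", {
  cfg <- synth_config(n_cells = 100, seed = 7)
  ts <- simulate_population(cfg)
  det <- detrend_trajectories(ts)
  peaks <- det |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(peak = peak_period(periodogram(intensity, 0.5))) |>
    dplyr::pull(peak)
  expect_lt(abs(mean(peaks) - 21), 0.5)
})

test_that("bead de-normalization round-trips exactly", {
  ts <- simulate_population(synth_config(n_cells = 4, duration_h = 48,
                                         bead_noise_sd = 0, seed = 3))
  beads <- attr(ts, "beads")
  norm <- normalize_by_beads(ts, beads)
  back <- dplyr::mutate(norm,
                        intensity = intensity * beads$intensity[match(t_h, beads$t_h)])
  expect_equal(back$intensity, ts$intensity, tolerance = 1e-12)
})

test_that("mixing offsets set the phase relation between subpopulations", {
  # zero offset: the two subpopulation mean trajectories agree closely
  cfg0 <- synth_config(n_cells = 1, duration_h = 72, seed = 5)
  m0 <- simulate_mixing(60, 0, cfg0)
  means <- m0 |>
    dplyr::group_by(subpopulation, t_h) |>
    dplyr::summarise(v = mean(intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = subpopulation, values_from = v)
  expect_gt(cor(means$A, means$B), 0.95)

  # 12 h offset with a 24 h period, noiseless: antiphase on the first cycle
  cfg <- synth_config(n_cells = 1, duration_h = 96, period_mean_h = 24,
                      period_sd_h = 0, phase_sd_h = 0, noise_sd = 0,
                      trend_rate = 0, seed = 6)
  m <- simulate_mixing(3, 12, cfg)
  means <- m |>
    dplyr::filter(t_h <= 24) |>
    dplyr::group_by(subpopulation, t_h) |>
    dplyr::summarise(v = mean(intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = subpopulation, values_from = v)
  expect_lt(cor(means$A, means$B), -0.99)
  expect_error(simulate_mixing(0, 12, cfg), "n_per_pop")
})

test_that("clustering the synthetic mixture recovers most true labels", {
  ts <- mixing_fixture(n_per_pop = 120, seed = 11)
  det <- detrend_trajectories(ts)
  cl <- cluster_trajectories(det, window_h = c(0, 30))
  acc <- clustering_accuracy(cl, attr(ts, "truth"))
  expect_gte(acc, 0.8)
})

test_that("density layouts reproduce the chamber well counts", {
  lay <- density_layout(c(126, 87, 55, 46))
  expect_identical(lay$wells, c(15876L, 7569L, 3025L, 2116L))
  expect_equal(lay$wells, lay$grid_side^2)
  expect_error(density_layout(0), "positive")
})

test_that("synchronization rises with coupling across the density series", {
  # couplings straddle the locking transition so K spans a wide range
  layouts <- density_layout(c(126, 87, 55, 46),
                            coupling_scale = c(2, 0.8, 0.3, 0.1))
  cfg <- synth_config(n_cells = 40, duration_h = 72, phase_sd_h = 4, seed = 1)
  slopes <- vapply(1:5, function(s) {
    cfg$seed <- s * 17
    sets <- simulate_density_series(layouts, cfg, kuramoto_sigma = 0.3)
    Ks <- vapply(sets, function(ts) {
      det <- detrend_trajectories(ts)
      ph <- det |>
        dplyr::group_by(cell_id) |>
        dplyr::arrange(t_h, .by_group = TRUE) |>
        dplyr::reframe(hilbert_phase(intensity, t_h)) |>
        dplyr::filter(!edge) |>
        dplyr::rename(phase = F_C)
      kuramoto_order(ph)$K
    }, numeric(1))
    coef(lm(Ks ~ layouts$coupling_scale))[2]
  }, numeric(1))
  # sign test over seeds: every replicate slope positive
  expect_identical(sum(slopes > 0), 5L)
  expect_equal(sign_test(slopes), 0.5^5)

  # zero coupling everywhere: K shows no density relation
  lay0 <- density_layout(c(126, 87, 55, 46), coupling_scale = 0)
  sets0 <- simulate_density_series(lay0, cfg, kuramoto_sigma = 0.3)
  Ks0 <- vapply(sets0, function(ts) {
    det <- detrend_trajectories(ts)
    ph <- det |>
      dplyr::group_by(cell_id) |>
      dplyr::arrange(t_h, .by_group = TRUE) |>
      dplyr::reframe(hilbert_phase(intensity, t_h)) |>
      dplyr::filter(!edge) |>
      dplyr::rename(phase = F_C)
    kuramoto_order(ph)$K
  }, numeric(1))
  sl0 <- coef(lm(Ks0 ~ lay0$wells))[2]
  expect_lt(abs(sl0) * max(lay0$wells), 0.5) # K change across the range is small
  expect_error(simulate_density_series(density_layout(126), cfg), "2 density")
})

test_that("the ODE engine produces circadian trajectories too", {
  cfg <- synth_config(n_cells = 3, duration_h = 120, engine = "ode", seed = 9)
  ts <- simulate_population(cfg)
  det <- detrend_trajectories(ts)
  peaks <- det |>
    dplyr::group_by(cell_id) |>
    dplyr::summarise(peak = peak_period(periodogram(intensity, 0.5))) |>
    dplyr::pull(peak)
  expect_true(all(peaks > 16 & peaks < 27))
})
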