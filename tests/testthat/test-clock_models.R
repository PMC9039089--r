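test_that("gene states are conserved by the right-hand sides", {
  for (seed in 1:5) {
    y <- random_clock_state(2, "quorum", seed)
    d <- quorum_rhs(y, quorum_rates())
    for (cell in 1:2) {
      sfx <- paste0("_c", cell)
      expect_identical(d[[paste0("wc1_gene", sfx)]], 0)
      expect_identical(d[[paste0("wc2_gene", sfx)]], 0)
      expect_equal(d[[paste0("frq_gene_off", sfx)]] +
                     d[[paste0("frq_gene_on", sfx)]], 0)
      expect_equal(d[[paste0("ccg_gene_off", sfx)]] +
                     d[[paste0("ccg_gene_on", sfx)]], 0)
      expect_equal(d[[paste0("ccg2_gene_off", sfx)]] +
                     d[[paste0("ccg2_gene_on", sfx)]], 0)
    }
  }
})

test_that("wc-1 mRNA derivative matches the hand-evaluated published rates", {
  # S1*1 - D1*1 - C1*1*1 with the published ensemble means
  y <- clock_state(1, "quorum", baseline = 0)
  y[c("wc1_gene_c1", "wc1_mrna_c1", "FRQ_c1")] <- 1
  d <- quorum_rhs(y, quorum_rates())
  expect_equal(d[["wc1_mrna_c1"]], 33.20978 - 1.164574 - 0.001665926,
               tolerance = 1e-10)
  expect_equal(d[["wc1_mrna_c1"]], 32.04354, tolerance = 1e-6)
})

test_that("R and compiled right-hand sides agree on random states", {
  for (seed in 1:4) {
    y <- random_clock_state(3, "quorum", seed)
    r <- quorum_rates()
    d_r <- quorum_rhs(y, r)
    d_c <- clocksync:::clock_rhs_cpp(0L, unname(y), unclass(r), 3L, FALSE, FALSE)
    expect_equal(unname(d_r), as.numeric(d_c), tolerance = 1e-12)

    yc <- random_clock_state(3, "contact", seed + 10)
    rc <- contact_rates(D_contact = 0.7)
    expect_equal(unname(contact_rhs(yc, rc)),
                 as.numeric(clocksync:::clock_rhs_cpp(1L, unname(yc), unclass(rc), 3L,
                                          FALSE, FALSE)),
                 tolerance = 1e-12)
  }
})

test_that("contact diffusion vanishes for equal signals and conserves total", {
  rc <- contact_rates(D_contact = 0.8)
  y <- random_clock_state(4, "contact", 7)
  y[paste0("S_c", 1:4)] <- 1.3
  d_with <- contact_rhs(y, rc)
  rc0 <- contact_rates(D_contact = 0)
  d_without <- contact_rhs(y, rc0)
  expect_equal(d_with[paste0("S_c", 1:4)], d_without[paste0("S_c", 1:4)])

  # unequal signals: diffusive exchange sums to zero over the chain
  y2 <- random_clock_state(5, "contact", 8)
  dd <- contact_rhs(y2, contact_rates(D_contact = 1.1)) -
    contact_rhs(y2, contact_rates(D_contact = 0))
  expect_equal(sum(dd[paste0("S_c", 1:5)]), 0, tolerance = 1e-12)
})

test_that("boundary coupling follows the single-neighbour rule", {
  rc <- contact_rates(D_contact = 0.5, D9 = 0, K_S1 = 0)
  y <- clock_state(2, "contact", baseline = 0)
  y["S_c1"] <- 1
  y["S_c2"] <- 3
  d <- contact_rhs(y, rc)
  expect_equal(unname(d[c("S_c1", "S_c2")]), c(1, -1))
})

test_that("printed bracketing multiplies the diffusion term by K_S1", {
  rc <- contact_rates(D_contact = 0.5, D9 = 0, K_S1 = 2)
  y <- clock_state(2, "contact", baseline = 0)
  y["S_c1"] <- 1
  y["S_c2"] <- 3
  d_conv <- contact_rhs(y, rc)
  d_lit <- contact_rhs(y, rc, printed_bracketing = TRUE)
  expect_equal(unname(d_conv[c("S_c1", "S_c2")]), c(1, -1))
  expect_equal(unname(d_lit[c("S_c1", "S_c2")]), c(2, -2))
})

test_that("zero rates freeze the state and conservation holds over 240 h", {
  r0 <- quorum_rates()
  r0[] <- 0
  r0 <- structure(r0, class = "clock_rates", model = "quorum")
  y <- random_clock_state(2, "quorum", 3)
  sim <- integrate_clock(r0, y, seq(0, 50, 10))
  expect_false(sim_failed(sim))
  for (col in names(y)) expect_equal(sim[[col]], rep(y[[col]], nrow(sim)))

  # demo oscillator: gene totals conserved to 1e-8 relative over 240 h
  rs <- clock_oscillator_rates()
  y0 <- clock_limit_cycle_state(c(0, 12))
  sim <- integrate_clock(rs, y0, seq(0, 240, 2))
  expect_false(sim_failed(sim))
  for (cell in 1:2) {
    for (g in c("frq_gene", "ccg_gene", "ccg2_gene")) {
      tot <- sim[[paste0(g, "_off_c", cell)]] + sim[[paste0(g, "_on_c", cell)]]
      expect_lt(max(abs(tot / tot[1] - 1)), 1e-8)
    }
    expect_lt(max(abs(sim[[paste0("wc1_gene_c", cell)]] - y0[[paste0("wc1_gene_c", cell)]])), 1e-8)
  }
})

test_that("integration self-converges when the tolerance is halved", {
  r <- clock_oscillator_rates()
  y0 <- clock_limit_cycle_state(0)
  tg <- seq(0, 120, 1)
  a <- integrate_clock(r, y0, tg, rtol = 1e-6)
  b <- integrate_clock(r, y0, tg, rtol = 5e-7)
  rel <- max(abs(a$CCG2_c1 - b$CCG2_c1) / max(abs(a$CCG2_c1)))
  expect_lt(rel, 1e-4)
})

test_that("identical cells stay identical under the quorum model", {
  r <- clock_oscillator_rates()
  y0 <- clock_limit_cycle_state(c(0, 0))
  sim <- integrate_clock(r, y0, seq(0, 100, 1))
  for (sp in c("FRQ", "WCC", "CCG2", "S")) {
    expect_equal(sim[[paste0(sp, "_c1")]], sim[[paste0(sp, "_c2")]],
                 tolerance = 1e-8)
  }
})

test_that("solver failure is flagged, never silent", {
  r <- clock_oscillator_rates()
  y0 <- clock_limit_cycle_state(0)
  sim <- integrate_clock(r, y0, seq(0, 240, 0.5), max_steps = 5)
  expect_true(sim_failed(sim))
  expect_match(sim$message, "step")
  expect_error(integrate_clock(r, y0, c(0, 0, 1)), "increasing")
})

test_that("negative concentrations can warn or error on request", {
  y <- clock_state(1, "quorum")
  y["FRQ_c1"] <- -0.1
  r <- quorum_rates()
  expect_silent(quorum_rhs(y, r))
  expect_warning(quorum_rhs(y, r, on_negative = "warn"), "negative")
  expect_error(quorum_rhs(y, r, on_negative = "error"), "negative")
})

test_that("the CCG-2 observable matches its mode contract", {
  r <- clock_oscillator_rates()
  y0 <- clock_limit_cycle_state(0)
  sim <- integrate_clock(r, y0, seq(0, 120, 0.5))
  raw <- observable_ccg2(sim, "raw")
  expect_equal(raw$value, sim$CCG2_c1)

  # constant reporter detrends to exactly zero
  sim_const <- sim
  sim_const$CCG2_c1 <- 3.7
  det <- observable_ccg2(sim_const, "detrended")
  expect_equal(det$value, rep(0, nrow(sim)), tolerance = 1e-12)

  # oscillating reporter keeps a circadian periodogram peak after detrending
  det2 <- observable_ccg2(sim, "detrended")
  pk <- peak_period(periodogram(det2$value[det2$t_h >= 12 & det2$t_h <= 108],
                                dt_h = 0.5))
  expect_gt(pk, 15)
  expect_lt(pk, 27)
})

test_that("model parameter counts are computed from configuration", {
  expect_identical(n_model_parameters("quorum", 2), 71L)
  # contact chain of 2: 42 states + 25 shared estimated rates + D_contact
  expect_identical(n_model_parameters("contact", 2), 68L)
  expect_identical(n_model_parameters("quorum", 2) -
                     n_model_parameters("contact", 2), 3L)
})
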