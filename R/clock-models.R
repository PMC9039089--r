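#' @useDynLib clocksync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical orderings shared with the compiled code. Do not reorder.
CLOCK_SPECIES <- c(
  "wc1_gene", "wc1_mrna", "wc1_mrna_stab", "WC1",
  "wc2_gene", "wc2_mrna", "WC2",
  "frq_gene_off", "frq_gene_on", "frq_mrna", "FRQ", "WCC",
  "ccg_gene_off", "ccg_gene_on", "ccg_mrna", "CCG",
  "ccg2_gene_off", "ccg2_gene_on", "ccg2_mrna", "CCG2", "S"
)

CLOCK_RATE_NAMES <- c(
  "A", "Abar", "S1", "S3", "S4", "D1", "D3", "C1", "L1", "L3",
  "D4", "D6", "D7", "D8", "C2", "P", "Ac", "Bc", "Sc", "Lc",
  "Dcr", "Dcp", "K_S1", "C4", "eta", "eta_ext", "D9", "D10",
  "S2", "D2", "L2", "D5", "Ac2", "Bc2", "Sc2", "Lc2", "Dcr2", "Dcp2",
  "n_hill", "m_hill"
)

# The 28 rate constants identified by the ensemble fit (quorum model); the
# remaining rates of the wc-2 branch and the ccg-2 reporter cascade were held
# fixed in the fit and default to their wc-1 / ccg analogues.
ESTIMATED_RATES <- c(
  "A", "Abar", "S1", "S3", "S4", "D1", "D3", "C1", "L1", "L3",
  "D4", "D6", "D7", "D8", "C2", "P", "Ac", "Bc", "Sc", "Lc",
  "Dcr", "Dcp", "K_S1", "C4", "eta", "eta_ext", "D9", "D10"
)

#' Published ensemble moments of the quorum-sensing model rate constants
#'
#' Ensemble means and standard errors of the 28 estimated rate constants of
#' the quorum-sensing clock-network model, as identified by ensemble
#' Metropolis-Hastings fitting to microwell fluorescence data. Units are
#' per-hour (first-order rates) or per-hour per-concentration (bimolecular
#' terms) in the arbitrary concentration units of the model.
#'
#' @return A tibble with columns `rate`, `mean`, `se`.
#' @export
#' @examples
#' published_rate_moments()
published_rate_moments <- function() {
  tibble::tibble(
    rate = ESTIMATED_RATES,
    mean = c(
      6.946009e-03, 9.969590e-02, 3.320978e+01, 1.041769e-03, 1.951816e+01,
      1.164574e+00, 1.870605e+00, 1.665926e-03, 4.165664e+01, 5.276481e+00,
      5.395039e-01, 5.761848e-01, 4.217466e-02, 4.741010e-05, 3.580439e+00,
      9.767857e+01, 1.064269e+01, 9.094971e-01, 1.490714e-03, 1.145927e-08,
      5.943974e+01, 4.044340e-01, 2.408651e+09, 1.234348e+00, 2.038943e+00,
      2.466155e+01, 1.484148e+01, 2.374897e+00
    ),
    se = c(
      3.313135e-06, 8.297570e-05, 1.923567e-02, 2.155980e-04, 8.880192e-03,
      9.405917e-04, 6.546756e-04, 1.348076e-06, 2.685045e-02, 3.137782e-03,
      2.537757e-04, 2.585495e-04, 3.477031e-05, 8.957513e-06, 2.470929e-03,
      5.976836e-02, 5.098955e-02, 2.667601e-03, 2.502344e-06, 3.711730e-11,
      1.366934e-01, 6.436382e-04, 2.156671e+08, 5.422941e-02, 7.304766e-01,
      2.222896e+00, 2.340141e-01, 7.021016e-01
    )
  )
}

rates_vector <- function(values) {
  stopifnot(all(CLOCK_RATE_NAMES %in% names(values)))
  out <- as.numeric(values[CLOCK_RATE_NAMES])
  names(out) <- CLOCK_RATE_NAMES
  if (any(out[setdiff(CLOCK_RATE_NAMES, c("n_hill", "m_hill"))] < 0))
    stop("all rate constants must be non-negative", call. = FALSE)
  out
}

#' Rate-constant sets for the two communication models
#'
#' `quorum_rates()` assembles the full rate vector of the quorum-sensing
#' model (mean-field external signal `S_e`); `contact_rates()` the
#' cell-contact variant, in which the in/out diffusion rates `eta`,
#' `eta_ext` and the external decay `D10` are replaced by a single
#' nearest-neighbour diffusion coefficient `D_contact`. Estimated rates
#' default to the published ensemble means
#' ([published_rate_moments()]); auxiliary rates that the fit held fixed
#' (`S2`, `D2`, `L2`, `D5`, and the ccg-2 reporter cascade) default to their
#' wc-1 / ccg analogues. Hill cooperativity coefficients `n_hill`, `m_hill`
#' default to 4.
#'
#' @param ... Named rate overrides, e.g. `quorum_rates(D6 = 0.4)`.
#' @param D_contact Nearest-neighbour diffusion coefficient of the contact
#'   model (per hour).
#' @return A named numeric vector of class `clock_rates` with a `model`
#'   attribute.
#' @export
#' @examples
#' r <- quorum_rates()
#' 1 / r[["D6"]] # FRQ protein lifetime, hours
quorum_rates <- function(...) {
  tab <- published_rate_moments()
  v <- stats::setNames(tab$mean, tab$rate)
  v[c("S2", "D2", "L2", "D5")] <- v[c("S1", "D1", "L1", "D4")]
  v[c("Ac2", "Bc2", "Sc2", "Lc2", "Dcr2", "Dcp2")] <-
    v[c("Ac", "Bc", "Sc", "Lc", "Dcr", "Dcp")]
  v[c("n_hill", "m_hill")] <- 4
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), CLOCK_RATE_NAMES)
    if (length(bad)) stop("unknown rate(s): ", paste(bad, collapse = ", "))
    v[names(dots)] <- dots
  }
  structure(rates_vector(v), class = "clock_rates", model = "quorum")
}

#' @rdname quorum_rates
#' @export
contact_rates <- function(D_contact = 1, ...) {
  v <- unclass(quorum_rates(...))
  # eta slot carries D_contact in the shared layout; eta_ext / D10 are inert
  v[["eta"]] <- D_contact
  v[["eta_ext"]] <- 0
  v[["D10"]] <- 0
  structure(v, class = "clock_rates", model = "contact")
}

#' @export
print.clock_rates <- function(x, ...) {
  cat("<clock_rates> model:", attr(x, "model"), "\n")
  print(unclass(x))
  invisible(x)
}

#' Number of free parameters of a configured model
#'
#' Counts estimated rate constants plus initial conditions, the bookkeeping
#' used in the chi-squared model comparison. For the quorum model with two
#' giant cells this is 28 rates + 43 initial conditions = 71. The contact
#' model drops \{`eta`, `eta_ext`, `D10`, `S_e(0)`\} and adds `D_contact`.
#'
#' @param model `"quorum"` or `"contact"`.
#' @param n_cells Number of giant cells (default 2).
#' @return Integer parameter count.
#' @export
#' @examples
#' n_model_parameters("quorum")  # 71
#' n_model_parameters("quorum") - n_model_parameters("contact")  # 3
n_model_parameters <- function(model = c("quorum", "contact"), n_cells = 2) {
  model <- match.arg(model)
  n_states <- length(CLOCK_SPECIES) * n_cells + if (model == "quorum") 1L else 0L
  n_rates <- if (model == "quorum") {
    length(ESTIMATED_RATES)
  } else {
    length(setdiff(ESTIMATED_RATES, c("eta", "eta_ext", "D10"))) + 1L # D_contact
  }
  as.integer(n_rates + n_states)
}

#' Build a model state vector
#'
#' Assembles the full state vector for `n_cells` giant cells (21 molecular
#' species each) plus, for the quorum model, the shared external signal
#' `S_e`. Gene states are set so each promoter pair sums to `gene_total`
#' (all probability mass on the inactive state by default); mRNA and protein
#' pools start at `baseline`.
#'
#' @param n_cells Number of giant cells.
#' @param model `"quorum"` or `"contact"`.
#' @param baseline Initial concentration of clock-gene mRNA/protein pools.
#'   The ccg/ccg-2 output cascades and the signal pools start at zero and
#'   build up on their own scale (the published signal production rate
#'   `K_S1` is so large that naive non-zero signal-cascade starts diverge).
#' @param gene_total Conserved total of each gene's on/off pair.
#' @param S_e Initial external signal (quorum model).
#' @param values Optional named overrides, names like `"FRQ_c1"` or `"S_e"`.
#' @return Named numeric state vector.
#' @export
clock_state <- function(n_cells = 2, model = c("quorum", "contact"),
                        baseline = 0.1, gene_total = 1, S_e = 0,
                        values = NULL) {
  model <- match.arg(model)
  per_cell <- stats::setNames(rep(baseline, length(CLOCK_SPECIES)), CLOCK_SPECIES)
  per_cell[c("wc1_gene", "wc2_gene", "frq_gene_off",
             "ccg_gene_off", "ccg2_gene_off")] <- gene_total
  per_cell[c("frq_gene_on", "ccg_gene_on", "ccg2_gene_on")] <- 0
  per_cell[c("ccg_mrna", "CCG", "ccg2_mrna", "CCG2", "S")] <- 0
  y <- rep(per_cell, n_cells)
  names(y) <- paste0(rep(CLOCK_SPECIES, n_cells), "_c",
                     rep(seq_len(n_cells), each = length(CLOCK_SPECIES)))
  if (model == "quorum") y <- c(y, S_e = S_e)
  if (!is.null(values)) {
    bad <- setdiff(names(values), names(y))
    if (length(bad)) stop("unknown state name(s): ", paste(bad, collapse = ", "))
    y[names(values)] <- values
  }
  y
}

n_cells_of <- function(y, model) {
  ns <- length(CLOCK_SPECIES)
  if (model == "quorum") (length(y) - 1L) %/% ns else length(y) %/% ns
}

#' Right-hand sides of the clock-network ODEs
#'
#' Pure-R evaluation of the time derivatives of the coupled clock network:
#' `quorum_rhs()` for the mean-field quorum-sensing model (per-cell signal
#' exchange with a shared external pool `S_e`), `contact_rhs()` for the
#' cell-contact variant in which the signal diffuses only between
#' neighbouring cells in a chain (single-neighbour coupling at the chain
#' ends). These are reference implementations used for testing and
#' documentation; [integrate_clock()] uses an equivalent compiled version.
#'
#' @param state Named state vector from [clock_state()].
#' @param rates A `clock_rates` vector.
#' @param printed_bracketing Contact model only: if `TRUE`, use the literal
#'   printed form in which the production constant `K_S1` also multiplies
#'   the diffusion term; the default applies `K_S1` to production only.
#' @param floor_c2 If `TRUE`, clamp the signal-modulated binding rate
#'   `(C2 - C4 * S_j)` at zero instead of letting it go negative.
#' @param on_negative What to do when a concentration is negative:
#'   `"ignore"` (integration may legitimately undershoot), `"warn"`, or
#'   `"error"`.
#' @return Named derivative vector, same layout as `state`.
#' @export
quorum_rhs <- function(state, rates, floor_c2 = FALSE,
                       on_negative = c("ignore", "warn", "error")) {
  on_negative <- match.arg(on_negative)
  check_negatives(state, on_negative)
  nc <- n_cells_of(state, "quorum")
  r <- as.list(unclass(rates))
  S_e <- state[["S_e"]]
  d <- state * 0
  for (j in seq_len(nc)) {
    x <- cell_view(state, j)
    dj <- cell_rhs_common(x, r, floor_c2)
    dj["S"] <- -r$D9 * x["S"] + r$K_S1 * x["CCG"] + r$eta * (S_e - x["S"])
    d[cell_idx(j)] <- dj
  }
  S_all <- state[paste0("S_c", seq_len(nc))]
  d["S_e"] <- -r$D10 * S_e + r$eta_ext * sum(S_all - S_e)
  d
}

#' @rdname quorum_rhs
#' @export
contact_rhs <- function(state, rates, printed_bracketing = FALSE,
                        floor_c2 = FALSE,
                        on_negative = c("ignore", "warn", "error")) {
  on_negative <- match.arg(on_negative)
  check_negatives(state, on_negative)
  nc <- n_cells_of(state, "contact")
  if (nc < 2) stop("contact model needs at least 2 cells in the chain")
  r <- as.list(unclass(rates))
  S_all <- unname(state[paste0("S_c", seq_len(nc))])
  lap <- vapply(seq_len(nc), function(j) {
    if (j == 1) -S_all[1] + S_all[2]
    else if (j == nc) -S_all[nc] + S_all[nc - 1]
    else -2 * S_all[j] + S_all[j + 1] + S_all[j - 1]
  }, numeric(1))
  d <- state * 0
  for (j in seq_len(nc)) {
    x <- cell_view(state, j)
    dj <- cell_rhs_common(x, r, floor_c2)
    dj["S"] <- if (printed_bracketing) {
      -r$D9 * x["S"] + r$K_S1 * (x["CCG"] + r$eta * lap[j])
    } else {
      -r$D9 * x["S"] + r$K_S1 * x["CCG"] + r$eta * lap[j]
    }
    d[cell_idx(j)] <- dj
  }
  d
}

cell_idx <- function(j) {
  ns <- length(CLOCK_SPECIES)
  (j - 1L) * ns + seq_len(ns)
}

cell_view <- function(state, j) {
  x <- state[cell_idx(j)]
  names(x) <- CLOCK_SPECIES
  x
}

check_negatives <- function(state, on_negative) {
  if (on_negative == "ignore" || all(state >= 0)) return(invisible())
  msg <- "negative concentration(s) in state vector"
  if (on_negative == "warn") warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
}

# Shared per-cell dynamics (everything except the signal equation).
cell_rhs_common <- function(x, r, floor_c2) {
  WCCn <- x[["WCC"]]^r$n_hill
  FRQm <- x[["FRQ"]]^r$m_hill
  cbind_rate <- r$C2 - r$C4 * x[["S"]]
  if (floor_c2) cbind_rate <- max(cbind_rate, 0)
  assoc <- cbind_rate * x[["WC2"]] * x[["WC1"]]
  onoff_frq <- r$A * x[["frq_gene_off"]] * WCCn - r$Abar * x[["frq_gene_on"]]
  onoff_ccg <- r$Ac * x[["ccg_gene_off"]] * WCCn - r$Bc * x[["ccg_gene_on"]]
  onoff_ccg2 <- r$Ac2 * x[["ccg2_gene_off"]] * WCCn - r$Bc2 * x[["ccg2_gene_on"]]
  c(
    wc1_gene = 0,
    wc1_mrna = r$S1 * x[["wc1_gene"]] - r$D1 * x[["wc1_mrna"]] -
      r$C1 * x[["wc1_mrna"]] * x[["FRQ"]],
    wc1_mrna_stab = r$C1 * x[["wc1_mrna"]] * x[["FRQ"]] -
      r$D7 * x[["wc1_mrna_stab"]],
    WC1 = r$L1 * x[["wc1_mrna_stab"]] - r$D4 * x[["WC1"]] - assoc,
    wc2_gene = 0,
    wc2_mrna = r$S2 * x[["wc2_gene"]] - r$D2 * x[["wc2_mrna"]],
    WC2 = r$L2 * x[["wc2_mrna"]] - r$D5 * x[["WC2"]] - assoc +
      r$P * x[["WCC"]] * FRQm,
    frq_gene_off = -onoff_frq,
    frq_gene_on = onoff_frq,
    frq_mrna = r$S3 * x[["frq_gene_off"]] + r$S4 * x[["frq_gene_on"]] -
      r$D3 * x[["frq_mrna"]],
    FRQ = r$L3 * x[["frq_mrna"]] - r$D6 * x[["FRQ"]],
    WCC = -r$n_hill * onoff_frq - r$D8 * x[["WCC"]] + assoc -
      r$P * x[["WCC"]] * FRQm,
    ccg_gene_off = -onoff_ccg,
    ccg_gene_on = onoff_ccg,
    ccg_mrna = r$Sc * x[["ccg_gene_on"]] - r$Dcr * x[["ccg_mrna"]],
    CCG = r$Lc * x[["ccg_mrna"]] - r$Dcp * x[["CCG"]],
    ccg2_gene_off = -onoff_ccg2,
    ccg2_gene_on = onoff_ccg2,
    ccg2_mrna = r$Sc2 * x[["ccg2_gene_on"]] - r$Dcr2 * x[["ccg2_mrna"]],
    CCG2 = r$Lc2 * x[["ccg2_mrna"]] - r$Dcp2 * x[["CCG2"]],
    S = 0
  )
}

#' Integrate the clock-network model
#'
#' Adaptive Runge-Kutta (embedded Cash-Karp 4/5) integration of the
#' quorum-sensing or cell-contact clock network, sampled on a user time
#' grid.
#'
#' @param rates A `clock_rates` vector from [quorum_rates()] or
#'   [contact_rates()]; its `model` attribute selects the communication
#'   model.
#' @param init Named initial state from [clock_state()].
#' @param t_grid Strictly increasing time grid in hours.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param printed_bracketing,floor_c2 See [quorum_rhs()].
#' @param max_steps Step-count guard against stiff blow-up.
#' @return A tibble with column `t_h` and one column per state variable, of
#'   class `clock_sim`, carrying `model` and `success` attributes. On solver
#'   failure an object of class `clock_failure` is returned (never silent
#'   `NaN`s); test with [sim_failed()].
#' @export
#' @examples
#' r <- quorum_rates()
#' sim <- integrate_clock(r, clock_state(2), seq(0, 48, 0.5))
integrate_clock <- function(rates, init, t_grid, rtol = 1e-6, atol = 1e-9,
                            printed_bracketing = FALSE, floor_c2 = FALSE,
                            max_steps = 1e6) {
  stopifnot(inherits(rates, "clock_rates"))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  model <- attr(rates, "model")
  model_id <- if (model == "quorum") 0L else 1L
  res <- integrate_clock_cpp(model_id, unclass(rates), unname(init),
                             as.numeric(t_grid), rtol, atol,
                             printed_bracketing, floor_c2,
                             as.integer(max_steps))
  if (!res$success) {
    return(structure(
      list(message = res$message, n_steps = res$n_steps, model = model),
      class = "clock_failure"
    ))
  }
  y <- res$y
  colnames(y) <- names(init)
  out <- tibble::as_tibble(as.data.frame(y))
  out <- tibble::add_column(out, t_h = as.numeric(t_grid), .before = 1)
  structure(out, class = c("clock_sim", class(out)),
            model = model, success = TRUE)
}

#' @rdname integrate_clock
#' @param x Object returned by [integrate_clock()].
#' @export
sim_failed <- function(x) inherits(x, "clock_failure")

#' @export
print.clock_failure <- function(x, ...) {
  cat("<clock integration failure>", x$message, "\n")
  invisible(x)
}

#' Fluorescence observable of a simulated clock network
#'
#' Extracts the per-cell CCG-2 reporter concentration, the model analogue of
#' the mCherry fluorescence driven by the ccg-2 promoter, optionally passed
#' through the same log/moving-average detrending pipeline applied to data
#' so that model and measurement are compared on identical footing.
#'
#' @param sim A `clock_sim` tibble from [integrate_clock()].
#' @param mode `"raw"` (identity on CCG-2) or `"detrended"` (see
#'   [detrend_series()]).
#' @param window_h Detrending window in hours (detrended mode).
#' @return A tibble with columns `cell_id`, `t_h`, `value`.
#' @export
observable_ccg2 <- function(sim, mode = c("raw", "detrended"), window_h = 24) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "clock_sim"))
  cols <- grep("^CCG2_c", names(sim), value = TRUE)
  dt_h <- sim$t_h[2] - sim$t_h[1]
  purrr::map_dfr(cols, function(cl) {
    v <- sim[[cl]]
    if (mode == "detrended") v <- detrend_series(v, window_h = window_h, dt_h = dt_h)
    tibble::tibble(
      cell_id = sub("^CCG2_", "", cl),
      t_h = sim$t_h,
      value = v
    )
  })
}
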