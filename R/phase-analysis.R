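#' Normalize cell fluorescence by a bead reference channel
#'
#' Per-frame division of each cell's fluorescence by the intensity of
#' reference beads imaged in parallel, removing shared excitation-lamp
#' drift.
#'
#' @param cells Trajectory tibble with columns `cell_id`, `t_h`,
#'   `intensity`.
#' @param beads Bead reference: a numeric vector on the same grid or a
#'   tibble with columns `t_h`, `intensity`. Must be strictly positive.
#' @return The trajectory tibble with `intensity` divided frame-wise by the
#'   bead intensity.
#' @export
normalize_by_beads <- function(cells, beads) {
  grid <- sort(unique(cells$t_h))
  if (is.data.frame(beads)) {
    if (!all(c("t_h", "intensity") %in% names(beads)))
      stop("bead tibble needs columns t_h, intensity")
    beads <- beads$intensity[match(grid, beads$t_h)]
  }
  if (length(beads) != length(grid))
    stop("bead series and cell time grid differ in length")
  if (any(!is.finite(beads)) || any(beads <= 0))
    stop("bead intensities must be strictly positive")
  ref <- beads[match(cells$t_h, grid)]
  dplyr::mutate(cells, intensity = .data$intensity / ref)
}

#' Log-detrend a series with a centred moving average
#'
#' Takes the natural log of a (strictly positive) fluorescence series and
#' subtracts a centred moving average spanning `window_h` hours, the
#' standard removal of photobleaching/growth trends before phase analysis.
#' Edge windows are truncated.
#'
#' @param x Numeric series, strictly positive.
#' @param window_h Moving-average window in hours; must be a positive
#'   multiple of the sampling interval.
#' @param dt_h Sampling interval in hours.
#' @param log Take logs first (default); `FALSE` detrends the raw series.
#' @return Detrended numeric series (log scale when `log = TRUE`).
#' @export
#' @examples
#' t <- seq(0, 240, 0.5)
#' y <- exp(-0.002 * t) * (1 + 0.3 * cos(2 * pi * t / 21))
#' d <- detrend_series(y, window_h = 24, dt_h = 0.5)
detrend_series <- function(x, window_h = 24, dt_h = 0.5, log = TRUE) {
  if (window_h <= 0 || abs(window_h / dt_h - round(window_h / dt_h)) > 1e-8)
    stop("window_h must be a positive multiple of the sampling interval")
  if (log) {
    if (any(x <= 0)) stop("non-positive intensities: cannot log-detrend")
    x <- base::log(x)
  }
  half <- round(window_h / dt_h / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  trend <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  x - trend
}

#' Detrend every cell of a trajectory set
#'
#' Applies [detrend_series()] cell-wise to a trajectory tibble.
#'
#' @inheritParams normalize_by_beads
#' @inheritParams detrend_series
#' @return The tibble with `intensity` replaced by its log-detrended value.
#' @export
detrend_trajectories <- function(cells, window_h = 24, log = TRUE) {
  dt_h <- time_step_of(cells$t_h)
  cells |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$t_h, .by_group = TRUE) |>
    dplyr::mutate(intensity = detrend_series(.data$intensity, window_h,
                                             dt_h, log = log)) |>
    dplyr::ungroup()
}

time_step_of <- function(t) {
  dt <- diff(sort(unique(t)))
  if (length(dt) == 0) stop("need at least two timepoints")
  if (max(dt) - min(dt) > 1e-8) stop("time grid is not uniform")
  dt[1]
}

#' FFT-based Hilbert transform
#'
#' Returns the Hilbert transform of `x` (the imaginary part of the analytic
#' signal), computed through the fast Fourier transform.
#'
#' @param x Numeric series (detrended, roughly zero-mean).
#' @return Numeric series of the same length.
#' @export
hilbert_transform <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  Im(analytic)
}

#' Instantaneous Hilbert phase of an oscillatory series
#'
#' Computes the raw Hilbert phase `F_H(t)` (two-argument arctangent of the
#' Hilbert transform against the signal, in (-pi, pi]) and its continuized
#' version `F_C(t)` free of 2*pi discontinuities. The first and last
#' `edge_exclude_h` hours are flagged: the FFT Hilbert transform is
#' unreliable near record boundaries.
#'
#' @param x Detrended, zero-mean numeric series (length >= 4).
#' @param t_h Time grid in hours (defaults to an index grid).
#' @param edge_exclude_h Width of the boundary region flagged in the `edge`
#'   column (hours).
#' @return A tibble with columns `t_h`, `F_H`, `F_C`, `edge`.
#' @export
#' @examples
#' t <- seq(0, 210, 0.5)
#' ph <- hilbert_phase(cos(2 * pi * t / 21), t)
hilbert_phase <- function(x, t_h = seq_along(x) - 1, edge_exclude_h = 12) {
  if (length(x) < 4) stop("need at least 4 samples for a Hilbert phase")
  if (all(x == 0)) stop("all-zero input: phase undefined")
  F_H <- atan2(hilbert_transform(x), x)
  edge <- t_h < min(t_h) + edge_exclude_h | t_h > max(t_h) - edge_exclude_h
  tibble::tibble(t_h = t_h, F_H = F_H, F_C = continuize_phase(F_H), edge = edge)
}

#' Continuize a wrapped phase series
#'
#' Recursively unwraps a raw Hilbert phase in (-pi, pi]: at each step the
#' integer number of turns `m` is chosen to minimize the jump
#' `|F_H(t+1) + 2*pi*m - F_C(t)|`, ties broken toward the `m` of smaller
#' magnitude, so successive increments never exceed pi in absolute value.
#'
#' @param F_H Wrapped phase series in (-pi, pi].
#' @return Unbounded continuized phase `F_C`, equal to `F_H` modulo 2*pi at
#'   every sample.
#' @export
continuize_phase <- function(F_H) {
  n <- length(F_H)
  F_C <- numeric(n)
  F_C[1] <- F_H[1]
  for (i in seq_len(n - 1L)) {
    target <- (F_C[i] - F_H[i + 1L]) / (2 * pi)
    m_lo <- floor(target)
    cand <- c(m_lo, m_lo + 1L)
    jump <- abs(F_H[i + 1L] + 2 * pi * cand - F_C[i])
    pick <- if (abs(jump[1] - jump[2]) < 1e-12) {
      cand[which.min(abs(cand))]
    } else {
      cand[which.min(jump)]
    }
    F_C[i + 1L] <- F_H[i + 1L] + 2 * pi * pick
  }
  F_C
}

#' Elapsed cycles between two times
#'
#' Number of oscillation cycles completed between `t0` and `t1`, from the
#' continuized phase: `(F_C(t1) - F_C(t0)) / (2*pi)`.
#'
#' @param phase A phase tibble from [hilbert_phase()] (or any tibble with
#'   `t_h` and `F_C` columns).
#' @param t0,t1 Times in the grid, `t0 <= t1` (equal times give 0 cycles).
#' @return Cycles (dimensionless, not rounded).
#' @export
count_cycles <- function(phase, t0, t1) {
  if (t0 > t1) stop("t0 must not exceed t1")
  i0 <- match(t0, phase$t_h)
  i1 <- match(t1, phase$t_h)
  if (is.na(i0) || is.na(i1)) stop("t0/t1 not in the phase time grid")
  (phase$F_C[i1] - phase$F_C[i0]) / (2 * pi)
}

#' Kuramoto order parameter of a set of phase trajectories
#'
#' Synchronization statistic across `n >= 2` oscillators on a common time
#' grid. The `standard` variant is the time average of the resultant length
#' `|n^-1 sum_j exp(i phase_j(t))|`: 1 for perfect synchrony, near 0 for
#' incoherent phases. The `printed` variant subtracts the time-mean phasor
#' inside the modulus before averaging (kept for comparison; it evaluates
#' to 0 for constant perfect synchrony and so fails the 1 = synchronized
#' calibration).
#'
#' @param phases Matrix of phases in radians, timepoints x oscillators
#'   (wrapped or continuized; only `exp(i*phase)` matters), or a tibble with
#'   columns `cell_id`, `t_h` and a phase column named `phase` or `F_C`.
#' @param variant `"standard"` or `"printed"`.
#' @param se_boot Number of bootstrap resamples over oscillators for the
#'   standard error (0 = none).
#' @param seed Optional seed for the bootstrap.
#' @return A one-row tibble: `K`, `se_K`, `n_oscillators`, `variant`.
#' @export
#' @examples
#' ph <- outer(seq(0, 48, 0.5), rep(2 * pi / 21, 5)) # 5 identical clocks
#' kuramoto_order(ph)$K # 1
kuramoto_order <- function(phases, variant = c("standard", "printed"),
                           se_boot = 0, seed = NULL) {
  variant <- match.arg(variant)
  phases <- phase_matrix_of(phases)
  n <- ncol(phases)
  if (n < 2) stop("need at least 2 oscillators")
  K_of <- function(mat) {
    z <- rowMeans(exp(1i * mat))
    if (variant == "printed") z <- z - mean(z)
    mean(Mod(z))
  }
  se_K <- NA_real_
  if (se_boot > 0) {
    boots <- with_seed_if(seed, {
      vapply(seq_len(se_boot), function(b) {
        K_of(phases[, sample.int(n, n, replace = TRUE), drop = FALSE])
      }, numeric(1))
    })
    se_K <- stats::sd(boots)
  }
  tibble::tibble(K = K_of(phases), se_K = se_K, n_oscillators = n,
                 variant = variant)
}

phase_matrix_of <- function(phases) {
  if (is.matrix(phases)) return(phases)
  if (is.data.frame(phases)) {
    col <- intersect(c("phase", "F_C", "F_H"), names(phases))[1]
    if (is.na(col)) stop("phase tibble needs a 'phase', 'F_C' or 'F_H' column")
    wide <- tidyr::pivot_wider(phases[, c("cell_id", "t_h", col)],
                               names_from = "cell_id",
                               values_from = tidyr::all_of(col))
    return(as.matrix(wide[, -1, drop = FALSE]))
  }
  stop("phases must be a matrix or a tidy phase tibble")
}

#' Periodogram of a uniformly sampled series
#'
#' FFT power spectrum reported against period in hours, with the period and
#' power of the spectral peak (the amplitude proxy used in
#' amplitude-vs-density analyses).
#'
#' @param x Detrended numeric series, length >= 8, uniform sampling.
#' @param dt_h Sampling interval in hours.
#' @return A tibble with columns `period_h`, `power` (zero frequency
#'   excluded), carrying attributes `peak_period_h` and `peak_power`; see
#'   [peak_period()].
#' @export
#' @examples
#' t <- seq(0, 239.5, 0.5)
#' p <- periodogram(cos(2 * pi * t / 30), dt_h = 0.5)
#' attr(p, "peak_period_h") # 30
periodogram <- function(x, dt_h = 0.5) {
  n <- length(x)
  if (n < 8) stop("need at least 8 samples for a periodogram")
  x <- x - mean(x)
  pw <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor(n / 2))
  freq <- k / (n * dt_h)
  out <- tibble::tibble(period_h = 1 / freq, power = pw[k + 1L])
  peak <- which.max(out$power)
  attr(out, "peak_period_h") <- out$period_h[peak]
  attr(out, "peak_power") <- out$power[peak]
  out
}

#' @rdname periodogram
#' @param p A periodogram tibble.
#' @export
peak_period <- function(p) attr(p, "peak_period_h")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state; with a NULL seed, evaluate as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
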