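#' Cluster single-cell trajectories into giant cells
#'
#' K-means clustering (20 restarts, fixed seed) of z-scored trajectory
#' segments over an early time window, the procedure used to split a mixed
#' population into its two phase groups; the cluster averages over the full
#' record act as "giant cell" field-of-view equivalents.
#'
#' @param cells Trajectory tibble (`cell_id`, `t_h`, `intensity`).
#' @param window_h Clustering window `c(from, to)` in hours (default 0-30).
#' @param k Number of clusters (default 2).
#' @param seed RNG seed for the restarts.
#' @param nstart K-means restarts.
#' @param method `"kmeans"` or `"ward"` (hierarchical, Ward linkage).
#' @return A list of class `cluster_result`: `labels` (tibble `cell_id`,
#'   `cluster`), `means` (tibble `cluster`, `t_h`, `value` over the full
#'   record), `window_h`, `k`, `degenerate` (all-identical input collapses
#'   to one effective cluster).
#' @export
cluster_trajectories <- function(cells, window_h = c(0, 30), k = 2,
                                 seed = 1, nstart = 20,
                                 method = c("kmeans", "ward")) {
  method <- match.arg(method)
  ids <- unique(cells$cell_id)
  if (length(ids) < k) stop("need at least k cells to form k clusters")
  seg <- cells |>
    dplyr::filter(.data$t_h >= window_h[1], .data$t_h <= window_h[2]) |>
    dplyr::arrange(.data$cell_id, .data$t_h)
  if (nrow(seg) == 0) stop("clustering window lies outside the record")
  X <- matrix(seg$intensity, nrow = length(ids), byrow = TRUE,
              dimnames = list(sort(ids), NULL))
  Xz <- t(apply(X, 1, function(v) {
    s <- stats::sd(v)
    if (s == 0) v * 0 else (v - mean(v)) / s
  }))
  degenerate <- all(apply(Xz, 2, stats::sd) == 0)
  labels <- if (degenerate) {
    rep(1L, nrow(Xz))
  } else if (method == "kmeans") {
    with_seed_if(seed, stats::kmeans(Xz, centers = k, nstart = nstart)$cluster)
  } else {
    stats::cutree(stats::hclust(stats::dist(Xz), method = "ward.D2"), k = k)
  }
  lab_tbl <- tibble::tibble(cell_id = rownames(Xz), cluster = as.integer(labels))
  means <- cells |>
    dplyr::inner_join(lab_tbl, by = "cell_id") |>
    dplyr::group_by(.data$cluster, .data$t_h) |>
    dplyr::summarise(value = mean(.data$intensity), .groups = "drop")
  structure(list(labels = lab_tbl, means = means, window_h = window_h,
                 k = k, degenerate = degenerate),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", x$k, "clusters over", nrow(x$labels), "cells;",
      "window", paste(x$window_h, collapse = "-"), "h",
      if (x$degenerate) "(degenerate input)" else "", "\n")
  invisible(x)
}

#' Label-recovery accuracy of a clustering against ground truth
#'
#' Fraction of cells assigned to their true subpopulation under the best
#' matching of cluster labels to truth labels (all permutations tried).
#'
#' @param result A `cluster_result` (or a labels tibble).
#' @param truth Tibble with columns `cell_id` and `subpopulation` (e.g. the
#'   `truth` attribute of [simulate_mixing()]).
#' @return Accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(result, truth) {
  labels <- if (inherits(result, "cluster_result")) result$labels else result
  m <- dplyr::inner_join(labels, truth, by = "cell_id")
  cl <- m$cluster
  tr <- as.integer(factor(m$subpopulation))
  perms <- perms_of(sort(unique(cl)))
  best <- 0
  for (p in perms) {
    acc <- mean(p[match(cl, sort(unique(cl)))] == tr)
    best <- max(best, acc)
  }
  best
}

perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

#' Per-timepoint bootstrap standard error of the population mean
#'
#' At each timepoint, cells are resampled with replacement `B` times and
#' the SE is the SD of the resampled means. Fixed seed gives identical
#' output.
#'
#' @param cells Trajectory tibble (>= 2 cells).
#' @param B Bootstrap resamples (>= 2).
#' @param seed RNG seed.
#' @return A tibble: `t_h`, `mean`, `se`.
#' @export
bootstrap_se <- function(cells, B = 1000, seed = 1) {
  if (B < 2) stop("need at least 2 bootstrap resamples")
  ids <- unique(cells$cell_id)
  if (length(ids) < 2) stop("need at least 2 cells")
  grid <- sort(unique(cells$t_h))
  X <- matrix(cells$intensity[order(cells$cell_id, cells$t_h)],
              nrow = length(ids), byrow = TRUE)
  nc <- nrow(X)
  se <- with_seed_if(seed, {
    boots <- vapply(seq_len(B), function(b) {
      colMeans(X[sample.int(nc, nc, replace = TRUE), , drop = FALSE])
    }, numeric(ncol(X)))
    apply(boots, 1, stats::sd)
  })
  tibble::tibble(t_h = grid, mean = colMeans(X), se = se)
}

#' Normalized bootstrap SEs for the single-cell vs multi-cell contrast
#'
#' Bootstrap SEs per timepoint for two groups of cells (e.g. isolated
#' single cells X vs cells sharing wells Y), each normalized by the pooled
#' per-timepoint root mean square over both groups,
#' `sqrt((1/n) (sum X^2 + sum Y^2))` with `n` the total cell count.
#'
#' @param group_x,group_y Trajectory tibbles on one grid.
#' @inheritParams bootstrap_se
#' @return A tibble: `t_h`, `se_x`, `se_y`, `rms`, `nse_x`, `nse_y`.
#' @export
normalized_se <- function(group_x, group_y, B = 1000, seed = 1) {
  bx <- bootstrap_se(group_x, B = B, seed = seed)
  by <- bootstrap_se(group_y, B = B, seed = seed + 1)
  if (!isTRUE(all.equal(bx$t_h, by$t_h)))
    stop("the two groups are on different time grids")
  n <- length(unique(group_x$cell_id)) + length(unique(group_y$cell_id))
  sumsq <- function(g) {
    g |>
      dplyr::group_by(.data$t_h) |>
      dplyr::summarise(ss = sum(.data$intensity^2), .groups = "drop") |>
      dplyr::arrange(.data$t_h) |>
      dplyr::pull(.data$ss)
  }
  rms <- sqrt((sumsq(group_x) + sumsq(group_y)) / n)
  tibble::tibble(t_h = bx$t_h, se_x = bx$se, se_y = by$se, rms = rms,
                 nse_x = bx$se / rms, nse_y = by$se / rms)
}

#' Variance-ratio (F) test between two per-timepoint variance series
#'
#' Compares overall variability of two groups across time as the ratio of
#' mean per-timepoint variances, with `df = (timepoints - 1, timepoints -
#' 1)`, the convention matching the printed F with equal dfs either side.
#'
#' @param var_a,var_b Per-timepoint variance (or squared-SE) series of the
#'   two groups, same length.
#' @param larger_over_smaller Put the larger mean variance in the
#'   numerator? (default `TRUE`).
#' @return A one-row tibble: `F`, `df1`, `df2`, `p.value`.
#' @export
variance_ratio <- function(var_a, var_b, larger_over_smaller = TRUE) {
  if (length(var_a) != length(var_b))
    stop("variance series differ in length")
  ma <- mean(var_a)
  mb <- mean(var_b)
  if (min(ma, mb) == 0) stop("zero variance in the denominator group")
  if (larger_over_smaller && mb > ma) {
    tmp <- ma; ma <- mb; mb <- tmp
  }
  F <- ma / mb
  df <- length(var_a) - 1L
  tibble::tibble(F = F, df1 = df, df2 = df,
                 p.value = stats::pf(F, df, df, lower.tail = FALSE))
}

#' Robust regression of synchronization on cell density
#'
#' Huber M-estimator line fit (iteratively reweighted least squares via
#' `MASS::rlm`) of Kuramoto K on wells per chamber, with a one-sided t-test
#' on a positive slope (the quorum-sensing prediction being that
#' synchronization increases with density).
#'
#' @param density Wells per chamber (>= 3 points).
#' @param K Kuramoto order parameter per chamber.
#' @return A one-row tibble: `intercept`, `slope`, `slope_se`, `t`, `df`,
#'   `p_one_sided`, plus the ordinary least squares `slope_ols` for
#'   comparison.
#' @export
density_regression <- function(density, K) {
  if (length(density) < 3) stop("need at least 3 density points")
  fit <- MASS::rlm(K ~ density, maxit = 100)
  co <- summary(fit)$coefficients
  slope <- co["density", "Value"]
  se <- co["density", "Std. Error"]
  df <- length(density) - 2L
  t <- slope / se
  ols <- stats::coef(stats::lm(K ~ density))[["density"]]
  tibble::tibble(intercept = co["(Intercept)", "Value"], slope = slope,
                 slope_se = se, t = t, df = df,
                 p_one_sided = stats::pt(t, df, lower.tail = FALSE),
                 slope_ols = ols)
}

#' Sign test on replicate regression slopes
#'
#' One-sided binomial tail probability that at least the observed number of
#' slopes are positive under the null of sign symmetry: `(1/2)^n` when all
#' `n` slopes are positive.
#'
#' @param slopes Signed slope estimates from replicate experiments; zeros
#'   are not allowed (ties are flagged as an error).
#' @return One-sided p-value.
#' @export
#' @examples
#' sign_test(c(.1, .2, .05, .3, .15)) # (1/2)^5 = 0.03125
sign_test <- function(slopes) {
  if (length(slopes) == 0) stop("empty slope list")
  if (any(slopes == 0)) stop("zero slopes (ties) cannot be sign-tested")
  n <- length(slopes)
  n_pos <- sum(slopes > 0)
  stats::pbinom(n_pos - 1, n, 0.5, lower.tail = FALSE)
}

#' Contrast two Kuramoto order parameters
#'
#' Normal-approximation z test of the difference of two K estimates with
#' bootstrap standard errors: `z = (K_a - K_b) / sqrt(se_a^2 + se_b^2)`,
#' two-sided p.
#'
#' @param K_a,K_b Kuramoto K estimates.
#' @param se_a,se_b Their (positive) standard errors.
#' @param n_a,n_b Oscillator counts behind each estimate (bookkeeping for
#'   the t-like degrees of freedom `n_a + n_b - 2`).
#' @return A one-row tibble: `z`, `df`, `p.value`.
#' @export
kuramoto_contrast <- function(K_a, se_a, K_b, se_b,
                              n_a = NA_integer_, n_b = NA_integer_) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive")
  z <- (K_a - K_b) / sqrt(se_a^2 + se_b^2)
  df <- if (is.na(n_a) || is.na(n_b)) NA_integer_ else
    as.integer(n_a + n_b - 2)
  tibble::tibble(z = z, df = df, p.value = 2 * stats::pnorm(-abs(z)))
}
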