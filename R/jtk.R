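# JTK-style rank-concordance test for rhythmicity.
#
# For each trial (period, lag) a reference cosine is evaluated at the
# sampling times; the test statistic is Kendall's S between the series and
# the reference. Everything is rank-based, so for a continuous series the
# null distribution is distribution-free and, for n <= 9, exactly
# enumerable over all n! orderings. Two grid corrections are offered:
# the exact joint null of the minimal two-sided tail over the whole
# (period, lag) grid (default; the references are strongly correlated, so
# Bonferroni overcorrects several-fold), and plain Bonferroni over the
# grid. Series with ties, and series longer than 9 points, fall back to
# per-reference tails (exact tie-aware enumeration or the normal
# approximation) with Bonferroni.

.jtk_null_cache <- new.env(parent = emptyenv())

# all permutations of 1..n as an (n! x n) matrix, built by insertion
perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- perm_matrix(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- p + (p >= i)
    out[[i]] <- cbind(rep(i, nrow(q)), q)
  }
  do.call(rbind, out)
}

kendall_s <- function(y, ref) {
  n <- length(y)
  idx <- combn(n, 2)
  sum(sign(y[idx[1, ]] - y[idx[2, ]]) * sign(ref[idx[1, ]] - ref[idx[2, ]]))
}

# Joint exact null over a reference grid: for every ordering of 1..n and
# every reference, Kendall's S; per-reference two-sided tail probabilities;
# and the null distribution of the minimal tail across references.
jtk_joint_null <- function(ref_ranks) {
  n <- ncol(ref_ranks)
  key <- paste(c(n, signif(as.vector(ref_ranks), 10)), collapse = ",")
  null <- .jtk_null_cache[[key]]
  if (!is.null(null)) return(null)
  pm <- perm_matrix(n)
  idx <- combn(n, 2)
  np <- nrow(pm)
  dsign <- sign(pm[, idx[1, ]] - pm[, idx[2, ]])   # np x pairs
  s_mat <- matrix(0, np, nrow(ref_ranks))
  tail_mat <- matrix(0, np, nrow(ref_ranks))
  abs_sorted <- vector("list", nrow(ref_ranks))
  for (j in seq_len(nrow(ref_ranks))) {
    sref <- sign(ref_ranks[j, idx[1, ]] - ref_ranks[j, idx[2, ]])
    s <- as.vector(dsign %*% sref)
    a <- abs(s)
    tail_mat[, j] <- (np - rank(a, ties.method = "min") + 1) / np
    s_mat[, j] <- s
    abs_sorted[[j]] <- sort(a)
  }
  null <- list(min_tail_sorted = sort(apply(tail_mat, 1, min)),
               abs_sorted = abs_sorted, np = np)
  .jtk_null_cache[[key]] <- null
  null
}

# Exact two-sided tail P(|S_null| >= s_abs) by enumerating all arrangements
# of the value multiset `yvals` against `ref` (tie-aware in both).
jtk_exact_tail <- function(yvals, ref) {
  n <- length(yvals)
  yr <- rank(yvals)
  rr <- rank(ref)
  key <- paste(c("m", n, sort(yr), signif(rr, 10)), collapse = ",")
  dist <- .jtk_null_cache[[key]]
  if (is.null(dist)) {
    pm <- perm_matrix(n)
    idx <- combn(n, 2)
    sref <- sign(rr[idx[1, ]] - rr[idx[2, ]])
    ys <- sort(yr)
    s_all <- numeric(nrow(pm))
    for (k in seq_len(ncol(idx))) {
      if (sref[k] == 0) next
      s_all <- s_all + sref[k] *
        sign(ys[pm[, idx[1, k]]] - ys[pm[, idx[2, k]]])
    }
    dist <- s_all
    .jtk_null_cache[[key]] <- dist
  }
  s_obs <- kendall_s(yr, rr)
  list(s = s_obs, p = mean(abs(dist) >= abs(s_obs)))
}

jtk_normal_tail <- function(yvals, ref) {
  s_obs <- kendall_s(rank(yvals), rank(ref))
  n <- length(yvals)
  v <- n * (n - 1) * (2 * n + 5) / 18   # tie corrections omitted: approximation
  p <- 2 * stats::pnorm(abs(s_obs) / sqrt(v), lower.tail = FALSE)
  list(s = s_obs, p = min(1, p))
}

jtk_reference_grid <- function(time, period_grid, phase_step) {
  # round so that symmetric sampling positions tie exactly (floating-point
  # jitter in cos() would otherwise break rank ties asymmetrically)
  refs <- do.call(rbind, lapply(period_grid, function(per) {
    lags <- seq(0, per - phase_step, by = phase_step)
    t(vapply(lags, function(lag) round(cos(2 * pi * (time - lag) / per), 9),
             numeric(length(time))))
  }))
  meta <- do.call(rbind, lapply(period_grid, function(per) {
    lags <- seq(0, per - phase_step, by = phase_step)
    cbind(period = rep(per, length(lags)), lag = lags)
  }))
  list(refs = refs, meta = meta)
}

#' JTK-style rhythmicity test
#'
#' Scans a grid of trial periods and phase lags; at each, computes
#' Kendall's S between the series and a reference cosine, with exact
#' (fully enumerated, distribution-free) two-sided tail probabilities for
#' series of up to 9 points. The period grid contains the multiples of the
#' sampling interval within `[min_period, max_period]`, matching the
#' test's rank construction.
#'
#' Grid correction: with `grid_correction = "exact"` (default) the minimal
#' per-reference tail is referred to its exact joint null over all n!
#' orderings — the proper correction, since the grid's reference cosines
#' are strongly correlated and Bonferroni overcorrects several-fold. With
#' `"bonferroni"` the minimal tail is multiplied by the number of
#' (period, lag) combinations. Tied series and series with more than 9
#' points use per-reference tails (tie-aware enumeration or the normal
#' approximation of S) with Bonferroni.
#'
#' @param time sampling times in hours
#' @param y expression values
#' @param min_period,max_period period window in hours (defaults 20, 28)
#' @param period_grid optional explicit period grid (overrides the window)
#' @param phase_step lag step in hours (default: the sampling interval)
#' @param grid_correction `"exact"` or `"bonferroni"`
#' @return list with `p`, `best_period`, `best_lag`, `tau` (tie-corrected
#'   Kendall tau at the best combination), and `n_tests`
#' @export
jtk_cycle <- function(time, y, min_period = 20, max_period = 28,
                      period_grid = NULL, phase_step = NULL,
                      grid_correction = c("exact", "bonferroni")) {
  stop_if_not(length(time) == length(y), "time and y lengths differ")
  stop_if_not(length(y) >= 5, "need at least 5 time points")
  grid_correction <- match.arg(grid_correction)
  dt <- min(diff(sort(unique(time))))
  if (is.null(phase_step)) phase_step <- dt
  if (is.null(period_grid)) {
    period_grid <- seq(ceiling(min_period / dt) * dt,
                       floor(max_period / dt) * dt, by = dt)
    stop_if_not(length(period_grid) >= 1,
                "no multiple of the sampling interval lies in [min_period, max_period]")
  }
  if (var(y) == 0) {
    return(list(p = 1, best_period = period_grid[1], best_lag = 0,
                tau = 0, n_tests = 0L))
  }
  rg <- jtk_reference_grid(time, period_grid, phase_step)
  n_tests <- nrow(rg$refs)
  n <- length(y)
  has_ties <- anyDuplicated(y) > 0

  tau_at <- function(ref, s) {
    idx <- combn(n, 2)
    dy <- sign(y[idx[1, ]] - y[idx[2, ]])
    dr <- sign(ref[idx[1, ]] - ref[idx[2, ]])
    denom <- sqrt(sum(dy != 0) * sum(dr != 0))
    if (denom > 0) s / denom else 0
  }

  if (grid_correction == "exact" && n <= 9 && !has_ties) {
    ref_ranks <- t(apply(rg$refs, 1, rank))
    null <- jtk_joint_null(ref_ranks)
    s_obs <- vapply(seq_len(n_tests), function(j) {
      kendall_s(y, rg$refs[j, ])
    }, numeric(1))
    tails <- vapply(seq_len(n_tests), function(j) {
      a <- null$abs_sorted[[j]]
      (null$np - findInterval(abs(s_obs[j]), a, left.open = TRUE)) / null$np
    }, numeric(1))
    # ties between a reference and its mirrored lag (S of opposite sign)
    # are resolved toward positive concordance
    minimal <- which(tails <= min(tails) + 1e-15)
    jbest <- minimal[which.max(s_obs[minimal])]
    mt <- null$min_tail_sorted
    p <- findInterval(min(tails) + 1e-12, mt) / length(mt)
    return(list(p = max(p, 1 / length(mt)),
                best_period = rg$meta[jbest, "period"],
                best_lag = rg$meta[jbest, "lag"],
                tau = tau_at(rg$refs[jbest, ], s_obs[jbest]),
                n_tests = n_tests))
  }

  # per-reference tails with Bonferroni
  exact <- n <= 9
  best <- list(p = Inf, j = 1L, s = 0)
  for (j in seq_len(n_tests)) {
    ref <- rg$refs[j, ]
    res <- if (exact) jtk_exact_tail(y, ref) else jtk_normal_tail(y, ref)
    # on tied tails prefer positive concordance (the mirrored lag)
    if (res$p < best$p || (res$p == best$p && res$s > best$s))
      best <- list(p = res$p, j = j, s = res$s)
  }
  list(p = min(1, best$p * n_tests),
       best_period = rg$meta[best$j, "period"],
       best_lag = rg$meta[best$j, "lag"],
       tau = tau_at(rg$refs[best$j, ], best$s),
       n_tests = n_tests)
}
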