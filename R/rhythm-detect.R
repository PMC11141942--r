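#' Combine p-values by Fisher's method
#'
#' `X2 = -2 * sum(log(p_i))` referred to a chi-square distribution with
#' `2k` degrees of freedom. Inputs of exactly zero are floored (default
#' 1e-300) with a warning to avoid `-Inf`.
#'
#' @param p numeric vector of p-values in `(0, 1]`
#' @param floor lower clip applied to zero/underflowed p-values
#' @return the combined p-value (a single p passes through unchanged)
#' @export
integrate_pvalues <- function(p, floor = 1e-300) {
  stop_if_not(length(p) >= 1, "need at least one p-value")
  stop_if_not(all(is.finite(p)) && all(p <= 1) && all(p >= 0),
              "p-values must lie in [0, 1]")
  if (any(p < floor)) {
    warn_f("%d p-value(s) below %.3g floored before Fisher combination",
           sum(p < floor), floor)
    p <- pmax(p, floor)
  }
  if (length(p) == 1) return(p)
  x2 <- -2 * sum(log(p))
  pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

.rhythm_null_cache <- new.env(parent = emptyenv())

# Empirical null of the combined rhythm statistic. The three periodicity
# statistics are computed on the same series, so their p-values are
# positively dependent and the plain Fisher chi-square reference is
# anti-conservative (and, because the exact JTK p is discrete, no scaled
# chi-square fits the null well either). Instead the Fisher statistic
# X = -2 sum(log p_i) is referred to its simulated null: `n_sim` internally
# seeded Gaussian null series analysed by the identical per-gene procedure.
# The null depends only on the sampling design and method set; the sorted
# draws are cached per design.
rhythm_null_xdist <- function(time, methods, min_period, max_period,
                              n_sim = 2000) {
  key <- paste(c(signif(time, 10), sort(methods), min_period, max_period,
                 n_sim), collapse = ",")
  tab <- .rhythm_null_cache[[key]]
  if (!is.null(tab)) return(tab)
  tp <- sort(unique(time))
  xs <- with_seed(651207L, {
    vapply(seq_len(n_sim), function(i) {
      y <- rnorm(length(time))
      x <- combined_rhythm_stat(time, y, methods, min_period, max_period)
      x
    }, numeric(1))
  })
  tab <- sort(xs)
  .rhythm_null_cache[[key]] <- tab
  tab
}

# Per-gene method p-values exactly as detect_rhythmic computes them,
# collapsed to the Fisher statistic.
combined_rhythm_stat <- function(time, y, methods, min_period, max_period) {
  p <- rhythm_method_pvalues(time, y, methods, min_period, max_period)$p
  -2 * sum(log(pmax(p[!is.na(p)], 1e-300)))
}

rhythm_method_pvalues <- function(time, y, methods, min_period, max_period) {
  tp <- sort(unique(time))
  dt <- min(diff(tp))
  grid <- seq(ceiling(min_period / dt) * dt,
              floor(max_period / dt) * dt, by = dt)
  if (!length(grid)) grid <- 24
  cos_fits <- lapply(grid, function(per) cosinor_fit(time, y, per))
  best <- which.min(vapply(cos_fits, `[[`, 1, "p"))
  p <- c(p_cosinor = NA_real_, p_jtk = NA_real_, p_ls = NA_real_)
  if ("cosinor" %in% methods)
    p["p_cosinor"] <- min(1, length(grid) * cos_fits[[best]]$p)
  if ("jtk" %in% methods)
    p["p_jtk"] <- jtk_cycle(time, y, min_period, max_period)$p
  if ("lomb_scargle" %in% methods) {
    ym <- if (anyDuplicated(time)) as.numeric(tapply(y, time, mean)) else y
    p["p_ls"] <- lomb_scargle(tp, ym, min_period, max_period)$p
  }
  list(p = p, best_fit = cos_fits[[best]])
}

#' Rhythm-detection configuration
#'
#' @param min_period,max_period period search window in hours (defaults
#'   20 and 28)
#' @param fdr_threshold BH FDR cutoff for calling a gene rhythmic
#'   (default 0.05)
#' @param methods subset of `c("cosinor", "jtk", "lomb_scargle")`
#' @param use_raw_p call rhythmicity on the raw integrated p instead of the
#'   BH-adjusted value (default FALSE; the FDR criterion is standard)
#' @return a `rhythm_config` list
#' @export
rhythm_config <- function(min_period = 20, max_period = 28,
                          fdr_threshold = 0.05,
                          methods = c("cosinor", "jtk", "lomb_scargle"),
                          use_raw_p = FALSE) {
  stop_if_not(min_period > 0 && min_period <= max_period,
              "need 0 < min_period <= max_period")
  stop_if_not(fdr_threshold > 0 && fdr_threshold < 1,
              "fdr_threshold must be in (0, 1)")
  methods <- match.arg(methods, c("cosinor", "jtk", "lomb_scargle"),
                       several.ok = TRUE)
  structure(list(min_period = min_period, max_period = max_period,
                 fdr_threshold = fdr_threshold, methods = methods,
                 use_raw_p = isTRUE(use_raw_p)),
            class = "rhythm_config")
}

#' Detect rhythmic genes in a temporal expression matrix
#'
#' Runs the enabled periodicity statistics per gene (cosinor F-test at the
#' best grid period, JTK-style rank concordance with exact small-sample
#' null, Lomb-Scargle on the replicate-mean series), combines them with
#' the Fisher statistic `-2 sum(log p)`, and applies Benjamini-Hochberg FDR
#' control across all tested genes. Because the three statistics are
#' computed on the same series their p-values are positively dependent, so
#' when more than one method is enabled the combined statistic is referred
#' to its empirical null: internally seeded Gaussian null series on the
#' same sampling design, analysed by the identical per-gene procedure
#' (computed once per design and cached). With a single method the plain
#' Fisher reference (the identity) applies. The reported cosinor p-value
#' is Bonferroni-adjusted for the period grid searched. Period, phase and
#' relative amplitude are taken from the cosinor fit at the best-fitting
#' grid period; phase is reported modulo that period.
#'
#' @param x a [temporal_matrix()], already expression-filtered
#' @param config a [rhythm_config()]
#' @return a `data.frame` (class `rhythmicity_table`) with one row per gene:
#'   gene, p_cosinor, p_jtk, p_ls, p_integrated, fdr, period_est, phase_est,
#'   amplitude_est, rhythmic
#' @export
detect_rhythmic <- function(x, config = rhythm_config()) {
  stopifnot(inherits(x, "temporal_matrix"), inherits(config, "rhythm_config"))
  genes <- rownames(x$values)
  usable <- length(x$time) >= 5
  if (!usable) stop("need at least 5 samples", call. = FALSE)
  one_gene <- function(g) {
    y <- x$values[g, ]
    mp <- rhythm_method_pvalues(x$time, y, config$methods,
                                config$min_period, config$max_period)
    cf <- mp$best_fit
    c(mp$p, period_est = cf$period, phase_est = cf$phase %% cf$period,
      amplitude_est = cf$amplitude_rel)
  }

  rows <- t(vapply(genes, one_gene, numeric(6)))
  ps <- rows[, c("p_cosinor", "p_jtk", "p_ls"), drop = FALSE]
  if (length(config$methods) > 1) {
    null_x <- rhythm_null_xdist(x$time, config$methods,
                                config$min_period, config$max_period)
    n_sim <- length(null_x)
    p_int <- apply(ps, 1, function(p) {
      x_obs <- -2 * sum(log(pmax(p[!is.na(p)], 1e-300)))
      (1 + n_sim - findInterval(x_obs, null_x, left.open = TRUE)) / (n_sim + 1)
    })
  } else {
    p_int <- apply(ps, 1, function(p) integrate_pvalues(p[!is.na(p)]))
  }
  fdr <- p.adjust(p_int, method = "BH")
  crit <- if (config$use_raw_p) p_int else fdr
  out <- data.frame(gene = genes,
                    p_cosinor = rows[, "p_cosinor"],
                    p_jtk = rows[, "p_jtk"],
                    p_ls = rows[, "p_ls"],
                    p_integrated = p_int,
                    fdr = fdr,
                    period_est = rows[, "period_est"],
                    phase_est = rows[, "phase_est"],
                    amplitude_est = rows[, "amplitude_est"],
                    rhythmic = crit <= config$fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("rhythmicity_table", "data.frame")
  attr(out, "config") <- config
  out
}

#' Write a rhythmicity table as TSV
#' @param table a `rhythmicity_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rhythm_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: gene, p_cosinor, p_jtk, p_ls, p_integrated, fdr, period_est, phase_est, amplitude_est, rhythmic", con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Differential rhythmicity across conditions
#'
#' A gene is differentially rhythmic when it is called rhythmic in one
#' condition and not in another. Given named rhythmicity tables on
#' overlapping gene universes, reports per-gene condition membership and all
#' Venn-style region counts.
#'
#' @param tables named list of `rhythmicity_table`s (2 or more)
#' @return list with `membership` (data.frame gene x condition logical),
#'   `regions` (Venn region counts, from [set_overlap_stats()]), and
#'   `exclusive` (named list of genes rhythmic in exactly one condition)
#' @export
differential_rhythmicity <- function(tables) {
  stop_if_not(is.list(tables) && length(tables) >= 2,
              "need at least two rhythmicity tables")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("cond", seq_along(tables))
  universes <- lapply(tables, function(t) t$gene)
  shared <- Reduce(intersect, universes)
  stop_if_not(length(shared) > 0, "gene universes are disjoint")
  sets <- lapply(tables, function(t) t$gene[t$rhythmic])
  universe <- Reduce(union, universes)
  membership <- data.frame(gene = universe, stringsAsFactors = FALSE)
  for (nm in names(sets)) membership[[nm]] <- membership$gene %in% sets[[nm]]
  regions <- set_overlap_stats(sets, universe)
  counts <- rowSums(membership[, -1, drop = FALSE])
  exclusive <- lapply(names(sets), function(nm) {
    membership$gene[membership[[nm]] & counts == 1]
  })
  names(exclusive) <- names(sets)
  list(membership = membership, regions = regions, exclusive = exclusive)
}
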