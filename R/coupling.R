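#' Pairwise gene-gene correlation between two gene sets
#'
#' Pearson correlation across the shared axis (time points after replicate
#' averaging for a [temporal_matrix()], or columns of a plain matrix — e.g.
#' samples of a tumor cohort) for every pair in `set_a x set_b`. Typical use
#' correlates candidate driver genes against the 15-gene core clock panel.
#' Zero-variance series yield `NA` cells, which downstream summaries skip.
#'
#' @param x a [temporal_matrix()] or a genes x samples matrix
#' @param set_a row gene ids (candidates)
#' @param set_b column gene ids (clock panel)
#' @param log2_mode correlate on `log2(x + 1)` instead of the natural scale
#' @return a `coupling_matrix`: list with `r` (|set_a| x |set_b| signed
#'   Pearson r), `r2`, and `n` (shared observations per cell)
#' @export
gene_gene_correlation <- function(x, set_a, set_b, log2_mode = FALSE) {
  m <- if (inherits(x, "temporal_matrix")) replicate_mean(x)$values else as.matrix(x)
  stop_if_not(ncol(m) >= 3, "need at least 3 shared observations")
  miss <- setdiff(c(set_a, set_b), rownames(m))
  stop_if_not(length(miss) == 0, "gene(s) absent from matrix: %s",
              paste(head(miss, 5), collapse = ", "))
  if (log2_mode) m <- log2(m + 1)
  A <- m[set_a, , drop = FALSE]
  B <- m[set_b, , drop = FALSE]
  r <- suppressWarnings(cor(t(A), t(B)))  # NA where a series has zero variance
  dimnames(r) <- list(set_a, set_b)
  structure(list(r = r, r2 = r^2,
                 n = matrix(ncol(m), nrow(r), ncol(r), dimnames = dimnames(r))),
            class = "coupling_matrix")
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat(sprintf("coupling_matrix: %d candidates x %d clock genes (n = %d)\n",
              nrow(x$r), ncol(x$r), x$n[1, 1]))
  invisible(x)
}

#' Summarize clock-gene coupling per candidate
#'
#' Applies the two R-squared tiers: a coupling is *significant* at
#' `r2 >= r2_sig` (inclusive) and *strong* at the `r2_strong` tier, where
#' both the inclusive (`>=`) and strict (`>`) conventions are reported.
#' Candidates are tiered `none` / `significant` / `strong-positive` /
#' `strong-negative` by their strongest partner.
#'
#' @param coupling a `coupling_matrix`
#' @param r2_sig significant-coupling threshold (default 0.3, inclusive)
#' @param r2_strong strong-coupling threshold (default 0.6)
#' @return list with `per_candidate` (gene, n_clock_sig, n_clock_strong,
#'   max_abs_r, max_r2, strongest_partner, tier), `per_clock` (clock gene,
#'   n_candidates_sig, n_candidates_strong), and `global` (counts of pairs:
#'   n_sig, n_strong_ge, n_strong_gt, n_strong_pos, n_strong_neg,
#'   frac_candidates_sig, frac_candidates_multi)
#' @export
coupling_summary <- function(coupling, r2_sig = 0.3, r2_strong = 0.6) {
  stopifnot(inherits(coupling, "coupling_matrix"))
  r <- coupling$r; r2 <- coupling$r2
  sig <- !is.na(r2) & r2 >= r2_sig
  strong_ge <- !is.na(r2) & r2 >= r2_strong
  strong_gt <- !is.na(r2) & r2 > r2_strong
  per_candidate <- data.frame(
    gene = rownames(r),
    n_clock_sig = rowSums(sig),
    n_clock_strong = rowSums(strong_ge),
    max_abs_r = apply(abs(r), 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)),
    max_r2 = apply(r2, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)),
    strongest_partner = colnames(r)[apply(r2, 1, function(v) {
      if (all(is.na(v))) NA_integer_ else which.max(v)
    })],
    stringsAsFactors = FALSE, row.names = NULL)
  best_r <- r[cbind(seq_len(nrow(r)),
                    match(per_candidate$strongest_partner, colnames(r)))]
  per_candidate$tier <- ifelse(
    is.na(per_candidate$max_r2) | per_candidate$max_r2 < r2_sig, "none",
    ifelse(per_candidate$max_r2 < r2_strong, "significant",
           ifelse(best_r >= 0, "strong-positive", "strong-negative")))
  per_clock <- data.frame(
    clock_gene = colnames(r),
    n_candidates_sig = colSums(sig),
    n_candidates_strong = colSums(strong_ge),
    stringsAsFactors = FALSE, row.names = NULL)
  global <- list(
    n_sig = sum(sig),
    n_strong_ge = sum(strong_ge),
    n_strong_gt = sum(strong_gt),
    n_strong_pos = sum(strong_gt & r > 0, na.rm = TRUE),
    n_strong_neg = sum(strong_gt & r < 0, na.rm = TRUE),
    frac_candidates_sig = mean(rowSums(sig) >= 1),
    frac_candidates_multi = mean(rowSums(sig) >= 2))
  list(per_candidate = per_candidate, per_clock = per_clock, global = global)
}

#' Concordance trend between two coupling profiles
#'
#' For each candidate present in both coupling matrices, regresses its
#' clock-gene coupling vector in cohort B on the one in cohort A: ordinary
#' least-squares slope, Pearson r, and the two-tailed t-test p-value on r.
#' Candidates missing in one cohort are skipped with a message.
#'
#' @param coupling_a,coupling_b `coupling_matrix` objects with identical
#'   clock-gene columns
#' @return data.frame with gene, slope, r, r2, p, n
#' @export
concordance_trend <- function(coupling_a, coupling_b) {
  stopifnot(inherits(coupling_a, "coupling_matrix"),
            inherits(coupling_b, "coupling_matrix"))
  stop_if_not(identical(colnames(coupling_a$r), colnames(coupling_b$r)),
              "clock-gene columns differ between cohorts")
  shared <- intersect(rownames(coupling_a$r), rownames(coupling_b$r))
  skipped <- setdiff(union(rownames(coupling_a$r), rownames(coupling_b$r)),
                     shared)
  if (length(skipped))
    message(sprintf("concordance_trend: %d candidate(s) missing in one cohort, skipped",
                    length(skipped)))
  stop_if_not(length(shared) > 0, "no candidate present in both cohorts")
  rows <- lapply(shared, function(g) {
    a <- coupling_a$r[g, ]; b <- coupling_b$r[g, ]
    ok <- complete.cases(a, b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 3 || var(a) == 0 || var(b) == 0)
      return(data.frame(gene = g, slope = NA_real_, r = NA_real_,
                        r2 = NA_real_, p = NA_real_, n = length(a)))
    ct <- cor.test(a, b)
    data.frame(gene = g, slope = unname(coef(lm(b ~ a))[2]),
               r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
               p = ct$p.value, n = length(a))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the strong-coupling bipartite network
#'
#' Edge list of (candidate, clock gene) pairs with `r2` strictly above
#' `r2_min` (default 0.6), annotated with the correlation sign.
#'
#' @param coupling a `coupling_matrix`
#' @param r2_min strict R-squared threshold
#' @return data.frame with candidate, clock_gene, r, r2, sign
#' @export
build_coupling_network <- function(coupling, r2_min = 0.6) {
  stopifnot(inherits(coupling, "coupling_matrix"))
  idx <- which(!is.na(coupling$r2) & coupling$r2 > r2_min, arr.ind = TRUE)
  out <- data.frame(candidate = rownames(coupling$r)[idx[, 1]],
                    clock_gene = colnames(coupling$r)[idx[, 2]],
                    r = coupling$r[idx], r2 = coupling$r2[idx],
                    sign = ifelse(coupling$r[idx] >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  out[order(-out$r2), , drop = FALSE]
}

#' Write a coupling matrix as long-format TSV
#' @param coupling a `coupling_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_coupling_tsv <- function(coupling, path) {
  stopifnot(inherits(coupling, "coupling_matrix"))
  long <- expand.grid(candidate = rownames(coupling$r),
                      clock_gene = colnames(coupling$r),
                      stringsAsFactors = FALSE)
  long$r <- coupling$r[cbind(long$candidate, long$clock_gene)]
  long$r2 <- long$r^2
  long$n <- coupling$n[1, 1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: candidate, clock_gene, r, r2, n", con)
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
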