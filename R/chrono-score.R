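#' Cumulative rhythmicity score of a gene set
#'
#' Each gene's replicate-mean temporal series is normalized to its own
#' maximum (so every gene peaks at 1), then the normalized series are
#' averaged across the set per time point. The score lies in (0, 1] and
#' reaches 1 at a time point only when every member peaks there. Genes with
#' an all-zero series are dropped with a warning.
#'
#' @param x a [temporal_matrix()]
#' @param gene_set non-empty character vector of member genes
#' @return list with `time`, `score`, and `n_genes` used
#' @export
rhythmicity_score <- function(x, gene_set) {
  stopifnot(inherits(x, "temporal_matrix"))
  stop_if_not(length(gene_set) > 0, "gene set is empty")
  miss <- setdiff(gene_set, rownames(x$values))
  stop_if_not(length(miss) == 0, "gene(s) absent from matrix: %s",
              paste(head(miss, 5), collapse = ", "))
  rm <- replicate_mean(x)
  m <- rm$values[gene_set, , drop = FALSE]
  mx <- apply(m, 1, max)
  if (any(mx == 0)) {
    warn_f("%d gene(s) with zero maximum dropped from rhythmicity score",
           sum(mx == 0))
    m <- m[mx > 0, , drop = FALSE]
    mx <- mx[mx > 0]
  }
  stop_if_not(nrow(m) > 0, "no usable genes for the rhythmicity score")
  norm <- m / mx
  list(time = rm$time, score = colMeans(norm), n_genes = nrow(m))
}

#' Correlate temporal drug efficacy with expression
#'
#' Pearson correlation between a per-time viability AUC series and a
#' rhythmicity score (or single-gene expression) series over their shared
#' time points. Reports signed r, R-squared and the two-tailed p-value.
#' Constant series are flagged undefined.
#'
#' @param time time points of `expression`
#' @param expression score or expression values at `time`
#' @param auc_time time points of `auc`
#' @param auc viability AUC values at `auc_time`
#' @return list with `r`, `r2`, `p`, `n`, `defined`
#' @export
efficacy_expression_correlation <- function(time, expression, auc_time, auc) {
  shared <- intersect(time, auc_time)
  stop_if_not(length(shared) >= 4, "need at least 4 shared time points")
  a <- expression[match(shared, time)]
  b <- auc[match(shared, auc_time)]
  if (var(a) == 0 || var(b) == 0) {
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_,
                n = length(shared), defined = FALSE))
  }
  ct <- cor.test(a, b)
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(shared), defined = TRUE)
}

#' Prioritize chronotherapy targets
#'
#' The target-ranking pipeline: (1) intersect rhythmic genes with the
#' cancer-driver list to form the rhythmic-driver (r-CDG) set; (2) shortlist
#' the `top_k` of them by maximal clique centrality (deterministic
#' tie-breaks: degree, then id); (3) order the shortlist by the strength of
#' clock coupling, `max |r|` over the clock panel, descending; (4) annotate
#' each target with the drugs that act on it. All intermediate scores are
#' retained in the output.
#'
#' @param rhythm_table a `rhythmicity_table` from [detect_rhythmic()]
#' @param cdg_list character vector of cancer driver gene ids
#' @param centrality_table a `centrality_table` covering the candidates
#' @param coupling a `coupling_matrix` with candidates in rows
#' @param drug_table optional data.frame with columns `gene`, `drug` (extra
#'   columns such as drug_class and source are carried through)
#' @param top_k shortlist size (default 17)
#' @return data.frame ranked best-first: rank, gene, mcc, mcc_rank,
#'   max_abs_r, strongest_partner, n_clock_sig, tier, drugs
#' @export
prioritize_targets <- function(rhythm_table, cdg_list, centrality_table,
                               coupling, drug_table = NULL, top_k = 17) {
  stopifnot(inherits(rhythm_table, "rhythmicity_table"),
            inherits(centrality_table, "centrality_table"),
            inherits(coupling, "coupling_matrix"))
  rcdg <- intersect(rhythm_table$gene[rhythm_table$rhythmic], cdg_list)
  if (!length(rcdg)) {
    warn_f("no rhythmic cancer driver genes; empty target table")
    return(data.frame(rank = integer(0), gene = character(0),
                      mcc = numeric(0), mcc_rank = integer(0),
                      max_abs_r = numeric(0),
                      strongest_partner = character(0),
                      n_clock_sig = integer(0), tier = character(0),
                      drugs = character(0)))
  }
  in_net <- intersect(rcdg, centrality_table$node)
  dropped <- setdiff(rcdg, in_net)
  if (length(dropped))
    warn_f("%d r-CDG(s) absent from the network, dropped from shortlist",
           length(dropped))
  ranked <- rank_by_mcc(centrality_table, in_net)
  shortlist <- head(ranked, top_k)
  cs <- coupling_summary(coupling)$per_candidate
  idx <- match(shortlist$node, cs$gene)
  out <- data.frame(gene = shortlist$node,
                    mcc = shortlist$mcc,
                    mcc_rank = shortlist$rank,
                    max_abs_r = cs$max_abs_r[idx],
                    strongest_partner = cs$strongest_partner[idx],
                    n_clock_sig = cs$n_clock_sig[idx],
                    tier = cs$tier[idx],
                    stringsAsFactors = FALSE)
  out$max_abs_r[is.na(out$max_abs_r)] <- 0
  out <- out[order(-out$max_abs_r, out$mcc_rank, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(drug_table)) {
    stop_if_not(all(c("gene", "drug") %in% names(drug_table)),
                "drug_table needs columns gene, drug")
    out$drugs <- vapply(out$gene, function(g) {
      paste(sort(unique(drug_table$drug[drug_table$gene == g])),
            collapse = ";")
    }, "")
  } else {
    out$drugs <- ""
  }
  rownames(out) <- NULL
  out[, c("rank", setdiff(names(out), "rank"))]
}
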