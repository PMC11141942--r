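#' Consensus hub calling from a centrality table
#'
#' A node is a hub when it sits in the top `top_frac` of at least
#' `min_params` of the twelve topology parameters. For eleven parameters
#' larger means more central; eccentricity is inverted before quantiling
#' (smaller = more central). The top set for each parameter is every node
#' whose score is at least as extreme as the `ceiling(top_frac * n)`-th most
#' extreme value, so ties at the cutoff are included (tied maximal nodes are
#' never dropped).
#'
#' @param table a `centrality_table` from [compute_centralities()]
#' @param top_frac top fraction per parameter (default 0.05)
#' @param min_params minimum number of parameters in whose top fraction a
#'   hub must appear (default 9 of 12)
#' @return `table` with columns `n_top_params` and `hub_consensus` appended
#' @export
identify_hubs <- function(table, top_frac = 0.05, min_params = 9) {
  stopifnot(inherits(table, "centrality_table"))
  stop_if_not(top_frac > 0 && top_frac < 1, "top_frac must be in (0, 1)")
  stop_if_not(min_params >= 1 && min_params <= 12,
              "min_params must be in [1, 12]")
  n <- nrow(table)
  if (n < ceiling(1 / top_frac))
    warn_f("only %d nodes: the top-%.0f%% cutoff is degenerate", n,
           100 * top_frac)
  params <- c("degree", "betweenness", "stress", "closeness", "eccentricity",
              "radiality", "clustering_coefficient", "mnc", "dmnc", "mcc",
              "bottleneck", "epc")
  k <- max(1L, ceiling(top_frac * n))
  in_top <- vapply(params, function(pm) {
    x <- table[[pm]]
    if (pm == "eccentricity") x <- -x
    thr <- sort(x, decreasing = TRUE)[k]
    x >= thr
  }, logical(n))
  if (n == 1) in_top <- matrix(in_top, nrow = 1, dimnames = list(NULL, params))
  table$n_top_params <- rowSums(in_top)
  table$hub_consensus <- table$n_top_params >= min_params
  table
}

#' Degree-threshold hub flag
#'
#' Flags nodes whose degree strictly exceeds `min_degree` (default 30),
#' the simple connectivity definition of a hub protein.
#'
#' @param table a `centrality_table`
#' @param min_degree strict lower bound on degree (default 30)
#' @return `table` with logical column `hub_degree` appended
#' @export
degree_hub_flag <- function(table, min_degree = 30) {
  stopifnot(inherits(table, "centrality_table"))
  table$hub_degree <- table$degree > min_degree
  table
}

#' Neighborhood subgraph around seed genes
#'
#' Induced subgraph on the seed genes plus every node within `order` hops
#' of a seed. Seeds missing from the graph are dropped with a warning.
#'
#' @param graph an [igraph::graph] with named vertices
#' @param seed_genes character vector of seed node ids (non-empty)
#' @param order hop distance (0 = seeds only, 1 = first-degree neighbors)
#' @return the induced [igraph::graph]
#' @export
neighborhood_subgraph <- function(graph, seed_genes, order = 1) {
  stop_if_not(length(seed_genes) > 0, "seed gene set is empty")
  present <- intersect(seed_genes, igraph::V(graph)$name)
  missing <- setdiff(seed_genes, present)
  if (length(missing))
    warn_f("%d seed gene(s) not in network, dropped: %s", length(missing),
           paste(head(missing, 5), collapse = ", "))
  stop_if_not(length(present) > 0, "no seed gene is present in the network")
  nb <- igraph::ego(graph, order = order, nodes = present)
  keep <- unique(unlist(lapply(nb, names)))
  igraph::induced_subgraph(graph, keep)
}

#' Rank candidate genes by maximal clique centrality
#'
#' Descending MCC; ties broken by degree (descending), then lexicographic
#' node id, so the ranking is a deterministic function of the table alone.
#'
#' @param table a `centrality_table`
#' @param candidate_genes candidates to rank (must appear in `table`)
#' @return data.frame with node, mcc, degree and rank, best first
#' @export
rank_by_mcc <- function(table, candidate_genes) {
  stopifnot(inherits(table, "centrality_table"))
  missing <- setdiff(candidate_genes, table$node)
  stop_if_not(length(missing) == 0, "candidate(s) not in table: %s",
              paste(head(missing, 5), collapse = ", "))
  sub <- table[table$node %in% candidate_genes,
               c("node", "mcc", "degree"), drop = FALSE]
  sub <- sub[order(-sub$mcc, -sub$degree, sub$node), , drop = FALSE]
  sub$rank <- seq_len(nrow(sub))
  rownames(sub) <- NULL
  sub
}

#' Write a centrality table as TSV
#' @param table a `centrality_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_centrality_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(names(table), collapse = ", ")), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
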