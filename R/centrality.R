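# Twelve topology parameters on an undirected simple graph, computed from
# first principles (BFS distance/path-count matrices, maximal-clique
# enumeration, Monte-Carlo edge percolation). igraph supplies the graph
# container and clique enumeration; shortest-path statistics are computed
# here so that path counts, tie-broken trees and per-component conventions
# are explicit and testable against independent oracles.

# BFS from every source: distance matrix D (Inf if unreachable) and
# shortest-path count matrix S.
apsp_counts <- function(adj, n) {
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); cnt <- rep(0, n)
    dist[s] <- 0; cnt[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (w in frontier) {
        for (u in adj[[w]]) {
          if (is.infinite(dist[u])) {
            dist[u] <- dist[w] + 1
            nxt <- c(nxt, u)
            cnt[u] <- cnt[u] + cnt[w]
          } else if (dist[u] == dist[w] + 1) {
            cnt[u] <- cnt[u] + cnt[w]
          }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
    S[s, ] <- cnt
  }
  list(D = D, S = S)
}

# BFS shortest-path tree from s with deterministic parent tie-breaking
# (lowest node index among equally near predecessors); returns subtree sizes.
bfs_tree_subtree_sizes <- function(adj, n, s, D) {
  parent <- rep(NA_integer_, n)
  reach <- which(is.finite(D[s, ]))
  for (w in setdiff(reach, s)) {
    preds <- adj[[w]][D[s, adj[[w]]] == D[s, w] - 1]
    parent[w] <- min(preds)
  }
  size <- rep(1L, n)
  ord <- reach[order(D[s, reach], decreasing = TRUE)]
  for (w in ord) {
    if (!is.na(parent[w])) size[parent[w]] <- size[parent[w]] + size[w]
  }
  list(size = size, reach = reach)
}

#' Compute twelve network topology parameters per node
#'
#' Scores every node of an undirected simple graph with the twelve
#' centrality parameters used for consensus hub calling: degree, betweenness,
#' stress, closeness, eccentricity, radiality, clustering coefficient, MNC,
#' DMNC, MCC, bottleneck and EPC.
#'
#' Definitions: betweenness sums the fraction of shortest s-t paths through
#' the node; stress sums their raw count; closeness is
#' `(|C|-1) / sum of distances` within the node's component; eccentricity is
#' the largest within-component distance (smaller = more central);
#' radiality is the mean over other component members of
#' `(component diameter + 1 - d(v, u))`; the clustering coefficient is
#' `2 * triangles / (deg * (deg - 1))`; MNC is the size of the largest
#' connected component of the subgraph induced on the node's neighbors and
#' DMNC divides that component's edge count by its node count raised to 1.7;
#' MCC sums `(|C| - 1)!` over the maximal cliques containing the node (for
#' an edgeless neighborhood this equals the degree); bottleneck counts
#' single-source BFS shortest-path trees (lowest-index parent tie-break) in
#' which the node's subtree holds more than a quarter of the tree's nodes;
#' EPC is the Monte-Carlo mean size of the node's connected component when
#' each edge is kept independently with probability `epc_keep_prob`.
#' Disconnected graphs are handled per component for the path-based scores.
#'
#' @param graph an undirected [igraph::graph] (simplified internally)
#' @param epc_trials Monte-Carlo trials for EPC (default 1000)
#' @param epc_keep_prob edge retention probability for EPC (default 0.5)
#' @param seed seed for the EPC stream
#' @return a `data.frame` (class `centrality_table`) with one row per node:
#'   node, degree, betweenness, stress, closeness, eccentricity, radiality,
#'   clustering_coefficient, mnc, dmnc, mcc, bottleneck, epc, mcc_rank
#' @export
compute_centralities <- function(graph, epc_trials = 1000,
                                 epc_keep_prob = 0.5, seed = 1L) {
  stop_if_not(igraph::vcount(graph) > 0, "graph is empty")
  g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)

  ap <- apsp_counts(adj, n)
  D <- ap$D; S <- ap$S
  comp <- igraph::components(g)
  memb <- comp$membership
  csize <- comp$csize[memb]
  cdiam <- vapply(seq_len(comp$no), function(k) {
    idx <- which(memb == k)
    if (length(idx) == 1) 0 else max(D[idx, idx])
  }, numeric(1))

  degree <- vapply(adj, length, 1L)
  clustering <- igraph::transitivity(g, type = "local", isolates = "zero")

  eccentricity <- vapply(seq_len(n), function(v) {
    d <- D[v, memb == memb[v]]
    if (length(d) <= 1) 0 else max(d)
  }, numeric(1))
  closeness <- vapply(seq_len(n), function(v) {
    idx <- which(memb == memb[v])
    if (length(idx) <= 1) return(0)
    (length(idx) - 1) / sum(D[v, idx])
  }, numeric(1))
  radiality <- vapply(seq_len(n), function(v) {
    idx <- setdiff(which(memb == memb[v]), v)
    if (!length(idx)) return(0)
    mean(cdiam[memb[v]] + 1 - D[v, idx])
  }, numeric(1))

  betweenness <- numeric(n); stress <- numeric(n)
  for (v in seq_len(n)) {
    idx <- setdiff(which(memb == memb[v]), v)
    if (length(idx) < 2) next
    on_path <- outer(D[idx, v], D[v, idx], "+") == D[idx, idx]
    pairs <- upper.tri(on_path) & on_path
    if (!any(pairs)) next
    count_through <- outer(S[idx, v], S[v, idx])
    betweenness[v] <- sum((count_through / S[idx, idx])[pairs])
    stress[v] <- sum(count_through[pairs])
  }

  mnc <- numeric(n); dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) == 0) next
    sub <- igraph::induced_subgraph(g, nb)
    cc <- igraph::components(sub)
    big <- which.max(cc$csize)
    mnc[v] <- cc$csize[big]
    sub2 <- igraph::induced_subgraph(sub, which(cc$membership == big))
    dmnc[v] <- igraph::ecount(sub2) / cc$csize[big]^1.7
  }

  mcc <- numeric(n)
  for (cl in igraph::max_cliques(g, min = 2)) {   # isolated nodes score 0
    idx <- as.integer(cl)
    mcc[idx] <- mcc[idx] + factorial(length(idx) - 1)
  }

  bottleneck <- numeric(n)
  for (s in seq_len(n)) {
    tr <- bfs_tree_subtree_sizes(adj, n, s, D)
    thr <- length(tr$reach) / 4
    hit <- tr$reach[tr$size[tr$reach] > thr]
    bottleneck[hit] <- bottleneck[hit] + 1
  }

  el <- igraph::as_edgelist(g, names = FALSE)
  epc <- with_seed(substream_seed(seed, "epc"), {
    acc <- numeric(n)
    m <- nrow(el)
    for (tr in seq_len(epc_trials)) {
      keep <- stats::runif(m) < epc_keep_prob
      sg <- igraph::graph_from_edgelist(el[keep, , drop = FALSE],
                                        directed = FALSE)
      sg <- igraph::add_vertices(sg, max(0, n - igraph::vcount(sg)))
      cc <- igraph::components(sg)
      acc <- acc + cc$csize[cc$membership[seq_len(n)]]
    }
    acc / epc_trials
  })

  out <- data.frame(node = ids, degree = as.numeric(degree),
                    betweenness = betweenness, stress = stress,
                    closeness = closeness, eccentricity = eccentricity,
                    radiality = radiality,
                    clustering_coefficient = clustering,
                    mnc = mnc, dmnc = dmnc, mcc = mcc,
                    bottleneck = bottleneck, epc = epc,
                    stringsAsFactors = FALSE)
  out$mcc_rank <- rank_order(out$mcc, out$degree, out$node)
  class(out) <- c("centrality_table", "data.frame")
  attr(out, "n_components") <- comp$no
  out
}

# Deterministic descending rank: primary score desc, then degree desc, then
# lexicographic id.
rank_order <- function(score, degree, id) {
  ord <- order(-score, -degree, id)
  r <- integer(length(score))
  r[ord] <- seq_along(score)
  r
}
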