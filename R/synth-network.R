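#' Generate a protein-interaction network with planted hubs
#'
#' Builds a sparse Erdos-Renyi background graph, then plants `n_planted_hubs`
#' hub nodes: each hub is embedded in its own clique (sizes from
#' `clique_sizes`, recycled) drawn from otherwise low-degree nodes, and
#' receives extra spoke edges until its degree strictly exceeds the maximum
#' background degree. The result emulates the topology of a curated
#' protein-protein interaction network in which a few central genes sit in
#' dense complexes.
#'
#' @param n_nodes total node count (ids `N001`, `N002`, ...)
#' @param n_planted_hubs number of hub nodes to plant (may be 0)
#' @param clique_sizes integer vector of planted clique sizes (each >= 3)
#' @param p_background background edge probability (default 2/n_nodes,
#'   mean degree ~2)
#' @param hub_spoke_frac fraction of the network each planted hub is wired
#'   to (default 0.3)
#' @param seed integer seed
#' @return list with `graph` (an [igraph::graph] with vertex name attribute)
#'   and `planted_hubs` (character vector of hub ids; empty when none)
#' @export
generate_ppi_network <- function(n_nodes, n_planted_hubs = 1,
                                 clique_sizes = 6,
                                 p_background = NULL,
                                 hub_spoke_frac = 0.3, seed = 1L) {
  stop_if_not(is_count(n_nodes) && n_nodes >= 3, "n_nodes must be >= 3")
  stop_if_not(is_count(n_planted_hubs) && n_planted_hubs <= n_nodes,
              "n_planted_hubs must be <= n_nodes")
  stop_if_not(all(clique_sizes >= 3), "clique sizes must be >= 3")
  stop_if_not(all(clique_sizes <= n_nodes), "clique size exceeds n_nodes")
  if (is.null(p_background)) p_background <- min(1, 2 / n_nodes)

  with_seed(substream_seed(seed, "ppi"), {
    ids <- sprintf("N%03d", seq_len(n_nodes))
    g <- igraph::sample_gnp(n_nodes, p_background, directed = FALSE)
    igraph::V(g)$name <- ids
    hubs <- character(0)
    if (n_planted_hubs > 0) {
      sizes <- rep_len(clique_sizes, n_planted_hubs)
      # reserve distinct members for each clique, hubs first
      pool <- sample(ids)
      hubs <- pool[seq_len(n_planted_hubs)]
      used <- n_planted_hubs
      for (h in seq_len(n_planted_hubs)) {
        k <- sizes[h] - 1L
        stop_if_not(used + k <= n_nodes,
                    "not enough nodes for the requested planted cliques")
        members <- c(hubs[h], pool[used + seq_len(k)])
        used <- used + k
        pairs <- combn(members, 2)
        g <- igraph::add_edges(g, as.vector(pairs))
      }
      g <- igraph::simplify(g)
      # wire each hub to a fixed fraction of the network (and past any
      # background degree) so planted hubs are unambiguous topological
      # centers: maximal degree, short paths to most of the graph
      deg <- igraph::degree(g)
      for (h in hubs) {
        target <- max(max(deg[setdiff(ids, hubs)]) + 2L,
                      ceiling(hub_spoke_frac * n_nodes))
        while (igraph::degree(g, h) < target) {
          cand <- setdiff(ids, c(h, names(igraph::neighbors(g, h))))
          if (!length(cand)) break
          g <- igraph::add_edges(g, c(h, sample(cand, 1)))
        }
        deg <- igraph::degree(g)
      }
    }
    g <- igraph::simplify(g)
    # connect stray components so path-based centralities are comparable
    # across the whole graph (the analysed giant component of a PPI
    # network); strays attach to the best-connected node, which keeps the
    # planted hubs at the topological center
    comp <- igraph::components(g)
    if (comp$no > 1) {
      giant <- which.max(comp$csize)
      anchor_pool <- which(comp$membership == giant)
      anchor <- anchor_pool[which.max(igraph::degree(g)[anchor_pool])]
      reps <- vapply(setdiff(seq_len(comp$no), giant), function(k) {
        min(which(comp$membership == k))
      }, integer(1))
      g <- igraph::add_edges(g, as.vector(rbind(ids[anchor], ids[reps])))
    }
    list(graph = g, planted_hubs = hubs)
  })
}

#' Read a gene network from an edge-list TSV
#'
#' Two id columns plus an optional confidence column in \[0, 1\]. Self-loops
#' and duplicate edges are collapsed; an optional confidence threshold keeps
#' only edges at or above the cutoff.
#'
#' @param path tab-separated edge list (no header, or header starting with `#`)
#' @param min_confidence optional confidence cutoff applied at load
#' @return an undirected simple [igraph::graph]
#' @export
read_edge_list <- function(path, min_confidence = NULL) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  stop_if_not(ncol(df) >= 2, "edge list needs at least two columns")
  if (!is.null(min_confidence) && ncol(df) >= 3) {
    df <- df[df[[3]] >= min_confidence, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' Write a gene network as an edge-list TSV
#' @param graph an igraph graph
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: node_a, node_b", con)
  write.table(el, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a gene network as GraphML
#' @param graph an igraph graph
#' @param path output path
#' @return `path`, invisibly
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
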