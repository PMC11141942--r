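# Independent oracles used across the suite. Everything here is written
# from first principles (enumeration, brute force, textbook formulas) and
# deliberately avoids the package's own code paths.

# all permutations of the elements of v, one per row
all_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- all_perms(v[-i])
    out[[i]] <- cbind(v[i], sub)
  }
  do.call(rbind, out)
}

# Kendall's S by direct double loop
oracle_kendall_s <- function(y, ref) {
  s <- 0
  n <- length(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(y[i] - y[j]) * sign(ref[i] - ref[j])
  }
  s
}

# Kendall's S for every row of an arrangement matrix against one reference
oracle_s_all <- function(pm, ref) {
  n <- ncol(pm)
  s <- numeric(nrow(pm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rs <- sign(ref[i] - ref[j])
    if (rs != 0) s <- s + rs * sign(pm[, i] - pm[, j])
  }
  s
}

# Exact two-sided tail of |S| by enumerating every arrangement of y
oracle_kendall_tail <- function(y, ref) {
  pm <- all_perms(y)
  s_obs <- oracle_kendall_s(y, ref)
  mean(abs(oracle_s_all(pm, ref)) >= abs(s_obs))
}

# Joint grid oracle: exact null of the minimal per-reference tail over a
# list of references, enumerated over every arrangement of y
oracle_jtk_grid_p <- function(y, refs) {
  pm <- all_perms(y)
  tails <- matrix(0, nrow(pm), nrow(refs))
  obs <- numeric(nrow(refs))
  for (j in seq_len(nrow(refs))) {
    a <- abs(oracle_s_all(pm, refs[j, ]))
    tails[, j] <- vapply(a, function(ai) mean(a >= ai), numeric(1))
    obs[j] <- mean(a >= abs(oracle_kendall_s(y, refs[j, ])))
  }
  min_tail <- apply(tails, 1, min)
  mean(min_tail <= min(obs) + 1e-12)
}

# Brute-force Benjamini-Hochberg adjusted p-values
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, m * p[ord[k]] / k)
    adj[ord[k]] <- val
    prev <- val
  }
  adj
}

# adjacency matrix of a small igraph
adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

# brute-force maximal cliques by subset enumeration (n <= 15)
oracle_max_cliques <- function(A) {
  n <- nrow(A)
  stopifnot(n <= 15)
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  is_clique <- vapply(subsets, function(s) {
    if (length(s) == 1) return(TRUE)
    all(A[s, s][upper.tri(diag(length(s)))] == 1)
  }, logical(1))
  cliques <- subsets[is_clique]
  keep <- vapply(seq_along(cliques), function(i) {
    s <- cliques[[i]]
    outside <- setdiff(seq_len(n), s)
    !any(vapply(outside, function(v) all(A[v, s] == 1), logical(1)))
  }, logical(1))
  cliques[keep]
}

oracle_mcc <- function(A) {
  cl <- oracle_max_cliques(A)
  mcc <- numeric(nrow(A))
  for (s in cl) {
    if (length(s) < 2) next  # isolated vertices: no clique with an edge
    mcc[s] <- mcc[s] + factorial(length(s) - 1)
  }
  mcc
}

# all shortest paths between every ordered pair by DFS enumeration of
# simple paths (small graphs only)
oracle_all_shortest_paths <- function(A) {
  n <- nrow(A)
  paths <- vector("list", n * n)
  dim(paths) <- c(n, n)
  enum <- function(cur, target, visited) {
    last <- cur[length(cur)]
    if (last == target) return(list(cur))
    out <- list()
    for (w in which(A[last, ] == 1)) {
      if (!visited[w]) {
        visited[w] <- TRUE
        out <- c(out, enum(c(cur, w), target, visited))
        visited[w] <- FALSE
      }
    }
    out
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    visited <- rep(FALSE, n); visited[s] <- TRUE
    all_p <- enum(s, t, visited)
    if (!length(all_p)) next
    lens <- vapply(all_p, length, 1L)
    paths[[s, t]] <- all_p[lens == min(lens)]
  }
  paths
}

oracle_betweenness_stress <- function(A) {
  n <- nrow(A)
  paths <- oracle_all_shortest_paths(A)
  bet <- numeric(n); str_ <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    sp <- paths[[s, t]]
    if (is.null(sp)) next
    sigma <- length(sp)
    for (v in setdiff(seq_len(n), c(s, t))) {
      through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      bet[v] <- bet[v] + through / sigma
      str_[v] <- str_[v] + through
    }
  }
  list(betweenness = bet, stress = str_)
}

# deterministic small random graph
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  list(graph = g, A = A)
}

# hand-built centrality table for hub-rule tests
make_cent_table <- function(df) {
  class(df) <- c("centrality_table", "data.frame")
  df
}

cent_params <- c("degree", "betweenness", "stress", "closeness",
                 "eccentricity", "radiality", "clustering_coefficient",
                 "mnc", "dmnc", "mcc", "bottleneck", "epc")
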