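#' Hypergeometric overrepresentation test for one gene set
#'
#' Upper-tail probability `P(X >= k)` of drawing at least the observed
#' overlap `k` between a query of size `n` and a pathway of size `K` from a
#' universe of size `N`, `X ~ Hypergeom(N, K, n)`. Ids outside the universe
#' are dropped with a warning. A depletion (lower-tail) flag is available.
#'
#' @param query character vector of query gene ids
#' @param gene_set character vector of pathway gene ids
#' @param universe character vector of all testable gene ids (non-empty)
#' @param depletion test underrepresentation instead (default FALSE)
#' @return one-row data.frame: k, K, n, N, expected, p
#' @export
hypergeometric_enrichment <- function(query, gene_set, universe,
                                      depletion = FALSE) {
  stop_if_not(length(universe) > 0, "universe is empty")
  universe <- unique(universe)
  drop_q <- setdiff(query, universe)
  drop_s <- setdiff(gene_set, universe)
  if (length(drop_q) || length(drop_s))
    warn_f("%d query and %d set id(s) outside universe dropped",
           length(drop_q), length(drop_s))
  query <- intersect(unique(query), universe)
  gene_set <- intersect(unique(gene_set), universe)
  N <- length(universe); K <- length(gene_set); n <- length(query)
  k <- length(intersect(query, gene_set))
  p <- if (depletion) {
    phyper(k, K, N - K, n, lower.tail = TRUE)
  } else {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  data.frame(k = k, K = K, n = n, N = N,
             expected = n * K / N, p = p)
}

#' Pathway overrepresentation across a gene-set collection
#'
#' Restricts each pathway to the universe, applies the size filter (sets
#' with fewer than `min_size` or more than `max_size` members are excluded;
#' both bounds inclusive for retention), runs the hypergeometric test per
#' surviving set, and BH-adjusts across them.
#'
#' @param query query gene ids
#' @param collection named list of gene-id vectors (e.g. from [read_gmt()])
#' @param universe universe gene ids
#' @param min_size,max_size retained set-size window (defaults 10 and 250)
#' @param depletion passed to [hypergeometric_enrichment()]
#' @return data.frame sorted by p: set, k, K, n, N, expected, p, fdr
#' @export
pathway_enrichment <- function(query, collection, universe,
                               min_size = 10, max_size = 250,
                               depletion = FALSE) {
  stop_if_not(length(collection) > 0, "collection is empty")
  stop_if_not(!is.null(names(collection)) && all(nzchar(names(collection))),
              "collection sets must be named")
  universe <- unique(universe)
  sizes <- vapply(collection, function(s) length(intersect(s, universe)), 1L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    warn_f("no gene set within the size window [%d, %d]", min_size, max_size)
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), expected = numeric(0),
                      p = numeric(0), fdr = numeric(0)))
  }
  query_u <- intersect(unique(query), universe)
  rows <- lapply(names(collection)[keep], function(nm) {
    row <- suppressWarnings(
      hypergeometric_enrichment(query_u, collection[[nm]], universe,
                                depletion = depletion))
    cbind(set = nm, row)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Venn region counts and percentages for 2-6 sets
#'
#' Every Venn region (exclusive membership pattern) is counted, together
#' with all pairwise overlaps; percentages are rounded to one decimal.
#'
#' @param sets named list of 2-6 character vectors
#' @param universe optional universe (defaults to the union)
#' @return list with `regions` (pattern, count, pct of union), `pairwise`
#'   (set_a, set_b, overlap, pct_of_a, pct_of_b), `union_size`
#' @export
set_overlap_stats <- function(sets, universe = NULL) {
  stop_if_not(is.list(sets) && length(sets) >= 2 && length(sets) <= 6,
              "need between 2 and 6 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  all_genes <- Reduce(union, sets)
  if (!is.null(universe)) {
    sets <- lapply(sets, intersect, unique(universe))
    all_genes <- Reduce(union, sets)
  }
  k <- length(sets)
  memb <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1)
  pattern <- apply(memb, 1, function(b) paste(as.integer(b), collapse = ""))
  pats <- vapply(seq_len(2^k - 1), function(i) {
    paste(as.integer(bitwAnd(i, 2^(seq_len(k) - 1)) > 0), collapse = "")
  }, "")
  counts <- vapply(pats, function(p) sum(pattern == p), 1L)
  regions <- data.frame(pattern = pats, count = as.integer(counts),
                        pct = round(100 * counts / max(1, length(all_genes)), 1),
                        stringsAsFactors = FALSE, row.names = NULL)
  attr(regions, "set_order") <- names(sets)
  pw <- combn(names(sets), 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pw)), function(j) {
    a <- pw[1, j]; b <- pw[2, j]
    ov <- length(intersect(sets[[a]], sets[[b]]))
    data.frame(set_a = a, set_b = b, overlap = ov,
               pct_of_a = round(100 * ov / max(1, length(sets[[a]])), 1),
               pct_of_b = round(100 * ov / max(1, length(sets[[b]])), 1),
               stringsAsFactors = FALSE)
  }))
  list(regions = regions, pairwise = pairwise,
       union_size = length(all_genes))
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated format: set name, description, then gene ids.
#'
#' @param path GMT file path
#' @return named list of character vectors, descriptions in attribute
#'   `"description"`
#' @export
read_gmt <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3)
  stop_if_not(length(bad) == 0, "GMT line %s has fewer than 3 fields",
              paste(head(bad, 3), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  stop_if_not(!anyDuplicated(names(sets)), "duplicate set name in %s", path)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output path
#' @param description optional vector of descriptions (recycled)
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, description = "na") {
  stop_if_not(!is.null(names(sets)) && all(nzchar(names(sets))),
              "sets must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
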