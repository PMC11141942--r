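#' Temporal expression matrix
#'
#' Container for a genes x samples grid of non-negative expression values
#' (TPM or normalized counts) sampled over circadian time. Each column is one
#' sample, labelled with its circadian time in hours since synchronization
#' and a replicate index. Replicated designs repeat time labels.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns. All values must be finite and non-negative.
#' @param time numeric vector of circadian times (hours), one per column.
#' @param replicate integer vector of replicate indices, one per column.
#'   Defaults to a single replicate.
#'
#' @return An object of class `temporal_matrix`: a list with elements
#'   `values`, `time`, `replicate`.
#' @export
temporal_matrix <- function(values, time, replicate = rep(1L, ncol(values))) {
  values <- as.matrix(values)
  stop_if_not(!is.null(rownames(values)), "values must have gene ids as rownames")
  stop_if_not(!anyDuplicated(rownames(values)),
              "duplicate gene id: %s",
              paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  stop_if_not(is.numeric(time) && length(time) == ncol(values),
              "time must be numeric with one entry per column")
  stop_if_not(all(is.finite(values)) && all(values >= 0),
              "expression values must be finite and non-negative")
  stop_if_not(length(replicate) == ncol(values),
              "replicate must have one entry per column")
  ord <- order(replicate, time)
  if (is.unsorted(ord)) {
    values <- values[, ord, drop = FALSE]
    time <- time[ord]
    replicate <- replicate[ord]
  }
  for (r in unique(replicate)) {
    tr <- time[replicate == r]
    stop_if_not(!anyDuplicated(tr),
                "duplicate time label within replicate %s", r)
  }
  colnames(values) <- paste0("CT", time, ifelse(max(replicate) > 1,
                                                paste0("_r", replicate), ""))
  structure(list(values = values, time = as.numeric(time),
                 replicate = as.integer(replicate)),
            class = "temporal_matrix")
}

#' @export
print.temporal_matrix <- function(x, ...) {
  cat(sprintf("temporal_matrix: %d genes x %d samples (%d time points, %d replicate%s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$time)),
              max(x$replicate), if (max(x$replicate) > 1) "s" else ""))
  cat("time (h):", paste(unique(x$time), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.temporal_matrix <- function(x) dim(x$values)

#' Subset a temporal matrix by gene id
#' @param x a `temporal_matrix`
#' @param genes character vector of gene ids to keep (order preserved)
#' @return a `temporal_matrix` restricted to `genes`
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "temporal_matrix"))
  missing <- setdiff(genes, rownames(x$values))
  if (length(missing))
    warn_f("%d gene id(s) not in matrix, dropped: %s", length(missing),
           paste(head(missing, 5), collapse = ", "))
  keep <- intersect(genes, rownames(x$values))
  temporal_matrix(x$values[keep, , drop = FALSE], x$time, x$replicate)
}

# Average replicates to a genes x time-points matrix (columns ordered by time).
replicate_mean <- function(x) {
  stopifnot(inherits(x, "temporal_matrix"))
  tp <- sort(unique(x$time))
  out <- vapply(tp, function(t0) {
    rowMeans(x$values[, x$time == t0, drop = FALSE])
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), paste0("CT", tp)))
  list(values = out, time = tp)
}

#' Read a temporal expression matrix from TSV
#'
#' Expects a header row whose first field names the gene-id column and whose
#' remaining fields are time labels, either `CT<hours>` (optionally with a
#' `_r<k>` replicate suffix) or plain numeric hours. Out-of-order time labels
#' are reordered with a warning; duplicate gene ids, ragged rows, negative
#' values and unparseable labels are errors that name the offending line.
#'
#' @param path path to a tab-separated file
#' @return a [temporal_matrix()]
#' @export
read_expression_tsv <- function(path) {
  stop_if_not(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  stop_if_not(length(lines) >= 2, "file %s has no data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_hdr <- length(fields[[1]])
  bad <- which(vapply(fields, length, 1L) != ncol_hdr)
  stop_if_not(length(bad) == 0, "ragged row(s) at line %s in %s",
              paste(head(bad, 3), collapse = ", "), path)
  labels <- fields[[1]][-1]
  parsed <- parse_time_labels(labels)
  ids <- vapply(fields[-1], `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  stop_if_not(length(dup) == 0, "duplicate gene id in %s: %s", path,
              paste(dup, collapse = ", "))
  vals <- t(vapply(fields[-1], function(f) {
    v <- suppressWarnings(as.numeric(f[-1]))
    v
  }, numeric(ncol_hdr - 1L)))
  nas <- which(rowSums(is.na(vals)) > 0)
  stop_if_not(length(nas) == 0, "non-numeric value(s) at data line %s in %s",
              paste(head(nas + 1L, 3), collapse = ", "), path)
  neg <- which(rowSums(vals < 0) > 0)
  stop_if_not(length(neg) == 0, "negative value(s) at data line %s in %s",
              paste(head(neg + 1L, 3), collapse = ", "), path)
  rownames(vals) <- ids
  ord <- order(parsed$replicate, parsed$time)
  if (any(ord != seq_along(ord))) {
    warn_f("time labels out of order in %s; columns reordered", path)
  }
  temporal_matrix(vals, parsed$time, parsed$replicate)
}

parse_time_labels <- function(labels) {
  rep_idx <- rep(1L, length(labels))
  has_rep <- grepl("_r[0-9]+$", labels)
  rep_idx[has_rep] <- as.integer(sub("^.*_r([0-9]+)$", "\\1", labels[has_rep]))
  core <- sub("_r[0-9]+$", "", labels)
  core <- sub("^(CT|ZT)", "", core, ignore.case = TRUE)
  tm <- suppressWarnings(as.numeric(core))
  bad <- labels[is.na(tm)]
  stop_if_not(length(bad) == 0, "unparseable time label(s): %s",
              paste(bad, collapse = ", "))
  list(time = tm, replicate = rep_idx)
}

#' Write a temporal expression matrix as TSV
#'
#' First column is the gene id, remaining columns are labelled `CT<hours>`
#' (with `_r<k>` suffix when replicated). A `#` comment line documents the
#' column schema so files round-trip through [read_expression_tsv()].
#'
#' @param x a [temporal_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "temporal_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: gene, then CT<hours>[_r<replicate>] expression values", con)
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter genes by mean expression
#'
#' Drops weakly expressed genes before rhythmicity analysis. In `count` mode,
#' genes with mean value below `min_mean_count` (default 6) are removed; in
#' `tpm` mode, genes with mean TPM below `min_tpm` (default 0.01) or with
#' missing/zero expression in more than `max_missing_reps` replicates are
#' removed. The boundary is inclusive: a gene at exactly the threshold is
#' kept.
#'
#' @param x a [temporal_matrix()]
#' @param min_mean_count minimum mean value in count mode
#' @param min_tpm minimum mean TPM in tpm mode
#' @param max_missing_reps maximum number of replicates allowed to have no
#'   expression (all-zero series) before a gene is removed (tpm mode)
#' @param mode `"count"` or `"tpm"`
#' @return the filtered `temporal_matrix`, with the removed gene ids in
#'   attribute `"removed"`
#' @export
filter_expression <- function(x, min_mean_count = 6, min_tpm = 0.01,
                              max_missing_reps = 2,
                              mode = c("count", "tpm")) {
  stopifnot(inherits(x, "temporal_matrix"))
  mode <- match.arg(mode)
  mu <- rowMeans(x$values)
  keep <- if (mode == "count") mu >= min_mean_count else mu >= min_tpm
  if (mode == "tpm" && max(x$replicate) > 1) {
    zero_reps <- vapply(rownames(x$values), function(g) {
      sum(vapply(unique(x$replicate), function(r) {
        all(x$values[g, x$replicate == r] == 0)
      }, logical(1)))
    }, integer(1))
    keep <- keep & (zero_reps <= max_missing_reps)
  }
  removed <- rownames(x$values)[!keep]
  if (!any(keep)) {
    warn_f("no genes survive the expression filter")
    out <- structure(list(values = x$values[0, , drop = FALSE],
                          time = x$time, replicate = x$replicate),
                     class = "temporal_matrix")
  } else {
    out <- temporal_matrix(x$values[keep, , drop = FALSE], x$time, x$replicate)
  }
  attr(out, "removed") <- removed
  out
}

#' Principal component projection of samples
#'
#' Centers (and optionally unit-scales) genes, then projects samples onto the
#' top-k eigenvectors of the sample covariance matrix. Used to check sample
#' grouping of temporal series. Zero-variance genes are dropped with a
#' warning.
#'
#' @param x a [temporal_matrix()] or a plain features x samples matrix
#' @param k number of components (default 2)
#' @param scale. unit-scale features before decomposition (default TRUE)
#' @return list with `coords` (samples x k), `var_explained` (fraction per
#'   component), and `sdev`
#' @export
pca_project <- function(x, k = 2, scale. = TRUE) {
  m <- if (inherits(x, "temporal_matrix")) x$values else as.matrix(x)
  stop_if_not(ncol(m) >= 2, "need at least 2 samples")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warn_f("%d zero-variance feature(s) dropped before PCA", sum(v == 0))
    m <- m[v > 0, , drop = FALSE]
  }
  stop_if_not(nrow(m) >= 1, "no features with variance remain")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = scale.)
  k <- min(k, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)],
       sdev = pc$sdev)
}
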