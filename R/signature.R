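#' Cluster signature genes by Ward hierarchical clustering
#'
#' Rows (genes) are z-scored, Euclidean distances computed, and the tree
#' built with the Ward squared-increment criterion (`ward.D2`) and cut to
#' exactly `k` clusters. Cluster indices are relabeled in descending order
#' of mean log2 fold change so that cluster `k` is the down-regulated one.
#'
#' @param expr Log-expression matrix restricted to the signature genes
#'   (e.g. FDR < 0.01 genes), genes in rows.
#' @param logfc Named per-gene log2 fold changes (used for ordering and
#'   direction labels).
#' @param k Number of clusters (default 4).
#' @return Object of class `"signature_clusters"`: data frame `genes`
#'   (`gene`, `cluster`, `direction`), `sizes`, `k`, and the `hclust` tree.
#' @export
cluster_signature <- function(expr, logfc, k = 4L) {
  if (nrow(expr) < k) stop("k = ", k, " exceeds number of genes (", nrow(expr), ")")
  z <- t(scale(t(expr)))
  z[!is.finite(z)] <- 0                      # constant genes carry no signal
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  lfc <- logfc[rownames(expr)]
  mean_lfc <- vapply(seq_len(k), function(j) mean(lfc[raw == j]), numeric(1))
  relabel <- order(order(mean_lfc, decreasing = TRUE))  # old -> new index
  cluster <- relabel[raw]
  genes <- data.frame(gene = rownames(expr), cluster = cluster,
                      direction = ifelse(mean_lfc[raw] >= 0, "up", "down"),
                      stringsAsFactors = FALSE)
  sizes <- as.integer(table(factor(cluster, levels = seq_len(k))))
  vi_log("signature", "k=%d clusters, sizes %s", k,
         paste(sizes, collapse = "/"))
  structure(list(genes = genes, sizes = sizes, k = as.integer(k), tree = hc),
            class = "signature_clusters")
}

#' @export
#' @method print signature_clusters
print.signature_clusters <- function(x, ...) {
  cat(sprintf("signature_clusters: %d genes in %d clusters (sizes %s)\n",
              nrow(x$genes), x$k, paste(x$sizes, collapse = "/")))
  invisible(x)
}

#' Gene list of one signature cluster
#'
#' @param clusters A `signature_clusters`.
#' @param j Cluster index.
#' @return Character vector of gene identifiers.
#' @export
cluster_genes <- function(clusters, j) {
  clusters$genes$gene[clusters$genes$cluster == j]
}

#' Signature clusters as a gene-set collection
#'
#' @param clusters A `signature_clusters`.
#' @param prefix Set-name prefix.
#' @return Named list of gene vectors (one set per cluster).
#' @export
clusters_as_gene_sets <- function(clusters, prefix = "VI_cluster_") {
  sets <- lapply(seq_len(clusters$k), function(j) cluster_genes(clusters, j))
  names(sets) <- paste0(prefix, seq_len(clusters$k))
  sets
}

#' Reference statistics for z-score scoring
#'
#' @param expr Training-cohort log-expression matrix.
#' @param genes Genes to compute statistics for (default all rows).
#' @return List with named `mean` and `sd` vectors.
#' @export
signature_reference <- function(expr, genes = rownames(expr)) {
  sub <- expr[intersect(genes, rownames(expr)), , drop = FALSE]
  list(mean = rowMeans(sub), sd = apply(sub, 1, stats::sd))
}

#' Mean z-score signature score
#'
#' Score of a sample = mean over the set genes of
#' `(logCPM - ref mean) / ref SD`, with reference statistics taken from a
#' stated cohort (the training cohort when scoring external data). Set
#' genes absent from the matrix, or with zero reference SD, are dropped
#' with a warning.
#'
#' @param expr Log-expression matrix to score.
#' @param genes Gene set.
#' @param reference Reference statistics from [signature_reference()];
#'   defaults to statistics of `expr` itself.
#' @return Named per-sample score vector.
#' @export
mean_zscore_score <- function(expr, genes, reference = NULL) {
  present <- intersect(genes, rownames(expr))
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " set gene(s) missing from matrix")
  if (length(present) == 0) stop("no set genes present in matrix")
  if (is.null(reference)) reference <- signature_reference(expr, present)
  mu <- reference$mean[present]; s <- reference$sd[present]
  zero <- !is.finite(s) | s == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero reference SD dropped")
    present <- present[!zero]; mu <- mu[!zero]; s <- s[!zero]
  }
  z <- (expr[present, , drop = FALSE] - mu) / s
  colMeans(z)
}

#' Binned-control module score
#'
#' The spot-level module score of the single-cell toolkits: genes are
#' binned into `n_bins` by average expression over all spots; for every
#' set gene `n_ctrl` control genes are sampled from its bin (without
#' replacement when the bin is large enough, with replacement otherwise);
#' the score of a spot is the mean expression of the set genes minus the
#' mean of all sampled controls.
#'
#' @param expr Log-normalized gene x spot expression matrix.
#' @param genes Gene set.
#' @param n_bins Expression bins (default 24).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed for control sampling.
#' @return Named per-spot score vector.
#' @export
module_score <- function(expr, genes, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0) stop("no set genes present in matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present), " set gene(s) missing from matrix")
  set.seed(stage_seed(seed, "module_score"))
  avg <- rowMeans(expr)
  bins <- if (n_bins <= 1) rep(1L, nrow(expr)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  ctrl <- unlist(lapply(present, function(g) {
    pool <- rownames(expr)[bins == bins[[which(rownames(expr) == g)]]]
    if (length(pool) >= n_ctrl) sample(pool, n_ctrl) else
      sample(pool, n_ctrl, replace = TRUE)
  }))
  set_mean <- colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Up-minus-down combined score
#'
#' Elementwise difference between an up-gene enrichment and a down-gene
#' enrichment computed on the same units.
#'
#' @param score_up,score_down Score vectors over identical units.
#' @return `score_up - score_down`.
#' @export
updown_score <- function(score_up, score_down) {
  if (length(score_up) != length(score_down))
    stop("score vectors must cover the same units")
  if (!is.null(names(score_up)) && !is.null(names(score_down)) &&
      !all(names(score_up) == names(score_down)))
    stop("score vectors must cover the same units")
  score_up - score_down
}
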