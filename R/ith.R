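#' Sample region pairs for heterogeneity analysis
#'
#' Intra mode draws one unordered pair of regions per tumor (tumors with
#' fewer than two regions are excluded with a warning); inter mode draws
#' `n_draws` pairs of regions from two distinct tumors, uniformly and
#' without reusing a region within one draw.
#'
#' @param samples Sample table with `sample_id`, `tumor_id` columns.
#' @param mode `"intra"` or `"inter"`.
#' @param n_draws Number of inter-tumor pairs (default: number of tumors,
#'   making the two sets of observations the same size).
#' @param seed Integer seed.
#' @return Data frame with columns `region_a`, `region_b` (and `tumor` for
#'   intra pairs).
#' @export
sample_region_pairs <- function(samples, mode = c("intra", "inter"),
                                n_draws = NULL, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(stage_seed(seed, paste0("pairs_", mode)))
  by_tumor <- split(samples$sample_id, samples$tumor_id)
  if (mode == "intra") {
    small <- names(by_tumor)[lengths(by_tumor) < 2]
    if (length(small) > 0) {
      warning(length(small), " tumor(s) with < 2 regions excluded")
      by_tumor <- by_tumor[lengths(by_tumor) >= 2]
    }
    if (length(by_tumor) == 0) stop("no tumor with >= 2 regions")
    pairs <- lapply(names(by_tumor), function(t) {
      r <- sample(by_tumor[[t]], 2)
      data.frame(tumor = t, region_a = r[1], region_b = r[2],
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, pairs))
  }
  if (length(by_tumor) < 2) stop("inter mode needs >= 2 tumors")
  if (is.null(n_draws)) n_draws <- length(by_tumor)
  pairs <- lapply(seq_len(n_draws), function(i) {
    ts <- sample(names(by_tumor), 2)
    data.frame(region_a = sample(by_tumor[[ts[1]]], 1),
               region_b = sample(by_tumor[[ts[2]]], 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pairs)
}

#' Intra- vs inter-tumor score heterogeneity
#'
#' Absolute score differences within intra-tumor pairs and across
#' inter-tumor pairs, a two-sided Wilcoxon rank-sum test between the two
#' sets, and the Spearman correlation of paired-region scores with the
#' A/B assignment randomized (seeded) so the correlation does not depend
#' on region ordering.
#'
#' @param scores Named per-region score vector.
#' @param intra_pairs,inter_pairs Pair tables from
#'   [sample_region_pairs()].
#' @param seed Integer seed for the A/B randomization.
#' @return List: `intra_diff`, `inter_diff` (absolute differences),
#'   `wilcoxon_p`, `spearman` (paired-region correlation), and
#'   `spearman_p`.
#' @export
ith_statistics <- function(scores, intra_pairs, inter_pairs, seed = 1L) {
  need <- unique(c(intra_pairs$region_a, intra_pairs$region_b,
                   inter_pairs$region_a, inter_pairs$region_b))
  if (!all(need %in% names(scores)))
    stop("scores missing for paired region(s)")
  intra_diff <- abs(scores[intra_pairs$region_a] -
                    scores[intra_pairs$region_b])
  inter_diff <- abs(scores[inter_pairs$region_a] -
                    scores[inter_pairs$region_b])
  wt <- suppressWarnings(stats::wilcox.test(intra_diff, inter_diff))

  set.seed(stage_seed(seed, "ith_ab"))
  flip <- stats::runif(nrow(intra_pairs)) < 0.5
  a <- ifelse(flip, intra_pairs$region_b, intra_pairs$region_a)
  b <- ifelse(flip, intra_pairs$region_a, intra_pairs$region_b)
  ct <- suppressWarnings(stats::cor.test(scores[a], scores[b],
                                         method = "spearman"))
  list(intra_diff = unname(intra_diff), inter_diff = unname(inter_diff),
       wilcoxon_p = wt$p.value, spearman = unname(ct$estimate),
       spearman_p = ct$p.value)
}

#' Rank genes by region-region correlation
#'
#' After the standard expression filter, each gene's Spearman correlation
#' between region-A and region-B expression across tumors (A/B
#' randomized, seeded) is computed and genes are ranked descending:
#' region-stable genes lead the list. The ranking can be fed to
#' [preranked_gsea()] with the predictor panel as the query set.
#'
#' @param expr Gene x region log-expression matrix.
#' @param intra_pairs Pair table from `sample_region_pairs(mode="intra")`.
#' @param seed Integer seed.
#' @return Named, descending vector of per-gene Spearman correlations.
#' @export
regionwise_gene_correlation <- function(expr, intra_pairs, seed = 1L) {
  if (nrow(intra_pairs) < 10) stop("need >= 10 tumors")
  set.seed(stage_seed(seed, "regionwise_ab"))
  flip <- stats::runif(nrow(intra_pairs)) < 0.5
  a <- ifelse(flip, intra_pairs$region_b, intra_pairs$region_a)
  b <- ifelse(flip, intra_pairs$region_a, intra_pairs$region_b)
  ea <- expr[, a, drop = FALSE]
  eb <- expr[, b, drop = FALSE]
  rho <- vapply(seq_len(nrow(expr)), function(g) {
    suppressWarnings(stats::cor(ea[g, ], eb[g, ], method = "spearman"))
  }, numeric(1))
  names(rho) <- rownames(expr)
  rho[is.na(rho)] <- 0
  ord <- order(-rho, names(rho))
  rho[ord]
}
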