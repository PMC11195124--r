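#' Rank genes for preranked enrichment
#'
#' Ranking metric: `-log10(p) * sign(logFC)`, sorted descending. Zero
#' p-values are clamped to the smallest positive double with a warning;
#' ties are broken lexicographically by gene identifier so the ranking is
#' deterministic.
#'
#' @param de A differential-expression result with columns `gene`,
#'   `PValue`, `logFC` (rows with `NA` p-values are dropped).
#' @return Named numeric vector of ranking scores, sorted descending.
#' @export
rank_genes <- function(de) {
  de <- de[!is.na(de$PValue), , drop = FALSE]
  p <- de$PValue
  if (any(p == 0)) {
    warning(sum(p == 0), " zero p-value(s) clamped")
    p[p == 0] <- .Machine$double.xmin
  }
  score <- -log10(p) * sign(de$logFC)
  ord <- order(-score, de$gene)
  stats::setNames(score[ord], de$gene[ord])
}

# weighted Kolmogorov-Smirnov running-sum enrichment score; returns the
# signed maximum deviation and its position
gsea_es <- function(scores, hit, weight = 1) {
  n <- length(scores); nh <- sum(hit)
  w <- abs(scores)^weight * hit
  sw <- sum(w)
  p_hit <- if (sw > 0) cumsum(w) / sw else cumsum(hit) / max(nh, 1)
  p_miss <- cumsum(!hit) / (n - nh)
  run <- p_hit - p_miss
  i <- which.max(abs(run))
  list(es = run[i], peak = i, running = run)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment: hits advance the
#' running sum proportionally to `|score|^weight` (normalized to sum 1),
#' misses decrement it by `1/(N - Nh)`; the enrichment score (ES) is the
#' signed maximum deviation. Significance comes from seeded gene-label
#' permutations of set membership, one-sided toward the observed sign with
#' a +1 pseudo-count; the normalized ES divides by the mean magnitude of
#' same-sign permutation scores. Sets with fewer than 2 ranked genes are
#' skipped with a warning.
#'
#' @param ranked Named, descending score vector from [rank_genes()].
#' @param sets Named list of gene sets.
#' @param weight Weighting exponent (default 1).
#' @param nperm Permutations (default 1000).
#' @param seed Integer seed.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return Data frame with one row per scored set: `set`, `size`, `es`,
#'   `nes`, `pval`, `padj`, `leading_edge` (comma-separated genes).
#' @export
preranked_gsea <- function(ranked, sets, weight = 1, nperm = 1000L,
                           seed = 1L, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  set.seed(stage_seed(seed, "gsea"))
  genes <- names(ranked)
  n <- length(genes)
  rows <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    if (length(members) < 2) {
      warning("set '", nm, "' has < 2 ranked genes; skipped")
      next
    }
    hit <- genes %in% members
    obs <- gsea_es(ranked, hit, weight)
    perm_es <- vapply(seq_len(nperm), function(i) {
      ph <- logical(n)
      ph[sample.int(n, length(members))] <- TRUE
      gsea_es(ranked, ph, weight)$es
    }, numeric(1))
    # one-sided toward the observed sign, normalized over the same-sign
    # permutations, +1 pseudo-count so p > 0 always
    if (obs$es >= 0) {
      pval <- (1 + sum(perm_es >= obs$es)) / (1 + sum(perm_es >= 0))
      same <- perm_es[perm_es > 0]
    } else {
      pval <- (1 + sum(perm_es <= obs$es)) / (1 + sum(perm_es <= 0))
      same <- -perm_es[perm_es < 0]
    }
    nes <- if (length(same) > 0) obs$es / mean(abs(same)) else NA_real_
    le <- if (obs$es >= 0) genes[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
      else genes[obs$peak:n][hit[obs$peak:n]]
    rows[[nm]] <- data.frame(set = nm, size = length(members), es = obs$es,
                             nes = nes, pval = pval,
                             leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$padj <- stats::p.adjust(out$pval, method =
                                if (adjust == "BH") "BH" else "bonferroni")
  rownames(out) <- NULL
  out[, c("set", "size", "es", "nes", "pval", "padj", "leading_edge")]
}

#' Fisher over-representation analysis
#'
#' One-sided Fisher exact (hypergeometric tail) test of the overlap
#' between a query gene list and each supplied set, within a stated
#' universe; BH adjustment across sets.
#'
#' @param query Query genes (must be a subset of `universe`).
#' @param universe Background genes.
#' @param sets Named list of gene sets (intersected with the universe).
#' @return Data frame: `set`, `overlap`, `set_size`, `odds_ratio`, `pval`,
#'   `padj`.
#' @export
fisher_ora <- function(query, universe, sets) {
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  n <- length(universe); q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    a <- length(intersect(query, s))
    b <- q - a
    c2 <- length(s) - a
    d <- n - q - c2
    or <- (a * d) / max(b * c2, .Machine$double.eps)
    p <- stats::phyper(a - 1, length(s), n - length(s), q, lower.tail = FALSE)
    data.frame(set = nm, overlap = a, set_size = length(s), odds_ratio = or,
               pval = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pval, method = "BH")
  out
}
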