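# Independent brute-force oracles used to pin the analytic operations.
# Each is coded directly from the definition of the statistic and shares
# no code with the package implementation.

# trimmed-mean-of-M-values factors, written out from the definition:
# reference column by upper-quartile proximity to the mean, 30%/5%
# two-sided trims on M and A, delta-method precision weights, factors
# rescaled to geometric mean 1
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; rc <- counts[, ref]
    nO <- lib[i]; nR <- lib[ref]
    keep <- obs > 0 & rc > 0
    o <- obs[keep]; r <- rc[keep]
    logR <- log2((o / nO) / (r / nR))
    absE <- (log2(o / nO) + log2(r / nR)) / 2
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# agglomerative Ward clustering by exhaustive pairwise evaluation of the
# squared-increment merge cost; returns the partition after every merge
oracle_ward_partitions <- function(z) {
  clusters <- lapply(seq_len(nrow(z)), identity)
  parts <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(z[a, , drop = FALSE])
      cb <- colMeans(z[b, , drop = FALSE])
      d <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
        sqrt(sum((ca - cb)^2))
      if (d < best[1]) best <- c(d, i, j)
    }
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    lab <- integer(nrow(z))
    for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
    parts[[length(parts) + 1]] <- lab
  }
  parts
}

# running-sum enrichment score by direct enumeration
oracle_gsea_es <- function(scores, members, weight = 1) {
  genes <- names(scores)
  hit <- genes %in% members
  nr <- sum(abs(scores[hit])^weight)
  run <- 0; best <- 0
  miss_step <- 1 / (length(genes) - sum(hit))
  for (i in seq_along(genes)) {
    run <- run + if (hit[i]) abs(scores[i])^weight / nr else -miss_step
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# AUROC by exhaustive positive/negative pair enumeration with half credit
# for ties
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Cox partial log-likelihood for untied data, maximized numerically
oracle_cox_beta <- function(time, event, x) {
  nll <- function(beta) {
    -sum(vapply(which(event == 1), function(i) {
      risk <- time >= time[i]
      beta * x[i] - log(sum(exp(beta * x[risk])))
    }, numeric(1)))
  }
  stats::optimize(nll, c(-10, 10), tol = 1e-10)$minimum
}

# weighted Pearson correlation by direct summation
oracle_weighted_cor <- function(a, b, w) {
  sw <- sum(w)
  ma <- sum(w * a) / sw; mb <- sum(w * b) / sw
  cov <- sum(w * (a - ma) * (b - mb)) / sw
  cov / sqrt(sum(w * (a - ma)^2) / sw * sum(w * (b - mb)^2) / sw)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2)); sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (sij - expected) / ((sa + sb) / 2 - expected)
}
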