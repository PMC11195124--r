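#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes TMM library-size normalization factors (reference column = the
#' sample whose upper-quartile count fraction is closest to the mean; 30%
#' two-sided trim on M-values, 5% on A-values; delta-method precision
#' weights; factors rescaled to geometric mean 1). Computation is
#' delegated to edgeR's TMM implementation.
#'
#' @param counts Gene x sample count matrix.
#' @return Named per-sample factor vector, geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Log2 counts-per-million
#'
#' `log2((count + prior * s) / (efflib + 2 * prior * s) * 1e6)` with
#' `efflib` the TMM-effective library size and `s = efflib / mean(efflib)`
#' the sample-proportional prior scaling, i.e. the conventional
#' prior-damped logCPM.
#'
#' @param counts Gene x sample count matrix.
#' @param factors Normalization factors from [tmm_factors()]; defaults to 1.
#' @param prior_count Pseudo-count (default 2).
#' @return Matrix of log2-CPM values with attributes `lib_size` (effective
#'   library sizes) and `norm_factors`.
#' @export
logcpm <- function(counts, factors = NULL, prior_count = 2) {
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  efflib <- colSums(counts) * factors
  if (any(efflib <= 0)) stop("non-positive effective library size")
  s <- efflib / mean(efflib)
  out <- log2(sweep(sweep(counts, 2, prior_count * s, "+"), 2,
                    efflib + 2 * prior_count * s, "/") * 1e6)
  attr(out, "lib_size") <- efflib
  attr(out, "norm_factors") <- factors
  out
}

#' Expression filter on counts-per-million
#'
#' Retains genes with CPM above `cpm_threshold` in at least
#' `ceiling(frac * n_samples)` samples; gene order is preserved. The
#' filter is idempotent.
#'
#' @param counts Gene x sample count matrix.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param frac Required fraction of samples (default 0.10).
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, cpm_threshold = 1, frac = 0.10) {
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  need <- ceiling(frac * ncol(counts))
  keep <- rowSums(cpm > cpm_threshold) >= need
  vi_log("filter_genes", "retained %d / %d genes (CPM > %g in >= %d samples)",
         sum(keep), nrow(counts), cpm_threshold, need)
  counts[keep, , drop = FALSE]
}

#' Quality-score sample filter
#'
#' Removes samples whose quality score (e.g. a transcript-integrity
#' number) deviates from the cohort mean by more than `sd_threshold`
#' standard deviations; mean and SD are computed once over all samples.
#'
#' @param quality Named per-sample quality scores (>= 3 samples).
#' @param sd_threshold Cut in SD units (default 2).
#' @return Character vector of retained sample names.
#' @export
filter_samples_quality <- function(quality, sd_threshold = 2) {
  if (length(quality) < 3) stop("need at least 3 samples")
  if (is.null(names(quality))) names(quality) <- seq_along(quality)
  s <- stats::sd(quality)
  keep <- if (s == 0) rep(TRUE, length(quality)) else
    abs(quality - mean(quality)) <= sd_threshold * s
  vi_log("filter_samples", "retained %d / %d samples (|score - mean| <= %g SD)",
         sum(keep), length(quality), sd_threshold)
  names(quality)[keep]
}

#' Reference-batch location/scale harmonization
#'
#' Per-gene location/scale batch adjustment of log-expression toward a
#' designated reference batch. Values are standardized with the reference
#' batch's gene means and variances; non-reference batch effects are
#' estimated per gene and, with `shrink = TRUE`, shrunk across genes by
#' empirical Bayes (normal prior on the location effect, inverse-gamma on
#' the scale effect, both moment-matched). Reference-batch columns are
#' returned bit-identical.
#'
#' @param expr Gene x sample log-expression matrix.
#' @param batch Per-sample batch labels.
#' @param reference Reference batch label.
#' @param shrink Apply empirical-Bayes shrinkage of the batch effects?
#' @return The adjusted matrix, same dimensions and dimnames.
#' @export
reference_batch_adjust <- function(expr, batch, reference, shrink = TRUE) {
  batch <- as.character(batch)
  if (length(batch) != ncol(expr)) stop("one batch label per column required")
  if (!reference %in% batch) stop("reference batch '", reference, "' absent")
  tab <- table(batch)
  if (any(tab < 2))
    stop("single-sample batch(es): ",
         paste(names(tab)[tab < 2], collapse = ", "))

  ref_cols <- batch == reference
  grand_mean <- rowMeans(expr[, ref_cols, drop = FALSE])
  pooled_var <- apply(expr[, ref_cols, drop = FALSE], 1, stats::var)
  pooled_var[pooled_var < 1e-12] <- 1e-12
  z <- (expr - grand_mean) / sqrt(pooled_var)

  out <- expr
  for (b in setdiff(unique(batch), reference)) {
    cols <- batch == b
    gamma_hat <- rowMeans(z[, cols, drop = FALSE])        # location effect
    delta_hat <- apply(z[, cols, drop = FALSE], 1, stats::var)
    delta_hat[delta_hat < 1e-12] <- 1e-12
    if (shrink) {
      # normal prior on gamma, inverse-gamma on delta, moment matched
      g_bar <- mean(gamma_hat); t2 <- stats::var(gamma_hat)
      n_b <- sum(cols)
      gamma_star <- (t2 * n_b * gamma_hat + delta_hat * g_bar) /
        (t2 * n_b + delta_hat)
      d_bar <- mean(delta_hat); s2 <- stats::var(delta_hat)
      a_prior <- (2 * s2 + d_bar^2) / max(s2, 1e-12)
      b_prior <- (d_bar * s2 + d_bar^3) / max(s2, 1e-12)
      resid2 <- rowSums((z[, cols, drop = FALSE] - gamma_star)^2)
      delta_star <- (b_prior + 0.5 * resid2) / (n_b / 2 + a_prior - 1)
      delta_star[delta_star < 1e-12] <- 1e-12
    } else {
      gamma_star <- gamma_hat
      delta_star <- delta_hat
    }
    adj <- (z[, cols, drop = FALSE] - gamma_star) / sqrt(delta_star)
    out[, cols] <- adj * sqrt(pooled_var) + grand_mean
  }
  vi_log("batch_adjust", "%d batches adjusted to reference '%s' (shrink=%s)",
         length(unique(batch)) - 1L, reference, shrink)
  out
}
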