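#' Benjamini-Hochberg FDR with NA pass-through
#'
#' Step-up adjustment over the non-missing p-values only; `NA` entries are
#' preserved and excluded from the denominator.
#'
#' @param p Vector of p-values in `[0, 1]` or `NA`.
#' @return FDR vector of the same length.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# single NB GLM fit with log link and fixed dispersion phi; phi ~ 0 uses
# the Poisson limit
nb_fit <- function(y, X, phi, offset) {
  fam <- if (phi < 1e-8) stats::poisson("log") else
    MASS::negative.binomial(theta = 1 / phi, link = "log")
  suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                  control = list(maxit = 100,
                                                 epsilon = 1e-8)))
}

# Cox-Reid adjusted profile log-likelihood of phi for one gene
nb_apl <- function(phi, y, X, offset) {
  fit <- nb_fit(y, X, phi, offset)
  mu <- pmax(fit$fitted.values, 1e-10)
  ll <- if (phi < 1e-8) sum(stats::dpois(y, mu, log = TRUE)) else
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  w <- mu / (1 + phi * mu)
  info <- crossprod(X, X * w)
  ll - 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus)
}

assert_full_rank <- function(design) {
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(design)
}

#' Estimate NB dispersions with empirical-Bayes moderation
#'
#' Per gene, the dispersion maximizes a weighted combination of the gene's
#' own Cox-Reid adjusted profile likelihood and the average adjusted
#' profile likelihood of all genes (the common-dispersion profile),
#' i.e. a weighted-likelihood empirical-Bayes scheme without a
#' mean-dispersion trend. The prior receives `prior_df` degrees of freedom
#' against the gene's residual degrees of freedom, so moderation is strong
#' in small cohorts and fades as replication grows; a gene with clear
#' evidence of high dispersion keeps it, which is what protects the
#' extreme tail of the likelihood-ratio test. All returned dispersions are
#' >= 1e-8.
#'
#' @param counts Gene x sample count matrix (already expression-filtered).
#' @param design Full-rank design matrix (samples x coefficients).
#' @param offset Per-sample log effective library size; defaults to
#'   `log(colSums(counts))`.
#' @param prior_df Prior degrees of freedom of the common-dispersion
#'   profile (default 10).
#' @param max_common_genes Cap on the genes averaged into the common
#'   profile (evenly spaced subset, deterministic).
#' @return Named per-gene dispersion vector with attributes
#'   `dispersion_genewise` (unmoderated per-gene maximizers) and
#'   `dispersion_common` (maximizer of the average profile).
#' @export
estimate_dispersions <- function(counts, design, offset = NULL,
                                 prior_df = 10,
                                 max_common_genes = 500L) {
  assert_full_rank(design)
  if (is.null(offset)) offset <- log(colSums(counts))
  lo <- log(1e-6); hi <- log(10)

  # each gene's adjusted profile likelihood on a fixed log-dispersion
  # grid; every maximizer below comes from a spline through these values,
  # so the GLM refits happen once per grid point only
  lp_grid <- seq(lo, hi, length.out = 30)
  apl <- vapply(lp_grid, function(lp) {
    vapply(seq_len(nrow(counts)), function(g) {
      nb_apl(exp(lp), counts[g, ], design, offset)
    }, numeric(1))
  }, numeric(nrow(counts)))
  apl <- matrix(apl, nrow = nrow(counts))

  spline_argmax <- function(vals) {
    f <- stats::splinefun(lp_grid, vals)
    stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-4)$maximum
  }
  genewise <- exp(apply(apl, 1, spline_argmax))

  idx <- if (nrow(counts) > max_common_genes) {
    unique(round(seq(1, nrow(counts), length.out = max_common_genes)))
  } else seq_len(nrow(counts))
  sbar <- colMeans(apl[idx, , drop = FALSE])
  common <- exp(spline_argmax(sbar))

  df_res <- max(ncol(counts) - ncol(design), 1L)
  w <- df_res / (df_res + prior_df)
  moderated <- exp(apply(w * apl + (1 - w) * rep(sbar, each = nrow(apl)),
                         1, spline_argmax))
  moderated <- pmax(moderated, 1e-8)
  names(moderated) <- rownames(counts)
  attr(moderated, "dispersion_genewise") <- genewise
  attr(moderated, "dispersion_common") <- common
  vi_log("dispersions", "%d genes; common dispersion %.4g (prior df %g)",
         nrow(counts), common, prior_df)
  moderated
}

#' NB GLM likelihood-ratio differential expression
#'
#' Fits, per gene, a full NB GLM (log link, library-size offset, fixed
#' per-gene dispersion) and a reduced model constrained to `contrast = 0`,
#' and tests the contrast by the likelihood-ratio chi-square (df 1).
#' P-values are BH-adjusted across the tested genes; genes whose IRLS fit
#' does not converge are flagged, get `NA` p-values, and are excluded from
#' the FDR denominator.
#'
#' @param counts Gene x sample count matrix.
#' @param design Full-rank design matrix.
#' @param contrast Numeric coefficient-combination vector (length
#'   `ncol(design)`), or the name of a single design column.
#' @param dispersions Per-gene dispersions from [estimate_dispersions()].
#' @param offset Per-sample log effective library size; defaults to
#'   `log(colSums(counts))`.
#' @return Data frame with columns `gene`, `logFC` (log2, for the
#'   contrast), `LR`, `PValue`, `FDR`, `dispersion`, `converged`.
#' @export
fit_nbglm_lrt <- function(counts, design, contrast, dispersions,
                          offset = NULL) {
  assert_full_rank(design)
  if (is.character(contrast)) {
    contrast <- as.numeric(colnames(design) == contrast)
    if (sum(contrast) != 1) stop("contrast column not found in design")
  }
  stopifnot(length(contrast) == ncol(design))
  if (is.null(offset)) offset <- log(colSums(counts))
  p <- ncol(design)
  # orthonormal complement of the contrast: reduced design spans
  # {X beta : contrast' beta = 0}
  Q <- qr.Q(qr(cbind(contrast / sqrt(sum(contrast^2)), diag(p))))
  C <- Q[, 2:p, drop = FALSE]
  design_red <- design %*% C

  n <- nrow(counts)
  logFC <- LR <- pval <- rep(NA_real_, n)
  converged <- logical(n)
  for (g in seq_len(n)) {
    phi <- dispersions[g]
    full <- nb_fit(counts[g, ], design, phi, offset)
    red <- nb_fit(counts[g, ], design_red, phi, offset)
    converged[g] <- isTRUE(full$converged) && isTRUE(red$converged)
    if (!converged[g]) next
    LR[g] <- max(red$deviance - full$deviance, 0)
    pval[g] <- stats::pchisq(LR[g], df = 1, lower.tail = FALSE)
    logFC[g] <- sum(contrast * full$coefficients) / log(2)
  }
  if (any(!converged))
    warning(sum(!converged), " gene(s) did not converge; excluded from FDR")
  res <- data.frame(gene = rownames(counts), logFC = logFC, LR = LR,
                    PValue = pval, FDR = bh_fdr(pval),
                    dispersion = as.numeric(dispersions),
                    converged = converged, stringsAsFactors = FALSE)
  vi_log("diffexpr", "%d genes tested, %d at FDR < 0.01", sum(converged),
         sum(res$FDR < 0.01, na.rm = TRUE))
  res
}

#' Grade design matrix and VI-vs-LMP contrast
#'
#' Builds the three-level tumor-grade design (reference level LMP) with an
#' optional lymphatic-invasion covariate, plus the coefficient vectors for
#' the VI-vs-LMP and LI contrasts.
#'
#' @param samples Sample table with a `grade` column (values LMP/NST/VI)
#'   and, if `li = TRUE`, a binary `li` column.
#' @param li Include the LI indicator as a covariate?
#' @return List with `design`, `contrast_vi` and (if `li`) `contrast_li`.
#' @export
grade_design <- function(samples, li = FALSE) {
  grade <- factor(samples$grade, levels = c("LMP", "NST", "VI"))
  if (anyNA(grade)) stop("grade must be one of LMP, NST, VI")
  grade <- droplevels(grade)            # absent grades would zero a column
  df <- data.frame(grade = grade)
  form <- ~grade
  if (li) {
    df$li <- as.integer(samples$li)
    form <- ~grade + li
  }
  design <- stats::model.matrix(form, df)
  out <- list(design = design,
              contrast_vi = as.numeric(colnames(design) == "gradeVI"))
  if (li) out$contrast_li <- as.numeric(colnames(design) == "li")
  out
}

#' One-call differential expression over the grade factor
#'
#' Convenience wrapper: dispersions + LRT for the VI-vs-LMP contrast with
#' TMM-effective library-size offsets.
#'
#' @param counts Filtered gene x sample count matrix.
#' @param samples Sample table with `grade` (and `li` if requested).
#' @param li Add the LI covariate.
#' @param contrast `"vi"` (default) or `"li"`.
#' @param factors Optional TMM factors for the offset.
#' @inheritParams estimate_dispersions
#' @return A `fit_nbglm_lrt()` result data frame.
#' @export
run_de <- function(counts, samples, li = FALSE, contrast = c("vi", "li"),
                   factors = NULL, prior_df = 10) {
  contrast <- match.arg(contrast)
  if (contrast == "li" && !li) stop("LI contrast requires li = TRUE")
  gd <- grade_design(samples, li = li)
  offset <- if (is.null(factors)) log(colSums(counts)) else
    log(colSums(counts) * factors)
  disp <- estimate_dispersions(counts, gd$design, offset = offset,
                               prior_df = prior_df)
  cvec <- if (contrast == "vi") gd$contrast_vi else gd$contrast_li
  fit_nbglm_lrt(counts, gd$design, cvec, disp, offset = offset)
}
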