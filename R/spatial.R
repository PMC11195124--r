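#' Spot quality control
#'
#' Removes spots in which fewer than `min_genes` genes are detected
#' (nonzero counts).
#'
#' @param grid A [spot_grid()].
#' @param min_genes Detected-gene floor (default 250).
#' @return The filtered `spot_grid`.
#' @export
spot_qc <- function(grid, min_genes = 250L) {
  detected <- colSums(grid$counts > 0)
  keep <- detected >= min_genes
  vi_log("spot_qc", "retained %d / %d spots (>= %d detected genes)",
         sum(keep), length(keep), min_genes)
  spot_grid(grid$counts[, keep, drop = FALSE],
            grid$spots[keep, , drop = FALSE],
            if (is.null(grid$proportions)) NULL else
              grid$proportions[keep, , drop = FALSE])
}

#' Log-normalize spot expression
#'
#' Per spot, counts are scaled to `scale_target` total and transformed
#' with `log1p`, the standard library-size normalization of the
#' single-cell toolkits.
#'
#' @param grid A QC'd [spot_grid()].
#' @param scale_target Target total per spot (default 10000).
#' @return Gene x spot matrix of log-normalized values.
#' @export
lognormalize_spots <- function(grid, scale_target = 1e4) {
  tot <- colSums(grid$counts)
  if (any(tot == 0)) stop("spot(s) with zero total counts; run spot_qc first")
  log1p(sweep(grid$counts, 2, tot / scale_target, "/"))
}

# kernel functions on scaled distance u = d / h
kernel_weight <- function(u, kernel) {
  switch(kernel,
         bisquare = ifelse(u < 1, (1 - u^2)^2, 0),
         gaussian = exp(-0.5 * u^2),
         stop("unknown kernel: ", kernel))
}

weighted_cor <- function(a, b, w) {
  sw <- sum(w)
  ma <- sum(w * a) / sw; mb <- sum(w * b) / sw
  va <- sum(w * (a - ma)^2) / sw; vb <- sum(w * (b - mb)^2) / sw
  if (va <= 0 || vb <= 0) return(NA_real_)
  sum(w * (a - ma) * (b - mb)) / sw / sqrt(va * vb)
}

#' Spatially weighted local correlation
#'
#' For every spot, a kernel-weighted Pearson correlation between two
#' per-spot score maps is computed over its neighborhood; with
#' `rank_transform = TRUE` the scores are globally rank-transformed first
#' (a Spearman analogue). Weights are computed within sample only; the
#' bandwidth is expressed in spot-pitch units (bandwidth 5 means a kernel
#' scale of five pitches). Spots with fewer than 3 positively weighted
#' neighbors get `NA`.
#'
#' @param grid A [spot_grid()] (counts are not used, only coordinates and
#'   sample membership).
#' @param scores_a,scores_b Named per-spot score vectors covering the
#'   grid's spots.
#' @param bandwidth Bandwidth in spot-pitch units (default 5).
#' @param kernel `"bisquare"` (default) or `"gaussian"`.
#' @param rank_transform Rank-transform the scores first?
#' @param pitch_um Spot pitch in micrometers (default: the smallest
#'   positive inter-spot distance).
#' @return List with `local` (per-spot coefficients), `per_sample` (mean
#'   coefficient per sample), and `mean` (equal-weight average of the
#'   per-sample means).
#' @export
weighted_local_correlation <- function(grid, scores_a, scores_b,
                                       bandwidth = 5,
                                       kernel = c("bisquare", "gaussian"),
                                       rank_transform = FALSE,
                                       pitch_um = NULL) {
  kernel <- match.arg(kernel)
  spots <- grid$spots
  a <- scores_a[spots$spot_id]; b <- scores_b[spots$spot_id]
  if (anyNA(a) || anyNA(b)) stop("scores must cover all spots in the grid")
  if (rank_transform) { a <- rank(a); b <- rank(b) }
  local <- rep(NA_real_, nrow(spots))
  for (sid in unique(spots$sample_id)) {
    idx <- which(spots$sample_id == sid)
    xy <- cbind(spots$x_um[idx], spots$y_um[idx])
    d <- as.matrix(stats::dist(xy))
    if (is.null(pitch_um)) {
      pos <- d[d > 0]
      pitch <- if (length(pos) > 0) min(pos) else 1
    } else pitch <- pitch_um
    h <- bandwidth * pitch
    for (i in seq_along(idx)) {
      w <- kernel_weight(d[i, ] / h, kernel)
      if (sum(w > 0) < 3) next
      local[idx[i]] <- weighted_cor(a[idx], b[idx], w)
    }
  }
  names(local) <- spots$spot_id
  per_sample <- tapply(local, spots$sample_id,
                       function(v) mean(v, na.rm = TRUE))
  list(local = local, per_sample = per_sample,
       mean = mean(per_sample, na.rm = TRUE))
}

#' Mixed-model association of a per-spot value with pathology regions
#'
#' Pathology labels with fewer than `downsample_n` spots are dropped; the
#' remaining labels are downsampled (seeded) to `downsample_n` spots each;
#' then a linear mixed model `value ~ label + (1 | sample)` is fitted by
#' REML with the stated reference level, and each label's Wald contrast
#' against the reference is reported with Bonferroni adjustment.
#'
#' @param grid A [spot_grid()].
#' @param values Named per-spot values (module score or cell-type
#'   proportion).
#' @param reference_label Reference pathology label (default
#'   `"normal lung"`).
#' @param downsample_n Spots per label (default 200); `Inf` disables
#'   downsampling (deterministic estimates).
#' @param seed Integer seed for the downsampler.
#' @return Data frame: `label`, `estimate`, `pval`, `padj`.
#' @export
region_association <- function(grid, values, reference_label = "normal lung",
                               downsample_n = 200L, seed = 1L) {
  spots <- grid$spots
  v <- values[spots$spot_id]
  if (anyNA(v)) stop("values must cover all spots in the grid")
  tab <- table(spots$label)
  keep_labels <- names(tab)[is.infinite(downsample_n) | tab >= downsample_n]
  dropped <- setdiff(names(tab), keep_labels)
  if (length(dropped) > 0)
    vi_log("region_association", "dropped label(s) with < %d spots: %s",
           downsample_n, paste(dropped, collapse = ", "))
  if (!reference_label %in% keep_labels)
    stop("reference label '", reference_label, "' absent after filtering")
  if (length(keep_labels) < 2) stop("need >= 2 labels after filtering")

  set.seed(stage_seed(seed, "region_downsample"))
  idx <- unlist(lapply(keep_labels, function(l) {
    li <- which(spots$label == l)
    if (is.finite(downsample_n) && length(li) > downsample_n)
      sort(sample(li, downsample_n)) else li
  }))
  df <- data.frame(value = v[idx],
                   label = factor(spots$label[idx],
                                  levels = c(reference_label,
                                             setdiff(sort(keep_labels),
                                                     reference_label))),
                   sample = spots$sample_id[idx])
  others <- levels(df$label)[-1]
  if (stats::var(df$value) == 0) {
    return(data.frame(label = others, estimate = 0, pval = 1, padj = 1,
                      stringsAsFactors = FALSE))
  }
  if (length(unique(df$sample)) > 1) {
    fit <- lmerTest::lmer(value ~ label + (1 | sample), data = df,
                          REML = TRUE)
  } else {
    warning("single sample: fitting a fixed-effects model without the ",
            "per-sample random intercept")
    fit <- stats::lm(value ~ label, data = df)
  }
  co <- stats::coef(summary(fit))
  colnames(co)[ncol(co)] <- "Pr(>|t|)"
  rows <- paste0("label", others)
  out <- data.frame(label = others,
                    estimate = co[rows, "Estimate"],
                    pval = co[rows, "Pr(>|t|)"],
                    stringsAsFactors = FALSE)
  out$padj <- pmin(out$pval * length(others), 1)
  rownames(out) <- NULL
  out
}

#' VI-status contrast within high-grade regions
#'
#' Restricted to spots annotated with high-grade growth patterns, fits the
#' linear mixed model `score ~ vi_status + pattern + (1 | sample)` (ML)
#' and tests the VI-status term by likelihood ratio against the model
#' without it.
#'
#' @param grid A [spot_grid()] (possibly several samples).
#' @param values Named per-spot scores.
#' @param highgrade_labels Labels counted as high-grade (default solid,
#'   micropapillary, cribriform, VI focus).
#' @param vi_status Named per-sample VI status (0/1).
#' @return List with `estimate` (VI+ shift) and `pval` (LRT).
#' @export
highgrade_vi_contrast <- function(grid, values,
                                  highgrade_labels = c("solid",
                                                       "micropapillary",
                                                       "cribriform",
                                                       "VI focus"),
                                  vi_status) {
  spots <- grid$spots
  sel <- spots$label %in% highgrade_labels
  if (!any(sel)) stop("empty stratum: no high-grade spots")
  df <- data.frame(value = values[spots$spot_id[sel]],
                   pattern = factor(spots$label[sel]),
                   sample = spots$sample_id[sel])
  df$vi <- vi_status[df$sample]
  if (anyNA(df$vi)) stop("vi_status must cover every contributing sample")
  if (length(unique(df$vi)) < 2)
    stop("need both VI+ and VI- samples among high-grade spots")
  has_pattern <- nlevels(droplevels(df$pattern)) > 1
  full <- if (has_pattern)
    lme4::lmer(value ~ vi + pattern + (1 | sample), data = df, REML = FALSE)
  else lme4::lmer(value ~ vi + (1 | sample), data = df, REML = FALSE)
  red <- if (has_pattern)
    lme4::lmer(value ~ pattern + (1 | sample), data = df, REML = FALSE)
  else lme4::lmer(value ~ 1 + (1 | sample), data = df, REML = FALSE)
  lrt <- stats::anova(red, full)
  list(estimate = unname(lme4::fixef(full)["vi"]),
       pval = lrt$`Pr(>Chisq)`[2])
}

#' Proximal/distal binning around labeled foci
#'
#' Per-spot Euclidean distance to the nearest spot carrying
#' `target_label`; spots within `threshold_um` (inclusive; labeled spots
#' are at distance 0) are proximal, the rest distal. A sample without any
#' labeled spot is entirely proximal, mirroring the convention that VI+
#' tumors without an invaded focus in the capture area count as proximal.
#'
#' @param grid A single-sample [spot_grid()].
#' @param target_label Label of the foci (default `"VI focus"`).
#' @param threshold_um Distance threshold in micrometers (default 1000).
#' @return Named factor over spots with levels `proximal`, `distal`.
#' @export
distance_bins <- function(grid, target_label = "VI focus",
                          threshold_um = 1000) {
  spots <- grid$spots
  if (length(unique(spots$sample_id)) > 1)
    stop("distance_bins expects a single-sample grid")
  tgt <- which(spots$label == target_label)
  if (length(tgt) == 0) {
    bin <- rep("proximal", nrow(spots))
  } else {
    dx <- outer(spots$x_um, spots$x_um[tgt], "-")
    dy <- outer(spots$y_um, spots$y_um[tgt], "-")
    dmin <- apply(sqrt(dx^2 + dy^2), 1, min)
    bin <- ifelse(dmin <= threshold_um, "proximal", "distal")
  }
  stats::setNames(factor(bin, levels = c("proximal", "distal")),
                  spots$spot_id)
}

#' Cell-type presence filter
#'
#' Keeps cell types with at least one predicted cell in at least
#' `ceiling(presence_frac * n_samples)` capture areas.
#'
#' @param pred_counts Cell-type x sample matrix of predicted cell counts.
#' @param presence_frac Required fraction of capture areas (default 0.20).
#' @return Character vector of retained cell-type names.
#' @export
celltype_presence_filter <- function(pred_counts, presence_frac = 0.20) {
  if (any(pred_counts < 0)) stop("predicted counts must be >= 0")
  need <- ceiling(presence_frac * ncol(pred_counts))
  keep <- rowSums(pred_counts >= 1) >= need
  rownames(pred_counts)[keep]
}
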