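#' Pipeline configuration
#'
#' Bundles every tunable constant of the VI-signature pipeline with the
#' protocol defaults: differential expression at FDR < 0.01, four gene
#' clusters, a 48-gene predictor panel, 100 outer cross-validation
#' iterations at a 70/30 split with 5 inner folds, 2000 bootstrap
#' replicates for the AUROC confidence interval, a 250-detected-gene spot
#' QC floor, 200-spot region downsampling, a 1-mm proximal/distal
#' distance threshold, and a spatial kernel bandwidth of five spot
#' pitches.
#'
#' @param fdr_threshold BH-FDR cutoff for calling a gene differentially
#'   expressed (proportion in (0,1]).
#' @param n_clusters Number of gene co-expression clusters cut from the
#'   Ward tree.
#' @param panel_size Number of genes in the VI predictor panel.
#' @param outer_iters Number of outer train/test resampling iterations.
#' @param outer_train_frac Fraction of samples in each outer training set.
#' @param inner_folds Number of inner cross-validation folds for ridge
#'   penalty selection.
#' @param n_boot_auroc Bootstrap replicates for the AUROC 95% CI.
#' @param min_genes_per_spot Spot QC floor: minimum detected genes.
#' @param region_downsample Spots per pathology label retained for the
#'   mixed-model region association (labels below this count are dropped).
#' @param distance_threshold_um Proximal/distal cut in micrometers.
#' @param bandwidth_spots Spatial kernel bandwidth in spot-pitch units.
#' @param gsea_weight Enrichment-score weighting exponent.
#' @param gsea_nperm Gene-label permutations for the GSEA p-value.
#' @param cpm_threshold CPM cutoff of the expression filter.
#' @param cpm_frac Fraction of samples that must pass `cpm_threshold`.
#' @param quality_sd_threshold Sample QC cut in standard deviations of the
#'   per-sample quality score.
#' @param top_n_markers Marker genes retained per cell type.
#' @param celltype_presence_frac Fraction of capture areas in which a cell
#'   type must be predicted present to be retained.
#' @param ridge_lambda_grid Candidate ridge penalties (log-spaced).
#' @param global_seed Integer seed from which per-stage substreams are
#'   derived.
#'
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(fdr_threshold = 0.01,
                            n_clusters = 4L,
                            panel_size = 48L,
                            outer_iters = 100L,
                            outer_train_frac = 0.70,
                            inner_folds = 5L,
                            n_boot_auroc = 2000L,
                            min_genes_per_spot = 250L,
                            region_downsample = 200L,
                            distance_threshold_um = 1000,
                            bandwidth_spots = 5,
                            gsea_weight = 1,
                            gsea_nperm = 1000L,
                            cpm_threshold = 1,
                            cpm_frac = 0.10,
                            quality_sd_threshold = 2,
                            top_n_markers = 50L,
                            celltype_presence_frac = 0.20,
                            ridge_lambda_grid = 10^seq(-3, 3, length.out = 30),
                            global_seed = 1L) {
  cfg <- list(
    fdr_threshold = fdr_threshold, n_clusters = as.integer(n_clusters),
    panel_size = as.integer(panel_size), outer_iters = as.integer(outer_iters),
    outer_train_frac = outer_train_frac, inner_folds = as.integer(inner_folds),
    n_boot_auroc = as.integer(n_boot_auroc),
    min_genes_per_spot = as.integer(min_genes_per_spot),
    region_downsample = as.integer(region_downsample),
    distance_threshold_um = distance_threshold_um,
    bandwidth_spots = bandwidth_spots, gsea_weight = gsea_weight,
    gsea_nperm = as.integer(gsea_nperm), cpm_threshold = cpm_threshold,
    cpm_frac = cpm_frac, quality_sd_threshold = quality_sd_threshold,
    top_n_markers = as.integer(top_n_markers),
    celltype_presence_frac = celltype_presence_frac,
    ridge_lambda_grid = ridge_lambda_grid,
    global_seed = as.integer(global_seed)
  )
  counts <- c("n_clusters", "panel_size", "outer_iters", "inner_folds",
              "n_boot_auroc", "min_genes_per_spot", "region_downsample",
              "gsea_nperm", "top_n_markers")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("pipeline_config: '", nm, "' must be a count >= 1")
  }
  props <- c("fdr_threshold", "outer_train_frac", "cpm_frac",
             "celltype_presence_frac")
  for (nm in props) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0 || cfg[[nm]] > 1)
      stop("pipeline_config: '", nm, "' must be a proportion in (0, 1]")
  }
  thresholds <- c("distance_threshold_um", "bandwidth_spots", "cpm_threshold",
                  "quality_sd_threshold", "gsea_weight")
  for (nm in thresholds) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("pipeline_config: '", nm, "' must be > 0")
  }
  if (any(cfg$ridge_lambda_grid < 0)) stop("ridge penalties must be >= 0")
  structure(cfg, class = "pipeline_config")
}

#' Deterministic per-stage seed
#'
#' Splits a global seed into reproducible substreams keyed by stage name
#' (and an optional iteration index), so that any stage can be re-run in
#' isolation with the same random stream it saw inside the full pipeline.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @param index Optional iteration index within the stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 65521
  val <- (as.double(seed) %% 2147483647) * 31 + h * 2654435 + as.double(index) * 97
  as.integer(val %% 2147483629) + 1L
}

# one structured log line per stage; suppressible via the usual
# suppressMessages()
vi_log <- function(stage, ...) {
  message(sprintf("[visig:%s] %s", stage, sprintf(...)))
}
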