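test_that("generators are pure functions of design and seed", {
  d <- sim_design(n_genes = 150L, n_samples = 20L)
  a <- suppressMessages(generate_bulk_cohort(d, seed = 1))
  b <- suppressMessages(generate_bulk_cohort(d, seed = 1))
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  c_ <- suppressMessages(generate_bulk_cohort(d, seed = 2))
  expect_false(identical(a$counts, c_$counts))

  g1 <- suppressWarnings(suppressMessages(generate_spot_grid(d, seed = 3)))
  g2 <- suppressWarnings(suppressMessages(generate_spot_grid(d, seed = 3)))
  expect_identical(g1$grid$counts, g2$grid$counts)
})

test_that("counts are conserved non-negative integers with planted structure", {
  d <- sim_design(n_genes = 200L, n_samples = 30L)
  sim <- suppressMessages(generate_bulk_cohort(d, seed = 4))
  expect_true(all(sim$counts >= 0))
  expect_identical(storage.mode(sim$counts), "integer")
  cl <- sim$truth$gene_cluster
  expect_identical(as.integer(table(cl[cl > 0])), d$cluster_sizes)
  # every planted gene sits in exactly one cluster
  expect_true(all(table(names(cl[cl > 0])) == 1))
  # grade labels and latent scores agree
  expect_equal(unname(sim$truth$latent_score),
               unname(c(LMP = 0, NST = 0.4, VI = 1)[sim$samples$grade]))
  expect_error(sim_design(n_genes = 100L, cluster_sizes = c(50, 30, 20, 10)),
               "exceed")
})

test_that("a null design produces only nominal-rate discoveries", {
  d <- sim_design(n_genes = 500L, n_samples = 60L,
                  effect_log2fc = rep(0, 4), module_sd = 0)
  sim <- suppressMessages(generate_bulk_cohort(d, seed = 9))
  counts <- suppressMessages(filter_genes(sim$counts))
  de <- suppressMessages(run_de(counts, sim$samples,
                                factors = tmm_factors(counts)))
  n_disc <- sum(de$FDR < 0.01, na.rm = TRUE)
  # ~ m * alpha false positives, +/- 3 binomial SD
  m <- nrow(counts)
  expect_lte(n_disc, m * 0.01 + 3 * sqrt(m * 0.01 * 0.99))
})

test_that("stronger planted effects do not reduce separability", {
  aucs <- vapply(c(0.4, 1.6), function(eff) {
    d <- sim_design(n_genes = 150L, n_samples = 80L,
                    effect_log2fc = c(eff, eff, eff, -eff))
    sim <- suppressMessages(generate_bulk_cohort(d, seed = 21))
    expr <- suppressMessages(logcpm(sim$counts,
                                    tmm_factors(sim$counts)))
    panel <- names(sim$truth$gene_cluster)[sim$truth$gene_cluster > 0][1:20]
    train <- seq_len(50); test <- 51:80
    m <- train_ridge_logit(t(expr[panel, train]), sim$samples$vi[train],
                           inner_folds = 3, seed = 2)
    auroc(predict_scores(m, expr[, test]), sim$samples$vi[test])$auroc
  }, numeric(1))
  expect_gte(aucs[2], aucs[1])
})

test_that("spot grids paint regions with the planted activity gradient", {
  d <- sim_design(n_genes = 300L)
  sg <- suppressWarnings(suppressMessages(generate_spot_grid(d, seed = 2)))
  g <- sg$grid
  expect_setequal(unique(g$spots$label),
                  c("normal lung", "stroma", "lepidic",
                    "desmoplastic stroma", "solid", "VI focus"))
  expect_true(all(g$spots$x_um %% d$spot_pitch_um == 0))

  # module-3 score separates VI focus from lepidic by construction
  norm <- lognormalize_spots(suppressMessages(spot_qc(g, 50)))
  cl3 <- names(sg$truth$gene_cluster)[sg$truth$gene_cluster == 3]
  ms <- module_score(norm, cl3, seed = 1)
  qc_labels <- suppressMessages(spot_qc(g, 50))$spots$label
  expect_gt(mean(ms[qc_labels == "VI focus"]),
            mean(ms[qc_labels == "lepidic"]))

  # the 1-mm proximal bin contains every focus spot
  bins <- distance_bins(g, "VI focus", 1000)
  expect_true(all(bins[g$spots$label == "VI focus"] == "proximal"))

  # a single-region layout cannot feed the region model: error contract
  flat <- default_spot_layout(8, 8, vi_focus = FALSE)
  flat$paints <- list()
  sg_flat <- suppressMessages(generate_spot_grid(d, flat, seed = 2))
  vals <- setNames(rnorm(ncol(sg_flat$grid$counts)),
                   colnames(sg_flat$grid$counts))
  expect_error(suppressMessages(
    region_association(sg_flat$grid, vals, "normal lung",
                       downsample_n = 10)), ">= 2 labels")
})

test_that("multi-region cohorts carry the tumor-latent structure", {
  d <- sim_design(n_genes = 150L, region_noise_sd = 0.2)
  mr <- suppressMessages(generate_multiregion(d, n_tumors = 10,
                                              regions_per_tumor = 3,
                                              seed = 5))
  expect_equal(ncol(mr$counts), 30)
  expect_equal(length(unique(mr$samples$tumor_id)), 10)
  # region scores cluster around their tumor latent
  spread <- tapply(mr$truth$region_score, mr$samples$tumor_id, sd)
  expect_lt(median(spread), 2 * 0.2 + 0.1)
  expect_error(generate_multiregion(d, n_tumors = 5,
                                    regions_per_tumor = 1), ">= 2")
})

test_that("library sizes equal column sums and overlap paints warn", {
  d <- sim_design(n_genes = 100L, n_samples = 10L)
  sim <- suppressMessages(generate_bulk_cohort(d, seed = 1))
  expect_identical(unname(colSums(sim$counts)),
                   as.numeric(colSums(sim$counts)))
  layout <- default_spot_layout(10, 10)
  expect_warning(suppressMessages(generate_spot_grid(d, layout, seed = 1)),
                 "later paint wins")
})
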