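test_that("spot QC applies the detected-gene floor exactly at the boundary", {
  g <- toy_grid(rep("t", 6), ng = 300)
  g$counts[, 1] <- 0L
  g$counts[1:249, 1] <- 1L                       # 249 detected -> removed
  g$counts[, 2] <- 0L
  g$counts[1:250, 2] <- 1L                       # 250 detected -> retained
  out <- suppressMessages(spot_qc(g, 250))
  expect_false(g$spots$spot_id[1] %in% out$spots$spot_id)
  expect_true(g$spots$spot_id[2] %in% out$spots$spot_id)
  # all above threshold: identity
  all_ok <- suppressMessages(spot_qc(g, 1))
  expect_identical(all_ok$counts, g$counts)
  # retained set equals brute-force evaluation
  brute <- colnames(g$counts)[colSums(g$counts > 0) >= 250]
  expect_identical(out$spots$spot_id, brute)
})

test_that("spot log-normalization matches the formula and is depth invariant", {
  g <- toy_grid(rep("t", 4), ng = 10)
  norm <- lognormalize_spots(g, 1e4)
  direct <- log1p(sweep(g$counts, 2, colSums(g$counts), "/") * 1e4)
  expect_equal(unname(norm), unname(direct), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a spot with one expressed gene hits log1p(scale_target)
  g2 <- toy_grid(rep("t", 2), ng = 5)
  g2$counts[, 1] <- c(7L, 0L, 0L, 0L, 0L)
  expect_equal(lognormalize_spots(g2, 1e4)[1, 1], log1p(1e4),
               tolerance = 1e-12, ignore_attr = TRUE)
  # uniform doubling cancels
  g3 <- g
  g3$counts <- g$counts * 2L
  expect_equal(lognormalize_spots(g3, 1e4), lognormalize_spots(g, 1e4),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("local correlation matches a brute-force weighted loop and its limits", {
  set.seed(12)
  g <- toy_grid(rep("t", 25), pitch = 100)
  a <- setNames(rnorm(25), g$spots$spot_id)
  b <- setNames(rnorm(25) + 0.5 * a, g$spots$spot_id)

  # identical maps: coefficient 1 wherever defined
  self <- weighted_local_correlation(g, a, a, bandwidth = 2)
  expect_true(all(abs(self$local[!is.na(self$local)] - 1) < 1e-12))

  # brute-force oracle, bisquare, bandwidth 2
  got <- weighted_local_correlation(g, a, b, bandwidth = 2,
                                    kernel = "bisquare")
  d <- as.matrix(dist(cbind(g$spots$x_um, g$spots$y_um)))
  for (i in c(1, 7, 13, 25)) {
    w <- pmax(1 - (d[i, ] / 200)^2, 0)^2 * (d[i, ] < 200)
    expect_equal(unname(got$local[i]), oracle_weighted_cor(a, b, w),
                 tolerance = 1e-12)
  }

  # huge gaussian bandwidth: every local coefficient -> global correlation
  wide <- weighted_local_correlation(g, a, b, bandwidth = 1e6,
                                     kernel = "gaussian")
  expect_true(all(abs(wide$local - cor(a, b)) < 1e-6))

  # rank transform reproduces global Spearman in the same limit
  sp <- weighted_local_correlation(g, a, b, bandwidth = 1e6,
                                   kernel = "gaussian",
                                   rank_transform = TRUE)
  expect_true(all(abs(sp$local - cor(a, b, method = "spearman")) < 1e-6))
})

test_that("region association drops sparse labels, finds planted shifts, and nulls out", {
  set.seed(3)
  labels <- c(rep("normal lung", 60), rep("solid", 60), rep("rare", 10))
  grids <- lapply(1:3, function(i) {
    g <- toy_grid(labels, seed = i, sample_id = paste0("s", i))
    g$spots$spot_id <- paste0("s", i, "_", g$spots$spot_id)
    colnames(g$counts) <- g$spots$spot_id
    g
  })
  big <- spot_grid(do.call(cbind, lapply(grids, `[[`, "counts")),
                   do.call(rbind, lapply(grids, `[[`, "spots")))
  vals <- setNames(rnorm(nrow(big$spots)), big$spots$spot_id)
  vals[big$spots$label == "solid"] <- vals[big$spots$label == "solid"] + 2

  res <- suppressMessages(region_association(big, vals, "normal lung",
                                             downsample_n = 50, seed = 1))
  expect_false("rare" %in% res$label)            # < 50 spots -> dropped
  expect_gt(res$estimate[res$label == "solid"], 1)
  expect_lt(res$padj[res$label == "solid"], 0.01)

  # constant values: estimates 0, adjusted p 1
  const <- setNames(rep(1, nrow(big$spots)), big$spots$spot_id)
  res0 <- suppressMessages(region_association(big, const, "normal lung",
                                              downsample_n = 50, seed = 1))
  expect_true(all(res0$estimate == 0) && all(res0$padj == 1))

  # downsampling off: deterministic result
  r1 <- suppressMessages(region_association(big, vals, "normal lung",
                                            downsample_n = Inf, seed = 1))
  r2 <- suppressMessages(region_association(big, vals, "normal lung",
                                            downsample_n = Inf, seed = 99))
  expect_identical(r1, r2)

  expect_error(suppressMessages(
    region_association(big, vals, "absent", downsample_n = 50)),
    "reference label")
})

test_that("the high-grade VI contrast recovers planted shifts and stays null-calibrated", {
  set.seed(8)
  labels <- c(rep("solid", 40), rep("normal lung", 20))
  build <- function(n_samp, shift_vi) {
    grids <- lapply(seq_len(n_samp), function(i) {
      g <- toy_grid(labels, seed = 50 + i, sample_id = paste0("t", i))
      g
    })
    big <- spot_grid(do.call(cbind, lapply(grids, `[[`, "counts")),
                     do.call(rbind, lapply(grids, `[[`, "spots")))
    vi <- setNames(rep_len(c(1, 0), n_samp), paste0("t", seq_len(n_samp)))
    vals <- setNames(rnorm(nrow(big$spots)), big$spots$spot_id)
    sel <- big$spots$label == "solid" & vi[big$spots$sample_id] == 1
    vals[sel] <- vals[sel] + shift_vi
    list(grid = big, vals = vals, vi = vi)
  }
  planted <- build(6, 1)
  res <- highgrade_vi_contrast(planted$grid, planted$vals,
                               vi_status = planted$vi)
  expect_gt(res$estimate, 0.5)
  expect_lt(res$pval, 0.01)

  # null: identically generated VI+ and VI- samples, 20 seeded replicates
  null_p <- vapply(1:20, function(r) {
    set.seed(100 + r)
    nn <- build(6, 0)
    nn$vals <- setNames(rnorm(nrow(nn$grid$spots)), nn$grid$spots$spot_id)
    suppressMessages(highgrade_vi_contrast(nn$grid, nn$vals,
                                           vi_status = nn$vi)$pval)
  }, numeric(1))
  expect_gt(min(null_p), 0.001)
  expect_gt(mean(null_p > 0.05), 0.7)            # no systematic inflation

  no_hg <- toy_grid(rep("normal lung", 9))
  expect_error(highgrade_vi_contrast(no_hg, setNames(rnorm(9),
                                                     no_hg$spots$spot_id),
                                     vi_status = c(s1 = 1)),
               "empty stratum")
})

test_that("distance binning follows the 1-mm rule and its conventions", {
  # 100-um pitch row of spots, focus at the origin
  n <- 15
  counts <- matrix(1L, 2, n, dimnames = list(c("gA", "gB"),
                                             sprintf("sp%02d", 1:n)))
  spots <- data.frame(spot_id = colnames(counts),
                      x_um = (0:(n - 1)) * 100, y_um = 0,
                      label = c("VI focus", rep("tumor", n - 1)),
                      sample_id = "s1", stringsAsFactors = FALSE)
  g <- spot_grid(counts, spots)
  bins <- distance_bins(g, "VI focus", 1000)
  expect_identical(as.character(bins[["sp01"]]), "proximal")  # distance 0
  expect_identical(as.character(bins[["sp11"]]), "proximal")  # 1000 um
  expect_identical(as.character(bins[["sp12"]]), "distal")    # 1100 um
  # monotone in the threshold: no proximal spot becomes distal
  wider <- distance_bins(g, "VI focus", 1200)
  expect_true(all(wider[bins == "proximal"] == "proximal"))
  # sample without any focus: everything proximal
  g2 <- g
  g2$spots$label <- "tumor"
  expect_true(all(distance_bins(g2, "VI focus", 1000) == "proximal"))
})

test_that("cell-type presence filtering uses the ceil-fraction rule", {
  pred <- rbind(everywhere = rep(5, 15),
                sparse = c(1, 1, rep(0, 13)),
                edge = c(1, 1, 1, rep(0, 12)))
  colnames(pred) <- sprintf("s%02d", 1:15)
  kept <- celltype_presence_filter(pred, 0.20)   # needs ceil(3) = 3
  expect_true("everywhere" %in% kept)
  expect_false("sparse" %in% kept)               # present in 2 < 3
  expect_true("edge" %in% kept)                  # exactly 3
  expect_identical(celltype_presence_filter(pred, 1e-9),
                   rownames(pred))
  expect_error(celltype_presence_filter(pred - 2, 0.2), ">= 0")
})

test_that("pseudo-bulk of a planted grid tracks a matched bulk profile", {
  d <- sim_design(n_genes = 300L, n_samples = 20L)
  bulk <- suppressMessages(generate_bulk_cohort(d, seed = 5))
  sg <- suppressWarnings(suppressMessages(
    generate_spot_grid(d, seed = 5, baseline = bulk$truth$baseline)))
  pseudo <- rowSums(sg$grid$counts)
  bulk_mean <- rowMeans(suppressMessages(logcpm(bulk$counts)))
  common <- intersect(names(pseudo), names(bulk_mean))
  rho <- cor(log1p(pseudo[common]), bulk_mean[common], method = "spearman")
  expect_gt(rho, 0.95)
})
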