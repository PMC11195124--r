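test_that("cluster quotas follow largest-remainder apportionment", {
  # shares 60/20/10/10% of 48: floors 28/9/4/4, remainders .8/.6/.8/.8
  expect_identical(largest_remainder(c(60L, 20L, 10L, 10L),
                                     c(0.6, 0.2, 0.1, 0.1), 48L),
                   c(29L, 9L, 5L, 5L))
  # quotas always sum to the panel and never exceed availability
  set.seed(2)
  for (i in 1:25) {
    avail <- rmultinom(1, 150, runif(4, 0.05, 1))[, 1] + 1L
    q <- largest_remainder(avail, avail / sum(avail), 48L)
    expect_identical(sum(q), 48L)
    expect_true(all(q <= avail))
  }
  expect_error(largest_remainder(c(10L, 10L), c(0.5, 0.5), 48L),
               "availability")
})

fake_de <- function(n, sig_n, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", 1:n)
  p <- runif(n, 0.2, 1)
  p[1:sig_n] <- runif(sig_n, 1e-8, 1e-4)
  data.frame(gene = genes, PValue = p, FDR = bh_fdr(p),
             logFC = rnorm(n), stringsAsFactors = FALSE)
}

fake_clusters <- function(genes, memb) {
  structure(list(genes = data.frame(gene = genes, cluster = memb,
                                    direction = "up",
                                    stringsAsFactors = FALSE),
                 sizes = as.integer(table(factor(memb, 1:4))), k = 4L),
            class = "signature_clusters")
}

test_that("feature selection is cluster-proportional with p-value ordering", {
  de <- fake_de(200, 100)
  memb <- rep_len(c(1, 1, 1, 1, 1, 1, 2, 2, 3, 4), 200)
  cl <- fake_clusters(de$gene, memb)
  panel <- select_features(de, cl, panel_size = 48, fdr_threshold = 0.01)
  expect_length(panel, 48)
  quota <- attr(panel, "quota")
  expect_identical(sum(quota), 48L)
  sig <- de$gene[de$FDR < 0.01]
  shares <- table(factor(memb[match(sig, de$gene)], 1:4)) / length(sig)
  expect_true(all(abs(quota - 48 * as.numeric(shares)) <= 1))
  # within each cluster, the selected genes are the smallest p-values
  for (j in 1:4) {
    cand <- sig[memb[match(sig, de$gene)] == j]
    best <- cand[order(de$PValue[match(cand, de$gene)])][seq_len(quota[j])]
    expect_setequal(intersect(panel, cand), best)
  }
  # exactly panel-size significant genes: all selected
  de48 <- fake_de(100, 48)
  cl48 <- fake_clusters(de48$gene, rep_len(1:4, 100))
  expect_setequal(select_features(de48, cl48, 48), de48$gene[1:48])
  # single cluster: top-48 by p
  clA <- fake_clusters(de$gene, rep(1, 200))
  pA <- select_features(de, clA, 48)
  expect_setequal(pA, de$gene[order(de$PValue)][1:48])
  expect_error(select_features(fake_de(100, 10), cl, 48), "significant")
})

test_that("ridge logit matches unpenalized MLE at lambda 0 and shrinks to prevalence", {
  set.seed(7)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, -0.5, 0)))
  Z <- scale(X)
  b0 <- visig:::ridge_irls(Z, y, 0)
  mle <- coef(glm(y ~ Z, family = binomial()))
  expect_equal(unname(b0), unname(mle), tolerance = 1e-4)

  bInf <- visig:::ridge_irls(Z, y, 1e8)
  expect_lt(max(abs(bInf[-1])), 1e-5)
  expect_equal(plogis(bInf[1]), mean(y), tolerance = 1e-4)
})

test_that("training recovers a planted 2-gene signal out of sample", {
  set.seed(30)
  n <- 200
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, sprintf("g%02d", 1:10)))
  y <- rbinom(n, 1, plogis(2 * x[, 1] - 2 * x[, 2]))
  train <- 1:140; test <- 141:200
  m <- train_ridge_logit(x[train, ], y[train], inner_folds = 5, seed = 1)
  expr_test <- t(x[test, ])
  auc <- auroc(predict_scores(m, expr_test), y[test])$auroc
  expect_gte(auc, 0.9)
  # the planted genes carry the largest standardized coefficients
  imp <- feature_importance(m)
  expect_setequal(imp$gene[1:2], c("g01", "g02"))
  expect_error(train_ridge_logit(x, rep(1, n)), "both classes")
})

test_that("AUROC equals exhaustive pair counting, with ties and bootstrap", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 0, 1, 0)
  got <- auroc(scores, labels, n_boot = 200, seed = 1)
  expect_equal(got$auroc, oracle_auroc(scores, labels))
  expect_true(got$ci[1] <= got$auroc && got$auroc <= got$ci[2])
  # equals the normalized Mann-Whitney U on random fixtures
  set.seed(10)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.05), 30, replace = TRUE)
    l <- rbinom(30, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(auroc(s, l)$auroc, oracle_auroc(s, l))
  }
  # perfect separation and the null
  expect_equal(auroc(c(3, 2, 1, 0), c(1, 1, 0, 0))$auroc, 1)
  set.seed(11)
  null_auc <- auroc(rnorm(1000), rbinom(1000, 1, 0.5))$auroc
  expect_lt(abs(null_auc - 0.5), 0.05)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("prediction applies the logistic model exactly", {
  model <- structure(list(genes = c("gA", "gB"),
                          mean = c(gA = 1, gB = 2), sd = c(gA = 2, gB = 4),
                          intercept = -0.5,
                          coefficients = c(gA = 1.2, gB = -0.7),
                          lambda = 1), class = "vi_predictor")
  expr <- matrix(c(3, 0,
                   6, 2), 2, 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("s1", "s2")))
  z <- (expr - c(1, 2)) / c(2, 4)
  hand <- plogis(-0.5 + 1.2 * z["gA", ] - 0.7 * z["gB", ])
  expect_equal(predict_scores(model, expr), hand, tolerance = 1e-12)
  model0 <- model
  model0$coefficients[] <- 0
  expect_equal(unname(predict_scores(model0, expr)),
               rep(plogis(-0.5), 2), tolerance = 1e-12)
  expect_error(predict_scores(model, expr[1, , drop = FALSE]), "missing")
})

test_that("feature importance handles ties and detects rank concentration", {
  m <- structure(list(coefficients = c(a = 0, b = 0, c = 0.9, d = 0)),
                 class = "vi_predictor")
  expect_identical(feature_importance(m)$gene[1], "c")

  # all-equal coefficients: exact tie handling gives KS p = 1
  genes <- sprintf("g%02d", 1:16)
  m2 <- structure(list(coefficients = setNames(rep(0.5, 16), genes)),
                  class = "vi_predictor")
  cl <- fake_clusters(genes, rep_len(1:4, 16))
  ks <- attr(feature_importance(m2, cl), "cluster_ks")
  expect_true(all(ks$pval == 1))

  # one cluster occupying the top ranks is detected
  coefs <- setNames(c(seq(2, 1.6, length.out = 4), runif(12, 0, 0.5)),
                    genes)
  m3 <- structure(list(coefficients = coefs), class = "vi_predictor")
  cl3 <- fake_clusters(genes, c(rep(1, 4), rep_len(2:4, 12)))
  ks3 <- attr(feature_importance(m3, cl3), "cluster_ks")
  expect_lt(ks3$pval[ks3$cluster == 1], 0.05)
  # matches a direct two-sample KS computation
  rk <- rank(-abs(coefs))
  direct <- suppressWarnings(ks.test(rk[1:4], rk[5:16]))
  expect_equal(ks3$D[ks3$cluster == 1], unname(direct$statistic))
})

nested_fixture <- function(n_genes = 120L, n_samples = 60L, effect = 1.5,
                           seed = 17) {
  d <- sim_design(n_genes = n_genes, n_samples = n_samples,
                  effect_log2fc = c(effect, effect, effect, -effect))
  sim <- suppressMessages(generate_bulk_cohort(d, seed = seed))
  counts <- suppressMessages(filter_genes(sim$counts))
  list(counts = counts, samples = sim$samples, truth = sim$truth)
}

test_that("nested CV is deterministic and leak-free", {
  fx <- nested_fixture()
  cfg <- pipeline_config(panel_size = 16L, outer_iters = 2L,
                         inner_folds = 3L)
  cv1 <- suppressMessages(nested_cv(fx$counts, fx$samples, cfg, seed = 5))
  cv2 <- suppressMessages(nested_cv(fx$counts, fx$samples, cfg, seed = 5))
  expect_identical(cv1$iterations, cv2$iterations)
  expect_identical(cv1$panels, cv2$panels)
  expect_equal(cv1$models[[1]]$coefficients, cv2$models[[1]]$coefficients)
  expect_equal(nrow(cv1$iterations), 2)
  expect_true(all(lengths(cv1$panels) == 16))

  # corrupting outer-test labels never changes the trained models
  splits <- list(visig:::stratified_split(fx$samples$vi, 0.7,
                                          stage_seed(5, "outer_split", 1)))
  cfg1 <- pipeline_config(panel_size = 16L, outer_iters = 1L,
                          inner_folds = 3L)
  cv_a <- suppressMessages(nested_cv(fx$counts, fx$samples, cfg1, seed = 5,
                                     splits = splits))
  corrupted <- fx$samples
  test_idx <- setdiff(seq_len(nrow(corrupted)), splits[[1]])
  corrupted$vi[test_idx] <- 1L - corrupted$vi[test_idx]
  corrupted$grade[test_idx] <- ifelse(corrupted$vi[test_idx] == 1, "VI",
                                      "LMP")
  cv_b <- suppressMessages(nested_cv(fx$counts, corrupted, cfg1, seed = 5,
                                     splits = splits))
  expect_identical(cv_a$panels, cv_b$panels)
  expect_equal(cv_a$models[[1]]$coefficients,
               cv_b$models[[1]]$coefficients)
  expect_equal(cv_a$models[[1]]$intercept, cv_b$models[[1]]$intercept)
})
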