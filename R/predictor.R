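#' Cluster-proportional feature selection
#'
#' Selects exactly `panel_size` genes so that each signature cluster
#' contributes in proportion to its share of the significant genes.
#' Fractional quotas are integerized by the largest-remainder method,
#' capped at each cluster's availability with the shortfall redistributed
#' the same way; within a cluster, genes are taken in ascending p-value
#' order (ties broken by descending `|logFC|`, then identifier).
#'
#' @param de Differential-expression result (`gene`, `PValue`, `logFC`,
#'   `FDR`).
#' @param clusters A [cluster_signature()] result covering the candidate
#'   genes.
#' @param panel_size Panel size (default 48).
#' @param fdr_threshold Significance cut defining the candidate pool
#'   (default 0.01).
#' @param genes Optional explicit candidate pool overriding the FDR rule.
#' @return Character vector of `panel_size` genes with a `quota`
#'   attribute.
#' @export
select_features <- function(de, clusters, panel_size = 48L,
                            fdr_threshold = 0.01, genes = NULL) {
  if (is.null(genes)) {
    genes <- de$gene[!is.na(de$FDR) & de$FDR < fdr_threshold]
    if (length(genes) < panel_size)
      stop("only ", length(genes), " significant genes at FDR < ",
           fdr_threshold, "; need ", panel_size)
  }
  if (length(genes) < panel_size)
    stop("candidate pool (", length(genes), ") smaller than panel_size")
  memb <- clusters$genes[match(genes, clusters$genes$gene), "cluster"]
  if (anyNA(memb)) stop("candidate gene(s) missing from the cluster map")
  k <- clusters$k
  avail <- vapply(seq_len(k), function(j) sum(memb == j), integer(1))
  quota <- largest_remainder(avail, avail / sum(avail), panel_size)

  de_sub <- de[match(genes, de$gene), ]
  selected <- character(0)
  for (j in seq_len(k)) {
    in_j <- which(memb == j)
    ord <- in_j[order(de_sub$PValue[in_j], -abs(de_sub$logFC[in_j]),
                      genes[in_j])]
    selected <- c(selected, genes[ord[seq_len(quota[j])]])
  }
  structure(selected, quota = quota)
}

# largest-remainder apportionment of `total` seats under per-class caps
largest_remainder <- function(avail, share, total) {
  if (sum(avail) < total) stop("availability below requested total")
  ideal <- share * total
  q <- pmin(floor(ideal), avail)
  frac <- ideal - floor(ideal)
  while ((rem <- total - sum(q)) > 0) {
    cand <- which(q < avail)
    ord <- cand[order(-frac[cand], -avail[cand], cand)]
    take <- ord[seq_len(min(rem, length(ord)))]
    q[take] <- q[take] + 1L
  }
  as.integer(q)
}

# ridge-penalized logistic IRLS: minimizes -loglik + lambda/2 * sum(beta^2)
# over standardized features; the intercept is unpenalized
ridge_irls <- function(X, y, lambda, maxit = 100L, tol = 1e-10) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- c(0, rep(lambda, p - 1))
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(Xi, Xi * w)
    diag(H) <- diag(H) + pen
    beta_new <- drop(solve(H, crossprod(Xi, w * z)))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new; break
    }
    beta <- beta_new
  }
  beta
}

# seeded stratified fold assignment
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train a ridge-penalized binomial-logit predictor
#'
#' Features are standardized by training mean/SD; the L2-penalized
#' log-likelihood (intercept unpenalized) is maximized by iteratively
#' reweighted least squares; the penalty is chosen to maximize the mean
#' held-out AUROC over seeded stratified inner folds (ties resolved
#' toward the stronger penalty), and the final model is refitted on all
#' training samples at the chosen penalty.
#'
#' @param x Sample x gene expression matrix (training data).
#' @param y Binary labels (0/1), both classes present.
#' @param lambda_grid Candidate penalties (default 30 points log-spaced in
#'   `[1e-3, 1e3]`).
#' @param inner_folds Inner CV folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return Object of class `"vi_predictor"`: `genes`, `mean`, `sd`,
#'   `intercept`, `coefficients` (on the standardized scale), `lambda`,
#'   `inner_cv` (per-penalty mean AUROC), `training_auroc`.
#' @export
train_ridge_logit <- function(x, y,
                              lambda_grid = 10^seq(-3, 3, length.out = 30),
                              inner_folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required for training")
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(x, 2, mu), 2, sd_, "/")

  fold <- stratified_folds(y, inner_folds, stage_seed(seed, "inner_folds"))
  cv_auc <- vapply(lambda_grid, function(lam) {
    mean(vapply(seq_len(inner_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2)
        return(NA_real_)
      b <- ridge_irls(Z[tr, , drop = FALSE], y[tr], lam)
      pred <- drop(cbind(1, Z[!tr, , drop = FALSE]) %*% b)
      auroc(pred, y[!tr])$auroc
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- max(which(cv_auc == max(cv_auc)))      # ties -> stronger penalty
  lambda <- lambda_grid[best]
  beta <- ridge_irls(Z, y, lambda)
  fitted <- drop(cbind(1, Z) %*% beta)
  model <- structure(list(
    genes = colnames(x),
    mean = mu, sd = sd_,
    intercept = unname(beta[1]),
    coefficients = stats::setNames(beta[-1], colnames(x)),
    lambda = lambda,
    inner_cv = data.frame(lambda = lambda_grid, mean_auroc = cv_auc),
    training_auroc = auroc(fitted, y)$auroc), class = "vi_predictor")
  model
}

#' @export
#' @method print vi_predictor
print.vi_predictor <- function(x, ...) {
  cat(sprintf("vi_predictor: %d genes, lambda = %.4g, training AUROC = %.3f\n",
              length(x$genes), x$lambda, x$training_auroc))
  invisible(x)
}

#' Score samples with a fitted VI predictor
#'
#' `logistic(intercept + sum(coef * standardized expression))`, with the
#' model's own training standardization. Cross-cohort matrices should be
#' harmonized with [reference_batch_adjust()] first.
#'
#' @param model A `vi_predictor`.
#' @param expr Gene x sample log-expression matrix containing every panel
#'   gene.
#' @return Named per-sample probability scores in (0, 1).
#' @export
predict_scores <- function(model, expr) {
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing) > 0)
    stop("panel gene(s) missing from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  z <- (expr[model$genes, , drop = FALSE] - model$mean) / model$sd
  stats::plogis(model$intercept + drop(crossprod(z, model$coefficients)))
}

#' AUROC with bootstrap confidence interval
#'
#' Pairwise-concordance AUROC (ties get half credit; equals the
#' normalized Mann-Whitney U), a percentile bootstrap 95% CI over seeded
#' resamples of (score, label) pairs, and the Wilcoxon rank-sum p-value
#' against AUROC = 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @param n_boot Bootstrap replicates (0 disables the CI).
#' @param seed Integer seed.
#' @return List: `auroc`, `ci` (length-2 or `NULL`), `pval`, `n_pos`,
#'   `n_neg`.
#' @export
auroc <- function(scores, labels, n_boot = 0L, seed = 1L) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required")
  est <- auroc_stat(scores, labels)
  ci <- NULL
  if (n_boot > 0) {
    set.seed(stage_seed(seed, "auroc_boot"))
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(labels), replace = TRUE)
      if (length(unique(labels[idx])) < 2) return(NA_real_)
      auroc_stat(scores[idx], labels[idx])
    }, numeric(1))
    ci <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  }
  pv <- suppressWarnings(stats::wilcox.test(scores[labels == 1],
                                            scores[labels == 0])$p.value)
  list(auroc = est, ci = ci, pval = pv, n_pos = n_pos, n_neg = n_neg)
}

auroc_stat <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Nested cross-validation of the VI predictor
#'
#' For each of `outer_iters` seeded stratified 70/30 splits: differential
#' expression, Ward clustering, and cluster-proportional feature
#' selection are re-run on the outer training set only; the ridge penalty
#' is chosen by inner-fold AUROC; the fitted model is evaluated once on
#' the untouched outer test set. If a training split yields fewer
#' significant genes than the panel size, the pool falls back to the top
#' `panel_size` genes by p-value (logged). Splits lacking a class are
#' resampled (seeded); more than 50 consecutive failures is an error.
#'
#' @param counts Filtered gene x sample count matrix.
#' @param samples Sample table with `grade` and `vi` columns.
#' @param config A [pipeline_config()].
#' @param seed Integer seed.
#' @param outer_iters Override of `config$outer_iters` (smaller runs for
#'   calibration studies).
#' @param splits Optional list of precomputed training-index vectors (one
#'   per iteration), bypassing the internal splitter.
#' @return Object of class `"cv_result"`: `iterations` data frame
#'   (`iter`, `n_significant`, `lambda`, `inner_auroc`, `test_auroc`),
#'   `panels` (list of selected gene vectors), `models` (list of
#'   `vi_predictor`s), and `summary` (mean/SD of test AUROC).
#' @export
nested_cv <- function(counts, samples, config = pipeline_config(),
                      seed = 1L, outer_iters = NULL, splits = NULL) {
  y <- as.integer(samples$vi)
  n <- length(y)
  iters <- if (is.null(outer_iters)) config$outer_iters else
    as.integer(outer_iters)
  rows <- vector("list", iters)
  panels <- models <- vector("list", iters)
  for (i in seq_len(iters)) {
    if (!is.null(splits)) {
      train <- splits[[i]]
    } else {
      train <- stratified_split(y, config$outer_train_frac,
                                stage_seed(seed, "outer_split", i))
    }
    test <- setdiff(seq_len(n), train)
    f_train <- tmm_factors(counts[, train, drop = FALSE])
    de <- suppressMessages(run_de(counts[, train, drop = FALSE],
                                  samples[train, , drop = FALSE],
                                  factors = f_train))
    sig <- de$gene[!is.na(de$FDR) & de$FDR < config$fdr_threshold]
    if (length(sig) < config$panel_size) {
      vi_log("nested_cv", "iter %d: %d significant genes < panel size; %s",
             i, length(sig), "falling back to top genes by p-value")
      sig <- de$gene[order(de$PValue)][seq_len(config$panel_size)]
    }
    expr_train <- logcpm(counts[, train, drop = FALSE], f_train)
    cl <- suppressMessages(cluster_signature(
      expr_train[sig, , drop = FALSE],
      stats::setNames(de$logFC, de$gene), k = config$n_clusters))
    panel <- select_features(de, cl, panel_size = config$panel_size,
                             fdr_threshold = config$fdr_threshold,
                             genes = sig)
    model <- train_ridge_logit(t(expr_train[panel, , drop = FALSE]),
                               y[train],
                               lambda_grid = config$ridge_lambda_grid,
                               inner_folds = config$inner_folds,
                               seed = stage_seed(seed, "inner", i))
    expr_test <- logcpm(counts[, test, drop = FALSE],
                        tmm_factors(counts[, test, drop = FALSE]))
    test_auc <- auroc(predict_scores(model, expr_test), y[test])$auroc
    rows[[i]] <- data.frame(iter = i, n_significant = length(sig),
                            lambda = model$lambda,
                            inner_auroc = max(model$inner_cv$mean_auroc),
                            test_auroc = test_auc)
    panels[[i]] <- panel
    models[[i]] <- model
  }
  iterations <- do.call(rbind, rows)
  vi_log("nested_cv", "%d iterations, mean test AUROC %.3f", iters,
         mean(iterations$test_auroc))
  structure(list(iterations = iterations, panels = panels, models = models,
                 summary = c(mean = mean(iterations$test_auroc),
                             sd = stats::sd(iterations$test_auroc))),
            class = "cv_result")
}

# seeded stratified split; returns training indices, guaranteeing both
# classes in both parts (resamples up to 50 times)
stratified_split <- function(y, train_frac, seed) {
  for (attempt in 0:50) {
    set.seed(seed + attempt)
    train <- unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, max(1L, round(train_frac * length(idx))))
    }))
    test <- setdiff(seq_along(y), train)
    if (length(unique(y[train])) == 2 && length(unique(y[test])) == 2) {
      if (attempt > 0)
        vi_log("nested_cv", "split resampled %d time(s)", attempt)
      return(sort(train))
    }
  }
  stop("could not produce a stratified split with both classes")
}

#' Feature importance and cluster rank enrichment
#'
#' Ranks the panel genes by the magnitude of their standardized
#' coefficients and, per cluster, tests by two-sample two-sided
#' Kolmogorov-Smirnov whether the cluster's genes sit unusually high or
#' low in the ranking relative to the remaining panel genes.
#'
#' @param model A `vi_predictor`.
#' @param clusters Optional [cluster_signature()] result covering the
#'   panel.
#' @return Data frame `gene`, `coefficient`, `rank` (1 = most important),
#'   plus, when `clusters` is given, an attribute `cluster_ks` with
#'   per-cluster KS statistics and p-values.
#' @export
feature_importance <- function(model, clusters = NULL) {
  imp <- abs(model$coefficients)
  ord <- order(-imp, names(imp))
  out <- data.frame(gene = names(imp)[ord],
                    coefficient = unname(model$coefficients[ord]),
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    rk <- rank(-imp)                                   # midranks under ties
    memb <- clusters$genes$cluster[match(names(imp), clusters$genes$gene)]
    ks <- lapply(sort(unique(memb[!is.na(memb)])), function(j) {
      a <- rk[which(memb == j)]
      b <- rk[which(memb != j)]
      if (length(a) == 0 || length(b) == 0)
        return(data.frame(cluster = j, D = NA, pval = NA))
      kt <- suppressWarnings(stats::ks.test(a, b))
      data.frame(cluster = j, D = unname(kt$statistic), pval = kt$p.value)
    })
    attr(out, "cluster_ks") <- do.call(rbind, ks)
  }
  out
}
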