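#' Simulation design for synthetic VI cohorts
#'
#' Describes the statistical structure every generator in the package
#' shares: negative-binomial counts (mean \eqn{\mu}, dispersion \eqn{\phi},
#' variance \eqn{\mu + \phi\mu^2}) with four planted gene modules whose
#' sizes default to the derived signature's cluster sizes (115/37/182/140),
#' three modules elevated and one suppressed in VI tumors, an attenuated
#' effect in NST tumors, a two-site additive batch shift on the log mean,
#' and per-sample module-level latent noise that gives each planted module
#' its own co-expression structure.
#'
#' @param n_genes Total genes simulated.
#' @param n_samples Samples in a bulk cohort.
#' @param grade_probs Probabilities of grades LMP, NST, VI (sum to 1).
#' @param cluster_sizes Sizes of the four planted modules.
#' @param effect_log2fc Signed per-module log2 fold change in VI vs LMP.
#' @param nst_attenuation Fraction of the VI effect expressed in NST.
#' @param module_sd SD of the per-sample, per-module latent activity
#'   (natural-log scale); this is what makes the planted modules
#'   recoverable as co-expression clusters.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   gene-wise NB dispersion.
#' @param libsize_logmean,libsize_logsd Log-normal library-size parameters.
#' @param batch_shift_logsd SD of the per-gene additive log-mean shift in
#'   the second collection site.
#' @param li_given_vi,li_given_novi Conditional probabilities of lymphatic
#'   invasion given VI status.
#' @param region_noise_sd SD of the region-level perturbation around the
#'   tumor latent score in multi-region tumors.
#' @param spot_pitch_um Center-to-center spot spacing of simulated grids.
#' @param spot_libsize Expected total counts per spot.
#' @return A validated list of class `"sim_design"`.
#' @export
sim_design <- function(n_genes = 2000L, n_samples = 100L,
                       grade_probs = c(LMP = 0.22, NST = 0.54, VI = 0.24),
                       cluster_sizes = NULL,
                       effect_log2fc = c(1, 1, 1, -1),
                       nst_attenuation = 0.4,
                       module_sd = 0.35,
                       dispersion_meanlog = log(0.1), dispersion_sdlog = 0.5,
                       libsize_logmean = log(2e6), libsize_logsd = 0.25,
                       batch_shift_logsd = 0.1,
                       li_given_vi = 0.6, li_given_novi = 0.15,
                       region_noise_sd = 0.25,
                       spot_pitch_um = 100, spot_libsize = 8000) {
  d <- as.list(environment())
  d$n_genes <- as.integer(n_genes); d$n_samples <- as.integer(n_samples)
  if (is.null(cluster_sizes)) {
    # signature cluster sizes at the 2000-gene reference scale, scaled
    # proportionally with the simulated transcriptome size
    cluster_sizes <- pmax(1L, round(c(115, 37, 182, 140) * d$n_genes / 2000))
  }
  d$cluster_sizes <- as.integer(cluster_sizes)
  if (abs(sum(grade_probs) - 1) > 1e-8) stop("grade_probs must sum to 1")
  if (length(d$cluster_sizes) != 4L || length(effect_log2fc) != 4L)
    stop("four planted modules are required")
  if (sum(d$cluster_sizes) > d$n_genes)
    stop("cluster sizes (", sum(d$cluster_sizes), ") exceed n_genes (",
         d$n_genes, ")")
  if (any(!is.finite(effect_log2fc))) stop("effect magnitudes must be finite")
  if (dispersion_sdlog < 0 || module_sd < 0 || region_noise_sd < 0)
    stop("noise SDs must be >= 0")
  structure(d, class = "sim_design")
}

# gene -> planted cluster map (0 = background gene); planted genes lead the
# gene order so fixtures are easy to inspect
planted_clusters <- function(design) {
  cl <- integer(design$n_genes)
  idx <- 1L
  for (j in 1:4) {
    n <- design$cluster_sizes[j]
    if (n > 0) cl[idx:(idx + n - 1L)] <- j
    idx <- idx + n
  }
  names(cl) <- sprintf("G%04d", seq_len(design$n_genes))
  cl
}

# shared count sampler: log-mean matrix -> NB counts scaled to library size
sample_counts <- function(log_rel, libsize, dispersion) {
  rel <- exp(log_rel)
  mu <- sweep(sweep(rel, 2, colSums(rel), "/"), 2, libsize, "*")
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow = nrow(mu), dimnames = dimnames(log_rel))
  storage.mode(cnt) <- "integer"
  cnt
}

#' Generate a synthetic bulk RNA-seq cohort
#'
#' Samples grades LMP/NST/VI, plants the four VI-associated modules
#' (clusters 1-3 up, cluster 4 down in VI, attenuated in NST, absent in
#' LMP), adds per-sample module-level latent activity, a two-site batch
#' shift, log-normal library sizes, and NB noise with gene-wise
#' dispersions. Lymphatic-invasion labels are drawn with the stated
#' conditional probabilities.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(design, seed)`.
#' @return List with `counts` (gene x sample integer matrix), `samples`
#'   (data frame: `sample_id`, `grade`, `vi`, `li`, `batch`), and `truth`
#'   (planted cluster map, per-sample latent VI score, baseline log
#'   abundances, dispersions).
#' @export
generate_bulk_cohort <- function(design, seed) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(stage_seed(seed, "bulk_cohort"))
  ng <- design$n_genes; ns <- design$n_samples
  cl <- planted_clusters(design)
  genes <- names(cl)
  samples <- sprintf("S%03d", seq_len(ns))

  grade <- sample(c("LMP", "NST", "VI"), ns, replace = TRUE,
                  prob = design$grade_probs)
  activity <- c(LMP = 0, NST = design$nst_attenuation, VI = 1)[grade]
  vi <- as.integer(grade == "VI")
  li <- stats::rbinom(ns, 1, ifelse(vi == 1, design$li_given_vi,
                                    design$li_given_novi))
  batch <- rep_len(c("siteA", "siteB"), ns)

  baseline <- stats::rnorm(ng, mean = 3, sd = 1.2)
  dispersion <- stats::rlnorm(ng, design$dispersion_meanlog,
                              design$dispersion_sdlog)
  libsize <- stats::rlnorm(ns, design$libsize_logmean, design$libsize_logsd)
  batch_shift <- stats::rnorm(ng, 0, design$batch_shift_logsd)

  eff <- log(2) * design$effect_log2fc        # natural-log per-module effect
  module_latent <- matrix(stats::rnorm(4L * ns, 0, design$module_sd), 4L, ns)

  log_rel <- matrix(baseline, ng, ns, dimnames = list(genes, samples))
  for (j in 1:4) {
    g <- which(cl == j)
    log_rel[g, ] <- log_rel[g, ] +
      rep(eff[j] * activity + module_latent[j, ], each = length(g))
  }
  log_rel[, batch == "siteB"] <- log_rel[, batch == "siteB"] +
    batch_shift

  counts <- sample_counts(log_rel, libsize, dispersion)
  vi_log("simulate", "bulk cohort: %d genes x %d samples (%d VI+)",
         ng, ns, sum(vi))
  list(counts = counts,
       samples = data.frame(sample_id = samples, grade = grade, vi = vi,
                            li = li, batch = batch, stringsAsFactors = FALSE),
       truth = list(gene_cluster = cl, latent_score = unname(activity),
                    baseline = stats::setNames(baseline, genes),
                    dispersion = stats::setNames(dispersion, genes),
                    module_latent = module_latent))
}

#' Default pathology layout for a simulated spot grid
#'
#' Paints rectangles and a small disc onto an `nx` by `ny` square lattice:
#' a normal-lung background, stroma and desmoplastic stroma bands, lepidic
#' and solid tumor blocks, and (optionally) a compact VI focus inside the
#' solid block.
#'
#' @param nx,ny Lattice dimensions in spots.
#' @param vi_focus Paint a VI focus?
#' @return A layout list consumed by [generate_spot_grid()].
#' @export
default_spot_layout <- function(nx = 20L, ny = 20L, vi_focus = TRUE) {
  paints <- list(
    list(label = "stroma", shape = "rect", x0 = 1, x1 = nx, y0 = 1,
         y1 = ceiling(ny * 0.15)),
    list(label = "lepidic", shape = "rect", x0 = 1, x1 = floor(nx * 0.4),
         y0 = ceiling(ny * 0.15) + 1, y1 = floor(ny * 0.6)),
    list(label = "desmoplastic stroma", shape = "rect",
         x0 = floor(nx * 0.4) + 1, x1 = floor(nx * 0.6),
         y0 = ceiling(ny * 0.15) + 1, y1 = floor(ny * 0.6)),
    list(label = "solid", shape = "rect", x0 = floor(nx * 0.6) + 1, x1 = nx,
         y0 = ceiling(ny * 0.15) + 1, y1 = floor(ny * 0.75))
  )
  if (vi_focus) {
    paints <- c(paints, list(list(label = "VI focus", shape = "disc",
                                  cx = floor(nx * 0.8), cy = floor(ny * 0.5),
                                  r = 1.6)))
  }
  list(nx = as.integer(nx), ny = as.integer(ny), background = "normal lung",
       paints = paints)
}

# per-label planted module activity (natural-log shift applied to the
# module's genes); VI focus carries the strongest cluster-1/3 elevation and
# the strongest cluster-4 suppression
region_module_activity <- function() {
  rbind("normal lung"          = c(0.0, 0.0, 0.0,  0.6),
        "stroma"               = c(0.0, 0.4, 0.0,  0.3),
        "desmoplastic stroma"  = c(0.0, 1.3, 0.2, -0.5),
        "lepidic"              = c(0.1, 0.0, 0.1,  0.5),
        "solid"                = c(0.9, 0.2, 0.9, -0.5),
        "micropapillary"       = c(0.8, 0.2, 0.8, -0.4),
        "cribriform"           = c(0.8, 0.2, 0.8, -0.4),
        "VI focus"             = c(1.5, 0.5, 1.6, -1.0))
}

#' Generate a synthetic spatial spot grid
#'
#' Lays spots on a square lattice at `spot_pitch_um` spacing, paints
#' pathology labels per `layout` (later paints overwrite earlier ones with
#' a warning), and draws NB counts whose planted-module log-means follow a
#' region-specific activity profile. For VI-positive samples an extra
#' elevation (`vi_bonus`) is added to modules 1-3 (and subtracted from
#' module 4) in high-grade regions, emulating tumor-wide angioinvasive
#' expression.
#'
#' @param design A [sim_design()].
#' @param layout Layout from [default_spot_layout()].
#' @param seed Integer seed.
#' @param sample_id Sample identifier stored per spot.
#' @param vi_positive Is the simulated tumor VI-positive?
#' @param vi_bonus Extra log-scale module activity in high-grade regions of
#'   VI-positive tumors.
#' @param baseline Optional per-gene baseline log abundances (defaults to a
#'   fresh draw), allowing spot grids matched to a bulk cohort's truth.
#' @return List with `grid` (a [spot_grid()]) and `truth` (planted cluster
#'   map, per-spot module activity matrix).
#' @export
generate_spot_grid <- function(design, layout = default_spot_layout(),
                               seed = 1L, sample_id = "sample1",
                               vi_positive = TRUE, vi_bonus = 0.5,
                               baseline = NULL) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(stage_seed(seed, paste0("spot_grid_", sample_id)))
  ng <- design$n_genes
  cl <- planted_clusters(design)
  genes <- names(cl)

  gx <- rep(seq_len(layout$nx), times = layout$ny)
  gy <- rep(seq_len(layout$ny), each = layout$nx)
  label <- rep(layout$background, length(gx))
  for (p in layout$paints) {
    inside <- if (p$shape == "rect") {
      gx >= p$x0 & gx <= p$x1 & gy >= p$y0 & gy <= p$y1
    } else {
      sqrt((gx - p$cx)^2 + (gy - p$cy)^2) <= p$r
    }
    if (any(inside & label != layout$background))
      warning("overlapping region paint for '", p$label, "'; later paint wins")
    label[inside] <- p$label
  }

  act <- region_module_activity()
  unknown <- setdiff(unique(label), rownames(act))
  if (length(unknown) > 0)
    stop("no module-activity profile for label(s): ",
         paste(unknown, collapse = ", "))
  A <- act[label, , drop = FALSE]                      # spots x 4
  highgrade <- label %in% c("solid", "micropapillary", "cribriform",
                            "VI focus")
  if (vi_positive && any(highgrade)) {
    A[highgrade, 1:3] <- A[highgrade, 1:3] + vi_bonus
    A[highgrade, 4] <- A[highgrade, 4] - vi_bonus
  }

  if (is.null(baseline)) baseline <- stats::rnorm(ng, 3, 1.2)
  dispersion <- stats::rlnorm(ng, design$dispersion_meanlog,
                              design$dispersion_sdlog)
  nspot <- length(gx)
  spot_ids <- sprintf("%s_spot%04d", sample_id, seq_len(nspot))
  log_rel <- matrix(baseline, ng, nspot, dimnames = list(genes, spot_ids))
  for (j in 1:4) {
    g <- which(cl == j)
    log_rel[g, ] <- log_rel[g, ] + rep(A[, j], each = length(g))
  }
  log_rel <- log_rel + stats::rnorm(length(log_rel), 0, 0.1)
  libsize <- stats::rlnorm(nspot, log(design$spot_libsize), 0.2)
  counts <- sample_counts(log_rel, libsize, dispersion)

  spots <- data.frame(spot_id = spot_ids,
                      x_um = (gx - 1) * design$spot_pitch_um,
                      y_um = (gy - 1) * design$spot_pitch_um,
                      label = label, sample_id = sample_id,
                      stringsAsFactors = FALSE)
  vi_log("simulate", "spot grid '%s': %d spots, labels: %s", sample_id,
         nspot, paste(sort(unique(label)), collapse = ", "))
  list(grid = spot_grid(counts, spots),
       truth = list(gene_cluster = cl, module_activity = A,
                    baseline = stats::setNames(baseline, genes)))
}

#' Generate a synthetic multi-region cohort
#'
#' Each tumor carries a latent VI score (standard normal); each region
#' expresses the planted modules at the tumor latent plus independent
#' region noise, so intra-tumor score differences are smaller than
#' inter-tumor ones whenever `region_noise_sd < 1`.
#'
#' @param design A [sim_design()].
#' @param n_tumors Number of tumors.
#' @param regions_per_tumor Regions sampled per tumor (>= 2).
#' @param seed Integer seed.
#' @return List with `counts` (gene x region), `samples` (data frame:
#'   `sample_id`, `tumor_id`, `region_id`), and `truth` (tumor latents,
#'   region scores, planted cluster map).
#' @export
generate_multiregion <- function(design, n_tumors = 63L,
                                 regions_per_tumor = 2L, seed = 1L) {
  stopifnot(inherits(design, "sim_design"))
  if (regions_per_tumor < 2L) stop("regions_per_tumor must be >= 2")
  set.seed(stage_seed(seed, "multiregion"))
  ng <- design$n_genes
  cl <- planted_clusters(design)
  genes <- names(cl)
  nreg <- n_tumors * regions_per_tumor

  tumor <- rep(sprintf("T%03d", seq_len(n_tumors)), each = regions_per_tumor)
  region <- rep(sprintf("R%d", seq_len(regions_per_tumor)), times = n_tumors)
  ids <- paste(tumor, region, sep = "_")

  latent <- stats::rnorm(n_tumors)
  score <- rep(latent, each = regions_per_tumor) +
    stats::rnorm(nreg, 0, design$region_noise_sd)

  baseline <- stats::rnorm(ng, 3, 1.2)
  dispersion <- stats::rlnorm(ng, design$dispersion_meanlog,
                              design$dispersion_sdlog)
  libsize <- stats::rlnorm(nreg, design$libsize_logmean, design$libsize_logsd)
  eff <- log(2) * design$effect_log2fc
  log_rel <- matrix(baseline, ng, nreg, dimnames = list(genes, ids))
  for (j in 1:4) {
    g <- which(cl == j)
    log_rel[g, ] <- log_rel[g, ] + rep(eff[j] * score, each = length(g))
  }
  counts <- sample_counts(log_rel, libsize, dispersion)
  vi_log("simulate", "multi-region cohort: %d tumors x %d regions",
         n_tumors, regions_per_tumor)
  list(counts = counts,
       samples = data.frame(sample_id = ids, tumor_id = tumor,
                            region_id = region, stringsAsFactors = FALSE),
       truth = list(gene_cluster = cl, tumor_latent =
                      stats::setNames(latent, unique(tumor)),
                    region_score = stats::setNames(score, ids)))
}

#' Generate proportional-hazards survival outcomes
#'
#' Event times are exponential with hazard
#' \eqn{\lambda_0 \exp(\beta \cdot \mathrm{score})}; censoring times are
#' independent Uniform(0, c), with c calibrated so the expected censoring
#' fraction equals `censor_rate`.
#'
#' @param scores Per-sample risk score (finite).
#' @param beta True log-hazard per unit score.
#' @param censor_rate Target fraction of censored samples in `[0, 1]`.
#' @param seed Integer seed.
#' @param baseline_hazard Baseline exponential hazard \eqn{\lambda_0}.
#' @return Data frame with columns `time` (> 0) and `event` (0/1), one row
#'   per score, plus the true `beta` as an attribute.
#' @export
generate_survival <- function(scores, beta, censor_rate = 0.3, seed = 1L,
                              baseline_hazard = 0.02) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  set.seed(stage_seed(seed, "survival"))
  lambda <- baseline_hazard * exp(beta * scores)
  t_event <- stats::rexp(length(scores), rate = lambda)
  if (censor_rate >= 1) {
    time <- pmax(t_event * stats::runif(length(scores)), 1e-8)
    return(structure(data.frame(time = time, event = 0L), beta = beta))
  }
  if (censor_rate <= 0) {
    return(structure(data.frame(time = t_event, event = 1L), beta = beta))
  }
  # censored <=> T > C; for C ~ Unif(0, cmax) and T ~ Exp(lambda):
  # P(T > C) = (1 - exp(-lambda * cmax)) / (lambda * cmax)
  frac_censored <- function(cmax) {
    mean((1 - exp(-lambda * cmax)) / (lambda * cmax)) - censor_rate
  }
  cmax <- stats::uniroot(frac_censored, lower = 1e-6,
                         upper = 1e6 / baseline_hazard)$root
  cens <- stats::runif(length(scores), 0, cmax)
  data.frame(time = pmin(t_event, cens),
             event = as.integer(t_event <= cens)) |>
    structure(beta = beta)
}
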