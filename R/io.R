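#' Read a gene-by-sample count matrix
#'
#' Supports the two plain-text layouts used throughout the pipeline: a TSV
#' with gene identifiers in the first column and sample identifiers in the
#' header, or a MatrixMarket triplet file accompanied by row-name and
#' column-name sidecar files (`<stem>.rownames.txt`, `<stem>.colnames.txt`,
#' one identifier per line).
#'
#' @param path File path (the `.mtx` file for `format = "mtx"`).
#' @param format Either `"tsv"` or `"mtx"`.
#' @return An integer matrix, genes in rows, samples in columns, identifiers
#'   preserved in file order.
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
  } else {
    stem <- sub("\\.mtx$", "", path)
    rn_path <- paste0(stem, ".rownames.txt")
    cn_path <- paste0(stem, ".colnames.txt")
    if (!file.exists(rn_path) || !file.exists(cn_path))
      stop("mtx triplet requires sidecar files: ", rn_path, ", ", cn_path)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(rn_path)
    cols <- readLines(cn_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cols))
      stop("mtx dimensions do not match sidecar name files")
    colnames(m) <- cols
  }
  check_duplicates(genes, "gene")
  check_duplicates(colnames(m), "sample")
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative or non-integer count entries at (row,col): ",
         paste(apply(utils::head(bad, 5), 1, paste, collapse = ","),
               collapse = "; "))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

check_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate ", what, " identifiers: ", paste(dup, collapse = ", "))
  invisible(ids)
}

#' Write a count matrix
#'
#' Inverse of [read_count_matrix()]; `format = "mtx"` writes the triplet
#' file plus the two name sidecars.
#'
#' @inheritParams read_count_matrix
#' @param counts Integer matrix with row and column names.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(stem, ".rownames.txt"))
    writeLines(colnames(counts), paste0(stem, ".colnames.txt"))
  }
  invisible(path)
}

#' Assemble a spot grid from its on-disk parts
#'
#' A spot grid is the package's Visium-like container: spot-by-gene counts,
#' spot coordinates in micrometers, and a pathology annotation per spot.
#'
#' @param counts_path TSV count matrix, genes in rows, spots in columns.
#' @param positions_path TSV with columns `spot_id`, `x_um`, `y_um` and
#'   optionally `sample_id`.
#' @param annotations_path Optional TSV with columns `spot_id`, `label`;
#'   spots absent from it are labeled `"unannotated"`.
#' @return A `spot_grid` object (see [spot_grid()]).
#' @export
read_spot_grid <- function(counts_path, positions_path, annotations_path = NULL) {
  counts <- read_count_matrix(counts_path, "tsv")
  pos <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing <- setdiff(colnames(counts), pos$spot_id)
  if (length(missing) > 0)
    stop(length(missing), " spot(s) present in counts but absent from positions")
  pos <- pos[match(colnames(counts), pos$spot_id), , drop = FALSE]
  label <- rep("unannotated", ncol(counts))
  if (!is.null(annotations_path) && file.exists(annotations_path)) {
    ann <- utils::read.table(annotations_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    hit <- match(colnames(counts), ann$spot_id)
    label[!is.na(hit)] <- ann$label[hit[!is.na(hit)]]
  }
  sample_id <- if ("sample_id" %in% names(pos)) pos$sample_id else "sample1"
  spot_grid(counts,
            data.frame(spot_id = colnames(counts), x_um = pos$x_um,
                       y_um = pos$y_um, label = label, sample_id = sample_id,
                       stringsAsFactors = FALSE))
}

#' Construct a spot grid
#'
#' @param counts Gene-by-spot integer count matrix.
#' @param spots Data frame with columns `spot_id`, `x_um`, `y_um`, `label`,
#'   `sample_id`, one row per count column, in column order.
#' @param proportions Optional spot-by-cell-type proportion matrix (rows sum
#'   to 1).
#' @return An object of class `"spot_grid"`.
#' @export
spot_grid <- function(counts, spots, proportions = NULL) {
  stopifnot(ncol(counts) == nrow(spots),
            all(colnames(counts) == spots$spot_id),
            all(is.finite(spots$x_um)), all(is.finite(spots$y_um)))
  if (!is.null(proportions)) {
    stopifnot(nrow(proportions) == nrow(spots))
    rs <- rowSums(proportions)
    if (any(proportions < 0) || any(abs(rs - 1) > 1e-6))
      stop("cell-type proportions must lie in [0,1] and sum to 1 per spot")
  }
  structure(list(counts = counts, spots = spots, proportions = proportions),
            class = "spot_grid")
}

#' @export
#' @method print spot_grid
print.spot_grid <- function(x, ...) {
  cat(sprintf("spot_grid: %d genes x %d spots, %d sample(s), labels: %s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$spots$sample_id)),
              paste(utils::head(sort(unique(x$spots$label)), 8), collapse = ", ")))
  invisible(x)
}

#' Write a spot grid to disk
#'
#' @param grid A `spot_grid`.
#' @param dir Output directory; files `counts.tsv`, `positions.tsv`,
#'   `annotations.tsv` are created.
#' @return `dir`, invisibly.
#' @export
write_spot_grid <- function(grid, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(grid$counts, file.path(dir, "counts.tsv"), "tsv")
  utils::write.table(grid$spots[, c("spot_id", "x_um", "y_um", "sample_id")],
                     file.path(dir, "positions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(grid$spots[, c("spot_id", "label")],
                     file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then gene identifiers. Duplicate genes within a set are
#' removed with a warning; set order and within-set gene order are
#' preserved.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with a `"description"`
#'   attribute carrying the per-set description.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", fields[1], "' removed")
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
    desc[fields[1]] <- fields[2]
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / restore a fitted VI predictor
#'
#' The model is stored as plain JSON: ordered gene panel, per-gene
#' training mean and SD, intercept, coefficients, and the ridge penalty.
#'
#' @param model A `vi_predictor` from [train_ridge_logit()].
#' @param path JSON path.
#' @return `path` invisibly (`write_model_json`); a `vi_predictor`
#'   (`read_model_json`).
#' @export
write_model_json <- function(model, path) {
  obj <- list(genes = model$genes, mean = unname(model$mean),
              sd = unname(model$sd), intercept = model$intercept,
              coefficients = unname(model$coefficients),
              lambda = model$lambda, training_auroc = model$training_auroc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(genes = obj$genes,
                 mean = stats::setNames(obj$mean, obj$genes),
                 sd = stats::setNames(obj$sd, obj$genes),
                 intercept = obj$intercept,
                 coefficients = stats::setNames(obj$coefficients, obj$genes),
                 lambda = obj$lambda, training_auroc = obj$training_auroc),
            class = "vi_predictor")
}
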