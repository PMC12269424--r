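#' Per-annotation average expression from a scRNA-seq reference
#'
#' Computes, for every category of the chosen annotation level, the
#' arithmetic mean expression of each gene over the cells carrying that
#' label. Categories appear in first-appearance (data) order, never
#' lexicographic, so results are locale-independent. Cells are accumulated
#' in blocks so the full dense matrix is never materialized at once.
#'
#' @param scrna a [ScRnaDataset()] (a [SpatialDataset()] also works).
#' @param level annotation-level name present in `scrna$annotations`.
#' @param block_size number of cells accumulated per block.
#' @return an `AnnotationAverages` object: list with `categories`,
#'   `gene_symbols` and a categories x genes `means` matrix.
#' @export
compute_annotation_averages <- function(scrna, level, block_size = 5000L) {
  labels <- annotation_labels(scrna, level)
  categories <- unique(labels)
  n <- n_cells(scrna)
  p <- n_genes(scrna)
  sums <- matrix(0, nrow = length(categories), ncol = p)
  counts <- integer(length(categories))
  fac <- factor(labels, levels = categories)
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, n)
    block <- dense_expression(scrna, cells = idx)
    bs <- rowsum(block, group = fac[idx])
    rows <- match(rownames(bs), categories)
    sums[rows, ] <- sums[rows, ] + bs
    counts <- counts + tabulate(fac[idx], nbins = length(categories))
  }
  means <- sums / counts
  new_annotation_averages(categories, scrna$gene_symbols, means)
}

new_annotation_averages <- function(categories, gene_symbols, means) {
  means <- as.matrix(means)
  storage.mode(means) <- "double"
  stopifnot(nrow(means) == length(categories),
            ncol(means) == length(gene_symbols))
  dimnames(means) <- NULL
  structure(list(categories = as.character(categories),
                 gene_symbols = as.character(gene_symbols),
                 means = means),
            class = c("AnnotationAverages", "list"))
}

#' @export
print.AnnotationAverages <- function(x, ...) {
  cat("AnnotationAverages: ", length(x$categories), " categories x ",
      length(x$gene_symbols), " genes\n", sep = "")
  invisible(x)
}

#' Project annotation averages onto spatial coordinates
#'
#' Each spatial cell's expression row is replaced by the mean-expression
#' vector of its annotation category from the reference, yielding an
#' approximate (transcriptome-wide, if the reference is) expression matrix
#' at the measured spatial locations. Coordinates and cell order are
#' unchanged. Cells whose label has no counterpart among the reference
#' categories receive an all-zero row and are recorded in
#' `unmatched_cells`; with `strict = TRUE` any unmatched label is an error.
#'
#' @param srt the [SpatialDataset()] providing coordinates and labels.
#' @param averages [compute_annotation_averages()] output (or loaded via
#'   [read_annotation_averages()]).
#' @param level annotation level of `srt` to match on.
#' @param strict error (instead of warn) on labels missing from `averages`.
#' @return a `ProjectedDataset`: a [SpatialDataset()] whose gene dimension
#'   is the reference panel, plus fields `source_level` and
#'   `unmatched_cells` (integer indices).
#' @export
project_to_spatial <- function(srt, averages, level, strict = FALSE) {
  labels <- annotation_labels(srt, level)
  row <- match(labels, averages$categories)
  unmatched <- which(is.na(row))
  if (length(unmatched) == length(labels)) {
    stop("no SRT label at level '", level, "' matches any reference ",
         "category: annotation taxonomies do not correspond", call. = FALSE)
  }
  if (length(unmatched)) {
    msg <- paste0(length(unmatched), " of ", length(labels), " cells carry ",
                  "labels absent from the reference averages")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  p <- length(averages$gene_symbols)
  X <- matrix(0, nrow = length(labels), ncol = p)
  ok <- !is.na(row)
  X[ok, ] <- averages$means[row[ok], , drop = FALSE]
  out <- SpatialDataset(X, srt$coordinates,
                        gene_symbols = averages$gene_symbols,
                        cell_ids = srt$cell_ids,
                        annotations = srt$annotations)
  out$source_level <- level
  out$unmatched_cells <- unmatched
  class(out) <- c("ProjectedDataset", class(out))
  out
}

#' Cluster-level correlation between measured and reference expression
#'
#' For one gene: Pearson correlation between the vector of per-category
#' mean expression measured in the SRT data and the vector of reference
#' category means, over the categories shared by both. This validates the
#' label-correspondence projection at the annotation level.
#'
#' @inheritParams project_to_spatial
#' @param gene gene symbol present in both panels.
#' @return Pearson r in \[-1, 1\], or `NA_real_` when either side has zero
#'   variance over the shared categories (undefined statistic).
#' @export
cluster_level_correlation <- function(srt, averages, level, gene) {
  labels <- annotation_labels(srt, level)
  shared <- intersect(unique(labels), averages$categories)
  if (length(shared) < 2L) {
    stop("need at least 2 shared annotation categories, got ",
         length(shared), call. = FALSE)
  }
  x <- gene_values(srt, gene)
  srt_means <- vapply(shared, function(cat) mean(x[labels == cat]), 0.0)
  j <- match(gene, averages$gene_symbols)
  if (is.na(j)) stop("gene '", gene, "' not in reference panel", call. = FALSE)
  ref_means <- averages$means[match(shared, averages$categories), j]
  safe_pearson(srt_means, ref_means)
}

#' Cell-level spatial correlation between measured and projected expression
#'
#' Pearson correlation across all cells between the measured expression of
#' a gene and its projected (annotation-average) expression at the same
#' spatial locations.
#'
#' @inheritParams cluster_level_correlation
#' @param projected the [project_to_spatial()] result on the same cells.
#' @return Pearson r, or `NA_real_` if either vector is constant.
#' @export
cell_level_spatial_correlation <- function(srt, projected, gene) {
  if (n_cells(srt) != n_cells(projected)) {
    stop("measured and projected datasets differ in cell count", call. = FALSE)
  }
  safe_pearson(gene_values(srt, gene), gene_values(projected, gene))
}

# Pearson r with an NA sentinel for zero-variance input (never silently 0)
safe_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}
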