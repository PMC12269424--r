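#' Spatially resolved transcriptomics dataset
#'
#' Container for a cell-by-gene expression matrix with per-cell spatial
#' coordinates and optional categorical annotations. This is the universal
#' substrate of the package: every selection, filtering and clustering
#' operation works on a `SpatialDataset`.
#'
#' @param expression numeric matrix or `Matrix::sparseMatrix`, cells x genes,
#'   non-negative. Sparse input is kept sparse; statistics densify single
#'   genes on demand.
#' @param coordinates numeric matrix, cells x d with d in {2, 3}, in the
#'   units of the source frame (CCF millimetres, pixels, ...).
#' @param gene_symbols character vector of unique gene symbols, one per
#'   column of `expression`. Lookups are exact-match and case-sensitive.
#' @param cell_ids character vector of unique cell identifiers. Defaults to
#'   `cell_1 ... cell_n`.
#' @param annotations named list mapping an annotation-level name to a
#'   per-cell character vector of labels (one label per cell; use an
#'   explicit sentinel such as `"unassigned"` for missing).
#'
#' @return An object of class `SpatialDataset`: a list with fields
#'   `expression`, `coordinates`, `gene_symbols`, `cell_ids`, `annotations`.
#' @export
SpatialDataset <- function(expression, coordinates, gene_symbols = NULL,
                           cell_ids = NULL, annotations = list()) {
  ds <- new_expression_dataset(expression, gene_symbols, cell_ids, annotations)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (nrow(coordinates) != n_cells_(ds)) {
    stop("structural error: expression has ", n_cells_(ds),
         " cells but coordinates has ", nrow(coordinates), " rows",
         call. = FALSE)
  }
  if (!ncol(coordinates) %in% c(2L, 3L)) {
    stop("coordinates must have 2 or 3 columns, got ", ncol(coordinates),
         call. = FALSE)
  }
  if (any(!is.finite(coordinates))) {
    stop("coordinates contain non-finite values", call. = FALSE)
  }
  if (is.null(colnames(coordinates))) {
    colnames(coordinates) <- c("x", "y", "z")[seq_len(ncol(coordinates))]
  }
  ds$coordinates <- coordinates
  class(ds) <- c("SpatialDataset", "list")
  ds
}

#' Annotated single-cell RNA-seq dataset
#'
#' Same structural contract as [SpatialDataset()] minus coordinates; used as
#' the reference from which per-annotation average expression is computed.
#'
#' @inheritParams SpatialDataset
#' @return An object of class `ScRnaDataset`.
#' @export
ScRnaDataset <- function(expression, gene_symbols = NULL, cell_ids = NULL,
                         annotations = list()) {
  ds <- new_expression_dataset(expression, gene_symbols, cell_ids, annotations)
  class(ds) <- c("ScRnaDataset", "list")
  ds
}

# shared construction/validation for expression + ids + annotations
new_expression_dataset <- function(expression, gene_symbols, cell_ids,
                                   annotations) {
  if (!methods::is(expression, "Matrix")) {
    expression <- as.matrix(expression)
    if (!is.numeric(expression)) stop("expression must be numeric", call. = FALSE)
  }
  n <- nrow(expression)
  p <- ncol(expression)
  if (is.null(gene_symbols)) gene_symbols <- colnames(expression)
  if (is.null(gene_symbols)) {
    stop("gene_symbols missing and expression has no column names", call. = FALSE)
  }
  gene_symbols <- as.character(gene_symbols)
  if (length(gene_symbols) != p) {
    stop("structural error: ", length(gene_symbols), " gene symbols for ",
         p, " expression columns", call. = FALSE)
  }
  dup <- unique(gene_symbols[duplicated(gene_symbols)])
  if (length(dup)) {
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(cell_ids)) cell_ids <- rownames(expression)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n) {
    stop("structural error: ", length(cell_ids), " cell ids for ", n,
         " expression rows", call. = FALSE)
  }
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids", call. = FALSE)
  annotations <- as.list(annotations)
  if (length(annotations) && is.null(names(annotations))) {
    stop("annotations must be a named list of per-cell label vectors",
         call. = FALSE)
  }
  for (lv in names(annotations)) {
    lab <- as.character(annotations[[lv]])
    if (length(lab) != n) {
      stop("annotation level '", lv, "' has ", length(lab),
           " labels for ", n, " cells", call. = FALSE)
    }
    if (anyNA(lab)) {
      stop("annotation level '", lv, "' contains NA; use an explicit ",
           "sentinel category instead", call. = FALSE)
    }
    annotations[[lv]] <- lab
  }
  dimnames(expression) <- NULL
  list(expression = expression, gene_symbols = gene_symbols,
       cell_ids = cell_ids, annotations = annotations)
}

n_cells_ <- function(ds) nrow(ds$expression)
n_genes_ <- function(ds) ncol(ds$expression)

#' Number of cells / genes in a dataset
#' @param ds a [SpatialDataset()] or [ScRnaDataset()]
#' @return integer count.
#' @export
n_cells <- function(ds) n_cells_(ds)

#' @rdname n_cells
#' @export
n_genes <- function(ds) n_genes_(ds)

#' Extract one gene's expression as a dense numeric vector
#'
#' @param ds dataset
#' @param gene gene symbol (exact, case-sensitive) or column index
#' @param cells optional integer vector of cell indices to subset
#' @return numeric vector of expression values.
#' @export
gene_values <- function(ds, gene, cells = NULL) {
  j <- gene_index(ds, gene)
  v <- ds$expression[, j]
  v <- as.numeric(v)
  if (!is.null(cells)) v <- v[cells]
  v
}

gene_index <- function(ds, gene) {
  if (is.numeric(gene)) {
    j <- as.integer(gene)
    if (j < 1L || j > n_genes_(ds)) stop("gene index out of range", call. = FALSE)
    return(j)
  }
  j <- match(gene, ds$gene_symbols)
  if (is.na(j)) stop("gene '", gene, "' not found in dataset", call. = FALSE)
  j
}

#' Annotation labels of a dataset at a given level
#'
#' @param ds dataset with annotations
#' @param level annotation-level name
#' @return character vector, one label per cell.
#' @export
annotation_labels <- function(ds, level) {
  if (!level %in% names(ds$annotations)) {
    stop("unknown annotation level '", level, "'; available: ",
         if (length(ds$annotations)) paste(names(ds$annotations), collapse = ", ")
         else "(none)", call. = FALSE)
  }
  ds$annotations[[level]]
}

#' @export
print.SpatialDataset <- function(x, ...) {
  cat("SpatialDataset: ", n_cells_(x), " cells x ", n_genes_(x), " genes, ",
      ncol(x$coordinates), "D coordinates\n", sep = "")
  if (length(x$annotations)) {
    cat("annotation levels: ", paste(names(x$annotations), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.ScRnaDataset <- function(x, ...) {
  cat("ScRnaDataset: ", n_cells_(x), " cells x ", n_genes_(x), " genes\n",
      sep = "")
  if (length(x$annotations)) {
    cat("annotation levels: ", paste(names(x$annotations), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# densify an expression matrix (or a column subset) to base matrix
dense_expression <- function(ds, cells = NULL, genes = NULL) {
  e <- ds$expression
  if (!is.null(cells)) e <- e[cells, , drop = FALSE]
  if (!is.null(genes)) e <- e[, genes, drop = FALSE]
  as.matrix(e)
}
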