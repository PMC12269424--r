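#' Read a spatially resolved transcriptomics dataset from h5ad or HDF5
#'
#' Supports the AnnData on-disk layout (`layout = "h5ad"`: expression in
#' `/X` dense or CSR/CSC sparse, coordinates under `/obsm/<coord_key>`,
#' annotations as `/obs` columns) and a generic HDF5 layout
#' (`layout = "h5"`) where explicit dataset paths are supplied in `config`.
#'
#' Cells and genes are never reordered relative to file order, and values
#' are preserved as stored (no transform is applied on read).
#'
#' @param path path to the file.
#' @param layout `"h5ad"` or `"h5"`.
#' @param coord_key name of the per-observation multidimensional slot that
#'   holds the coordinates (h5ad layout); default `"spatial"`.
#' @param config for `layout = "h5"`, a named list of HDF5 dataset paths:
#'   `expression`, `coordinates`, `gene_symbols`, `cell_ids` (optional),
#'   `annotations` (optional named list level -> path), and optional logical
#'   `transpose` to force the expression orientation when it cannot be
#'   inferred from the gene/cell counts.
#' @param sparse keep a sparse on-disk matrix sparse in memory (default TRUE).
#' @return a [SpatialDataset()].
#' @export
read_spatial <- function(path, layout = c("h5ad", "h5"), coord_key = "spatial",
                         config = list(), sparse = TRUE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (layout == "h5ad") {
    read_spatial_h5ad(path, coord_key, sparse)
  } else {
    read_spatial_h5(path, config)
  }
}

read_spatial_h5ad <- function(path, coord_key, sparse) {
  contents <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (!"X" %in% contents) {
    stop("structural error: no 'X' matrix in ", path, call. = FALSE)
  }
  X <- read_h5_matrix(path, "X", sparse = sparse)
  obs <- read_h5ad_dataframe(path, "obs")
  var <- read_h5ad_dataframe(path, "var")
  obsm <- if ("obsm" %in% contents) rhdf5::h5ls(path, recursive = FALSE) else NULL
  obsm_names <- tryCatch(names(rhdf5::h5read(path, "obsm", read.attributes = FALSE)),
                         error = function(e) character())
  if (!coord_key %in% obsm_names) {
    stop("structural error: coordinate key '", coord_key,
         "' not found under obsm (available: ",
         if (length(obsm_names)) paste(obsm_names, collapse = ", ") else "none",
         ")", call. = FALSE)
  }
  coords <- t(rhdf5::h5read(path, paste0("obsm/", coord_key)))
  if (nrow(coords) != nrow(X)) {
    stop("structural error: expression has ", nrow(X),
         " cells but coordinates has ", nrow(coords), call. = FALSE)
  }
  SpatialDataset(X, coords,
                 gene_symbols = var$index,
                 cell_ids = obs$index,
                 annotations = obs$columns)
}

read_spatial_h5 <- function(path, config) {
  req <- c("expression", "coordinates", "gene_symbols")
  missing <- setdiff(req, names(config))
  if (length(missing)) {
    stop("generic h5 layout requires config paths for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  genes <- as.character(rhdf5::h5read(path, config$gene_symbols))
  X <- rhdf5::h5read(path, config$expression)
  cells <- if (!is.null(config$cell_ids))
    as.character(rhdf5::h5read(path, config$cell_ids)) else NULL
  # orient cells x genes; rhdf5 reverses C-order dims, so infer from counts
  if (!is.null(config$transpose)) {
    if (isTRUE(config$transpose)) X <- t(X)
  } else if (ncol(X) == length(genes) && nrow(X) != length(genes)) {
    # already cells x genes
  } else if (nrow(X) == length(genes) && ncol(X) != length(genes)) {
    X <- t(X)
  } else if (nrow(X) == ncol(X)) {
    stop("square expression matrix: set config$transpose explicitly",
         call. = FALSE)
  } else {
    stop("structural error: expression dims ", nrow(X), "x", ncol(X),
         " do not match ", length(genes), " gene symbols", call. = FALSE)
  }
  coords <- rhdf5::h5read(path, config$coordinates)
  if (nrow(coords) != nrow(X)) coords <- t(coords)
  ann <- list()
  for (lv in names(config$annotations)) {
    ann[[lv]] <- as.character(rhdf5::h5read(path, config$annotations[[lv]]))
  }
  SpatialDataset(X, coords, gene_symbols = genes, cell_ids = cells,
                 annotations = ann)
}

#' Read an annotated scRNA-seq dataset from h5ad
#'
#' @inheritParams read_spatial
#' @return a [ScRnaDataset()].
#' @export
read_scrna <- function(path, sparse = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  X <- read_h5_matrix(path, "X", sparse = sparse)
  obs <- read_h5ad_dataframe(path, "obs")
  var <- read_h5ad_dataframe(path, "var")
  ScRnaDataset(X, gene_symbols = var$index, cell_ids = obs$index,
               annotations = obs$columns)
}

# Read /X (or any matrix slot): dense array, or AnnData CSR/CSC group.
# Returns cells x genes. rhdf5 presents C-order dims reversed, hence t().
read_h5_matrix <- function(path, name, sparse = TRUE) {
  info <- rhdf5::h5ls(path)
  entry <- info[paste0(ifelse(info$group == "/", "", info$group), "/",
                       info$name) == paste0("/", name), , drop = FALSE]
  if (nrow(entry) && entry$otype[1] == "H5I_GROUP") {
    at <- rhdf5::h5readAttributes(path, name)
    enc <- as.character(at[["encoding-type"]])
    shape <- as.integer(at[["shape"]]) # (n_obs, n_var)
    g <- rhdf5::h5read(path, name)
    data <- as.numeric(g$data)
    indices <- as.integer(g$indices)
    indptr <- as.integer(g$indptr)
    if (length(enc) && enc == "csc_matrix") {
      M <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = c(shape[1], shape[2]))
    } else { # csr over obs == csc of the transpose
      Mt <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                 dims = c(shape[2], shape[1]))
      M <- Matrix::t(Mt)
    }
    if (!sparse) M <- as.matrix(M)
    return(M)
  }
  X <- rhdf5::h5read(path, name)
  t(as.matrix(X))
}

# Read an AnnData dataframe group (obs/var): index + string/categorical cols.
read_h5ad_dataframe <- function(path, name) {
  ls_all <- rhdf5::h5ls(path)
  children <- ls_all$name[ls_all$group == paste0("/", name)]
  if (!length(children)) return(list(index = NULL, columns = list()))
  at <- tryCatch(rhdf5::h5readAttributes(path, name), error = function(e) list())
  index_name <- if (!is.null(at[["_index"]])) as.character(at[["_index"]]) else "_index"
  if (!index_name %in% children) {
    index_name <- intersect(c("_index", "index", "obs_names", "var_names"),
                            children)[1]
  }
  idx <- if (!is.na(index_name) && length(index_name))
    as.character(rhdf5::h5read(path, paste0(name, "/", index_name))) else NULL
  col_order <- if (!is.null(at[["column-order"]]))
    as.character(at[["column-order"]]) else setdiff(children, index_name)
  cols <- list()
  for (cn in col_order) {
    if (!cn %in% children) next
    cpath <- paste0(name, "/", cn)
    centry <- ls_all[ls_all$group == paste0("/", name) & ls_all$name == cn, ]
    v <- rhdf5::h5read(path, cpath)
    if (is.list(v) && all(c("categories", "codes") %in% names(v))) {
      codes <- as.integer(v$codes)
      lab <- as.character(v$categories)[ifelse(codes < 0L, NA_integer_, codes + 1L)]
      cols[[cn]] <- lab
    } else if (is.factor(v)) {
      cols[[cn]] <- as.character(v)
    } else {
      cols[[cn]] <- as.character(as.vector(v))
    }
  }
  list(index = idx, columns = cols)
}

#' Write a dataset to an h5ad file
#'
#' Emits a minimal AnnData-compatible layout: dense float `/X`, `/obs` with
#' cell ids and annotation columns as string arrays, `/var` with gene
#' symbols, and (for spatial data) `/obsm/<coord_key>`.
#'
#' @param ds a [SpatialDataset()] or [ScRnaDataset()]
#' @param path destination file (overwritten if present)
#' @param coord_key obsm key for the coordinates
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(ds, path, coord_key = "spatial") {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  h5_write_attrs(path, ".", list(`encoding-type` = "anndata",
                                 `encoding-version` = "0.1.0"))
  X <- dense_expression(ds)
  rhdf5::h5write(t(X), path, "X") # file sees cells x genes in C order
  h5_write_attrs(path, "X", list(`encoding-type` = "array",
                                 `encoding-version` = "0.2.0"))
  write_h5ad_dataframe(path, "obs", ds$cell_ids, ds$annotations)
  write_h5ad_dataframe(path, "var", ds$gene_symbols, list())
  if (!is.null(ds$coordinates)) {
    rhdf5::h5createGroup(path, "obsm")
    h5_write_attrs(path, "obsm", list(`encoding-type` = "dict",
                                      `encoding-version` = "0.1.0"))
    rhdf5::h5write(t(ds$coordinates), path, paste0("obsm/", coord_key))
    h5_write_attrs(path, paste0("obsm/", coord_key),
                   list(`encoding-type` = "array", `encoding-version` = "0.2.0"))
  }
  invisible(path)
}

write_h5ad_dataframe <- function(path, name, index, columns) {
  rhdf5::h5createGroup(path, name)
  rhdf5::h5write(index, path, paste0(name, "/_index"))
  h5_write_attrs(path, paste0(name, "/_index"),
                 list(`encoding-type` = "string-array",
                      `encoding-version` = "0.2.0"))
  for (cn in names(columns)) {
    rhdf5::h5write(as.character(columns[[cn]]), path, paste0(name, "/", cn))
    h5_write_attrs(path, paste0(name, "/", cn),
                   list(`encoding-type` = "string-array",
                        `encoding-version` = "0.2.0"))
  }
  at <- list(`_index` = "_index", `encoding-type` = "dataframe",
             `encoding-version` = "0.2.0",
             `column-order` = as.character(names(columns)))
  h5_write_attrs(path, name, at, scalar_skip = "column-order")
}

h5_write_attrs <- function(path, objname, attrs, scalar_skip = character()) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, objname)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE)
  for (nm in names(attrs)) {
    val <- attrs[[nm]]
    if (is.character(val) && length(val) == 0L) {
      # zero-length string-array attribute (h5writeAttribute cannot)
      tid <- rhdf5::H5Tcopy("H5T_C_S1")
      rhdf5::H5Tset_size(tid, NULL)
      rhdf5::H5Tset_cset(tid, "UTF-8")
      sid <- rhdf5::H5Screate_simple(dims = 0)
      aid <- rhdf5::H5Acreate(oid, nm, tid, sid)
      rhdf5::H5Aclose(aid)
      rhdf5::H5Sclose(sid)
    } else {
      rhdf5::h5writeAttribute(val, oid, nm,
                              asScalar = !(nm %in% scalar_skip),
                              variableLengthString = TRUE, encoding = "UTF-8")
    }
  }
  invisible(NULL)
}

#' Read / write a per-annotation average-expression matrix
#'
#' The on-disk format is either CSV (rows = annotation categories, first
#' column = category label, remaining columns = genes) or h5ad (categories
#' as observations). Category labels and gene symbols are preserved
#' verbatim, in file order.
#'
#' @param path file path; format chosen by extension (`.csv` vs `.h5ad`)
#'   unless `format` is given.
#' @param format `"csv"` or `"h5ad"`.
#' @return an `AnnotationAverages` object (see [compute_annotation_averages()]).
#' @export
read_annotation_averages <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% (if (grepl("\\.h5ad$", path)) "h5ad" else "csv")
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    categories <- as.character(df[[1]])
    means <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(means) <- "double"
    genes <- colnames(means)
  } else {
    means <- as.matrix(read_h5_matrix(path, "X", sparse = FALSE))
    obs <- read_h5ad_dataframe(path, "obs")
    var <- read_h5ad_dataframe(path, "var")
    categories <- obs$index
    genes <- var$index
  }
  dup <- unique(categories[duplicated(categories)])
  if (length(dup)) {
    stop("duplicate annotation category labels: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  new_annotation_averages(categories, genes, means)
}

#' @param averages an `AnnotationAverages` object
#' @rdname read_annotation_averages
#' @export
write_annotation_averages <- function(averages, path, format = NULL) {
  format <- format %||% (if (grepl("\\.h5ad$", path)) "h5ad" else "csv")
  if (format == "csv") {
    df <- data.frame(category = averages$categories, check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- averages$means
    colnames(m) <- averages$gene_symbols
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    write_table(df, path, format = "csv")
  } else {
    ds <- list(expression = averages$means, gene_symbols = averages$gene_symbols,
               cell_ids = averages$categories, annotations = list(),
               coordinates = NULL)
    write_h5ad(structure(ds, class = c("ScRnaDataset", "list")), path)
  }
  invisible(path)
}

#' Write a tabular result to CSV or JSON
#'
#' Columns keep their given order; floating-point values are serialized
#' with 15 significant digits so that read-back reproduces them.
#'
#' @param table a data.frame (gene score table, module assignment,
#'   enrichment table, ...). An empty table yields a header-only file.
#' @param path destination path.
#' @param format `"csv"` or `"json"` (JSON records: one object per row).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (format == "csv") {
    out <- table
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
    }
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
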