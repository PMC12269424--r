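#' Correlation distance between two expression profiles
#'
#' `d = 1 - pearson(g1, g2)`, in \[0, 2\]: 0 for perfectly correlated
#' profiles, 2 for perfectly anticorrelated ones. Pearson already centers
#' and scales, so the distance is invariant to per-gene affine rescaling
#' with positive slope.
#'
#' @param g1,g2 numeric vectors of equal length (a gene's expression over
#'   the selected cells), non-constant.
#' @return numeric distance.
#' @export
correlation_distance <- function(g1, g2) {
  r <- safe_pearson(g1, g2)
  if (is.na(r)) {
    stop("correlation distance undefined for a constant profile; ",
         "constant genes must be excluded at the filtering stage",
         call. = FALSE)
  }
  1 - r
}

#' Cluster retained genes into local co-expression modules
#'
#' Agglomerative hierarchical clustering of the retained genes on the
#' pairwise correlation-distance matrix (1 - Pearson r of the genes'
#' expression over the selected cells), with the tree cut to exactly `k`
#' flat modules. Module ids are relabelled deterministically: descending
#' module size, ties by the lexicographically first member gene.
#'
#' @param table a [filter_genes()] result (its retained genes are
#'   clustered), or a character vector of gene symbols.
#' @param ds the dataset the expression is taken from.
#' @param selection the [CellSelection] defining the local context.
#' @param k number of modules (1 <= k <= number of retained genes). A
#'   required user choice: there is no automatic model selection.
#' @param linkage agglomeration method, `"average"` (UPGMA, default) or
#'   `"complete"`.
#' @return a `GeneModuleSet`: list with `genes`, integer `labels` (1..k),
#'   `k`, `linkage`, `mean_maps` (k x n_selected matrix of per-module mean
#'   expression), `normalized_maps` (min-max scaled per module, in
#'   \[0, 1\]), `selection`, and the `hclust` tree.
#' @export
cluster_genes <- function(table, ds, selection, k,
                          linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  genes <- if (is.character(table)) table else retained_genes(table)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > length(genes)) {
    stop("k = ", k, " exceeds the ", length(genes), " retained genes",
         call. = FALSE)
  }
  gi <- vapply(genes, function(g) gene_index(ds, g), 0L)
  E <- dense_expression(ds, cells = selection$indices, genes = gi) # cells x genes
  sds <- apply(E, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression within the selection for gene(s): ",
         paste(genes[sds == 0], collapse = ", "),
         "; exclude them before clustering", call. = FALSE)
  }
  if (length(genes) == 1L) {
    tree <- NULL
    raw <- 1L
  } else {
    D <- 1 - stats::cor(E, method = "pearson")
    D[D < 0] <- 0 # guard rounding below zero
    tree <- stats::hclust(stats::as.dist(D), method = linkage)
    raw <- stats::cutree(tree, k = k)
  }
  labels <- relabel_modules(raw, genes)
  mean_maps <- t(vapply(seq_len(k), function(m) {
    rowMeans(E[, labels == m, drop = FALSE])
  }, numeric(nrow(E))))
  normalized_maps <- t(apply(mean_maps, 1, minmax_scale))
  structure(list(genes = genes, labels = labels, k = k, linkage = linkage,
                 mean_maps = mean_maps, normalized_maps = normalized_maps,
                 selection = selection, tree = tree),
            class = c("GeneModuleSet", "list"))
}

# deterministic ids: descending size, ties by lexicographically first gene
relabel_modules <- function(raw, genes) {
  ids <- sort(unique(raw))
  size <- vapply(ids, function(m) sum(raw == m), 0L)
  first_gene <- vapply(ids, function(m) min(genes[raw == m]), "")
  new_order <- ids[order(-size, first_gene)]
  match(raw, new_order)
}

#' @export
print.GeneModuleSet <- function(x, ...) {
  cat("GeneModuleSet: ", length(x$genes), " genes in ", x$k,
      " modules (", x$linkage, " linkage)\n", sep = "")
  for (m in seq_len(x$k)) {
    mem <- x$genes[x$labels == m]
    cat("  module ", m, " (", length(mem), " genes): ",
        paste(utils::head(mem, 6), collapse = ", "),
        if (length(mem) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Mean spatial expression map of one module
#'
#' Per selected cell, the arithmetic mean expression over the module's
#' member genes, plus a min-max normalized variant
#' `(v - min) / (max - min)` over the selection (all-zero if the map is
#' constant), which is what color-coded spatial views display.
#'
#' @param modules a [cluster_genes()] result
#' @param module_id module id in 1..k
#' @return list with numeric vectors `mean` and `normalized` (one value
#'   per selected cell).
#' @export
module_mean_map <- function(modules, module_id) {
  m <- as.integer(module_id)
  if (m < 1L || m > modules$k) stop("module id out of range", call. = FALSE)
  list(mean = modules$mean_maps[m, ], normalized = modules$normalized_maps[m, ])
}

minmax_scale <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Module assignment table
#'
#' @param modules a [cluster_genes()] result
#' @return data.frame with columns `gene` and `module`.
#' @export
module_assignments <- function(modules) {
  data.frame(gene = modules$genes, module = modules$labels,
             stringsAsFactors = FALSE)
}

#' Static scatter plot of a module's normalized mean map
#'
#' A headless stand-in for interactive 3D rendering: plots the selected
#' cells at their first two coordinate axes, coloured by the module's
#' normalized mean expression (light yellow = low, red = high), with
#' unselected cells in grey.
#'
#' @param modules a [cluster_genes()] result
#' @param ds the source dataset (for coordinates)
#' @param module_id module id
#' @param path optional PNG path; when given the plot is written there.
#' @return `path` (or NULL) invisibly.
#' @export
plot_module_map <- function(modules, ds, module_id, path = NULL) {
  v <- module_mean_map(modules, module_id)$normalized
  sel <- modules$selection$indices
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  pal <- grDevices::colorRamp(c("#FFFFCC", "#CC0000"))
  cols <- grDevices::rgb(pal(v), maxColorValue = 255)
  graphics::plot(ds$coordinates[, 1], ds$coordinates[, 2], col = "grey85",
                 pch = 16, cex = 0.5, xlab = colnames(ds$coordinates)[1],
                 ylab = colnames(ds$coordinates)[2],
                 main = paste0("module ", module_id, " mean expression"))
  graphics::points(ds$coordinates[sel, 1], ds$coordinates[sel, 2],
                   col = cols, pch = 16, cex = 0.7)
  invisible(path)
}
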