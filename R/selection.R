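#' Cell selections
#'
#' A `CellSelection` is an ordered, duplicate-free set of cell indices into
#' a dataset, together with the provenance of how it was produced
#' (annotation label, flood-fill parameters, or an explicit list).
#'
#' @name CellSelection
NULL

new_cell_selection <- function(indices, provenance, dataset_ref = NULL) {
  indices <- as.integer(indices)
  if (!length(indices)) stop("selection is empty", call. = FALSE)
  if (anyDuplicated(indices)) stop("selection has duplicate indices", call. = FALSE)
  structure(list(indices = indices, provenance = provenance,
                 dataset_ref = dataset_ref),
            class = c("CellSelection", "list"))
}

#' @export
print.CellSelection <- function(x, ...) {
  cat("CellSelection: ", length(x$indices), " cells (",
      x$provenance$type, ")\n", sep = "")
  invisible(x)
}

#' @export
length.CellSelection <- function(x) length(x$indices)

#' Select cells carrying an annotation label
#'
#' @param ds a [SpatialDataset()]
#' @param level annotation-level name
#' @param label category label at that level
#' @return a [CellSelection] of all matching cells, in dataset order.
#' @export
select_by_annotation <- function(ds, level, label) {
  labels <- annotation_labels(ds, level)
  idx <- which(labels == label)
  if (!length(idx)) {
    avail <- unique(labels)
    near <- avail[order(utils::adist(label, avail))][seq_len(min(3, length(avail)))]
    stop("label '", label, "' matches no cell at level '", level,
         "'; nearest labels: ", paste(near, collapse = ", "), call. = FALSE)
  }
  new_cell_selection(idx, list(type = "annotation", level = level,
                               label = label))
}

#' Build a k-nearest-neighbour graph in transcriptome space
#'
#' Exact brute-force kNN on the expression rows. Distances are computed in
#' row blocks so memory stays bounded for large datasets. Neighbour lists
#' exclude self, are sorted by ascending distance, and ties are broken by
#' the lower cell index so the graph is fully deterministic.
#'
#' @param ds a [SpatialDataset()] (or any dataset with an expression matrix)
#' @param k number of neighbours; clipped to n - 1 with a warning if
#'   `k >= n`.
#' @param metric `"euclidean"`, `"cosine"` (1 - cosine similarity) or
#'   `"correlation"` (1 - Pearson r) on expression rows.
#' @param block_size rows per distance block.
#' @return a `KnnGraph`: list with integer `neighbors` (n x k, row i = the
#'   k nearest cells of i), `distances` (same shape), `metric`, `k`.
#' @export
build_knn_graph <- function(ds, k = 10L,
                            metric = c("euclidean", "cosine", "correlation"),
                            block_size = 1024L) {
  metric <- match.arg(metric)
  X <- dense_expression(ds)
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k >= n) {
    warning("k = ", k, " >= n = ", n, "; clipped to ", n - 1L, call. = FALSE)
    k <- n - 1L
  }
  k <- as.integer(k)
  if (metric == "correlation") {
    X <- X - rowMeans(X)
    metric_impl <- "cosine"
  } else {
    metric_impl <- metric
  }
  if (metric_impl == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    if (any(nrm == 0)) {
      stop("zero-norm expression row(s) under ", metric, " metric: cells ",
           paste(utils::head(which(nrm == 0), 5), collapse = ", "),
           call. = FALSE)
    }
    X <- X / nrm
  }
  sq <- rowSums(X^2)
  neighbors <- matrix(0L, n, k)
  distances <- matrix(0.0, n, k)
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    rows <- s:min(s + block_size - 1L, n)
    G <- X[rows, , drop = FALSE] %*% t(X)
    if (metric_impl == "euclidean") {
      D <- sqrt(pmax(outer(sq[rows], sq, "+") - 2 * G, 0))
    } else {
      D <- 1 - G # unit rows: cosine (or correlation) distance
    }
    for (ri in seq_along(rows)) {
      i <- rows[ri]
      d <- D[ri, ]
      d[i] <- Inf # exclude self
      ord <- order(d, seq_len(n))[seq_len(k)]
      neighbors[i, ] <- ord
      distances[i, ] <- d[ord]
    }
  }
  structure(list(neighbors = neighbors, distances = distances,
                 metric = metric, k = k, n = n, method = "brute-force-exact"),
            class = c("KnnGraph", "list"))
}

#' @export
print.KnnGraph <- function(x, ...) {
  cat("KnnGraph: ", x$n, " cells, k = ", x$k, ", metric = ", x$metric,
      "\n", sep = "")
  invisible(x)
}

#' Flood-fill selection of transcriptomically similar cells
#'
#' Breadth-first traversal from a seed cell over the directed out-edges of
#' the transcriptomic kNN graph: the frontier is expanded `steps` times, a
#' cell flooding to its own k nearest neighbours at each step. The kNN `k`
#' plays the role of the "flood nodes" parameter of interactive spatial
#' explorers and `steps` their "flood steps"; defaults elsewhere in the
#' package are k = 10, steps = 10.
#'
#' @param graph a [build_knn_graph()] result.
#' @param seed seed cell index.
#' @param steps number of frontier expansions (>= 0); `steps = 0` selects
#'   only the seed.
#' @return a [CellSelection] of visited cells in BFS order (seed first).
#' @export
flood_fill <- function(graph, seed, steps = 10L) {
  seed <- as.integer(seed)
  if (seed < 1L || seed > graph$n) stop("seed index out of range", call. = FALSE)
  if (steps < 0L) stop("steps must be >= 0", call. = FALSE)
  visited <- logical(graph$n)
  visited[seed] <- TRUE
  order_visited <- seed
  frontier <- seed
  step <- 0L
  while (step < steps && length(frontier)) {
    nxt <- as.vector(t(graph$neighbors[frontier, , drop = FALSE]))
    nxt <- nxt[!visited[nxt]]
    nxt <- nxt[!duplicated(nxt)]
    visited[nxt] <- TRUE
    order_visited <- c(order_visited, nxt)
    frontier <- nxt
    step <- step + 1L
  }
  new_cell_selection(order_visited,
                     list(type = "floodfill", seed = seed,
                          k_neighbors = graph$k, steps = as.integer(steps),
                          metric = graph$metric))
}

#' Selection from an explicit index list
#'
#' The headless analogue of lassoing cells in an embedding: indices are
#' validated, de-duplicated keeping first occurrence, and order-preserved.
#'
#' @param ds dataset the indices refer to
#' @param indices integer cell indices (1-based), non-empty
#' @return a [CellSelection] with provenance `explicit`.
#' @export
select_explicit <- function(ds, indices) {
  indices <- as.integer(indices)
  if (!length(indices)) stop("empty index list", call. = FALSE)
  bad <- indices[indices < 1L | indices > n_cells(ds)]
  if (length(bad)) {
    stop("index out of range: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  new_cell_selection(indices[!duplicated(indices)], list(type = "explicit"))
}

#' Serialize / restore a selection as JSON
#'
#' @param selection a [CellSelection]
#' @param path file path
#' @return `path` invisibly / the restored [CellSelection].
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(list(dataset_ref = selection$dataset_ref,
                            provenance = selection$provenance,
                            indices = selection$indices),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_cell_selection(x$indices, as.list(x$provenance), x$dataset_ref)
}
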