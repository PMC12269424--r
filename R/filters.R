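#' Differential expression score of a gene for a selection
#'
#' Difference between the mean expression of the gene over the selected
#' cells and its mean over the whole dataset. Positive scores mark genes
#' high in the selection; the score is 0 for any gene when the selection is
#' the whole dataset.
#'
#' @param ds a [SpatialDataset()]
#' @param selection a [CellSelection] into `ds`
#' @param gene gene symbol or index
#' @return a single numeric score.
#' @export
differential_score <- function(ds, selection, gene) {
  x <- gene_values(ds, gene)
  mean(x[selection$indices]) - mean(x)
}

#' Spatial weight matrix from coordinates of selected cells
#'
#' Euclidean distances between the selected cells' coordinates define the
#' weights. Two schemes are offered: `knn` (binary: w_ij = 1 iff j is among
#' the k spatially nearest neighbours of i; generally asymmetric) and
#' `invdist` (w_ij = 1/d_ij for distances up to `cutoff`, 0 beyond). The
#' diagonal is always zero.
#'
#' @param coords numeric matrix of coordinates of the selected cells
#'   (cells x d), at least 3 rows.
#' @param scheme `"knn"` or `"invdist"`.
#' @param k neighbour count for the knn scheme (default 15, clipped to
#'   n - 1).
#' @param cutoff distance cutoff for the invdist scheme.
#' @return a `SpatialWeightMatrix`: list with sparse `w` (n x n), scalar
#'   `W` (= sum of all weights), `scheme`, `n`.
#' @export
build_weights <- function(coords, scheme = c("knn", "invdist"), k = 15L,
                          cutoff = NULL) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 cells to build spatial weights", call. = FALSE)
  D <- as.matrix(stats::dist(coords))
  if (scheme == "knn") {
    if (k >= n) {
      warning("k = ", k, " >= n = ", n, "; clipped to ", n - 1L, call. = FALSE)
      k <- n - 1L
    }
    ii <- integer(0); jj <- integer(0)
    for (i in seq_len(n)) {
      d <- D[i, ]
      d[i] <- Inf
      nb <- order(d, seq_len(n))[seq_len(k)] # index tie-break
      ii <- c(ii, rep.int(i, k)); jj <- c(jj, nb)
    }
    w <- Matrix::sparseMatrix(i = ii, j = jj, x = 1.0, dims = c(n, n))
  } else {
    if (is.null(cutoff) || cutoff <= 0) {
      stop("invdist scheme requires a positive cutoff", call. = FALSE)
    }
    sel <- which(D <= cutoff & upper.tri(D) | D <= cutoff & lower.tri(D),
                 arr.ind = TRUE)
    if (!nrow(sel)) {
      stop("cutoff ", cutoff, " is smaller than every pairwise distance ",
           "(W = 0); increase it or use the knn scheme", call. = FALSE)
    }
    dvals <- D[sel]
    if (any(dvals == 0)) {
      stop("coincident points give infinite inverse-distance weights; ",
           "use the knn scheme", call. = FALSE)
    }
    w <- Matrix::sparseMatrix(i = sel[, 1], j = sel[, 2], x = 1 / dvals,
                              dims = c(n, n))
  }
  structure(list(w = w, W = sum(w), scheme = scheme, n = n,
                 params = if (scheme == "knn") list(k = as.integer(k))
                          else list(cutoff = cutoff)),
            class = c("SpatialWeightMatrix", "list"))
}

#' @export
print.SpatialWeightMatrix <- function(x, ...) {
  cat("SpatialWeightMatrix: ", x$n, " cells, scheme = ", x$scheme,
      ", W = ", format(x$W), "\n", sep = "")
  invisible(x)
}

# Null-hypothesis moments of Moran's I under the normality assumption.
# E(I) = -1/(N-1); Var(I) = (N^2 S1 - N S2 + 3 W^2) / (W^2 (N^2 - 1)) - E(I)^2
# with S1 = 1/2 sum (w_ij + w_ji)^2, S2 = sum_i (w_i. + w_.i)^2.
moran_null_moments <- function(weights) {
  w <- weights$w
  N <- weights$n
  W <- weights$W
  S1 <- sum((w + Matrix::t(w))^2) / 2
  S2 <- sum((Matrix::rowSums(w) + Matrix::colSums(w))^2)
  EI <- -1 / (N - 1)
  VarI <- (N^2 * S1 - N * S2 + 3 * W^2) / (W^2 * (N^2 - 1)) - EI^2
  # the closed form can dip below 0 for tiny N with dense weights
  list(expected = EI, var = VarI, sd = if (VarI > 0) sqrt(VarI) else NaN)
}

#' Moran's I spatial autocorrelation of a gene within a selection
#'
#' Computes the global Moran's I statistic
#' \deqn{I = \frac{N}{W} \frac{\sum_i \sum_j w_{ij} (x_i - \bar x)(x_j - \bar x)}
#'                          {\sum_i (x_i - \bar x)^2}}
#' over the selected cells only, where `w` is the spatial weight matrix
#' built from those cells' coordinates, `N` the number of selected cells
#' and `W` the sum of all weights. The statistic is compared against its
#' null expectation \eqn{E(I) = -1/(N-1)} and a Z-score is derived under
#' the normality assumption.
#'
#' Moran's I is invariant to adding a constant to the expression and to
#' positive rescaling; a constant gene has an undefined statistic and
#' returns the `NA` sentinel (it is excluded from ranking downstream, never
#' scored 0).
#'
#' @inheritParams differential_score
#' @param weights a [build_weights()] result on the selection's coordinates.
#' @return a `MoransIResult`: list with `I`, `expected`, `z`, `N`.
#' @export
morans_i <- function(ds, selection, gene, weights) {
  if (weights$n != length(selection$indices)) {
    stop("weight matrix was built for ", weights$n, " cells but the ",
         "selection has ", length(selection$indices), call. = FALSE)
  }
  x <- gene_values(ds, gene, cells = selection$indices)
  mom <- moran_null_moments(weights)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    return(structure(list(I = NA_real_, expected = mom$expected, z = NA_real_,
                          N = weights$n),
                     class = c("MoransIResult", "list")))
  }
  num <- sum(xc * as.numeric(weights$w %*% xc))
  I <- (weights$n / weights$W) * num / denom
  structure(list(I = I, expected = mom$expected,
                 z = (I - mom$expected) / mom$sd, N = weights$n),
            class = c("MoransIResult", "list"))
}

#' @export
print.MoransIResult <- function(x, ...) {
  cat("Moran's I = ", format(x$I), " (E[I] = ", format(x$expected),
      ", Z = ", format(x$z), ", N = ", x$N, ")\n", sep = "")
  invisible(x)
}

#' Correlation of a gene's expression with a spatial axis
#'
#' Pearson correlation, over the selected cells, between a gene's
#' expression and one coordinate axis (for CCF-aligned data: e.g. the
#' anterior-posterior or dorsal-ventral axis). Large |r| flags genes with a
#' spatial gradient along that axis.
#'
#' @inheritParams differential_score
#' @param axis `"x"`, `"y"` or `"z"` (or a 1-based axis index)
#' @return Pearson r, or `NA_real_` if either vector is constant.
#' @export
axis_correlation <- function(ds, selection, gene, axis) {
  a <- axis_index(ds, axis)
  if (length(selection$indices) < 3L) {
    stop("need at least 3 selected cells", call. = FALSE)
  }
  x <- gene_values(ds, gene, cells = selection$indices)
  coord <- ds$coordinates[selection$indices, a]
  safe_pearson(x, coord)
}

axis_index <- function(ds, axis) {
  d <- ncol(ds$coordinates)
  if (is.numeric(axis)) {
    a <- as.integer(axis)
  } else {
    a <- match(tolower(axis), c("x", "y", "z"))
    if (is.na(a)) stop("axis must be one of x, y, z", call. = FALSE)
  }
  if (a < 1L || a > d) {
    stop("axis '", axis, "' not available: coordinates are ", d, "D",
         call. = FALSE)
  }
  a
}

#' Score all genes within a selection and retain the top N
#'
#' Applies one of the three gene filters to every gene of the dataset,
#' within the selected cells:
#' * `differential` — selection mean minus whole-dataset mean; ranking key
#'   is the signed score, descending (the filter targets genes high in the
#'   selection).
#' * `moran` — Moran's I Z-score; ranking key is |Z|, so both clustered and
#'   dispersed non-random patterns rank high.
#' * `axis` — Pearson r with a coordinate axis; ranking key is |r|, so
#'   gradients of both directions survive to the clustering stage.
#'
#' Genes with an undefined statistic (zero variance within the selection)
#' are excluded from the ranking. Ties are broken lexicographically by gene
#' symbol, making the table a total order: re-running yields an identical
#' table.
#'
#' @inheritParams differential_score
#' @param metric `"differential"`, `"moran"` or `"axis"`.
#' @param n_keep number of genes to retain (>= 1). If it exceeds the number
#'   of finite-score genes, all of those are retained with a warning.
#' @param weights [build_weights()] result (metric `"moran"` only); built
#'   automatically with the default knn scheme when omitted.
#' @param axis coordinate axis (metric `"axis"` only).
#' @param weight_scheme,weight_k,weight_cutoff weight-construction
#'   parameters used when `weights` is omitted.
#' @return a `GeneScoreTable`: data.frame with columns `gene`, `score`,
#'   `ranking_key`, `retained`, sorted by descending ranking key (ties by
#'   symbol), with unranked (NA) genes last. Attributes `metric` and
#'   `params` record provenance.
#' @export
filter_genes <- function(ds, selection, metric = c("differential", "moran", "axis"),
                         n_keep, weights = NULL, axis = NULL,
                         weight_scheme = "knn", weight_k = 15L,
                         weight_cutoff = NULL) {
  metric <- match.arg(metric)
  n_keep <- as.integer(n_keep)
  if (n_keep < 1L) stop("n_keep must be >= 1", call. = FALSE)
  sel <- selection$indices
  Xs <- dense_expression(ds, cells = sel)
  params <- list()
  if (metric == "differential") {
    score <- colMeans(Xs) - colMeans(dense_expression(ds))
    key <- score
  } else if (metric == "moran") {
    if (is.null(weights)) {
      weights <- build_weights(ds$coordinates[sel, , drop = FALSE],
                               scheme = weight_scheme, k = weight_k,
                               cutoff = weight_cutoff)
    }
    if (weights$n != length(sel)) {
      stop("weight matrix size does not match selection", call. = FALSE)
    }
    mom <- moran_null_moments(weights)
    Xc <- sweep(Xs, 2, colMeans(Xs))
    denom <- colSums(Xc^2)
    num <- colSums(Xc * as.matrix(weights$w %*% Xc))
    I <- (weights$n / weights$W) * num / denom
    I[denom == 0] <- NA_real_
    score <- (I - mom$expected) / mom$sd
    key <- abs(score)
    params <- list(weight_scheme = weights$scheme, weight_params = weights$params)
  } else {
    a <- axis_index(ds, axis %||% stop("metric 'axis' requires an axis",
                                       call. = FALSE))
    coord <- ds$coordinates[sel, a]
    cc <- coord - mean(coord)
    sc <- sqrt(sum(cc^2))
    Xc <- sweep(Xs, 2, colMeans(Xs))
    sx <- sqrt(colSums(Xc^2))
    score <- as.numeric(crossprod(Xc, cc)) / (sx * sc)
    score[sx == 0] <- NA_real_
    if (sc == 0) score[] <- NA_real_
    key <- abs(score)
    params <- list(axis = colnames(ds$coordinates)[a])
  }
  genes <- ds$gene_symbols
  finite <- is.finite(key)
  ord <- order(!finite, -ifelse(finite, key, -Inf), genes)
  n_finite <- sum(finite)
  if (n_keep > n_finite) {
    warning("n_keep = ", n_keep, " exceeds the ", n_finite,
            " genes with a finite score; retaining all of them", call. = FALSE)
    n_keep <- n_finite
  }
  retained <- logical(length(genes))
  retained[ord[seq_len(n_keep)]] <- TRUE
  out <- data.frame(gene = genes[ord], score = score[ord],
                    ranking_key = key[ord], retained = retained[ord],
                    stringsAsFactors = FALSE)
  attr(out, "metric") <- metric
  attr(out, "params") <- params
  attr(out, "n_keep") <- n_keep
  class(out) <- c("GeneScoreTable", "data.frame")
  out
}

#' Retained genes of a score table
#' @param table a [filter_genes()] result
#' @return character vector of retained gene symbols, in ranking order.
#' @export
retained_genes <- function(table) table$gene[table$retained]
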