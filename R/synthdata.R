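#' Specification for a paired synthetic SRT + pseudo-scRNA dataset
#'
#' Describes a 3D (or 2D) grid of cells with an annotation mosaic and
#' planted gene classes, so that every analysis stage of the package can be
#' exercised without downloading a reference atlas:
#' * gradient genes — `amplitude * t` along a chosen axis (`t` the
#'   normalized coordinate), in both orientations, plus Gaussian noise;
#' * hotspot genes — `amplitude * exp(-d^2 / (2 r^2))` around a center;
#' * marker genes — `amplitude * 1[annotation == A]` plus noise, one per
#'   annotation region (cycling);
#' * noise genes — no planted structure, truncated Gaussian around a
#'   baseline.
#'
#' The annotation mosaic is a set of contiguous slabs along the second
#' coordinate axis, so markers and gradients along the first axis remain
#' unconfounded. The pseudo-scRNA companion carries the full gene panel
#' (the SRT carries only the shared panel) with cells drawn per annotation
#' region at virtual locations inside that region.
#'
#' @param grid_dims integer grid dimensions, length 2 or 3 (default
#'   `c(10, 10, 5)`: 500 cells). Coordinates are the grid points jittered
#'   by U(-0.3, 0.3) to avoid degenerate distance ties.
#' @param n_annotations number of annotation regions (slabs along axis 2).
#' @param n_gradient_pos,n_gradient_neg gradient gene counts per sign.
#' @param gradient_axis axis of the planted gradients (`"x"`/`"y"`/`"z"`).
#' @param n_hotspot hotspot gene count; `hotspot_radius` in grid units.
#' @param n_marker marker gene count (assigned to annotations cyclically).
#' @param n_noise structureless gene count in the shared panel.
#' @param n_scrna_extra_noise,n_scrna_extra_marker genes present only in
#'   the pseudo-scRNA (full) panel.
#' @param amplitude signal amplitude shared by the planted classes.
#' @param noise_sd Gaussian noise s.d. added to planted genes; default
#'   `0.05 * amplitude`.
#' @param baseline,baseline_sd mean and s.d. of the structureless genes.
#' @param n_scrna_per_annotation pseudo-scRNA cells sampled per region.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return a `SynthSpec` list.
#' @export
synth_spec <- function(grid_dims = c(10L, 10L, 5L), n_annotations = 4L,
                       n_gradient_pos = 5L, n_gradient_neg = 5L,
                       gradient_axis = "x", n_hotspot = 2L,
                       hotspot_radius = 2, n_marker = n_annotations,
                       n_noise = 104L, n_scrna_extra_noise = 36L,
                       n_scrna_extra_marker = 4L, amplitude = 5,
                       noise_sd = 0.05 * amplitude, baseline = 1,
                       baseline_sd = 0.5, n_scrna_per_annotation = 50L,
                       seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (!length(grid_dims) %in% c(2L, 3L)) {
    stop("grid_dims must have length 2 or 3", call. = FALSE)
  }
  if (n_annotations > grid_dims[2]) {
    stop("infeasible geometry: ", n_annotations, " annotation slabs do not ",
         "fit a grid of ", grid_dims[2], " voxels along axis 2", call. = FALSE)
  }
  spec <- list(grid_dims = grid_dims, n_annotations = as.integer(n_annotations),
               n_gradient_pos = as.integer(n_gradient_pos),
               n_gradient_neg = as.integer(n_gradient_neg),
               gradient_axis = gradient_axis, n_hotspot = as.integer(n_hotspot),
               hotspot_radius = hotspot_radius, n_marker = as.integer(n_marker),
               n_noise = as.integer(n_noise),
               n_scrna_extra_noise = as.integer(n_scrna_extra_noise),
               n_scrna_extra_marker = as.integer(n_scrna_extra_marker),
               amplitude = amplitude, noise_sd = noise_sd,
               baseline = baseline, baseline_sd = baseline_sd,
               n_scrna_per_annotation = as.integer(n_scrna_per_annotation),
               seed = as.integer(seed))
  class(spec) <- c("SynthSpec", "list")
  spec
}

# gene catalogue for a spec: data.frame(gene, class, sign/annotation, shared)
synth_gene_catalogue <- function(spec) {
  rows <- list()
  add <- function(n, prefix, class, param) {
    if (n < 1L) return()
    rows[[length(rows) + 1L]] <<-
      data.frame(gene = sprintf("%s_%02d", prefix, seq_len(n)),
                 class = class, param = param, stringsAsFactors = FALSE)
  }
  ax <- spec$gradient_axis
  add(spec$n_gradient_pos, paste0("grad_", ax, "p"), "gradient",
      paste0("+", ax))
  add(spec$n_gradient_neg, paste0("grad_", ax, "n"), "gradient",
      paste0("-", ax))
  add(spec$n_hotspot, "hot", "hotspot", "center")
  if (spec$n_marker >= 1L) {
    ann <- sprintf("region_%d", ((seq_len(spec$n_marker) - 1L) %%
                                   spec$n_annotations) + 1L)
    rows[[length(rows) + 1L]] <-
      data.frame(gene = sprintf("mark_%02d", seq_len(spec$n_marker)),
                 class = "marker", param = ann, stringsAsFactors = FALSE)
  }
  add(spec$n_noise, "noise", "noise", "")
  shared <- do.call(rbind, rows)
  shared$shared <- TRUE
  rows <- list()
  add(spec$n_scrna_extra_noise, "sc_noise", "noise", "")
  if (spec$n_scrna_extra_marker >= 1L) {
    ann <- sprintf("region_%d", ((seq_len(spec$n_scrna_extra_marker) - 1L) %%
                                   spec$n_annotations) + 1L)
    rows[[length(rows) + 1L]] <-
      data.frame(gene = sprintf("sc_mark_%02d",
                                seq_len(spec$n_scrna_extra_marker)),
                 class = "marker", param = ann, stringsAsFactors = FALSE)
  }
  extra <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(extra)) extra$shared <- FALSE
  out <- rbind(shared, extra)
  rownames(out) <- NULL
  out
}

# expression for an arbitrary set of cells given coords + labels
synth_expression <- function(spec, catalogue, coords, labels) {
  n <- nrow(coords)
  ax <- axis_letter_index(spec$gradient_axis, ncol(coords))
  rng <- c(1, spec$grid_dims[ax])
  tt <- (coords[, ax] - rng[1]) / (rng[2] - rng[1])
  center <- (spec$grid_dims[seq_len(ncol(coords))] + 1) / 2
  d2 <- rowSums(sweep(coords, 2, center)^2)
  X <- matrix(0.0, nrow = n, ncol = nrow(catalogue))
  for (j in seq_len(nrow(catalogue))) {
    cls <- catalogue$class[j]
    base <- switch(cls,
      gradient = {
        s <- substr(catalogue$param[j], 1, 1)
        if (s == "+") spec$amplitude * tt else spec$amplitude * (1 - tt)
      },
      hotspot = spec$amplitude * exp(-d2 / (2 * spec$hotspot_radius^2)),
      marker = spec$amplitude * as.numeric(labels == catalogue$param[j]),
      noise = rep(spec$baseline, n))
    sd <- if (cls == "noise") spec$baseline_sd else spec$noise_sd
    X[, j] <- pmax(0, base + stats::rnorm(n, 0, sd))
  }
  colnames(X) <- catalogue$gene
  X
}

axis_letter_index <- function(axis, d) {
  a <- match(tolower(axis), c("x", "y", "z"))
  if (is.na(a) || a > d) stop("invalid gradient axis '", axis, "'", call. = FALSE)
  a
}

#' Generate the paired synthetic datasets
#'
#' Deterministic given `spec$seed`: two calls with the same spec are
#' bit-identical.
#'
#' @param spec a [synth_spec()]
#' @return list with `srt` (a [SpatialDataset()], shared panel),
#'   `scrna` (a [ScRnaDataset()], full panel, same annotation taxonomy)
#'   and `ground_truth` (data.frame: gene, class, param, shared).
#' @export
generate_synthetic <- function(spec = synth_spec()) {
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  catalogue <- synth_gene_catalogue(spec)
  d <- length(spec$grid_dims)
  grid <- as.matrix(expand.grid(lapply(spec$grid_dims, seq_len)))
  colnames(grid) <- c("x", "y", "z")[seq_len(d)]
  n <- nrow(grid)
  coords <- grid + matrix(stats::runif(n * d, -0.3, 0.3), n, d)
  # annotation mosaic: contiguous slabs along axis 2
  slab <- cut(grid[, 2], breaks = spec$n_annotations, labels = FALSE)
  labels <- sprintf("region_%d", slab)
  shared_cat <- catalogue[catalogue$shared, , drop = FALSE]
  X_srt <- synth_expression(spec, shared_cat, coords, labels)
  srt <- SpatialDataset(X_srt, coords,
                        gene_symbols = shared_cat$gene,
                        cell_ids = sprintf("srt_%04d", seq_len(n)),
                        annotations = list(region = labels))
  # pseudo-scRNA: cells per region at virtual in-region locations
  ylims <- vapply(seq_len(spec$n_annotations), function(r) {
    range(grid[slab == r, 2])
  }, numeric(2))
  sc_coords <- NULL; sc_labels <- character()
  for (r in seq_len(spec$n_annotations)) {
    m <- spec$n_scrna_per_annotation
    cc <- matrix(0, m, d)
    for (a in seq_len(d)) {
      lo <- if (a == 2) ylims[1, r] else 1
      hi <- if (a == 2) ylims[2, r] else spec$grid_dims[a]
      cc[, a] <- stats::runif(m, lo, hi)
    }
    sc_coords <- rbind(sc_coords, cc)
    sc_labels <- c(sc_labels, rep(sprintf("region_%d", r), m))
  }
  X_sc <- synth_expression(spec, catalogue, sc_coords, sc_labels)
  scrna <- ScRnaDataset(X_sc, gene_symbols = catalogue$gene,
                        cell_ids = sprintf("sc_%04d", seq_len(nrow(X_sc))),
                        annotations = list(region = sc_labels))
  list(srt = srt, scrna = scrna, ground_truth = catalogue, spec = spec)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic pair to disk as an io-readable fixture
#'
#' Emits `srt.h5ad`, `scrna.h5ad` and `ground_truth.csv` under `dir`.
#'
#' @param sim a [generate_synthetic()] result
#' @param dir output directory (created if absent)
#' @return named character vector of the three paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(srt = file.path(dir, "srt.h5ad"),
             scrna = file.path(dir, "scrna.h5ad"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  write_h5ad(sim$srt, paths[["srt"]])
  write_h5ad(sim$scrna, paths[["scrna"]])
  write_table(sim$ground_truth, paths[["ground_truth"]], format = "csv")
  invisible(paths)
}
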