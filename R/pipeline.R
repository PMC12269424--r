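#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file path) with sections
#' `data`, `projection`, `selection`, `filter`, `clustering`, `enrichment`,
#' `output`, `seed`. Unknown section names or unknown keys inside a section
#' are rejected before any computation, so typos fail fast.
#'
#' Section keys:
#' * `data` — either `synthetic: true` (plus optional [synth_spec()]
#'   overrides under `spec`) or `srt` (path), with optional `layout`,
#'   `coord_key`, `h5_config`, `scrna` (path) or `averages` (path).
#' * `projection` — `enabled` (logical), `level`; analysis then runs on the
#'   projected dataset.
#' * `selection` — `mode`: `"annotation"` (`level`, `label`), `"flood"`
#'   (`seed_cell`, `k`, `steps`, `metric`), or `"explicit"` (`indices`).
#' * `filter` — `metric`, `n_keep`, optional `axis`, `weight_scheme`,
#'   `weight_k`, `weight_cutoff`.
#' * `clustering` — `k`, optional `linkage`.
#' * `enrichment` — optional; `provider` (only `"offline"` runs without
#'   network), `term_table` (path), optional `organism`,
#'   `use_panel_background` (default TRUE), `alpha`.
#' * `output` — `dir`.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config (class `PipelineConfig`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path", call. = FALSE)
  allowed <- list(
    data = c("synthetic", "spec", "srt", "layout", "coord_key", "h5_config",
             "scrna", "averages"),
    projection = c("enabled", "level", "strict"),
    selection = c("mode", "level", "label", "seed_cell", "k", "steps",
                  "metric", "indices"),
    filter = c("metric", "n_keep", "axis", "weight_scheme", "weight_k",
               "weight_cutoff"),
    clustering = c("k", "linkage"),
    enrichment = c("provider", "term_table", "organism",
                   "use_panel_background", "alpha"),
    output = "dir",
    seed = NULL)
  unknown <- setdiff(names(config), names(allowed))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in intersect(names(config), names(allowed))) {
    if (is.null(allowed[[sec]])) next
    bad <- setdiff(names(config[[sec]]), allowed[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  for (sec in c("data", "selection", "filter", "clustering")) {
    if (is.null(config[[sec]])) {
      stop("config section '", sec, "' is required", call. = FALSE)
    }
  }
  if (is.null(config$selection$mode) ||
      !config$selection$mode %in% c("annotation", "flood", "explicit")) {
    stop("selection$mode must be annotation, flood or explicit", call. = FALSE)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  class(config) <- c("PipelineConfig", "list")
  config
}

#' Run the full pipeline from a configuration
#'
#' Executes (load/generate data) -> (optional projection) -> selection ->
#' gene filtering -> gene clustering -> (optional enrichment), writing
#' every intermediate artifact plus a manifest to the output directory:
#' `selection.json`, `gene_scores.csv`, `module_assignments.csv`,
#' `module_maps.csv`, `enrichment.csv` (when configured) and
#' `manifest.json` (config echo + hash, package and R versions, per-stage
#' wall times, artifact list). A stage failure aborts with the stage name;
#' artifacts of completed stages are preserved. Runs are deterministic:
#' identical config + seed yield byte-identical tables.
#'
#' @param config a [pipeline_config()] (or list / YAML path accepted by it)
#' @param out_dir output directory; defaults to `config$output$dir`.
#' @return invisibly, a list with the run directory, the manifest and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- pipeline_config(config)
  out_dir <- out_dir %||% config$output$dir %||%
    stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  artifacts <- character()
  timings <- list()
  log_stage <- function(stage, secs) {
    timings[[stage]] <<- round(secs, 3)
    message(sprintf("[spacomod] stage=%s wall=%.3fs", stage, secs))
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    log_stage(name, proc.time()[["elapsed"]] - t0)
    res
  }

  data <- stage("load", function() load_pipeline_data(config))
  ds <- data$srt
  if (isTRUE(config$projection$enabled)) {
    ds <- stage("projection", function() {
      averages <- data$averages %||%
        compute_annotation_averages(data$scrna, config$projection$level)
      project_to_spatial(data$srt, averages, config$projection$level,
                         strict = isTRUE(config$projection$strict))
    })
  }
  selection <- stage("selection", function() {
    sc <- config$selection
    switch(sc$mode,
      annotation = select_by_annotation(ds, sc$level, sc$label),
      flood = {
        g <- build_knn_graph(ds, k = sc$k %||% 10L,
                             metric = sc$metric %||% "euclidean")
        flood_fill(g, sc$seed_cell, steps = sc$steps %||% 10L)
      },
      explicit = select_explicit(ds, unlist(sc$indices)))
  })
  p <- file.path(out_dir, "selection.json")
  write_selection(selection, p); artifacts <- c(artifacts, p)

  scores <- stage("filter", function() {
    fc <- config$filter
    filter_genes(ds, selection, metric = fc$metric, n_keep = fc$n_keep,
                 axis = fc$axis,
                 weight_scheme = fc$weight_scheme %||% "knn",
                 weight_k = fc$weight_k %||% 15L,
                 weight_cutoff = fc$weight_cutoff)
  })
  p <- file.path(out_dir, "gene_scores.csv")
  write_table(scores, p); artifacts <- c(artifacts, p)

  modules <- stage("clustering", function() {
    cluster_genes(scores, ds, selection, k = config$clustering$k,
                  linkage = config$clustering$linkage %||% "average")
  })
  p <- file.path(out_dir, "module_assignments.csv")
  write_table(module_assignments(modules), p); artifacts <- c(artifacts, p)
  maps <- data.frame(cell_id = ds$cell_ids[selection$indices],
                     stringsAsFactors = FALSE)
  for (m in seq_len(modules$k)) {
    maps[[paste0("module_", m)]] <- modules$mean_maps[m, ]
    maps[[paste0("module_", m, "_normalized")]] <- modules$normalized_maps[m, ]
  }
  p <- file.path(out_dir, "module_maps.csv")
  write_table(maps, p); artifacts <- c(artifacts, p)

  enrichment <- NULL
  if (!is.null(config$enrichment)) {
    enrichment <- stage("enrichment", function() {
      ec <- config$enrichment
      provider <- ec$provider %||% "offline"
      background <- if (isTRUE(ec$use_panel_background %||% TRUE))
        ds$gene_symbols else NULL
      tt <- if (!is.null(ec$term_table)) read_term_table(ec$term_table)
      out <- NULL
      for (m in seq_len(modules$k)) {
        genes <- modules$genes[modules$labels == m]
        res <- if (provider == "offline") {
          enrich_offline(genes, background %||% ds$gene_symbols, tt,
                         alpha = ec$alpha %||% 0.05)
        } else {
          enrich(enrichment_query(genes, background,
                                  organism = ec$organism %||% "mmusculus",
                                  provider = provider),
                 alpha = ec$alpha %||% 0.05)
        }
        tab <- res$table
        if (nrow(tab)) tab <- cbind(module = m, tab)
        out <- rbind(out, tab)
      }
      out %||% data.frame(module = integer(), term_id = character(),
                          term_name = character(), p_value = numeric(),
                          p_adjusted = numeric(), overlap = character(),
                          overlap_size = integer(), term_size = integer())
    })
    p <- file.path(out_dir, "enrichment.csv")
    write_table(enrichment, p); artifacts <- c(artifacts, p)
  }

  cfg_plain <- unclass(config)
  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg_plain, cfg_file)
  manifest <- list(
    config = cfg_plain,
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    versions = list(spacomod = as.character(utils::packageVersion("spacomod")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timings_sec = timings,
    artifacts = basename(artifacts))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir, manifest = manifest, selection = selection,
                 scores = scores, modules = modules, enrichment = enrichment))
}

load_pipeline_data <- function(config) {
  dc <- config$data
  if (isTRUE(dc$synthetic)) {
    spec_args <- dc$spec %||% list()
    spec_args$seed <- spec_args$seed %||% config$seed
    sim <- generate_synthetic(do.call(synth_spec, spec_args))
    return(list(srt = sim$srt, scrna = sim$scrna, averages = NULL))
  }
  if (is.null(dc$srt)) stop("data$srt path (or data$synthetic) required",
                            call. = FALSE)
  srt <- read_spatial(dc$srt, layout = dc$layout %||% "h5ad",
                      coord_key = dc$coord_key %||% "spatial",
                      config = dc$h5_config %||% list())
  scrna <- if (!is.null(dc$scrna)) read_scrna(dc$scrna)
  averages <- if (!is.null(dc$averages)) read_annotation_averages(dc$averages)
  list(srt = srt, scrna = scrna, averages = averages)
}
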