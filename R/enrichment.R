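#' Construct a gene-set enrichment query
#'
#' Validates the combination of provider, background and organism before
#' any computation or network call. The ToppGene API accepts neither a
#' custom background nor an organism, so those are rejected up front; it is
#' intended for transcriptome-wide (projected scRNA-seq) queries. For
#' queries restricted to an SRT gene panel, the full measured panel should
#' be passed as `background_genes` so overrepresentation is assessed
#' against the assayable universe.
#'
#' @param query_genes character vector of gene symbols (>= 1).
#' @param background_genes optional character vector; must be a superset of
#'   `query_genes`.
#' @param organism organism identifier (g:Profiler style, e.g. `"mmusculus"`).
#' @param provider `"offline"`, `"gprofiler"` or `"toppgene"`.
#' @param correction multiple-testing correction; `"bonferroni"`.
#' @return an `EnrichmentQuery` object.
#' @export
enrichment_query <- function(query_genes, background_genes = NULL,
                             organism = "mmusculus",
                             provider = c("offline", "gprofiler", "toppgene"),
                             correction = "bonferroni") {
  provider <- match.arg(provider)
  query_genes <- unique(as.character(query_genes))
  if (!length(query_genes)) stop("query gene list is empty", call. = FALSE)
  if (!is.null(background_genes)) {
    background_genes <- unique(as.character(background_genes))
    missing <- setdiff(query_genes, background_genes)
    if (length(missing)) {
      stop("background must contain every query gene; missing: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (provider == "toppgene" && !is.null(background_genes)) {
    stop("config error: the ToppGene API does not support a custom ",
         "background gene set; use gprofiler or offline", call. = FALSE)
  }
  structure(list(query_genes = query_genes,
                 background_genes = background_genes,
                 organism = organism, provider = provider,
                 correction = correction),
            class = c("EnrichmentQuery", "list"))
}

new_enrichment_result <- function(rows, query, provider) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows)) rows <- rows[order(rows$p_adjusted, rows$term_id), ]
  rownames(rows) <- NULL
  structure(list(table = rows, provider = provider, query = query),
            class = c("EnrichmentResult", "list"))
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("EnrichmentResult (", x$provider, "): ", nrow(x$table),
      " significant terms for ", length(x$query$query_genes),
      " query genes\n", sep = "")
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Run an enrichment query
#'
#' Dispatches on the provider: the offline engine needs a `term_table`;
#' online providers (g:Profiler g:GOSt, ToppGene ToppFun) need network
#' access and the `httr` package. Online responses are mapped into the same
#' `EnrichmentResult` shape. An empty result set is a valid outcome, not an
#' error; transport failures raise a condition of class
#' `spacomod_transport_error` so callers can retry.
#'
#' @param query an [enrichment_query()]
#' @param term_table offline provider: named list term_id -> character
#'   vector of member gene symbols, or a list as returned by
#'   [read_term_table()].
#' @param alpha significance threshold applied to adjusted p-values.
#' @param timeout per-request timeout in seconds (online providers).
#' @param max_attempts transport retry count (online providers).
#' @return an `EnrichmentResult`: table of
#'   `(term_id, term_name, p_value, p_adjusted, overlap)` sorted by
#'   ascending adjusted p-value.
#' @export
enrich <- function(query, term_table = NULL, alpha = 0.05, timeout = 30,
                   max_attempts = 3) {
  switch(query$provider,
    offline = {
      if (is.null(term_table)) {
        stop("offline provider requires a term_table", call. = FALSE)
      }
      enrich_offline(query$query_genes,
                     query$background_genes %||%
                       stop("offline provider requires background_genes",
                            call. = FALSE),
                     term_table, correction = query$correction, alpha = alpha)
    },
    gprofiler = enrich_gprofiler(query, alpha, timeout, max_attempts),
    toppgene = enrich_toppgene(query, alpha, timeout, max_attempts))
}

#' Offline hypergeometric overrepresentation with Bonferroni correction
#'
#' For each term, the one-sided hypergeometric tail probability
#' `P(X >= overlap)` of drawing at least the observed overlap when
#' `|query|` genes are drawn without replacement from the background
#' universe containing `|term ∩ background|` term genes. Adjusted p-values
#' are Bonferroni: `min(1, m * p)` with `m` the number of terms tested.
#' Deterministic and network-free; also serves as the test double for the
#' online providers.
#'
#' @param query_genes gene symbols of the module under test.
#' @param background_genes the gene universe (must cover the query).
#' @param term_table named list `term_id -> gene symbols`, or a list with
#'   entries `genes` (that named list) and optional `names` (term_id ->
#'   readable name), as produced by [read_term_table()].
#' @param correction only `"bonferroni"` is implemented.
#' @param alpha report terms with `p_adjusted <= alpha`; `alpha = 1` keeps
#'   every term with nonzero overlap.
#' @return an `EnrichmentResult` (see [enrich()]).
#' @export
enrich_offline <- function(query_genes, background_genes, term_table,
                           correction = "bonferroni", alpha = 0.05) {
  if (!length(background_genes)) stop("empty background", call. = FALSE)
  query_genes <- unique(as.character(query_genes))
  background_genes <- unique(as.character(background_genes))
  missing <- setdiff(query_genes, background_genes)
  if (length(missing)) {
    stop("background must contain every query gene; missing: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  if (!identical(correction, "bonferroni")) {
    stop("only bonferroni correction is implemented", call. = FALSE)
  }
  tt <- normalize_term_table(term_table)
  terms <- names(tt$genes)
  m <- length(terms)
  if (!m) stop("term table is empty", call. = FALSE)
  Nbg <- length(background_genes)
  ndraw <- length(query_genes)
  rows <- lapply(terms, function(tid) {
    tg <- intersect(tt$genes[[tid]], background_genes)
    ov <- query_genes[query_genes %in% tg] # preserves query order
    kobs <- length(ov)
    # upper tail P(X >= kobs); phyper is P(X <= q) so use q = kobs - 1
    p <- stats::phyper(kobs - 1, length(tg), Nbg - length(tg), ndraw,
                       lower.tail = FALSE)
    data.frame(term_id = tid,
               term_name = tt$names[[tid]] %||% tid,
               p_value = p,
               p_adjusted = min(1, m * p),
               overlap = paste(ov, collapse = ";"),
               overlap_size = kobs,
               term_size = length(tg),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  rows <- rows[rows$overlap_size > 0 & rows$p_adjusted <= alpha, , drop = FALSE]
  q <- enrichment_query(query_genes, background_genes, provider = "offline",
                        correction = correction)
  new_enrichment_result(rows, q, "offline")
}

normalize_term_table <- function(term_table) {
  if (is.list(term_table) && !is.null(term_table$genes)) {
    list(genes = term_table$genes, names = term_table$names %||% list())
  } else {
    if (is.null(names(term_table))) {
      stop("term_table must be a named list (term_id -> genes)", call. = FALSE)
    }
    list(genes = term_table, names = list())
  }
}

#' Read a term -> gene-set table (two-column TSV or GMT)
#'
#' TSV: two columns `term_id<TAB>gene_symbol`, one row per membership, with
#' an optional third column giving the term's readable name. GMT: standard
#' `term<TAB>description<TAB>gene1<TAB>gene2...` lines.
#'
#' @param path file path; `.gmt` extension selects GMT parsing.
#' @return list with `genes` (named list term_id -> gene symbols) and
#'   `names` (named list term_id -> readable name).
#' @export
read_term_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- vapply(parts, `[[`, "", 1L)
    genes <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(genes) <- ids
    nms <- as.list(vapply(parts, `[[`, "", 2L))
    names(nms) <- ids
    return(list(genes = genes, names = nms))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  genes <- lapply(split(df[[2]], df[[1]]), unique)
  nms <- list()
  if (ncol(df) >= 3) {
    first <- df[!duplicated(df[[1]]), ]
    nms <- as.list(first[[3]])
    names(nms) <- first[[1]]
  }
  list(genes = genes, names = nms)
}

#' Overlap genes of a term, in query order
#'
#' @param result an [enrich()] result
#' @param term_id term identifier present in the result
#' @return character vector of the term's overlap genes.
#' @export
genes_for_term <- function(result, term_id) {
  i <- match(term_id, result$table$term_id)
  if (is.na(i)) stop("unknown term '", term_id, "'", call. = FALSE)
  strsplit(result$table$overlap[i], ";", fixed = TRUE)[[1]]
}

# ---- online providers ------------------------------------------------------
# Request builders are pure functions so payload construction is testable
# without network access.

build_gprofiler_request <- function(query) {
  body <- list(organism = query$organism,
               query = query$query_genes,
               sources = list("GO:BP", "GO:MF", "GO:CC"),
               significance_threshold_method = "bonferroni",
               user_threshold = 0.05)
  if (!is.null(query$background_genes)) {
    body$domain_scope <- "custom"
    body$background <- query$background_genes
  }
  list(url = "https://biit.cs.ut.ee/gprofiler/api/gost/profile/", body = body)
}

build_toppgene_request <- function(query) {
  list(url = "https://toppgene.cchmc.org/API/enrich",
       body = list(Symbols = query$query_genes,
                   Categories = list(list(Type = "GeneOntologyBiologicalProcess",
                                          PValue = 0.05,
                                          Correction = "Bonferroni"))))
}

http_post_json <- function(url, body, timeout, max_attempts) {
  if (!requireNamespace("httr", quietly = TRUE)) {
    stop("online enrichment providers require the 'httr' package",
         call. = FALSE)
  }
  attempt <- 1
  repeat {
    resp <- tryCatch(
      httr::POST(url, body = jsonlite::toJSON(body, auto_unbox = TRUE),
                 httr::content_type_json(), httr::timeout(timeout)),
      error = function(e) e)
    ok <- !inherits(resp, "error") && httr::status_code(resp) < 400
    if (ok) {
      return(jsonlite::fromJSON(httr::content(resp, as = "text",
                                              encoding = "UTF-8"),
                                simplifyVector = FALSE))
    }
    if (attempt >= max_attempts) {
      msg <- if (inherits(resp, "error")) conditionMessage(resp)
             else paste("HTTP", httr::status_code(resp))
      stop(structure(class = c("spacomod_transport_error", "error",
                               "condition"),
                     list(message = paste0("enrichment request failed after ",
                                           attempt, " attempts: ", msg),
                          call = NULL)))
    }
    Sys.sleep(2^(attempt - 1))
    attempt <- attempt + 1
  }
}

enrich_gprofiler <- function(query, alpha, timeout, max_attempts) {
  req <- build_gprofiler_request(query)
  resp <- http_post_json(req$url, req$body, timeout, max_attempts)
  rows <- lapply(resp$result, function(r) {
    data.frame(term_id = r$native, term_name = r$name,
               p_value = r$p_value, p_adjusted = r$p_value,
               overlap = paste(intersect(query$query_genes,
                                         unlist(r$intersections)),
                               collapse = ";"),
               overlap_size = r$intersection_size %||% NA_integer_,
               term_size = r$term_size %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(), term_name = character(),
               p_value = numeric(), p_adjusted = numeric(),
               overlap = character(), overlap_size = integer(),
               term_size = integer())
  rows <- rows[!is.na(rows$p_adjusted) & rows$p_adjusted <= alpha, ,
               drop = FALSE]
  new_enrichment_result(rows, query, "gprofiler")
}

enrich_toppgene <- function(query, alpha, timeout, max_attempts) {
  req <- build_toppgene_request(query)
  resp <- http_post_json(req$url, req$body, timeout, max_attempts)
  rows <- lapply(resp$Annotations, function(r) {
    genes <- vapply(r$Genes %||% list(), function(g) g$Symbol %||% "", "")
    data.frame(term_id = r$ID, term_name = r$Name,
               p_value = r$PValue,
               p_adjusted = r$QValueBonferroni %||% r$PValue,
               overlap = paste(intersect(query$query_genes, genes),
                               collapse = ";"),
               overlap_size = length(intersect(query$query_genes, genes)),
               term_size = r$TotalGenes %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(), term_name = character(),
               p_value = numeric(), p_adjusted = numeric(),
               overlap = character(), overlap_size = integer(),
               term_size = integer())
  rows <- rows[!is.na(rows$p_adjusted) & rows$p_adjusted <= alpha, ,
               drop = FALSE]
  new_enrichment_result(rows, query, "toppgene")
}
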