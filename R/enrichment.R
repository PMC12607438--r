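# Hypergeometric term enrichment over user-supplied annotations and
# confidence-filtered PPI hub analysis. Annotation content (GO/KEGG-style
# terms, STRING-style edges) is always supplied as input tables; nothing is
# fetched from a database.

#' Hypergeometric enrichment of a gene set against an annotation map
#'
#' For each term with at least one query hit, computes the upper-tail
#' hypergeometric p-value for drawing `k` term genes in a query of size `n`
#' from a universe of size `N` containing `K` term genes, then adjusts with
#' BH within each namespace. Annotation genes outside the universe are
#' dropped; query genes outside the universe are an error.
#'
#' @param query_genes Character vector of query gene ids (subset of
#'   `universe`).
#' @param annotation Data.frame `term_id`, `term_name`, `namespace`,
#'   `gene_id`.
#' @param universe Character vector: the background gene set.
#' @return Data.frame `term_id`, `term_name`, `namespace`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, `genes` (comma-separated overlap), sorted by p.
#' @export
hypergeom_enrich <- function(query_genes, annotation, universe) {
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  outside <- setdiff(query_genes, universe)
  if (length(outside))
    stop("query genes outside universe: ",
         paste(utils::head(outside, 3), collapse = ", "))
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  n <- length(query_genes)
  N <- length(universe)
  terms <- unique(annotation[, c("term_id", "term_name", "namespace")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- unique(annotation$gene_id[
      annotation$term_id == terms$term_id[i]])
    if (!length(genes)) return(NULL)  # empty term sets are invalid input
    hit <- intersect(genes, query_genes)
    k <- length(hit)
    if (k == 0) return(NULL)
    K <- length(genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               namespace = terms$namespace[i], k = k, K = K, n = n, N = N,
               p = min(1, p), genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p = numeric(0), q = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (ns in unique(out$namespace))
    out$q[out$namespace == ns] <- bh_adjust(out$p[out$namespace == ns])
  out <- out[order(out$p, out$term_id), ,
             drop = FALSE][, c("term_id", "term_name", "namespace",
                               "k", "K", "n", "N", "p", "q", "genes")]
  rownames(out) <- NULL
  out
}

#' Filter PPI edges by confidence and rank hub genes by degree
#'
#' Keeps undirected edges with `confidence >= min_conf` (inclusive), drops
#' self-loops and duplicate edges, and reports the `top_n` genes by degree
#' (ties broken by gene name).
#'
#' @param edges Data.frame `gene_a`, `gene_b`, `confidence` in [0, 1].
#' @param min_conf Confidence floor (default 0.40).
#' @param top_n Number of hub genes to report.
#' @return List: `edges` (filtered), `hubs` (data.frame `gene`, `degree`).
#' @export
ppi_filter_and_hubs <- function(edges, min_conf = 0.40, top_n = 10) {
  stopifnot(all(edges$confidence >= 0), all(edges$confidence <= 1))
  e <- edges[edges$confidence >= min_conf &
               edges$gene_a != edges$gene_b, , drop = FALSE]
  key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  e <- e[!duplicated(key), , drop = FALSE]
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL
  if (nrow(e)) {
    deg <- table(c(e$gene_a, e$gene_b))
    ord <- order(-as.integer(deg), names(deg))
    hubs <- data.frame(gene = names(deg)[ord],
                       degree = as.integer(deg)[ord],
                       stringsAsFactors = FALSE)
    hubs <- utils::head(hubs, top_n)
  } else {
    hubs <- data.frame(gene = character(0), degree = integer(0),
                       stringsAsFactors = FALSE)
  }
  list(edges = e, hubs = hubs)
}

#' Long-format term-to-gene table for enriched terms
#'
#' One row per (term, overlapping gene) with the term's q-value, sorted by
#' q then term — the tabular backbone of Sankey/bubble-style reporting.
#' Row count equals the sum of the per-term overlap counts `k`.
#'
#' @param enrichment [hypergeom_enrich()] output.
#' @return Data.frame `term_id`, `gene_id`, `q`.
#' @export
pathway_gene_table <- function(enrichment) {
  if (!nrow(enrichment))
    return(data.frame(term_id = character(0), gene_id = character(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(enrichment)), function(i) {
    genes <- strsplit(enrichment$genes[i], ",")[[1]]
    data.frame(term_id = enrichment$term_id[i], gene_id = genes,
               q = enrichment$q[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$q, out$term_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
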