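# Sign-constrained correlation filtering and ceRNA triad assembly. The
# sponge logic requires the miRNA to be negatively correlated with both its
# circRNA sponge and its mRNA target, while circRNA and mRNA move together
# (positive correlation), on top of predicted binding and differential
# expression of all three members.

#' Pearson correlation with a t-distribution p-value
#'
#' Standard product-moment correlation; the two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. A
#' perfect correlation (|r| = 1) returns the smallest representable
#' positive p rather than 0. A constant vector makes r undefined: the
#' result is flagged degenerate (`r = NA`, `p = NA`), never silently 0.
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @return List with `r`, `p`, `n`, `degenerate`.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3), c(6, 4, 2))  # r = -1
pearson_cor <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need equal-length vectors, n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(r = r, p = p, n = n, degenerate = FALSE)
}

# log2(CPM + 1) expression profiles over the given samples.
log_cpm <- function(counts, samples) {
  m <- counts[, samples, drop = FALSE]
  log2(cpm_matrix(m) + 1)
}

de_ids <- function(de_table) {
  if (is.null(de_table) || !nrow(de_table)) return(character(0))
  de_table$feature_id[de_table$call != "ns"]
}

#' Build sign-constrained correlation edges for one contrast
#'
#' Candidate pairs are (DE circRNA x DE miRNA with predicted binding),
#' (DE miRNA x DE mRNA with predicted binding), and (DE circRNA x DE mRNA
#' sharing at least one predicted miRNA). Each candidate is kept iff its
#' Pearson correlation on log2(CPM+1) profiles passes the sign-specific
#' threshold (`r <= r_neg_max` for the two repressive classes,
#' `r >= r_pos_min` for circRNA-mRNA) at `p <= corr_p_max`.
#'
#' @param de_tables Named list of [call_de()] outputs:
#'   `circRNA`, `miRNA`, `mRNA`.
#' @param target_pairs [predict_pairs()] output.
#' @param counts Named list of count matrices per layer.
#' @param design Design table.
#' @param contrast Character `c(A, B)`.
#' @param config [cerna_config()] list. `corr_samples = "all"` correlates
#'   over every sample; `"contrast"` (default) over the two groups only.
#' @return List of edge data.frames `circ_mir`, `mir_mrna`, `circ_mrna`,
#'   each with `node_a`, `node_b`, `r`, `p`, `n`.
#' @export
build_pairs <- function(de_tables, target_pairs, counts, design, contrast,
                        config = cerna_config()) {
  validate_design(design)
  samples <- if (config$corr_samples == "all") design$sample_id
  else design$sample_id[design$group %in% contrast]
  dec <- de_ids(de_tables$circRNA)
  dem <- de_ids(de_tables$miRNA)
  deg <- de_ids(de_tables$mRNA)
  if (!length(dec) || !length(dem) || !length(deg))
    warning("empty DE table for at least one layer; pairs will be empty")

  expr <- list(
    circRNA = log_cpm(counts$circRNA, samples),
    miRNA = log_cpm(counts$miRNA, samples),
    mRNA = log_cpm(counts$mRNA, samples))

  edge_df <- function() data.frame(
    node_a = character(0), node_b = character(0), r = numeric(0),
    p = numeric(0), n = integer(0), stringsAsFactors = FALSE)

  test_edges <- function(pairs, layer_a, layer_b, sign) {
    if (!nrow(pairs)) return(edge_df())
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs[i, 1]
      b <- pairs[i, 2]
      ct <- pearson_cor(expr[[layer_a]][a, ], expr[[layer_b]][b, ])
      if (ct$degenerate) return(NULL)
      ok <- if (sign == "neg") ct$r <= config$r_neg_max
      else ct$r >= config$r_pos_min
      if (!ok || ct$p > config$corr_p_max) return(NULL)
      data.frame(node_a = a, node_b = b, r = ct$r, p = ct$p, n = ct$n,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(edge_df())
    out <- do.call(rbind, rows)
    out[order(out$node_a, out$node_b), , drop = FALSE]
  }

  tp <- target_pairs
  cm_cand <- unique(tp[tp$target_kind == "circRNA" &
                         tp$target_id %in% dec & tp$mirna_id %in% dem,
                       c("target_id", "mirna_id")])
  mm_cand <- unique(tp[tp$target_kind == "utr3" &
                         tp$target_id %in% deg & tp$mirna_id %in% dem,
                       c("mirna_id", "target_id")])
  # circ-mRNA candidates share >= 1 predicted (and DE) miRNA
  cg_cand <- if (nrow(cm_cand) && nrow(mm_cand)) {
    j <- merge(cm_cand, mm_cand, by = "mirna_id")
    unique(j[, c("target_id.x", "target_id.y")])
  } else data.frame(a = character(0), b = character(0))
  names(cg_cand) <- c("circ", "mrna")

  list(
    circ_mir = test_edges(cm_cand, "circRNA", "miRNA", "neg"),
    mir_mrna = test_edges(mm_cand, "miRNA", "mRNA", "neg"),
    circ_mrna = test_edges(cg_cand, "circRNA", "mRNA", "pos"))
}

#' Assemble ceRNA triads from the three edge classes
#'
#' A triad (circRNA, miRNA, mRNA) is emitted iff the circRNA-miRNA and
#' miRNA-mRNA repressive edges exist for a shared miRNA and the positive
#' circRNA-mRNA edge exists as well. Output is deduplicated and sorted.
#'
#' @param pair_sets Output of [build_pairs()].
#' @return Data.frame: `circ_id`, `mir_id`, `mrna_id` and the r/p of the
#'   three edges (`r_cm`, `p_cm`, `r_mg`, `p_mg`, `r_cg`, `p_cg`).
#' @export
assemble_triads <- function(pair_sets) {
  cm <- pair_sets$circ_mir
  mg <- pair_sets$mir_mrna
  cg <- pair_sets$circ_mrna
  empty <- data.frame(circ_id = character(0), mir_id = character(0),
                      mrna_id = character(0), r_cm = numeric(0),
                      p_cm = numeric(0), r_mg = numeric(0),
                      p_mg = numeric(0), r_cg = numeric(0),
                      p_cg = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(cm) || !nrow(mg) || !nrow(cg)) return(empty)
  j <- merge(
    stats::setNames(cm, c("circ_id", "mir_id", "r_cm", "p_cm", "n_cm")),
    stats::setNames(mg, c("mir_id", "mrna_id", "r_mg", "p_mg", "n_mg")),
    by = "mir_id")
  j <- merge(
    j, stats::setNames(cg, c("circ_id", "mrna_id", "r_cg", "p_cg", "n_cg")),
    by = c("circ_id", "mrna_id"))
  if (!nrow(j)) return(empty)
  out <- j[, c("circ_id", "mir_id", "mrna_id", "r_cm", "p_cm",
               "r_mg", "p_mg", "r_cg", "p_cg")]
  out <- out[!duplicated(out[, 1:3]), , drop = FALSE]
  out <- out[order(out$circ_id, out$mir_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bipartite DEM-DEG regulatory network
#'
#' miRNA-mRNA edges passing the binding and negative-correlation filters,
#' optionally restricted to a gene whitelist (e.g. a reproduction-associated
#' screen). A `NULL` whitelist applies no restriction; an empty character
#' vector yields an empty network.
#'
#' @param de_mirnas,de_genes [call_de()] outputs for miRNA and mRNA.
#' @param target_pairs [predict_pairs()] output.
#' @param counts Named list of count matrices (`miRNA`, `mRNA`).
#' @param design Design table.
#' @param contrast Character `c(A, B)`.
#' @param config [cerna_config()] list.
#' @param whitelist Optional character vector of mRNA ids.
#' @return Edge data.frame `node_a` (miRNA), `node_b` (mRNA), `r`, `p`, `n`.
#' @export
dem_deg_network <- function(de_mirnas, de_genes, target_pairs, counts,
                            design, contrast, config = cerna_config(),
                            whitelist = NULL) {
  if (!is.null(whitelist))
    de_genes <- de_genes[de_genes$feature_id %in% whitelist, , drop = FALSE]
  samples <- if (config$corr_samples == "all") design$sample_id
  else design$sample_id[design$group %in% contrast]
  dem <- de_ids(de_mirnas)
  deg <- de_ids(de_genes)
  tp <- target_pairs
  cand <- unique(tp[tp$target_kind == "utr3" & tp$target_id %in% deg &
                      tp$mirna_id %in% dem, c("mirna_id", "target_id")])
  if (!nrow(cand))
    return(data.frame(node_a = character(0), node_b = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE))
  expr_m <- log_cpm(counts$miRNA, samples)
  expr_g <- log_cpm(counts$mRNA, samples)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    ct <- pearson_cor(expr_m[cand$mirna_id[i], ], expr_g[cand$target_id[i], ])
    if (ct$degenerate || ct$r > config$r_neg_max ||
        ct$p > config$corr_p_max) return(NULL)
    data.frame(node_a = cand$mirna_id[i], node_b = cand$target_id[i],
               r = ct$r, p = ct$p, n = ct$n, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(node_a = character(0), node_b = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

# Unique relationship pairs (circ-mir and mir-mrna) of a triad table.
triad_pairs <- function(triads) {
  if (!nrow(triads))
    return(data.frame(mir_id = character(0), partner = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  unique(rbind(
    data.frame(mir_id = triads$mir_id, partner = triads$circ_id,
               class = "circ_mir", stringsAsFactors = FALSE),
    data.frame(mir_id = triads$mir_id, partner = triads$mrna_id,
               class = "mir_mrna", stringsAsFactors = FALSE)))
}

#' Select the core network shared by several comparisons
#'
#' Per comparison, miRNAs are ranked by the number of relationship pairs
#' they appear in (degree over unique circRNA-miRNA plus miRNA-mRNA pairs),
#' with ties broken by miRNA id, and the top `k` are taken. The core is the
#' set intersection of those per-comparison top-k sets; the returned triads
#' are the input triads whose miRNA is in the core.
#'
#' @param triads_by_comparison Named list (>= 2) of [assemble_triads()]
#'   outputs.
#' @param k Top-k cutoff per comparison (>= 1).
#' @return List of class `"core_network"`: `mirnas` (core set), `top_k`
#'   (per-comparison ranked top-k ids), `triads` (per-comparison filtered
#'   triad tables), `k`.
#' @export
select_core <- function(triads_by_comparison, k = 10) {
  if (k < 1) stop("k must be >= 1")
  if (length(triads_by_comparison) < 2)
    stop("need >= 2 comparisons")
  top_k <- lapply(triads_by_comparison, function(tr) {
    pr <- triad_pairs(tr)
    if (!nrow(pr)) return(character(0))
    deg <- table(pr$mir_id)
    ord <- order(-as.integer(deg), names(deg))
    utils::head(names(deg)[ord], k)
  })
  core <- Reduce(intersect, top_k)
  triads <- lapply(triads_by_comparison, function(tr)
    tr[tr$mir_id %in% core, , drop = FALSE])
  structure(list(mirnas = sort(core), top_k = top_k, triads = triads,
                 k = k), class = "core_network")
}

#' Integrate two core networks into one cross-comparison triple network
#'
#' A triad is kept iff its (miRNA, mRNA) identity occurs in both cores and
#' its mRNA is in the whitelist (`NULL` = no restriction; an empty set
#' yields an empty integration). The result is the deduplicated union of
#' the qualifying triads from both cores plus the flattened interaction
#' pair list (each triad contributes its circRNA-miRNA and miRNA-mRNA
#' pairs, deduplicated).
#'
#' @param core_a,core_b `"core_network"` objects (or plain triad tables).
#' @param gene_whitelist Optional character vector of mRNA ids.
#' @return List: `triads` (circ_id, mir_id, mrna_id), `pairs`
#'   (source, relation, target, with `sponges`/`targets` relations).
#' @export
integrate_networks <- function(core_a, core_b, gene_whitelist = NULL) {
  flat <- function(x) {
    tr <- if (inherits(x, "core_network"))
      do.call(rbind, lapply(x$triads, function(t)
        t[, c("circ_id", "mir_id", "mrna_id"), drop = FALSE]))
    else x[, c("circ_id", "mir_id", "mrna_id"), drop = FALSE]
    if (is.null(tr)) tr <- data.frame(circ_id = character(0),
                                      mir_id = character(0),
                                      mrna_id = character(0))
    unique(tr)
  }
  ta <- flat(core_a)
  tb <- flat(core_b)
  key <- function(t) paste(t$mir_id, t$mrna_id, sep = "|")
  shared <- intersect(key(ta), key(tb))
  all_tr <- unique(rbind(ta, tb))
  keep <- key(all_tr) %in% shared
  if (!is.null(gene_whitelist))
    keep <- keep & all_tr$mrna_id %in% gene_whitelist
  tr <- all_tr[keep, , drop = FALSE]
  tr <- tr[order(tr$circ_id, tr$mir_id, tr$mrna_id), , drop = FALSE]
  rownames(tr) <- NULL
  pairs <- if (nrow(tr)) unique(rbind(
    data.frame(source = tr$circ_id, relation = "sponges",
               target = tr$mir_id, stringsAsFactors = FALSE),
    data.frame(source = tr$mir_id, relation = "targets",
               target = tr$mrna_id, stringsAsFactors = FALSE)))
  else data.frame(source = character(0), relation = character(0),
                  target = character(0), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$source, pairs$target), , drop = FALSE]
  rownames(pairs) <- NULL
  list(triads = tr, pairs = pairs)
}
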