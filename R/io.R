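# Readers and writers for the on-disk interchange formats: everything is
# tab-separated UTF-8 with a mandatory header row, plus FASTA for sequences
# and SIF/GraphML for network export.

#' Read a sample-to-group design table
#'
#' @param path TSV file with columns `sample_id` and `group`.
#' @return A data.frame with columns `sample_id`, `group`.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_design(d)
  d[, c("sample_id", "group")]
}

#' Write a design table
#' @param design Data.frame with `sample_id` and `group` columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  write_tsv(design[, c("sample_id", "group")], path)
}

#' Validate a design table
#'
#' Checks uniqueness of sample ids, non-empty group labels, and that every
#' group carries at least two replicates (required by any two-group test).
#'
#' @param design Data.frame with `sample_id` and `group` columns.
#' @return `design`, invisibly.
#' @export
validate_design <- function(design) {
  if (!all(c("sample_id", "group") %in% names(design)))
    stop("design must have columns sample_id and group")
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design")
  if (any(!nzchar(design$group)) || any(is.na(design$group)))
    stop("group names must be non-empty")
  if (any(table(design$group) < 2))
    stop("every group needs >= 2 samples")
  invisible(design)
}

#' Read a count matrix for one RNA layer
#'
#' The file must be a TSV whose first column is `feature_id` followed by one
#' column per sample. Columns are reordered to match the design; a sample
#' present in the design but absent from the file is an error, as are
#' duplicated features and non-integer or negative counts.
#'
#' @param path Counts TSV.
#' @param design Design table (see [read_design()]).
#' @return Integer matrix, features x samples, with dimnames.
#' @export
read_counts <- function(path, design) {
  validate_design(design)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "feature_id")
    stop("first column must be feature_id")
  if (anyDuplicated(d$feature_id))
    stop("duplicate feature ids in ", path)
  missing <- setdiff(design$sample_id, names(d)[-1])
  if (length(missing))
    stop("samples in design but not in counts file: ",
         paste(missing, collapse = ", "))
  m <- as.matrix(d[, design$sample_id, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    stop("counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- d$feature_id
  m
}

#' Write a count matrix
#' @param counts Integer matrix with feature rownames and sample colnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  d <- data.frame(feature_id = rownames(counts), counts,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(d, path)
}

# Shared TSV writer: tab-separated, no quoting, no row names, "\n" endings.
# All pipeline outputs funnel through here so runs diff cleanly.
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read sequences from FASTA
#'
#' Sequences are upper-cased and DNA-style `T` is normalized to RNA `U`.
#' Only the alphabet `ACGUN` is accepted after normalization; empty
#' sequences and duplicated ids are errors.
#'
#' @param path FASTA file.
#' @param kind Sequence kind tag: `"miRNA"`, `"utr3"` or `"circRNA"`.
#' @return Data.frame with columns `id`, `seq`, `kind`.
#' @export
read_fasta <- function(path, kind = c("miRNA", "utr3", "circRNA")) {
  kind <- match.arg(kind)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  seqs <- normalize_rna(as.character(ss))
  if (any(!nzchar(seqs))) stop("empty sequence in ", path)
  data.frame(id = ids, seq = unname(seqs), kind = kind,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#' @param records Data.frame with `id` and `seq` columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- normalize_rna(records$seq)
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# Upper-case, T->U, validate ACGUN alphabet.
normalize_rna <- function(x) {
  x <- chartr("t", "u", tolower(x))
  x <- toupper(x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad))
    stop("illegal characters in sequence(s): ",
         paste(utils::head(which(bad), 3), collapse = ", "))
  x
}

#' Export a network edge table
#'
#' Edges must carry `source`, `target` and `relation` columns; node kind tags
#' (`source_kind`, `target_kind`) are kept in the TSV dialect. The SIF
#' dialect writes `source<TAB>relation<TAB>target` rows loadable by
#' Cytoscape; the relation vocabulary is `sponges` (circRNA-miRNA),
#' `targets` (miRNA-mRNA) and `ppi`. Rows are written in a deterministic
#' order (sorted by source then target).
#'
#' @param edges Edge data.frame.
#' @param path Output path.
#' @param dialect One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path, dialect = c("sif", "graphml", "tsv")) {
  if (is.character(dialect) && length(dialect) == 1 &&
      !dialect %in% c("sif", "graphml", "tsv"))
    stop("unknown dialect: ", dialect)
  dialect <- match.arg(dialect)
  need <- c("source", "relation", "target")
  if (nrow(edges) && !all(need %in% names(edges)))
    stop("edges need columns source, relation, target")
  if (nrow(edges))
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  if (dialect == "sif") {
    lines <- if (nrow(edges))
      paste(edges$source, edges$relation, edges$target, sep = "\t")
    else character(0)
    writeLines(lines, path)
  } else if (dialect == "tsv") {
    write_tsv(edges, path)
  } else {
    if (nrow(edges)) {
      verts <- unique(data.frame(
        name = c(edges$source, edges$target),
        kind = c(edges$source_kind %||% rep("node", nrow(edges)),
                 edges$target_kind %||% rep("node", nrow(edges))),
        stringsAsFactors = FALSE))
      verts <- verts[!duplicated(verts$name), , drop = FALSE]
      g <- igraph::graph_from_data_frame(
        edges[, c("source", "target", "relation")],
        directed = FALSE, vertices = verts)
    } else {
      g <- igraph::make_empty_graph(0, directed = FALSE)
    }
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
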