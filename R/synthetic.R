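# Synthetic three-layer data with planted ceRNA sponge axes.
#
# The generator emulates the study design the pipeline is meant for: a small
# grouped ovary-style experiment (4 groups x 3 replicates by default) with
# negative-binomial counts for mRNAs, circRNAs and miRNAs, plus sequences in
# which each planted axis carries a real seed match and 3'-supplementary
# block so the sequence-based target filter can recover it.

#' Default parameters for the synthetic dataset
#'
#' @param n_mrna,n_circ,n_mir Number of features per layer.
#' @param n_axes Number of planted circRNA-miRNA-mRNA sponge axes.
#' @param effect_size Planted group effect in log2 units (the absolute
#'   log2 fold change seen by a contrast between adjacent groups).
#' @param dispersion Negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param baseline_mean Mean of the log-normal baseline expression per
#'   feature (counts at library factor 1).
#' @param n_de_extra Named vector: number of additional (non-axis)
#'   differentially expressed features planted per layer.
#' @param lib_factor_range Library-size factors are drawn log-uniformly in
#'   this range.
#' @return A list of class `"synth_params"`.
#' @export
synth_params <- function(n_mrna = 300, n_circ = 80, n_mir = 60,
                         n_axes = 10, effect_size = 3, dispersion = 0.05,
                         baseline_mean = 150,
                         n_de_extra = c(mRNA = 20, circRNA = 10, miRNA = 8),
                         lib_factor_range = c(0.7, 1.4)) {
  stopifnot(dispersion >= 0, baseline_mean > 0,
            n_axes <= min(n_mrna, n_circ, n_mir))
  p <- list(n_mrna = n_mrna, n_circ = n_circ, n_mir = n_mir,
            n_axes = n_axes, effect_size = effect_size,
            dispersion = dispersion, baseline_mean = baseline_mean,
            n_de_extra = n_de_extra, lib_factor_range = lib_factor_range)
  class(p) <- "synth_params"
  p
}

#' Simulate a grouped sample design
#'
#' @param n_groups Number of groups (>= 2).
#' @param reps Replicates per group (>= 2).
#' @param group_names Optional group labels; default `Group1..GroupN`.
#' @return Design data.frame with `sample_id` (`<group>_r<j>`) and `group`.
#' @export
#' @examples
#' simulate_design(4, 3)  # 12 samples
simulate_design <- function(n_groups = 4, reps = 3, group_names = NULL) {
  if (n_groups < 2) stop("n_groups must be >= 2")
  if (reps < 2) stop("reps must be >= 2")
  if (is.null(group_names)) group_names <- paste0("Group", seq_len(n_groups))
  stopifnot(length(group_names) == n_groups, !anyDuplicated(group_names))
  d <- data.frame(
    sample_id = paste0(rep(group_names, each = reps), "_r", seq_len(reps)),
    group = rep(group_names, each = reps),
    stringsAsFactors = FALSE)
  validate_design(d)
  d
}

#' Simulate counts for the three RNA layers with planted sponge axes
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(group offset) * library factor` and variance
#' `mu + phi * mu^2`. For each planted axis the miRNA receives an
#' alternating group offset of `+/- effect_size/2` and its circRNA and mRNA
#' partners receive the negated offsets, so the miRNA is anti-correlated (in
#' expectation) with both partners while circRNA and mRNA share a profile.
#' Additional non-axis DE features receive random group offsets; all other
#' features are null.
#'
#' @param params A [synth_params()] list.
#' @param design Design table from [simulate_design()].
#' @param seed Integer seed.
#' @return List with `counts` (named list of integer matrices per layer)
#'   and `truth` (class `"cerna_truth"`: `axes`, `de_features`, `offsets`
#'   per layer, `lib_factors` per layer, `baselines`, parameters).
#' @export
simulate_counts <- function(params, design, seed) {
  stopifnot(inherits(params, "synth_params"))
  validate_design(design)
  if (params$dispersion < 0) stop("dispersion must be >= 0")
  set.seed(seed)
  groups <- unique(design$group)
  ng <- length(groups)
  ids <- list(
    mRNA = sprintf("mRNA_%03d", seq_len(params$n_mrna)),
    circRNA = sprintf("circ_%03d", seq_len(params$n_circ)),
    miRNA = sprintf("miR_%03d", seq_len(params$n_mir)))

  # planted axes use the first n_axes features of each layer, paired 1:1;
  # feature indices are private to the generator, the truth table is the API
  axes <- data.frame(
    circ_id = ids$circRNA[seq_len(params$n_axes)],
    mir_id = ids$miRNA[seq_len(params$n_axes)],
    mrna_id = ids$mRNA[seq_len(params$n_axes)],
    effect_size = params$effect_size *
      sample(c(-1, 1), params$n_axes, replace = TRUE),
    stringsAsFactors = FALSE)
  if (any(axes$effect_size == 0)) stop("planted effect must be non-zero")

  # alternating +/- 1/2 pattern over groups: adjacent-group contrasts see
  # the full |effect_size| and the profile spans all samples
  alt <- rep_len(c(0.5, -0.5), ng)
  offsets <- lapply(ids, function(f)
    matrix(0, length(f), ng, dimnames = list(f, groups)))
  for (i in seq_len(nrow(axes))) {
    prof <- alt * axes$effect_size[i]
    offsets$miRNA[axes$mir_id[i], ] <- prof
    offsets$circRNA[axes$circ_id[i], ] <- -prof
    offsets$mRNA[axes$mrna_id[i], ] <- -prof
  }

  # extra (non-axis) DE features: random half-split of groups, +/- effect/2
  de_extra <- list()
  for (layer in names(ids)) {
    n_extra <- unname(params$n_de_extra[layer])
    if (is.na(n_extra) || n_extra == 0) next
    pool <- setdiff(ids[[layer]], c(axes$circ_id, axes$mir_id, axes$mrna_id))
    picked <- utils::head(pool, n_extra)
    for (f in picked) {
      hi <- sample(ng, max(1, ng %/% 2))
      prof <- rep(-params$effect_size / 2, ng)
      prof[hi] <- params$effect_size / 2
      prof <- prof * sample(c(-1, 1), 1)
      offsets[[layer]][f, ] <- prof
    }
    de_extra[[layer]] <- picked
  }

  de_features <- do.call(rbind, lapply(names(ids), function(layer) {
    off <- offsets[[layer]]
    hit <- rownames(off)[rowSums(off != 0) > 0]
    if (!length(hit)) return(NULL)
    data.frame(layer = layer, feature_id = hit,
               group_contrast = paste0(groups[1], "_vs_", groups[2]),
               true_log2fc = off[hit, 2] - off[hit, 1],
               stringsAsFactors = FALSE)
  }))

  baselines <- lapply(ids, function(f) {
    b <- stats::rlnorm(length(f),
                       meanlog = log(params$baseline_mean) - 0.5,
                       sdlog = 1)
    names(b) <- f
    b
  })
  lfr <- params$lib_factor_range
  lib_factors <- lapply(ids, function(f) {
    lf <- exp(stats::runif(nrow(design), log(lfr[1]), log(lfr[2])))
    if (any(lf <= 0)) stop("degenerate library size")
    names(lf) <- design$sample_id
    lf
  })

  counts <- list()
  gidx <- match(design$group, groups)
  for (layer in names(ids)) {
    mu <- outer(baselines[[layer]], lib_factors[[layer]]) *
      2^(offsets[[layer]][, gidx, drop = FALSE])
    y <- if (params$dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / params$dispersion)
    else stats::rpois(length(mu), mu)
    m <- matrix(as.integer(y), nrow(mu), ncol(mu),
                dimnames = list(names(baselines[[layer]]), design$sample_id))
    counts[[layer]] <- m
  }

  truth <- list(axes = axes, de_features = de_features, offsets = offsets,
                baselines = baselines, lib_factors = lib_factors,
                feature_ids = ids, dispersion = params$dispersion,
                baseline_mean = params$baseline_mean, groups = groups,
                params = params)
  class(truth) <- "cerna_truth"
  list(counts = counts, truth = truth)
}

#' Simulate miRNA, 3'UTR and circRNA sequences consistent with the truth
#'
#' Each planted (miRNA, target) pair gets one exact 8mer seed site
#' (reverse complement of miRNA positions 2-8 followed by an A) plus an
#' upstream 9-nt 3'-supplementary complementary block (reverse complement
#' of miRNA positions 13-21), so both the site score and the duplex-energy
#' filter pass even for AU-rich seeds whose stacks are weak. Decoy sequences are scrubbed
#' of any 7mer-or-better site for planted miRNAs. miRNAs are 20-24 nt with a
#' 5' uridine bias (first base U with probability 0.8).
#'
#' @param truth `"cerna_truth"` object from [simulate_counts()].
#' @param seed Integer seed.
#' @return Data.frame of sequence records (`id`, `seq`, `kind`).
#' @export
simulate_sequences <- function(truth, seed) {
  stopifnot(inherits(truth, "cerna_truth"))
  set.seed(seed)
  ids <- truth$feature_ids
  bases <- c("A", "C", "G", "U")

  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE),
                                collapse = "")
  mir_len <- sample(20:24, length(ids$miRNA), replace = TRUE,
                    prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
  mirs <- vapply(seq_along(ids$miRNA), function(i) {
    first <- if (stats::runif(1) < 0.8) "U" else sample(c("A", "C", "G"), 1)
    paste0(first, rand_seq(mir_len[i] - 1))
  }, character(1))
  names(mirs) <- ids$miRNA
  if (any(grepl("N", substr(mirs, 2, 8))))
    stop("ambiguous base in a miRNA seed region")

  utr_len <- round(stats::runif(length(ids$mRNA), 150, 400))
  utrs <- vapply(utr_len, rand_seq, character(1))
  names(utrs) <- ids$mRNA
  circ_len <- round(exp(stats::runif(length(ids$circRNA),
                                     log(200), log(1500))))
  circs <- vapply(circ_len, rand_seq, character(1))
  names(circs) <- ids$circRNA

  # planted site cassette: [supp block][2 nt spacer][8mer seed site]
  plant <- function(target, mir) {
    seed8 <- paste0(revcomp_rna(substr(mir, 2, 8)), "A")
    supp <- revcomp_rna(substr(mir, 13, 21))
    ins <- paste0(supp, paste(sample(bases, 2, replace = TRUE),
                              collapse = ""), seed8)
    # replace an interior stretch so target length is preserved
    w <- nchar(ins)
    pos <- sample(seq(35, nchar(target) - w - 35), 1)
    paste0(substr(target, 1, pos - 1), ins,
           substr(target, pos + w, nchar(target)))
  }
  for (i in seq_len(nrow(truth$axes))) {
    m <- mirs[truth$axes$mir_id[i]]
    utrs[truth$axes$mrna_id[i]] <- plant(utrs[truth$axes$mrna_id[i]], m)
    circs[truth$axes$circ_id[i]] <- plant(circs[truth$axes$circ_id[i]], m)
  }

  # scrub 7mer-or-better sites for planted miRNAs from every sequence that
  # is not that miRNA's planted partner (circRNAs checked on the circular
  # extension so no site hides across the back-splice junction)
  planted <- truth$axes
  scrub <- function(seqs, circular) {
    for (k in seq_len(nrow(planted))) {
      m <- mirs[planted$mir_id[k]]
      pats <- c(revcomp_rna(substr(m, 2, 8)),                 # 7mer-m8 core
                paste0(revcomp_rna(substr(m, 2, 7)), "A"))    # 7mer-A1
      own <- c(planted$mrna_id[k], planted$circ_id[k])
      for (id in setdiff(names(seqs), own)) {
        s <- seqs[[id]]
        for (iter in 1:60) {
          ext <- if (circular) paste0(s, substr(s, 1, 7)) else s
          hit <- regexpr(paste(pats, collapse = "|"), ext)
          if (hit < 0) break
          # mutate a base inside the matched window, mapped back onto the
          # un-extended sequence for BSJ-spanning hits
          p <- ((hit + 2 - 1) %% nchar(s)) + 1
          old <- substr(s, p, p)
          substr(s, p, p) <- sample(setdiff(bases, old), 1)
        }
        seqs[[id]] <- s
      }
    }
    seqs
  }
  utrs <- scrub(utrs, circular = FALSE)
  circs <- scrub(circs, circular = TRUE)

  rbind(
    data.frame(id = names(mirs), seq = unname(mirs), kind = "miRNA",
               stringsAsFactors = FALSE),
    data.frame(id = names(utrs), seq = unname(utrs), kind = "utr3",
               stringsAsFactors = FALSE),
    data.frame(id = names(circs), seq = unname(circs), kind = "circRNA",
               stringsAsFactors = FALSE))
}

#' Simulate a synthetic term annotation over the mRNA universe
#'
#' The first term is seeded with the planted-axis mRNAs (a "reproduction
#' associated"-style gene set) so enrichment of recovered targets is
#' non-trivial; remaining terms are random draws.
#'
#' @param truth `"cerna_truth"` object.
#' @param n_terms Number of terms.
#' @param seed Integer seed.
#' @return Annotation data.frame: `term_id`, `term_name`, `namespace`,
#'   `gene_id`.
#' @export
simulate_annotation <- function(truth, n_terms = 25, seed = 1) {
  set.seed(seed)
  genes <- truth$feature_ids$mRNA
  rows <- list()
  for (t in seq_len(n_terms)) {
    size <- sample(10:40, 1)
    members <- if (t == 1)
      unique(c(truth$axes$mrna_id,
               sample(genes, max(0, size - nrow(truth$axes)))))
    else sample(genes, size)
    rows[[t]] <- data.frame(
      term_id = sprintf("TERM:%04d", t),
      term_name = if (t == 1) "reproductive process" else
        sprintf("process %04d", t),
      namespace = if (t <= ceiling(n_terms / 2)) "BP" else "pathway",
      gene_id = sort(unique(members)), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate a synthetic PPI edge table over host genes
#'
#' @param truth `"cerna_truth"` object.
#' @param n_edges Number of undirected edges.
#' @param seed Integer seed.
#' @return Data.frame `gene_a`, `gene_b`, `confidence` (no self-loops).
#' @export
simulate_ppi <- function(truth, n_edges = 200, seed = 1) {
  set.seed(seed)
  genes <- truth$feature_ids$mRNA
  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  keep <- a != b
  d <- data.frame(gene_a = pmin(a, b)[keep], gene_b = pmax(a, b)[keep],
                  confidence = round(stats::runif(sum(keep)), 3),
                  stringsAsFactors = FALSE)
  d[!duplicated(d[, 1:2]), ]
}

#' Generate the full synthetic dataset
#'
#' Convenience wrapper chaining [simulate_design()], [simulate_counts()],
#' [simulate_sequences()], [simulate_annotation()] and [simulate_ppi()],
#' with child seeds derived from one master seed.
#'
#' @param params [synth_params()] list.
#' @param seed Master integer seed.
#' @param n_groups,reps,group_names Passed to [simulate_design()].
#' @return List: `design`, `counts`, `truth`, `sequences`, `annotation`,
#'   `ppi`.
#' @export
simulate_dataset <- function(params = synth_params(), seed = 1,
                             n_groups = 4, reps = 3, group_names = NULL) {
  design <- simulate_design(n_groups, reps, group_names)
  cn <- simulate_counts(params, design, stage_seed(seed, "counts"))
  seqs <- simulate_sequences(cn$truth, stage_seed(seed, "sequences"))
  ann <- simulate_annotation(cn$truth, seed = stage_seed(seed, "annotation"))
  ppi <- simulate_ppi(cn$truth, seed = stage_seed(seed, "ppi"))
  list(design = design, counts = cn$counts, truth = cn$truth,
       sequences = seqs, annotation = ann, ppi = ppi)
}

#' Write the truth table of a synthetic dataset
#'
#' Two TSVs: the planted axes and the full per-feature per-group log2
#' offsets, so every planted effect is recoverable from disk alone.
#'
#' @param truth `"cerna_truth"` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(truth$axes, file.path(dir, "truth_axes.tsv"))
  long <- do.call(rbind, lapply(names(truth$offsets), function(layer) {
    off <- truth$offsets[[layer]]
    data.frame(layer = layer,
               feature_id = rep(rownames(off), ncol(off)),
               group = rep(colnames(off), each = nrow(off)),
               log2_offset = as.vector(off), stringsAsFactors = FALSE)
  }))
  long <- long[long$log2_offset != 0, ]
  write_tsv(long, file.path(dir, "truth_offsets.tsv"))
  invisible(dir)
}
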