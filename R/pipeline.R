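# End-to-end orchestration: simulate (or load) -> differential expression
# -> target prediction -> correlation filtering -> triad assembly -> core
# selection / integration -> enrichment + PPI, with every stage's table
# written under one run directory and a machine-readable summary.

#' Run the full ceRNA inference pipeline
#'
#' Executes every stage in order and writes its artifacts under
#' `config$out_dir`: `input/` (design, counts, sequences, truth), `de/`
#' (one TSV per layer and contrast), `targets/`, `correlations/`,
#' `network/` (triads, SIF exports, core and integrated networks) and
#' `enrichment/` (term enrichment, pathway-gene table, PPI edges and hubs),
#' plus `summary.json` with the headline counts. Identical seed and
#' configuration give byte-identical outputs. A failing stage aborts with
#' the stage name in the error message.
#'
#' @param config [cerna_config()] list. `config$contrasts` defaults to the
#'   first/second and third/fourth design groups.
#' @param dataset Optional pre-built dataset (as from [simulate_dataset()]);
#'   when `NULL` one is simulated from `config$rng_seed`.
#' @param params [synth_params()] used when simulating.
#' @return Invisibly, a list with the summary, per-contrast DE tables,
#'   target pairs, per-contrast triads, core and integrated networks.
#' @export
run_pipeline <- function(config = cerna_config(), dataset = NULL,
                         params = synth_params()) {
  validate_config(config)
  out <- config$out_dir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  for (d in c("", "input", "de", "targets", "correlations", "network",
              "enrichment"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  ds <- stage("simulate", {
    if (is.null(dataset)) simulate_dataset(params, config$rng_seed)
    else dataset
  })
  stage("write-input", {
    write_design(ds$design, file.path(out, "input", "design.tsv"))
    for (layer in names(ds$counts))
      write_counts(ds$counts[[layer]],
                   file.path(out, "input", paste0("counts_", layer, ".tsv")))
    for (kind in unique(ds$sequences$kind))
      write_fasta(ds$sequences[ds$sequences$kind == kind, ],
                  file.path(out, "input", paste0(kind, ".fasta")))
    if (!is.null(ds$truth)) write_truth(ds$truth, file.path(out, "input"))
    if (!is.null(ds$annotation))
      write_tsv(ds$annotation, file.path(out, "input", "annotation.tsv"))
    if (!is.null(ds$ppi))
      write_tsv(ds$ppi, file.path(out, "input", "ppi.tsv"))
  })

  groups <- unique(ds$design$group)
  contrasts <- config$contrasts
  if (is.null(contrasts)) {
    contrasts <- list(c(groups[1], groups[2]))
    if (length(groups) >= 4)
      contrasts <- c(contrasts, list(c(groups[3], groups[4])))
  }
  cname <- vapply(contrasts, function(ct) paste(ct, collapse = "_vs_"),
                  character(1))

  de <- stage("de", {
    res <- list()
    for (i in seq_along(contrasts)) {
      res[[cname[i]]] <- list(
        circRNA = call_de(ds$counts$circRNA, ds$design, contrasts[[i]],
                          "circRNA", config),
        mRNA = call_de(ds$counts$mRNA, ds$design, contrasts[[i]],
                       "mRNA", config),
        miRNA = call_de(ds$counts$miRNA, ds$design, contrasts[[i]],
                        "miRNA", config))
      for (layer in names(res[[cname[i]]]))
        write_tsv(res[[cname[i]]][[layer]],
                  file.path(out, "de",
                            paste0("de_", layer, "_", cname[i], ".tsv")))
    }
    res
  })

  pairs <- stage("targets", {
    dem_all <- unique(unlist(lapply(de, function(d) de_ids(d$miRNA))))
    dec_all <- unique(unlist(lapply(de, function(d) de_ids(d$circRNA))))
    deg_all <- unique(unlist(lapply(de, function(d) de_ids(d$mRNA))))
    mirs <- ds$sequences[ds$sequences$kind == "miRNA" &
                           ds$sequences$id %in% dem_all, , drop = FALSE]
    tgts <- ds$sequences[
      (ds$sequences$kind == "circRNA" & ds$sequences$id %in% dec_all) |
        (ds$sequences$kind == "utr3" & ds$sequences$id %in% deg_all), ,
      drop = FALSE]
    tp <- predict_pairs(mirs, tgts, config)
    write_tsv(tp, file.path(out, "targets", "target_pairs.tsv"))
    tp
  })

  triads <- list()
  edges <- list()
  for (i in seq_along(contrasts)) {
    nm <- cname[i]
    edges[[nm]] <- stage("correlate", {
      e <- build_pairs(de[[nm]], pairs, ds$counts, ds$design,
                       contrasts[[i]], config)
      for (cl in names(e))
        write_tsv(e[[cl]], file.path(out, "correlations",
                                     paste0(cl, "_", nm, ".tsv")))
      e
    })
    triads[[nm]] <- stage("network", {
      tr <- assemble_triads(edges[[nm]])
      write_tsv(tr, file.path(out, "network", paste0("triads_", nm, ".tsv")))
      sif <- triads_to_edges(tr)
      write_network(sif, file.path(out, "network",
                                   paste0("network_", nm, ".sif")), "sif")
      tr
    })
  }

  core <- integrated <- NULL
  if (length(contrasts) >= 2) {
    core <- stage("core", {
      co <- select_core(triads, k = config$top_k_mirnas)
      writeLines(co$mirnas, file.path(out, "network", "core_mirnas.txt"))
      co
    })
    integrated <- stage("integrate", {
      co_a <- triads[[1]][triads[[1]]$mir_id %in% core$mirnas, ,
                          drop = FALSE]
      co_b <- triads[[2]][triads[[2]]$mir_id %in% core$mirnas, ,
                          drop = FALSE]
      ig <- integrate_networks(co_a, co_b, config$gene_whitelist)
      write_tsv(ig$triads, file.path(out, "network",
                                     "integrated_triads.tsv"))
      write_tsv(ig$pairs, file.path(out, "network",
                                    "integrated_pairs.tsv"))
      ig
    })
  }

  enrich <- stage("enrich", {
    if (is.null(ds$annotation)) NULL else {
      universe <- unique(ds$annotation$gene_id)
      query <- intersect(
        unique(unlist(lapply(de, function(d) de_ids(d$mRNA)))), universe)
      en <- hypergeom_enrich(query, ds$annotation, universe)
      write_tsv(en, file.path(out, "enrichment", "enrichment.tsv"))
      write_tsv(pathway_gene_table(en),
                file.path(out, "enrichment", "pathway_genes.tsv"))
      en
    }
  })

  ppi <- stage("ppi", {
    if (is.null(ds$ppi)) NULL else {
      ph <- ppi_filter_and_hubs(ds$ppi, config$ppi_conf_min,
                                config$top_k_mirnas)
      write_tsv(ph$edges, file.path(out, "enrichment", "ppi_edges.tsv"))
      write_tsv(ph$hubs, file.path(out, "enrichment", "ppi_hubs.tsv"))
      ph
    }
  })

  summary <- stage("summary", {
    s <- list(
      seed = config$rng_seed,
      contrasts = as.list(stats::setNames(
        lapply(cname, function(nm) list(
          n_dec = length(de_ids(de[[nm]]$circRNA)),
          n_dem = length(de_ids(de[[nm]]$miRNA)),
          n_deg = length(de_ids(de[[nm]]$mRNA)),
          n_circ_mir_edges = nrow(edges[[nm]]$circ_mir),
          n_mir_mrna_edges = nrow(edges[[nm]]$mir_mrna),
          n_circ_mrna_edges = nrow(edges[[nm]]$circ_mrna),
          n_triads = nrow(triads[[nm]]))), cname)),
      n_target_pairs = nrow(pairs),
      n_core_mirnas = if (is.null(core)) NA_integer_
        else length(core$mirnas),
      n_integrated_triads = if (is.null(integrated)) NA_integer_
        else nrow(integrated$triads),
      n_integrated_pairs = if (is.null(integrated)) NA_integer_
        else nrow(integrated$pairs),
      n_enriched_terms_q05 = if (is.null(enrich)) NA_integer_
        else sum(enrich$q <= 0.05),
      n_ppi_edges = if (is.null(ppi)) NA_integer_ else nrow(ppi$edges))
    jsonlite::write_json(s, file.path(out, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    s
  })

  invisible(list(summary = summary, de = de, target_pairs = pairs,
                 edges = edges, triads = triads, core = core,
                 integrated = integrated, enrichment = enrich, ppi = ppi,
                 dataset = ds))
}

#' Flatten a triad table into typed sponge/target edges
#'
#' @param triads [assemble_triads()] output.
#' @return Edge data.frame with `source`, `relation`, `target`,
#'   `source_kind`, `target_kind`, suitable for [write_network()].
#' @export
triads_to_edges <- function(triads) {
  if (!nrow(triads))
    return(data.frame(source = character(0), relation = character(0),
                      target = character(0), source_kind = character(0),
                      target_kind = character(0), stringsAsFactors = FALSE))
  unique(rbind(
    data.frame(source = triads$circ_id, relation = "sponges",
               target = triads$mir_id, source_kind = "circRNA",
               target_kind = "miRNA", stringsAsFactors = FALSE),
    data.frame(source = triads$mir_id, relation = "targets",
               target = triads$mrna_id, source_kind = "miRNA",
               target_kind = "mRNA", stringsAsFactors = FALSE)))
}

#' Compare a triad table against the planted truth
#'
#' @param triads [assemble_triads()] output.
#' @param truth `"cerna_truth"` object.
#' @return List: `recall` (planted axes recovered / planted), `unplanted`
#'   (reported triads not planted / reported; 0 when none reported),
#'   `n_triads`.
#' @export
score_recovery <- function(triads, truth) {
  planted <- paste(truth$axes$circ_id, truth$axes$mir_id,
                   truth$axes$mrna_id)
  found <- if (nrow(triads)) paste(triads$circ_id, triads$mir_id,
                                   triads$mrna_id) else character(0)
  recall <- mean(planted %in% found)
  unplanted <- if (length(found)) mean(!(found %in% planted)) else 0
  list(recall = recall, unplanted = unplanted, n_triads = length(found))
}
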