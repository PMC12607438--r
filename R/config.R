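#' Pipeline configuration
#'
#' Bundles every tunable threshold of the ceRNA inference pipeline together
#' with the master RNG seed and input/output paths. Defaults reproduce the
#' thresholds commonly used for this kind of analysis: |log2FC| >= 1 with
#' BH q <= 0.05 for circRNA/mRNA differential expression, raw p <= 0.05 for
#' miRNA differential expression, a 0-100 target-site score cutoff of 50
#' combined with a duplex free energy cutoff of -10 kcal/mol, Pearson
#' r <= -0.4 (repressive edges) / r >= +0.4 (circRNA-mRNA edges) at
#' p <= 0.05, a PPI confidence floor of 0.40, and top-10 miRNA core
#' selection.
#'
#' @param lfc_min Minimum |log2 fold change| for circRNA/mRNA calls (>= 0).
#' @param q_max Maximum BH-adjusted p for circRNA/mRNA calls, in (0, 1].
#' @param p_max Maximum raw p for miRNA calls, in (0, 1].
#' @param r_neg_max Maximum (most permissive) Pearson r for repressive
#'   circRNA-miRNA and miRNA-mRNA edges; must be negative.
#' @param r_pos_min Minimum Pearson r for circRNA-mRNA edges; must be positive.
#' @param corr_p_max Maximum correlation p-value, in (0, 1].
#' @param site_score_min Minimum target-site score, on the 0-100 scale.
#' @param energy_max_kcal Maximum (least stable) duplex free energy in
#'   kcal/mol; pairs with energy above this are discarded.
#' @param ppi_conf_min Minimum PPI confidence score, in [0, 1].
#' @param top_k_mirnas Number of top-degree miRNAs kept per comparison when
#'   selecting the core network (positive integer).
#' @param rng_seed Master seed; every stochastic stage derives a child seed
#'   from it via [stage_seed()].
#' @param corr_samples Which samples correlations are computed on:
#'   `"contrast"` (the two groups being compared) or `"all"` (every sample).
#' @param out_dir Output directory for [run_pipeline()].
#' @param contrasts List of length-2 character vectors, each `c(A, B)` naming
#'   two design groups; fold changes are reported as log2(B/A).
#' @param gene_whitelist Optional character vector of mRNA ids used to
#'   restrict the integrated cross-comparison network; `NULL` = no
#'   restriction.
#'
#' @return A validated list of class `"cerna_config"`.
#' @export
#' @examples
#' cfg <- cerna_config(rng_seed = 1)
#' cfg$q_max
cerna_config <- function(lfc_min = 1, q_max = 0.05, p_max = 0.05,
                         r_neg_max = -0.4, r_pos_min = 0.4,
                         corr_p_max = 0.05, site_score_min = 50,
                         energy_max_kcal = -10, ppi_conf_min = 0.40,
                         top_k_mirnas = 10, rng_seed = 1,
                         corr_samples = c("contrast", "all"),
                         out_dir = "cerna_run", contrasts = NULL,
                         gene_whitelist = NULL) {
  cfg <- list(
    lfc_min = lfc_min, q_max = q_max, p_max = p_max,
    r_neg_max = r_neg_max, r_pos_min = r_pos_min,
    corr_p_max = corr_p_max, site_score_min = site_score_min,
    energy_max_kcal = energy_max_kcal, ppi_conf_min = ppi_conf_min,
    top_k_mirnas = as.integer(top_k_mirnas),
    rng_seed = as.integer(rng_seed),
    corr_samples = match.arg(corr_samples),
    out_dir = out_dir, contrasts = contrasts,
    gene_whitelist = gene_whitelist
  )
  class(cfg) <- "cerna_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A `"cerna_config"` list.
#' @return `cfg`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "cerna_config"))
  if (!is.numeric(cfg$lfc_min) || cfg$lfc_min < 0)
    stop("lfc_min must be a non-negative number")
  for (nm in c("q_max", "p_max", "corr_p_max")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(nm, " must lie in [0, 1]")
  }
  if (!(cfg$r_neg_max < 0)) stop("r_neg_max must be negative")
  if (!(cfg$r_pos_min > 0)) stop("r_pos_min must be positive")
  if (cfg$site_score_min < 0 || cfg$site_score_min > 100)
    stop("site_score_min must lie in [0, 100]")
  if (cfg$ppi_conf_min < 0 || cfg$ppi_conf_min > 1)
    stop("ppi_conf_min must lie in [0, 1]")
  if (cfg$top_k_mirnas < 1) stop("top_k_mirnas must be >= 1")
  invisible(cfg)
}

#' Derive a stage-specific child seed from the master seed
#'
#' Each stochastic stage of the pipeline is seeded with a deterministic
#' function of the master seed and the stage name, so stages are individually
#' reproducible and re-ordering stages cannot silently shift the random
#' stream.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed in [0, 2^31 - 1).
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(seed, stage) {
  stopifnot(length(stage) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 1009 + h * 97) %% (2^31 - 1))
}
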