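# Independent oracles and small fixture builders shared by the tests.

# Brute-force two-sided p for the conditional NB split: enumerate all splits
# of the total via dnbinom/dpois products at an arbitrary mean and apply the
# minimum-likelihood tail rule. Independent of the package's lgamma route.
oracle_exact_p <- function(a, b, phi, mu = 5) {
  s_a <- sum(a)
  t <- s_a + sum(b)
  if (t == 0) return(1)
  n_a <- length(a)
  n_b <- length(b)
  s <- 0:t
  w <- if (phi == 0)
    stats::dpois(s, n_a * mu) * stats::dpois(t - s, n_b * mu)
  else
    stats::dnbinom(s, size = n_a / phi, mu = n_a * mu) *
      stats::dnbinom(t - s, size = n_b / phi, mu = n_b * mu)
  pr <- w / sum(w)
  sum(pr[pr <= pr[s_a + 1] * (1 + 1e-7)])
}

# Exhaustive per-window seed-site scan written as a character loop, kept
# deliberately naive and separate from the package's vectorized scan.
oracle_site_scan <- function(mir, tgt, circular = FALSE) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mv <- strsplit(mir, "")[[1]]
  ext <- if (circular) paste0(tgt, substr(tgt, 1, 7)) else tgt
  tv <- strsplit(ext, "")[[1]]
  out <- NULL
  for (p in seq_len(length(tv) - 5)) {
    if (circular && p > nchar(tgt)) break
    ok <- TRUE
    for (i in 2:7) {                      # m[i] pairs target p + 7 - i
      if (comp[[mv[i]]] != tv[p + 7 - i]) { ok <- FALSE; break }
    }
    if (!ok) next
    m8 <- p > 1 && comp[[mv[8]]] == tv[p - 1]
    a1 <- p + 6 <= length(tv) && tv[p + 6] == "A"
    type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
      else if (a1) "7mer-A1" else "6mer"
    out <- rbind(out, data.frame(position = p - 1L, site_type = type,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) data.frame(position = integer(0),
                               site_type = character(0)) else out
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# Desk-scale generator parameters for fast unit tests.
small_params <- function(...) synth_params(
  n_mrna = 40, n_circ = 15, n_mir = 12, n_axes = 3,
  n_de_extra = c(mRNA = 4, circRNA = 2, miRNA = 2), ...)

# One single-contrast recovery run: simulate, DE, DE-restricted target
# prediction, correlation filtering, triads, scored against the truth.
run_axis_recovery <- function(seed, permute = FALSE,
                              params = synth_params()) {
  ds <- simulate_dataset(params, seed)
  design <- ds$design
  if (permute) {
    set.seed(stage_seed(seed, "permute"))
    design$group <- sample(design$group)
  }
  ct <- unique(design$group)[1:2]
  cfg <- cerna_config(rng_seed = seed)
  de <- list(
    circRNA = call_de(ds$counts$circRNA, design, ct, "circRNA", cfg),
    mRNA = call_de(ds$counts$mRNA, design, ct, "mRNA", cfg),
    miRNA = call_de(ds$counts$miRNA, design, ct, "miRNA", cfg))
  ids <- function(d) d$feature_id[d$call != "ns"]
  mirs <- ds$sequences[ds$sequences$kind == "miRNA" &
                         ds$sequences$id %in% ids(de$miRNA), ]
  tgts <- ds$sequences[
    (ds$sequences$kind == "circRNA" & ds$sequences$id %in% ids(de$circRNA)) |
      (ds$sequences$kind == "utr3" & ds$sequences$id %in% ids(de$mRNA)), ]
  tp <- predict_pairs(mirs, tgts, cfg)
  tr <- suppressWarnings(
    assemble_triads(build_pairs(de, tp, ds$counts, design, ct, cfg)))
  unlist(score_recovery(tr, ds$truth))
}

# Toy triad table builder: one row per (circ, mir, mrna) triple.
toy_triads <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(circ_id = m[, 1], mir_id = m[, 2], mrna_id = m[, 3],
             r_cm = -0.9, p_cm = 0.01, r_mg = -0.9, p_mg = 0.01,
             r_cg = 0.9, p_cg = 0.01, stringsAsFactors = FALSE)
}
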