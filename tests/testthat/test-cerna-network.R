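# Correlation edges, triad assembly, core selection, integration.

test_that("Pearson correlation matches the definition and cor.test", {
  expect_equal(pearson_cor(c(1, 2, 3), c(6, 4, 2))$r, -1)
  got <- pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(got$r, 0.6)
  ref <- stats::cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # t = 0.6 * sqrt(2 / 0.64) on 2 df
  expect_equal(got$p, 2 * stats::pt(-0.6 * sqrt(2 / 0.64), 2),
               tolerance = 1e-12)
  # perfect correlation: smallest positive p, never zero
  expect_gt(pearson_cor(c(1, 2, 3), c(2, 4, 6))$p, 0)
  # constant vector: explicit degenerate flag, not a silent zero
  dg <- pearson_cor(c(1, 1, 1), c(1, 2, 3))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$r))
  expect_error(pearson_cor(c(1, 2), c(1, 2)), "n >= 3")
})

make_toy_world <- function(seed = 13) {
  ds <- simulate_dataset(small_params(), seed)
  ct <- unique(ds$design$group)[1:2]
  cfg <- cerna_config(rng_seed = seed)
  de <- list(
    circRNA = call_de(ds$counts$circRNA, ds$design, ct, "circRNA", cfg),
    mRNA = call_de(ds$counts$mRNA, ds$design, ct, "mRNA", cfg),
    miRNA = call_de(ds$counts$miRNA, ds$design, ct, "miRNA", cfg))
  ids <- function(d) d$feature_id[d$call != "ns"]
  mirs <- ds$sequences[ds$sequences$kind == "miRNA" &
                         ds$sequences$id %in% ids(de$miRNA), ]
  tgts <- ds$sequences[
    (ds$sequences$kind == "circRNA" & ds$sequences$id %in% ids(de$circRNA)) |
      (ds$sequences$kind == "utr3" & ds$sequences$id %in% ids(de$mRNA)), ]
  tp <- predict_pairs(mirs, tgts, cfg)
  list(ds = ds, ct = ct, cfg = cfg, de = de, tp = tp)
}

test_that("edge building honors sign constraints and degenerate thresholds", {
  w <- make_toy_world()
  e <- build_pairs(w$de, w$tp, w$ds$counts, w$ds$design, w$ct, w$cfg)
  expect_true(all(e$circ_mir$r <= -0.4))
  expect_true(all(e$mir_mrna$r <= -0.4))
  expect_true(all(e$circ_mrna$r >= 0.4))
  expect_true(all(c(e$circ_mir$p, e$mir_mrna$p, e$circ_mrna$p) <= 0.05))

  # unattainable negative threshold kills all repressive edges
  e0 <- build_pairs(w$de, w$tp, w$ds$counts, w$ds$design, w$ct,
                    cerna_config(r_neg_max = -1.01))
  expect_equal(nrow(e0$circ_mir), 0)
  expect_equal(nrow(e0$mir_mrna), 0)

  # shuffled sample labels leave few candidate pairs significant
  set.seed(99)
  perm_design <- w$ds$design
  perm_design$group <- sample(perm_design$group)
  de_p <- list(
    circRNA = call_de(w$ds$counts$circRNA, perm_design, w$ct, "circRNA",
                      w$cfg),
    mRNA = call_de(w$ds$counts$mRNA, perm_design, w$ct, "mRNA", w$cfg),
    miRNA = call_de(w$ds$counts$miRNA, perm_design, w$ct, "miRNA", w$cfg))
  ep <- suppressWarnings(
    build_pairs(de_p, w$tp, w$ds$counts, perm_design, w$ct, w$cfg))
  expect_lte(nrow(assemble_triads(ep)), 1)
})

test_that("triad assembly equals brute-force enumeration on toy instances", {
  # hand instance: all three edges present for one triple
  edge <- function(a, b, r) data.frame(node_a = a, node_b = b, r = r,
                                       p = 0.01, n = 6,
                                       stringsAsFactors = FALSE)
  ps <- list(circ_mir = edge("c1", "m1", -0.8),
             mir_mrna = edge("m1", "g1", -0.7),
             circ_mrna = edge("c1", "g1", 0.9))
  tr <- assemble_triads(ps)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$circ_id, "c1")
  expect_equal(tr$r_cg, 0.9)

  # missing positive edge: no triad
  ps$circ_mrna <- ps$circ_mrna[0, ]
  expect_equal(nrow(assemble_triads(ps)), 0)

  # random 5x5x5 instance vs triple-loop enumeration
  set.seed(31)
  circ <- paste0("c", 1:5); mir <- paste0("m", 1:5); gene <- paste0("g", 1:5)
  pick <- function(a, b, p = 0.3) {
    g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    g <- g[runif(nrow(g)) < p, ]
    data.frame(node_a = g$a, node_b = g$b, r = -0.8, p = 0.01, n = 6,
               stringsAsFactors = FALSE)
  }
  ps2 <- list(circ_mir = pick(circ, mir), mir_mrna = pick(mir, gene),
              circ_mrna = transform(pick(circ, gene), r = 0.8))
  got <- assemble_triads(ps2)
  want <- 0
  for (c_ in circ) for (m_ in mir) for (g_ in gene) {
    if (any(ps2$circ_mir$node_a == c_ & ps2$circ_mir$node_b == m_) &&
        any(ps2$mir_mrna$node_a == m_ & ps2$mir_mrna$node_b == g_) &&
        any(ps2$circ_mrna$node_a == c_ & ps2$circ_mrna$node_b == g_))
      want <- want + 1
  }
  expect_equal(nrow(got), want)
  expect_false(any(duplicated(got[, 1:3])))
})

test_that("DEM-DEG networks respect the whitelist semantics", {
  w <- make_toy_world()
  full <- dem_deg_network(w$de$miRNA, w$de$mRNA, w$tp, w$ds$counts,
                          w$ds$design, w$ct, w$cfg, whitelist = NULL)
  none <- dem_deg_network(w$de$miRNA, w$de$mRNA, w$tp, w$ds$counts,
                          w$ds$design, w$ct, w$cfg, whitelist = character(0))
  expect_equal(nrow(none), 0)
  expect_gte(nrow(full), nrow(none))
  if (nrow(full)) {
    # restricting to the observed genes reproduces the unrestricted network
    again <- dem_deg_network(w$de$miRNA, w$de$mRNA, w$tp, w$ds$counts,
                             w$ds$design, w$ct, w$cfg,
                             whitelist = unique(full$node_b))
    expect_equal(again, full)
    expect_true(all(full$r <= -0.4))
  }
})

test_that("core selection ranks miRNAs by pair degree with id tie-breaks", {
  # miR A appears in 5 relationship pairs, miR B in 3
  tr_a <- toy_triads("c1", "mA", "g1", "c2", "mA", "g1", "c3", "mA", "g2",
                     "c1", "mB", "g1", "c2", "mB", "g2")
  tr_b <- toy_triads("c1", "mA", "g1", "c9", "mA", "g9",
                     "c1", "mB", "g1", "c2", "mB", "g2")
  core <- select_core(list(x = tr_a, y = tr_b), k = 1)
  expect_equal(core$mirnas, "mA")
  expect_equal(nrow(core$triads$x), 3)

  # identical triad sets: core = top-k of either
  same <- select_core(list(x = tr_a, y = tr_a), k = 2)
  expect_setequal(same$mirnas, c("mA", "mB"))

  # disjoint top-k sets: empty core
  tr_c <- toy_triads("c1", "mZ", "g1")
  disj <- select_core(list(x = tr_a, y = tr_c), k = 1)
  expect_length(disj$mirnas, 0)
  expect_equal(nrow(disj$triads$x), 0)
  expect_error(select_core(list(x = tr_a, y = tr_b), k = 0), "k must be")
  expect_error(select_core(list(x = tr_a), k = 1), ">= 2 comparisons")
})

test_that("integration keeps shared whitelisted triads and flattens pairs", {
  a <- toy_triads("c1", "m1", "g1", "c2", "m2", "g2")
  b <- toy_triads("c1", "m1", "g1", "c3", "m3", "g3")
  got <- integrate_networks(a, b, gene_whitelist = c("g1", "g3"))
  expect_equal(nrow(got$triads), 1)
  expect_equal(got$triads$mrna_id, "g1")
  expect_equal(nrow(got$pairs), 2)  # one sponge + one target pair
  expect_setequal(got$pairs$relation, c("sponges", "targets"))

  # empty whitelist set yields an empty integration
  expect_equal(nrow(integrate_networks(a, b, character(0))$triads), 0)
  # NULL whitelist applies no gene restriction
  expect_equal(nrow(integrate_networks(a, a, NULL)$triads), 2)
})
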