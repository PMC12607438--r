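# Seed-site scanning, the 0-100 site score, duplex energy, pair filtering.

test_that("site scan types canonical sites and finds nothing in decoys", {
  m <- "UGGAAUGUAAAGAAGUAUGUAU"
  # revcomp of m1-8 with the A1 adenine: one 8mer
  s <- site_scan(m, paste0("GGGGGG", "ACAUUCCA", "GGGG"))
  expect_equal(nrow(s), 1)
  expect_equal(s$site_type, "8mer")
  expect_equal(s$position, 7L)  # 0-based start of the 6mer core

  # dropping the A1 leaves a 7mer-m8; dropping m8 leaves 7mer-A1
  expect_equal(site_scan(m, "GGGGGGACAUUCCGGGGG")$site_type, "7mer-m8")
  expect_equal(site_scan(m, "GGGGGGGCAUUCCAGGGG")$site_type, "7mer-A1")
  expect_equal(site_scan(m, "GGGGGGGCAUUCCGGGGG")$site_type, "6mer")

  # no complementary window at all
  expect_equal(nrow(site_scan(m, "GGGGGGGGGGGGGGGG")), 0)
  expect_error(site_scan("UGGAAUG", "ACGUACGU"), "shorter than 8")
  expect_error(site_scan("UNGGAAUGAA", "ACGUACGUAA"), "ambiguous")
})

test_that("site scan equals the exhaustive window oracle, incl. circular", {
  set.seed(77)
  for (k in 1:40) {
    mir <- random_rna(sample(20:24, 1))
    circular <- k > 20
    tgt <- random_rna(sample(50:150, 1))
    if (k %% 4 == 0) {
      # force a hit so non-empty cases are well represented
      core <- revcomp_rna(substr(mir, 2, 7))
      pos <- sample(nchar(tgt) - 10, 1)
      substr(tgt, pos, pos + 5) <- core
    }
    got <- site_scan(mir, if (circular)
      list(id = "t", seq = tgt, kind = "circRNA")
      else tgt)
    want <- oracle_site_scan(mir, tgt, circular)
    expect_equal(got$position, want$position)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("BSJ-spanning sites are found on circular targets only", {
  set.seed(5)
  m <- "UGGAAUGUAAAGAAGUAUGUAU"
  site8 <- "ACAUUCCA"
  # split the site across the sequence end: last 5 nt + first 3 nt
  tgt <- paste0(substr(site8, 6, 8), random_rna(40), substr(site8, 1, 5))
  expect_equal(nrow(site_scan(m, list(id = "t", seq = tgt,
                                      kind = "utr3"))), 0)
  s <- site_scan(m, list(id = "t", seq = tgt, kind = "circRNA"))
  expect_equal(nrow(s), 1)
  expect_equal(s$site_type, "8mer")
})

test_that("site scores follow the base-plus-AU-bonus formula and ordering", {
  expect_equal(site_score("8mer", strrep("AU", 30)), 100)
  expect_equal(site_score("6mer", strrep("GC", 30)), 30)
  expect_equal(site_score("7mer-m8", "AUGC"), 72.5)
  expect_equal(site_score("8mer", ""), 75)
  ctx <- "AUGGCCAU"
  sc <- vapply(c("6mer", "7mer-A1", "7mer-m8", "8mer"), site_score,
               numeric(1), context = ctx)
  expect_true(all(diff(sc) > 0))  # 8mer > 7mer-m8 > 7mer-A1 > 6mer
  expect_error(site_score("9mer", ""), "unknown site type")
})

test_that("duplex energy sums the shipped stack table over the pairing", {
  m <- "UGGAAUGUAAAGAAGUAUGUAU"
  tgt <- paste0("GGGGGGGGGG", "GCAUUCCG", "GGGG")  # isolated 6mer
  site <- site_scan(m, tgt)
  expect_equal(site$site_type, "6mer")
  e <- duplex_energy(m, tgt, site[1, ])
  # independent hand sum: stacks over miRNA dinucleotides 2-7 (all WC)
  tab <- cernapipe:::.stack_table
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mv <- strsplit(m, "")[[1]]
  want <- 4.09
  for (i in 2:6)
    want <- want + tab[[paste0(mv[i], mv[i + 1], "/",
                               comp[mv[i]], comp[mv[i + 1]])]]
  expect_equal(e, want)

  # a 3'-supplementary block strictly lowers the energy
  supp <- revcomp_rna(substr(m, 13, 18))
  tgt2 <- paste0("GGGG", supp, "GG", "GCAUUCCG", "GGGG")
  site2 <- site_scan(m, tgt2)
  expect_lt(duplex_energy(m, tgt2, site2[1, ]), e)

  # initiation penalty is positive and every stack is stabilizing
  expect_gt(4.09, 0)
  expect_true(all(cernapipe:::.stack_table < 0))
  expect_error(duplex_energy(m, "GGGGGGGGGGGG",
                             data.frame(position = 0, site_type = "6mer")),
               "does not match")
})

test_that("pair prediction keeps planted pairs and filters decoys", {
  ds <- simulate_dataset(small_params(), seed = 21)
  ax <- ds$truth$axes
  cfg <- cerna_config()
  mirs <- ds$sequences[ds$sequences$id %in% ax$mir_id, ]
  tgts <- ds$sequences[ds$sequences$kind != "miRNA", ]
  tp <- predict_pairs(mirs, tgts, cfg)
  planted <- c(paste(ax$mir_id, ax$mrna_id), paste(ax$mir_id, ax$circ_id))
  expect_true(all(planted %in% paste(tp$mirna_id, tp$target_id)))

  # permissive thresholds retain every pair with at least one site
  all_cfg <- cerna_config(site_score_min = 0, energy_max_kcal = Inf)
  tp_all <- predict_pairs(mirs, tgts, all_cfg)
  n_with_site <- sum(vapply(seq_len(nrow(mirs)), function(i)
    sum(vapply(seq_len(nrow(tgts)), function(j)
      nrow(site_scan(mirs[i, ], tgts[j, ])) > 0, logical(1))),
    numeric(1)))
  expect_equal(nrow(tp_all), n_with_site)

  # tightening either filter never adds pairs
  expect_lte(nrow(predict_pairs(mirs, tgts,
                                cerna_config(site_score_min = 70))), nrow(tp))
  expect_lte(nrow(predict_pairs(mirs, tgts,
                                cerna_config(energy_max_kcal = -15))),
             nrow(tp))

  # a 6mer-only decoy in GC context scores 30 and is rejected
  mir <- "UGGAAUGUAAAGAAGUAUGUAU"
  decoy <- data.frame(id = "d", seq = paste0(strrep("G", 30), "GCAUUCCG",
                                             strrep("G", 30)),
                      kind = "utr3", stringsAsFactors = FALSE)
  got <- predict_pairs(data.frame(id = "m", seq = mir, kind = "miRNA"),
                       decoy, cerna_config())
  expect_equal(nrow(got), 0)
})
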