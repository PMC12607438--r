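# Sequence-based miRNA target prediction: canonical seed-site taxonomy
# (6mer, 7mer-A1, 7mer-m8, 8mer), a transparent 0-100 site score, and a
# simplified nearest-neighbor duplex free energy. Pairs are retained by the
# intersection of the two filters (score floor AND energy ceiling), which
# mirrors the common practice of intersecting a site-context predictor with
# an energy-based predictor.

.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

#' Reverse complement of an RNA string
#' @param x RNA string (ACGUN).
#' @return Reverse complement string.
#' @export
revcomp_rna <- function(x) {
  chars <- rev(strsplit(x, "")[[1]])
  paste(.RNA_COMP[chars], collapse = "")
}

# TRUE if bases b1 (on one strand) and b2 (other strand) form a pair.
pairs_ok <- function(b1, b2, allow_gu = FALSE) {
  wc <- (.RNA_COMP[b1] == b2) & b1 != "N" & b2 != "N"
  if (!allow_gu) return(wc)
  gu <- (b1 == "G" & b2 == "U") | (b1 == "U" & b2 == "G")
  wc | gu
}

#' Scan a target sequence for canonical miRNA seed sites
#'
#' A site exists wherever a 6-nt target window is the reverse complement of
#' miRNA positions 2-7 (the seed core). The site is typed by two upgrades:
#' `7mer-m8` when the target base 5' of the core pairs miRNA position 8,
#' `7mer-A1` when the target base 3' of the core is an A (opposite miRNA
#' position 1), and `8mer` when both hold. All matching windows are
#' reported; overlaps are not resolved. Positions are 0-based starts of the
#' seed-core match on the target as given (5'->3'; no reverse-strand scan).
#' For circRNAs the first 7 nt are appended to the end so sites spanning the
#' back-splice junction are found; their positions wrap around the original
#' length.
#'
#' @param mirna miRNA record (list/row with `id`, `seq`) or plain string.
#' @param target Target record (`id`, `seq`, `kind`) or plain string.
#' @param circular Treat target as circular; default TRUE when the target
#'   record's `kind` is `"circRNA"`.
#' @return Data.frame of sites: `mirna_id`, `target_id`, `target_kind`,
#'   `position`, `site_type`.
#' @export
site_scan <- function(mirna, target, circular = NULL) {
  m_id <- if (is.character(mirna)) "miRNA" else mirna$id
  t_id <- if (is.character(target)) "target" else target$id
  t_kind <- if (is.character(target)) "utr3" else target$kind
  m <- normalize_rna(if (is.character(mirna)) mirna else mirna$seq)
  tg <- normalize_rna(if (is.character(target)) target else target$seq)
  if (is.null(circular)) circular <- identical(t_kind, "circRNA")
  if (nchar(m) < 8) stop("miRNA shorter than 8 nt")
  if (nchar(tg) < 8) stop("target shorter than 8 nt")
  if (grepl("N", substr(m, 2, 8))) stop("ambiguous base in seed region")

  len0 <- nchar(tg)
  ext <- if (circular) paste0(tg, substr(tg, 1, 7)) else tg
  core <- revcomp_rna(substr(m, 2, 7))
  n <- nchar(ext)
  starts <- seq_len(n - 5)
  hit <- starts[substring(ext, starts, starts + 5) == core]
  hit <- hit[hit <= len0]  # each circular window counted once
  empty <- data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), position = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE)
  if (!length(hit)) return(empty)

  m8c <- .RNA_COMP[substr(m, 8, 8)]
  site_type <- vapply(hit, function(p) {
    has_m8 <- p > 1 && substr(ext, p - 1, p - 1) == m8c
    has_a1 <- p + 6 <= n && substr(ext, p + 6, p + 6) == "A"
    if (has_m8 && has_a1) "8mer"
    else if (has_m8) "7mer-m8"
    else if (has_a1) "7mer-A1"
    else "6mer"
  }, character(1))
  data.frame(mirna_id = m_id, target_id = t_id, target_kind = t_kind,
             position = hit - 1L, site_type = site_type,
             stringsAsFactors = FALSE)
}

.SITE_BASE <- c("6mer" = 30, "7mer-A1" = 50, "7mer-m8" = 60, "8mer" = 75)

#' Score a seed site on a 0-100 scale
#'
#' Base points by site type (6mer 30, 7mer-A1 50, 7mer-m8 60, 8mer 75) plus
#' an AU-context bonus of `25 * (fraction of A/U in the +/- 30 nt flanks)`,
#' clamped to [0, 100]. AU-rich flanks favor site accessibility, which is
#' the qualitative behavior of context-style scores.
#'
#' @param site_type One of `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"`.
#' @param context Concatenated flanking sequence (up to 30 nt each side of
#'   the site, site excluded); `""` gives no bonus.
#' @return Score in [0, 100].
#' @export
#' @examples
#' site_score("7mer-m8", "AUGCAUGC")  # half A/U flanks -> 72.5
site_score <- function(site_type, context = "") {
  if (!site_type %in% names(.SITE_BASE)) stop("unknown site type")
  frac <- if (nzchar(context)) {
    ch <- strsplit(normalize_rna(context), "")[[1]]
    mean(ch %in% c("A", "U"))
  } else 0
  min(100, max(0, .SITE_BASE[[site_type]] + 25 * frac))
}

# Nearest-neighbor stacking free energies (kcal/mol), Turner-style values,
# keyed "XY/ZW": top strand 5'-XY-3' paired with bottom strand 3'-ZW-5'.
# Watson-Crick stacks use the standard table; wobble-containing stacks get
# fixed mildly stabilizing values. All entries are < 0.
.stack_table <- local({
  wc <- c("AA/UU" = -0.93, "AU/AU" = -1.10, "UA/UA" = -1.33,
          "CU/AG" = -2.08, "CA/UG" = -2.11, "GU/AC" = -2.24,
          "GA/UC" = -2.35, "CG/CG" = -2.36, "GG/CC" = -3.26,
          "GC/GC" = -3.42)
  # symmetry: 5'-XY-3'/3'-ZW-5' == 5'-WZ-3'/3'-YX-5'
  sym <- function(k) {
    a <- strsplit(sub("/.*", "", k), "")[[1]]
    b <- strsplit(sub(".*/", "", k), "")[[1]]
    paste0(b[2], b[1], "/", a[2], a[1])
  }
  tab <- wc
  for (k in names(wc)) tab[sym(k)] <- wc[[k]]
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  for (p1 in pairs) for (p2 in pairs) {
    k <- paste0(substr(p1, 1, 1), substr(p2, 1, 1), "/",
                substr(p1, 2, 2), substr(p2, 2, 2))
    if (is.null(tab[k]) || is.na(tab[k])) {
      n_gu <- (p1 %in% c("GU", "UG")) + (p2 %in% c("GU", "UG"))
      tab[k] <- if (n_gu == 2) -0.5 else -1.2
    }
  }
  tab
})

stack_energy <- function(x1, x2, y1, y2) {
  v <- .stack_table[paste0(x1, x2, "/", y1, y2)]
  if (is.na(v)) 0 else unname(v)
}

#' Simplified nearest-neighbor duplex free energy of a miRNA site
#'
#' `energy = +4.09 (initiation) + sum of stacking terms` over consecutive
#' base pairs in the seed duplex (miRNA positions 2-7, extended to 8 for
#' m8-type sites) and in the longest contiguous 3'-supplementary
#' complementary block between the miRNA 3' region (positions 12-21,
#' spanning the canonical 13-17 supplementary pairing region) and the 20 nt
#' of target immediately 5' of the site. G:U wobbles count as pairs in the
#' supplementary block but not in the seed. More pairing always lowers the
#' energy (every stack term is negative).
#'
#' @param mirna miRNA record or string.
#' @param target Target record or string (as scanned, i.e. circular targets
#'   must be evaluated against the site's coordinates on the given string).
#' @param site One row of [site_scan()] output.
#' @return Free energy in kcal/mol (negative = stable).
#' @export
duplex_energy <- function(mirna, target, site) {
  m <- normalize_rna(if (is.character(mirna)) mirna else mirna$seq)
  tg <- normalize_rna(if (is.character(target)) target else target$seq)
  t_kind <- if (is.character(target)) "utr3" else target$kind
  if (identical(t_kind, "circRNA")) tg <- paste0(tg, substr(tg, 1, 7))
  p <- site$position + 1L  # 1-based start of the seed core on the target
  core <- revcomp_rna(substr(m, 2, 7))
  if (substring(tg, p, p + 5) != core)
    stop("site does not match target sequence")

  mv <- strsplit(m, "")[[1]]
  tv <- strsplit(tg, "")[[1]]
  # seed pairs: miRNA positions 2..7 (..8 for m8 sites), antiparallel, so
  # miRNA position 2 pairs the 3'-most core base (target position p+5)
  seed_hi <- if (site$site_type %in% c("7mer-m8", "8mer")) 8L else 7L
  mpos <- 2:seed_hi
  tpos <- (p + 7L) - mpos  # m2 pairs target p+5, m7 pairs p, m8 pairs p-1
  e <- 4.09
  for (i in seq_len(length(mpos) - 1)) {
    e <- e + stack_energy(mv[mpos[i]], mv[mpos[i + 1]],
                          tv[tpos[i]], tv[tpos[i + 1]])
  }

  # 3'-supplementary block: longest contiguous run of pairs (G:U allowed)
  # between miRNA positions 12-21 and the 20-nt upstream target flank
  sup_lo <- 12L
  sup_hi <- min(nchar(m), 21L)
  flank_hi <- p - 2L
  flank_lo <- max(1L, p - 21L)
  best <- integer(0)
  best_m <- integer(0)
  if (sup_hi > sup_lo && flank_hi >= flank_lo) {
    for (tstart in flank_lo:flank_hi) {
      # align miRNA sup_lo.. ascending against target descending from tstart
      run_m <- integer(0)
      run_t <- integer(0)
      mi <- sup_lo
      ti <- tstart
      while (mi <= sup_hi && ti >= flank_lo) {
        if (pairs_ok(mv[mi], tv[ti], allow_gu = TRUE)) {
          run_m <- c(run_m, mi)
          run_t <- c(run_t, ti)
          if (length(run_m) > length(best)) {
            best <- run_t
            best_m <- run_m
          }
        } else {
          run_m <- integer(0)
          run_t <- integer(0)
        }
        mi <- mi + 1L
        ti <- ti - 1L
      }
    }
  }
  if (length(best_m) >= 2) {
    for (i in seq_len(length(best_m) - 1)) {
      e <- e + stack_energy(mv[best_m[i]], mv[best_m[i + 1]],
                            tv[best[i]], tv[best[i + 1]])
    }
  }
  e
}

#' Predict miRNA-target pairs under score and energy thresholds
#'
#' Scans every (miRNA, target) combination, scores each site (AU context
#' from the +/- 30 nt flanks) and computes its duplex energy, keeps the best
#' site per pair (highest score, ties by lower energy then smaller
#' position), and retains the pair iff
#' `score >= site_score_min` and `energy <= energy_max_kcal`.
#'
#' @param mirnas Data.frame of miRNA records (`id`, `seq`).
#' @param targets Data.frame of target records (`id`, `seq`, `kind` in
#'   `utr3`/`circRNA`).
#' @param config [cerna_config()] list.
#' @return Data.frame: `mirna_id`, `target_id`, `target_kind`, `site_type`,
#'   `position`, `score`, `energy_kcal`, `n_sites`.
#' @export
predict_pairs <- function(mirnas, targets, config = cerna_config()) {
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    mir <- mirnas[i, ]
    for (j in seq_len(nrow(targets))) {
      tgt <- targets[j, ]
      sites <- site_scan(mir, tgt)
      if (!nrow(sites)) next
      ext <- if (identical(tgt$kind, "circRNA"))
        paste0(tgt$seq, substr(tgt$seq, 1, 7)) else tgt$seq
      scored <- score_sites(mir$seq, ext, tgt$kind, sites)
      best <- scored[order(-scored$score, scored$energy_kcal,
                           scored$position), ][1, ]
      best$n_sites <- nrow(scored)
      out[[length(out) + 1]] <- best
    }
  }
  if (!length(out))
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_kind = character(0), site_type = character(0),
                      position = integer(0), score = numeric(0),
                      energy_kcal = numeric(0), n_sites = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  keep <- res$score >= config$site_score_min &
    res$energy_kcal <= config$energy_max_kcal
  res[keep, , drop = FALSE]
}

# Attach score and energy columns to site_scan() output.
score_sites <- function(mir_seq, ext_target, t_kind, sites) {
  n <- nchar(ext_target)
  sites$score <- NA_real_
  sites$energy_kcal <- NA_real_
  for (k in seq_len(nrow(sites))) {
    p <- sites$position[k] + 1L
    st <- sites$site_type[k]
    lo <- if (st %in% c("7mer-m8", "8mer")) p - 1L else p
    hi <- if (st %in% c("7mer-A1", "8mer")) p + 6L else p + 5L
    flank <- paste0(substring(ext_target, max(1, lo - 30), lo - 1),
                    substring(ext_target, hi + 1, min(n, hi + 30)))
    sites$score[k] <- site_score(st, flank)
    sites$energy_kcal[k] <- duplex_energy(
      mir_seq, list(seq = ext_target, kind = "utr3"), sites[k, ])
  }
  sites
}
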