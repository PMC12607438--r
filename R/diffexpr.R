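# Two-group differential expression for count data: TMM normalization,
# a conditional negative-binomial exact test with a common dispersion, BH
# correction, and layer-specific significance rules.

#' Trimmed mean of M-values normalization factors
#'
#' Composition-correction factors in the TMM convention: M- and A-values are
#' computed on library-size-scaled proportions against a reference sample
#' (the one whose 75th count percentile is closest to the mean), the extreme
#' 30% of M-values and 5% of A-values are trimmed, and the remaining
#' M-values are averaged with inverse asymptotic-variance weights. Factors
#' are rescaled to geometric mean 1; the effective library size of sample j
#' is `colSums(counts)[j] * factors[j]`. A sample that differs from another
#' only in depth therefore gets a factor of ~1.
#'
#' @param counts Integer matrix, features x samples (>= 2 samples).
#' @return Numeric vector of positive factors, one per sample, with
#'   attribute `method = "TMM"`.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2) stop("need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample column")
  f75 <- apply(counts, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "method") <- "TMM"
  f
}

# One TMM factor of obs against ref (both raw count vectors).
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  o <- obs[keep] / n_obs
  r <- ref[keep] / n_ref
  logR <- log2(o / r)
  absE <- (log2(o) + log2(r)) / 2
  v <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
    (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  rkR <- rank(logR)
  rkA <- rank(absE)
  sel <- rkR >= loL & rkR <= hiL & rkA >= loS & rkA <= hiS
  if (!any(sel)) return(1)
  f <- sum(logR[sel] / v[sel]) / sum(1 / v[sel])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Counts per million on TMM-effective library sizes
#'
#' @param counts Integer matrix, features x samples.
#' @param factors Normalization factors from [tmm_factors()]; computed if
#'   `NULL`.
#' @return Numeric CPM matrix of the same shape.
#' @export
cpm_matrix <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts) * as.numeric(factors)
  t(t(counts) / eff) * 1e6
}

#' Conditional negative-binomial exact test for two groups
#'
#' Tests equality of mean expression between two groups of replicate counts
#' whose library sizes have already been equalized. Conditional on the total
#' `t`, the two group sums are negative-binomial convolutions sharing the
#' success parameter, so the split distribution is free of the unknown mean:
#' `Pr(s | t) ~ C(s + nA/phi - 1, s) * C(t - s + nB/phi - 1, t - s)`. The
#' two-sided p-value sums the probabilities of all splits at most as likely
#' as the observed one (minimum-likelihood rule); at `phi = 0` the split
#' distribution is the Poisson-limit binomial. The symmetric/modal observed
#' split yields p = 1.
#'
#' @param counts_a,counts_b Non-negative integer replicate vectors.
#' @param dispersion Common NB dispersion phi >= 0.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' exact_nb_test(c(5, 5), c(5, 5), 0.1)  # symmetric: p = 1
exact_nb_test <- function(counts_a, counts_b, dispersion) {
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  if (dispersion < 0) stop("dispersion must be >= 0")
  s_a <- sum(counts_a)
  t <- s_a + sum(counts_b)
  if (t == 0) return(1)
  n_a <- length(counts_a)
  n_b <- length(counts_b)
  s <- 0:t
  if (dispersion == 0) {
    logp <- stats::dbinom(s, t, n_a / (n_a + n_b), log = TRUE)
  } else {
    r_a <- n_a / dispersion
    r_b <- n_b / dispersion
    logw <- lgamma(s + r_a) - lgamma(s + 1) +
      lgamma(t - s + r_b) - lgamma(t - s + 1)
    logp <- logw - logsumexp(logw)
  }
  # include ties up to a relative tolerance, as exact conditional tests do
  min(1, sum(exp(logp)[logp <= logp[s_a + 1] + log1p(1e-7)]))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Method-of-moments common dispersion
#'
#' Per feature and replicated group, computes `(s^2 - xbar) / xbar^2` on
#' library-normalized counts (counts scaled by effective library size to the
#' mean library), averages across groups, and returns the median over
#' features, floored at zero. This is a deliberately simple, robust common
#' estimate shared by all features of a layer.
#'
#' @param counts Integer matrix, features x samples.
#' @param design Design table covering the columns of `counts`.
#' @param factors Optional normalization factors (TMM computed if `NULL`).
#' @return Non-negative dispersion estimate.
#' @export
estimate_common_dispersion <- function(counts, design, factors = NULL) {
  validate_design(design)
  stopifnot(all(design$sample_id %in% colnames(counts)))
  counts <- counts[, design$sample_id, drop = FALSE]
  reps <- table(design$group)
  if (!any(reps >= 2)) stop("no replicated group")
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts) * as.numeric(factors)
  norm <- t(t(counts) / eff) * mean(colSums(counts))
  per_group <- lapply(names(reps)[reps >= 2], function(g) {
    m <- norm[, design$sample_id[design$group == g], drop = FALSE]
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  })
  avg <- rowMeans(do.call(cbind, per_group), na.rm = TRUE)
  avg <- avg[is.finite(avg)]
  if (!length(avg)) return(0)
  max(0, stats::median(avg))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with respect to input positions.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.002))
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call differential expression for one layer and contrast
#'
#' Normalizes with TMM, computes group-mean CPM and
#' `log2fc = log2((CPM_B + 0.5) / (CPM_A + 0.5))` for contrast `c(A, B)`,
#' equalizes library sizes to their geometric mean (rounding half to even)
#' so the conditional NB exact test applies, estimates a common dispersion,
#' tests every feature, and adjusts with BH. circRNA and mRNA calls require
#' `|log2fc| >= lfc_min` and `q <= q_max`; miRNA calls use raw `p <= p_max`
#' with no fold-change filter.
#'
#' @param counts Integer matrix, features x samples.
#' @param design Design table.
#' @param contrast Character vector `c(A, B)`; log2fc is log2(B/A).
#' @param layer One of `"circRNA"`, `"mRNA"`, `"miRNA"`.
#' @param config [cerna_config()] list.
#' @return Data.frame with `feature_id`, `mean_a`, `mean_b`, `log2fc`, `p`,
#'   `q`, `call` (`up` / `down` / `ns`).
#' @export
call_de <- function(counts, design, contrast,
                    layer = c("circRNA", "mRNA", "miRNA"),
                    config = cerna_config()) {
  layer <- match.arg(layer)
  validate_design(design)
  if (!all(contrast %in% design$group))
    stop("unknown group in contrast: ",
         paste(setdiff(contrast, design$group), collapse = ", "))
  stopifnot(length(contrast) == 2)
  counts <- counts[, design$sample_id, drop = FALSE]
  a_cols <- design$sample_id[design$group == contrast[1]]
  b_cols <- design$sample_id[design$group == contrast[2]]

  # normalization and the common dispersion use the whole design: within-
  # group variability is unaffected by group effects and more replicated
  # groups stabilize the estimate
  factors <- tmm_factors(counts)
  cpm <- cpm_matrix(counts, factors)
  mean_a <- rowMeans(cpm[, a_cols, drop = FALSE])
  mean_b <- rowMeans(cpm[, b_cols, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))

  # equalize effective library sizes so the exact conditional test applies
  eff <- colSums(counts) * as.numeric(factors)
  geo <- exp(mean(log(eff)))
  eq <- round(t(t(counts) * (geo / eff)))
  storage.mode(eq) <- "integer"
  phi <- estimate_common_dispersion(eq, design,
                                    factors = rep(1, ncol(eq)))
  p <- vapply(seq_len(nrow(eq)), function(i)
    exact_nb_test(eq[i, a_cols], eq[i, b_cols], phi), numeric(1))
  q <- bh_adjust(p)

  sig <- if (layer == "miRNA") p <= config$p_max
  else q <= config$q_max & abs(log2fc) >= config$lfc_min
  call <- ifelse(!sig, "ns", ifelse(log2fc > 0, "up", "down"))
  data.frame(feature_id = rownames(counts), mean_a = mean_a,
             mean_b = mean_b, log2fc = log2fc, p = p, q = q,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Computes `dCt = Ct_target - Ct_reference` within each condition (means
#' over replicate wells), `ddCt = dCt_treated - dCt_control`, and returns
#' the fold change `2^-ddCt`.
#'
#' @param ct_target_treated,ct_target_control Ct replicate vectors for the
#'   gene of interest.
#' @param ct_ref_treated,ct_ref_control Ct replicate vectors for the
#'   reference gene.
#' @return Positive fold change.
#' @export
#' @examples
#' relative_quantification(20, 18, 15, 15)  # ddCt = 2 -> 0.25
relative_quantification <- function(ct_target_treated, ct_target_control,
                                    ct_ref_treated, ct_ref_control) {
  vals <- c(ct_target_treated, ct_target_control,
            ct_ref_treated, ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  d_treated <- mean(ct_target_treated) - mean(ct_ref_treated)
  d_control <- mean(ct_target_control) - mean(ct_ref_control)
  2^-(d_treated - d_control)
}
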