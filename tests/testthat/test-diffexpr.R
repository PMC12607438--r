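# Normalization, the conditional NB exact test, dispersion, BH, DE calls.

test_that("TMM factors are symmetric, equivariant and match edgeR", {
  set.seed(1)
  m <- matrix(rnbinom(500 * 4, mu = 100, size = 10), 500, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(as.vector(tmm_factors(same)), rep(1, 3))

  # pure depth difference is absorbed: factors stay ~1
  dup <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  expect_equal(as.vector(tmm_factors(dup)), c(1, 1), tolerance = 1e-6)

  # permutation equivariance
  f <- tmm_factors(m)
  perm <- c(3, 1, 4, 2)
  expect_equal(as.vector(tmm_factors(m[, perm])), as.vector(f[perm]),
               tolerance = 1e-12)

  # independent reference implementation
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(as.vector(f), as.vector(ref), tolerance = 1e-8)
})

test_that("exact NB test matches independent enumeration and symmetries", {
  # swapping groups leaves p unchanged
  a <- c(4, 9, 2); b <- c(11, 8, 5)
  expect_equal(exact_nb_test(a, b, 0.2), exact_nb_test(b, a, 0.2))
  # symmetric split is modal: p = 1
  expect_equal(exact_nb_test(c(5, 5), c(5, 5), 0.3), 1)
  expect_equal(exact_nb_test(c(0, 0), c(0, 0), 0.1), 1)
  # Poisson limit equals the exact binomial test (same tail rule)
  for (tot in list(c(3, 7, 12), c(0, 2))) {
    p_pkg <- exact_nb_test(tot, c(9, 1), 0)
    p_ref <- stats::binom.test(sum(tot), sum(tot) + 10,
                               length(tot) / (length(tot) + 2))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
  # NB enumeration oracle on random small configurations
  set.seed(42)
  for (k in 1:25) {
    phi <- sample(c(0.05, 0.1, 0.5), 1)
    a <- rpois(sample(2:3, 1), 4)
    b <- rpois(sample(2:3, 1), 4)
    expect_equal(exact_nb_test(a, b, phi), oracle_exact_p(a, b, phi),
                 tolerance = 1e-10)
  }
  expect_error(exact_nb_test(c(-1, 2), c(1, 1), 0.1), "negative")
  expect_error(exact_nb_test(c(1, 2), c(1, 1), -0.1), "dispersion")
})

test_that("common dispersion estimates recover the simulation truth", {
  d <- simulate_design(2, 8)
  set.seed(7)
  pois <- matrix(rpois(500 * 16, 100), 500,
                 dimnames = list(NULL, d$sample_id))
  expect_lte(estimate_common_dispersion(pois, d), 0.01)

  nb <- matrix(rnbinom(2000 * 16, mu = 100, size = 5), 2000,
               dimnames = list(NULL, d$sample_id))
  phi_hat <- estimate_common_dispersion(nb, d)
  expect_gte(phi_hat, 0.15)
  expect_lte(phi_hat, 0.25)

  # single feature with zero within-group variance
  flat <- matrix(5L, 1, 16, dimnames = list("f", d$sample_id))
  expect_equal(estimate_common_dispersion(flat, d), 0)
})

test_that("BH adjustment reproduces the hand step-up and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))       # q monotone in p
  expect_equal(q[which.max(p)], max(p))        # largest p: q = p
  expect_lte(sum(q <= 0.05), sum(p <= 0.05))   # never more rejections
})

test_that("DE calls have power on planted effects and honor thresholds", {
  cfg <- cerna_config()
  d <- simulate_design(2, 3)
  hits <- 0
  for (seed in 1:25) {
    set.seed(seed)
    m <- matrix(rnbinom(200 * 6, mu = 200, size = 20), 200)
    m[1, 4:6] <- rnbinom(3, mu = 200 * 2^3, size = 20)
    dimnames(m) <- list(paste0("f", 1:200), d$sample_id)
    de <- call_de(m, d, c("Group1", "Group2"), "mRNA", cfg)
    hits <- hits + (de$call[1] == "up")
  }
  expect_gte(hits / 25, 0.9)

  # group swap negates log2fc and preserves p
  set.seed(10)
  m <- matrix(rnbinom(100 * 6, mu = 100, size = 20), 100,
              dimnames = list(paste0("f", 1:100), d$sample_id))
  de_ab <- call_de(m, d, c("Group1", "Group2"), "mRNA", cfg)
  de_ba <- call_de(m, d, c("Group2", "Group1"), "mRNA", cfg)
  expect_equal(de_ba$log2fc, -de_ab$log2fc)
  expect_equal(de_ba$p, de_ab$p)

  # q_max = 0 silences all circRNA/mRNA calls
  de0 <- call_de(m, d, c("Group1", "Group2"), "mRNA",
                 cerna_config(q_max = 0))
  expect_true(all(de0$call == "ns"))
  expect_error(call_de(m, d, c("Group1", "GroupX"), "mRNA", cfg),
               "unknown group")
})

test_that("null DE p-values are close to uniform at the 5% level", {
  d <- simulate_design(4, 3)
  set.seed(2025)
  lib <- exp(runif(12, log(0.7), log(1.4)))
  mu <- outer(rlnorm(2000, log(100), 1), lib)
  m <- matrix(rnbinom(length(mu), mu = mu, size = 20), 2000,
              dimnames = list(paste0("f", 1:2000), d$sample_id))
  de <- call_de(m, d, c("Group1", "Group2"), "mRNA", cerna_config())
  frac <- mean(de$p < 0.05)
  # the common-dispersion estimate leaves the raw-p rule mildly liberal
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
  expect_equal(sum(de$call != "ns"), 0)
})

test_that("depth rescaling of one sample does not change DE calls", {
  d <- simulate_design(2, 3)
  set.seed(8)
  m <- matrix(rnbinom(300 * 6, mu = 150, size = 20), 300,
              dimnames = list(paste0("f", 1:300), d$sample_id))
  m[1:5, 4:6] <- matrix(rnbinom(15, mu = 150 * 8, size = 20), 5)
  base <- call_de(m, d, c("Group1", "Group2"), "mRNA", cerna_config())
  for (c_scale in c(0.5, 2)) {
    m2 <- m
    m2[, 2] <- as.integer(round(m[, 2] * c_scale))
    de2 <- call_de(m2, d, c("Group1", "Group2"), "mRNA", cerna_config())
    expect_equal(de2$call[1:5], base$call[1:5])
    expect_gte(mean(de2$call == base$call), 0.99)
  }
})

test_that("2^-ddCt quantification matches hand computations", {
  expect_equal(relative_quantification(20, 20, 15, 15), 1)
  expect_equal(relative_quantification(16, 18, 15, 15), 4)  # ddCt = -2
  expect_equal(relative_quantification(20, 18, 15, 15), 0.25)
  # replicate wells are averaged
  expect_equal(relative_quantification(c(20, 20), c(18, 18),
                                       c(15, 15), c(15, 15)), 0.25)
  expect_error(relative_quantification(NA, 18, 15, 15), "finite")
})
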