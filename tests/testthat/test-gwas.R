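test_that("third-haplotype dosage counts copies of the untagged haplotype", {
  sim <- simulate_pair_genotypes(c(AB = 0, Ab = 0.45, aB = 0.35, ab = 0.2),
                                 n = 400, seed = 121)
  pt <- build_pair_table(sim$gm, 1, 2)
  st <- detect_corners(pt, small_n = 0)
  expect_equal(st$missing_haplotypes, "AB")
  ph <- phase_pair(sim$gm, 1, 2, st)
  d3 <- third_haplotype_dosage(ph, st)
  expect_equal(attr(d3, "haplotype"), "ab")  # complement of missing AB
  # dosage = true copy count of ab per individual
  truth_ct <- (sim$truth$hap1 == "ab") + (sim$truth$hap2 == "ab")
  expect_equal(as.integer(d3), truth_ct)
  # identity: sums to 2N * f_third
  hf <- haplotype_freqs_direct(pt, st)
  expect_equal(sum(d3), round(2 * pt$n * hf$f[["ab"]]))
  # complement identity with the two single-SNP tag dosages:
  # copies of Ab = dosage of A at SNP1, copies of aB = dosage of B at SNP2
  tagA <- 2L - sim$gm$dosage[, 1]           # A is ref: copies of allele A
  tagB <- 2L - sim$gm$dosage[, 2]
  expect_equal(as.integer(d3), unname(2L - tagA - tagB))
  st4 <- detect_corners(pair_table_from_counts(matrix(5L, 3, 3)), small_n = 0)
  expect_error(third_haplotype_dosage(ph, st4), "three segregating")
})

test_that("VanRaden GRM matches a hand computation and centers columns", {
  dos <- rbind(c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 0L), c(1L, 2L, 1L, 1L))
  map <- data.frame(id = paste0("g", 1:4), chrom = "1", pos = 1:4 * 10L,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, map)
  G <- vanraden_grm(gm)
  p <- colMeans(dos) / 2
  Z <- sweep(dos, 2, 2 * p)
  expect_equal(unname(G), Z %*% t(Z) / (2 * sum(p * (1 - p))))
  expect_equal(colSums(Z), rep(0, 4))
  expect_true(isSymmetric(G))

  # duplicated individuals: off-diagonal equals the diagonal entry
  gm2 <- genotype_matrix(rbind(dos, dos[1, ]), map)
  G2 <- vanraden_grm(gm2)
  expect_equal(G2[1, 4], G2[1, 1])

  gm$dosage[1, 1] <- NA
  expect_error(vanraden_grm(gm), "missing")
})

test_that("null REML recovers simulated variance components", {
  gm <- random_snp_gm(400, 300, seed = 501)
  grm <- vanraden_grm(gm)
  ph <- simulate_phenotypes(gm, sigma2_a = 1, sigma2_e = 1, grm = grm,
                            seed = 502)
  fit <- fit_null_lmm(ph, grm)
  # heritability 0.5: estimate well inside (0, 1) and near truth
  expect_gt(fit$h2, 0.25); expect_lt(fit$h2, 0.75)
  expect_equal(fit$sigma2_a + fit$sigma2_e,
               stats::var(ph$y), tolerance = 0.3)

  # degenerate limit: no additive variance
  ph0 <- simulate_phenotypes(gm, sigma2_a = 0, sigma2_e = 1, grm = grm,
                             seed = 503)
  fit0 <- fit_null_lmm(ph0, grm)
  expect_lt(fit0$h2, 0.15)

  # relabeling invariance: permuting individuals consistently changes nothing
  perm <- sample(nrow(ph))
  fitp <- fit_null_lmm(ph[perm, ], grm)
  expect_equal(fitp$sigma2_a, fit$sigma2_a, tolerance = 1e-6)
  expect_equal(fitp$logREML, fit$logREML, tolerance = 1e-6)
})

test_that("fixed-effect factors enter by reference-level coding", {
  gm <- random_snp_gm(300, 150, seed = 621)
  grm <- vanraden_grm(gm)
  set.seed(622)
  fac <- list(parity = sample(1:6, 300, TRUE), season = sample(1:4, 300, TRUE))
  ph <- simulate_phenotypes(gm, sigma2_a = 0.5, sigma2_e = 1, grm = grm,
                            factors = fac, seed = 623)
  fit <- fit_null_lmm(ph, grm, fixed = c("parity", "season"))
  expect_length(fit$beta, 1 + 5 + 3)
  # estimated parity contrasts correlate with the simulated level effects
  eff <- attr(ph, "truth")$factor_effects$parity
  est <- fit$beta[paste0("parity", 2:6)]
  tru <- eff[as.character(2:6)] - eff[["1"]]
  expect_gt(stats::cor(est, tru), 0.9)
})

test_that("association tests control type-I error and recover effects", {
  gm <- random_snp_gm(435, 300, seed = 701)
  grm <- vanraden_grm(gm)
  ph <- simulate_phenotypes(gm, sigma2_a = 1, sigma2_e = 1, grm = grm,
                            seed = 702)
  fit <- fit_null_lmm(ph, grm)
  set.seed(703)
  p <- replicate(500, {
    x <- rbinom(435, 2L, runif(1, 0.1, 0.5))
    association_test(x, fit)$p
  })
  alpha_hat <- mean(p < 0.05)
  expect_gt(alpha_hat, 0.03); expect_lt(alpha_hat, 0.07)

  # effect recovery at n = 435, MAF 0.2
  set.seed(704)
  x <- rbinom(435, 2L, 0.2)
  est <- replicate(30, {
    phe <- simulate_phenotypes(gm, dosage = x, effect = 0.5, sigma2_a = 1,
                               sigma2_e = 1, grm = grm,
                               seed = sample.int(1e6, 1))
    association_test(x, fit_null_lmm(phe, grm))$effect
  })
  expect_lt(abs(mean(est) - 0.5), 3 * stats::sd(est) / sqrt(length(est)))

  # constant dosage is skipped with a reason
  sk <- association_test(rep(1, 435), fit)
  expect_true(sk$skipped)
  expect_match(sk$reason, "variance")
})

test_that("fixed-VC (EMMAX-style) and full per-test REML p-values agree", {
  gm <- random_snp_gm(200, 150, seed = 801)
  grm <- vanraden_grm(gm)
  ph <- simulate_phenotypes(gm, sigma2_a = 1, sigma2_e = 1, grm = grm,
                            seed = 802)
  fit <- fit_null_lmm(ph, grm)
  set.seed(803)
  for (k in 1:5) {
    x <- rbinom(200, 2L, 0.3)
    a <- association_test(x, fit)
    b <- full_reml_test(x, ph, grm)
    expect_equal(a$p, b$p, tolerance = 0.1)
    expect_equal(a$effect, b$effect, tolerance = 0.05)
  }
})

test_that("effective number of tests follows the published reduction", {
  expect_identical(effective_tests(20339, 3578, 10380), 11630L)
  expect_identical(effective_tests(500, 0, 0), 500L)
  expect_identical(effective_tests(100, 10, 30), 75L)
  expect_error(effective_tests(10, 20, 30), "not positive")
})

test_that("BH adjustment with effective tests reduces to standard BH", {
  p <- c(0.001, 0.02, 0.9)
  adj <- bh_adjust(p, m_eff = 3)
  expect_equal(adj$p_adj, c(0.003, 0.03, 0.9))
  expect_equal(bh_adjust(c(0.01), m_eff = 1)$p_adj, 0.01)

  set.seed(12)
  pr <- runif(200)^2
  expect_equal(bh_adjust(pr)$p_adj, stats::p.adjust(pr, method = "BH"))
  # monotone in rank, capped at 1, smaller m_eff never increases adjustment
  a_small <- bh_adjust(pr, m_eff = 120)$p_adj
  expect_true(all(diff(a_small[order(pr)]) >= -1e-12))
  expect_true(all(a_small <= bh_adjust(pr)$p_adj + 1e-12))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.1, 0)), "0, 1")
})

test_that("the joint GWAS detects a causal third haplotype missed by SM tests", {
  # two non-causal haplotypes (Ab, aB) share the mean; the third (ab)
  # carries the effect, so neither single-SNP allele contrast tags it
  sim <- simulate_pair_genotypes(c(AB = 0, Ab = 0.4, aB = 0.4, ab = 0.2),
                                 n = 435, seed = 901)
  bg <- random_snp_gm(435, 200, seed = 902)
  map <- rbind(bg$map,
               data.frame(id = c("c1", "c2"), chrom = "2", pos = c(100L, 200L),
                          ref = "A", alt = "G"))
  gm <- genotype_matrix(cbind(bg$dosage, sim$gm$dosage), map)
  x3 <- (sim$truth$hap1 == "ab") + (sim$truth$hap2 == "ab")
  ph <- simulate_phenotypes(gm, dosage = x3, effect = 0.7, sigma2_a = 0.5,
                            sigma2_e = 1, seed = 903)
  gw <- run_gwas(gm, ph)
  ca <- gw[gw$test == "CA" & gw$chrom == "2", ]
  sm <- gw[gw$test == "SM" & gw$chrom == "2", ]
  expect_equal(nrow(ca), 1L)
  expect_lt(ca$p, min(sm$p))
  expect_true(ca$significant)
  expect_equal(ca$bp, "100-200")
  expect_equal(ca$effect, 0.7, tolerance = 0.35)
  # m_eff bookkeeping: one three-haplotype pair among the consecutive pairs
  expect_equal(attr(gw, "n_three_hap_pairs"), 1L)
  expect_equal(attr(gw, "m_eff"),
               effective_tests(202, attr(gw, "n_full_ld_pairs"), 1L))
})

test_that("a null genome stays FDR-controlled", {
  gm <- random_snp_gm(300, 120, seed = 951)
  ph <- simulate_phenotypes(gm, sigma2_a = 0.5, sigma2_e = 1, seed = 952)
  gw <- run_gwas(gm, ph)
  expect_lte(sum(gw$significant), 2L)
  expect_true(all(gw$test == "SM") || attr(gw, "n_three_hap_pairs") > 0)
})
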