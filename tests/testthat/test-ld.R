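chr2_pt <- function() pair_table_from_counts(chr2_counts())
chr2_st <- function() suppressWarnings(detect_corners(chr2_pt()))

test_that("direct gamete counting reproduces the worked frequencies", {
  hf <- haplotype_freqs_direct(chr2_pt(), chr2_st())
  expect_equal(unname(round(hf$f, 2)), c(0.90, 0.06, 0.04, 0.00))
  expect_identical(unname(hf$f["ab"]), 0)  # missing haplotype exactly zero
  expect_equal(sum(hf$f), 1)

  # corner-I fixture counted by hand: gametes over 2N = 16
  n <- matrix(c(0L, 0L, 2L, 0L, 1L, 1L, 2L, 1L, 1L), 3L, byrow = TRUE)
  pt <- pair_table_from_counts(n)
  st <- detect_corners(pt, small_n = 0)
  expect_equal(st$missing_haplotypes, "AB")
  f <- haplotype_freqs_direct(pt, st)$f
  expect_equal(unname(f), c(0, 6 / 16, 6 / 16, 4 / 16))

  # single AAbb individual: all gametes Ab
  one <- matrix(0L, 3L, 3L); one[1L, 3L] <- 1L
  f1 <- haplotype_freqs_direct(pair_table_from_counts(one),
                               suppressWarnings(detect_corners(
                                 pair_table_from_counts(one))))$f
  expect_equal(unname(f1), c(0, 1, 0, 0))
})

test_that("allele frequencies are marginal gene counts consistent with gametes", {
  af <- allele_freqs_from_table(chr2_pt())
  expect_equal(af[["A"]], 834 / 870)
  expect_equal(af[["B"]], 817 / 870)
  expect_equal(af[["A"]] + af[["a"]], 1)

  dh <- matrix(0L, 3L, 3L); dh[2L, 2L] <- 10L
  expect_equal(unname(allele_freqs_from_table(pair_table_from_counts(dh))),
               rep(0.5, 4))

  hf <- haplotype_freqs_direct(chr2_pt(), chr2_st())
  expect_equal(hf$f[["AB"]] + hf$f[["Ab"]], af[["A"]])
  expect_equal(hf$f[["AB"]] + hf$f[["aB"]], af[["B"]])
})

test_that("D, D' and r2 follow from haplotype frequencies", {
  two <- ld_from_freqs(c(AB = 0, Ab = 0.5, aB = 0.5, ab = 0))
  expect_equal(two$D, -0.25)
  expect_equal(two$r2, 1)
  expect_equal(abs(two$D_prime), 1)

  indep <- ld_from_freqs(c(AB = 0.25, Ab = 0.25, aB = 0.25, ab = 0.25))
  expect_equal(indep$D, 0)
  expect_equal(indep$r2, 0)

  # chr2 frequencies (781/53/36/0 gametes): r2 by direct evaluation
  chr2 <- ld_from_freqs(c(AB = 781, Ab = 53, aB = 36, ab = 0) / 870)
  expect_equal(chr2$r2, 0.0028, tolerance = 0.02)
  expect_lt(chr2$r2, 0.005)

  expect_error(ld_from_freqs(c(AB = 0.6, Ab = 0.4, aB = 0, ab = 0)),
               "monomorphic")
})

test_that("closed-form count r2 equals the frequency route in every corner", {
  # corner-I fixture
  n <- matrix(c(0L, 0L, 2L, 0L, 1L, 1L, 2L, 1L, 1L), 3L, byrow = TRUE)
  for (flip in list(identity,
                    function(m) m[, 3:1],          # -> corner II (missing Ab)
                    function(m) m[3:1, ],          # -> corner III (missing aB)
                    function(m) m[3:1, 3:1])) {    # -> corner IV (missing ab)
    pt <- pair_table_from_counts(flip(n))
    st <- detect_corners(pt, small_n = 0)
    expect_equal(st$n_haplotypes, 3L)
    direct <- r2_direct(pt, st)
    generic <- ld_from_freqs(haplotype_freqs_direct(pt, st))
    expect_equal(direct$r2, generic$r2, tolerance = 1e-12)
  }

  # chr2 equality of the two routes
  expect_equal(r2_direct(chr2_pt(), chr2_st())$r2,
               ld_from_freqs(haplotype_freqs_direct(chr2_pt(), chr2_st()))$r2,
               tolerance = 1e-12)

  # two-haplotype complete LD forces r2 = 1
  n2 <- matrix(c(5L, 0L, 0L, 0L, 4L, 0L, 0L, 0L, 6L), 3L, byrow = TRUE)
  st2 <- detect_corners(pair_table_from_counts(n2), small_n = 0)
  expect_equal(r2_direct(pair_table_from_counts(n2), st2)$r2, 1)
})

test_that("EM converges to the published estimates on the worked example", {
  em <- em_haplotype_freqs(chr2_pt())
  expect_true(em$converged)
  expect_equal(unname(round(em$f, 2)), c(0.94, 0.02, 0.00, 0.04))
  expect_equal(round(ld_from_freqs(em)$r2, 3), 0.665)
  # log-likelihood is non-decreasing at every iteration
  expect_true(all(diff(em$loglik_trace) > -1e-8))
})

test_that("EM equals direct counting when no double heterozygotes exist", {
  n <- matrix(c(4L, 3L, 2L, 5L, 0L, 1L, 2L, 2L, 3L), 3L, byrow = TRUE)
  pt <- pair_table_from_counts(n)
  em <- em_haplotype_freqs(pt)
  # no latent data: the M-step is plain gamete counting regardless of corner
  fixed <- c(2 * n[1, 1] + n[1, 2] + n[2, 1], 2 * n[1, 3] + n[1, 2] + n[2, 3],
             2 * n[3, 1] + n[2, 1] + n[3, 2], 2 * n[3, 3] + n[3, 2] + n[2, 3])
  expect_equal(unname(em$f), fixed / (2 * pt$n))
  expect_equal(em$n_iter, 2L)  # second pass just confirms the fixed point
})

test_that("EM recovers simulated truth and restarts keep the best likelihood", {
  truth <- c(AB = 0, Ab = 0.5, aB = 0.3, ab = 0.2)
  sim <- simulate_pair_genotypes(truth, n = 1000, seed = 77)
  pt <- build_pair_table(sim$gm, 1, 2)
  em <- em_haplotype_freqs(pt, n_restarts = 3, seed = 78)
  expect_lt(max(abs(em$f - truth)), 0.04)  # ~2.5 binomial SDs at n=2000
  em0 <- em_haplotype_freqs(pt)
  expect_gte(em$loglik, em0$loglik - 1e-6)
})

test_that("method comparison flags only inconsistent tables", {
  # simulated 3-haplotype pairs: both methods agree closely
  set.seed(10)
  maps <- list()
  dos <- NULL
  truth_list <- list(c(AB = 0, Ab = 0.5, aB = 0.3, ab = 0.2),
                     c(AB = 0.6, Ab = 0.25, aB = 0.15, ab = 0),
                     c(AB = 0.45, Ab = 0, aB = 0.35, ab = 0.2))
  for (k in seq_along(truth_list)) {
    sim <- simulate_pair_genotypes(truth_list[[k]], n = 500, seed = 300 + k)
    dos <- cbind(dos, sim$gm$dosage)
  }
  map <- data.frame(id = paste0("p", 1:6), chrom = rep(1:3, each = 2),
                    pos = rep(c(100L, 200L), 3), ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, map)
  cmp <- compare_methods(gm)
  expect_equal(nrow(cmp), 3L)
  expect_lt(attr(cmp, "summary")$mean_abs_delta, 0.01)
  expect_false(any(cmp$discordant))

  # the chr2 pair is discordant (|delta r2| ~ 0.66)
  cmp2 <- suppressWarnings(compare_methods(chr2_gm()))
  expect_equal(cmp2$abs_delta, 0.663, tolerance = 0.01)
  expect_true(cmp2$discordant)

  # a pair with no double heterozygotes has delta exactly 0
  d <- rbind(matrix(c(0L, 0L), 50, 2, byrow = TRUE),
             matrix(c(0L, 1L), 20, 2, byrow = TRUE),
             matrix(c(0L, 2L), 5, 2, byrow = TRUE),
             matrix(c(1L, 0L), 10, 2, byrow = TRUE),
             matrix(c(2L, 0L), 4, 2, byrow = TRUE))
  gm_nodh <- genotype_matrix(d, data.frame(id = c("x1", "x2"), chrom = "9",
                                           pos = c(1L, 2L), ref = "A",
                                           alt = "G", stringsAsFactors = FALSE))
  cmp3 <- compare_methods(gm_nodh)
  expect_equal(cmp3$abs_delta, 0, tolerance = 1e-9)
})

test_that("frequencies from either method are proper distributions", {
  set.seed(99)
  for (k in 1:5) {
    f <- stats::rgamma(4, 1); f <- f / sum(f); names(f) <- c("AB", "Ab", "aB", "ab")
    f["ab"] <- 0; f <- f / sum(f)
    sim <- simulate_pair_genotypes(f, n = 200, seed = 600 + k)
    pt <- build_pair_table(sim$gm, 1, 2)
    st <- detect_corners(pt, small_n = 0)
    if (st$monomorphic) next
    em <- em_haplotype_freqs(pt)
    expect_equal(sum(em$f), 1, tolerance = 1e-9)
    expect_true(all(em$f >= 0 & em$f <= 1))
    if (st$n_haplotypes <= 3L) {
      hf <- haplotype_freqs_direct(pt, st)
      expect_equal(sum(hf$f), 1, tolerance = 1e-12)
      expect_true(all(hf$f >= 0 & hf$f <= 1))
      r <- r2_direct(pt, st)$r2
      expect_gte(r, 0); expect_lte(r, 1)
    }
  }
})
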