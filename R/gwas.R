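# Mixed-model association testing. The polygenic background is modeled with
# a VanRaden genomic relationship matrix; variance components are estimated
# once by REML on the null model via a spectral decomposition of G and then
# held fixed for every marker test (the EMMAX approximation), so thousands
# of tests cost one eigendecomposition plus a GLS solve each.

#' Dosage of the third haplotype
#'
#' When three haplotypes segregate at a SNP pair, single-marker tests at the
#' two SNPs tag two of them; the third haplotype - the complement of the
#' missing one (missing AB implies third ab) - is tagged by neither. Its
#' per-individual copy number (0, 1, 2) is read off the exact phasing.
#'
#' @param phased `data.frame` from [phase_pair()].
#' @param status the pair's `corner_status`; must have `n_haplotypes == 3`.
#' @return named integer vector of copies of the third haplotype, with
#'   attribute `haplotype`.
#' @export
third_haplotype_dosage <- function(phased, status) {
  stopifnot(inherits(status, "corner_status"))
  if (status$n_haplotypes != 3L)
    stop("third-haplotype dosage requires exactly three segregating haplotypes")
  third <- hap_complement(status$missing_haplotypes[1L])
  d <- (phased$hap1 == third) + (phased$hap2 == third)
  structure(stats::setNames(as.integer(d), phased$sample_id),
            haplotype = third)
}

#' VanRaden genomic relationship matrix
#'
#' G = Z Z' / (2 sum p_j (1 - p_j)) with Z the dosage matrix column-centered
#' at twice the observed alt-allele frequency.
#'
#' @param gm a [genotype_matrix()] without missing genotypes; monomorphic
#'   SNPs are dropped.
#' @return symmetric matrix over individuals (class `matrix`), with sample
#'   ids as dimnames.
#' @export
vanraden_grm <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  M <- gm$dosage
  if (anyNA(M)) stop("missing genotypes: run apply_qc(require_complete = TRUE)")
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (sum(poly) < 2L) stop("need at least two polymorphic SNPs")
  M <- M[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(gm$dosage), rownames(gm$dosage))
  G
}

#' REML fit of the null polygenic model
#'
#' Fits y = W b + a + e with a ~ N(0, G sigma2_a), e ~ N(0, I sigma2_e) by
#' restricted maximum likelihood, profiling the ratio
#' delta = sigma2_e / sigma2_a on the spectrum of G (one eigendecomposition,
#' 1-D optimization). A non-positive-semi-definite G is stabilized by adding
#' a small ridge to its diagonal (with a message).
#'
#' @param pheno `data.frame` with a `sample_id` column, the response column
#'   and any fixed-effect factor columns.
#' @param grm GRM over (at least) the phenotyped individuals.
#' @param response name of the trait column (default `"y"`).
#' @param fixed character vector of factor column names for the fixed
#'   effects (reference-level coding); intercept only when `NULL`.
#' @return object of class `lmm_fit`: variance components `sigma2_a`,
#'   `sigma2_e`, fixed effects `beta`, `logREML`, plus the rotated data
#'   reused by [association_test()].
#' @export
fit_null_lmm <- function(pheno, grm, response = "y", fixed = NULL) {
  stopifnot(is.data.frame(pheno), "sample_id" %in% names(pheno))
  ids <- as.character(pheno$sample_id)
  if (!all(ids %in% rownames(grm)))
    stop("phenotyped individuals missing from the GRM")
  G <- grm[ids, ids]
  y <- pheno[[response]]
  if (!is.numeric(y)) stop("response column `", response, "` must be numeric")
  W <- if (is.null(fixed)) matrix(1, length(y), 1L,
                                  dimnames = list(NULL, "(Intercept)"))
       else stats::model.matrix(stats::reformulate(fixed),
                                data = as.data.frame(lapply(pheno[fixed], factor)))
  if (qr(W)$rank < ncol(W)) stop("fixed-effect design matrix is rank deficient")
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    message("GRM is not positive semi-definite; adding ridge to the diagonal")
  }
  lam <- pmax(eg$values, 0) + 1e-6  # ridge keeps V invertible as delta -> 0
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Ws <- crossprod(U, W)
  n <- length(y); p <- ncol(W)
  reml <- function(logd) {
    d <- exp(logd)
    w <- 1 / (lam + d)
    WtW <- crossprod(Ws * w, Ws)
    b <- solve(WtW, crossprod(Ws * w, ys))
    r <- ys - Ws %*% b
    rss <- sum(w * r^2)
    s2a <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2a) + sum(log(lam + d)) +
            determinant(WtW, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(reml, interval = c(-12, 12), maximum = TRUE, tol = 1e-8)
  d <- exp(opt$maximum)
  w <- 1 / (lam + d)
  WtW <- crossprod(Ws * w, Ws)
  b <- solve(WtW, crossprod(Ws * w, ys))
  s2a <- sum(w * (ys - Ws %*% b)^2) / (n - p)
  fit <- list(sigma2_a = s2a, sigma2_e = d * s2a, delta = d,
              beta = stats::setNames(drop(b), colnames(W)),
              logREML = opt$objective,
              h2 = s2a / (s2a + d * s2a),
              U = U, lambda = lam, ys = ys, Ws = Ws, ids = ids, n = n)
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("lmm_fit (REML, spectral):\n")
  cat("  sigma2_a =", signif(x$sigma2_a, 4), " sigma2_e =",
      signif(x$sigma2_e, 4), " h2 =", round(x$h2, 3), "\n")
  cat("  fixed effects:", length(x$beta), " logREML =",
      signif(x$logREML, 6), "\n")
  invisible(x)
}

#' Single-marker or haplotype association test
#'
#' Generalized least squares of the trait on the fixed effects plus one
#' dosage covariate, under V = G sigma2_a + I sigma2_e with the variance
#' components held at their null REML estimates. The reported p-value is the
#' Wald test of the dosage coefficient.
#'
#' @param dosage named numeric vector (0/1/2 copies), names = sample ids
#'   matching the fit; unnamed vectors must align with the fit's order.
#' @param fit an `lmm_fit` from [fit_null_lmm()].
#' @return list with `effect`, `se`, `z`, `p`, `skipped`, `reason`.
#' @export
association_test <- function(dosage, fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  x <- if (!is.null(names(dosage))) dosage[fit$ids] else dosage
  if (anyNA(x)) return(list(effect = NA_real_, se = NA_real_, z = NA_real_,
                            p = NA_real_, skipped = TRUE,
                            reason = "missing dosage"))
  if (stats::var(x) == 0)
    return(list(effect = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                skipped = TRUE, reason = "zero dosage variance"))
  xs <- drop(crossprod(fit$U, x))
  X <- cbind(fit$Ws, dosage = xs)
  w <- 1 / (fit$sigma2_a * (fit$lambda + fit$delta))
  XtX <- crossprod(X * w, X)
  b <- solve(XtX, crossprod(X * w, fit$ys))
  cv <- solve(XtX)
  k <- ncol(X)
  se <- sqrt(cv[k, k])
  z <- b[k] / se
  list(effect = unname(b[k]), se = se, z = unname(z),
       p = 2 * stats::pnorm(-abs(z)), skipped = FALSE, reason = NA_character_)
}

#' Effective number of tests
#'
#' Total SNPs minus half the SNPs in full LD (two-haplotype consecutive
#' pairs) minus two thirds of the three-haplotype consecutive pairs; the
#' reduction acknowledges that the three tests on a pair share haplotypes.
#'
#' @param n_snps total single-marker tests.
#' @param n_full_ld_pairs consecutive pairs with two segregating haplotypes.
#' @param n_three_hap_pairs consecutive pairs with three segregating
#'   haplotypes.
#' @return integer count (nearest-integer rounding).
#' @export
effective_tests <- function(n_snps, n_full_ld_pairs, n_three_hap_pairs) {
  stopifnot(n_snps >= 0, n_full_ld_pairs >= 0, n_three_hap_pairs >= 0)
  m <- round(n_snps - n_full_ld_pairs / 2 - (2 / 3) * n_three_hap_pairs)
  if (m <= 0) stop("effective number of tests is not positive")
  as.integer(m)
}

#' Benjamini-Hochberg adjustment with an effective number of tests
#'
#' Step-up adjustment p_(i) * m_eff / i with monotonicity enforcement and a
#' cap at 1, where `m_eff` replaces the raw test count to account for
#' correlated tests (it may be smaller than `length(p)`). With
#' `m_eff = length(p)` this is exactly the standard BH adjustment.
#'
#' @param p raw p-values in (0, 1].
#' @param m_eff effective number of tests (default `length(p)`).
#' @param alpha FDR level for the significance flags (default 0.05).
#' @return list with `p_adj` (in input order) and `significant`.
#' @export
bh_adjust <- function(p, m_eff = length(p), alpha = 0.05) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  o <- order(p)
  ranked <- p[o] * m_eff / seq_along(p)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(length(p))
  out[o] <- adj
  list(p_adj = out, significant = out <= alpha)
}

#' Joint single-marker and third-haplotype GWAS
#'
#' For every SNP, a single-marker (SM) test on alt-allele dosage; for every
#' consecutive pair with exactly three segregating haplotypes, a
#' third-haplotype (CA) test on the phased copy number of the haplotype
#' tagged by neither SNP. Pair classification counts feed
#' [effective_tests()], and all p-values are adjusted jointly by
#' [bh_adjust()].
#'
#' @param gm a QC'd [genotype_matrix()] (no missing genotypes).
#' @param pheno phenotype `data.frame` as in [fit_null_lmm()].
#' @param response,fixed passed to [fit_null_lmm()].
#' @param alpha genome-wide FDR level (default 0.05).
#' @param grm,fit optional precomputed pieces.
#' @return `data.frame` of class `gwas_result`: `marker`, `chrom`, `bp`
#'   (single position, or "start-end" for CA tests), `test` ("SM"/"CA"),
#'   `effect`, `se`, `p`, `p_adj`, `significant`; attributes `m_eff`,
#'   `n_full_ld_pairs`, `n_three_hap_pairs`, `fit`.
#' @export
run_gwas <- function(gm, pheno, response = "y", fixed = NULL, alpha = 0.05,
                     grm = NULL, fit = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(grm)) grm <- vanraden_grm(gm)
  if (is.null(fit)) fit <- fit_null_lmm(pheno, grm, response, fixed)
  rows <- list()
  for (s in seq_len(ncol(gm$dosage))) {
    d <- stats::setNames(gm$dosage[, s], rownames(gm$dosage))
    at <- association_test(d, fit)
    if (at$skipped) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker = gm$map$id[s], chrom = gm$map$chrom[s],
      bp = as.character(gm$map$pos[s]), test = "SM",
      effect = at$effect, se = at$se, p = at$p, stringsAsFactors = FALSE)
  }
  pairs <- consecutive_pairs(gm)
  n2 <- 0L; n3 <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    pt <- build_pair_table(gm, i, j)
    st <- detect_corners(pt, small_n = 0)
    if (st$monomorphic) next
    if (st$n_haplotypes == 2L) n2 <- n2 + 1L
    if (st$n_haplotypes != 3L) next
    n3 <- n3 + 1L
    ph <- phase_pair(gm, i, j, st)
    d3 <- third_haplotype_dosage(ph, st)
    at <- association_test(d3, fit)
    if (at$skipped) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker = gm$map$id[i], chrom = gm$map$chrom[i],
      bp = paste0(gm$map$pos[i], "-", gm$map$pos[j]), test = "CA",
      effect = at$effect, se = at$se, p = at$p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no testable markers")
  out <- do.call(rbind, rows)
  m_eff <- effective_tests(ncol(gm$dosage), n2, n3)
  adj <- bh_adjust(out$p, m_eff = m_eff, alpha = alpha)
  out$p_adj <- adj$p_adj
  out$significant <- adj$significant
  ord <- order(out$chrom, as.numeric(sub("-.*$", "", out$bp)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m_eff") <- m_eff
  attr(out, "n_full_ld_pairs") <- n2
  attr(out, "n_three_hap_pairs") <- n3
  attr(out, "fit") <- fit
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("gwas_result:", sum(x$test == "SM"), "SM tests +",
      sum(x$test == "CA"), "CA tests; m_eff =", attr(x, "m_eff"), "\n")
  cat("  significant at FDR:", sum(x$significant), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Manhattan-style plot of GWAS results
#'
#' -log10 adjusted p by position, colored by test type.
#'
#' @param x a `gwas_result`.
#' @param y ignored.
#' @param ... passed to [plot()].
#' @export
plot.gwas_result <- function(x, y, ...) {
  bp <- as.numeric(sub("-.*$", "", x$bp))
  chr <- factor(x$chrom, levels = unique(x$chrom))
  off <- c(0, cumsum(tapply(bp, chr, max)))[as.integer(chr)]
  plot(off + bp, -log10(x$p_adj),
       col = ifelse(x$test == "CA", "firebrick", "grey30"),
       pch = 16, cex = 0.6, xlab = "genome position",
       ylab = expression(-log[10](p[adj])), ...)
  graphics::abline(h = -log10(0.05), lty = 2)
  invisible(x)
}
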