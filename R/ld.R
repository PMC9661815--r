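# Direct LD estimation from exactly phased gametes, and the Excoffier-Slatkin
# two-locus EM baseline under Hardy-Weinberg equilibrium.

#' Direct haplotype-frequency estimation by gamete counting
#'
#' When at most three haplotypes segregate, every individual's two gametes
#' are known exactly (double heterozygotes take the forced phase), so
#' haplotype frequencies are plain counts over 2N gametes. The missing
#' haplotype's frequency is exactly 0.
#'
#' @param pt a `pair_table`.
#' @param status its `corner_status` (computed when omitted);
#'   `n_haplotypes` must be at most 3.
#' @return object of class `haplotype_freqs`: list with `f` (named numeric,
#'   AB/Ab/aB/ab, summing to 1), `source = "corners"`, `n_gametes`,
#'   `missing`, `ambiguous`.
#' @export
haplotype_freqs_direct <- function(pt, status = NULL) {
  stopifnot(inherits(pt, "pair_table"))
  if (is.null(status)) status <- detect_corners(pt, small_n = 0)
  if (status$n_haplotypes == 4L)
    stop("four haplotypes segregate: direct gamete counting is not applicable")
  n <- pt$counts
  cnt <- c(AB = 2 * n[1, 1] + n[1, 2] + n[2, 1],
           Ab = 2 * n[1, 3] + n[1, 2] + n[2, 3],
           aB = 2 * n[3, 1] + n[2, 1] + n[3, 2],
           ab = 2 * n[3, 3] + n[3, 2] + n[2, 3])
  ndh <- n[2, 2]
  if (ndh > 0L) {
    if (status$double_het_phase == "AB/ab") {
      cnt["AB"] <- cnt["AB"] + ndh; cnt["ab"] <- cnt["ab"] + ndh
    } else if (status$double_het_phase == "Ab/aB") {
      cnt["Ab"] <- cnt["Ab"] + ndh; cnt["aB"] <- cnt["aB"] + ndh
    } else stop("double heterozygotes present but phase undefined")
  }
  f <- cnt / (2 * pt$n)
  f[status$missing_haplotypes] <- 0  # exact zero by construction
  structure(list(f = f, source = "corners", n_gametes = 2L * pt$n,
                 missing = status$missing_haplotypes,
                 ambiguous = status$ambiguous),
            class = "haplotype_freqs")
}

#' @export
print.haplotype_freqs <- function(x, digits = 4, ...) {
  cat("haplotype_freqs (", x$source, "):\n", sep = "")
  print(round(x$f, digits))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  if (isTRUE(x$ambiguous)) cat("  (ambiguous corner tie)\n")
  invisible(x)
}

#' Marginal allele frequencies from a pair table
#'
#' Gene-counting estimates f_A = (2 n_AA + n_Aa) / 2N etc., from the table's
#' row and column marginals.
#'
#' @param pt a `pair_table` with N > 0.
#' @return named numeric `c(A, a, B, b)`.
#' @export
allele_freqs_from_table <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  if (pt$n == 0L) stop("empty pair table (N = 0)")
  n <- pt$counts
  c(A = (2 * sum(n[1, ]) + sum(n[2, ])) / (2 * pt$n),
    a = (2 * sum(n[3, ]) + sum(n[2, ])) / (2 * pt$n),
    B = (2 * sum(n[, 1]) + sum(n[, 2])) / (2 * pt$n),
    b = (2 * sum(n[, 3]) + sum(n[, 2])) / (2 * pt$n))
}

#' Linkage disequilibrium from haplotype frequencies
#'
#' D = f_AB f_ab - f_Ab f_aB; D' scales D by its maximum attainable absolute
#' value given the allele frequencies (Lewontin); r2 = D^2 / (f_A f_a f_B f_b).
#'
#' @param freqs a `haplotype_freqs` or a named numeric with entries
#'   AB, Ab, aB, ab summing to 1.
#' @return object of class `ld_result`: list with `D`, `D_prime`, `r2`,
#'   `allele_freqs`, `haplotype_freqs`, `method`.
#' @export
ld_from_freqs <- function(freqs) {
  method <- "freqs"
  if (inherits(freqs, "haplotype_freqs")) {
    method <- freqs$source
    freqs <- freqs$f
  }
  f <- freqs[HAPLOTYPES]
  if (anyNA(f) || abs(sum(f) - 1) > 1e-9)
    stop("`freqs` must contain AB, Ab, aB, ab summing to 1")
  fA <- f[["AB"]] + f[["Ab"]]; fB <- f[["AB"]] + f[["aB"]]
  fa <- 1 - fA; fb <- 1 - fB
  if (fA <= 0 || fa <= 0)
    stop("left locus is monomorphic: LD undefined")
  if (fB <= 0 || fb <= 0)
    stop("right locus is monomorphic: LD undefined")
  D <- f[["AB"]] * f[["ab"]] - f[["Ab"]] * f[["aB"]]
  Dmax <- if (D > 0) min(fA * fb, fa * fB) else min(fA * fB, fa * fb)
  Dp <- if (D == 0) 0 else D / Dmax
  r2 <- D^2 / (fA * fa * fB * fb)
  structure(list(D = unname(D), D_prime = unname(Dp), r2 = unname(r2),
                 allele_freqs = c(A = fA, a = fa, B = fB, b = fb),
                 haplotype_freqs = f, method = method),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, digits = 4, ...) {
  cat("ld_result (", x$method, "): D = ", round(x$D, digits),
      ", D' = ", round(x$D_prime, digits),
      ", r2 = ", round(x$r2, digits), "\n", sep = "")
  invisible(x)
}

# reorient counts so the missing haplotype is AB (corner I): flip rows for
# a missing 'a' haplotype, columns for a missing 'b' haplotype
orient_to_corner1 <- function(counts, missing_hap) {
  if (substr(missing_hap, 1, 1) == "a") counts <- counts[3:1, , drop = FALSE]
  if (substr(missing_hap, 2, 2) == "b") counts <- counts[, 3:1, drop = FALSE]
  counts
}

#' Direct (closed-form) r2 when the four-gamete test fails
#'
#' Evaluates the substituted count formula for the corner-I orientation
#' (missing haplotype AB):
#' r2 = \[(2 n_AAbb + n_AABb + n_Aabb + n_AaBb)(2 n_aaBB + n_AaBB + n_aaBb +
#' n_AaBb) / sqrt((2 n_AA + n_Aa)(2 n_aa + n_Aa)(2 n_BB + n_Bb)(2 n_bb +
#' n_Bb))\]^2; the other three corners are relabelings obtained by flipping
#' rows/columns. Two-haplotype tables are computed from the phased
#' frequencies (r2 = 1 whenever both loci are polymorphic).
#'
#' @inheritParams haplotype_freqs_direct
#' @return an `ld_result` with `method = "corners"`; identical (to numerical
#'   precision) to `ld_from_freqs(haplotype_freqs_direct(pt, status))`.
#' @export
r2_direct <- function(pt, status = NULL) {
  stopifnot(inherits(pt, "pair_table"))
  if (is.null(status)) status <- detect_corners(pt, small_n = 0)
  if (status$n_haplotypes == 4L)
    stop("four haplotypes segregate: direct estimation is not applicable")
  res <- ld_from_freqs(haplotype_freqs_direct(pt, status))
  if (status$n_haplotypes == 3L) {
    n <- orient_to_corner1(pt$counts, status$missing_haplotypes[1L])
    num <- (2 * n[1, 3] + n[1, 2] + n[2, 3] + n[2, 2]) *
           (2 * n[3, 1] + n[2, 1] + n[3, 2] + n[2, 2])
    den <- sqrt((2 * sum(n[1, ]) + sum(n[2, ])) *
                (2 * sum(n[3, ]) + sum(n[2, ])) *
                (2 * sum(n[, 1]) + sum(n[, 2])) *
                (2 * sum(n[, 3]) + sum(n[, 2])))
    res$r2 <- (-num / den)^2
  }
  res$method <- "corners"
  res
}

# HWE genotype-class log-likelihood of the 3x3 counts given haplotype freqs
em_loglik <- function(n, f) {
  p <- matrix(c(f["AB"]^2,            2 * f["AB"] * f["Ab"], f["Ab"]^2,
                2 * f["AB"] * f["aB"],
                2 * f["AB"] * f["ab"] + 2 * f["Ab"] * f["aB"],
                2 * f["Ab"] * f["ab"],
                f["aB"]^2,            2 * f["aB"] * f["ab"], f["ab"]^2),
              3L, 3L, byrow = TRUE)
  sum(n[n > 0] * log(p[n > 0]))
}

#' Two-locus EM haplotype-frequency estimation (Excoffier-Slatkin)
#'
#' Maximum-likelihood haplotype frequencies under Hardy-Weinberg
#' equilibrium. The E-step allocates double heterozygotes to the AB/ab phase
#' with responsibility f_AB f_ab / (f_AB f_ab + f_Ab f_aB); the M-step
#' recounts gametes. The default start is the linkage-equilibrium point
#' (products of allele frequencies); the likelihood surface can hold local
#' maxima in small samples, so random restarts are available and the run
#' with the highest log-likelihood is kept.
#'
#' @param pt a `pair_table` with N > 0.
#' @param init `"le"` (linkage-equilibrium products, default), `"uniform"`,
#'   or a named numeric of starting frequencies.
#' @param tol convergence threshold on the maximum absolute frequency change
#'   (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @param n_restarts additional random (Dirichlet) starts beyond `init`.
#' @param seed RNG seed for the restarts.
#' @return a `haplotype_freqs` with `source = "em"` and extra fields
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`.
#' @export
em_haplotype_freqs <- function(pt, init = "le", tol = 1e-10, max_iter = 10000,
                               n_restarts = 0, seed = NULL) {
  stopifnot(inherits(pt, "pair_table"))
  if (pt$n == 0L) stop("empty pair table (N = 0)")
  af <- allele_freqs_from_table(pt)
  starts <- list()
  if (is.numeric(init)) {
    starts[[1L]] <- init[HAPLOTYPES] / sum(init)
  } else if (identical(init, "uniform")) {
    starts[[1L]] <- stats::setNames(rep(0.25, 4L), HAPLOTYPES)
  } else {
    starts[[1L]] <- c(AB = af[["A"]] * af[["B"]], Ab = af[["A"]] * af[["b"]],
                      aB = af[["a"]] * af[["B"]], ab = af[["a"]] * af[["b"]])
  }
  if (n_restarts > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (k in seq_len(n_restarts)) {
      g <- stats::rgamma(4L, 1)
      starts[[k + 1L]] <- stats::setNames(g / sum(g), HAPLOTYPES)
    }
  }
  best <- NULL
  for (f0 in starts) {
    run <- em_run(pt$counts, pt$n, f0, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged)
    warning("EM did not converge in ", max_iter,
            " iterations; returning best iterate")
  structure(list(f = best$f, source = "em", n_gametes = 2L * pt$n,
                 missing = character(0), ambiguous = FALSE,
                 loglik = best$loglik, loglik_trace = best$trace,
                 n_iter = best$n_iter, converged = best$converged),
            class = "haplotype_freqs")
}

em_run <- function(n, N, f, tol, max_iter) {
  trace <- em_loglik(n, f)
  converged <- FALSE
  it <- 0L
  fixed <- c(AB = 2 * n[1, 1] + n[1, 2] + n[2, 1],
             Ab = 2 * n[1, 3] + n[1, 2] + n[2, 3],
             aB = 2 * n[3, 1] + n[2, 1] + n[3, 2],
             ab = 2 * n[3, 3] + n[3, 2] + n[2, 3])
  ndh <- n[2, 2]
  while (it < max_iter) {
    it <- it + 1L
    num <- f[["AB"]] * f[["ab"]]
    den <- num + f[["Ab"]] * f[["aB"]]
    r <- if (den > 0) num / den else 0.5
    cnt <- fixed + ndh * c(r, 1 - r, 1 - r, r)
    fn <- cnt / (2 * N)
    delta <- max(abs(fn - f))
    f <- fn
    trace <- c(trace, em_loglik(n, f))
    if (delta < tol) { converged <- TRUE; break }
  }
  list(f = f, loglik = trace[length(trace)], trace = trace,
       n_iter = it, converged = converged)
}

#' Compare direct (Corners') and EM r2 across SNP pairs
#'
#' For each eligible pair (at most three segregating haplotypes, both loci
#' polymorphic) computes r2 by both routes and their absolute difference.
#' The two agree except when the genotype counts are internally inconsistent
#' (e.g. through genotyping error), so pairs with |delta r2| at or above
#' `discordance` are flagged as likely genotyping errors.
#'
#' @param gm a [genotype_matrix()].
#' @param pairs two-column integer matrix of SNP index pairs; default all
#'   consecutive pairs within each chromosome.
#' @param discordance flagging threshold on |delta r2| (default 0.04).
#' @return `data.frame` of class `ld_comparison`, one row per eligible pair,
#'   with attribute `summary` (mean |delta r2|, pair classification counts).
#' @export
compare_methods <- function(gm, pairs = NULL, discordance = 0.04) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(pairs)) pairs <- consecutive_pairs(gm)
  pairs <- as.matrix(pairs)
  n_class <- c(`2` = 0L, `3` = 0L, `4` = 0L, mono = 0L)
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    pt <- build_pair_table(gm, pairs[k, 1L], pairs[k, 2L])
    st <- detect_corners(pt, small_n = 0)
    if (st$monomorphic) { n_class["mono"] <- n_class["mono"] + 1L; next }
    cls <- as.character(st$n_haplotypes)
    n_class[cls] <- n_class[cls] + 1L
    if (st$n_haplotypes > 3L) next
    ldc <- r2_direct(pt, st)
    lde <- ld_from_freqs(em_haplotype_freqs(pt))
    rows[[k]] <- data.frame(
      id1 = pt$snp1$id, id2 = pt$snp2$id, chrom = pt$snp1$chrom,
      pos1 = pt$snp1$pos, pos2 = pt$snp2$pos, N = pt$n,
      n_haplotypes = st$n_haplotypes,
      missing_hap = paste(st$missing_haplotypes, collapse = ","),
      r2_corners = ldc$r2, r2_em = lde$r2,
      abs_delta = abs(ldc$r2 - lde$r2),
      ambiguous = st$ambiguous, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no eligible pairs (with 2 or 3 segregating haplotypes)")
  out <- do.call(rbind, rows)
  out$discordant <- out$abs_delta >= discordance
  attr(out, "summary") <- list(mean_abs_delta = mean(out$abs_delta),
                               n_discordant = sum(out$discordant),
                               n_class = n_class)
  class(out) <- c("ld_comparison", "data.frame")
  out
}

#' @export
print.ld_comparison <- function(x, ...) {
  s <- attr(x, "summary")
  cat("ld_comparison:", nrow(x), "pairs with <= 3 haplotypes\n")
  cat("  mean |delta r2| =", signif(s$mean_abs_delta, 3),
      "| discordant (>= threshold):", s$n_discordant, "\n")
  cat("  pair classes: 2-hap", s$n_class[["2"]], "| 3-hap", s$n_class[["3"]],
      "| 4-hap", s$n_class[["4"]], "| monomorphic", s$n_class[["mono"]], "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# all consecutive SNP index pairs within each chromosome
consecutive_pairs <- function(gm) {
  idx <- seq_len(nrow(gm$map))
  keep <- gm$map$chrom[-length(idx)] == gm$map$chrom[-1L]
  cbind(idx[-length(idx)][keep], idx[-1L][keep])
}

#' Per-pair LD table over consecutive SNPs
#'
#' Classifies every pair and estimates LD by the requested method(s);
#' four-haplotype pairs are estimated by EM only (the direct path requires a
#' failing four-gamete test).
#'
#' @param gm a [genotype_matrix()].
#' @param pairs as in [compare_methods()].
#' @param method `"corners"`, `"em"`, or `"both"`.
#' @return `data.frame` with one row per pair and method.
#' @export
ld_table <- function(gm, pairs = NULL, method = c("corners", "em", "both")) {
  method <- match.arg(method)
  if (is.null(pairs)) pairs <- consecutive_pairs(gm)
  pairs <- as.matrix(pairs)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    pt <- build_pair_table(gm, pairs[k, 1L], pairs[k, 2L])
    st <- detect_corners(pt, small_n = 0)
    if (st$monomorphic) next
    for (m in if (method == "both") c("corners", "em") else method) {
      if (m == "corners" && st$n_haplotypes > 3L) next
      ld <- if (m == "corners") r2_direct(pt, st)
            else ld_from_freqs(em_haplotype_freqs(pt))
      f <- if (m == "corners") haplotype_freqs_direct(pt, st)$f
           else ld$haplotype_freqs
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pt$snp1$chrom, pos1 = pt$snp1$pos, pos2 = pt$snp2$pos,
        id1 = pt$snp1$id, id2 = pt$snp2$id, N = pt$n,
        n_haplotypes = st$n_haplotypes,
        missing_hap = paste(st$missing_haplotypes, collapse = ","),
        method = m, f_AB = f[["AB"]], f_Ab = f[["Ab"]], f_aB = f[["aB"]],
        f_ab = f[["ab"]], D = ld$D, Dprime = ld$D_prime, r2 = ld$r2,
        ambiguous = st$ambiguous, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no estimable pairs")
  do.call(rbind, rows)
}
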