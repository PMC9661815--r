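# Haplotypes are named over abstract alleles with A/B = ref at the left/right
# SNP: "AB", "Ab", "aB", "ab". Corner c of the 3x3 genotype-count table is
# empty iff its three cells are all zero; every genotype in corner c carries
# at least one copy of the corresponding haplotype, so an absent haplotype
# empties its corner.

HAPLOTYPES <- c("AB", "Ab", "aB", "ab")

# cells (row, col) of each corner; rows AA/Aa/aa, cols BB/Bb/bb
CORNER_CELLS <- list(
  I   = cbind(c(1L, 1L, 2L), c(1L, 2L, 1L)),  # AABB, AABb, AaBB -> missing AB
  II  = cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)),  # AABb, AAbb, Aabb -> missing Ab
  III = cbind(c(2L, 3L, 3L), c(1L, 1L, 2L)),  # AaBB, aaBB, aaBb -> missing aB
  IV  = cbind(c(2L, 3L, 3L), c(3L, 3L, 2L))   # Aabb, aaBb, aabb -> missing ab
)
CORNER_HAP <- c(I = "AB", II = "Ab", III = "aB", IV = "ab")

# flip both alleles of a haplotype name ("AB" -> "ab")
hap_complement <- function(h) chartr("AaBb", "aAbB", h)

#' Two-locus genotype-count table
#'
#' Tallies the 3x3 table of two-locus genotype counts n_ij (rows AA/Aa/aa at
#' the left SNP, columns BB/Bb/bb at the right SNP) over individuals with
#' complete genotypes at both SNPs. This table is the sole sufficient
#' statistic of the Corners' Algorithm.
#'
#' @param gm a [genotype_matrix()].
#' @param i,j distinct SNP column indices (or marker ids).
#' @return object of class `pair_table`: list with `counts` (3x3 integer
#'   matrix), `n` (complete-case individuals), `snp1`, `snp2` (map rows,
#'   left SNP first by position when on the same chromosome).
#' @export
build_pair_table <- function(gm, i, j) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.character(i)) i <- match(i, gm$map$id)
  if (is.character(j)) j <- match(j, gm$map$id)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > ncol(gm$dosage) ||
      j > ncol(gm$dosage)) stop("SNP index out of range")
  if (i == j) stop("`i` and `j` must name distinct SNPs")
  if (gm$map$chrom[i] == gm$map$chrom[j] && gm$map$pos[i] > gm$map$pos[j]) {
    tmp <- i; i <- j; j <- tmp
  }
  d1 <- gm$dosage[, i]; d2 <- gm$dosage[, j]
  cc <- !is.na(d1) & !is.na(d2)
  counts <- matrix(0L, 3L, 3L,
                   dimnames = list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb")))
  tab <- table(factor(d1[cc], levels = 0:2), factor(d2[cc], levels = 0:2))
  counts[] <- as.integer(tab)
  pt <- list(counts = counts, n = sum(cc),
             snp1 = gm$map[i, , drop = FALSE], snp2 = gm$map[j, , drop = FALSE],
             idx = c(i, j))
  class(pt) <- "pair_table"
  pt
}

#' Build a pair table directly from printed genotype counts
#'
#' @param counts 3x3 matrix of non-negative counts, rows AA/Aa/aa, columns
#'   BB/Bb/bb.
#' @param snp1,snp2 optional single-row map `data.frame`s.
#' @return a `pair_table`.
#' @export
pair_table_from_counts <- function(counts, snp1 = NULL, snp2 = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3L, 3L)), all(counts >= 0))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(c("AA", "Aa", "aa"), c("BB", "Bb", "bb"))
  structure(list(counts = counts, n = sum(counts), snp1 = snp1, snp2 = snp2,
                 idx = NULL), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("pair_table (N =", x$n, "complete cases)\n")
  if (!is.null(x$snp1))
    cat(" ", x$snp1$id, "x", x$snp2$id, "\n")
  print(x$counts)
  invisible(x)
}

#' Detect empty corners and classify the four-gamete test
#'
#' A corner with all three cells at exactly zero marks its haplotype as
#' missing. One empty corner means three haplotypes segregate and the phase
#' of double heterozygotes is forced; an empty opposite-corner pair ({I,IV}
#' or {II,III}) means two haplotypes segregate (complete LD); no empty corner
#' means all four haplotypes are present (the four-gamete test passes).
#' When two adjacent (non-opposite) corners are simultaneously empty the data
#' cannot distinguish the two phasings: corners are taken in precedence order
#' IV > III > II > I and the result is flagged `ambiguous` with a warning.
#'
#' @param pt a `pair_table`.
#' @param small_n warn when the table has fewer complete cases than this
#'   (default 50): an empty corner in a small sample is weak evidence that
#'   the haplotype is absent from the population.
#' @return object of class `corner_status`: list with `empty_corners`,
#'   `n_haplotypes` (2, 3 or 4), `missing_haplotypes`, `double_het_phase`
#'   ("AB/ab", "Ab/aB" or "undefined"), `ambiguous`, `monomorphic`, `n`.
#' @export
detect_corners <- function(pt, small_n = 50) {
  stopifnot(inherits(pt, "pair_table"))
  n <- pt$counts
  if (pt$n == 0L) stop("empty pair table (N = 0)")
  if (pt$n < small_n)
    warning("only ", pt$n, " complete cases: an empty corner may reflect ",
            "sampling rather than a missing haplotype")
  # marginal allele presence
  hasA <- 2L * sum(n[1L, ]) + sum(n[2L, ]) > 0L
  hasa <- 2L * sum(n[3L, ]) + sum(n[2L, ]) > 0L
  hasB <- 2L * sum(n[, 1L]) + sum(n[, 2L]) > 0L
  hasb <- 2L * sum(n[, 3L]) + sum(n[, 2L]) > 0L
  empty <- names(CORNER_CELLS)[vapply(CORNER_CELLS,
                                      function(cc) all(n[cc] == 0L), logical(1))]
  mono <- !(hasA && hasa) || !(hasB && hasb)
  if (mono) {
    present <- outer(c(A = hasA, a = hasa), c(B = hasB, b = hasb), "&")
    obs <- HAPLOTYPES[c(present["A", "B"], present["A", "b"],
                        present["a", "B"], present["a", "b"])]
    st <- list(empty_corners = empty, n_haplotypes = length(obs),
               missing_haplotypes = setdiff(HAPLOTYPES, obs),
               double_het_phase = "undefined", ambiguous = FALSE,
               monomorphic = TRUE, n = pt$n)
    class(st) <- "corner_status"
    return(st)
  }
  opp14 <- all(c("I", "IV") %in% empty)
  opp23 <- all(c("II", "III") %in% empty)
  if (opp14 && opp23) {
    # only double heterozygotes observed; indistinguishable, use precedence
    warning("all four corners empty (only double heterozygotes observed); ",
            "phase assigned by corner precedence and flagged ambiguous")
    miss <- c("ab", "AB")
    st_phase <- "Ab/aB"; nh <- 2L; amb <- TRUE
  } else if (opp14 || opp23) {
    miss <- if (opp14) c("AB", "ab") else c("Ab", "aB")
    st_phase <- if (opp14) "Ab/aB" else "AB/ab"
    nh <- 2L
    amb <- length(empty) > 2L
    if (amb) warning("extra empty corner beyond an opposite pair; flagged ambiguous")
  } else if (length(empty) >= 1L) {
    pick <- c("IV", "III", "II", "I")[match(TRUE, c("IV", "III", "II", "I") %in% empty)]
    miss <- CORNER_HAP[[pick]]
    st_phase <- if (miss %in% c("AB", "ab")) "Ab/aB" else "AB/ab"
    nh <- 3L
    amb <- length(empty) > 1L
    if (amb)
      warning("adjacent corners ", paste(empty, collapse = ", "),
              " all empty; corner ", pick, " selected by precedence ",
              "(IV > III > II > I); phasing is ambiguous")
  } else {
    miss <- character(0)
    st_phase <- "undefined"
    nh <- 4L
    amb <- FALSE
  }
  st <- list(empty_corners = empty, n_haplotypes = nh,
             missing_haplotypes = unname(miss), double_het_phase = st_phase,
             ambiguous = amb, monomorphic = FALSE, n = pt$n)
  class(st) <- "corner_status"
  st
}

#' @export
print.corner_status <- function(x, ...) {
  cat("corner_status:", x$n_haplotypes, "haplotype(s) segregating\n")
  if (length(x$empty_corners))
    cat("  empty corner(s):", paste(x$empty_corners, collapse = ", "), "\n")
  if (length(x$missing_haplotypes))
    cat("  missing haplotype(s):", paste(x$missing_haplotypes, collapse = ", "), "\n")
  cat("  double-heterozygote phase:", x$double_het_phase, "\n")
  if (x$ambiguous) cat("  (ambiguous: tie broken by corner precedence)\n")
  if (x$monomorphic) cat("  (a locus is monomorphic in this table)\n")
  invisible(x)
}

#' Number of segregating haplotypes for a SNP pair
#'
#' Thin wrapper over [detect_corners()]: 2 or 3 means the four-gamete test
#' fails, 4 means it passes.
#'
#' @inheritParams detect_corners
#' @return integer 2, 3 or 4 with attribute `status` (the `corner_status`).
#' @export
four_gamete_test <- function(pt, small_n = 0) {
  st <- detect_corners(pt, small_n = small_n)
  structure(st$n_haplotypes, status = st)
}

# unambiguous haplotype pairs by genotype cell; centre resolved by status
DIP_HAPS <- list(
  "0,0" = c("AB", "AB"), "0,1" = c("AB", "Ab"), "0,2" = c("Ab", "Ab"),
  "1,0" = c("AB", "aB"), "1,2" = c("Ab", "ab"),
  "2,0" = c("aB", "aB"), "2,1" = c("aB", "ab"), "2,2" = c("ab", "ab")
)

#' Exact phasing of a SNP pair
#'
#' Assigns each complete-case individual its unordered haplotype pair. All
#' genotypes but the double heterozygote are phased by genotype alone; the
#' double heterozygote is phased per the forced phase in `status`.
#'
#' @param gm a [genotype_matrix()].
#' @param i,j SNP indices as in [build_pair_table()].
#' @param status a `corner_status` for this pair with `n_haplotypes <= 3`;
#'   computed from the data when omitted.
#' @return `data.frame` with columns `sample_id`, `hap1`, `hap2` (abstract
#'   AB-coding) and `allele1`, `allele2` (concrete two-character allele
#'   strings).
#' @export
phase_pair <- function(gm, i, j, status = NULL) {
  pt <- build_pair_table(gm, i, j)
  if (is.null(status)) status <- detect_corners(pt, small_n = 0)
  if (status$n_haplotypes == 4L)
    stop("four haplotypes segregate: phase of double heterozygotes is not ",
         "determined (four-gamete test passes)")
  i <- pt$idx[1L]; j <- pt$idx[2L]
  d1 <- gm$dosage[, i]; d2 <- gm$dosage[, j]
  cc <- which(!is.na(d1) & !is.na(d2))
  key <- paste(d1[cc], d2[cc], sep = ",")
  dh <- key == "1,1"
  if (any(dh) && status$double_het_phase == "undefined")
    stop("double heterozygotes present but phase undefined for this pair")
  haps <- DIP_HAPS[key]
  if (any(dh)) {
    ph <- strsplit(status$double_het_phase, "/", fixed = TRUE)[[1L]]
    haps[dh] <- list(ph)
  }
  h1 <- vapply(haps, `[`, character(1), 1L)
  h2 <- vapply(haps, `[`, character(1), 2L)
  out <- data.frame(sample_id = rownames(gm$dosage)[cc],
                    hap1 = unname(h1), hap2 = unname(h2),
                    stringsAsFactors = FALSE)
  out$allele1 <- hap_alleles(out$hap1, pt$snp1, pt$snp2)
  out$allele2 <- hap_alleles(out$hap2, pt$snp1, pt$snp2)
  out
}

# "Ab" -> concrete allele string, e.g. ref1 alt2 -> "AG"
hap_alleles <- function(h, snp1, snp2) {
  if (is.null(snp1) || is.null(snp2)) return(NA_character_)
  a1 <- ifelse(substr(h, 1L, 1L) == "A", snp1$ref, snp1$alt)
  a2 <- ifelse(substr(h, 2L, 2L) == "B", snp2$ref, snp2$alt)
  paste0(a1, a2)
}
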