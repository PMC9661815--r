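# Haplotyping of chromosomal regions in which every SNP pair (consecutive
# and nonconsecutive) fails the four-gamete test. Within such a region no
# recombinant gamete is observed, so pairwise forced phases chain into
# full-length haplotype strings usable as alleles of one multi-allelic locus.

#' Test whether every SNP pair in a window fails the four-gamete test
#'
#' @param gm a [genotype_matrix()].
#' @param snp_indices at least two SNP column indices on one chromosome.
#' @return list with `ok` (logical), `status` (named list of `corner_status`
#'   keyed `"i:j"` over all pairs), and `offending` (first pair with four
#'   haplotypes, or `NULL`).
#' @export
all_pairs_fail_4gt <- function(gm, snp_indices) {
  stopifnot(inherits(gm, "genotype_matrix"), length(snp_indices) >= 2L)
  idx <- sort(as.integer(snp_indices))
  if (length(unique(gm$map$chrom[idx])) != 1L)
    stop("region SNPs must lie on one chromosome")
  status <- list()
  offending <- NULL
  ok <- TRUE
  for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1L):length(idx)) {
    i <- idx[a]; j <- idx[b]
    st <- detect_corners(build_pair_table(gm, i, j), small_n = 0)
    status[[paste0(i, ":", j)]] <- st
    if (st$n_haplotypes == 4L && is.null(offending)) {
      ok <- FALSE
      offending <- c(i, j)
    }
  }
  list(ok = ok, status = status, offending = offending)
}

#' Scan a genome for maximal regions failing the four-gamete test pairwise
#'
#' Finds, per chromosome, maximal contiguous SNP intervals in which every
#' pair of SNPs has at most three segregating haplotypes. The property is
#' hereditary (any sub-interval of a valid interval is valid), so a
#' two-pointer sweep that, on adding SNP j, checks only the pairs (k, j) for
#' k inside the window is exact. Maximal windows can overlap at boundaries;
#' all are reported, with an `overlaps_previous` flag.
#'
#' @param gm a [genotype_matrix()].
#' @param min_snps minimum SNPs per region (default 2).
#' @return list of `region` objects: each a list with `chrom`,
#'   `snp_indices`, `start_pos`, `end_pos`, `status` (pairwise
#'   `corner_status` as in [all_pairs_fail_4gt()]), `overlaps_previous`.
#' @export
scan_regions <- function(gm, min_snps = 2L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  regions <- list()
  for (chr in unique(gm$map$chrom)) {
    idx <- which(gm$map$chrom == chr)
    m <- length(idx)
    if (m < min_snps) next
    s <- 1L
    prev_end <- -1L
    for (j in 2L:m) {
      # shrink window until all pairs (k, j) fail the 4GT
      repeat {
        bad <- 0L
        if (s < j) for (k in s:(j - 1L)) {
          st <- detect_corners(build_pair_table(gm, idx[k], idx[j]), small_n = 0)
          if (st$n_haplotypes == 4L) bad <- k
        }
        if (bad == 0L) break
        # emit the maximal window ending at j - 1 before moving the left edge
        if (j - s >= min_snps && (j - 1L) > prev_end) {
          regions[[length(regions) + 1L]] <- make_region(gm, idx[s:(j - 1L)])
          prev_end <- j - 1L
        }
        s <- bad + 1L
      }
    }
    if (m - s + 1L >= min_snps && m > prev_end)
      regions[[length(regions) + 1L]] <- make_region(gm, idx[s:m])
  }
  if (length(regions) > 1L) {
    for (r in 2:length(regions)) {
      a <- regions[[r - 1L]]; b <- regions[[r]]
      regions[[r]]$overlaps_previous <- a$chrom == b$chrom &&
        max(a$snp_indices) >= min(b$snp_indices)
    }
  }
  regions
}

make_region <- function(gm, snp_indices) {
  ap <- all_pairs_fail_4gt(gm, snp_indices)
  stopifnot(ap$ok)
  structure(list(chrom = gm$map$chrom[snp_indices[1L]],
                 snp_indices = snp_indices,
                 start_pos = gm$map$pos[snp_indices[1L]],
                 end_pos = gm$map$pos[snp_indices[length(snp_indices)]],
                 status = ap$status, overlaps_previous = FALSE),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat("region: chr", x$chrom, " ", x$start_pos, "-", x$end_pos, " (",
      length(x$snp_indices), " SNPs, all pairs fail the four-gamete test)\n",
      sep = "")
  invisible(x)
}

#' Assemble full-length region haplotypes for every individual
#'
#' For each individual, reads the forced two-SNP phase at every pair of its
#' heterozygous SNPs and chains them into two haplotype strings (one allele
#' character per SNP, in map order); homozygous positions are filled
#' identically on both strings. Phase chaining is a union of pairwise sign
#' constraints with full cycle-consistency checking: a contradiction (only
#' possible under genotyping error) is an error naming the individual and
#' the conflicting SNP triple. Individuals needing an ambiguous pair
#' (adjacent-corner tie) are flagged and excluded from the frequency table
#' rather than guessed.
#'
#' @param gm a [genotype_matrix()] with complete genotypes over the region.
#' @param region a `region` (from [scan_regions()]) or a vector of SNP
#'   indices.
#' @return object of class `region_haplotypes`: list with `region`,
#'   `haplotypes` (`data.frame`: `sample_id`, `hap1`, `hap2`, `ambiguous`),
#'   `allele_freqs` (named frequencies of the haplotype alleles over
#'   non-ambiguous gametes), `pic`, `heterozygosity`, `n_excluded`.
#' @export
assemble_haplotypes <- function(gm, region) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!inherits(region, "region")) region <- make_region(gm, region)
  idx <- region$snp_indices
  k <- length(idx)
  dos <- gm$dosage[, idx, drop = FALSE]
  miss <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(miss) > 0L)
    stop("missing genotype for individual ", rownames(gm$dosage)[miss[1L, 1L]],
         " at SNP ", gm$map$id[idx[miss[1L, 2L]]],
         ": complete data are required for region assembly")
  ref <- gm$map$ref[idx]; alt <- gm$map$alt[idx]
  n_ind <- nrow(dos)
  hap1 <- hap2 <- character(n_ind)
  amb <- logical(n_ind)
  for (r in seq_len(n_ind)) {
    d <- dos[r, ]
    het <- which(d == 1L)
    # x[h] = +1 if strand 1 carries ref at het SNP h
    x <- rep(1L, length(het))
    if (length(het) >= 2L) {
      sgn <- matrix(NA_integer_, length(het), length(het))
      for (a in seq_along(het)[-length(het)]) for (b in (a + 1L):length(het)) {
        key <- paste0(idx[het[a]], ":", idx[het[b]])
        st <- region$status[[key]]
        if (is.null(st)) {
          st <- detect_corners(build_pair_table(gm, idx[het[a]], idx[het[b]]),
                               small_n = 0)
        }
        if (st$ambiguous) amb[r] <- TRUE
        if (st$double_het_phase == "AB/ab") sgn[a, b] <- 1L
        else if (st$double_het_phase == "Ab/aB") sgn[a, b] <- -1L
        else stop("no forced phase for pair ", key,
                  " needed by individual ", rownames(dos)[r])
      }
      x <- c(1L, sgn[1L, 2:length(het)])
      for (a in 2:length(het)) for (b in seq_along(het)) {
        if (b > a && x[a] * x[b] != sgn[a, b])
          stop("inconsistent pairwise phases for individual ",
               rownames(dos)[r], " at SNP triple (",
               paste(gm$map$id[idx[het[c(1L, a, b)]]], collapse = ", "),
               "): likely genotyping error")
      }
    }
    s1 <- s2 <- ifelse(d == 0L, ref, alt)  # homozygous fill (d==2 -> alt)
    s1[het] <- ifelse(x > 0L, ref[het], alt[het])
    s2[het] <- ifelse(x > 0L, alt[het], ref[het])
    hap1[r] <- paste(s1, collapse = "")
    hap2[r] <- paste(s2, collapse = "")
  }
  haps <- data.frame(sample_id = rownames(dos), hap1 = hap1, hap2 = hap2,
                     ambiguous = amb, stringsAsFactors = FALSE)
  keep <- !amb
  af <- if (any(keep)) {
    tab <- table(c(hap1[keep], hap2[keep]))
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  } else stats::setNames(numeric(0), character(0))
  if (sum(amb) > 0L)
    message(sum(amb), " individual(s) excluded from haplotype frequencies ",
            "(ambiguous pairwise phase)")
  structure(list(region = region, haplotypes = haps, allele_freqs = af,
                 pic = if (length(af)) pic(af) else NA_real_,
                 heterozygosity = if (length(af)) heterozygosity(af) else NA_real_,
                 n_excluded = sum(amb)),
            class = "region_haplotypes")
}

#' @export
print.region_haplotypes <- function(x, ...) {
  print(x$region)
  cat("  ", nrow(x$haplotypes), " individuals phased; ",
      length(x$allele_freqs), " haplotype alleles; PIC = ",
      round(x$pic, 3), ", heterozygosity = ", round(x$heterozygosity, 3),
      "\n", sep = "")
  if (x$n_excluded > 0L) cat("  excluded (ambiguous):", x$n_excluded, "\n")
  invisible(x)
}

#' Haplotype-allele frequencies of an assembled region
#'
#' @param rh a `region_haplotypes`.
#' @return named numeric of frequencies over 2N gametes (non-ambiguous
#'   individuals), summing to 1.
#' @export
haplotype_allele_freqs <- function(rh) {
  stopifnot(inherits(rh, "region_haplotypes"))
  rh$allele_freqs
}

#' Expected heterozygosity of a multi-allelic locus
#'
#' 1 - sum of squared allele frequencies.
#'
#' @param freqs numeric allele frequencies summing to 1.
#' @return fraction in `[0, 1]`.
#' @export
heterozygosity <- function(freqs) {
  check_freqs(freqs)
  1 - sum(freqs^2)
}

#' Polymorphism information content (Botstein)
#'
#' PIC = 1 - sum f_i^2 - sum_{i<j} 2 f_i^2 f_j^2; always at most the
#' expected heterozygosity.
#'
#' @inheritParams heterozygosity
#' @return fraction in `[0, 1]`.
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  s2 <- sum(freqs^2)
  1 - s2 - (s2^2 - sum(freqs^4))
}

check_freqs <- function(freqs) {
  if (length(freqs) == 0L) stop("empty frequency table")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-6)
    stop("frequencies must be non-negative and sum to 1")
  invisible(freqs)
}

#' Region summary table
#'
#' One row per region: coordinates, SNP and allele counts, PIC and
#' heterozygosity (assembling haplotypes for each region).
#'
#' @param gm a [genotype_matrix()].
#' @param regions list of `region` objects (default [scan_regions()]).
#' @return `data.frame` with columns `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `n_haplotype_alleles`, `pic`, `heterozygosity`,
#'   `n_excluded`, `overlaps_previous`.
#' @export
region_table <- function(gm, regions = scan_regions(gm)) {
  if (length(regions) == 0L)
    return(data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_snps = integer(0),
                      n_haplotype_alleles = integer(0), pic = numeric(0),
                      heterozygosity = numeric(0), n_excluded = integer(0),
                      overlaps_previous = logical(0)))
  do.call(rbind, lapply(regions, function(rg) {
    rh <- assemble_haplotypes(gm, rg)
    data.frame(chrom = rg$chrom, start_bp = rg$start_pos, end_bp = rg$end_pos,
               n_snps = length(rg$snp_indices),
               n_haplotype_alleles = length(rh$allele_freqs),
               pic = rh$pic, heterozygosity = rh$heterozygosity,
               n_excluded = rh$n_excluded,
               overlaps_previous = rg$overlaps_previous,
               stringsAsFactors = FALSE)
  }))
}

#' Write region haplotypes as a phased VCF
#'
#' Emits the region's SNPs with `|`-separated GT and a PS (phase set) tag
#' anchored at the region start. Ambiguous individuals are written unphased.
#'
#' @param rh a `region_haplotypes`.
#' @param gm the [genotype_matrix()] it was assembled from.
#' @param path output path (vcfR appends `.gz`).
#' @export
write_phased_vcf <- function(rh, gm, path) {
  stopifnot(inherits(rh, "region_haplotypes"))
  idx <- rh$region$snp_indices
  map <- gm$map[idx, , drop = FALSE]
  ps <- as.character(rh$region$start_pos)
  h1 <- do.call(rbind, strsplit(rh$haplotypes$hap1, ""))
  h2 <- do.call(rbind, strsplit(rh$haplotypes$hap2, ""))
  gt <- matrix("", nrow = length(idx), ncol = nrow(h1))
  for (s in seq_along(idx)) {
    a1 <- ifelse(h1[, s] == map$ref[s], "0", "1")
    a2 <- ifelse(h2[, s] == map$ref[s], "0", "1")
    sep <- ifelse(rh$haplotypes$ambiguous, "/", "|")
    gt[s, ] <- paste0(a1, sep, a2, ":", ps)
  }
  fix <- cbind(CHROM = map$chrom, POS = as.character(map$pos), ID = map$id,
               REF = map$ref, ALT = map$alt, QUAL = ".", FILTER = "PASS",
               INFO = ".")
  gt <- cbind(FORMAT = "GT:PS", gt)
  colnames(gt) <- c("FORMAT", rh$haplotypes$sample_id)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
            "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">")
  v <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
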