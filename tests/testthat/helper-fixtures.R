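# Shared fixtures and independent oracles, built in code at test time.

# --- worked-example table: 382 AABB, 17 AABb, 36 AaBb (N = 435) -------------
chr2_counts <- function() {
  n <- matrix(0L, 3L, 3L)
  n[1L, 1L] <- 382L; n[1L, 2L] <- 17L; n[2L, 2L] <- 36L
  n
}

# the same table built through the genotype pipeline (dosage 0 = AA/BB)
chr2_gm <- function() {
  d1 <- c(rep(0L, 382L + 17L), rep(1L, 36L))
  d2 <- c(rep(0L, 382L), rep(1L, 17L + 36L))
  map <- data.frame(id = c("chr2_left", "chr2_right"), chrom = "2",
                    pos = c(39631490L, 39638306L), ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  genotype_matrix(cbind(d1, d2), map)
}

# --- small VCF fixture ------------------------------------------------------
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "0/1", "./.", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}

# --- independent phasing oracle ---------------------------------------------
# Definite gametes come from every genotype but the double heterozygote.
# Enumerate both phases for the double heterozygotes and keep assignments
# that introduce no haplotype outside the definitely observed set. Returns
# the set of valid phases for the double heterozygote ("AB/ab", "Ab/aB").
exhaustive_phase_oracle <- function(counts) {
  cell_haps <- vector("list", 9L); dim(cell_haps) <- c(3L, 3L)
  cell_haps[[1L, 1L]] <- c("AB", "AB"); cell_haps[[1L, 2L]] <- c("AB", "Ab")
  cell_haps[[1L, 3L]] <- c("Ab", "Ab"); cell_haps[[2L, 1L]] <- c("AB", "aB")
  cell_haps[[2L, 3L]] <- c("Ab", "ab"); cell_haps[[3L, 1L]] <- c("aB", "aB")
  cell_haps[[3L, 2L]] <- c("aB", "ab"); cell_haps[[3L, 3L]] <- c("ab", "ab")
  definite <- character(0)
  for (r in 1:3) for (c in 1:3)
    if (!(r == 2 && c == 2) && counts[r, c] > 0L)
      definite <- union(definite, cell_haps[[r, c]])
  valid <- character(0)
  if (all(c("AB", "ab") %in% definite)) valid <- c(valid, "AB/ab")
  if (all(c("Ab", "aB") %in% definite)) valid <- c(valid, "Ab/aB")
  valid
}

# --- brute-force region assembly oracle -------------------------------------
# Enumerates the 2^(h-1) strand assignments over an individual's h het SNPs
# and keeps those whose implied two-SNP haplotype pairs never use a missing
# haplotype of the corresponding pairwise corner status. Returns the list of
# valid unordered string pairs.
region_assembly_oracle <- function(gm, region, sample_row) {
  idx <- region$snp_indices
  d <- gm$dosage[sample_row, idx]
  ref <- gm$map$ref[idx]; alt <- gm$map$alt[idx]
  het <- which(d == 1L)
  h <- length(het)
  base1 <- base2 <- ifelse(d == 0L, ref, alt)
  if (h == 0L) return(list(sort(c(paste(base1, collapse = ""),
                                  paste(base2, collapse = "")))))
  valid <- list()
  for (mask in 0:(2^(h - 1) - 1)) {
    # first het SNP fixed ref-on-strand-1 to factor out the strand swap
    x <- c(1L, ifelse(bitwAnd(mask, 2^(seq_len(h - 1) - 1)) > 0L, -1L, 1L))
    ok <- TRUE
    if (h >= 2L) for (a in 1:(h - 1)) for (b in (a + 1):h) {
      st <- region$status[[paste0(idx[het[a]], ":", idx[het[b]])]]
      # haplotype on strand 1 for this pair in abstract coding
      ha <- paste0(if (x[a] > 0) "A" else "a", if (x[b] > 0) "B" else "b")
      hb <- chartr("AaBb", "aAbB", ha)
      if (ha %in% st$missing_haplotypes || hb %in% st$missing_haplotypes) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    s1 <- base1; s2 <- base2
    s1[het] <- ifelse(x > 0L, ref[het], alt[het])
    s2[het] <- ifelse(x > 0L, alt[het], ref[het])
    valid[[length(valid) + 1L]] <- sort(c(paste(s1, collapse = ""),
                                          paste(s2, collapse = "")))
  }
  unique(valid)
}

# --- GWAS helpers -----------------------------------------------------------
# genotype matrix of m independent SNPs for building a dense GRM
random_snp_gm <- function(n, m, seed, maf_range = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  dos <- vapply(p, function(pp) rbinom(n, 2L, pp), integer(n))
  map <- data.frame(id = paste0("m", seq_len(m)), chrom = "1",
                    pos = 1000L * seq_len(m), ref = "A", alt = "G",
                    stringsAsFactors = FALSE)
  genotype_matrix(dos, map)
}

# full REML refit with the dosage in the fixed effects (oracle for the
# fixed-variance-component approximation)
full_reml_test <- function(dosage, pheno, grm, fixed = NULL) {
  ph <- pheno
  ph$.dose <- if (!is.null(names(dosage))) dosage[ph$sample_id] else dosage
  # refit variance components with dosage as a covariate, then Wald test
  ids <- ph$sample_id
  G <- grm[ids, ids]
  y <- ph$y
  W0 <- if (is.null(fixed)) matrix(1, length(y), 1L)
        else stats::model.matrix(stats::reformulate(fixed),
                                 as.data.frame(lapply(ph[fixed], factor)))
  W <- cbind(W0, dose = ph$.dose)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0) + 1e-6
  ys <- drop(crossprod(eg$vectors, y)); Ws <- crossprod(eg$vectors, W)
  n <- length(y); p <- ncol(W)
  reml <- function(logd) {
    d <- exp(logd); w <- 1 / (lam + d)
    WtW <- crossprod(Ws * w, Ws)
    b <- solve(WtW, crossprod(Ws * w, ys))
    rss <- sum(w * (ys - Ws %*% b)^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(lam + d)) +
            determinant(WtW, logarithm = TRUE)$modulus + (n - p))
  }
  opt <- stats::optimize(reml, c(-12, 12), maximum = TRUE, tol = 1e-8)
  d <- exp(opt$maximum); w <- 1 / (lam + d)
  WtW <- crossprod(Ws * w, Ws)
  b <- solve(WtW, crossprod(Ws * w, ys))
  s2 <- sum(w * (ys - Ws %*% b)^2) / (n - p)
  se <- sqrt(s2 * solve(WtW)[p, p])
  z <- b[p] / se
  list(effect = unname(b[p]), se = unname(se),
       p = 2 * stats::pnorm(-abs(z)))
}
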