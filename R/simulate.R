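# Seeded generators for two-locus and multi-SNP region genotypes and for
# phenotypes with a polygenic background. Individuals are random unions of
# two gametes drawn independently from the haplotype pool, i.e.
# Hardy-Weinberg equilibrium at the haplotype level - the assumption under
# which the EM baseline is the natural comparator. The simulation truth is
# always returned alongside the observed data so oracle tests never have to
# re-derive it.

default_pair_map <- function() {
  data.frame(id = c("snp1", "snp2"), chrom = "1", pos = c(1000L, 2000L),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Build a genotype matrix from known haplotype strings
#'
#' Turns per-individual pairs of haplotype strings (one allele character per
#' SNP) into unphased dosages against a marker map. Useful for constructing
#' cohorts with known truth.
#'
#' @param hap1,hap2 character vectors of equal-length haplotype strings.
#' @param map marker map (`id`, `chrom`, `pos`, `ref`, `alt`), one row per
#'   string position.
#' @param sample_ids optional individual labels.
#' @return a [genotype_matrix()].
#' @export
genotypes_from_haplotypes <- function(hap1, hap2, map, sample_ids = NULL) {
  stopifnot(length(hap1) == length(hap2))
  m1 <- do.call(rbind, strsplit(hap1, ""))
  m2 <- do.call(rbind, strsplit(hap2, ""))
  if (ncol(m1) != nrow(map)) stop("haplotype length does not match map")
  for (s in seq_len(ncol(m1))) {
    ok <- c(map$ref[s], map$alt[s])
    if (!all(c(m1[, s], m2[, s]) %in% ok))
      stop("allele not in {ref, alt} at SNP ", map$id[s])
  }
  dos <- matrix(0L, nrow(m1), ncol(m1))
  for (s in seq_len(ncol(m1)))
    dos[, s] <- (m1[, s] == map$alt[s]) + (m2[, s] == map$alt[s])
  genotype_matrix(dos, map, sample_ids = sample_ids)
}

#' Simulate two-SNP genotypes from haplotype frequencies
#'
#' Each individual is the union of two gametes drawn independently from the
#' given haplotype frequencies; genotypes are returned unphased, with the
#' true phases kept separately.
#'
#' @param freqs named numeric over AB/Ab/aB/ab summing to 1 (or a
#'   `haplotype_freqs`).
#' @param n number of individuals (> 0).
#' @param seed RNG seed (required: generators are seed-deterministic).
#' @param map optional 2-row marker map.
#' @return list with `gm` (a [genotype_matrix()]) and `truth`
#'   (`data.frame`: `sample_id`, `hap1`, `hap2` in abstract AB-coding).
#' @export
simulate_pair_genotypes <- function(freqs, n, seed, map = default_pair_map()) {
  if (inherits(freqs, "haplotype_freqs")) freqs <- freqs$f
  f <- freqs[HAPLOTYPES]
  if (anyNA(f) || abs(sum(f) - 1) > 1e-9)
    stop("`freqs` must cover AB, Ab, aB, ab and sum to 1")
  if (n <= 0) stop("`n` must be positive")
  set.seed(seed)
  g1 <- sample(HAPLOTYPES, n, replace = TRUE, prob = f)
  g2 <- sample(HAPLOTYPES, n, replace = TRUE, prob = f)
  # abstract A/B = ref at either SNP; translate to concrete allele strings
  s1 <- paste0(ifelse(substr(g1, 1, 1) == "A", map$ref[1], map$alt[1]),
               ifelse(substr(g1, 2, 2) == "B", map$ref[2], map$alt[2]))
  s2 <- paste0(ifelse(substr(g2, 1, 1) == "A", map$ref[1], map$alt[1]),
               ifelse(substr(g2, 2, 2) == "B", map$ref[2], map$alt[2]))
  gm <- genotypes_from_haplotypes(s1, s2, map)
  list(gm = gm,
       truth = data.frame(sample_id = rownames(gm$dosage), hap1 = g1,
                          hap2 = g2, stringsAsFactors = FALSE))
}

#' Simulate a multi-SNP region from a haplotype pool
#'
#' @param pool character vector of equal-length haplotype strings.
#' @param freqs pool frequencies summing to 1.
#' @param n number of individuals.
#' @param seed RNG seed.
#' @param map optional marker map (defaults to SNPs at 1 kb spacing with
#'   ref/alt taken from the pool's alleles per site).
#' @return list with `gm` and `truth` (`sample_id`, `hap1`, `hap2` as
#'   concrete strings). A warning is issued if the pool itself induces all
#'   four gametes for some SNP pair (the region cannot then pass
#'   [all_pairs_fail_4gt()]).
#' @export
simulate_region <- function(pool, freqs, n, seed, map = NULL) {
  stopifnot(length(pool) == length(freqs))
  if (abs(sum(freqs) - 1) > 1e-9) stop("pool frequencies must sum to 1")
  L <- unique(nchar(pool))
  if (length(L) != 1L) stop("pool strings must have equal length")
  pm <- do.call(rbind, strsplit(pool, ""))
  for (a in seq_len(L - 1L)) for (b in (a + 1L):L) {
    if (length(unique(paste0(pm[, a], pm[, b]))) >= 4L) {
      warning("pool induces four gametes for SNP pair (", a, ", ", b,
              "): region will not pass all_pairs_fail_4gt")
      break
    }
  }
  if (is.null(map)) {
    alle <- lapply(seq_len(L), function(s) sort(unique(pm[, s])))
    map <- data.frame(id = paste0("snp", seq_len(L)), chrom = "1",
                      pos = 1000L * seq_len(L),
                      ref = vapply(alle, `[`, character(1), 1L),
                      alt = vapply(alle, function(x)
                        if (length(x) > 1L) x[2L] else setdiff(c("A", "C", "G", "T"), x)[1L],
                        character(1)),
                      stringsAsFactors = FALSE)
  }
  set.seed(seed)
  h1 <- sample(pool, n, replace = TRUE, prob = freqs)
  h2 <- sample(pool, n, replace = TRUE, prob = freqs)
  gm <- genotypes_from_haplotypes(h1, h2, map)
  list(gm = gm,
       truth = data.frame(sample_id = rownames(gm$dosage), hap1 = h1,
                          hap2 = h2, stringsAsFactors = FALSE))
}

#' Simulate phenotypes with a causal dosage and polygenic background
#'
#' y = W b + g x + a + e with a ~ N(0, G sigma2_a), e ~ N(0, I sigma2_e).
#' All generated components are returned for recovery tests.
#'
#' @param gm a [genotype_matrix()] (used for the GRM unless one is given).
#' @param dosage causal covariate (0/1/2 per individual), or `NULL` for a
#'   pure null trait.
#' @param effect substitution effect g in trait units per copy (default 0).
#' @param sigma2_a,sigma2_e additive and residual variances (defaults 1, 1).
#' @param factors named list of factor-level vectors per individual (e.g.
#'   parity classes); each named element adds an effect drawn from
#'   `factor_sd` times standard normals per level.
#' @param factor_sd standard deviation of the simulated factor-level
#'   effects (default 0.5).
#' @param grm optional precomputed GRM.
#' @param seed RNG seed.
#' @return `data.frame` (`sample_id`, `y`, factor columns) with attribute
#'   `truth` (list of the generated components).
#' @export
simulate_phenotypes <- function(gm, dosage = NULL, effect = 0, sigma2_a = 1,
                                sigma2_e = 1, factors = NULL, factor_sd = 0.5,
                                grm = NULL, seed = 1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$dosage)
  if (is.null(grm)) grm <- vanraden_grm(gm)
  set.seed(seed)
  a <- if (sigma2_a > 0) {
    eg <- eigen(grm, symmetric = TRUE)
    drop(eg$vectors %*% (sqrt(pmax(eg$values, 0) * sigma2_a) * stats::rnorm(n)))
  } else rep(0, n)
  e <- stats::rnorm(n, sd = sqrt(sigma2_e))
  y <- a + e
  truth <- list(a = a, e = e, effect = effect, sigma2_a = sigma2_a,
                sigma2_e = sigma2_e)
  out <- data.frame(sample_id = rownames(gm$dosage), stringsAsFactors = FALSE)
  if (!is.null(factors)) {
    fx <- list()
    for (nm in names(factors)) {
      lev <- factors[[nm]]
      eff <- stats::setNames(stats::rnorm(length(unique(lev)), sd = factor_sd),
                             unique(lev))
      y <- y + eff[as.character(lev)]
      out[[nm]] <- lev
      fx[[nm]] <- eff
    }
    truth$factor_effects <- fx
  }
  if (!is.null(dosage)) {
    x <- if (!is.null(names(dosage))) dosage[out$sample_id] else dosage
    y <- y + effect * x
    truth$dosage <- x
  }
  out$y <- unname(y)
  attr(out, "truth") <- truth
  out
}

#' Inject random genotyping errors
#'
#' Each genotype is flipped to a uniformly chosen different value in
#' {0, 1, 2} with probability `rate`.
#'
#' @param gm a [genotype_matrix()].
#' @param rate error probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return a [genotype_matrix()] with errors applied (missing stays missing).
#' @export
add_genotyping_errors <- function(gm, rate, seed) {
  stopifnot(inherits(gm, "genotype_matrix"), rate >= 0, rate < 1)
  if (rate == 0) return(gm)
  set.seed(seed)
  dos <- gm$dosage
  flip <- !is.na(dos) & matrix(stats::runif(length(dos)) < rate, nrow(dos))
  if (any(flip)) {
    cur <- dos[flip]
    dos[flip] <- vapply(cur, function(v) sample(setdiff(0:2, v), 1L), integer(1))
  }
  genotype_matrix(dos, gm$map)
}

#' The published nine-SNP SSC1 example region
#'
#' Haplotype pool (six strings over nine SNPs) with its estimated
#' frequencies, and the marker map, for the worked chromosomal-region
#' example; stored as plain-text under `inst/extdata`.
#'
#' @return list with `pool` (`data.frame`: `haplotype`, `frequency`) and
#'   `map`.
#' @export
ssc1_example <- function() {
  pool <- utils::read.table(system.file("extdata", "ssc1_region_haplotypes.tsv",
                                        package = "fourgamete"),
                            header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  map <- utils::read.table(system.file("extdata", "ssc1_region_map.tsv",
                                       package = "fourgamete"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  list(pool = pool, map = map)
}
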