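#' Genotype matrix of alt-allele dosages
#'
#' Container for diploid biallelic SNP genotypes coded as the number of copies
#' of the alternate allele (0, 1, 2; `NA` = missing). Rows are individuals,
#' columns are SNPs. A map `data.frame` carries marker metadata. Throughout
#' the package the abstract alleles A/a (left SNP) and B/b (right SNP) are
#' identified with ref/alt in file order, so haplotype "AB" means
#' ref-ref.
#'
#' @param dosage integer matrix, individuals x SNPs, values in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names marker ids
#'   (supplied via `sample_ids` / `map$id` if absent).
#' @param map `data.frame` with columns `id`, `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`; one row per SNP, in column order of `dosage`. SNPs must be
#'   sorted by position within each chromosome.
#' @param sample_ids optional character vector of individual labels.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (integer matrix) and `map`.
#' @export
genotype_matrix <- function(dosage, map, sample_ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!is.data.frame(map)) stop("`map` must be a data.frame")
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map)))
    stop("`map` must have columns ", paste(need, collapse = ", "))
  map <- as.data.frame(map)[, need]
  map$id <- as.character(map$id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  map$ref <- as.character(map$ref)
  map$alt <- as.character(map$alt)
  if (nrow(map) != ncol(dosage))
    stop("map has ", nrow(map), " rows but dosage has ", ncol(dosage), " columns")
  if (any(map$pos < 1L)) stop("positions must be >= 1")
  if (any(map$ref == map$alt)) stop("ref and alt allele must differ")
  if (anyDuplicated(paste(map$chrom, map$pos)))
    stop("duplicated (chrom, pos) in map")
  if (is.unsorted_within(map$chrom, map$pos))
    stop("SNPs must be sorted by position within chromosome")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (!is.null(sample_ids)) rownames(dosage) <- as.character(sample_ids)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("ind", seq_len(nrow(dosage)))
  if (anyDuplicated(rownames(dosage))) stop("sample ids must be unique")
  colnames(dosage) <- map$id
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

# sortedness of pos within runs of chrom
is.unsorted_within <- function(chrom, pos) {
  any(vapply(split(pos, factor(chrom, levels = unique(chrom))),
             is.unsorted, logical(1)))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  nmiss <- sum(is.na(x$dosage))
  if (nmiss > 0) cat("  missing genotypes:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read biallelic SNP genotypes from a VCF file
#'
#' Decodes unphased GT fields into alt-allele dosages. Multi-allelic or
#' non-SNP records are skipped (with a message) or rejected.
#'
#' @param path path to a VCF 4.x file.
#' @param skip_nonbiallelic if `TRUE` (default) silently drop multi-allelic
#'   and non-SNP records; if `FALSE`, error when any is present.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, skip_nonbiallelic = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)
  ok <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  ok[is.na(ok)] <- FALSE
  if (!all(ok)) {
    if (!skip_nonbiallelic)
      stop(sum(!ok), " non-biallelic/non-SNP record(s) in ", path)
    message("skipping ", sum(!ok), " non-biallelic/non-SNP record(s)")
  }
  if (!any(ok)) stop("no biallelic SNP records in VCF: ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[ok, , drop = FALSE]
  fix <- fix[ok, , drop = FALSE]
  dos <- apply(gt, 2, gt_to_dosage)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L, dimnames = list(NULL, colnames(gt)))
  id <- fix$ID
  id[is.na(id) | id == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(id) | id == "."]
  map <- data.frame(id = id, chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(t(dos), map, sample_ids = colnames(gt))
}

gt_to_dosage <- function(g) {
  al <- strsplit(sub(":.*$", "", g), "[/|]")
  vapply(al, function(a) {
    if (length(a) != 2L || any(a == ".") || any(is.na(a))) return(NA_integer_)
    a <- suppressWarnings(as.integer(a))
    if (any(is.na(a)) || any(a > 1L)) return(NA_integer_)
    sum(a)
  }, integer(1))
}

#' Read a genotype dosage matrix from TSV with a sidecar map file
#'
#' The matrix file has a header row of SNP ids and one row per individual
#' (first column = sample id); cells are 0/1/2/NA. The map file is a TSV with
#' columns `id`, `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path genotype TSV path.
#' @param map_path marker map TSV path.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, map_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  dos <- as.matrix(tab[, -1L, drop = FALSE])
  ok <- matrix(dos %in% c("0", "1", "2", NA, "NA"), nrow(dos))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("invalid genotype value '", dos[bad[1L, , drop = FALSE]],
         "' at row ", bad[1L, 1L], " (", ids[bad[1L, 1L]], "), column ",
         colnames(dos)[bad[1L, 2L]])
  storage.mode(dos) <- "integer"
  map <- map[match(colnames(dos), map$id), , drop = FALSE]
  if (anyNA(map$id)) stop("map file is missing some SNPs present in the matrix")
  genotype_matrix(dos, map, sample_ids = ids)
}

#' Write a genotype matrix (and its map) as TSV
#'
#' Inverse of [read_genotype_tsv()]; the round trip is lossless.
#'
#' @param gm a [genotype_matrix()].
#' @param path genotype TSV path to write.
#' @param map_path map TSV path to write.
#' @export
write_genotype_tsv <- function(gm, path, map_path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- data.frame(sample_id = rownames(gm$dosage), gm$dosage,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minor-allele-frequency and completeness filters
#'
#' Removes SNPs with minor-allele frequency below `maf_min` (computed on
#' non-missing genotypes) and, optionally, SNPs with any missing genotype.
#' Missing data is fatal to exact phasing of the affected individual, so
#' region-scale analyses conventionally require complete SNPs; per-pair
#' analyses can instead use complete cases pair by pair.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minimum minor-allele frequency in `[0, 0.5)`; default 0.05.
#' @param require_complete drop SNPs with any missing genotype (default
#'   `FALSE`).
#' @return the filtered [genotype_matrix()], SNP order preserved.
#' @export
apply_qc <- function(gm, maf_min = 0.05, require_complete = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (maf_min < 0 || maf_min >= 0.5) stop("`maf_min` must be in [0, 0.5)")
  p <- colMeans(gm$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_min
  if (require_complete) keep <- keep & colSums(is.na(gm$dosage)) == 0L
  if (!any(keep)) stop("all SNPs removed by QC filters")
  genotype_matrix(gm$dosage[, keep, drop = FALSE], gm$map[keep, , drop = FALSE])
}

#' Write a result table as TSV
#'
#' Stable column order (as given), fixed float precision.
#'
#' @param records non-empty `data.frame`.
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6).
#' @export
write_results <- function(records, path, digits = 6) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame")
  out <- records
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], signif, digits = digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
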