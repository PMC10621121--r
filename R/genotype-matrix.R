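#' Phased genotype container
#'
#' Holds phased biallelic haplotypes together with their variant metadata.
#' Rows of `haplotypes` are haplotypes (two consecutive rows per sample when
#' phased), columns are variants; an entry of 1 denotes the alternate allele,
#' 0 the reference allele, and `NA` a missing call.
#'
#' @param variant_ids Character vector of SNP identifiers.
#' @param chrom Chromosome label per variant.
#' @param pos 1-based physical position per variant; strictly increasing
#'   within each chromosome.
#' @param ref_allele,alt_allele Single-character alleles per variant.
#' @param haplotypes Integer matrix, `2 * n_samples` rows by `n_variants`
#'   columns, entries in `{0, 1, NA}`.
#' @param sample_ids Character vector of sample identifiers.
#' @param ancestral_allele Optional single-character ancestral allele per
#'   variant (`NA` where unknown).
#' @param phased Logical flag; haplotype-based statistics require `TRUE`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variant_ids, chrom, pos, ref_allele, alt_allele,
                            haplotypes, sample_ids,
                            ancestral_allele = NULL, phased = TRUE) {
  m <- length(variant_ids)
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (is.null(ancestral_allele)) ancestral_allele <- rep(NA_character_, m)
  gm <- structure(list(
    variant_ids = as.character(variant_ids),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    ancestral_allele = as.character(ancestral_allele),
    haplotypes = haplotypes,
    sample_ids = as.character(sample_ids),
    phased = isTRUE(phased)
  ), class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype_matrix
#'
#' Checks every structural invariant of the container: positions strictly
#' increasing within chromosome, binary haplotype entries, single-character
#' biallelic alleles, and row count equal to twice the sample count when
#' phased.
#'
#' @param gm A `genotype_matrix`.
#' @return `gm`, invisibly; stops on the first violated invariant.
#' @export
validate_genotype_matrix <- function(gm) {
  m <- length(gm$variant_ids)
  lens <- c(length(gm$chrom), length(gm$pos), length(gm$ref_allele),
            length(gm$alt_allele), length(gm$ancestral_allele),
            ncol(gm$haplotypes))
  if (any(lens != m)) stop("variant metadata lengths disagree")
  if (gm$phased && nrow(gm$haplotypes) != 2L * length(gm$sample_ids))
    stop("phased matrix must have 2 x n_samples haplotype rows")
  vals <- gm$haplotypes[!is.na(gm$haplotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("haplotype entries must be 0, 1 or NA")
  if (any(nchar(gm$ref_allele) != 1L) || any(nchar(gm$alt_allele) != 1L))
    stop("alleles must be single characters (biallelic SNPs only)")
  if (m > 1L) {
    for (chr in unique(gm$chrom)) {
      p <- gm$pos[gm$chrom == chr]
      if (any(diff(p) <= 0L))
        stop("positions must be strictly increasing within chromosome ", chr)
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples (%s)\n",
              length(x$variant_ids), length(x$sample_ids),
              if (x$phased) "phased" else "unphased"))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$chrom), collapse = ", ")))
  n_aa <- sum(!is.na(x$ancestral_allele))
  cat(sprintf("  ancestral allele annotated: %d/%d\n", n_aa,
              length(x$variant_ids)))
  invisible(x)
}

#' Number of variants / samples
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_variants <- function(gm) length(gm$variant_ids)

#' @rdname n_variants
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' Subset a genotype matrix by variant and/or sample
#'
#' @param gm A `genotype_matrix`.
#' @param variants Logical, integer, or character (id) selector of variants.
#' @param samples Optional character vector of sample ids to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, variants = NULL, samples = NULL) {
  vi <- seq_along(gm$variant_ids)
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, gm$variant_ids)
          else vi[variants]
    if (anyNA(vi)) stop("unknown variant ids in subset")
  }
  rows <- seq_len(nrow(gm$haplotypes))
  sample_ids <- gm$sample_ids
  if (!is.null(samples)) {
    si <- match(samples, gm$sample_ids)
    if (anyNA(si)) stop("unknown sample ids: ",
                        paste(samples[is.na(si)], collapse = ", "))
    rows <- as.vector(rbind(2L * si - 1L, 2L * si))
    sample_ids <- gm$sample_ids[si]
  }
  genotype_matrix(gm$variant_ids[vi], gm$chrom[vi], gm$pos[vi],
                  gm$ref_allele[vi], gm$alt_allele[vi],
                  gm$haplotypes[rows, vi, drop = FALSE], sample_ids,
                  ancestral_allele = gm$ancestral_allele[vi],
                  phased = gm$phased)
}

# Rows of the haplotype matrix belonging to the given samples.
hap_rows_for_samples <- function(gm, sample_ids) {
  si <- match(sample_ids, gm$sample_ids)
  if (anyNA(si)) stop("samples absent from genotype matrix: ",
                      paste(sample_ids[is.na(si)], collapse = ", "))
  as.vector(rbind(2L * si - 1L, 2L * si))
}

# Per-sample diploid genotype dosage matrix (n_samples x m, NA if either
# haplotype is missing).
genotype_dosage <- function(gm, sample_ids = NULL) {
  sample_ids <- sample_ids %||% gm$sample_ids
  rows <- hap_rows_for_samples(gm, sample_ids)
  h <- gm$haplotypes[rows, , drop = FALSE]
  odd <- seq(1L, nrow(h), by = 2L)
  g <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  rownames(g) <- sample_ids
  g
}
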