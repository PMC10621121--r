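#' Per-SNP allele frequency within a population
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [population_panel()].
#' @param pop Population code.
#' @param allele `"alt"` (default), `"ref"`, or a character vector of
#'   per-variant allele letters (e.g. GWAS effect alleles), each of which
#'   must match the variant's ref or alt allele.
#' @return Named numeric vector of frequencies (NA where every call is
#'   missing); requested-allele counts divided by non-missing haplotype
#'   counts.
#' @export
allele_frequency <- function(gm, panel, pop, allele = "alt") {
  rows <- hap_rows_for_samples(gm, panel_samples(panel, pop))
  h <- gm$haplotypes[rows, , drop = FALSE]
  n_obs <- colSums(!is.na(h))
  alt_count <- colSums(h, na.rm = TRUE)
  if (identical(allele, "alt")) {
    count <- alt_count
  } else if (identical(allele, "ref")) {
    count <- n_obs - alt_count
  } else {
    allele <- toupper(rep_len(as.character(allele), n_variants(gm)))
    is_alt <- allele == gm$alt_allele
    is_ref <- allele == gm$ref_allele
    bad <- which(!is_alt & !is_ref)
    if (length(bad))
      stop("allele matches neither ref nor alt at SNP(s): ",
           paste(utils::head(gm$variant_ids[bad], 10L), collapse = ", "))
    count <- ifelse(is_alt, alt_count, n_obs - alt_count)
  }
  out <- ifelse(n_obs > 0L, count / n_obs, NA_real_)
  names(out) <- gm$variant_ids
  out
}

#' Per-SNP Weir-Cockerham Fst between two populations
#'
#' The Weir & Cockerham (1984) two-population variance-component estimator,
#' computed per SNP from diploid genotype counts; observed heterozygosity
#' enters the within-individual component `c`. Samples with a missing call
#' at a SNP are excluded at that SNP only (pairwise-complete counts).
#' Estimates may be negative; SNPs monomorphic in both populations (or with
#' fewer than two usable samples in either population) yield `NA` and are
#' counted in a message.
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [population_panel()].
#' @param popA,popB Population codes.
#' @return A data.frame of class `fst_result` with columns `variant_id`,
#'   `theta`, `a`, `b`, `c` (among-population, among-individual and
#'   within-individual variance components; `theta = a / (a + b + c)`).
#' @export
fst_wc <- function(gm, panel, popA, popB) {
  g1 <- genotype_dosage(gm, panel_samples(panel, popA))
  g2 <- genotype_dosage(gm, panel_samples(panel, popB))
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(g2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2

  usable <- n1 >= 2L & n2 >= 2L
  poly <- pbar > 0 & pbar < 1
  denom <- a + b + cc
  theta <- ifelse(usable & poly & denom != 0, a / denom, NA_real_)
  a[!usable] <- b[!usable] <- cc[!usable] <- NA_real_
  theta[!usable | !poly] <- NA_real_
  n_bad <- sum(!usable)
  if (n_bad > 0L)
    message("fst_wc: ", n_bad,
            " SNP(s) with < 2 usable samples in a population set to NA")
  structure(data.frame(variant_id = gm$variant_ids, theta = theta,
                       a = a, b = b, c = cc, stringsAsFactors = FALSE),
            class = c("fst_result", "data.frame"),
            pops = c(popA, popB))
}

#' Population branch statistic from three pairwise Fst results
#'
#' For triplet (A, B, C) with A the focal population, each pairwise Fst is
#' clamped to `[0, 1 - 1e-6]` and log-transformed to a branch length
#' `T = -ln(1 - Fst)`; then `PBS = (T_AB + T_AC - T_BC) / 2`. Negative Fst
#' estimates are clamped to zero only here — the `fst_result` keeps the raw
#' signed values — and Fst of 1 is clamped just below 1 so branch lengths
#' stay finite.
#'
#' @param fst_ab,fst_ac,fst_bc `fst_result` data.frames for pairs (A,B),
#'   (A,C) and (B,C); all three must cover the same variants.
#' @param triplet Optional character vector of the three population codes
#'   (A, B, C), recorded in the result.
#' @return A data.frame of class `pbs_result` with columns `variant_id`,
#'   `pbs`, `t_ab`, `t_ac`, `t_bc` (NA where any input Fst is NA).
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc, triplet = NULL) {
  ids <- fst_ab$variant_id
  for (other in list(fst_ac, fst_bc)) {
    if (!identical(sort(ids), sort(other$variant_id))) {
      diff <- c(setdiff(ids, other$variant_id),
                setdiff(other$variant_id, ids))
      stop("variant sets misaligned across Fst inputs; symmetric ",
           "difference: ", paste(utils::head(diff, 10L), collapse = ", "))
    }
  }
  branch <- function(fst) {
    t <- -log(1 - pmin(pmax(fst, 0), 1 - 1e-6))
    t
  }
  t_ab <- branch(fst_ab$theta)
  t_ac <- branch(fst_ac$theta[match(ids, fst_ac$variant_id)])
  t_bc <- branch(fst_bc$theta[match(ids, fst_bc$variant_id)])
  structure(data.frame(variant_id = ids,
                       pbs = (t_ab + t_ac - t_bc) / 2,
                       t_ab = t_ab, t_ac = t_ac, t_bc = t_bc,
                       stringsAsFactors = FALSE),
            class = c("pbs_result", "data.frame"),
            triplet = triplet)
}

# Mean pairwise identity-tract length (in sites, including the focal site)
# within one haplotype class. haps: 0/1 matrix rows = class members.
mean_tract_length <- function(haps, focal, max_extend) {
  k <- nrow(haps); m <- ncol(haps)
  if (k < 2L) return(NA_real_)
  pr <- utils::combn(k, 2L)
  i1 <- pr[1L, ]; i2 <- pr[2L, ]
  ext <- function(dir) {
    total <- numeric(length(i1))
    alive <- rep(TRUE, length(i1))
    steps <- if (dir > 0) seq(focal + 1L, min(m, focal + max_extend))
             else seq(focal - 1L, max(1L, focal - max_extend))
    if (focal + dir < 1L || focal + dir > m) return(total)
    for (s in steps) {
      cs <- haps[, s]
      alive <- alive & (cs[i1] == cs[i2])
      if (!any(alive)) break
      total <- total + alive
    }
    total
  }
  1 + mean(ext(+1L)) + mean(ext(-1L))
}

#' Raw nSL at a focal site of a haplotype matrix
#'
#' Haplotypes are split by their allele at the focal site into the
#' ancestral-allele and derived-allele carrier classes. Within each class,
#' the identity tract of a haplotype pair is the number of consecutive sites
#' (counted in segregating sites, focal site included) over which the two
#' haplotypes are identical, truncated at the data edge or after
#' `max_extend` sites on either side. `SL_A` and `SL_D` are the mean
#' pairwise tract lengths of the two classes and `raw nSL = ln(SL_A /
#' SL_D)`: negative values indicate extended haplotype homozygosity around
#' the derived allele, the classic footprint of a recent sweep.
#'
#' @param haps 0/1 haplotype matrix (rows haplotypes, columns sites), with
#'   no missing entries.
#' @param focal Focal site (column) index.
#' @param derived_allele Value (0 or 1) that encodes the derived allele at
#'   the focal column.
#' @param maf_min Minimum derived-allele frequency (both tails).
#' @param max_extend Maximum number of sites scanned on each side of the
#'   focal site.
#' @return A list with `raw`, `sl_a`, `sl_d`, `daf`, `n_anc`, `n_der`, and
#'   `skipped` (NULL, or a string naming why the site was skipped).
#' @export
nsl_raw <- function(haps, focal, derived_allele = 1L, maf_min = 0.05,
                    max_extend = 100L) {
  stopifnot(is.matrix(haps), focal >= 1L, focal <= ncol(haps))
  if (anyNA(haps)) stop("haplotype matrix must be complete for nSL")
  der <- haps[, focal] == derived_allele
  daf <- mean(der)
  out <- list(raw = NA_real_, sl_a = NA_real_, sl_d = NA_real_, daf = daf,
              n_anc = sum(!der), n_der = sum(der), skipped = NULL)
  if (daf < maf_min || daf > 1 - maf_min) {
    out$skipped <- "derived-allele frequency outside [maf_min, 1 - maf_min]"
    return(out)
  }
  if (sum(der) < 2L || sum(!der) < 2L) {
    out$skipped <- "carrier class with fewer than 2 haplotypes"
    return(out)
  }
  out$sl_a <- mean_tract_length(haps[!der, , drop = FALSE], focal, max_extend)
  out$sl_d <- mean_tract_length(haps[der, , drop = FALSE], focal, max_extend)
  out$raw <- log(out$sl_a / out$sl_d)
  out
}

#' nSL scan over the variants of a genotype matrix
#'
#' Recodes each focal variant to ancestral/derived using the `AA`
#' annotation, restricts to one population's haplotypes, drops variants
#' carrying any missing call, and computes [nsl_raw()] at every eligible
#' focal variant. Variants whose ancestral allele is missing or matches
#' neither allele are skipped and counted.
#'
#' @param gm A phased [genotype_matrix()] with ancestral-allele annotation.
#' @param panel Optional [population_panel()]; with `pop`, restricts to that
#'   population's haplotypes.
#' @param pop Optional population code.
#' @param maf_min,max_extend See [nsl_raw()].
#' @return A data.frame of class `nsl_result` with columns `variant_id`,
#'   `chrom`, `pos`, `daf`, `sl_a`, `sl_d`, `raw`, `zscore` (NA until
#'   [nsl_normalize()]), `bin_id`, and `skipped`.
#' @export
nsl_scan <- function(gm, panel = NULL, pop = NULL, maf_min = 0.05,
                     max_extend = 100L) {
  if (!gm$phased) stop("nSL requires phased haplotypes")
  if (!is.null(pop)) gm <- subset_genotypes(gm, samples = panel_samples(panel, pop))
  complete <- colSums(is.na(gm$haplotypes)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message("nsl_scan: dropped ", n_dropped,
            " variant(s) with missing calls")
    gm <- subset_genotypes(gm, variants = complete)
  }
  m <- n_variants(gm)
  aa <- gm$ancestral_allele
  derived_is_alt <- ifelse(is.na(aa), NA,
                           ifelse(aa == gm$ref_allele, TRUE,
                                  ifelse(aa == gm$alt_allele, FALSE, NA)))
  n_bad_aa <- sum(is.na(derived_is_alt))
  if (n_bad_aa > 0L)
    message("nsl_scan: skipped ", n_bad_aa,
            " variant(s) with missing or mismatching ancestral allele")
  res <- data.frame(variant_id = gm$variant_ids, chrom = gm$chrom,
                    pos = gm$pos, daf = NA_real_, sl_a = NA_real_,
                    sl_d = NA_real_, raw = NA_real_, zscore = NA_real_,
                    bin_id = NA_integer_, skipped = NA_character_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    if (is.na(derived_is_alt[j])) {
      res$skipped[j] <- "ancestral allele missing or mismatching"
      next
    }
    r <- nsl_raw(gm$haplotypes, j,
                 derived_allele = if (derived_is_alt[j]) 1L else 0L,
                 maf_min = maf_min, max_extend = max_extend)
    res$daf[j] <- r$daf; res$sl_a[j] <- r$sl_a; res$sl_d[j] <- r$sl_d
    res$raw[j] <- r$raw
    if (!is.null(r$skipped)) res$skipped[j] <- r$skipped
  }
  structure(res, class = c("nsl_result", "data.frame"))
}

#' Frequency-bin normalization of raw nSL scores
#'
#' Raw nSL depends strongly on the derived-allele frequency, so scores are
#' standardized within equal-width frequency bins: `zscore = (raw - bin
#' mean) / bin sd` (population standard deviation), using `n_bins`
#' equal-width bins on (0, 1). Bins holding fewer than two scores yield NA.
#' The conventional selection threshold `|nSL| >= 2` applies to these
#' normalized scores.
#'
#' @param results An `nsl_result` data.frame (or any data.frame with `daf`
#'   and `raw` columns).
#' @param n_bins Number of derived-allele-frequency bins (default 20).
#' @return The input with `zscore` and `bin_id` filled (bins are 0-based:
#'   `bin_id = floor(daf * n_bins)`).
#' @export
nsl_normalize <- function(results, n_bins = 20L) {
  stopifnot(n_bins >= 1L)
  ok <- is.finite(results$raw) & is.finite(results$daf)
  bin <- ifelse(ok, pmin(floor(results$daf * n_bins), n_bins - 1L),
                NA_integer_)
  z <- rep(NA_real_, nrow(results))
  for (b in unique(bin[!is.na(bin)])) {
    idx <- which(!is.na(bin) & bin == b)
    if (length(idx) < 2L) next
    x <- results$raw[idx]
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))
    if (sdev > 0) z[idx] <- (x - mu) / sdev
  }
  results$bin_id <- as.integer(bin)
  results$zscore <- z
  results
}

#' Write per-SNP statistics as TSV
#'
#' @param results A data.frame with at least `variant_id` (and optionally
#'   `chrom`, `pos`) columns.
#' @param path Output path.
#' @param comment Optional header comment lines (prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(results, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
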