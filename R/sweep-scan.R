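#' Configuration of the selective-sweep filter cascade
#'
#' Central home for the cascade's constants: the upper-tail PBS quantile,
#' the GWAS association threshold, the normalized-nSL locus threshold, and
#' the LD pruning parameters.
#'
#' @param pbs_quantile Upper-tail quantile retained per PBS triplet
#'   (default 0.99).
#' @param gwas_p_max GWAS association threshold; SNPs must have `p <
#'   gwas_p_max` (strict) to survive (default 5e-3).
#' @param nsl_abs_min Normalized-nSL threshold applied at the locus top SNP
#'   (inclusive, default 2).
#' @param ld_r2_max LD pruning threshold on squared haplotype correlation
#'   (default 0.1).
#' @param clump_window_kb Physical window for pruning, in kilobases
#'   (default 500).
#' @return A validated `sweep_scan_config` list.
#' @export
sweep_scan_config <- function(pbs_quantile = 0.99, gwas_p_max = 5e-3,
                              nsl_abs_min = 2, ld_r2_max = 0.1,
                              clump_window_kb = 500) {
  stopifnot(pbs_quantile > 0, pbs_quantile < 1, gwas_p_max > 0,
            nsl_abs_min > 0, ld_r2_max > 0, clump_window_kb > 0)
  structure(list(pbs_quantile = pbs_quantile, gwas_p_max = gwas_p_max,
                 nsl_abs_min = nsl_abs_min, ld_r2_max = ld_r2_max,
                 clump_window_kb = clump_window_kb),
            class = "sweep_scan_config")
}

#' Greedy p-ranked LD clumping
#'
#' Visits SNPs in order of ascending GWAS p-value and keeps each SNP unless
#' its squared Pearson correlation (r2, computed between haplotype
#' indicator vectors in the named populations) with an already-kept SNP
#' within `window_kb` exceeds `r2_max`. SNPs absent from the GWAS table are
#' visited last (treated as p = 1) and counted in a message. Ties in p are
#' broken by position, so the kept set is deterministic.
#'
#' @param gm A [genotype_matrix()] whose variants are position-sorted.
#' @param panel A [population_panel()].
#' @param pops Population (or super-population) codes defining the LD
#'   reference haplotypes.
#' @param gwas GWAS record data.frame (see [read_gwas_table()]).
#' @param r2_max Pruning threshold (default 0.1).
#' @param window_kb Physical window in kb (default 500).
#' @return Character vector of kept SNP ids.
#' @export
ld_prune <- function(gm, panel, pops, gwas, r2_max = 0.1, window_kb = 500) {
  rows <- hap_rows_for_samples(gm, panel_samples(panel, pops))
  h <- gm$haplotypes[rows, , drop = FALSE]
  m <- n_variants(gm)
  p <- gwas$p[match(gm$variant_ids, gwas$rsid)]
  n_missing <- sum(is.na(p))
  if (n_missing > 0L)
    message("ld_prune: ", n_missing,
            " SNP(s) absent from GWAS table treated as p = 1")
  p[is.na(p)] <- 1
  ord <- order(p, gm$pos)
  win <- window_kb * 1000
  kept <- integer(0)
  for (j in ord) {
    near <- kept[gm$chrom[kept] == gm$chrom[j] &
                   abs(gm$pos[kept] - gm$pos[j]) <= win]
    drop <- FALSE
    for (k in near) {
      r <- suppressWarnings(stats::cor(h[, j], h[, k],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_max) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, j)
  }
  gm$variant_ids[sort(kept)]
}

#' Intersection of upper-tail PBS outliers across triplets
#'
#' For each PBS result, retains the SNPs whose PBS is at or above the
#' empirical `q`-quantile (linear interpolation; ties at the threshold are
#' retained) of that triplet's finite PBS values, then intersects the
#' retained sets. The intersection is taken over the SNP ids shared by all
#' results.
#'
#' @param pbs_sets List of `pbs_result` data.frames (one per population
#'   triplet).
#' @param q Upper-tail quantile (default 0.99).
#' @return Character vector of SNP ids in the intersection.
#' @export
pbs_outlier_intersection <- function(pbs_sets, q = 0.99) {
  stopifnot(length(pbs_sets) >= 1L, q > 0, q < 1)
  shared <- Reduce(intersect, lapply(pbs_sets, function(x) x$variant_id))
  retained <- lapply(pbs_sets, function(x) {
    x <- x[x$variant_id %in% shared & is.finite(x$pbs), ]
    thr <- stats::quantile(x$pbs, q, type = 7, names = FALSE)
    x$variant_id[x$pbs >= thr]
  })
  Reduce(intersect, retained)
}

#' Filter SNP ids by GWAS association p-value
#'
#' @param ids Character vector of SNP ids.
#' @param gwas GWAS record data.frame.
#' @param p_max Threshold; the comparison is strict (`p < p_max`). SNPs
#'   missing from the table are dropped and counted in a message.
#' @return Character vector of surviving SNP ids.
#' @export
gwas_p_filter <- function(ids, gwas, p_max = 5e-3) {
  p <- gwas$p[match(ids, gwas$rsid)]
  n_missing <- sum(is.na(p))
  if (n_missing > 0L)
    message("gwas_p_filter: dropped ", n_missing,
            " SNP(s) absent from GWAS table")
  ids[!is.na(p) & p < p_max]
}

#' Annotate a SNP set to genes
#'
#' A gene is reported if at least one of its mapped SNPs is in `ids`
#' (union semantics; genes are deduplicated).
#'
#' @param ids Character vector of SNP ids.
#' @param gene_map A [gene_map()].
#' @return A list with `genes` (character vector) and `hits` (named list:
#'   gene -> its SNPs among `ids`).
#' @export
annotate_genes <- function(ids, gene_map) {
  hits <- lapply(gene_map, function(snps) intersect(snps, ids))
  hits <- hits[lengths(hits) > 0L]
  list(genes = names(hits), hits = hits)
}

#' Locus filter on the normalized nSL score of each locus top SNP
#'
#' For each locus, the top SNP is the member with the smallest GWAS p-value
#' (ties broken by smaller position, using the order of `nsl`); the locus
#' is retained iff the absolute normalized nSL of that top SNP meets the
#' threshold (inclusive comparison).
#'
#' @param loci Named list: locus id -> character vector of member SNP ids.
#' @param gwas GWAS record data.frame.
#' @param nsl An `nsl_result` data.frame with `zscore` filled (see
#'   [nsl_normalize()]).
#' @param threshold Normalized-score threshold (default 2; `|z| >=
#'   threshold` retains).
#' @param gene_map Optional [gene_map()] used to attach genes to retained
#'   loci.
#' @return A data.frame of class `locus_result` with one row per locus:
#'   `locus`, `n_snps`, `top_snp`, `top_p`, `top_nsl`, `retained`, `genes`
#'   (comma-joined).
#' @export
top_snp_nsl_filter <- function(loci, gwas, nsl, threshold = 2,
                               gene_map = NULL) {
  stopifnot(length(loci) >= 1L, all(lengths(loci) > 0L))
  rows <- lapply(names(loci), function(loc) {
    snps <- loci[[loc]]
    p <- gwas$p[match(snps, gwas$rsid)]
    p[is.na(p)] <- 1
    pos <- nsl$pos[match(snps, nsl$variant_id)]
    pos[is.na(pos)] <- .Machine$integer.max
    top <- snps[order(p, pos)][1L]
    z <- nsl$zscore[match(top, nsl$variant_id)]
    genes <- if (!is.null(gene_map))
      paste(annotate_genes(snps, gene_map)$genes, collapse = ",") else ""
    data.frame(locus = loc, n_snps = length(snps), top_snp = top,
               top_p = min(p), top_nsl = z,
               retained = !is.na(z) && abs(z) >= threshold,
               genes = genes, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("locus_result", "data.frame"))
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For a term with `K` genes in the universe and `k` hits among the `n`
#' query genes drawn from a universe of `N`, the p-value is the upper-tail
#' hypergeometric probability `P(X >= k)`; p-values are adjusted across
#' terms by Benjamini-Hochberg.
#'
#' @param genes Character vector of query genes (must lie in `universe`).
#' @param term_map A [term_map()].
#' @param universe Character vector: the gene universe.
#' @return A data.frame with columns `term`, `name`, `K`, `k`, `p`,
#'   `p_adjusted`, sorted by `p`.
#' @export
enrich_genesets <- function(genes, term_map, universe) {
  stopifnot(all(genes %in% universe))
  N <- length(universe); n <- length(genes)
  rows <- lapply(names(term_map$term_to_genes), function(tid) {
    tg <- intersect(term_map$term_to_genes[[tid]], universe)
    K <- length(tg)
    k <- length(intersect(tg, genes))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tid, name = unname(term_map$term_name[tid]),
               K = K, k = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Run the full selective-sweep filter cascade
#'
#' LD pruning of GWAS SNPs, intersection of upper-tail PBS outliers across
#' the triplets, strict GWAS p filtering, gene annotation, and (when a
#' locus map is supplied) the top-SNP nSL locus filter, followed by
#' hypergeometric gene-set enrichment.
#'
#' @param gm A [genotype_matrix()].
#' @param panel A [population_panel()].
#' @param gwas GWAS record data.frame.
#' @param pbs_sets List of `pbs_result` data.frames.
#' @param gene_map A [gene_map()].
#' @param config A [sweep_scan_config()].
#' @param ld_pops Populations defining the LD reference (default all).
#' @param nsl Optional normalized `nsl_result` for the locus filter.
#' @param loci Optional named list locus -> SNP ids.
#' @param term_map Optional [term_map()] for enrichment.
#' @return A list with elements `pruned`, `pbs_outliers`, `passed_gwas`,
#'   `genes`, `loci` (`locus_result` or NULL), `enrichment` (or NULL) and
#'   `counts` (per-stage input/output sizes).
#' @export
sweep_scan <- function(gm, panel, gwas, pbs_sets, gene_map,
                       config = sweep_scan_config(),
                       ld_pops = NULL, nsl = NULL, loci = NULL,
                       term_map = NULL) {
  ld_pops <- ld_pops %||% unique(panel$sample_to_pop)
  pruned <- ld_prune(gm, panel, ld_pops, gwas,
                     r2_max = config$ld_r2_max,
                     window_kb = config$clump_window_kb)
  outliers <- pbs_outlier_intersection(pbs_sets, config$pbs_quantile)
  outliers <- intersect(outliers, pruned)
  passed <- gwas_p_filter(outliers, gwas, config$gwas_p_max)
  ann <- annotate_genes(passed, gene_map)
  locus_res <- if (!is.null(loci) && !is.null(nsl))
    top_snp_nsl_filter(loci, gwas, nsl, config$nsl_abs_min, gene_map)
  enrichment <- if (!is.null(term_map)) {
    nsl_genes <- if (!is.null(locus_res) && any(locus_res$retained)) {
      unique(unlist(strsplit(locus_res$genes[locus_res$retained], ",")))
    } else character(0)
    query <- union(ann$genes, setdiff(nsl_genes, ""))
    if (length(query))
      enrich_genesets(intersect(query, names(gene_map)), term_map,
                      names(gene_map))
  }
  list(pruned = pruned, pbs_outliers = outliers, passed_gwas = passed,
       genes = ann$genes, gene_hits = ann$hits, loci = locus_res,
       enrichment = enrichment,
       counts = c(n_input = n_variants(gm), n_pruned = length(pruned),
                  n_pbs_outliers = length(outliers),
                  n_passed_gwas = length(passed),
                  n_genes = length(ann$genes)))
}
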