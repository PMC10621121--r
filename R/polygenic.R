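#' Partition each gene's SNPs into position-ordered bins
#'
#' SNP-count distributions over genes are heavily skewed, so each gene's
#' SNPs (sorted by position) are chunked into consecutive windows of
#' `window` SNPs — 11 by default, the modal gene size. A terminal remainder
#' of at least `min_remainder` SNPs forms its own bin; a smaller remainder
#' is merged into the preceding bin, so bin sizes stay within
#' `[min_remainder, window + min_remainder - 1]` and a gene with at most
#' `window` SNPs is a single bin.
#'
#' @param gene_map A [gene_map()].
#' @param positions Named integer vector: SNP id -> physical position. Every
#'   mapped SNP must be present.
#' @param window Bin window size in SNPs (default 11).
#' @param min_remainder Smallest remainder kept as its own bin (default 6).
#' @return A data.frame of class `bin_spec` with columns `gene`, `bin`
#'   (ordinal within gene), `size`, and `snps` (list column of SNP ids).
#' @export
make_bins <- function(gene_map, positions, window = 11L, min_remainder = 6L) {
  stopifnot(window >= 1L, min_remainder >= 1L, min_remainder <= window)
  all_snps <- unlist(gene_map, use.names = FALSE)
  pos_all <- positions[match(all_snps, names(positions))]
  if (anyNA(pos_all)) {
    missing <- all_snps[is.na(pos_all)]
    stop("SNP(s) without positions: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  }
  gene_idx <- rep(seq_along(gene_map), lengths(gene_map))
  # position-sort within each gene block
  ord <- order(gene_idx, pos_all)
  snps_sorted <- all_snps[ord]
  bin_sizes_for <- function(n) {
    n_full <- n %/% window
    rem <- n %% window
    sizes <- rep(window, n_full)
    if (rem >= min_remainder || n_full == 0L) sizes <- c(sizes, rem)
    else if (rem > 0L) sizes[n_full] <- sizes[n_full] + rem
    sizes[sizes > 0L]
  }
  sizes_by_gene <- lapply(lengths(gene_map), bin_sizes_for)
  n_bins <- lengths(sizes_by_gene)
  sizes <- unlist(sizes_by_gene, use.names = FALSE)
  out <- data.frame(gene = rep(names(gene_map), n_bins),
                    bin = unlist(lapply(n_bins, seq_len), use.names = FALSE),
                    size = sizes, stringsAsFactors = FALSE)
  out$snps <- I(unname(split(snps_sorted,
                             rep(seq_along(sizes), sizes))))
  structure(out, class = c("bin_spec", "data.frame"))
}

#' Null distribution of mean PBS over random SNP sets
#'
#' Draws `n_perm` uniform samples of `k` distinct SNPs from the genome-wide
#' PBS pool and records each sample's mean, giving the permutation null for
#' a bin of `k` SNPs.
#'
#' @param pbs_pool Numeric vector of finite genome-wide PBS values.
#' @param k Bin size (number of SNPs per draw).
#' @param n_perm Number of permutation iterations (default 1e5).
#' @param seed RNG seed.
#' @return Sorted numeric vector of `n_perm` null mean-PBS values.
#' @export
null_mean_pbs <- function(pbs_pool, k, n_perm = 1e5L, seed = NULL) {
  pool <- pbs_pool[is.finite(pbs_pool)]
  m <- length(pool)
  stopifnot(k >= 1L, m > k)
  with_seed(seed, {
    # draw all n_perm x k indices at once, then redraw the rare rows that
    # contain a duplicate so every draw is a k-subset without replacement
    idx <- matrix(sample.int(m, n_perm * k, replace = TRUE), n_perm, k)
    if (k > 1L) {
      has_dup <- function(rows)
        apply(rows, 1L, function(x) anyDuplicated(x) > 0L)
      bad <- which(has_dup(idx))
      while (length(bad)) {
        idx[bad, ] <- matrix(sample.int(m, length(bad) * k, replace = TRUE),
                             length(bad), k)
        bad <- bad[has_dup(idx[bad, , drop = FALSE])]
      }
    }
    sort(rowMeans(matrix(pool[idx], n_perm, k)))
  })
}

#' Permutation-based PBS selection index per bin
#'
#' For each bin, the index is the permutation tail probability that the
#' mean PBS of `k` randomly chosen SNPs is at least the bin's observed mean
#' PBS, with an add-one correction so the index is never zero:
#' `index = (1 + #\{null means >= observed\}) / (1 + n_perm)`. Bins of the
#' same size share a single cached null sample. Bin indices are then
#' FDR-adjusted (Benjamini-Hochberg) across bins.
#'
#' @param bins A `bin_spec` from [make_bins()].
#' @param pbs_values Named numeric vector: SNP id -> PBS value. Bins
#'   containing a SNP with no finite PBS are skipped with a message.
#' @param n_perm Number of permutation iterations (default 1e5).
#' @param seed RNG seed (one null sample per bin size is derived from it).
#' @param pbs_pool Optional pool of finite PBS values to draw from;
#'   defaults to `pbs_values`.
#' @return A data.frame of class `bin_index_result`: `gene`, `bin`, `size`,
#'   `observed_mean`, `index`, `q` (BH-adjusted index).
#' @export
selection_index <- function(bins, pbs_values, n_perm = 1e5L, seed = 1L,
                            pbs_pool = NULL) {
  pool <- (pbs_pool %||% pbs_values)
  pool <- pool[is.finite(pool)]
  bin_of <- rep(seq_len(nrow(bins)), lengths(bins$snps))
  vals <- pbs_values[match(unlist(bins$snps, use.names = FALSE),
                           names(pbs_values))]
  ok_bin <- as.logical(tapply(is.finite(vals), bin_of, all))
  obs <- rep(NA_real_, nrow(bins))
  obs[ok_bin] <- (rowsum(ifelse(is.finite(vals), vals, 0), bin_of) /
                    lengths(bins$snps))[ok_bin]
  n_skipped <- sum(!is.finite(obs))
  if (n_skipped > 0L)
    message("selection_index: skipped ", n_skipped,
            " bin(s) with missing PBS values")
  idx <- rep(NA_real_, nrow(bins))
  for (k in sort(unique(bins$size[is.finite(obs)]))) {
    null_k <- null_mean_pbs(pool, k, n_perm = n_perm,
                            seed = derive_seed(seed, paste0("bin_size_", k)))
    sel <- which(bins$size == k & is.finite(obs))
    # exceed count via position in the sorted null sample
    n_below <- findInterval(obs[sel], null_k, left.open = TRUE)
    idx[sel] <- (1 + (n_perm - n_below)) / (1 + n_perm)
  }
  out <- data.frame(gene = bins$gene, bin = bins$bin, size = bins$size,
                    observed_mean = obs, index = idx,
                    stringsAsFactors = FALSE)
  out$q <- NA_real_
  ok <- is.finite(idx)
  out$q[ok] <- bh_fdr(idx[ok])
  structure(out, class = c("bin_index_result", "data.frame"))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; adjusted values lie in
#' `[value, 1]`.
#'
#' @param values Numeric vector of tail probabilities.
#' @return Numeric vector of BH-adjusted values, in the input order.
#' @export
bh_fdr <- function(values) {
  stats::p.adjust(values, method = "BH")
}

#' Per-gene PBS selection index
#'
#' The per-gene index is the unweighted mean of the gene's bin indices;
#' genes with index strictly below `sig_threshold` are flagged as carrying
#' a nonrandom constant allele-frequency shift. By default the mean is
#' taken over the raw permutation indices, which keeps the per-gene index a
#' calibrated tail probability (about 1% of genes flagged at threshold 0.01
#' under neutrality); set `use_adjusted = TRUE` to average the FDR-adjusted
#' bin indices instead.
#'
#' @param bin_results A `bin_index_result` from [selection_index()].
#' @param sig_threshold Significance threshold (default 0.01, strict `<`).
#' @param use_adjusted Average `q` instead of `index` (default FALSE).
#' @return A data.frame of class `gene_index_result`: `gene`, `n_bins`,
#'   `n_snps`, `index`, `significant`.
#' @export
gene_index <- function(bin_results, sig_threshold = 0.01,
                       use_adjusted = FALSE) {
  val <- if (use_adjusted) bin_results$q else bin_results$index
  ok <- is.finite(val)
  sums <- rowsum(cbind(idx = val[ok], size = bin_results$size[ok], one = 1),
                 group = bin_results$gene[ok])
  out <- data.frame(gene = rownames(sums),
                    n_bins = as.integer(sums[, "one"]),
                    n_snps = as.integer(sums[, "size"]),
                    index = sums[, "idx"] / sums[, "one"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$significant <- out$index < sig_threshold
  structure(out, class = c("gene_index_result", "data.frame"))
}

#' Regression check of gene-size bias in the selection index
#'
#' Ordinary least squares of the per-gene index on gene size (SNP count),
#' with intercept. A flat, non-significant slope indicates the binning
#' scheme removed the size confound.
#'
#' @param gene_results A `gene_index_result`.
#' @param gene_sizes Optional named vector gene -> size in SNPs; defaults
#'   to the `n_snps` column.
#' @return A list with `slope`, `intercept`, `adj_r_squared`, `f_p` (the
#'   F-test p-value) and the fitted `lm` object.
#' @export
check_size_bias <- function(gene_results, gene_sizes = NULL) {
  size <- if (is.null(gene_sizes)) gene_results$n_snps
          else unname(gene_sizes[gene_results$gene])
  fit <- stats::lm(gene_results$index ~ size)
  sm <- summary(fit)
  f_p <- if (is.null(sm$fstatistic)) NA_real_
         else unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L],
                               sm$fstatistic[3L], lower.tail = FALSE))
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       adj_r_squared = sm$adj.r.squared, f_p = f_p, fit = fit)
}

#' Drop terms with below-median gene counts
#'
#' Term gene sets are intersected with the scored gene universe; the median
#' of the resulting counts is computed and terms with a count strictly
#' below the median are removed (ties at the median are retained).
#'
#' @param term_map A [term_map()].
#' @param universe Character vector of scored genes.
#' @return The filtered [term_map()] (gene sets restricted to the
#'   universe), with attribute `median_count`.
#' @export
filter_terms <- function(term_map, universe) {
  t2g <- lapply(term_map$term_to_genes, intersect, y = universe)
  counts <- lengths(t2g)
  med <- stats::median(counts)
  keep <- counts >= med & counts > 0L
  out <- term_map(t2g[keep], term_map$term_name[names(t2g)[keep]])
  attr(out, "median_count") <- med
  out
}

#' Prune redundant terms by hierarchical clustering of gene overlap
#'
#' Pairwise term distance is one minus the Jaccard similarity of their gene
#' sets; terms are clustered by Ward agglomeration and the tree is cut at
#' `cut_height`. Within each cluster only the term with the largest gene
#' count survives (ties broken by lexicographically smallest term id). A
#' user-supplied distance matrix (e.g. a semantic similarity) may replace
#' the Jaccard default.
#'
#' @param term_map A [term_map()].
#' @param cut_height Tree cut height (default 0.5).
#' @param dist_matrix Optional `dist` object or symmetric matrix of
#'   pairwise term distances (rows/columns in `names(term_to_genes)`
#'   order).
#' @param method Agglomeration method passed to [stats::hclust()]
#'   (default `"ward.D2"`).
#' @return The pruned [term_map()], with attribute `clusters` (named
#'   integer vector of cluster memberships).
#' @export
prune_terms <- function(term_map, cut_height = 0.5, dist_matrix = NULL,
                        method = "ward.D2") {
  t2g <- term_map$term_to_genes
  ids <- names(t2g)
  if (length(ids) < 2L) return(term_map)
  if (is.null(dist_matrix)) {
    n <- length(ids)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- t2g[[i]]; b <- t2g[[j]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      d[i, j] <- d[j, i] <- 1 - jac
    }
    dist_matrix <- stats::as.dist(d)
  } else if (!inherits(dist_matrix, "dist")) {
    dist_matrix <- stats::as.dist(dist_matrix)
  }
  hc <- stats::hclust(dist_matrix, method = method)
  cl <- stats::cutree(hc, h = cut_height)
  keep <- vapply(split(ids, cl), function(members) {
    sizes <- lengths(t2g[members])
    members[order(-sizes, members)][1L]
  }, character(1))
  out <- term_map(t2g[sort(keep)], term_map$term_name[sort(keep)])
  attr(out, "clusters") <- cl
  out
}

#' Two-sample proportion test for enrichment of selected genes in a term
#'
#' Compares the proportion of significant genes (per-gene index below the
#' threshold) inside a term against the complement of the term, with a
#' pooled-variance z statistic and no continuity correction; the p-value is
#' one-sided for the term proportion exceeding the background.
#'
#' @param term_genes Character vector of the term's genes (must be scored).
#' @param gene_results A `gene_index_result` covering all scored genes.
#' @return A one-row data.frame of class `term_test_result`: `n_term`,
#'   `n_background`, `k_term`, `k_background`, `z`, `p`.
#' @export
term_proportion_test <- function(term_genes, gene_results) {
  in_term <- gene_results$gene %in% term_genes
  if (!any(in_term) || all(in_term))
    stop("term and background groups must both be non-empty")
  missing <- setdiff(term_genes, gene_results$gene)
  if (length(missing))
    stop("term gene(s) not scored: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  n1 <- sum(in_term); n2 <- sum(!in_term)
  k1 <- sum(gene_results$significant[in_term])
  k2 <- sum(gene_results$significant[!in_term])
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se > 0) (p1 - p2) / se else 0
  # floor against underflow so the tail probability stays in (0, 1]
  p_val <- max(stats::pnorm(z, lower.tail = FALSE), .Machine$double.xmin)
  structure(data.frame(n_term = n1, n_background = n2, k_term = k1,
                       k_background = k2, z = z, p = p_val),
            class = c("term_test_result", "data.frame"))
}

#' Scan every term for polygenic adaptation
#'
#' Applies [term_proportion_test()] to each term of a (typically filtered
#' and pruned) term map.
#'
#' @param term_map A [term_map()].
#' @param gene_results A `gene_index_result`.
#' @return A data.frame with one row per term (`term`, `name`, plus the
#'   [term_proportion_test()] columns), sorted by `p`.
#' @export
term_scan <- function(term_map, gene_results) {
  rows <- lapply(names(term_map$term_to_genes), function(tid) {
    tg <- intersect(term_map$term_to_genes[[tid]], gene_results$gene)
    if (length(tg) == 0L || length(tg) == nrow(gene_results)) return(NULL)
    cbind(data.frame(term = tid, name = unname(term_map$term_name[tid]),
                     stringsAsFactors = FALSE),
          term_proportion_test(tg, gene_results))
  })
  out <- do.call(rbind, rows)
  out[order(out$p), ]
}

#' Run the full polygenic-adaptation scan
#'
#' Bins genes, computes permutation-based bin selection indices, aggregates
#' to per-gene indices, checks size bias, filters and prunes the term map,
#' and tests every surviving term with the two-sample proportion test.
#'
#' @param gene_map A [gene_map()].
#' @param positions Named vector SNP id -> position.
#' @param pbs_values Named vector SNP id -> PBS.
#' @param term_map A [term_map()].
#' @param window Bin window size (default 11).
#' @param n_perm Permutation iterations (default 1e5).
#' @param sig_threshold Per-gene significance threshold (default 0.01).
#' @param cut_height Term-pruning tree cut height (default 0.5).
#' @param seed RNG seed.
#' @return A list with `bins`, `bin_index`, `gene_index`, `size_bias`,
#'   `terms_kept` (pruned [term_map()]) and `term_tests`.
#' @export
polygenic_scan <- function(gene_map, positions, pbs_values, term_map,
                           window = 11L, n_perm = 1e5L,
                           sig_threshold = 0.01, cut_height = 0.5,
                           seed = 1L) {
  bins <- make_bins(gene_map, positions, window = window)
  bin_idx <- selection_index(bins, pbs_values, n_perm = n_perm, seed = seed)
  genes <- gene_index(bin_idx, sig_threshold = sig_threshold)
  bias <- check_size_bias(genes)
  terms <- filter_terms(term_map, genes$gene)
  terms <- prune_terms(terms, cut_height = cut_height)
  tests <- term_scan(terms, genes)
  list(bins = bins, bin_index = bin_idx, gene_index = genes,
       size_bias = bias[c("slope", "adj_r_squared", "f_p")],
       terms_kept = terms, term_tests = tests)
}
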