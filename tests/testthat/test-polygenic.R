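positions_for <- function(gmap) {
  snps <- unlist(gmap, use.names = FALSE)
  setNames(seq_along(snps) * 10L, snps)
}

test_that("make_bins chunks gene SNPs with the small-remainder merge rule", {
  gmap <- gene_map(list(A = paste0("a", 1:11), B = paste0("b", 1:25),
                        C = paste0("c", 1:28), D = paste0("d", 1:3)))
  bins <- make_bins(gmap, positions_for(gmap))
  expect_identical(bins$size[bins$gene == "A"], 11L)
  expect_identical(bins$size[bins$gene == "B"], c(11L, 14L))
  expect_identical(bins$size[bins$gene == "C"], c(11L, 11L, 6L))
  expect_identical(bins$size[bins$gene == "D"], 3L)
  # bins partition each gene's SNP set, in position order
  for (g in names(gmap)) {
    got <- unlist(bins$snps[bins$gene == g])
    expect_identical(sort(got), sort(gmap[[g]]))
    expect_identical(anyDuplicated(got), 0L)
  }
  expect_error(make_bins(gmap, positions_for(gmap)[-1]), "without positions")
})

test_that("null_mean_pbs draws k-subsets and matches pool moments", {
  # constant pool: every null mean equals the constant
  expect_true(all(null_mean_pbs(rep(0.7, 100), 5, n_perm = 200,
                                seed = 1) == 0.7))
  # mean of null means approaches the pool mean
  set.seed(2)
  pool <- rexp(2000)
  nm <- null_mean_pbs(pool, 8, n_perm = 5000, seed = 3)
  mc_se <- sd(nm) / sqrt(length(nm))
  expect_lt(abs(mean(nm) - mean(pool)), 3 * mc_se)
  # sampling is without replacement: with a pool of k + 1 values, every
  # achievable mean excludes exactly one element
  pool_small <- c(0, 10, 20, 30, 40)
  nm2 <- null_mean_pbs(pool_small, 4, n_perm = 500, seed = 4)
  allowed <- sapply(1:5, function(i) mean(pool_small[-i]))
  expect_true(all(nm2 %in% allowed))
})

test_that("selection_index is the add-one-corrected upper tail", {
  gmap <- gene_map(list(HI = paste0("h", 1:5), LO = paste0("l", 1:5)))
  pos <- positions_for(gmap)
  pool <- setNames(runif(500), paste0("p", 1:500))
  vals <- c(pool, setNames(rep(100, 5), paste0("h", 1:5)),
            setNames(rep(-100, 5), paste0("l", 1:5)))
  bins <- make_bins(gmap, pos)
  res <- selection_index(bins, vals, n_perm = 1000, seed = 5,
                         pbs_pool = pool)
  expect_equal(res$index[res$gene == "HI"], 1 / 1001)
  expect_equal(res$index[res$gene == "LO"], 1)
  expect_true(all(res$q >= res$index))
})

test_that("bin indices are uniform under the null", {
  set.seed(6)
  pool <- setNames(rnorm(5000), paste0("s", 1:5000))
  gmap <- gene_map(split(paste0("s", 1:2200), rep(1:200, each = 11)))
  bins <- make_bins(gmap, setNames(seq_len(5000), paste0("s", 1:5000)))
  res <- selection_index(bins, pool, n_perm = 2000, seed = 7)
  ks <- suppressWarnings(ks.test(res$index, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_fdr reproduces the step-up construction", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(8)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  # permutation invariance
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("gene_index averages bin indices with a strict threshold", {
  br <- structure(data.frame(
    gene = c("A", "B", "B", "C"), bin = c(1, 1, 2, 1),
    size = c(11, 11, 8, 11),
    observed_mean = 0, index = c(0.004, 0.005, 0.015, 0.02),
    q = c(0.016, 0.02, 0.03, 0.04)),
    class = c("bin_index_result", "data.frame"))
  gi <- gene_index(br)
  expect_equal(gi$index[gi$gene == "A"], 0.004)
  expect_equal(gi$index[gi$gene == "B"], 0.010)
  expect_false(gi$significant[gi$gene == "B"]) # 0.010 < 0.01 is false
  expect_true(gi$significant[gi$gene == "A"])
  expect_identical(gi$n_snps[gi$gene == "B"], 19L)
  # adjusted-index variant averages q instead
  gi2 <- gene_index(br, use_adjusted = TRUE)
  expect_equal(gi2$index[gi2$gene == "B"], 0.025)
  # 5-gene hand-computed fixture
  br5 <- structure(data.frame(
    gene = rep(paste0("g", 1:5), times = c(1, 2, 3, 1, 2)),
    bin = c(1, 1, 2, 1, 2, 3, 1, 1, 2), size = 11,
    observed_mean = 0,
    index = c(0.5, 0.2, 0.4, 0.1, 0.2, 0.6, 0.008, 0.9, 0.7),
    q = NA), class = c("bin_index_result", "data.frame"))
  gi5 <- gene_index(br5)
  expect_equal(gi5$index,
               c(0.5, 0.3, 0.3, 0.008, 0.8))
  expect_identical(gi5$significant, c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("check_size_bias runs OLS of index on size", {
  gr <- structure(data.frame(gene = paste0("g", 1:10),
                             n_bins = 1L, n_snps = 1:10,
                             index = rep(0.4, 10), significant = FALSE),
                  class = c("gene_index_result", "data.frame"))
  sb <- suppressWarnings(check_size_bias(gr))
  expect_equal(sb$slope, 0)
  # perfectly linear index: adjusted R-squared 1, vanishing p
  gr$index <- 0.01 * (1:10) + 0.05
  sb2 <- suppressWarnings(check_size_bias(gr))
  expect_equal(sb2$adj_r_squared, 1)
  expect_lt(sb2$f_p, 1e-12)
  # normal-equations oracle on a noisy 10-point fixture
  set.seed(9)
  gr$index <- 0.3 + 0.01 * (1:10) + rnorm(10, 0, 0.05)
  sb3 <- check_size_bias(gr)
  o <- oracle_wls(gr$n_snps, gr$index, rep(1, 10))
  expect_equal(sb3$slope, o$slope, tolerance = 1e-10)
  expect_equal(sb3$intercept, o$intercept, tolerance = 1e-10)
})

test_that("filter_terms drops below-median terms, keeping ties", {
  mk_tm <- function(sizes) {
    term_map(lapply(setNames(sizes, paste0("T", seq_along(sizes))),
                    function(k) paste0("g", 1:k)))
  }
  uni <- paste0("g", 1:100)
  # equal sizes: everything retained
  expect_length(filter_terms(mk_tm(c(5, 5, 5)), uni)$term_to_genes, 3L)
  # sizes (1,2,3,4,100): median 3, terms of size >= 3 retained
  ft <- filter_terms(mk_tm(c(1, 2, 3, 4, 100)), uni)
  expect_setequal(names(ft$term_to_genes), c("T3", "T4", "T5"))
  expect_equal(attr(ft, "median_count"), 3)
  # intersection with the universe drives the counts
  tm <- term_map(list(A = c("g1", "g2", "zz"), B = c("g3", "g4", "g5"),
                      C = c("g6", "g7")))
  ft2 <- filter_terms(tm, uni) # counts 2, 3, 2 -> median 2, all kept
  expect_identical(ft2$term_to_genes$A, c("g1", "g2"))
  expect_length(ft2$term_to_genes, 3L)
})

test_that("prune_terms keeps one representative per overlap cluster", {
  # identical terms collapse to the larger / lexicographically first
  tm <- term_map(list(B = c("g1", "g2"), A = c("g1", "g2")))
  pr <- prune_terms(tm)
  expect_identical(names(pr$term_to_genes), "A")
  # pairwise disjoint terms (distance 1) all survive a 0.5 cut
  tm2 <- term_map(list(X = paste0("x", 1:4), Y = paste0("y", 1:4),
                       Z = paste0("z", 1:4)))
  expect_length(prune_terms(tm2, 0.5)$term_to_genes, 3L)
})

test_that("prune_terms clustering agrees with a step-by-step Ward oracle", {
  t2g <- list(T1 = paste0("g", 1:10), T2 = paste0("g", 2:10),
              T3 = paste0("g", c(1:5, 20:24)), T4 = paste0("h", 1:8),
              T5 = paste0("h", c(1:7, 30)), T6 = paste0("k", 1:6))
  tm <- term_map(t2g)
  n <- length(t2g)
  d <- matrix(0, n, n, dimnames = list(names(t2g), names(t2g)))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    jac <- length(intersect(t2g[[i]], t2g[[j]])) /
      length(union(t2g[[i]], t2g[[j]]))
    d[i, j] <- d[j, i] <- 1 - jac
  }
  for (h in c(0.3, 0.5, 0.8)) {
    pr <- prune_terms(tm, cut_height = h)
    got <- attr(pr, "clusters")
    want <- oracle_ward_cut(d, h)
    # same partition (up to label permutation)
    expect_identical(unname(vapply(split(names(got), got), paste,
                                   "", collapse = ",")) |> sort(),
                     unname(vapply(split(names(want), want), paste,
                                   "", collapse = ",")) |> sort())
  }
})

test_that("term_proportion_test matches the pooled-z closed form", {
  mk_gr <- function(sig) structure(
    data.frame(gene = paste0("g", seq_along(sig)), n_bins = 1L,
               n_snps = 11L, index = ifelse(sig, 0.005, 0.5),
               significant = sig),
    class = c("gene_index_result", "data.frame"))
  # equal proportions: z = 0, p = 0.5
  gr <- mk_gr(rep(c(TRUE, FALSE), 10))
  res <- term_proportion_test(paste0("g", 1:10), gr)
  expect_equal(res$z, 0)
  expect_equal(res$p, 0.5)
  # term all-significant vs background none, sizes (16, 1000)
  gr2 <- mk_gr(c(rep(TRUE, 16), rep(FALSE, 1000)))
  res2 <- term_proportion_test(paste0("g", 1:16), gr2)
  o2 <- oracle_prop_z(16, 16, 0, 1000)
  expect_equal(res2$z, o2$z, tolerance = 1e-12)
  expect_equal(res2$p, o2$p, tolerance = 1e-12)
  # fixture: 5/20 in the term vs 10/1000 in the complement
  sig <- c(rep(TRUE, 5), rep(FALSE, 15), rep(TRUE, 10), rep(FALSE, 990))
  gr3 <- mk_gr(sig)
  res3 <- term_proportion_test(paste0("g", 1:20), gr3)
  o3 <- oracle_prop_z(5, 20, 10, 1000)
  expect_equal(res3$z, o3$z, tolerance = 1e-12)
  expect_error(term_proportion_test(paste0("g", 1:20), gr3[1:20, ]),
               "non-empty")
})

test_that("selection_index output is byte-stable across identical runs", {
  gmap <- gene_map(split(paste0("s", 1:110), rep(1:10, each = 11)))
  pos <- setNames(seq_len(110), paste0("s", 1:110))
  vals <- setNames(rnorm(110), paste0("s", 1:110))
  bins <- make_bins(gmap, pos)
  r1 <- selection_index(bins, vals, n_perm = 500, seed = 42)
  r2 <- selection_index(bins, vals, n_perm = 500, seed = 42)
  expect_identical(r1, r2)
})
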