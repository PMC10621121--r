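make_ld_fixture <- function(m, n = 20, blocks = NULL, seed = 1) {
  set.seed(seed)
  haps <- matrix(rbinom(2 * n * m, 1, 0.5), 2 * n, m)
  if (!is.null(blocks)) {
    for (b in blocks) haps[, b] <- haps[, b[1]] # perfect LD within block
  }
  gm <- genotype_matrix(paste0("v", 1:m), rep("1", m), seq_len(m) * 1000,
                        rep("A", m), rep("G", m), haps, paste0("s", 1:n))
  panel <- population_panel(setNames(rep("EUR", n), paste0("s", 1:n)))
  list(gm = gm, panel = panel)
}

test_that("ld_prune keeps the most significant SNP of a correlated pair", {
  fx <- make_ld_fixture(2, blocks = list(1:2), seed = 2)
  gwas <- make_gwas(c("v1", "v2"), c(1e-3, 1e-5))
  expect_identical(ld_prune(fx$gm, fx$panel, "EUR", gwas), "v2")
  # mutually uncorrelated SNPs all survive
  fx2 <- make_ld_fixture(6, n = 400, seed = 3)
  gwas2 <- make_gwas(paste0("v", 1:6), runif(6, 1e-6, 1e-3))
  expect_identical(ld_prune(fx2$gm, fx2$panel, "EUR", gwas2),
                   paste0("v", 1:6))
})

test_that("ld_prune agrees with an exhaustive pairwise oracle", {
  fx <- make_ld_fixture(50, n = 30,
                        blocks = list(1:5, 10:13, 30:40), seed = 4)
  gwas <- make_gwas(paste0("v", 1:50), runif(50, 1e-8, 1))
  kept <- ld_prune(fx$gm, fx$panel, "EUR", gwas, r2_max = 0.1,
                   window_kb = 500)
  rows <- 1:60
  r2 <- function(i, j) cor(fx$gm$haplotypes[rows, i],
                           fx$gm$haplotypes[rows, j])^2
  ki <- match(kept, fx$gm$variant_ids)
  # kept SNPs are mutually below the threshold within the window
  for (i in ki) for (j in ki) if (i < j &&
      abs(fx$gm$pos[i] - fx$gm$pos[j]) <= 5e5)
    expect_lte(r2(i, j), 0.1)
  # every dropped SNP is explained by a kept, better-ranked neighbor
  p <- gwas$p[match(fx$gm$variant_ids, gwas$rsid)]
  for (i in setdiff(1:50, ki)) {
    culprits <- ki[p[ki] <= p[i] &
                     abs(fx$gm$pos[ki] - fx$gm$pos[i]) <= 5e5]
    expect_true(any(vapply(culprits, function(j) r2(i, j) > 0.1, TRUE)))
  }
})

test_that("pbs_outlier_intersection retains shared upper tails", {
  mk <- function(ids, v) structure(
    data.frame(variant_id = ids, pbs = v),
    class = c("pbs_result", "data.frame"))
  ids <- paste0("v", 1:100)
  v <- seq(0, 1, length.out = 100)
  # identical sets: each triplet's own top (1 - q) fraction
  same <- pbs_outlier_intersection(list(mk(ids, v), mk(ids, v), mk(ids, v)),
                                   q = 0.9)
  thr <- quantile(v, 0.9, type = 7)
  expect_setequal(same, ids[v >= thr])
  # disjoint tails intersect to nothing
  disj <- pbs_outlier_intersection(
    list(mk(ids, v), mk(ids, rev(v)), mk(ids, v)), q = 0.95)
  expect_length(disj, 0)
})

test_that("spiked SNPs rise into the PBS outlier intersection", {
  # five populations; POP0 is focal in three triplets sharing outgroup POP4
  arch_seed <- 91
  sim <- simulate_frequency_table(simulation_config(
    n_snps = 1000, n_pops = 5, drift = 0.03, seed = arch_seed))
  # plant the shift where there is headroom for it (clipping would mute a
  # +0.6 shift at SNPs whose ancestral frequency is already high)
  spiked <- which(sim$p_anc > 0.15 & sim$p_anc < 0.35)[1:20]
  freqs <- spike_selection(sim$freqs, spiked, 1L, +0.6)
  g <- simulate_genotypes(freqs, 100, seed = arch_seed + 1)
  fst <- function(a, b) fst_wc(g$gm, g$panel, a, b)
  f_a4 <- fst("POP0", "POP4")
  triplets <- lapply(c("POP1", "POP2", "POP3"), function(b)
    pbs(fst("POP0", b), f_a4, fst(b, "POP4")))
  hits <- pbs_outlier_intersection(triplets, q = 0.97)
  truth <- g$gm$variant_ids[spiked]
  expect_gte(length(intersect(hits, truth)), 19)
  false_pos <- setdiff(hits, truth)
  expect_lte(length(false_pos) / (1000 - 20), 0.01)
})

test_that("gwas_p_filter applies a strict threshold", {
  gwas <- make_gwas(paste0("v", 1:3), c(5.0e-3, 4.9e-3, 0.5))
  expect_identical(gwas_p_filter(paste0("v", 1:3), gwas, 5e-3), "v2")
  # SNPs absent from the table are dropped with a count
  expect_message(out <- gwas_p_filter(c("v2", "vX"), gwas, 5e-3),
                 "dropped 1")
  expect_identical(out, "v2")
  # hand-filtered 10-record fixture
  set.seed(5)
  p <- runif(10, 0, 0.02)
  gwas10 <- make_gwas(paste0("s", 1:10), p)
  expect_identical(gwas_p_filter(paste0("s", 1:10), gwas10, 5e-3),
                   paste0("s", 1:10)[p < 5e-3])
})

test_that("annotate_genes uses union semantics over gene SNP sets", {
  gmap <- gene_map(list(G1 = c("v1", "v2"), G2 = c("v2", "v3"),
                        G3 = "v4"))
  ann <- annotate_genes("v2", gmap)
  expect_setequal(ann$genes, c("G1", "G2"))
  expect_length(annotate_genes(character(0), gmap)$genes, 0)
  ann2 <- annotate_genes(c("v1", "v4"), gmap)
  expect_setequal(ann2$genes, c("G1", "G3"))
  expect_identical(ann2$hits$G1, "v1")
})

test_that("top_snp_nsl_filter applies the inclusive top-SNP rule", {
  nsl <- data.frame(variant_id = paste0("v", 1:4), pos = 1:4 * 100,
                    zscore = c(2.0, 1.99, 3.0, 0.5))
  gwas <- make_gwas(paste0("v", 1:4), c(1e-6, 1e-8, 1e-4, 1e-5))
  # |z| = 2.0 at the top SNP retains the locus (inclusive comparison)
  res1 <- top_snp_nsl_filter(list(L1 = "v1"), gwas, nsl)
  expect_true(res1$retained)
  # top SNP below threshold drops the locus even when a member passes
  res2 <- top_snp_nsl_filter(list(L2 = c("v2", "v3")), gwas, nsl)
  expect_identical(res2$top_snp, "v2")
  expect_false(res2$retained)
})

test_that("planted sweep loci are recovered by the top-SNP filter", {
  # 20 loci; 6 planted with |z| >= 2 at their top SNP
  set.seed(6)
  ids <- sprintf("v%02d", 1:60)
  loci <- split(ids, rep(1:20, each = 3))
  names(loci) <- paste0("L", 1:20)
  planted <- paste0("L", c(2, 5, 9, 11, 16, 20))
  z <- runif(60, -1.2, 1.2)
  gwas <- make_gwas(ids, runif(60, 1e-8, 1e-3))
  for (loc in names(loci)) {
    snps <- loci[[loc]]
    top <- snps[which.min(gwas$p[match(snps, gwas$rsid)])]
    if (loc %in% planted) z[match(top, ids)] <- -2.5
  }
  nsl <- data.frame(variant_id = ids, pos = seq_along(ids) * 50, zscore = z)
  res <- top_snp_nsl_filter(loci, gwas, nsl)
  expect_setequal(res$locus[res$retained], planted)
})

test_that("hypergeometric enrichment matches direct combinatorial sums", {
  universe <- paste0("g", 1:20)
  tm <- term_map(list(ALL = universe,
                      T1 = paste0("g", 1:5)))
  # term = universe is never enriched
  res <- enrich_genesets(paste0("g", 1:5), tm, universe)
  expect_equal(res$p[res$term == "ALL"], 1)
  # perfect overlap k = K = n with N = 20: p = 1 / C(20, 5)
  expect_equal(res$p[res$term == "T1"], 1 / choose(20, 5),
               tolerance = 1e-12)
  # N=20, K=5, n=5, k=4: sum of the pmf over k in {4, 5}
  res4 <- enrich_genesets(c(paste0("g", 1:4), "g10"), tm, universe)
  expect_equal(res4$p[res4$term == "T1"], oracle_hyper(4, 5, 20, 5),
               tolerance = 1e-12)
  # brute-force equivalence on 100 random configurations
  set.seed(7)
  for (i in 1:100) {
    N <- sample(10:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- paste0("x", 1:N)
    tmi <- term_map(list(T = uni[1:K]))
    query <- sample(uni, n)
    k <- sum(query %in% uni[1:K])
    res <- enrich_genesets(query, tmi, uni)
    expect_equal(res$p, oracle_hyper(k, K, N, n), tolerance = 1e-12)
  }
})

test_that("the filter cascade only shrinks as thresholds tighten", {
  mk <- function(ids, v) structure(
    data.frame(variant_id = ids, pbs = v),
    class = c("pbs_result", "data.frame"))
  set.seed(8)
  ids <- paste0("v", 1:200)
  sets <- list(mk(ids, rnorm(200)), mk(ids, rnorm(200)))
  out_q <- lapply(c(0.8, 0.9, 0.95), function(q)
    pbs_outlier_intersection(sets, q))
  expect_true(all(out_q[[2]] %in% out_q[[1]]))
  expect_true(all(out_q[[3]] %in% out_q[[2]]))
  gwas <- make_gwas(ids, runif(200, 1e-6, 1))
  f1 <- gwas_p_filter(ids, gwas, 0.05)
  f2 <- gwas_p_filter(ids, gwas, 0.01)
  expect_true(all(f2 %in% f1))
  # repeated runs are identical (pure functions)
  expect_identical(pbs_outlier_intersection(sets, 0.9),
                   pbs_outlier_intersection(sets, 0.9))
})

test_that("sweep_scan composes the cascade and reports stage counts", {
  set.seed(99)
  sim <- simulate_frequency_table(simulation_config(
    n_snps = 120, n_pops = 4, drift = 0.05, seed = 100))
  spiked <- which(sim$p_anc > 0.2 & sim$p_anc < 0.4)[1:6]
  freqs <- spike_selection(sim$freqs, spiked, 1L, +0.55)
  g <- simulate_genotypes(freqs, 60, seed = 101)
  fst <- function(a, b) fst_wc(g$gm, g$panel, a, b)
  pbs_sets <- list(
    pbs(fst("POP0", "POP1"), fst("POP0", "POP3"), fst("POP1", "POP3")),
    pbs(fst("POP0", "POP2"), fst("POP0", "POP3"), fst("POP2", "POP3")))
  ids <- g$gm$variant_ids
  gwas <- make_gwas(ids, ifelse(seq_along(ids) %in% spiked, 1e-6,
                                runif(length(ids), 1e-4, 1)))
  gmap <- gene_map(split(ids, rep(1:24, each = 5)))
  names(gmap) <- paste0("G", 1:24)
  tmap <- term_map(list(T1 = paste0("G", 1:6), T2 = paste0("G", 7:24)))
  # LD reference restricted to one population: pooling all populations
  # would see stratification-induced LD among the co-spiked SNPs
  res <- suppressMessages(
    sweep_scan(g$gm, g$panel, gwas, pbs_sets, gmap,
               config = sweep_scan_config(pbs_quantile = 0.9),
               ld_pops = "POP1", term_map = tmap))
  # spiked SNPs survive to the end of the SNP-level cascade
  expect_gte(length(intersect(res$passed_gwas, ids[spiked])), 4)
  # counts shrink monotonically through the cascade
  expect_lte(res$counts[["n_passed_gwas"]], res$counts[["n_pbs_outliers"]])
  expect_lte(res$counts[["n_pbs_outliers"]], res$counts[["n_pruned"]])
  # genes hosting the spiked SNPs are annotated and enrichment runs
  expect_true(all(res$genes %in% names(gmap)))
  expect_identical(nrow(res$enrichment), 2L)
})
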