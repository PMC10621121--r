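test_that("allele_frequency counts the requested allele per population", {
  fx <- random_geno_gm(m = 6, n_per_pop = 5, seed = 31)
  # direct tally oracle on each 10-haplotype population column
  rows1 <- 1:10
  for (j in 1:6) {
    f <- allele_frequency(fx$gm, fx$panel, "P1")[j]
    expect_equal(unname(f), sum(fx$gm$haplotypes[rows1, j]) / 10)
  }
  # all-reference column has alt frequency 0
  gm0 <- genotype_matrix("v1", "1", 100, "A", "G",
                         matrix(0L, 4, 1), c("s1", "s2"))
  panel0 <- population_panel(c(s1 = "P", s2 = "P"))
  expect_equal(unname(allele_frequency(gm0, panel0, "P")), 0)
  expect_equal(unname(allele_frequency(gm0, panel0, "P", allele = "ref")), 1)
  # per-variant allele spec resolves against ref/alt and errors on mismatch
  expect_equal(unname(allele_frequency(gm0, panel0, "P", allele = "G")), 0)
  expect_error(allele_frequency(gm0, panel0, "P", allele = "T"), "v1")
})

test_that("fst_wc handles fixed and heterozygote-only configurations", {
  n <- 10
  haps <- cbind(c(rep(1L, 2 * n), rep(0L, 2 * n)))
  gm <- genotype_matrix("v1", "1", 100, "A", "G", haps,
                        paste0("s", 1:(2 * n)))
  panel <- population_panel(setNames(rep(c("A", "B"), each = n),
                                     paste0("s", 1:(2 * n))))
  expect_equal(fst_wc(gm, panel, "A", "B")$theta, 1)

  # every sample heterozygous in both populations: no among-population
  # variance, so theta <= 0
  haps_het <- cbind(rep(c(0L, 1L), 2 * n))
  gm2 <- genotype_matrix("v1", "1", 100, "A", "G", haps_het,
                         paste0("s", 1:(2 * n)))
  expect_lte(fst_wc(gm2, panel, "A", "B")$theta, 0)
})

test_that("fst_wc equals the direct WC84 transcription on random fixtures", {
  for (s in 1:100) {
    fx <- random_geno_gm(m = 5, n_per_pop = 5, seed = 1000 + s)
    res <- fst_wc(fx$gm, fx$panel, "P1", "P2")
    for (j in 1:5) {
      g <- fx$gm$haplotypes[seq(1, 20, 2), j] +
        fx$gm$haplotypes[seq(2, 20, 2), j]
      o <- oracle_wc_fst(g[1:5], g[6:10])
      expect_equal(res$a[j], o$a, tolerance = 1e-12)
      expect_equal(res$b[j], o$b, tolerance = 1e-12)
      expect_equal(res$c[j], o$c, tolerance = 1e-12)
      if (is.na(o$theta)) expect_true(is.na(res$theta[j]))
      else expect_equal(res$theta[j], o$theta, tolerance = 1e-12)
    }
  }
})

test_that("fst_wc uses pairwise-complete genotypes under missingness", {
  fx <- random_geno_gm(m = 4, n_per_pop = 5, seed = 77)
  h <- fx$gm$haplotypes
  h[1:2, 2] <- NA # sample s1 missing at variant 2
  gm <- genotype_matrix(fx$gm$variant_ids, fx$gm$chrom, fx$gm$pos,
                        fx$gm$ref_allele, fx$gm$alt_allele, h,
                        fx$gm$sample_ids)
  res <- fst_wc(gm, fx$panel, "P1", "P2")
  g1 <- h[seq(1, 20, 2), 2] + h[seq(2, 20, 2), 2]
  o <- oracle_wc_fst(g1[1:5], g1[6:10])
  if (is.na(o$theta)) expect_true(is.na(res$theta[2]))
  else expect_equal(res$theta[2], o$theta, tolerance = 1e-12)
})

test_that("pbs follows its defining branch-length formula", {
  mk <- function(theta) structure(
    data.frame(variant_id = paste0("v", seq_along(theta)), theta = theta,
               a = NA, b = NA, c = NA), class = c("fst_result", "data.frame"))
  # all-zero Fst gives zero PBS
  expect_equal(pbs(mk(0), mk(0), mk(0))$pbs, 0)
  # forced by the formula: (T + T - 0)/2 with T = -ln(0.5)
  expect_equal(pbs(mk(0.5), mk(0.5), mk(0))$pbs, log(2), tolerance = 1e-12)
  # brute-force equality on 1000 random triples (incl. negatives and ones)
  set.seed(41)
  f1 <- runif(1000, -0.2, 1); f2 <- runif(1000, -0.2, 1)
  f3 <- runif(1000, -0.2, 1)
  res <- pbs(mk(f1), mk(f2), mk(f3))
  expected <- mapply(oracle_pbs, f1, f2, f3)
  expect_equal(res$pbs, expected, tolerance = 1e-12)
  # symmetry in the outgroup pair: swapping B and C leaves PBS unchanged
  expect_equal(pbs(mk(f2), mk(f1), mk(f3))$pbs, res$pbs)
  # strict monotonicity in fst_ab
  expect_true(all(diff(pbs(mk(seq(0, 0.9, 0.1)), mk(rep(0.3, 10)),
                           mk(rep(0.2, 10)))$pbs) > 0))
  # misaligned variant universes are reported with the difference
  bad <- mk(c(0.1, 0.2))
  bad$variant_id <- c("v1", "vX")
  expect_error(pbs(mk(c(0.1, 0.2)), bad, mk(c(0.1, 0.2))), "vX")
})

test_that("nsl_raw matches the exhaustive pairwise oracle", {
  # 6-haplotype x 9-site fixture
  set.seed(51)
  haps <- matrix(rbinom(54, 1, 0.5), 6, 9)
  haps[, 5] <- c(0, 0, 0, 1, 1, 1)
  r <- nsl_raw(haps, 5, maf_min = 0.05, max_extend = 100)
  o <- oracle_nsl(haps, 5)
  expect_equal(r$raw, o$raw, tolerance = 1e-12)
  expect_equal(r$sl_a, o$sl_a, tolerance = 1e-12)
  expect_equal(r$sl_d, o$sl_d, tolerance = 1e-12)
  # 100 random fixtures, varying shapes and truncation caps
  for (s in 1:100) {
    set.seed(100 + s)
    n <- sample(4:12, 1); m <- sample(5:25, 1)
    h <- matrix(rbinom(n * m, 1, 0.5), n, m)
    focal <- sample(m, 1)
    if (sum(h[, focal]) < 2 || sum(1 - h[, focal]) < 2) next
    cap <- sample(c(3L, 100L), 1)
    r <- nsl_raw(h, focal, maf_min = 0, max_extend = cap)
    o <- oracle_nsl(h, focal, max_extend = cap)
    expect_equal(r$raw, o$raw, tolerance = 1e-12)
  }
})

test_that("nsl_raw sign convention and symmetry behave as defined", {
  # mirror classes: identical haplotype sets in both classes give raw = 0
  block <- matrix(rbinom(4 * 11, 1, 0.5), 4, 11)
  haps <- rbind(block, block)
  haps[, 6] <- c(rep(0, 4), rep(1, 4))
  expect_equal(nsl_raw(haps, 6)$raw, 0)
  # homogeneous derived class, maximally diverse ancestral class: raw < 0
  derived <- matrix(rep(c(1, 0, 1, 0, 1, 1, 0, 1, 0), each = 4), 4, 9)
  derived[, 5] <- 1
  ancestral <- matrix(c(0, 0, 0, 0, 1, 1, 1, 0, 0,
                        1, 0, 1, 1, 0, 0, 1, 1, 0,
                        0, 1, 1, 0, 0, 0, 0, 0, 1,
                        1, 1, 0, 1, 1, 0, 1, 1, 1), 4, 9, byrow = TRUE)
  ancestral[, 5] <- 0
  expect_lt(nsl_raw(rbind(derived, ancestral), 5)$raw, 0)
  # guard rails: extreme frequency and tiny classes are skipped
  h <- matrix(rbinom(100, 1, 0.5), 10, 10)
  h[, 4] <- c(1, rep(0, 9)) # daf = 0.1
  expect_match(nsl_raw(h, 4, maf_min = 0.2)$skipped, "frequency")
  expect_match(nsl_raw(h, 4, maf_min = 0.05)$skipped, "carrier class")
})

test_that("nsl_scan recodes by ancestral allele and skips bad annotation", {
  set.seed(61)
  m <- 12; n <- 10
  haps <- matrix(rbinom(2 * n * m, 1, 0.5), 2 * n, m)
  aa <- rep(c("A", "G", "T"), 4) # ref, alt, mismatching
  gm <- genotype_matrix(paste0("v", 1:m), rep("1", m), seq_len(m) * 10,
                        rep("A", m), rep("G", m), haps, paste0("s", 1:n),
                        ancestral_allele = aa)
  expect_message(res <- nsl_scan(gm, maf_min = 0), "skipped 4")
  expect_true(all(is.na(res$raw[aa == "T"])))
  # where AA = alt, the derived allele is ref: daf is the ref frequency
  j <- which(aa == "G")[1]
  expect_equal(res$daf[j], mean(haps[, j] == 0))
  # where AA = ref, raw agrees with the derived-coded oracle
  j2 <- which(aa == "A")[1]
  if (is.finite(res$raw[j2]))
    expect_equal(res$raw[j2], oracle_nsl(haps, j2)$raw, tolerance = 1e-12)
})

test_that("nsl_normalize standardizes within frequency bins", {
  df <- data.frame(variant_id = c("a", "b"), daf = c(0.42, 0.44),
                   raw = c(-1, 1), zscore = NA, bin_id = NA)
  out <- nsl_normalize(df)
  expect_equal(out$zscore, c(-1, 1)) # population-sd standardization
  # bin assignment is floor(daf * n_bins): daf 0.049 lands in bin 0
  df2 <- data.frame(daf = c(0.049, 0.051, 0.999), raw = c(1, 2, 3))
  out2 <- nsl_normalize(df2, n_bins = 20)
  expect_identical(out2$bin_id, c(0L, 1L, 19L))
  # within every occupied bin: mean 0, population sd 1 (to 1e-9)
  set.seed(71)
  df3 <- data.frame(daf = runif(500), raw = rnorm(500))
  out3 <- nsl_normalize(df3)
  for (b in unique(out3$bin_id)) {
    z <- out3$zscore[out3$bin_id == b & !is.na(out3$zscore)]
    if (length(z) < 2) next
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-9)
  }
})

test_that("focal-site |nSL z| separates planted sweeps from matched nulls", {
  n_sweep <- 20; n_null <- 60
  run_one <- function(seed, plant) {
    sw <- simulate_sweep_region(sweep_config(
      n_haplotypes = 100, n_sites = 121, core_freq = 0.6, core_span = 81,
      plant_core = plant, seed = seed))
    nsl_raw(sw$haps, sw$focal)
  }
  sweeps <- lapply(seq_len(n_sweep), run_one, plant = TRUE)
  nulls <- lapply(1000 + seq_len(n_null), run_one, plant = FALSE)
  df <- data.frame(
    daf = vapply(c(sweeps, nulls), `[[`, 0, "daf"),
    raw = vapply(c(sweeps, nulls), `[[`, 0, "raw"))
  z <- nsl_normalize(df)$zscore
  z_sweep <- abs(z[seq_len(n_sweep)])
  z_null <- abs(z[-seq_len(n_sweep)])
  expect_gt(mean(z_sweep), quantile(z_null, 0.95))
})
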