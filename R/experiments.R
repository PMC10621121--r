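# Reproducible simulation studies over the full pipeline: calibration of
# the permutation index under neutrality, power against planted polygenic
# and sweep signals, estimator calibration for MR, and Bayes-factor
# separation for the environmental test. These are the package's own
# validation protocols; scripts/acceptance.R and the test suite both call
# them.

# One synthetic PBS study: gene/term architecture plus a Balding-Nichols
# three-population genotype simulation scored with Weir-Cockerham Fst and
# PBS (focal population = POP0).
simulate_pbs_study <- function(seed, n_genes = 4000L, n_terms = 100L,
                               drift = 0.05, sample_size = 60L) {
  arch <- simulate_gene_architecture(n_genes = n_genes, n_terms = n_terms,
                                     seed = derive_seed(seed, "architecture"))
  snp_ids <- unlist(arch$gene_map, use.names = FALSE)
  sim <- simulate_frequency_table(simulation_config(
    n_snps = length(snp_ids), n_pops = 3L, drift = drift,
    sample_sizes = sample_size, seed = derive_seed(seed, "frequencies")))
  colnames(sim$freqs) <- snp_ids
  g <- simulate_genotypes(sim$freqs, sample_size,
                          seed = derive_seed(seed, "genotypes"))
  f_ab <- fst_wc(g$gm, g$panel, "POP0", "POP1")
  f_ac <- fst_wc(g$gm, g$panel, "POP0", "POP2")
  f_bc <- fst_wc(g$gm, g$panel, "POP1", "POP2")
  pr <- pbs(f_ab, f_ac, f_bc, triplet = c("POP0", "POP1", "POP2"))
  list(arch = arch,
       pbs_values = stats::setNames(pr$pbs, pr$variant_id),
       positions = stats::setNames(g$gm$pos, g$gm$variant_ids))
}

#' Null calibration of the PBS selection index
#'
#' Simulates neutral (no-selection) studies and measures, per seed, the
#' fraction of genes whose selection index falls below the significance
#' threshold, a Kolmogorov-Smirnov uniformity p-value for the bin indices,
#' and the F-test p-value of the index-on-gene-size regression. Under
#' neutrality the per-gene index is a calibrated tail probability, so the
#' flagged fraction should sit near the threshold, bin indices should be
#' uniform, and gene size should not predict the index.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param n_genes,n_terms Architecture size per replicate.
#' @param n_perm Permutation iterations.
#' @param sig_threshold Per-gene significance threshold (default 0.01).
#' @param drift,sample_size Balding-Nichols drift and per-population
#'   diploid sample size.
#' @return A list with `per_seed` (data.frame: seed, frac_sig, ks_p,
#'   size_bias_p) and `bin_indices` (list of per-seed index vectors).
#' @export
experiment_null_calibration <- function(seeds = 1:10, n_genes = 4000L,
                                        n_terms = 100L, n_perm = 5000L,
                                        sig_threshold = 0.01, drift = 0.05,
                                        sample_size = 60L) {
  per_seed <- list(); bin_indices <- list()
  for (s in seeds) {
    st <- simulate_pbs_study(s, n_genes, n_terms, drift, sample_size)
    bins <- make_bins(st$arch$gene_map, st$positions)
    bi <- selection_index(bins, st$pbs_values, n_perm = n_perm,
                          seed = derive_seed(s, "permutation"))
    gi <- gene_index(bi, sig_threshold = sig_threshold)
    idx <- bi$index[is.finite(bi$index)]
    ks <- suppressWarnings(stats::ks.test(idx, "punif"))$p.value
    sb <- check_size_bias(gi)
    per_seed[[as.character(s)]] <- data.frame(
      seed = s, frac_sig = mean(gi$significant), ks_p = ks,
      size_bias_p = sb$f_p)
    bin_indices[[as.character(s)]] <- idx
  }
  list(per_seed = do.call(rbind, per_seed), bin_indices = bin_indices)
}

#' Power of the selection index against planted polygenic shifts
#'
#' Each replicate plants a polygenic signal by raising the PBS of every
#' SNP in the planted term's genes by `spike_sd` pooled standard
#' deviations, then runs the full polygenic scan (index, per-gene
#' aggregation, term filtering/pruning, proportion tests). Reported per
#' replicate: the fraction of planted genes flagged significant and
#' whether the planted term attains the smallest proportion-test p among
#' all surviving terms.
#'
#' @param n_reps Number of replicates.
#' @param spike_sd Spike size in pooled standard deviations of PBS.
#' @param n_genes,n_terms,n_perm,sig_threshold,drift,sample_size As in
#'   [experiment_null_calibration()].
#' @param seed0 Base seed; replicate r uses `seed0 + r`.
#' @return A data.frame with one row per replicate: `rep`, `sensitivity`,
#'   `planted_first`, `planted_p`.
#' @export
experiment_polygenic_power <- function(n_reps = 50L, spike_sd = 2,
                                       n_genes = 4000L, n_terms = 100L,
                                       n_perm = 5000L, sig_threshold = 0.01,
                                       drift = 0.05, sample_size = 60L,
                                       seed0 = 1000L) {
  rows <- list()
  for (r in seq_len(n_reps)) {
    st <- simulate_pbs_study(seed0 + r, n_genes, n_terms, drift, sample_size)
    arch <- st$arch
    vals <- st$pbs_values
    planted_snps <- unlist(arch$gene_map[arch$planted_genes],
                           use.names = FALSE)
    pool_sd <- stats::sd(vals[is.finite(vals)])
    vals[planted_snps] <- vals[planted_snps] + spike_sd * pool_sd
    bins <- make_bins(arch$gene_map, st$positions)
    bi <- selection_index(bins, vals, n_perm = n_perm,
                          seed = derive_seed(seed0 + r, "permutation"))
    gi <- gene_index(bi, sig_threshold = sig_threshold)
    sens <- mean(gi$significant[gi$gene %in% arch$planted_genes])
    terms <- prune_terms(filter_terms(arch$term_map, gi$gene))
    tt <- term_scan(terms, gi)
    planted_p <- tt$p[tt$term == arch$planted_term]
    first <- length(planted_p) == 1L && planted_p[1] == min(tt$p)
    rows[[r]] <- data.frame(rep = r, sensitivity = sens,
                            planted_first = first,
                            planted_p = if (length(planted_p)) planted_p[1]
                                        else NA_real_)
  }
  do.call(rbind, rows)
}

#' Power of the top-SNP nSL filter against planted sweeps
#'
#' Generates sweep regions alongside frequency-matched neutral regions
#' (same copying-mosaic background, no core haplotype), computes raw nSL
#' at every focal site, bin-normalizes all scores together, and applies
#' the top-SNP locus filter. Reported: the fraction of sweep loci retained
#' (sensitivity) and the fraction of neutral loci retained.
#'
#' @param n_sweeps,n_neutral Replicate counts for the two classes.
#' @param core_freq,n_haplotypes,n_sites,core_span Sweep generator
#'   settings.
#' @param threshold Normalized-score threshold (default 2).
#' @param seed0 Base seed.
#' @return A list with `sensitivity`, `neutral_rate` and the `locus_result`
#'   table.
#' @export
experiment_sweep_power <- function(n_sweeps = 50L, n_neutral = 450L,
                                   core_freq = 0.6, n_haplotypes = 200L,
                                   n_sites = 201L, core_span = 101L,
                                   threshold = 2, seed0 = 2000L) {
  run_one <- function(seed, plant) {
    sw <- simulate_sweep_region(sweep_config(
      n_haplotypes = n_haplotypes, n_sites = n_sites,
      core_freq = core_freq, core_span = core_span,
      plant_core = plant, seed = seed))
    nsl_raw(sw$haps, sw$focal)
  }
  res <- c(lapply(seq_len(n_sweeps), function(r) run_one(seed0 + r, TRUE)),
           lapply(seq_len(n_neutral),
                  function(r) run_one(seed0 + 5000L + r, FALSE)))
  ids <- sprintf("focal%03d", seq_along(res))
  nsl <- nsl_normalize(data.frame(
    variant_id = ids, pos = seq_along(ids) * 1000L,
    daf = vapply(res, `[[`, 0, "daf"), raw = vapply(res, `[[`, 0, "raw")))
  loci <- stats::setNames(as.list(ids), sub("focal", "locus", ids))
  gwas <- data.frame(rsid = ids, effect_allele = "G", other_allele = "A",
                     beta = -0.01, se = 0.005, p = 1e-8,
                     stringsAsFactors = FALSE)
  lr <- top_snp_nsl_filter(loci, gwas, nsl, threshold = threshold)
  is_sweep <- seq_along(res) <= n_sweeps
  list(sensitivity = mean(lr$retained[is_sweep]),
       neutral_rate = mean(lr$retained[!is_sweep]),
       loci = lr)
}

#' Calibration of the MR estimators on simulated instrument sets
#'
#' Simulates two-sample summary statistics with a known causal effect and
#' no directional pleiotropy, and measures the coverage of the IVW 95%
#' confidence interval and the type-I error of the Egger intercept test at
#' the 5% level.
#'
#' @param n_reps Number of simulated instrument sets.
#' @param n_instruments Instruments per set.
#' @param causal_beta True causal effect.
#' @param seed0 Base seed.
#' @return A list with `coverage`, `egger_type1`, and the per-replicate
#'   data.frame `per_rep`.
#' @export
experiment_mr_calibration <- function(n_reps = 500L, n_instruments = 50L,
                                      causal_beta = 0.2, seed0 = 3000L) {
  rows <- lapply(seq_len(n_reps), function(r) {
    s <- simulate_mr_instruments(mr_sim_config(
      n_instruments = n_instruments, causal_beta = causal_beta,
      pleiotropy_alpha = 0, seed = seed0 + r))
    instr <- harmonize(s$exposure, s$outcome)
    ivw <- mr_ivw(instr)
    eg <- mr_egger(instr)
    ci <- ivw$estimate + c(-1, 1) * stats::qnorm(0.975) * ivw$se
    data.frame(rep = r,
               covered = ci[1] <= causal_beta & causal_beta <= ci[2],
               egger_intercept_p = eg$p[eg$method == "Egger-intercept"])
  })
  per_rep <- do.call(rbind, rows)
  list(coverage = mean(per_rep$covered),
       egger_type1 = mean(per_rep$egger_intercept_p < 0.05),
       per_rep = per_rep)
}

#' Separation of environment-correlated SNPs by Bayes factor
#'
#' Each replicate simulates signal SNPs (true linear environmental effect)
#' and null SNPs under an identity population covariance, scans both with
#' [env_scan()] machinery, and records the one-sided Mann-Whitney p-value
#' for signal Bayes factors exceeding null Bayes factors.
#'
#' @param n_reps Number of replicates.
#' @param n_pops Number of populations.
#' @param beta_true Environmental effect for signal SNPs.
#' @param n_signal,n_null SNP counts per class.
#' @param seed0 Base seed.
#' @return A data.frame with `rep` and `mw_p`.
#' @export
experiment_env_separation <- function(n_reps = 20L, n_pops = 10L,
                                      beta_true = 0.25, n_signal = 500L,
                                      n_null = 500L, seed0 = 4000L) {
  env <- seq(8, 64, length.out = n_pops)
  env_std <- as.numeric(scale(env))
  rows <- lapply(seq_len(n_reps), function(r) {
    e <- simulate_env_correlated_freqs(diag(n_pops), env, beta_true,
                                       n_signal, n_null, seed = seed0 + r)
    y <- standardize_freqs(e$freqs)
    sig <- e$is_signal[match(colnames(y), colnames(e$freqs))]
    mod <- estimate_covariance(y[, !sig, drop = FALSE])
    bf <- apply(y, 2L, function(v) env_bayes_factor(v, env_std, mod)$bf)
    mw <- stats::wilcox.test(bf[sig], bf[!sig],
                             alternative = "greater")$p.value
    data.frame(rep = r, mw_p = mw)
  })
  do.call(rbind, rows)
}
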