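#' Configuration for Balding-Nichols frequency simulation
#'
#' Population allele frequencies diverge from a shared ancestral frequency
#' under pure drift: given ancestral frequency `p` and drift parameter `F`,
#' each population's frequency is an independent
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` draw, so `E(p_pop) = p` and
#' `Var(p_pop) = F p (1 - p)`.
#'
#' @param n_snps Number of SNPs.
#' @param n_pops Number of populations.
#' @param drift Drift parameter `F` in (0, 1); either a scalar or one value
#'   per population.
#' @param sample_sizes Diploid sample count per population (scalar or
#'   per-population), used by [simulate_genotypes()].
#' @param ancestral_freq_range Interval from which ancestral frequencies are
#'   drawn uniformly; must lie strictly inside (0, 1).
#' @param seed RNG seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_snps = 1000L, n_pops = 3L, drift = 0.05,
                              sample_sizes = 100L,
                              ancestral_freq_range = c(0.05, 0.95),
                              seed = 1L) {
  drift <- rep_len(drift, n_pops)
  sample_sizes <- rep_len(as.integer(sample_sizes), n_pops)
  stopifnot(n_snps >= 1L, n_pops >= 1L,
            all(drift > 0), all(drift < 1),
            all(sample_sizes >= 2L),
            length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] <= ancestral_freq_range[2])
  structure(list(n_snps = as.integer(n_snps), n_pops = as.integer(n_pops),
                 drift = drift, sample_sizes = sample_sizes,
                 ancestral_freq_range = ancestral_freq_range,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate per-population allele frequencies under Balding-Nichols drift
#'
#' @param cfg A [simulation_config()].
#' @return A list with `freqs` (an `n_pops` x `n_snps` matrix of
#'   alternate-allele frequencies, rows named `POP0..POPk`) and `p_anc` (the
#'   ancestral frequencies).
#' @export
simulate_frequency_table <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    p_anc <- stats::runif(cfg$n_snps, cfg$ancestral_freq_range[1],
                          cfg$ancestral_freq_range[2])
    freqs <- matrix(NA_real_, cfg$n_pops, cfg$n_snps)
    for (i in seq_len(cfg$n_pops)) {
      f <- cfg$drift[i]
      freqs[i, ] <- stats::rbeta(cfg$n_snps,
                                 p_anc * (1 - f) / f,
                                 (1 - p_anc) * (1 - f) / f)
    }
    rownames(freqs) <- paste0("POP", seq_len(cfg$n_pops) - 1L)
    colnames(freqs) <- paste0("snp", seq_len(cfg$n_snps))
    list(freqs = freqs, p_anc = p_anc)
  })
}

#' Shift allele frequencies of selected SNPs in one population
#'
#' Adds a signed offset to the frequencies of the named SNPs in the named
#' population, clipping the result to `[0.01, 0.99]`; all other entries are
#' untouched. This plants a directional frequency shift that PBS-based
#' statistics should detect.
#'
#' @param freqs Population-by-SNP frequency matrix.
#' @param snp_indices Column indices (or names) of the SNPs to shift.
#' @param target_pop Row name or index of the population under selection.
#' @param shift Signed frequency offset.
#' @return The shifted frequency matrix.
#' @export
spike_selection <- function(freqs, snp_indices, target_pop, shift) {
  stopifnot(is.matrix(freqs))
  shifted <- unname(freqs[target_pop, snp_indices] + shift)
  freqs[target_pop, snp_indices] <- pmax(pmin(shifted, 0.99), 0.01)
  freqs
}

#' Simulate phased genotypes from population allele frequencies
#'
#' Each haplotype allele is an independent Bernoulli draw with its
#' population's SNP frequency.
#'
#' @param freqs Population-by-SNP alternate-allele frequency matrix (rows
#'   named with population codes, or `POP0..` assumed).
#' @param sample_sizes Diploid sample count per population (scalar or one
#'   per population).
#' @param seed RNG seed.
#' @param chrom Chromosome label for the variant metadata.
#' @return A list with `gm` (a [genotype_matrix()]) and `panel` (a
#'   [population_panel()]).
#' @export
simulate_genotypes <- function(freqs, sample_sizes, seed = 1L, chrom = "1") {
  stopifnot(is.matrix(freqs), all(freqs >= 0), all(freqs <= 1))
  n_pops <- nrow(freqs); m <- ncol(freqs)
  pops <- rownames(freqs) %||% paste0("POP", seq_len(n_pops) - 1L)
  sample_sizes <- rep_len(as.integer(sample_sizes), n_pops)
  with_seed(seed, {
    haps <- matrix(NA_integer_, 2L * sum(sample_sizes), m)
    row0 <- 0L
    sample_ids <- character(0)
    sample_pops <- character(0)
    for (i in seq_len(n_pops)) {
      nh <- 2L * sample_sizes[i]
      draws <- matrix(stats::rbinom(nh * m, 1L, rep(freqs[i, ], each = nh)),
                      nrow = nh)
      haps[row0 + seq_len(nh), ] <- draws
      row0 <- row0 + nh
      ids <- sprintf("%s_S%03d", pops[i], seq_len(sample_sizes[i]))
      sample_ids <- c(sample_ids, ids)
      sample_pops <- c(sample_pops, rep(pops[i], sample_sizes[i]))
    }
    ids <- colnames(freqs) %||% paste0("snp", seq_len(m))
    gm <- genotype_matrix(ids, rep(chrom, m), seq_len(m) * 1000L,
                          rep("A", m), rep("G", m), haps, sample_ids,
                          ancestral_allele = rep("A", m), phased = TRUE)
    list(gm = gm,
         panel = population_panel(stats::setNames(sample_pops, sample_ids)))
  })
}

#' Configuration for the copying-mosaic sweep generator
#'
#' @param n_haplotypes Number of haplotypes in the sample.
#' @param n_sites Number of segregating sites.
#' @param core_freq Frequency `f_c` of the swept core haplotype; the focal
#'   site's derived allele is carried by exactly the core copies.
#' @param core_span Number of consecutive sites (centred on the focal site)
#'   over which core copies are identical.
#' @param mutation_rate Per-site probability that a core copy carries a
#'   private mutation inside the core span.
#' @param founder_count Number of founder haplotypes for the neutral copying
#'   background.
#' @param switch_rate Per-site probability that a background haplotype
#'   switches to a different founder template.
#' @param plant_core If `FALSE`, the core haplotype is not copied in: the
#'   region stays a neutral mosaic but the focal site's derived allele is
#'   still assigned to a random `core_freq` fraction of haplotypes, giving
#'   a frequency-matched neutral null for the sweep generator.
#' @param seed RNG seed.
#' @return A validated `sweep_config` list.
#' @export
sweep_config <- function(n_haplotypes = 200L, n_sites = 201L,
                         core_freq = 0.5, core_span = 101L,
                         mutation_rate = 0.02, founder_count = 12L,
                         switch_rate = 0.15, plant_core = TRUE, seed = 1L) {
  stopifnot(core_freq > 0, core_freq < 1,
            core_freq * n_haplotypes >= 2,
            core_span <= n_sites, core_span >= 1L,
            mutation_rate >= 0, mutation_rate < 1,
            founder_count >= 2L, switch_rate > 0, switch_rate <= 1)
  structure(list(n_haplotypes = as.integer(n_haplotypes),
                 n_sites = as.integer(n_sites),
                 core_freq = core_freq, core_span = as.integer(core_span),
                 mutation_rate = mutation_rate,
                 founder_count = as.integer(founder_count),
                 switch_rate = switch_rate,
                 plant_core = isTRUE(plant_core), seed = seed),
            class = "sweep_config")
}

#' Simulate a haplotype region carrying a partial selective sweep
#'
#' Background haplotypes are mosaics of `founder_count` random founder
#' haplotypes, switching template with probability `switch_rate` per site —
#' a crude stand-in for recombination that yields short identity tracts. A
#' fraction `core_freq` of haplotypes is then replaced, over `core_span`
#' sites centred on the focal site, by copies of a single core haplotype
#' (each perturbed by private mutations at `mutation_rate`), emulating the
#' long shared haplotype a sweep drags to high frequency. The focal site's
#' derived allele marks exactly the core copies.
#'
#' @param cfg A [sweep_config()].
#' @return A list with `haps` (0/1 matrix, ancestral = 0 at the focal site),
#'   `focal` (focal site index), `is_core` (logical truth labels per
#'   haplotype) and `positions` (site positions).
#' @export
simulate_sweep_region <- function(cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_haplotypes; m <- cfg$n_sites
    founders <- matrix(stats::rbinom(cfg$founder_count * m, 1L, 0.5),
                       nrow = cfg$founder_count)
    # mosaic background: per-haplotype founder path with geometric tracts
    haps <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      tmpl <- sample.int(cfg$founder_count, 1L)
      switches <- stats::runif(m) < cfg$switch_rate
      for (s in seq_len(m)) {
        if (switches[s]) tmpl <- sample.int(cfg$founder_count, 1L)
        haps[i, s] <- founders[tmpl, s]
      }
    }
    focal <- (m + 1L) %/% 2L
    half <- (cfg$core_span - 1L) %/% 2L
    span <- max(1L, focal - half):min(m, focal - half + cfg$core_span - 1L)
    n_core <- round(cfg$core_freq * n)
    core_rows <- sample.int(n, n_core)
    if (cfg$plant_core) {
      core_hap <- stats::rbinom(length(span), 1L, 0.5)
      for (i in core_rows) {
        copy <- core_hap
        mut <- stats::runif(length(span)) < cfg$mutation_rate
        copy[mut] <- 1L - copy[mut]
        haps[i, span] <- copy
      }
    }
    # focal site: derived allele (1) on exactly the core copies
    haps[, focal] <- 0L
    haps[core_rows, focal] <- 1L
    is_core <- seq_len(n) %in% core_rows
    list(haps = haps, focal = focal, is_core = is_core,
         positions = seq_len(m) * 100L)
  })
}

#' Simulate a gene/term architecture with a planted selected term
#'
#' Gene sizes (SNPs per gene) are drawn from a shifted negative binomial
#' tuned so the modal size is 11, mimicking the skewed SNP-count
#' distribution of annotated trait genes. Terms sample genes at random; one
#' planted term's genes are flagged as truth labels for selection spiking.
#'
#' @param n_genes Number of genes.
#' @param n_terms Number of terms.
#' @param genes_per_term Interval from which each term's gene count is drawn
#'   uniformly.
#' @param planted_term_size Gene count of the planted (selected) term.
#' @param seed RNG seed.
#' @return A list with `gene_map` ([gene_map()]), `term_map` ([term_map()]),
#'   `planted_term` (its id), `planted_genes` (character vector) and
#'   `gene_sizes` (named integer vector).
#' @export
simulate_gene_architecture <- function(n_genes = 4000L, n_terms = 100L,
                                       genes_per_term = c(10L, 30L),
                                       planted_term_size = 24L, seed = 1L) {
  stopifnot(n_genes >= 10L, n_terms >= 2L, planted_term_size >= 2L)
  with_seed(seed, {
    # skewed mixture with a decisive mode at 11: a 12% point mass at the
    # modal size on top of 2 + NB(size 20, prob 2/3), whose own mode
    # (r-1)(1-p)/p = 9.5 also shifts to 11; mean ~11.9, long right tail
    sizes <- 2L + stats::rnbinom(n_genes, size = 20, prob = 2 / 3)
    at_mode <- stats::runif(n_genes) < 0.12
    sizes[at_mode] <- 11L
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    names(sizes) <- genes
    snp_counter <- 0L
    g2s <- lapply(seq_len(n_genes), function(i) {
      ids <- sprintf("rs%07d", snp_counter + seq_len(sizes[i]))
      snp_counter <<- snp_counter + sizes[i]
      ids
    })
    names(g2s) <- genes
    planted_genes <- sample(genes, planted_term_size)
    t2g <- vector("list", n_terms)
    names(t2g) <- sprintf("TERM%03d", seq_len(n_terms))
    t2g[[1L]] <- planted_genes
    for (t in 2L:n_terms) {
      k <- sample(genes_per_term[1]:genes_per_term[2], 1L)
      t2g[[t]] <- sample(genes, k)
    }
    list(gene_map = gene_map(g2s), term_map = term_map(t2g),
         planted_term = names(t2g)[1L], planted_genes = planted_genes,
         gene_sizes = sizes)
  })
}

#' Simulate environmentally correlated population allele frequencies
#'
#' Standardized frequency vectors are drawn from a multivariate normal with
#' population covariance `omega`; for the first `n_signal` SNPs a linear
#' environmental effect `beta_true * env` (env z-standardized across
#' populations) is added. Vectors are back-transformed to frequencies around
#' a random baseline and clipped to (0, 1).
#'
#' @param omega L x L population covariance matrix of standardized
#'   frequencies.
#' @param env Numeric environmental value per population (length L).
#' @param beta_true Environmental effect on the standardized scale.
#' @param n_signal,n_null Counts of signal and null SNPs.
#' @param seed RNG seed.
#' @return A list with `freqs` (L x (n_signal + n_null) frequency matrix),
#'   `is_signal` (logical per SNP) and `env_std` (the standardized
#'   environment).
#' @export
simulate_env_correlated_freqs <- function(omega, env, beta_true,
                                          n_signal, n_null, seed = 1L) {
  stopifnot(is.matrix(omega), nrow(omega) == ncol(omega),
            length(env) == nrow(omega), n_signal >= 0L, n_null >= 0L)
  L <- nrow(omega)
  m <- n_signal + n_null
  env_std <- as.numeric(scale(env))
  with_seed(seed, {
    R <- chol(omega)
    z <- matrix(stats::rnorm(L * m), L, m)
    y <- t(R) %*% z
    if (n_signal > 0L)
      y[, seq_len(n_signal)] <- y[, seq_len(n_signal)] + beta_true * env_std
    p_bar <- stats::runif(m, 0.25, 0.75)
    freqs <- sweep(y, 2L, sqrt(p_bar * (1 - p_bar)) / 2, `*`)
    freqs <- sweep(freqs, 2L, p_bar, `+`)
    freqs <- pmax(pmin(freqs, 0.999), 0.001)
    rownames(freqs) <- rownames(omega) %||% paste0("POP", seq_len(L) - 1L)
    colnames(freqs) <- paste0("snp", seq_len(m))
    list(freqs = freqs,
         is_signal = seq_len(m) <= n_signal,
         env_std = env_std)
  })
}

#' Configuration for simulated Mendelian-randomization instruments
#'
#' @param n_instruments Number of instruments (>= 3).
#' @param causal_beta True causal effect of the exposure on the outcome.
#' @param pleiotropy_alpha Directional pleiotropy intercept added to every
#'   outcome effect.
#' @param beta_x_range Interval of instrument strengths (exposure effects).
#' @param se_x,se_y Standard-error scales of the exposure and outcome
#'   effect estimates.
#' @param flip_fraction Fraction of outcome records whose alleles are
#'   swapped (with the outcome beta negated) to exercise harmonization.
#' @param palindromic_fraction Fraction of instruments given A/T or C/G
#'   alleles, which harmonization must drop.
#' @param seed RNG seed.
#' @return A validated `mr_sim_config` list.
#' @export
mr_sim_config <- function(n_instruments = 50L, causal_beta = 0.2,
                          pleiotropy_alpha = 0, beta_x_range = c(0.05, 0.3),
                          se_x = 0.01, se_y = 0.05, flip_fraction = 0,
                          palindromic_fraction = 0, seed = 1L) {
  stopifnot(n_instruments >= 3L, se_x > 0, se_y > 0,
            flip_fraction >= 0, flip_fraction <= 1,
            palindromic_fraction >= 0, palindromic_fraction < 1)
  structure(list(n_instruments = as.integer(n_instruments),
                 causal_beta = causal_beta,
                 pleiotropy_alpha = pleiotropy_alpha,
                 beta_x_range = beta_x_range, se_x = se_x, se_y = se_y,
                 flip_fraction = flip_fraction,
                 palindromic_fraction = palindromic_fraction, seed = seed),
            class = "mr_sim_config")
}

#' Simulate exposure and outcome summary statistics for two-sample MR
#'
#' Exposure effects are uniform on `beta_x_range`; outcome effects follow
#' `beta_y = pleiotropy_alpha + causal_beta * beta_x + N(0, se_y^2)`, with
#' reported standard errors equal to the generating scales. Estimation error
#' `N(0, se_x^2)` is added to the reported exposure effects. A configurable
#' fraction of outcome rows has its alleles swapped (beta negated) and a
#' fraction of instruments is made palindromic, so harmonization is
#' exercised.
#'
#' @param cfg An [mr_sim_config()].
#' @return A list with `exposure` and `outcome` GWAS record data.frames and
#'   `truth` (the generating parameters plus per-instrument latent effects).
#' @export
simulate_mr_instruments <- function(cfg) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_instruments
    rsid <- sprintf("rs%06d", seq_len(n))
    bx_true <- stats::runif(n, cfg$beta_x_range[1], cfg$beta_x_range[2])
    by_true <- cfg$pleiotropy_alpha + cfg$causal_beta * bx_true
    bx_hat <- bx_true + stats::rnorm(n, 0, cfg$se_x)
    by_hat <- by_true + stats::rnorm(n, 0, cfg$se_y)
    n_pal <- round(cfg$palindromic_fraction * n)
    pal <- seq_len(n) <= n_pal
    a1 <- ifelse(pal, "A", "A")
    a2 <- ifelse(pal, "T", "G")
    p_from <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)), 1e-300)
    exposure <- data.frame(rsid = rsid, effect_allele = a1, other_allele = a2,
                           beta = bx_hat, se = rep(cfg$se_x, n),
                           p = p_from(bx_hat, cfg$se_x),
                           stringsAsFactors = FALSE)
    outcome <- data.frame(rsid = rsid, effect_allele = a1, other_allele = a2,
                          beta = by_hat, se = rep(cfg$se_y, n),
                          p = p_from(by_hat, cfg$se_y),
                          stringsAsFactors = FALSE)
    flip <- stats::runif(n) < cfg$flip_fraction
    outcome$effect_allele[flip] <- a2[flip]
    outcome$other_allele[flip] <- a1[flip]
    outcome$beta[flip] <- -outcome$beta[flip]
    list(exposure = exposure, outcome = outcome,
         truth = list(causal_beta = cfg$causal_beta,
                      pleiotropy_alpha = cfg$pleiotropy_alpha,
                      beta_x = bx_true, beta_y = by_true,
                      flipped = flip, palindromic = pal))
  })
}
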