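#' Default pipeline configuration
#'
#' Central home for every stage's tunables: the sweep-cascade constants
#' (PBS quantile 0.99, GWAS threshold 5e-3, |nSL| threshold 2, LD r2 0.1),
#' the polygenic-scan constants (window 11, 100,000 permutations,
#' significance 0.01, tree cut 0.5), the environmental-test constants
#' (prior bound 0.3, 201 grid points, shrinkage 0.05), and the simulation
#' sizes used by the synthetic smoke test.
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pbs_quantile = 0.99, gwas_p_max = 5e-3, nsl_abs_min = 2,
    ld_r2_max = 0.1, clump_window_kb = 500,
    window_size = 11L, n_perm = 1e5L, sig_threshold = 0.01,
    cut_height = 0.5,
    beta_bound = 0.3, grid_points = 201L, shrinkage = 0.05,
    sim_n_genes = 400L, sim_n_terms = 40L, sim_n_pops = 3L,
    sim_drift = 0.05, sim_sample_size = 60L,
    seed = 1L, out_dir = "adaptscan-run")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      cfg$seed != round(cfg$seed))
    stop("config field 'seed' must be a single integer")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path) %||% list())
}

config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")] # hash the analysis, not paths
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), ""), sep = "=", collapse = ";")
  format(sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 1e8, scientific = FALSE)
}

stage_log <- function(log_path, stage, ...) {
  msg <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                 paste(sprintf(...), collapse = " "))
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

output_header <- function(cfg) {
  sprintf("adaptscan %s | config %s | seed %d",
          as.character(utils::packageVersion("adaptscan")),
          config_hash(cfg), as.integer(cfg$seed))
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates a synthetic study with planted truth (drifting populations, a
#' spiked focal population, gene/term architecture, environment-correlated
#' SNPs, simulated instruments) and runs every analysis stage on it:
#' per-SNP PBS, the sweep filter cascade, the polygenic PBS selection
#' index scan, the environmental Bayes-factor scan, and two-sample MR. All
#' tables are written as TSV under `out_dir`, each with a header comment
#' carrying the package version, a config hash, and the seed.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if absent); defaults to the
#'   config's `out_dir`.
#' @return Invisibly, a list with the stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  hdr <- output_header(config)
  seed <- as.integer(config$seed)

  # --- simulate ---------------------------------------------------------
  arch <- simulate_gene_architecture(n_genes = config$sim_n_genes,
                                     n_terms = config$sim_n_terms,
                                     seed = derive_seed(seed, "architecture"))
  snp_ids <- unlist(arch$gene_map, use.names = FALSE)
  m <- length(snp_ids)
  sim <- simulate_frequency_table(simulation_config(
    n_snps = m, n_pops = config$sim_n_pops, drift = config$sim_drift,
    sample_sizes = config$sim_sample_size,
    seed = derive_seed(seed, "frequencies")))
  planted_snps <- which(snp_ids %in%
                          unlist(arch$gene_map[arch$planted_genes]))
  freqs <- spike_selection(sim$freqs, planted_snps, 1L, +0.25)
  colnames(freqs) <- snp_ids
  geno <- simulate_genotypes(freqs, config$sim_sample_size,
                             seed = derive_seed(seed, "genotypes"))
  geno$gm$variant_ids <- snp_ids
  stage_log(log_path, "simulate", "%d SNPs, %d genes, %d terms, seed %d",
            m, config$sim_n_genes, config$sim_n_terms, seed)

  # --- selection statistics --------------------------------------------
  pops <- rownames(freqs)
  f_ab <- fst_wc(geno$gm, geno$panel, pops[1], pops[2])
  f_ac <- fst_wc(geno$gm, geno$panel, pops[1], pops[3])
  f_bc <- fst_wc(geno$gm, geno$panel, pops[2], pops[3])
  pbs_res <- pbs(f_ab, f_ac, f_bc, triplet = pops[1:3])
  write_stats_tsv(pbs_res, file.path(out_dir, "pbs.tsv"), hdr)
  stage_log(log_path, "selection_stats", "PBS for %d SNPs (%s)",
            nrow(pbs_res), paste(pops[1:3], collapse = "-"))

  # --- polygenic scan ---------------------------------------------------
  positions <- stats::setNames(geno$gm$pos, geno$gm$variant_ids)
  pbs_values <- stats::setNames(pbs_res$pbs, pbs_res$variant_id)
  poly <- polygenic_scan(arch$gene_map, positions, pbs_values,
                         arch$term_map, window = config$window_size,
                         n_perm = config$n_perm,
                         sig_threshold = config$sig_threshold,
                         cut_height = config$cut_height,
                         seed = derive_seed(seed, "permutation"))
  write_stats_tsv(poly$bin_index, file.path(out_dir, "bin_index.tsv"), hdr)
  write_stats_tsv(poly$gene_index, file.path(out_dir, "gene_index.tsv"), hdr)
  write_stats_tsv(poly$term_tests, file.path(out_dir, "term_tests.tsv"), hdr)
  stage_log(log_path, "polygenic_scan",
            "%d bins, %d/%d significant genes, top term %s",
            nrow(poly$bin_index), sum(poly$gene_index$significant),
            nrow(poly$gene_index), poly$term_tests$term[1])

  # --- environmental scan ----------------------------------------------
  L <- 8L
  env <- data.frame(latitude = seq(5, 65, length.out = L))
  rownames(env) <- paste0("POP", seq_len(L) - 1L)
  class(env) <- c("env_table", "data.frame")
  envsim <- simulate_env_correlated_freqs(diag(L), env$latitude,
                                          beta_true = 0.25,
                                          n_signal = 40L, n_null = 160L,
                                          seed = derive_seed(seed, "env"))
  scan <- env_scan(envsim$freqs, env,
                   control_snps = colnames(envsim$freqs)[!envsim$is_signal],
                   shrinkage = config$shrinkage,
                   beta_bound = config$beta_bound,
                   grid_points = config$grid_points)
  write_stats_tsv(scan, file.path(out_dir, "env_bf.tsv"), hdr)
  stage_log(log_path, "env_scan", "%d SNP x env Bayes factors", nrow(scan))

  # --- Mendelian randomization -----------------------------------------
  mrsim <- simulate_mr_instruments(mr_sim_config(
    n_instruments = 50L, causal_beta = 0.2, flip_fraction = 0.3,
    seed = derive_seed(seed, "mr")))
  mr_res <- mr_analysis(mrsim$exposure, mrsim$outcome)
  write_stats_tsv(mr_res$estimates, file.path(out_dir, "mr_estimates.tsv"),
                  hdr)
  write_stats_tsv(mr_res$loo, file.path(out_dir, "mr_leave_one_out.tsv"),
                  hdr)
  stage_log(log_path, "mr", "IVW %.3f (true 0.2), Egger intercept p %.3f",
            mr_res$estimates$estimate[1], mr_res$estimates$p[3])

  invisible(list(architecture = arch, pbs = pbs_res, polygenic = poly,
                 env = scan, mr = mr_res, config = config))
}
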