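# adaptscan

Selection scans and polygenic-adaptation tests for multi-population
variant data.

`adaptscan` is for population geneticists who want to ask, end to end,
whether the loci underlying a complex trait show signatures of local
adaptation — the motivating case being trait loci whose frequencies may
track an environmental gradient such as sunlight exposure. It combines
four analyses that are usually scattered across separate tools:

1. **Per-SNP sweep statistics.** Weir–Cockerham Fst
   (`theta = a / (a + b + c)` from per-SNP variance components), the
   population branch statistic for a triplet (A, B, C) with focal
   population A,

   ```
   T = -ln(1 - Fst),   PBS_A = (T_AB + T_AC - T_BC) / 2,
   ```

   and the haplotype statistic nSL, `ln(SL_A / SL_D)`, comparing mean
   pairwise identity-tract lengths (counted in segregating sites) between
   ancestral- and derived-allele carriers, normalized within
   derived-allele-frequency bins. A filter cascade (LD clumping at
   r² < 0.1, intersection of 99th-percentile PBS outliers across
   triplets, GWAS `p < 5e-3`, and an inclusive `|nSL| >= 2` rule at each
   locus top SNP) distils candidate sweep loci, followed by
   hypergeometric gene-set enrichment with BH correction.

2. **The PBS selection index** for polygenic adaptation: genes are binned
   into windows of 11 SNPs (the modal gene size), and each bin's index is
   the permutation tail probability

   ```
   index = (1 + #{random k-SNP sets with mean PBS >= observed}) / (1 + n_perm)
   ```

   (100,000 iterations by default), FDR-adjusted across bins; the
   per-gene index is the mean over bins, significant below 0.01. Term
   maps are median-filtered and Ward-pruned, and each term is tested with
   a one-sided pooled-variance two-sample proportion test for an excess
   of significant genes.

3. **Gene–environment Bayes factors**: standardized population allele
   frequencies are modelled as multivariate normal with a covariance
   estimated from control SNPs; the Bayes factor integrates a linear
   environmental effect over a uniform grid against the covariance-only
   null.

4. **Two-sample Mendelian randomization**: allele harmonization
   (palindromes dropped, swapped alleles sign-flipped), fixed-effect IVW,
   MR-Egger with the intercept t-test for directional pleiotropy, and
   leave-one-out sensitivity analysis.

A first-class synthetic-data module (Balding–Nichols frequency
divergence, copying-mosaic sweep haplotypes, gene/term architectures with
a planted selected term, environment-correlated frequencies, simulated
instrument sets) provides known ground truth for every stage, so the
pipeline is testable with no downloads.

## Worked example

Simulate a 300-gene study in which the genes of one term carry a planted
+0.3 frequency shift in the focal population, score every SNP with PBS,
and run the polygenic scan:

```r
library(adaptscan)

arch <- simulate_gene_architecture(n_genes = 300, n_terms = 30, seed = 42)
snp_ids <- unlist(arch$gene_map, use.names = FALSE)
sim <- simulate_frequency_table(simulation_config(
  n_snps = length(snp_ids), n_pops = 3, drift = 0.05,
  sample_sizes = 60, seed = 43))
colnames(sim$freqs) <- snp_ids
planted <- which(snp_ids %in% unlist(arch$gene_map[arch$planted_genes]))
freqs <- spike_selection(sim$freqs, planted, "POP0", +0.3)
g <- simulate_genotypes(freqs, 60, seed = 44)

pr <- pbs(fst_wc(g$gm, g$panel, "POP0", "POP1"),
          fst_wc(g$gm, g$panel, "POP0", "POP2"),
          fst_wc(g$gm, g$panel, "POP1", "POP2"),
          triplet = c("POP0", "POP1", "POP2"))
head(pr, 3)
#>   variant_id          pbs        t_ab       t_ac       t_bc
#> 1  rs0000001  0.090625974 0.048261078 0.15350151 0.02051064
#> 2  rs0000002 -0.008625485 0.009452596 0.00000000 0.02670357
#> 3  rs0000003  0.011066114 0.000000000 0.02213223 0.00000000

scan <- polygenic_scan(arch$gene_map,
                       setNames(g$gm$pos, g$gm$variant_ids),
                       setNames(pr$pbs, pr$variant_id),
                       arch$term_map, n_perm = 10000, seed = 45)
sum(scan$gene_index$significant)
#> [1] 20
head(scan$term_tests[, c("term", "n_term", "k_term", "z", "p")], 2)
#>     term n_term k_term         z            p
#>  TERM001     22     20 16.372249 1.509249e-60
#>  TERM020     18      4  2.705299 3.412143e-03
scan$size_bias
#> $slope        [1] -0.00156039
#> $adj_r_squared [1] -0.00294978
#> $f_p          [1] 0.7192778
```

The planted term (`TERM001`; 20 of its 22 scored genes flagged) tops the
proportion-test ranking by fifty orders of magnitude, while the
index-on-gene-size regression is flat (p = 0.72): the binning scheme
removed the size confound. Per-SNP PBS is positive where the focal branch
carries the frequency shift (`t_ab`, `t_ac` large, `t_bc` small).

Real data enter through `read_vcf()` (phased VCF with `AA` ancestral
annotation), `read_panel()`, `read_gwas_table()`, `read_gene_map()`,
`read_term_map()` and `read_env_table()`; `run_pipeline()` executes the
synthetic end-to-end smoke test, and `inst/cli/adaptscan.R` wraps it for
the shell.

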