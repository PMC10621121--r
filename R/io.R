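#' Read phased biallelic SNPs from a VCF file
#'
#' Parses a (possibly gzipped) VCF into a [genotype_matrix()]. Multi-allelic
#' records and records whose REF or ALT is not a single nucleotide are
#' dropped, with a message reporting the count. The ancestral allele is taken
#' from the `AA` INFO key when present (first character, upper-cased).
#'
#' @param path Path to a VCF (v4.x) file, plain or gzipped.
#' @param region Optional region string `"chrom:start-end"` (1-based,
#'   inclusive at both ends).
#' @param samples Optional character vector of sample ids to retain.
#' @param require_phased If `TRUE` (default), any unphased genotype raises a
#'   validation error naming the first offending record; haplotype statistics
#'   are meaningless on unphased data.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL, samples = NULL,
                     require_phased = TRUE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF contains no records: ", path)

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    parts <- regmatches(region,
                        regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(parts) != 4L) stop("malformed region string: ", region)
    pos <- as.integer(fix[, "POS"])
    keep <- keep & fix[, "CHROM"] == parts[2] &
      pos >= as.integer(parts[3]) & pos <= as.integer(parts[4])
  }
  snp <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_dropped <- sum(keep & !snp)
  if (n_dropped > 0L)
    message("read_vcf: dropped ", n_dropped,
            " multi-allelic or non-SNP record(s)")
  keep <- keep & snp

  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNPs left after filtering")
  gt <- vcf@gt[keep, , drop = FALSE]
  all_samples <- colnames(gt)[-1L]
  if (is.null(samples)) samples <- all_samples
  si <- match(samples, all_samples)
  if (anyNA(si)) stop("samples absent from VCF: ",
                      paste(samples[is.na(si)], collapse = ", "))
  gt <- gt[, c(1L, si + 1L), drop = FALSE]

  # GT is always the leading FORMAT field per VCF spec
  gt_only <- matrix(sub(":.*$", "", gt[, -1L, drop = FALSE]),
                    nrow = nrow(fix))
  unphased <- matrix(grepl("/", gt_only, fixed = TRUE), nrow = nrow(fix))
  if (any(unphased)) {
    if (require_phased) {
      first <- which(unphased, arr.ind = TRUE)[1L, ]
      stop("unphased genotype at record ", fix[first[1L], "ID"],
           " (", fix[first[1L], "CHROM"], ":", fix[first[1L], "POS"],
           "), sample ", samples[first[2L]],
           "; haplotype statistics require phased data")
    }
    gt_only <- gsub("/", "|", gt_only, fixed = TRUE)
  }

  a1 <- substr(gt_only, 1L, 1L)
  a2 <- substr(gt_only, 3L, 3L)
  to_int <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out[!x %in% c("0", "1")] <- NA_integer_
    out
  }
  m <- nrow(fix); n <- length(samples)
  haps <- matrix(NA_integer_, nrow = 2L * n, ncol = m)
  haps[seq(1L, 2L * n, by = 2L), ] <- t(matrix(to_int(a1), nrow = m))
  haps[seq(2L, 2L * n, by = 2L), ] <- t(matrix(to_int(a2), nrow = m))

  info <- fix[, "INFO"]
  aa <- rep(NA_character_, m)
  has_aa <- grepl("(^|;)AA=", info)
  aa[has_aa] <- toupper(substr(sub("^.*(^|;)AA=", "", info[has_aa]), 1L, 1L))
  aa[!aa %in% c("A", "C", "G", "T")] <- NA_character_

  ids <- fix[, "ID"]
  miss <- is.na(ids) | ids == "."
  ids[miss] <- paste0(fix[miss, "CHROM"], ":", fix[miss, "POS"])

  genotype_matrix(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                  fix[, "REF"], fix[, "ALT"], haps, samples,
                  ancestral_allele = aa, phased = TRUE)
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCF v4.2 file with phased GT fields and the ancestral
#' allele in the `AA` INFO key, in the dialect [read_vcf()] expects; a
#' `write_vcf` then `read_vcf` round trip reproduces the haplotypes exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  validate_genotype_matrix(gm)
  n <- length(gm$sample_ids); m <- length(gm$variant_ids)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")), con)
  odd <- seq(1L, 2L * n, by = 2L)
  for (j in seq_len(m)) {
    h1 <- gm$haplotypes[odd, j]
    h2 <- gm$haplotypes[odd + 1L, j]
    gt <- paste(ifelse(is.na(h1), ".", h1), ifelse(is.na(h2), ".", h2),
                sep = "|")
    info <- if (is.na(gm$ancestral_allele[j])) "."
            else paste0("AA=", gm$ancestral_allele[j])
    writeLines(paste(c(gm$chrom[j], gm$pos[j], gm$variant_ids[j],
                       gm$ref_allele[j], gm$alt_allele[j], ".", "PASS",
                       info, "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample-to-population panel
#'
#' Accepts the 1000 Genomes style panel layout: a header line followed by
#' whitespace- or tab-delimited columns `sample`, `pop`, `super_pop`
#' (additional columns are ignored).
#'
#' @param path Path to the panel file.
#' @return A `population_panel`: list with `sample_to_pop` and
#'   `pop_to_superpop` named character vectors.
#' @export
read_panel <- function(path) {
  df <- read_delim_sniffed(path)
  need <- c("sample", "pop")
  if (!all(need %in% names(df)))
    stop("panel must contain columns 'sample' and 'pop'")
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s) in panel: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  if (any(!nzchar(df$pop)) || anyNA(df$pop))
    stop("empty population code in panel")
  population_panel(stats::setNames(as.character(df$pop),
                                   as.character(df$sample)),
                   if ("super_pop" %in% names(df))
                     stats::setNames(as.character(df$super_pop),
                                     as.character(df$pop))[
                       !duplicated(df$pop)]
                   else NULL)
}

#' Construct a population panel
#'
#' @param sample_to_pop Named character vector mapping sample id to
#'   population code.
#' @param pop_to_superpop Optional named character vector mapping population
#'   code to super-population code.
#' @return A `population_panel` object.
#' @export
population_panel <- function(sample_to_pop, pop_to_superpop = NULL) {
  stopifnot(!is.null(names(sample_to_pop)), all(nzchar(sample_to_pop)))
  if (anyDuplicated(names(sample_to_pop)))
    stop("every sample must map to exactly one population")
  structure(list(sample_to_pop = sample_to_pop,
                 pop_to_superpop = pop_to_superpop),
            class = "population_panel")
}

#' Samples belonging to one or more populations (or super-populations)
#'
#' @param panel A `population_panel`.
#' @param pops Character vector of population or super-population codes.
#' @return Character vector of sample ids.
#' @export
panel_samples <- function(panel, pops) {
  hit <- panel$sample_to_pop %in% pops
  if (!is.null(panel$pop_to_superpop)) {
    sp <- panel$pop_to_superpop[panel$sample_to_pop]
    hit <- hit | (!is.na(sp) & sp %in% pops)
  }
  if (!any(hit)) stop("no samples found for population(s): ",
                      paste(pops, collapse = ", "))
  names(panel$sample_to_pop)[hit]
}

#' @export
print.population_panel <- function(x, ...) {
  cat(sprintf("population_panel: %d samples, %d populations\n",
              length(x$sample_to_pop), length(unique(x$sample_to_pop))))
  print(table(x$sample_to_pop))
  invisible(x)
}

#' Write a population panel
#' @param panel A `population_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  sp <- if (!is.null(panel$pop_to_superpop))
    panel$pop_to_superpop[panel$sample_to_pop] else panel$sample_to_pop
  utils::write.table(
    data.frame(sample = names(panel$sample_to_pop),
               pop = unname(panel$sample_to_pop),
               super_pop = unname(sp)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Reads a delimited summary-statistics table and maps its columns onto the
#' canonical fields `rsid`, `effect_allele` (A1), `other_allele` (A2),
#' `beta`, `se`, `p`. Rows violating the record invariants (p outside
#' `(0, 1]`, non-positive standard error, identical alleles) raise a
#' validation error naming the offending line numbers.
#'
#' @param path Path to a TSV/CSV file with a header.
#' @param column_map Named character vector mapping canonical field names to
#'   column names in the file, e.g. `c(rsid = "SNP", effect_allele = "A1",
#'   other_allele = "A2", beta = "BETA", se = "SE", p = "P")`. Defaults to
#'   the canonical names themselves.
#' @return A data.frame with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `p`.
#' @export
read_gwas_table <- function(path, column_map = NULL) {
  canonical <- c("rsid", "effect_allele", "other_allele", "beta", "se", "p")
  column_map <- column_map %||% stats::setNames(canonical, canonical)
  if (!all(canonical %in% names(column_map)))
    stop("column_map must name: ", paste(canonical, collapse = ", "))
  df <- read_delim_sniffed(path)
  missing_cols <- setdiff(unname(column_map[canonical]), names(df))
  if (length(missing_cols))
    stop("columns absent from GWAS table: ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    rsid = as.character(df[[column_map[["rsid"]]]]),
    effect_allele = toupper(as.character(df[[column_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(df[[column_map[["other_allele"]]]])),
    beta = as.numeric(df[[column_map[["beta"]]]]),
    se = as.numeric(df[[column_map[["se"]]]]),
    p = as.numeric(df[[column_map[["p"]]]]),
    stringsAsFactors = FALSE)
  validate_gwas_records(out)
  out
}

validate_gwas_records <- function(records) {
  bad <- which(!is.finite(records$p) | records$p <= 0 | records$p > 1)
  if (length(bad))
    stop("GWAS p-value outside (0, 1] at data line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  bad <- which(!is.finite(records$se) | records$se <= 0)
  if (length(bad))
    stop("non-positive GWAS standard error at data line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  bad <- which(records$effect_allele == records$other_allele)
  if (length(bad))
    stop("identical effect and other allele at data line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  if (anyDuplicated(records$rsid))
    stop("duplicate rsid(s) in GWAS table: ",
         paste(unique(records$rsid[duplicated(records$rsid)]), collapse = ", "))
  invisible(records)
}

#' Write GWAS summary statistics
#' @param records GWAS record data.frame (see [read_gwas_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-SNP map
#'
#' Long-format table with columns `gene` and `snp`, one row per assignment.
#'
#' @param path Path to a TSV/CSV file with a header.
#' @return A named list mapping gene symbol to a character vector of SNP ids
#'   (class `gene_map`).
#' @export
read_gene_map <- function(path) {
  df <- read_delim_sniffed(path)
  if (!all(c("gene", "snp") %in% names(df)))
    stop("gene map must contain columns 'gene' and 'snp'")
  key <- paste(df$gene, df$snp, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate gene/snp pair at data line(s): ",
         paste(which(duplicated(key)) + 1L, collapse = ", "))
  gene_map(split(as.character(df$snp), as.character(df$gene)))
}

#' Construct/validate a gene map
#' @param gene_to_snps Named list: gene symbol -> character vector of SNP ids.
#' @return The validated list with class `gene_map`.
#' @export
gene_map <- function(gene_to_snps) {
  if (any(lengths(gene_to_snps) == 0L)) stop("gene with empty SNP set")
  if (any(vapply(gene_to_snps, anyDuplicated, 1L) > 0L))
    stop("duplicate SNP ids within a gene")
  structure(gene_to_snps, class = "gene_map")
}

#' Write a gene map
#' @param map A `gene_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  utils::write.table(
    data.frame(gene = rep(names(map), lengths(map)),
               snp = unlist(map, use.names = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a term-to-gene map
#'
#' Long-format table with columns `term` and `gene`, plus an optional `name`
#' column carrying a human-readable term label.
#'
#' @param path Path to a TSV/CSV file with a header.
#' @return A `term_map`: list with `term_to_genes` (named list of gene sets)
#'   and `term_name` (named character vector).
#' @export
read_term_map <- function(path) {
  df <- read_delim_sniffed(path)
  if (!all(c("term", "gene") %in% names(df)))
    stop("term map must contain columns 'term' and 'gene'")
  t2g <- lapply(split(as.character(df$gene), as.character(df$term)), unique)
  nm <- if ("name" %in% names(df))
    vapply(split(as.character(df$name), as.character(df$term)), `[`, "", 1L)
  else stats::setNames(names(t2g), names(t2g))
  term_map(t2g, nm)
}

#' Construct/validate a term map
#' @param term_to_genes Named list: term id -> character vector of genes.
#' @param term_name Optional named character vector of term labels.
#' @return A `term_map` object.
#' @export
term_map <- function(term_to_genes, term_name = NULL) {
  if (any(lengths(term_to_genes) == 0L)) stop("term with empty gene set")
  term_name <- term_name %||%
    stats::setNames(names(term_to_genes), names(term_to_genes))
  structure(list(term_to_genes = term_to_genes,
                 term_name = term_name[names(term_to_genes)]),
            class = "term_map")
}

#' Write a term map
#' @param map A `term_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(map, path) {
  t2g <- map$term_to_genes
  utils::write.table(
    data.frame(term = rep(names(t2g), lengths(t2g)),
               gene = unlist(t2g, use.names = FALSE),
               name = rep(unname(map$term_name), lengths(t2g))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population environment table
#'
#' A table with a `pop` column and one numeric column per environmental
#' variable (e.g. latitude, longitude, temperature, sunshine duration).
#'
#' @param path Path to a TSV/CSV file with a header.
#' @return A data.frame with rownames set to population codes and one numeric
#'   column per variable (class `env_table`).
#' @export
read_env_table <- function(path) {
  df <- read_delim_sniffed(path)
  if (!"pop" %in% names(df)) stop("environment table must have a 'pop' column")
  if (anyDuplicated(df$pop)) stop("duplicate population in environment table")
  out <- df[setdiff(names(df), "pop")]
  if (!all(vapply(out, is.numeric, TRUE)))
    stop("environment columns must be numeric")
  if (any(!vapply(out, function(x) all(is.finite(x)), TRUE)))
    stop("non-finite environmental value")
  rownames(out) <- as.character(df$pop)
  class(out) <- c("env_table", "data.frame")
  out
}

#' Write a population environment table
#' @param env An `env_table` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_table <- function(env, path) {
  utils::write.table(cbind(pop = rownames(env), as.data.frame(env)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
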