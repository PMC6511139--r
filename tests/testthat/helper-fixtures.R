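# Shared in-code fixtures.

# Tiny genotype_matrix from an explicit dosage matrix (samples x variants).
toy_genotypes <- function(dosage, chrom = NULL, pos = NULL) {
  n <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  ids <- if (!is.null(colnames(dosage))) colnames(dosage) else
    paste0("v", seq_len(n))
  colnames(dosage) <- ids
  sample_ids <- sprintf("s%03d", seq_len(nrow(dosage)))
  rownames(dosage) <- sample_ids
  structure(list(
    dosage = dosage,
    variants = data.frame(chrom = chrom, pos = as.integer(pos), id = ids,
                          ref = "A", alt = "G", stringsAsFactors = FALSE),
    sample_ids = sample_ids), class = "genotype_matrix")
}

# Minimal census for hand-built enrichment problems.
toy_census <- function(T_C) {
  total <- sum(T_C)
  list(T = total, T_C = T_C, genomic_frequency = T_C / total,
       scheme = "TOY")
}

# 5-sample toy VCF exercising GT, DS precedence and missing genotypes.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("s", 1:5)), collapse = "\t"),
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0/1", "0/0"), collapse = "\t"),
    paste(c("1", "200", "rs2", "A", "G", ".", "PASS", ".", "GT:DS",
            "1/1:1.73", "0/0:0.12", "0/1:1.02", "0/0:0.0", "0/1:0.9"),
          collapse = "\t"),
    paste(c("1", "300", "rs3", "A", "G", ".", "PASS", ".", "GT",
            "./.", "0/1", "1/1", "0/1", "0/0"), collapse = "\t"))
  writeLines(lines, path)
  path
}

# Simulated dataset shared by the QTL/pipeline tests (cached per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 400, n_variants = 3000,
                        n_chromosomes = 2, ld_block_size = 20,
                        n_causal = 6, heritability = 0.6, seed = 42)
      genome <- simulate_annotated_genome(cfg)
      geno <- simulate_genotypes(cfg)
      phen <- simulate_phenotypes(geno, genome$categories, cfg)
      cache <<- list(cfg = cfg, genome = genome, geno = geno, phen = phen)
    }
    cache
  }
})

# Simulate QTL candidate category counts straight from the generative
# model the estimator assumes: each QTL has one causal variant whose
# category is drawn with probability proportional to lambda_C * f_C, plus
# background candidates drawn at genomic frequencies.
sim_qtl_counts <- function(n_qtl, lambda, f, set_sizes = 1:20) {
  cats <- names(f)
  pi_true <- lambda * f / sum(lambda * f)
  counts <- matrix(0L, nrow = n_qtl, ncol = length(cats),
                   dimnames = list(NULL, cats))
  for (q in seq_len(n_qtl)) {
    causal <- sample(cats, 1, prob = pi_true)
    counts[q, causal] <- 1L
    extra <- sample(set_sizes, 1) - 1L
    if (extra > 0) {
      bg <- table(factor(sample(cats, extra, replace = TRUE, prob = f),
                         levels = cats))
      counts[q, ] <- counts[q, ] + as.integer(bg)
    }
  }
  counts
}
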