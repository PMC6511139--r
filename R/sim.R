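#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic genotype /
#' annotation / phenotype generator.  Category frequencies refer to the
#' eight-category scheme labels (high, moderate, low, UTR, OC, RE, ncRNA,
#' NKI) and must sum to 1; omitted categories get frequency 0.
#'
#' @param n_samples Number of diploid samples.
#' @param n_variants Total number of variants across chromosomes.
#' @param n_chromosomes Number of chromosomes (variants split evenly).
#' @param ld_block_size Variants per LD block; blocks are independent.
#' @param maf_range Length-2 numeric in (0, 0.5]: target minor allele
#'   frequencies are drawn uniformly from this range.
#' @param category_frequencies Named numeric: eight-scheme category ->
#'   genomic fraction, summing to 1 (within 1e-9).
#' @param causal_enrichment Named numeric: category -> relative per-variant
#'   causal rate multiplier (>= 0); unnamed categories default to 1.
#' @param n_causal Number of causal variants.
#' @param heritability Fraction of phenotypic variance that is genetic, in
#'   \[0, 1\].
#' @param seed Integer seed; all generator functions are deterministic
#'   given the config.
#' @param n_founders Founder haplotypes per LD block.
#' @param copy_prob Probability that a variant copies the previous
#'   variant's founder allele vector within a block (1 = whole block
#'   perfectly correlated; block boundaries always redraw).
#' @param spacing_bp Base pairs between adjacent variants on a chromosome.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300,
                       n_variants = 5000,
                       n_chromosomes = 2,
                       ld_block_size = 25,
                       maf_range = c(0.05, 0.5),
                       category_frequencies = c(
                         high = 0.002, moderate = 0.008, low = 0.03,
                         UTR = 0.01, OC = 0.05, RE = 0.05, ncRNA = 0.01,
                         NKI = 0.84),
                       causal_enrichment = c(moderate = 10, high = 10),
                       n_causal = 10,
                       heritability = 0.5,
                       seed = 1L,
                       n_founders = 16,
                       copy_prob = 0.9,
                       spacing_bp = 5000) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_variants = as.integer(n_variants),
              n_chromosomes = as.integer(n_chromosomes),
              ld_block_size = as.integer(ld_block_size),
              maf_range = as.numeric(maf_range),
              category_frequencies = category_frequencies,
              causal_enrichment = causal_enrichment,
              n_causal = as.integer(n_causal),
              heritability = as.numeric(heritability),
              seed = as.integer(seed),
              n_founders = as.integer(n_founders),
              copy_prob = as.numeric(copy_prob),
              spacing_bp = as.integer(spacing_bp))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  f <- cfg$category_frequencies
  if (is.null(names(f)) || !all(names(f) %in% CATEGORIES_EIGHT)) {
    stop("category_frequencies must be named with eight-scheme labels: ",
         paste(CATEGORIES_EIGHT, collapse = ", "))
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stop("category_frequencies must sum to 1 (got ", sum(f), ")")
  }
  if (any(f < 0)) stop("category_frequencies must be non-negative")
  if (cfg$heritability < 0 || cfg$heritability > 1) {
    stop("heritability must be in [0, 1]")
  }
  if (cfg$n_causal > cfg$n_variants) stop("n_causal exceeds n_variants")
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must be an increasing pair in (0, 0.5]")
  }
  if (any(cfg$causal_enrichment < 0)) stop("causal_enrichment must be >= 0")
  if (cfg$copy_prob < 0 || cfg$copy_prob > 1) stop("copy_prob must be in [0, 1]")
  if (cfg$n_founders < 2) stop("need at least 2 founder haplotypes")
  if (abs(cfg$seed) >= 2^31 - 16) stop("seed out of 32-bit integer range")
  invisible(cfg)
}

# Variant coordinate table implied by a config: chromosomes get equal
# shares, positions on a regular grid.
sim_variant_table <- function(cfg) {
  per_chrom <- rep(cfg$n_variants %/% cfg$n_chromosomes, cfg$n_chromosomes)
  rem <- cfg$n_variants %% cfg$n_chromosomes
  if (rem > 0) per_chrom[seq_len(rem)] <- per_chrom[seq_len(rem)] + 1L
  chrom <- rep(as.character(seq_len(cfg$n_chromosomes)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) seq_len(k) * cfg$spacing_bp))
  data.frame(chrom = chrom, pos = as.integer(pos),
             id = paste0("var_", chrom, "_", pos),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Simulate an annotated genome
#'
#' Draws an eight-scheme category per variant from the configured category
#' frequencies, then emits a VEP-style annotation table and interval sets
#' (open chromatin, UTR, regulatory elements, ncRNA) that induce exactly
#' that classification.  A fraction of UTR-category variants also fall in
#' open-chromatin intervals, exercising the UTR-over-OC precedence of the
#' eight-category scheme (such variants are OC under the five-category
#' scheme).
#'
#' @param config A [sim_config()].
#' @return List: `variants` (chrom/pos/id/ref/alt), `annotations` (long
#'   variant_id/consequence table), `interval_sets` (named list of
#'   chrom/start/end data frames: oc, utr, re, ncrna), `categories`
#'   (per-variant eight-scheme truth labels).
#' @export
simulate_annotated_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  variants <- sim_variant_table(config)
  n <- nrow(variants)

  freqs <- setNames(numeric(length(CATEGORIES_EIGHT)), CATEGORIES_EIGHT)
  freqs[names(config$category_frequencies)] <- config$category_frequencies
  cat8 <- sample(CATEGORIES_EIGHT, n, replace = TRUE, prob = freqs)

  term_pool <- list(
    high = c("stop_gained", "stop_lost", "splice_donor_variant"),
    moderate = "missense_variant",
    low = c("synonymous_variant", "upstream_gene_variant",
            "downstream_gene_variant", "splice_region_variant"),
    modifier = c("intergenic_variant", "intron_variant")
  )
  consequence <- character(n)
  for (i in seq_len(n)) {
    pool <- switch(cat8[i], high = , moderate = , low = term_pool[[cat8[i]]],
                   term_pool$modifier)
    consequence[i] <- pool[sample.int(length(pool), 1)]
  }
  annotations <- data.frame(variant_id = variants$id,
                            consequence = consequence,
                            stringsAsFactors = FALSE)
  # second transcript row for a subset, always lower impact
  extra <- which(runif(n) < 0.1)
  if (length(extra) > 0) {
    annotations <- rbind(annotations, data.frame(
      variant_id = variants$id[extra],
      consequence = "intron_variant", stringsAsFactors = FALSE))
  }

  one_bp <- function(idx) {
    if (length(idx) == 0) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    }
    data.frame(chrom = variants$chrom[idx], start = variants$pos[idx],
               end = variants$pos[idx], stringsAsFactors = FALSE)
  }
  utr_idx <- which(cat8 == "UTR")
  oc_idx <- which(cat8 == "OC")
  # UTR precedence over OC: some UTR variants are also open chromatin
  oc_extra <- utr_idx[runif(length(utr_idx)) < 0.3]
  interval_sets <- list(
    oc = one_bp(sort(c(oc_idx, oc_extra))),
    utr = one_bp(utr_idx),
    re = one_bp(which(cat8 == "RE")),
    ncrna = one_bp(which(cat8 == "ncRNA"))
  )
  list(variants = variants, annotations = annotations,
       interval_sets = interval_sets, categories = cat8)
}

#' Simulate LD-block genotype dosages
#'
#' Founder-vector copying model: each LD block carries `n_founders` founder
#' haplotypes.  Along a block, each variant either copies the previous
#' variant's founder allele vector (probability `copy_prob`) or redraws it
#' with an alt-allele count matched to a target MAF drawn from `maf_range`
#' (clamped so founders are never monomorphic).  Each sample haplotype
#' picks one founder per block uniformly and copies it exactly; dosage is
#' the sum of two haplotypes.  Within-block r-squared is therefore high
#' (1 within a copy segment) and between-block r-squared is at the level
#' of sampling noise.
#'
#' @param config A [sim_config()].
#' @return List of class `genotype_matrix`: `dosage` (samples x variants
#'   integer matrix, colnames = variant ids), `variants` (coordinate data
#'   frame), `sample_ids`.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  if (config$n_samples < 2) stop("need at least 2 samples")
  set.seed(config$seed + 2L)
  variants <- sim_variant_table(config)
  n <- nrow(variants)
  K <- config$n_founders
  ns <- config$n_samples

  founder <- matrix(0L, nrow = K, ncol = n)
  new_vector <- function() {
    p <- runif(1, config$maf_range[1], config$maf_range[2])
    m <- min(max(round(p * K), 1L), K - 1L)
    v <- integer(K)
    v[sample.int(K, m)] <- 1L
    v
  }
  block_of <- integer(n)
  for (chrom in unique(variants$chrom)) {
    idx <- which(variants$chrom == chrom)
    blk <- (seq_along(idx) - 1L) %/% config$ld_block_size
    block_of[idx] <- blk + max(c(0L, block_of)) + 1L
    for (j in seq_along(idx)) {
      i <- idx[j]
      new_block <- j == 1 || blk[j] != blk[j - 1]
      if (new_block || runif(1) >= config$copy_prob) {
        founder[, i] <- new_vector()
      } else {
        founder[, i] <- founder[, idx[j - 1]]
      }
    }
  }

  blocks <- unique(block_of)
  dosage <- matrix(0L, nrow = ns, ncol = n)
  for (b in blocks) {
    cols <- which(block_of == b)
    f1 <- sample.int(K, ns, replace = TRUE)
    f2 <- sample.int(K, ns, replace = TRUE)
    dosage[, cols] <- founder[f1, cols, drop = FALSE] +
      founder[f2, cols, drop = FALSE]
  }
  colnames(dosage) <- variants$id
  sample_ids <- sprintf("sample_%04d", seq_len(ns))
  rownames(dosage) <- sample_ids
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' Simulate a quantitative phenotype with category-enriched causal variants
#'
#' Causal variants are sampled without replacement with probability
#' proportional to the configured enrichment multiplier of their annotation
#' category; per-causal effects are drawn standard normal and the genetic
#' values rescaled jointly so their sample variance equals `heritability`
#' (residuals N(0, 1 - heritability)); many small effects, one trait per
#' call.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param categories Character vector of eight-scheme category labels, one
#'   per variant (same order as the genotype columns).
#' @param config A [sim_config()].
#' @return List: `phenotype` (data frame sample_id/value), `truth` (data
#'   frame causal_variant_id/effect_size/category).
#' @export
simulate_phenotypes <- function(genotypes, categories, config) {
  validate_sim_config(config)
  stopifnot(length(categories) == ncol(genotypes$dosage))
  set.seed(config$seed + 3L)
  n <- ncol(genotypes$dosage)
  mult <- setNames(rep(1, length(CATEGORIES_EIGHT)), CATEGORIES_EIGHT)
  mult[names(config$causal_enrichment)] <- config$causal_enrichment
  w <- mult[categories]
  if (sum(w > 0) < config$n_causal) {
    stop("fewer variants with positive causal weight than n_causal")
  }
  causal <- sample.int(n, config$n_causal, prob = w)
  beta <- rnorm(config$n_causal)
  g <- as.vector(genotypes$dosage[, causal, drop = FALSE] %*% beta)
  vg <- var(g)
  h2 <- config$heritability
  if (h2 == 0) {
    g <- g * 0
  } else {
    if (vg == 0) stop("zero genetic variance with positive heritability")
    scale <- sqrt(h2 / vg)
    g <- g * scale
    beta <- beta * scale
  }
  e <- rnorm(config$n_samples, sd = sqrt(1 - h2))
  value <- g + e
  list(
    phenotype = data.frame(sample_id = genotypes$sample_ids, value = value,
                           stringsAsFactors = FALSE),
    truth = data.frame(
      causal_variant_id = colnames(genotypes$dosage)[causal],
      effect_size = beta,
      category = categories[causal],
      stringsAsFactors = FALSE)
  )
}
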