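test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(category_frequencies = c(NKI = 0.9)),
               "sum to 1")
  expect_error(sim_config(heritability = 1.2), "heritability")
  expect_error(sim_config(n_variants = 10, n_causal = 20), "n_causal")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
})

test_that("annotated genome matches configured category frequencies", {
  # degenerate frequency vector: everything NKI
  cfg <- sim_config(n_variants = 500,
                    category_frequencies = c(NKI = 1.0), seed = 3)
  g <- simulate_annotated_genome(cfg)
  expect_true(all(g$categories == "NKI"))
  expect_equal(nrow(g$interval_sets$oc), 0)

  # binomial check: 20,000 variants at moderate frequency 0.01
  cfg2 <- sim_config(
    n_variants = 20000, n_chromosomes = 4,
    category_frequencies = c(moderate = 0.01, NKI = 0.99), seed = 11)
  g2 <- simulate_annotated_genome(cfg2)
  n_mod <- sum(g2$categories == "moderate")
  expected <- 20000 * 0.01
  sd3 <- 3 * sqrt(20000 * 0.01 * 0.99)
  expect_lt(abs(n_mod - expected), sd3)
})

test_that("genome generation is deterministic given the seed", {
  cfg <- sim_config(n_variants = 800, seed = 5)
  expect_identical(simulate_annotated_genome(cfg),
                   simulate_annotated_genome(cfg))
  expect_identical(simulate_genotypes(cfg)$dosage,
                   simulate_genotypes(cfg)$dosage)
})

test_that("induced classification reproduces the truth categories", {
  cfg <- sim_config(n_variants = 2000, seed = 9)
  g <- simulate_annotated_genome(cfg)
  assignment <- suppressWarnings(
    assign_categories(g$variants, g$annotations, g$interval_sets))
  expect_identical(assignment$cat8, g$categories)
})

test_that("ld_block_size = 1 gives independent adjacent variants", {
  cfg <- sim_config(n_samples = 200, n_variants = 1001, n_chromosomes = 1,
                    ld_block_size = 1, seed = 13)
  geno <- simulate_genotypes(cfg)
  r2 <- vapply(seq_len(1000), function(j) {
    as.numeric(ld_r2(geno$dosage[, j], geno$dosage[, j + 1]))
  }, numeric(1))
  # mean r2 between independent vectors is about 1/(n-1)
  expect_lt(mean(r2), 3 / 200)
  expect_gt(mean(r2), 0.2 / 200)
})

test_that("copy probability 1 makes a block perfectly correlated", {
  cfg <- sim_config(n_samples = 100, n_variants = 20, n_chromosomes = 1,
                    ld_block_size = 20, copy_prob = 1, seed = 17)
  geno <- simulate_genotypes(cfg)
  expect_true(all(geno$dosage == geno$dosage[, 1]))
  expect_equal(as.numeric(ld_r2(geno$dosage[, 1], geno$dosage[, 7])), 1)
})

test_that("within-block LD is high, between-block LD near zero", {
  cfg <- sim_config(n_samples = 500, n_variants = 600, n_chromosomes = 1,
                    ld_block_size = 30, seed = 19)
  geno <- simulate_genotypes(cfg)
  within <- vapply(seq(1, 571, by = 30), function(j) {
    as.numeric(ld_r2(geno$dosage[, j], geno$dosage[, j + 5]))
  }, numeric(1))
  between <- vapply(seq(30, 570, by = 30), function(j) {
    as.numeric(ld_r2(geno$dosage[, j], geno$dosage[, j + 1]))
  }, numeric(1))
  expect_gt(mean(within), 0.3)
  expect_lt(mean(between), 0.05)
})

test_that("sample MAF stays inside the configured range", {
  cfg <- sim_config(n_samples = 1000, n_variants = 2000, n_chromosomes = 2,
                    maf_range = c(0.05, 0.5), seed = 23)
  geno <- simulate_genotypes(cfg)
  maf <- apply(geno$dosage, 2, dosage_maf)
  expect_gte(mean(maf >= 0.01), 0.99)
})

test_that("null heritability gives genotype-independent phenotypes", {
  cfg <- sim_config(n_samples = 500, n_variants = 2000, n_chromosomes = 2,
                    ld_block_size = 1, heritability = 0, seed = 29)
  genome <- simulate_annotated_genome(cfg)
  geno <- simulate_genotypes(cfg)
  phen <- simulate_phenotypes(geno, genome$categories, cfg)
  res <- assoc_scan(geno, phen$phenotype$value)
  ks <- suppressWarnings(ks.test(res$p[!is.na(res$p)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("variance decomposition matches the target heritability", {
  for (h2 in c(0.3, 0.8)) {
    cfg <- sim_config(n_samples = 1000, n_variants = 1000,
                      heritability = h2, n_causal = 20, seed = 31)
    genome <- simulate_annotated_genome(cfg)
    geno <- simulate_genotypes(cfg)
    phen <- simulate_phenotypes(geno, genome$categories, cfg)
    tr <- phen$truth
    g <- as.vector(geno$dosage[, tr$causal_variant_id] %*% tr$effect_size)
    expect_lt(abs(var(g) / var(phen$phenotype$value) - h2), 0.05)
  }
})

test_that("heritability 1 with zero genetic variance errors", {
  cfg <- sim_config(n_samples = 50, n_variants = 10, n_chromosomes = 1,
                    heritability = 1, n_causal = 1, copy_prob = 1, seed = 37)
  geno <- simulate_genotypes(cfg)
  geno$dosage[] <- 1L  # constant dosages: no genetic variance
  expect_error(simulate_phenotypes(geno, rep("NKI", 10), cfg),
               "zero genetic variance")
})

test_that("causal sampling follows the enrichment multipliers", {
  # closed form: multiplier 10 on a 1% category gives causal fraction
  # 10*0.01 / (10*0.01 + 0.99) = 0.0917 per draw
  cfg <- sim_config(
    n_samples = 60, n_variants = 2000, n_causal = 1,
    category_frequencies = c(moderate = 0.01, NKI = 0.99),
    causal_enrichment = c(moderate = 10), seed = 41)
  genome <- simulate_annotated_genome(cfg)
  geno <- simulate_genotypes(cfg)
  hits <- 0
  for (r in 1:200) {
    cfg$seed <- 41L + r
    phen <- simulate_phenotypes(geno, genome$categories, cfg)
    hits <- hits + (phen$truth$category == "moderate")
  }
  p_expected <- sum(genome$categories == "moderate") * 10 /
    (sum(genome$categories == "moderate") * 10 +
       sum(genome$categories != "moderate"))
  expect_lt(abs(hits / 200 - p_expected),
            3 * sqrt(p_expected * (1 - p_expected) / 200) + 0.01)

  # all-1 multipliers: causal categories match genomic frequencies
  cfg2 <- sim_config(n_samples = 60, n_variants = 5000, n_causal = 500,
                     causal_enrichment = c(NKI = 1), seed = 43)
  genome2 <- simulate_annotated_genome(cfg2)
  geno2 <- simulate_genotypes(cfg2)
  phen2 <- simulate_phenotypes(geno2, genome2$categories, cfg2)
  frac_nki_causal <- mean(phen2$truth$category == "NKI")
  frac_nki_genome <- mean(genome2$categories == "NKI")
  expect_lt(abs(frac_nki_causal - frac_nki_genome), 0.05)
})
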