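test_that("ld_r2 is the squared Pearson correlation of dosages", {
  a <- c(0, 1, 2, 0)
  expect_equal(as.numeric(ld_r2(a, a)), 1)
  # allele-coding invariance
  expect_equal(as.numeric(ld_r2(a, 2 - a)), 1)
  # hand/brute-force Pearson on the 4-sample toy:
  # cov terms give r = 0.75/sqrt(2.75*0.75), r^2 = 0.27273
  b <- c(0, 1, 1, 1)
  expect_equal(as.numeric(ld_r2(a, b)), cor(a, b)^2)
  expect_equal(as.numeric(ld_r2(a, b)), 0.2727273, tolerance = 1e-6)
  # constant vector: flagged 0
  r <- ld_r2(a, rep(1, 4))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "undefined"))
  expect_error(ld_r2(a, b[1:3]), "unequal")
  expect_error(ld_r2(c(1, NA, NA, 2), c(1, NA, NA, 2)), "complete pairs")
})

mk_results <- function(ids, pos, nlp, chrom = "1") {
  data.frame(id = ids, chrom = chrom, pos = pos, neglog10p = nlp,
             p = 10^-nlp, round = 1L, stringsAsFactors = FALSE)
}

test_that("find_lead honors the threshold and tie-break rules", {
  res <- mk_results(c("a", "b", "c"), c(500, 900, 100), c(7, 8.2, 6))
  expect_null(find_lead(res, 8.5))
  res$neglog10p[1] <- 9.0
  expect_equal(find_lead(res, 8.5)$id, "a")
  # tie at 10: smaller position wins
  res2 <- mk_results(c("x", "y"), c(900, 500), c(10, 10))
  expect_equal(find_lead(res2, 8.5)$id, "y")
  # position tie: lexicographic id
  res3 <- mk_results(c("z", "w"), c(500, 500), c(10, 10))
  expect_equal(find_lead(res3, 8.5)$id, "w")
  expect_null(find_lead(res[0, ], 8.5))
})

test_that("lone-lead rule uses an inclusive 1 Mb window", {
  res <- mk_results(c("lead", "near", "far"),
                    c(5e6, 5e6 + 1e6, 5e6 + 1e6 + 1),
                    c(12, 9, 9))
  lead <- res[1, ]
  # second significant SNP at exactly +1 Mb: window inclusive, not lone
  expect_false(is_lone_lead(lead, res[1:2, ], threshold_neglog10 = 8.5))
  # only a SNP beyond the window: lone
  expect_true(is_lone_lead(lead, res[c(1, 3), ], threshold_neglog10 = 8.5))
  # sub-threshold neighbor does not count
  res$neglog10p[2] <- 8.0
  expect_true(is_lone_lead(lead, res[1:2, ], threshold_neglog10 = 8.5))
})

test_that("candidate sets respect the r2 and significance cutoffs", {
  set.seed(10)
  n <- 300
  lead <- rbinom(n, 2, 0.5)
  noisy_copy <- function(x, k) {
    i <- sample.int(n, k)
    x[i] <- rbinom(k, 2, 0.5)
    x
  }
  d <- cbind(lead = lead,
             strong = noisy_copy(lead, 15),   # r2 well above 0.2
             weak = noisy_copy(lead, 270),    # r2 near zero
             indep = rbinom(n, 2, 0.5))
  g <- toy_genotypes(d)
  r1 <- mk_results(colnames(d), g$variants$pos, c(12, 11, 10, 10))
  cs <- candidate_set("lead", r1, g, r2_min = 0.2, threshold = 8.5)
  expect_true(all(c("lead", "strong") %in% cs$variant_id))
  expect_false("weak" %in% cs$variant_id)
  expect_false("indep" %in% cs$variant_id)
  # significant proxy rule: strong proxy with sub-threshold round-1 p
  r1$neglog10p[2] <- 5
  cs2 <- candidate_set("lead", r1, g, threshold = 8.5)
  expect_false("strong" %in% cs2$variant_id)
  # r2 exactly at the cutoff is excluded (strict inequality)
  d3 <- cbind(lead = c(0, 1, 2, 0, 1, 2), proxy = c(0, 1, 2, 0, 1, 2))
  g3 <- toy_genotypes(d3)
  r13 <- mk_results(colnames(d3), g3$variants$pos, c(12, 12))
  cs3 <- candidate_set("lead", r13, g3, r2_min = 1)
  expect_equal(cs3$variant_id, "lead")
})

test_that("iterative conditional detection finds well-separated QTL", {
  # two strong causal variants on one chromosome, far apart
  cfg <- sim_config(n_samples = 500, n_variants = 1000, n_chromosomes = 1,
                    ld_block_size = 10, seed = 59)
  geno <- simulate_genotypes(cfg)
  c1 <- 105; c2 <- 905  # 4 Mb apart at 5 kb spacing
  set.seed(60)
  y <- 0.8 * geno$dosage[, c1] + 0.6 * geno$dosage[, c2] + rnorm(500)
  thr <- flat_bonferroni(0.05, 1000)$neglog10
  det <- detect_qtl_chromosome(geno, y, threshold = thr)
  expect_equal(nrow(det$qtl), 2)
  expect_equal(det$qtl$round, c(1, 2))
  # round-1 lead tags the stronger causal variant
  lead1 <- det$qtl$lead_id[1]
  expect_gt(as.numeric(ld_r2(geno$dosage[, lead1], geno$dosage[, c1])), 0.8)
  lead2 <- det$qtl$lead_id[2]
  expect_gt(as.numeric(ld_r2(geno$dosage[, lead2], geno$dosage[, c2])), 0.8)
  # every reported lead is round-1 significant
  r1 <- setNames(det$round1$neglog10p, det$round1$id)
  expect_true(all(r1[det$qtl$lead_id] > thr))
})

test_that("no signal gives an empty QTL list", {
  cfg <- sim_config(n_samples = 200, n_variants = 300, n_chromosomes = 1,
                    heritability = 0, seed = 61)
  geno <- simulate_genotypes(cfg)
  set.seed(62)
  det <- detect_qtl_chromosome(geno, rnorm(200), threshold = 8.5)
  expect_null(det$qtl)
  expect_equal(det$n_rounds, 1)
})

test_that("full detection run keeps candidate sets on-chromosome and deduplicated", {
  s <- shared_sim()
  keep <- qc_filter(s$geno)
  gq <- subset_genotypes(s$geno, keep)
  thr <- flat_bonferroni(0.05, length(keep))$neglog10
  det <- detect_qtl(gq, s$phen$phenotype$value, threshold = thr)
  expect_gt(nrow(det$qtl), 0)
  expect_false(any(duplicated(det$candidates$variant_id)))
  chrom_of <- setNames(gq$variants$chrom, gq$variants$id)
  lead_chrom <- chrom_of[det$qtl$lead_id[match(det$candidates$qtl_id,
                                               det$qtl$qtl_id)]]
  expect_equal(unname(chrom_of[det$candidates$variant_id]),
               unname(lead_chrom))
  # each QTL's candidate set contains its lead
  for (q in det$qtl$qtl_id) {
    expect_true(det$qtl$lead_id[det$qtl$qtl_id == q] %in%
                  det$candidates$variant_id[det$candidates$qtl_id == q])
  }
  # all candidates are round-1 significant with r2 above the cutoff
  expect_true(all(det$candidates$round1_neglog10p > thr))
  expect_true(all(det$candidates$r2 > 0.2 |
                    det$candidates$variant_id %in% det$qtl$lead_id))
})

test_that("causal variants are recovered in candidate sets", {
  # well-separated strong causal variants: most should be tagged
  hits <- 0; total <- 0
  for (rep_i in 1:5) {
    cfg <- sim_config(n_samples = 500, n_variants = 1500, n_chromosomes = 3,
                      ld_block_size = 10, n_causal = 3, heritability = 0.6,
                      seed = 70 + rep_i)
    genome <- simulate_annotated_genome(cfg)
    geno <- simulate_genotypes(cfg)
    phen <- simulate_phenotypes(geno, genome$categories, cfg)
    thr <- flat_bonferroni(0.05, 1500)$neglog10
    det <- detect_qtl(geno, phen$phenotype$value, threshold = thr)
    total <- total + nrow(phen$truth)
    if (!is.null(det$candidates)) {
      hits <- hits + sum(phen$truth$causal_variant_id %in%
                           det$candidates$variant_id)
    }
  }
  expect_gte(hits / total, 0.6)
})
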