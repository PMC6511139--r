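test_that("flat Bonferroni threshold behaves like a logarithm", {
  fb <- flat_bonferroni(0.05, 16503508)
  expect_equal(round(fb$neglog10, 1), 8.5)
  expect_equal(flat_bonferroni(0.05, 1)$p_bc, 0.05)
  # doubling T raises the -log10 threshold by log10(2)
  expect_equal(flat_bonferroni(0.05, 2e6)$neglog10 -
                 flat_bonferroni(0.05, 1e6)$neglog10,
               log10(2), tolerance = 1e-12)
})

test_that("category weights match the hand-evaluated formula", {
  # (T_A, e_A) = (10, 5), (T_B, e_B) = (90, 0.5): normalizer 0.95
  cen <- toy_census(c(A = 10, B = 90))
  w <- category_weights(c(A = 5, B = 0.5), cen)
  expect_equal(w[["A"]], 5 / 0.95, tolerance = 1e-12)
  expect_equal(w[["B"]], 0.5 / 0.95, tolerance = 1e-12)
  expect_equal(sum(c(10, 90) * w), 100, tolerance = 1e-9)
  # all enrichments 1: weights 1, thresholds reduce to flat Bonferroni
  w1 <- category_weights(c(A = 1, B = 1), cen)
  expect_equal(unname(w1), c(1, 1))
  expect_error(category_weights(c(A = 0, B = 0), cen), "normalizer")
})

test_that("weight-sum conservation holds on randomized inputs", {
  set.seed(30)
  for (case in 1:200) {
    k <- sample(2:8, 1)
    T_C <- setNames(sample(10:1e5, k), paste0("c", 1:k))
    e <- setNames(rexp(k), names(T_C))
    w <- category_weights(e, toy_census(T_C))
    expect_lt(abs(sum(T_C * w) - sum(T_C)) / sum(T_C), 1e-9)
  }
})

test_that("threshold table applies the NA rule and proportionality", {
  cen <- toy_census(c(A = 100, B = 800, C = 100))
  e <- c(A = 5, B = 0.89, C = 2)
  w <- category_weights(e, cen)
  fb <- flat_bonferroni(0.05, cen$T)
  tt <- category_thresholds(w, fb$p_bc, e)
  expect_equal(tt$p_wt, fb$p_bc * tt$weight, tolerance = 1e-15)
  # non-enriched category falls back to the flat threshold
  expect_true(tt$na_flag[tt$category == "B"])
  expect_equal(tt$applied_threshold[tt$category == "B"], fb$p_bc)
  # proportionality between non-NA categories
  expect_equal(tt$p_wt[tt$category == "A"] / tt$p_wt[tt$category == "C"],
               e[["A"]] / e[["C"]], tolerance = 1e-12)
  # alpha budget: sum T_C * P_wt = alpha before the NA fallback
  expect_equal(sum(cen$T_C * tt$p_wt), 0.05, tolerance = 1e-12)
  # after the fallback the budget can only grow
  expect_gte(sum(cen$T_C * tt$applied_threshold), 0.05 - 1e-15)
})

test_that("published table thresholds are recovered by proportionality", {
  rec <- recompute_reference_thresholds()
  expect_equal(nrow(rec), 13)
  expect_equal(rec$recomputed, rec$threshold, tolerance = 5e-3)
  # the four-category moderate cell from the low-impact anchor
  expect_equal(3.84e-7 * 4.40 / 245.45, 6.88e-9, tolerance = 1e-3)
  # the eight-category moderate cell from the high-impact row
  expect_equal(1.02e-7 * 17.16 / 33.69, 5.20e-8, tolerance = 1e-3)
})

test_that("applying thresholds counts flat vs weighted significance", {
  assignment <- data.frame(
    variant_id = paste0("v", 1:8),
    cat4 = c(rep("moderate", 5), rep("other", 3)),
    stringsAsFactors = FALSE)
  res <- data.frame(id = paste0("v", 1:8),
                    p = c(rep(1e-10, 5), 1e-12, 0.5, 0.5),
                    stringsAsFactors = FALSE)
  # P_bc = 3e-11; moderate weight 10 lifts its threshold to 3e-10
  tt <- category_thresholds(
    c(moderate = 10, other = 0.5), 3e-11,
    c(moderate = 8, other = 0.9))
  appl <- apply_thresholds(res, assignment, tt, "FOUR")
  cmp <- appl$comparison
  expect_equal(cmp$n_sig_flat[cmp$category == "moderate"], 0)
  expect_equal(cmp$n_sig_weighted[cmp$category == "moderate"], 5)
  # NA category identical under both corrections
  expect_equal(cmp$n_sig_flat[cmp$category == "other"],
               cmp$n_sig_weighted[cmp$category == "other"])
  expect_setequal(appl$new_significant, paste0("v", 1:5))
  expect_equal(cmp$n_sig_flat[cmp$category == "total"], 1)
  expect_error(apply_thresholds(
    data.frame(id = "vX", p = 0.1), assignment, tt, "FOUR"),
    "without category")
})

test_that("all-unit weights reduce the comparison to the flat regime", {
  s <- shared_sim()
  keep <- qc_filter(s$geno)
  gq <- subset_genotypes(s$geno, keep)
  res <- assoc_scan(gq, s$phen$phenotype$value)
  assignment <- suppressWarnings(assign_categories(
    gq$variants, s$genome$annotations, s$genome$interval_sets))
  cen <- category_census(assignment, "EIGHT")
  e1 <- setNames(rep(1, 8), scheme_categories("EIGHT"))
  tt <- category_thresholds(category_weights(e1, cen),
                            flat_bonferroni(0.05, cen$T)$p_bc, e1)
  appl <- apply_thresholds(res, assignment, tt, "EIGHT")
  expect_equal(appl$comparison$n_sig_flat, appl$comparison$n_sig_weighted)
  expect_equal(length(appl$new_significant), 0)
})

test_that("raising a category's enrichment never lowers its weighted count", {
  set.seed(31)
  assignment <- data.frame(
    variant_id = paste0("v", 1:200),
    cat4 = sample(c("moderate", "other"), 200, replace = TRUE),
    stringsAsFactors = FALSE)
  res <- data.frame(id = assignment$variant_id,
                    p = 10^-runif(200, 2, 9), stringsAsFactors = FALSE)
  cen <- toy_census(c(moderate = 50, other = 950))
  p_bc <- 1e-6
  count_mod <- function(e_mod) {
    e <- c(moderate = e_mod, other = 0.9)
    tt <- category_thresholds(category_weights(e, cen), p_bc, e)
    appl <- apply_thresholds(res, assignment, tt, "FOUR")
    appl$comparison$n_sig_weighted[appl$comparison$category == "moderate"]
  }
  counts <- vapply(c(1.5, 3, 6, 12, 24), count_mod, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
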