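#' Flat Bonferroni threshold
#'
#' @param alpha Family-wise error rate.
#' @param T Number of simultaneous tests.
#' @return List: `p_bc` (per-test threshold alpha / T) and `neglog10`
#'   (-log10 of it).
#' @export
flat_bonferroni <- function(alpha = 0.05, T) {
  stopifnot(T >= 1, alpha > 0, alpha < 1)
  p_bc <- alpha / T
  list(p_bc = p_bc, neglog10 = -log10(p_bc))
}

#' Per-category weights for the weighted Bonferroni correction
#'
#' w_C = e_C / ((1/T) * sum_C' T_C' e_C'); the normalizer sums over all
#' categories, including non-enriched ones, so the candidate-count
#' weighted mean weight is 1 and sum_C T_C w_C = T exactly.
#'
#' @param enrichment Named numeric e_C per category (>= 0).
#' @param census List from [category_census()] covering the same
#'   categories.
#' @param normalizer `"all"` (default: sum over every category) or
#'   `"enriched-only"` (sum restricted to categories with e_C > 1; the
#'   weight-sum identity then holds over that subset only).
#' @return Named numeric w_C.
#' @export
category_weights <- function(enrichment, census,
                             normalizer = c("all", "enriched-only")) {
  normalizer <- match.arg(normalizer)
  cats <- names(enrichment)
  T_C <- census$T_C[cats]
  if (anyNA(T_C)) stop("census does not cover all enrichment categories")
  if (any(enrichment < 0)) stop("negative enrichment")
  use <- if (normalizer == "all") rep(TRUE, length(cats)) else enrichment > 1
  denom <- sum(T_C[use] * enrichment[use]) / sum(T_C[use])
  if (!is.finite(denom) || denom <= 0) {
    stop("weight normalizer is zero; all enrichments vanish")
  }
  setNames(enrichment / denom, cats)
}

#' Weighted significance thresholds per category
#'
#' P_wt,C = P_bc * w_C.  Categories with no enrichment (e_C <= 1) get no
#' category-based threshold (`na_flag`); their applied threshold falls
#' back to the flat Bonferroni P_bc, so their significant-variant counts
#' are identical under both corrections.
#'
#' @param weights Named numeric from [category_weights()].
#' @param p_bc Flat Bonferroni per-test threshold.
#' @param enrichment Named numeric e_C (same categories).
#' @return Data frame of class `threshold_table`: category, enrichment,
#'   weight, p_wt, applied_threshold, na_flag; attribute `p_bc`.
#' @export
category_thresholds <- function(weights, p_bc, enrichment) {
  stopifnot(identical(names(weights), names(enrichment)))
  na_flag <- enrichment <= 1
  p_wt <- p_bc * weights
  out <- data.frame(category = names(weights),
                    enrichment = as.numeric(enrichment),
                    weight = as.numeric(weights),
                    p_wt = as.numeric(p_wt),
                    applied_threshold = ifelse(na_flag, p_bc, p_wt),
                    na_flag = na_flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "p_bc") <- p_bc
  class(out) <- c("threshold_table", class(out))
  out
}

#' Apply flat and weighted thresholds to association results
#'
#' Per category, counts variants significant under the flat Bonferroni
#' threshold and under the category's applied threshold, and lists the
#' variants that are significant only under the weighted correction.
#'
#' @param assoc_results Round-1 association results (data frame with `id`,
#'   `p`).
#' @param assignment Data frame from [assign_categories()].
#' @param threshold_table From [category_thresholds()].
#' @param scheme Scheme of the threshold table.
#' @return List: `comparison` (data frame category/n_sig_flat/
#'   n_sig_weighted with a totals row), `new_significant` (ids significant
#'   only under the weighted thresholds).
#' @export
apply_thresholds <- function(assoc_results, assignment, threshold_table,
                             scheme) {
  col <- switch(toupper(scheme), FOUR = "cat4", FIVE = "cat5", EIGHT = "cat8")
  lab <- assignment[[col]][match(assoc_results$id, assignment$variant_id)]
  if (anyNA(lab)) {
    stop("variant(s) without category assignment: ",
         paste(head(assoc_results$id[is.na(lab)], 5), collapse = ", "))
  }
  p_bc <- attr(threshold_table, "p_bc")
  applied <- setNames(threshold_table$applied_threshold,
                      threshold_table$category)
  p <- assoc_results$p
  ok <- !is.na(p)
  flat_sig <- ok & p < p_bc
  wt_sig <- ok & p < applied[lab]
  comparison <- data.frame(
    category = threshold_table$category,
    n_sig_flat = vapply(threshold_table$category,
                        function(cc) sum(flat_sig[lab == cc]), integer(1)),
    n_sig_weighted = vapply(threshold_table$category,
                            function(cc) sum(wt_sig[lab == cc]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  comparison <- rbind(comparison,
                      data.frame(category = "total",
                                 n_sig_flat = sum(comparison$n_sig_flat),
                                 n_sig_weighted = sum(comparison$n_sig_weighted),
                                 stringsAsFactors = FALSE))
  list(comparison = comparison,
       new_significant = assoc_results$id[wt_sig & !flat_sig])
}

#' End-to-end power experiment: flat vs weighted Bonferroni
#'
#' For each replicate: simulate an annotated genome, genotypes and a
#' phenotype; QC; detect QTL and candidate sets; classify variants;
#' estimate enrichment; derive weighted thresholds; and measure power as
#' the fraction of true causal variants significant under each regime
#' (on the round-1 scan).  The detection threshold is the flat Bonferroni
#' threshold for the number of post-QC tests.
#'
#' @param sim_cfg A [sim_config()]; its seed is advanced per replicate.
#' @param scheme Category scheme used for enrichment and weighting.
#' @param n_replicates Number of simulation replicates.
#' @param seed Base seed.
#' @param alpha Family-wise error rate.
#' @return Data frame, one row per replicate: n_qtl, n_candidates,
#'   power_flat, power_weighted, n_sig_flat, n_sig_weighted.
#' @export
power_experiment <- function(sim_cfg, scheme = "EIGHT", n_replicates = 10,
                             seed = 1L, alpha = 0.05) {
  rows <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    cfg <- sim_cfg
    cfg$seed <- as.integer(seed + 16L * rep_i)
    genome <- simulate_annotated_genome(cfg)
    geno <- simulate_genotypes(cfg)
    phen <- simulate_phenotypes(geno, genome$categories, cfg)

    keep <- qc_filter(geno)
    geno_qc <- subset_genotypes(geno, keep)
    fb <- flat_bonferroni(alpha, length(keep))

    det <- detect_qtl(geno_qc, phen$phenotype$value,
                      threshold = fb$neglog10)
    assignment <- assign_categories(
      geno_qc$variants, genome$annotations, genome$interval_sets)
    census <- category_census(assignment, scheme)

    causal <- intersect(phen$truth$causal_variant_id, keep)
    r1 <- det$round1
    if (is.null(det$candidates) || nrow(det$candidates) == 0) {
      rows[[rep_i]] <- data.frame(
        replicate = rep_i, n_qtl = 0L, n_candidates = 0L,
        power_flat = mean(r1$p[match(causal, r1$id)] < fb$p_bc, na.rm = TRUE),
        power_weighted = mean(r1$p[match(causal, r1$id)] < fb$p_bc,
                              na.rm = TRUE),
        n_sig_flat = sum(r1$p < fb$p_bc, na.rm = TRUE),
        n_sig_weighted = sum(r1$p < fb$p_bc, na.rm = TRUE))
      next
    }
    counts <- qtl_category_counts(det$candidates, assignment, scheme)
    est <- estimate_enrichment(counts, census)
    w <- category_weights(est$enrichment, census)
    tt <- category_thresholds(w, fb$p_bc, est$enrichment)
    appl <- apply_thresholds(r1, assignment, tt, scheme)

    col <- switch(toupper(scheme), FOUR = "cat4", FIVE = "cat5",
                  EIGHT = "cat8")
    lab <- assignment[[col]][match(causal, assignment$variant_id)]
    applied <- setNames(tt$applied_threshold, tt$category)
    p_causal <- r1$p[match(causal, r1$id)]
    tot <- appl$comparison[appl$comparison$category == "total", ]
    rows[[rep_i]] <- data.frame(
      replicate = rep_i,
      n_qtl = nrow(det$qtl), n_candidates = nrow(det$candidates),
      power_flat = mean(p_causal < fb$p_bc, na.rm = TRUE),
      power_weighted = mean(p_causal < applied[lab], na.rm = TRUE),
      n_sig_flat = tot$n_sig_flat, n_sig_weighted = tot$n_sig_weighted)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published reference enrichment tables
#'
#' Per-category enrichment estimates, bootstrap confidence intervals and
#' category-based significance thresholds reported by a whole-genome
#' sequence GWAS of quantitative traits in dairy cattle, for the 4-, 5-
#' and 8-category schemes.  Bundled as a consistency check of the
#' threshold-proportionality identity (see
#' [recompute_reference_thresholds()]); `NA` thresholds mark
#' non-enriched categories.
#'
#' @return Data frame: scheme, category, n_candidates, enrichment,
#'   ci_low, ci_high, threshold.
#' @export
reference_enrichment_tables <- function() {
  path <- system.file("extdata", "reference_enrichment_tables.tsv",
                      package = "annogwas")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute reference thresholds from the proportionality identity
#'
#' For any two categories with a category-based threshold, P_wt,A /
#' P_wt,B = e_A / e_B.  Using, per scheme, only the published enrichments
#' and the threshold of one anchor category (the thresholded category
#' with the most candidates), every other published threshold is
#' recomputed.  Residual disagreement reflects only the rounding of the
#' published values.
#'
#' @param tab Data frame as returned by [reference_enrichment_tables()].
#' @return `tab` restricted to thresholded rows, with columns
#'   `recomputed` and `rel_err`; anchor rows carry `is_anchor = TRUE`.
#' @export
recompute_reference_thresholds <- function(tab = reference_enrichment_tables()) {
  out <- list()
  for (sc in unique(tab$scheme)) {
    rows <- tab[tab$scheme == sc & !is.na(tab$threshold), , drop = FALSE]
    anchor <- rows[which.max(rows$n_candidates), ]
    rows$recomputed <- anchor$threshold * rows$enrichment / anchor$enrichment
    rows$rel_err <- abs(rows$recomputed - rows$threshold) / rows$threshold
    rows$is_anchor <- rows$category == anchor$category
    out[[sc]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
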