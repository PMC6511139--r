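#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosages over complete pairs (the usual
#' PLINK-style genotypic r-squared).  Constant vectors are undefined and
#' return 0 with attribute `undefined = TRUE`.
#'
#' @param dosage_a,dosage_b Equal-length dosage vectors.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) stop("unequal vector lengths")
  ok <- complete.cases(dosage_a, dosage_b)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (sd(a) == 0 || sd(b) == 0) {
    return(structure(0, undefined = TRUE))
  }
  cor(a, b)^2
}

#' Lead SNP of a scan round
#'
#' The variant with the largest -log10(p) if it exceeds the significance
#' threshold; ties broken by smaller position, then lexicographic id.
#'
#' @param results Association results for one chromosome and round (data
#'   frame from [assoc_scan()]).
#' @param threshold_neglog10 Genome-wide significance threshold on the
#'   -log10(p) scale.
#' @return One-row data frame (the lead's result row), or NULL if no
#'   variant exceeds the threshold.
#' @export
find_lead <- function(results, threshold_neglog10 = 8.5) {
  ok <- !is.na(results$neglog10p) & results$neglog10p > threshold_neglog10
  if (!any(ok)) return(NULL)
  cand <- results[ok, , drop = FALSE]
  ord <- order(-cand$neglog10p, cand$pos, cand$id)
  cand[ord[1], , drop = FALSE]
}

#' Is a lead SNP the only significant SNP within its window?
#'
#' A lead that is the only significant variant within +/- `window_bp`
#' (inclusive) of its position may be a false positive or mis-mapped and
#' is not reported as a QTL.
#'
#' @param lead One-row data frame (a [find_lead()] result).
#' @param results Association results for the lead's chromosome and round.
#' @param window_bp Flanking window in base pairs.
#' @param threshold_neglog10 Significance threshold.
#' @return TRUE iff no other significant variant lies within the window.
#' @export
is_lone_lead <- function(lead, results, window_bp = 1e6,
                         threshold_neglog10 = 8.5) {
  sig <- !is.na(results$neglog10p) &
    results$neglog10p > threshold_neglog10 &
    results$id != lead$id &
    abs(results$pos - lead$pos) <= window_bp
  !any(sig)
}

#' Iterative conditional QTL detection on one chromosome
#'
#' Round 1 is the unconditional scan; each subsequent round refits every
#' variant with the dosages of all leads accepted so far as covariates.  A
#' round-k lead (k >= 2) is accepted only if it was also significant in
#' round 1; otherwise the scan stops.  Lone leads (no other significant
#' variant within +/- 1 Mb) are excluded from the QTL list but, by
#' default, still conditioned on so the scan can move past them.
#'
#' @param genotypes QC-filtered `genotype_matrix` for one chromosome.
#' @param phenotype Trait vector aligned with samples.
#' @param threshold Significance threshold on the -log10(p) scale.
#' @param window_bp Lone-lead flanking window.
#' @param condition_on_lone Keep conditioning on excluded lone leads
#'   (TRUE, default) or stop the scan at the first lone lead (FALSE).
#' @param model Association model passed to [assoc_scan()].
#' @param max_rounds Hard cap on conditioning rounds.
#' @return List: `qtl` (data frame lead_id/chrom/pos/round/neglog10p/
#'   conditioned_on), `round1` (round-1 scan results), `n_rounds`.
#' @export
detect_qtl_chromosome <- function(genotypes, phenotype, threshold = 8.5,
                                  window_bp = 1e6, condition_on_lone = TRUE,
                                  model = "ols", max_rounds = 50) {
  chroms <- unique(genotypes$variants$chrom)
  if (length(chroms) != 1) stop("detect_qtl_chromosome expects one chromosome")
  round1 <- assoc_scan(genotypes, phenotype, model = model, round = 1L)
  r1_nlp <- setNames(round1$neglog10p, round1$id)

  qtl <- list()
  cond_ids <- character(0)
  results <- round1
  round_k <- 1L
  repeat {
    lead <- find_lead(results, threshold)
    if (is.null(lead)) break
    if (round_k >= 2 && !(isTRUE(r1_nlp[[lead$id]] > threshold))) break
    lone <- is_lone_lead(lead, results, window_bp, threshold)
    if (!lone) {
      qtl[[length(qtl) + 1]] <- data.frame(
        lead_id = lead$id, chrom = lead$chrom, pos = lead$pos,
        round = round_k, neglog10p = lead$neglog10p,
        conditioned_on = paste(cond_ids, collapse = ","),
        stringsAsFactors = FALSE)
    } else if (!condition_on_lone) {
      break
    }
    cond_ids <- c(cond_ids, lead$id)
    round_k <- round_k + 1L
    if (round_k > max_rounds) {
      stop("conditional scan did not terminate within ", max_rounds, " rounds")
    }
    covar <- genotypes$dosage[, cond_ids, drop = FALSE]
    results <- assoc_scan(genotypes, phenotype, covariate_dosages = covar,
                          model = model, round = round_k)
  }
  list(qtl = if (length(qtl) > 0) do.call(rbind, qtl) else NULL,
       round1 = round1, n_rounds = round_k)
}

#' LD candidate set of a detected QTL
#'
#' Candidates are the variants on the lead's chromosome whose r-squared
#' with the lead is strictly greater than `r2_min` and whose round-1
#' -log10(p) exceeds the significance threshold (non-significant proxies
#' are discarded), plus the lead itself.
#'
#' @param lead_id Lead variant id.
#' @param round1_results Round-1 association results for the chromosome.
#' @param genotypes `genotype_matrix` holding the chromosome's dosages.
#' @param r2_min r-squared cutoff (strict inequality).
#' @param threshold Significance threshold on the -log10(p) scale.
#' @return Data frame `variant_id`, `r2`, `round1_neglog10p` (lead
#'   included, r2 = 1).
#' @export
candidate_set <- function(lead_id, round1_results, genotypes, r2_min = 0.2,
                          threshold = 8.5) {
  lead_dose <- genotypes$dosage[, lead_id]
  chrom <- genotypes$variants$chrom[genotypes$variants$id == lead_id]
  on_chrom <- round1_results[round1_results$chrom == chrom, , drop = FALSE]
  sig <- on_chrom[!is.na(on_chrom$neglog10p) &
                    on_chrom$neglog10p > threshold, , drop = FALSE]
  r2 <- vapply(sig$id, function(v) {
    as.numeric(ld_r2(genotypes$dosage[, v], lead_dose))
  }, numeric(1))
  keep <- r2 > r2_min | sig$id == lead_id
  out <- data.frame(variant_id = sig$id[keep], r2 = r2[keep],
                    round1_neglog10p = sig$neglog10p[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!lead_id %in% out$variant_id) {
    stop("lead ", lead_id, " is not round-1 significant; inconsistent inputs")
  }
  out[order(-out$r2, out$variant_id), , drop = FALSE]
}

#' Detect QTL across all chromosomes and extract candidate sets
#'
#' Runs [detect_qtl_chromosome()] per chromosome, then
#' [candidate_set()] for every accepted lead.  A variant qualifying as a
#' candidate for two QTL is assigned to the QTL with the larger r-squared,
#' so candidate sets within one trait are disjoint.
#'
#' @param genotypes QC-filtered `genotype_matrix` (all chromosomes).
#' @param phenotype Trait vector.
#' @param trait Trait label recorded in the output.
#' @inheritParams detect_qtl_chromosome
#' @inheritParams candidate_set
#' @return List: `qtl` (data frame with trait/qtl_id/lead columns),
#'   `candidates` (data frame qtl_id/variant_id/r2/round1_neglog10p),
#'   `round1` (genome-wide round-1 results).
#' @export
detect_qtl <- function(genotypes, phenotype, trait = "trait",
                       threshold = 8.5, r2_min = 0.2, window_bp = 1e6,
                       condition_on_lone = TRUE, model = "ols") {
  chroms <- unique(genotypes$variants$chrom)
  qtl_all <- list(); round1_all <- list(); cand_all <- list()
  for (ch in chroms) {
    ids <- genotypes$variants$id[genotypes$variants$chrom == ch]
    sub <- subset_genotypes(genotypes, ids)
    det <- detect_qtl_chromosome(sub, phenotype, threshold = threshold,
                                 window_bp = window_bp,
                                 condition_on_lone = condition_on_lone,
                                 model = model)
    round1_all[[ch]] <- det$round1
    if (!is.null(det$qtl) && nrow(det$qtl) > 0) {
      for (i in seq_len(nrow(det$qtl))) {
        lead_id <- det$qtl$lead_id[i]
        qtl_id <- paste0(trait, ":", lead_id)
        cs <- candidate_set(lead_id, det$round1, sub, r2_min = r2_min,
                            threshold = threshold)
        cs$qtl_id <- qtl_id
        cand_all[[qtl_id]] <- cs
        row <- det$qtl[i, , drop = FALSE]
        row$trait <- trait; row$qtl_id <- qtl_id
        row$n_candidates <- nrow(cs)
        qtl_all[[qtl_id]] <- row
      }
    }
  }
  qtl <- if (length(qtl_all) > 0) do.call(rbind, qtl_all) else NULL
  candidates <- if (length(cand_all) > 0) do.call(rbind, cand_all) else NULL
  if (!is.null(candidates)) {
    # keep each variant only in the QTL where its r2 is largest; a QTL's
    # own lead always stays with its QTL (ties at r2 = 1 notwithstanding)
    lead_of <- setNames(qtl$lead_id, qtl$qtl_id)
    own_lead <- candidates$variant_id == lead_of[candidates$qtl_id]
    ord <- order(candidates$variant_id, -own_lead, -candidates$r2)
    candidates <- candidates[ord, , drop = FALSE]
    candidates <- candidates[!duplicated(candidates$variant_id), , drop = FALSE]
    rownames(candidates) <- NULL
    keep_n <- table(candidates$qtl_id)
    qtl$n_candidates <- as.integer(keep_n[qtl$qtl_id])
    qtl$n_candidates[is.na(qtl$n_candidates)] <- 0L
  }
  if (!is.null(qtl)) rownames(qtl) <- NULL
  list(qtl = qtl, candidates = candidates,
       round1 = do.call(rbind, c(round1_all, list(make.row.names = FALSE))))
}
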