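#' Default VEP consequence-to-impact map
#'
#' Maps VEP consequence terms to impact classes HIGH/MODERATE/LOW/MODIFIER.
#' The defaults follow the classification used for the category schemes:
#' notably `upstream_gene_variant` and `downstream_gene_variant` are classed
#' LOW (stock VEP calls them MODIFIER).  Supply a YAML file mapping impact
#' class to a list of terms to override, e.g. to restore stock VEP
#' semantics.
#'
#' @param path Optional YAML file with keys HIGH/MODERATE/LOW/MODIFIER, each
#'   a list of consequence terms.
#' @return Named character vector: consequence term -> impact class.
#' @export
vep_impact_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "impact_map.yaml", package = "annogwas")
  }
  entries <- yaml::read_yaml(path)
  stopifnot(all(names(entries) %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  map <- character(0)
  for (impact in names(entries)) {
    terms <- unlist(entries[[impact]])
    map[terms] <- impact
  }
  map
}

IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")

#' Highest impact among a variant's consequence terms
#'
#' When a variant carries multiple annotations (e.g. one per transcript),
#' the highest-impact one is retained, under HIGH > MODERATE > LOW >
#' MODIFIER.  Unknown terms map to MODIFIER with a warning.
#'
#' @param terms Character vector of consequence terms for one variant.
#' @param impact_map Named vector from [vep_impact_map()].
#' @return One of `"HIGH"`, `"MODERATE"`, `"LOW"`, `"MODIFIER"`.
#' @export
impact_rank <- function(terms, impact_map = vep_impact_map()) {
  if (length(terms) == 0) {
    warning("variant with no consequence terms; classed MODIFIER")
    return("MODIFIER")
  }
  impacts <- impact_map[terms]
  unknown <- terms[is.na(impacts)]
  if (length(unknown) > 0) {
    warning("unknown consequence term(s) mapped to MODIFIER: ",
            paste(unique(unknown), collapse = ", "))
    impacts[is.na(impacts)] <- "MODIFIER"
  }
  IMPACT_LEVELS[min(match(impacts, IMPACT_LEVELS))]
}

#' Classify one variant into a category of a scheme
#'
#' FOUR: impact class directly (MODIFIER -> "other").  FIVE: MODIFIER
#' variants in open chromatin -> "OC", else "NKF".  EIGHT: MODIFIER variants
#' are assigned by precedence UTR > OC > RE > ncRNA > NKI.  Variants with
#' impact HIGH/MODERATE/LOW are never reassigned by interval membership.
#'
#' @param impact Impact class of the variant.
#' @param memberships Named logical vector with elements `oc`, `utr`, `re`,
#'   `ncrna`.
#' @param scheme `"FOUR"`, `"FIVE"` or `"EIGHT"`.
#' @return Category label.
#' @export
classify_variant <- function(impact, memberships, scheme) {
  cats <- scheme_categories(scheme)  # validates scheme
  if (impact != "MODIFIER") {
    return(c(HIGH = "high", MODERATE = "moderate", LOW = "low")[[impact]])
  }
  switch(toupper(scheme),
    FOUR = "other",
    FIVE = if (isTRUE(memberships[["oc"]])) "OC" else "NKF",
    EIGHT = {
      if (isTRUE(memberships[["utr"]])) "UTR"
      else if (isTRUE(memberships[["oc"]])) "OC"
      else if (isTRUE(memberships[["re"]])) "RE"
      else if (isTRUE(memberships[["ncrna"]])) "ncRNA"
      else "NKI"
    }
  )
}

#' Interval membership flags for variants
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based).
#' @param interval_sets Named list of interval data frames (columns `chrom`,
#'   `start`, `end`, 1-based inclusive), as from [read_bed_intervals()].
#'   Expected names (any subset): `oc`, `utr`, `re`, `ncrna`.  `oc` may be a
#'   union of several experimental sets (ATAC-seq, H3K27Ac, H3K4me3).
#' @return Logical matrix, one row per variant, columns oc/utr/re/ncrna.
#' @export
variant_memberships <- function(variants, interval_sets) {
  vr <- GenomicRanges::GRanges(
    seqnames = as.character(variants$chrom),
    ranges = IRanges::IRanges(start = variants$pos, end = variants$pos)
  )
  out <- matrix(FALSE, nrow = nrow(variants), ncol = 4,
                dimnames = list(NULL, c("oc", "utr", "re", "ncrna")))
  for (nm in intersect(names(interval_sets), colnames(out))) {
    iv <- interval_sets[[nm]]
    if (is.null(iv) || nrow(iv) == 0) next
    ir <- GenomicRanges::GRanges(
      seqnames = as.character(iv$chrom),
      ranges = IRanges::IRanges(start = iv$start, end = iv$end)
    )
    out[, nm] <- IRanges::overlapsAny(vr, ir)
  }
  out
}

#' Assign annotation categories to all variants
#'
#' Combines per-variant highest-impact consequence with interval
#' memberships and classifies under all three schemes.  Variants present in
#' the genotype set but absent from the annotation table are classed
#' MODIFIER (no known consequence).
#'
#' @param variants Data frame with `chrom`, `pos`, `id`.
#' @param annotations Long data frame with columns `variant_id`,
#'   `consequence` (one term per row), as from [read_vep_table()].
#' @param interval_sets Named list of interval data frames (see
#'   [variant_memberships()]).
#' @param impact_map Named vector from [vep_impact_map()].
#' @return Data frame: `variant_id`, `impact`, `oc`, `utr`, `re`, `ncrna`,
#'   `cat4`, `cat5`, `cat8`.
#' @export
assign_categories <- function(variants, annotations, interval_sets,
                              impact_map = vep_impact_map()) {
  terms_by_variant <- split(annotations$consequence, annotations$variant_id)
  unknown <- setdiff(unique(annotations$consequence), names(impact_map))
  if (length(unknown) > 0) {
    warning("unknown consequence term(s) mapped to MODIFIER: ",
            paste(unknown, collapse = ", "))
  }
  impact_of <- function(terms) {
    imp <- impact_map[terms]
    imp[is.na(imp)] <- "MODIFIER"
    IMPACT_LEVELS[min(match(imp, IMPACT_LEVELS))]
  }
  impacts <- vapply(terms_by_variant, impact_of, character(1))
  impact <- impacts[match(variants$id, names(impacts))]
  impact[is.na(impact)] <- "MODIFIER"

  mem <- variant_memberships(variants, interval_sets)
  n <- nrow(variants)
  cat4 <- cat5 <- cat8 <- character(n)
  for (i in seq_len(n)) {
    m <- mem[i, ]
    cat4[i] <- classify_variant(impact[i], m, "FOUR")
    cat5[i] <- classify_variant(impact[i], m, "FIVE")
    cat8[i] <- classify_variant(impact[i], m, "EIGHT")
  }
  data.frame(variant_id = variants$id, impact = impact,
             oc = mem[, "oc"], utr = mem[, "utr"], re = mem[, "re"],
             ncrna = mem[, "ncrna"],
             cat4 = cat4, cat5 = cat5, cat8 = cat8,
             stringsAsFactors = FALSE)
}

#' Genome-wide category census
#'
#' Counts variants per category over all tested (post-QC) variants — the
#' denominator of the enrichment and weight computations, not just the
#' candidate sets.
#'
#' @param assignment Data frame from [assign_categories()].
#' @param scheme `"FOUR"`, `"FIVE"` or `"EIGHT"`.
#' @return List with `T` (total count), `T_C` (named counts) and
#'   `genomic_frequency` (named, sums to 1).
#' @export
category_census <- function(assignment, scheme) {
  cats <- scheme_categories(scheme)
  col <- switch(toupper(scheme), FOUR = "cat4", FIVE = "cat5", EIGHT = "cat8")
  lab <- factor(assignment[[col]], levels = cats)
  if (anyNA(lab)) stop("assignment contains labels outside scheme ", scheme)
  T_C <- table(lab)
  T_C <- setNames(as.integer(T_C), names(T_C))
  total <- sum(T_C)
  list(T = total, T_C = T_C, genomic_frequency = T_C / total,
       scheme = toupper(scheme))
}

#' Tally of retained highest-impact consequence terms
#'
#' For each variant the single highest-impact term is retained (ties broken
#' by first occurrence) and tallied — the overall distribution of
#' annotations across the variant set.
#'
#' @inheritParams assign_categories
#' @return Data frame `consequence`, `n`, sorted by decreasing count.
#' @export
summarize_consequences <- function(annotations, impact_map = vep_impact_map()) {
  pick <- function(terms) {
    imp <- impact_map[terms]
    imp[is.na(imp)] <- "MODIFIER"
    terms[which.min(match(imp, IMPACT_LEVELS))]
  }
  retained <- vapply(split(annotations$consequence, annotations$variant_id),
                     pick, character(1))
  tab <- sort(table(retained), decreasing = TRUE)
  data.frame(consequence = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
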