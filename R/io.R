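#' Read genotype dosages from a VCF
#'
#' Dosage is taken from the DS FORMAT field when present for an entry, else
#' computed as the alt-allele count of GT.  Missing genotypes are
#' mean-imputed per variant for analysis and flagged; variants missing in
#' more than `max_missing` of samples are dropped.  Only bi-allelic SNV
#' records are accepted.
#'
#' @param path VCF file (plain or bgzipped).
#' @param max_missing Maximum fraction of missing genotypes per variant.
#' @return A `genotype_matrix` (see [simulate_genotypes()]) with an extra
#'   element `missingness` (per-variant fraction imputed).
#' @export
read_vcf_dosages <- function(path, max_missing = 0.1) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0) stop("VCF has no genotype columns")
  fmt <- vcf@gt[, 1]
  has_gt <- any(grepl("GT", fmt, fixed = TRUE))
  has_ds <- any(grepl("DS", fmt, fixed = TRUE))
  if (!has_gt && !has_ds) stop("VCF has neither GT nor DS FORMAT fields")

  bi <- vcfR::is.biallelic(vcf)
  if (!all(bi)) {
    warning(sum(!bi), " non-bi-allelic record(s) dropped")
    vcf <- vcf[bi, ]
  }
  fix <- vcfR::getFIX(vcf)
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"],
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  no_id <- is.na(variants$id) | variants$id == "."
  variants$id[no_id] <- paste0(variants$chrom[no_id], ":", variants$pos[no_id])
  if (anyDuplicated(variants[c("chrom", "pos", "ref", "alt")])) {
    stop("duplicate (chrom, pos, ref, alt) records in VCF")
  }

  ds <- if (has_ds) vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE) else NULL
  dose <- NULL
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alt_count <- function(x) {
      out <- rep(NA_real_, length(x))
      ok <- !is.na(x) & !grepl("\\.", x)
      alleles <- strsplit(gsub("\\|", "/", x[ok]), "/", fixed = FALSE)
      out[ok] <- vapply(alleles, function(a) sum(a != "0"), numeric(1))
      out
    }
    dose <- apply(gt, 2, alt_count)
    if (is.null(dim(dose))) dose <- matrix(dose, nrow = nrow(gt))
    dimnames(dose) <- dimnames(gt)
  }
  if (!is.null(ds)) {
    if (is.null(dose)) dose <- ds else dose[!is.na(ds)] <- ds[!is.na(ds)]
  }

  dose <- t(dose)  # samples x variants
  colnames(dose) <- variants$id
  miss_frac <- colMeans(is.na(dose))
  keep <- miss_frac <= max_missing
  if (!all(keep)) {
    warning(sum(!keep), " variant(s) dropped for missingness > ", max_missing)
    dose <- dose[, keep, drop = FALSE]
    variants <- variants[keep, , drop = FALSE]
    miss_frac <- miss_frac[keep]
  }
  for (j in which(miss_frac > 0)) {
    m <- mean(dose[, j], na.rm = TRUE)
    dose[is.na(dose[, j]), j] <- m
  }
  structure(list(dosage = dose, variants = variants,
                 sample_ids = rownames(dose),
                 missingness = setNames(miss_frac, variants$id)),
            class = "genotype_matrix")
}

#' Read a BED file as 1-based inclusive intervals
#'
#' BED's 0-based half-open \[start, end) is converted to 1-based inclusive
#' \[start + 1, end\] at this boundary; all internal coordinates are
#' 1-based inclusive.
#'
#' @param path 3+ column BED file (no header).
#' @param name Interval class label (e.g. "oc", "utr", "re", "ncrna").
#' @return Data frame `chrom`, `start`, `end` with attribute `name`.
#' @export
read_bed_intervals <- function(path, name = basename(path)) {
  bed <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    fill = FALSE, sep = "")
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns: ", path)
  bed <- bed[, 1:3]
  bed[[1]] <- as.character(bed[[1]])
  names(bed) <- c("chrom", "start0", "end")
  bad <- which(bed$end <= bed$start0)
  if (length(bad) > 0) {
    stop("BED record(s) with end <= start at line(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  out <- data.frame(chrom = as.character(bed$chrom),
                    start = bed$start0 + 1L, end = as.integer(bed$end),
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  out
}

#' Write intervals as BED (converting back to 0-based half-open)
#'
#' @param intervals Data frame `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output file.
#' @export
write_bed_intervals <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a VEP-style annotation table
#'
#' Expects tab-separated VEP output with a variant identifier column
#' (`#Uploaded_variation` or `Uploaded_variation`) and a `Consequence`
#' column whose comma-separated terms are split; multiple rows per variant
#' (one per transcript) are allowed and all terms are collected.
#'
#' @param path VEP TSV.
#' @param known_ids Optional variant ids of the genotype set; annotated
#'   variants absent from it trigger a warning (they are retained for the
#'   census only if `keep_unknown`).
#' @param keep_unknown Keep annotation rows for variants not in
#'   `known_ids`.
#' @return Long data frame `variant_id`, `consequence` (one term per row,
#'   de-duplicated per variant).
#' @export
read_vep_table <- function(path, known_ids = NULL, keep_unknown = TRUE) {
  header <- readLines(path, n = 50)
  skip <- sum(grepl("^##", header))
  tab <- read.delim(path, skip = skip, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(tab) <- sub("^#", "", names(tab))
  idcol <- intersect(c("Uploaded_variation", "variant_id", "ID"), names(tab))
  if (length(idcol) == 0) stop("no variant identifier column in VEP table")
  if (!"Consequence" %in% names(tab)) stop("no Consequence column in VEP table")
  terms <- strsplit(tab$Consequence, ",", fixed = TRUE)
  out <- data.frame(variant_id = rep(tab[[idcol[1]]], lengths(terms)),
                    consequence = trimws(unlist(terms)),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  if (!is.null(known_ids)) {
    unknown <- setdiff(unique(out$variant_id), known_ids)
    if (length(unknown) > 0) {
      warning(length(unknown),
              " annotated variant(s) absent from the genotype set")
      if (!keep_unknown) out <- out[out$variant_id %in% known_ids, ]
    }
  }
  out
}

#' Write a minimal GT-only VCF for simulated genotypes
#'
#' @param genotypes A `genotype_matrix` with integer dosages in 0..2.
#' @param path Output path (plain text).
#' @export
write_vcf_genotypes <- function(genotypes, path) {
  v <- genotypes$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=annogwas_simulator",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$sample_ids),
                     collapse = "\t")), con)
  dm <- t(genotypes$dosage)  # variants x samples
  gt <- matrix(gt_codes[dm + 1L], nrow = nrow(dm))
  lines <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a VEP-style annotation table
#'
#' One row per (variant, consequence) with the minimal columns the reader
#' requires.
#'
#' @param annotations Long data frame `variant_id`, `consequence`.
#' @param variants Variant coordinate table (chrom/pos/id).
#' @param path Output path.
#' @export
write_vep_table <- function(annotations, variants, path) {
  loc <- paste0(variants$chrom, ":", variants$pos)[
    match(annotations$variant_id, variants$id)]
  tab <- data.frame("#Uploaded_variation" = annotations$variant_id,
                    Location = loc, Allele = "G",
                    Consequence = annotations$consequence,
                    IMPACT = "-", check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a TSV results table
#'
#' Plain tab-separated writer used for all pipeline outputs; numeric values
#' keep full double precision so tables round-trip through
#' [read_results_table()].
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_results_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV results table
#'
#' @param path File written by [write_results_table()].
#' @return Data frame.
#' @export
read_results_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be YAML or JSON: ", path)
}
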