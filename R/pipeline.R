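#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()], with the
#' field-standard defaults: r2_min = 0.2, maf_min = 0.01, hwe_min = 1e-6,
#' alpha = 0.05, 100 bootstrap resamples.  `threshold_neglog10 = "auto"`
#' sets the genome-wide significance threshold to the flat Bonferroni
#' threshold for the number of post-QC tests (for 16,503,508 tests this
#' is the conventional 8.5); a fixed number may be supplied instead.
#'
#' @param ... Overrides of any default field.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # simulation (used by the "simulate" stage)
    n_samples = 300, n_variants = 5000, n_chromosomes = 2,
    ld_block_size = 25, maf_range = c(0.05, 0.5),
    n_causal = 10, heritability = 0.5, seed = 1L,
    # analysis
    threshold_neglog10 = "auto", r2_min = 0.2, maf_min = 0.01,
    hwe_min = 1e-6, scheme = "EIGHT", n_boot = 100, alpha = 0.05,
    model = "ols", condition_on_lone = TRUE, ci = "normal",
    normalizer = "all", tukey = FALSE, trait = "trait")
  modifyList(defaults, list(...))
}

pipeline_paths <- function(outdir) {
  files <- c(
    vcf = "genotypes.vcf", phenotype = "phenotype.tsv",
    vep = "annotations.tsv", truth = "truth.tsv",
    oc = "oc.bed", utr = "utr.bed", re = "re.bed", ncrna = "ncrna.bed",
    assoc = "assoc_round1.tsv", qtl = "qtl.tsv",
    candidates = "candidates.tsv", assignment = "assignment.tsv",
    census = "census.tsv", consequences = "consequence_summary.tsv",
    enrichment = "enrichment.tsv", thresholds = "thresholds.tsv",
    comparison = "comparison.tsv", new_sig = "new_significant.tsv",
    power = "power.tsv", config = "config_used.yaml")
  setNames(file.path(outdir, files), names(files))
}

require_stage_inputs <- function(paths, keys, producer) {
  missing <- keys[!file.exists(paths[keys])]
  if (length(missing) > 0) {
    stop("missing input file(s) ", paste(basename(paths[missing]),
                                         collapse = ", "),
         "; run the '", producer, "' stage first", call. = FALSE)
  }
}

load_pipeline_inputs <- function(paths, cfg) {
  geno <- read_vcf_dosages(paths[["vcf"]])
  phen <- read_results_table(paths[["phenotype"]])
  phen <- phen[match(geno$sample_ids, phen$sample_id), ]
  keep <- qc_filter(geno, maf_min = cfg$maf_min, hwe_min = cfg$hwe_min)
  geno_qc <- subset_genotypes(geno, keep)
  y <- phen$value
  if (isTRUE(cfg$tukey)) {
    ok <- tukey_filter(y)
    y <- y[ok]
    geno_qc$dosage <- geno_qc$dosage[ok, , drop = FALSE]
    geno_qc$sample_ids <- geno_qc$sample_ids[ok]
  }
  thr <- cfg$threshold_neglog10
  if (identical(thr, "auto")) {
    thr <- flat_bonferroni(cfg$alpha, ncol(geno_qc$dosage))$neglog10
  }
  list(geno = geno_qc, y = y, threshold = as.numeric(thr))
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate`, `gwas`, `detect-qtl` (includes candidate
#' extraction), `annotate`, `enrich`, `thresholds`, `apply`,
#' `power-experiment`, `all`.  Each stage reads its declared inputs from
#' `outdir`, writes TSV outputs there, and fails with an actionable error
#' naming the producing stage when an input is missing.  The effective
#' configuration is echoed to `config_used.yaml`.
#'
#' @param stage Stage name.
#' @param config List from [pipeline_config()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the paths of the files written.
#' @export
run_stage <- function(stage, config = pipeline_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- pipeline_paths(outdir)
  cfg <- config
  yaml::write_yaml(cfg, paths[["config"]])
  written <- character(0)

  if (stage == "all") {
    for (st in c("simulate", "gwas", "detect-qtl", "annotate", "enrich",
                 "thresholds", "apply")) {
      written <- c(written, run_stage(st, config, outdir))
    }
    return(invisible(unique(written)))
  }

  if (stage == "simulate") {
    sim_cfg <- sim_config(
      n_samples = cfg$n_samples, n_variants = cfg$n_variants,
      n_chromosomes = cfg$n_chromosomes, ld_block_size = cfg$ld_block_size,
      maf_range = cfg$maf_range, n_causal = cfg$n_causal,
      heritability = cfg$heritability, seed = cfg$seed)
    genome <- simulate_annotated_genome(sim_cfg)
    geno <- simulate_genotypes(sim_cfg)
    phen <- simulate_phenotypes(geno, genome$categories, sim_cfg)
    write_vcf_genotypes(geno, paths[["vcf"]])
    write_results_table(phen$phenotype, paths[["phenotype"]])
    write_vep_table(genome$annotations, genome$variants, paths[["vep"]])
    write_results_table(phen$truth, paths[["truth"]])
    for (nm in c("oc", "utr", "re", "ncrna")) {
      write_bed_intervals(genome$interval_sets[[nm]], paths[[nm]])
    }
    written <- paths[c("vcf", "phenotype", "vep", "truth", "oc", "utr",
                       "re", "ncrna")]
  } else if (stage == "gwas") {
    require_stage_inputs(paths, c("vcf", "phenotype"), "simulate")
    inp <- load_pipeline_inputs(paths, cfg)
    res <- assoc_scan(inp$geno, inp$y, model = cfg$model)
    write_results_table(res, paths[["assoc"]])
    written <- paths[["assoc"]]
  } else if (stage == "detect-qtl") {
    require_stage_inputs(paths, c("vcf", "phenotype"), "simulate")
    inp <- load_pipeline_inputs(paths, cfg)
    det <- detect_qtl(inp$geno, inp$y, trait = cfg$trait,
                      threshold = inp$threshold, r2_min = cfg$r2_min,
                      condition_on_lone = cfg$condition_on_lone,
                      model = cfg$model)
    qtl <- det$qtl
    if (is.null(qtl)) {
      qtl <- data.frame(lead_id = character(0), chrom = character(0),
                        pos = integer(0), round = integer(0),
                        neglog10p = numeric(0), conditioned_on = character(0),
                        trait = character(0), qtl_id = character(0),
                        n_candidates = integer(0))
    }
    cand <- det$candidates
    if (is.null(cand)) {
      cand <- data.frame(variant_id = character(0), r2 = numeric(0),
                         round1_neglog10p = numeric(0), qtl_id = character(0))
    }
    write_results_table(qtl, paths[["qtl"]])
    write_results_table(cand, paths[["candidates"]])
    write_results_table(det$round1, paths[["assoc"]])
    written <- paths[c("qtl", "candidates", "assoc")]
  } else if (stage == "annotate") {
    require_stage_inputs(paths, c("vcf", "vep", "oc", "utr", "re", "ncrna"),
                         "simulate")
    geno <- read_vcf_dosages(paths[["vcf"]])
    keep <- qc_filter(geno, maf_min = cfg$maf_min, hwe_min = cfg$hwe_min)
    geno_qc <- subset_genotypes(geno, keep)
    interval_sets <- lapply(
      setNames(c("oc", "utr", "re", "ncrna"), c("oc", "utr", "re", "ncrna")),
      function(nm) read_bed_intervals(paths[[nm]], nm))
    ann <- read_vep_table(paths[["vep"]], known_ids = geno_qc$variants$id)
    assignment <- assign_categories(geno_qc$variants, ann, interval_sets)
    write_results_table(assignment, paths[["assignment"]])
    census <- category_census(assignment, cfg$scheme)
    write_results_table(
      data.frame(category = names(census$T_C), T_C = census$T_C,
                 genomic_frequency = census$genomic_frequency),
      paths[["census"]])
    write_results_table(summarize_consequences(ann), paths[["consequences"]])
    written <- paths[c("assignment", "census", "consequences")]
  } else if (stage == "enrich") {
    require_stage_inputs(paths, "candidates", "detect-qtl")
    require_stage_inputs(paths, "assignment", "annotate")
    cand <- read_results_table(paths[["candidates"]])
    if (nrow(cand) == 0) stop("no QTL candidates; nothing to estimate")
    assignment <- read_results_table(paths[["assignment"]])
    census <- category_census(assignment, cfg$scheme)
    counts <- qtl_category_counts(cand, assignment, cfg$scheme)
    est <- bootstrap_enrichment(counts, census, n_boot = cfg$n_boot,
                                seed = cfg$seed, ci = cfg$ci)
    write_results_table(est$table, paths[["enrichment"]])
    written <- paths[["enrichment"]]
  } else if (stage == "thresholds") {
    require_stage_inputs(paths, "enrichment", "enrich")
    require_stage_inputs(paths, "assignment", "annotate")
    enr <- read_results_table(paths[["enrichment"]])
    assignment <- read_results_table(paths[["assignment"]])
    census <- category_census(assignment, cfg$scheme)
    fb <- flat_bonferroni(cfg$alpha, census$T)
    e <- setNames(enr$enrichment, enr$category)
    w <- category_weights(e, census, normalizer = cfg$normalizer)
    tt <- category_thresholds(w, fb$p_bc, e)
    tt$T_C <- as.integer(census$T_C[tt$category])
    tt$p_bc <- fb$p_bc
    write_results_table(tt, paths[["thresholds"]])
    written <- paths[["thresholds"]]
  } else if (stage == "apply") {
    require_stage_inputs(paths, "assoc", "gwas")
    require_stage_inputs(paths, "assignment", "annotate")
    require_stage_inputs(paths, "thresholds", "thresholds")
    res <- read_results_table(paths[["assoc"]])
    assignment <- read_results_table(paths[["assignment"]])
    ttab <- read_results_table(paths[["thresholds"]])
    tt <- category_thresholds(setNames(ttab$weight, ttab$category),
                              ttab$p_bc[1],
                              setNames(ttab$enrichment, ttab$category))
    appl <- apply_thresholds(res, assignment, tt, cfg$scheme)
    write_results_table(appl$comparison, paths[["comparison"]])
    write_results_table(
      data.frame(variant_id = appl$new_significant), paths[["new_sig"]])
    written <- paths[c("comparison", "new_sig")]
  } else if (stage == "power-experiment") {
    sim_cfg <- sim_config(
      n_samples = cfg$n_samples, n_variants = cfg$n_variants,
      n_chromosomes = cfg$n_chromosomes, ld_block_size = cfg$ld_block_size,
      maf_range = cfg$maf_range, n_causal = cfg$n_causal,
      heritability = cfg$heritability, seed = cfg$seed)
    pow <- power_experiment(sim_cfg, scheme = cfg$scheme,
                            n_replicates = cfg$n_replicates %||% 10,
                            seed = cfg$seed, alpha = cfg$alpha)
    write_results_table(pow, paths[["power"]])
    written <- paths[["power"]]
  } else {
    stop("unknown stage: ", stage)
  }
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole pipeline
#'
#' Convenience wrapper equivalent to `run_stage("all", ...)`.
#'
#' @inheritParams run_stage
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  run_stage("all", config, outdir)
}
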