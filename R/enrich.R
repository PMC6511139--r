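#' Per-QTL candidate category counts
#'
#' Builds the Q x C count matrix n_qC (candidates of category C in QTL q)
#' that the enrichment estimator consumes.
#'
#' @param candidates Data frame `qtl_id`, `variant_id` (from
#'   [detect_qtl()]; lists from several traits may be row-bound).
#' @param assignment Data frame from [assign_categories()].
#' @param scheme `"FOUR"`, `"FIVE"` or `"EIGHT"`.
#' @return Integer matrix, rows = QTL, columns = scheme categories.
#' @export
qtl_category_counts <- function(candidates, assignment, scheme) {
  cats <- scheme_categories(scheme)
  col <- switch(toupper(scheme), FOUR = "cat4", FIVE = "cat5", EIGHT = "cat8")
  lab <- assignment[[col]][match(candidates$variant_id, assignment$variant_id)]
  if (anyNA(lab)) {
    stop("candidate variant(s) missing category assignment: ",
         paste(head(candidates$variant_id[is.na(lab)], 5), collapse = ", "))
  }
  tab <- table(factor(candidates$qtl_id, levels = unique(candidates$qtl_id)),
               factor(lab, levels = cats))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), cats))
  if (any(rowSums(counts) < 1)) stop("QTL with an empty candidate set")
  counts
}

#' Maximum-likelihood category enrichment (EM)
#'
#' Model: each QTL harbors exactly one causal variant; within a QTL the
#' causal prior over candidates is proportional to the per-variant
#' category rate lambda_C.  The likelihood L(lambda) = prod_q
#' sum_C n_qC * lambda_C is maximized subject to
#' sum_C lambda_C * (T_C / T) = 1 by EM: the E-step computes the
#' responsibility r_qC = n_qC lambda_C / sum n_qC' lambda_C'; the M-step
#' sets pi_C = mean_q r_qC and lambda_C = pi_C / (T_C / T).  pi_C is the
#' probability that a causal variant is of category C; the enrichment e_C
#' = lambda_C is that probability divided by the category's genomic
#' frequency.  Categories absent from every candidate set get pi = e = 0.
#'
#' @param qtl_counts Matrix from [qtl_category_counts()].
#' @param census List from [category_census()] (same scheme).
#' @param tol Convergence tolerance on max |delta lambda|.
#' @param max_iter Iteration cap.
#' @return List of class `enrichment_estimate`: `pi`, `enrichment` (named
#'   per category), `n_candidates`, `loglik` (per-iteration trace),
#'   `converged`, `census`.
#' @export
estimate_enrichment <- function(qtl_counts, census, tol = 1e-8,
                                max_iter = 10000) {
  if (is.null(dim(qtl_counts)) || nrow(qtl_counts) == 0) {
    stop("need at least one QTL")
  }
  cats <- colnames(qtl_counts)
  f <- census$genomic_frequency[cats]
  if (anyNA(f)) stop("census does not cover all count categories")
  present <- colSums(qtl_counts) > 0
  if (any(present & f == 0)) {
    stop("category with candidates but zero genomic frequency: ",
         paste(cats[present & f == 0], collapse = ", "))
  }
  Q <- nrow(qtl_counts)
  lambda <- setNames(rep(1, length(cats)), cats)
  lambda[!present] <- 0
  # renormalize the start point onto the constraint surface
  lambda <- lambda / sum(lambda * f)
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.vector(qtl_counts %*% lambda)
    loglik <- c(loglik, sum(log(s)))
    r <- qtl_counts * rep(lambda, each = Q) / s
    pi <- colMeans(r)
    new_lambda <- ifelse(f > 0, pi / f, 0)
    delta <- max(abs(new_lambda - lambda))
    lambda <- new_lambda
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(pi = pi, enrichment = lambda,
                 n_candidates = colSums(qtl_counts),
                 loglik = loglik, converged = converged, census = census),
            class = "enrichment_estimate")
}

#' Bootstrap confidence intervals for category enrichment
#'
#' The QTL list is resampled with replacement (Q draws) `n_boot` times and
#' the estimator re-run on each resample.  The default 95% CI is the
#' normal approximation, point estimate +/- 1.96 x bootstrap SD; a
#' percentile CI is available via `ci`.
#'
#' @inheritParams estimate_enrichment
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer seed (resampling is deterministic given it).
#' @param ci `"normal"` (default) or `"percentile"`.
#' @return `enrichment_estimate` with a data frame element `table`:
#'   category, n_candidates, pi, enrichment, boot_mean, boot_se, ci_low,
#'   ci_high.
#' @export
bootstrap_enrichment <- function(qtl_counts, census, n_boot = 100,
                                 seed = 1L, ci = c("normal", "percentile")) {
  ci <- match.arg(ci)
  if (n_boot < 2) stop("need at least 2 bootstrap resamples")
  est <- estimate_enrichment(qtl_counts, census)
  Q <- nrow(qtl_counts)
  set.seed(seed)
  boots <- matrix(NA_real_, nrow = n_boot, ncol = ncol(qtl_counts),
                  dimnames = list(NULL, colnames(qtl_counts)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(Q, Q, replace = TRUE)
    boots[b, ] <- estimate_enrichment(qtl_counts[idx, , drop = FALSE],
                                      census)$enrichment
  }
  boot_mean <- colMeans(boots)
  boot_se <- apply(boots, 2, sd)
  if (ci == "normal") {
    ci_low <- est$enrichment - 1.96 * boot_se
    ci_high <- est$enrichment + 1.96 * boot_se
  } else {
    qs <- apply(boots, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    ci_low <- qs[1, ]; ci_high <- qs[2, ]
  }
  est$boot <- boots
  est$table <- data.frame(
    category = colnames(qtl_counts),
    n_candidates = as.integer(est$n_candidates),
    pi = as.numeric(est$pi),
    enrichment = as.numeric(est$enrichment),
    boot_mean = as.numeric(boot_mean),
    boot_se = as.numeric(boot_se),
    ci_low = as.numeric(ci_low),
    ci_high = as.numeric(ci_high),
    stringsAsFactors = FALSE)
  est
}

#' Constrained-likelihood grid search for two categories
#'
#' Independent check of the EM estimator for the 2-category case: the
#' constraint leaves one free parameter, scanned on a grid.
#'
#' @param qtl_counts Q x 2 count matrix.
#' @param census Matching census.
#' @param resolution Grid step on pi_1.
#' @return Named enrichment vector at the grid maximum.
#' @export
grid_search_enrichment <- function(qtl_counts, census, resolution = 1e-6) {
  stopifnot(ncol(qtl_counts) == 2)
  cats <- colnames(qtl_counts)
  f <- census$genomic_frequency[cats]
  pi1 <- seq(0, 1, by = resolution)
  n1 <- qtl_counts[, 1]; n2 <- qtl_counts[, 2]
  # evaluate in chunks to bound memory
  best_ll <- -Inf; best_pi1 <- NA_real_
  chunk <- 100000
  for (start in seq(1, length(pi1), by = chunk)) {
    p <- pi1[start:min(start + chunk - 1, length(pi1))]
    l1 <- p / f[1]; l2 <- (1 - p) / f[2]
    ll <- colSums(log(outer(n1, l1) + outer(n2, l2)))
    i <- which.max(ll)
    if (ll[i] > best_ll) { best_ll <- ll[i]; best_pi1 <- p[i] }
  }
  setNames(c(best_pi1 / f[1], (1 - best_pi1) / f[2]), cats)
}
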