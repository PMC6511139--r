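#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts
#' against expected Hardy-Weinberg proportions at the sample allele
#' frequency.  Monomorphic sites return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return P-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  observed <- c(n_AA, n_Aa, n_aa)
  chi2 <- sum((observed - expected)^2 / expected)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

# Genotype counts from (possibly fractional) dosages: fractional values are
# rounded to the nearest genotype for the HWE test only.
dosage_geno_counts <- function(d) {
  g <- round(d)
  c(n_aa = sum(g == 0), n_Aa = sum(g == 1), n_AA = sum(g == 2))
}

#' Minor allele frequency from dosages
#'
#' Allele frequency is mean dosage / 2, folded to the minor allele.
#'
#' @param d Dosage vector (0-2 scale).
#' @return MAF in \[0, 0.5\].
#' @export
dosage_maf <- function(d) {
  p <- mean(d) / 2
  min(p, 1 - p)
}

#' Quality-control filter on variants
#'
#' Keeps a variant iff MAF >= `maf_min` and its HWE test p-value >=
#' `hwe_min` (i.e. excludes variants with MAF below 1% or deviating from
#' Hardy-Weinberg proportions at P < 1e-6, by default).
#'
#' @param genotypes A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency retained.
#' @param hwe_min Minimum HWE p-value retained.
#' @return Character vector of retained variant ids.
#' @export
qc_filter <- function(genotypes, maf_min = 0.01, hwe_min = 1e-6) {
  d <- genotypes$dosage
  maf <- apply(d, 2, dosage_maf)
  hwe <- apply(d, 2, function(x) {
    cnt <- dosage_geno_counts(x)
    hwe_test(cnt[["n_AA"]], cnt[["n_Aa"]], cnt[["n_aa"]])
  })
  colnames(d)[maf >= maf_min & hwe >= hwe_min]
}

#' Subset a genotype matrix to chosen variants
#'
#' @param genotypes A `genotype_matrix`.
#' @param ids Variant ids to keep (order preserved as given).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(genotypes, ids) {
  keep <- match(ids, colnames(genotypes$dosage))
  if (anyNA(keep)) stop("unknown variant id(s): ",
                        paste(head(ids[is.na(keep)], 5), collapse = ", "))
  structure(list(dosage = genotypes$dosage[, keep, drop = FALSE],
                 variants = genotypes$variants[keep, , drop = FALSE],
                 sample_ids = genotypes$sample_ids),
            class = "genotype_matrix")
}

#' Tukey outlier filter for phenotypes
#'
#' Keeps values within \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] (fences inclusive);
#' quartiles by linear interpolation between order statistics
#' (`quantile(type = 7)`).
#'
#' @param values Numeric phenotype vector.
#' @return Logical vector: TRUE for retained values.
#' @export
tukey_filter <- function(values) {
  if (length(values) < 4) {
    warning("fewer than 4 values; Tukey filter passed through")
    return(rep(TRUE, length(values)))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
}

# -log10 two-sided p from a t statistic, computed on the log scale so
# extreme statistics do not underflow.
neglog10_p_t <- function(tstat, df) {
  -(log(2) + pt(-abs(tstat), df = df, log.p = TRUE)) / log(10)
}

NEGLOG10_XMIN <- -log10(.Machine$double.xmin)

#' Single-marker association scan
#'
#' Fits `trait = intercept + beta * dosage + gamma * covariates` per
#' variant by ordinary least squares with a two-sided Wald (t) test, or by
#' an eigen-rotated mixed model (`model = "lmm"`, see Details).  Covariates
#' are typically the dosages of already-detected lead SNPs (conditional
#' scan).  Variants collinear with the covariates are reported with p = 1
#' and flag `"collinear"`; monomorphic variants with flag `"monomorphic"`
#' and NA results; perfect fits (zero residual variance) are flagged
#' `"boundary"` with the p-value clamped at the smallest representable
#' double.
#'
#' @details The mixed model builds a genomic relationship matrix from
#' standardized dosages, estimates the variance ratio once on the null
#' model by REML profiling over the GRM eigenvalues, and then tests each
#' variant by generalized least squares on the eigen-rotated data.
#'
#' @param genotypes A `genotype_matrix` (samples aligned with `phenotype`).
#' @param phenotype Numeric trait vector, one value per sample.
#' @param covariate_dosages Optional numeric matrix (samples x covariates).
#' @param model `"ols"` (default) or `"lmm"`.
#' @param round Conditioning round index recorded in the output (1 =
#'   unconditional).
#' @return Data frame: `id`, `chrom`, `pos`, `maf`, `beta`, `se`, `p`,
#'   `neglog10p`, `round`, `flag`.
#' @export
assoc_scan <- function(genotypes, phenotype, covariate_dosages = NULL,
                       model = c("ols", "lmm"), round = 1L) {
  model <- match.arg(model)
  G <- genotypes$dosage
  n <- nrow(G)
  if (length(phenotype) != n) stop("phenotype length does not match samples")
  k <- if (is.null(covariate_dosages)) 0L else ncol(covariate_dosages)
  if (n <= 2 + k) stop("too few samples for ", k, " covariate(s)")

  y <- phenotype
  X <- cbind(intercept = rep(1, n), covariate_dosages)

  if (model == "lmm") {
    rot <- lmm_rotation(G, y, X)
    y <- rot$y; X <- rot$X; G <- rot$G
  }

  qrX <- qr(X)
  yr <- qr.resid(qrX, y)
  Gr <- qr.resid(qrX, G)
  df <- n - qrX$rank - 1  # rank, so degenerate covariates do not cost df

  g_ss <- colSums(Gr^2)
  raw_var <- apply(G, 2, var)
  y_ss <- sum(yr^2)
  xy <- colSums(Gr * yr)

  beta <- xy / g_ss
  rss <- y_ss - beta^2 * g_ss
  rss[rss < 0] <- 0
  sigma2 <- rss / df
  se <- sqrt(sigma2 / g_ss)
  tstat <- beta / se

  collinear <- g_ss < 1e-10 * pmax(colSums(G^2), 1)
  monomorphic <- raw_var == 0
  boundary <- !collinear & !monomorphic & (sigma2 == 0 | !is.finite(tstat))

  neglog10p <- neglog10_p_t(tstat, df)
  neglog10p[boundary] <- NEGLOG10_XMIN
  p <- 10^(-neglog10p)
  p <- pmax(p, .Machine$double.xmin)

  flag <- rep("", ncol(G))
  flag[boundary] <- "boundary"
  flag[collinear] <- "collinear"
  p[collinear] <- 1; neglog10p[collinear] <- 0
  beta[collinear] <- 0; se[collinear] <- NA_real_
  flag[monomorphic] <- "monomorphic"
  p[monomorphic] <- NA_real_; neglog10p[monomorphic] <- NA_real_
  beta[monomorphic] <- NA_real_; se[monomorphic] <- NA_real_

  data.frame(id = genotypes$variants$id,
             chrom = genotypes$variants$chrom,
             pos = genotypes$variants$pos,
             maf = apply(genotypes$dosage, 2, dosage_maf),
             beta = beta, se = se, p = p, neglog10p = neglog10p,
             round = as.integer(round), flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Eigen-rotation for the mixed model: estimate h2 on the null model by
# REML over the GRM spectrum, then whiten y, X and G.
lmm_rotation <- function(G, y, X) {
  Z <- scale(G)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  Z[is.na(Z)] <- 0
  A <- tcrossprod(Z) / ncol(Z)
  eig <- eigen(A, symmetric = TRUE)
  U <- eig$vectors
  d <- pmax(eig$values, 0)
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  n <- length(y)
  p <- ncol(X)
  reml_nll <- function(h2) {
    v <- h2 * d + (1 - h2)
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    b <- solve(XtWX, XtWy)
    r <- ys - Xs %*% b
    rss <- sum(r^2 * w)
    s2 <- rss / (n - p)
    0.5 * (sum(log(v)) + (n - p) * log(s2) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(reml_nll, interval = c(1e-4, 1 - 1e-4))
  v <- opt$minimum * d + (1 - opt$minimum)
  w <- 1 / sqrt(v)
  list(y = as.vector(ys) * w, X = Xs * w, G = crossprod(U, G) * w,
       h2 = opt$minimum)
}
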