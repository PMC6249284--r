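#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of the observed genotype counts
#' against the p^2 / 2pq / q^2 expectations at the estimated allele
#' frequency. Monomorphic SNPs return p = 1 by convention.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote, in any consistent order).
#' @return List with `chisq`, `df` (1), and `p`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("no genotyped subjects", call. = FALSE)
  p <- (2 * n_aa + n_ab) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) {
    return(list(chisq = 0, df = 1L, p = 1))
  }
  expected <- n * c(p^2, 2 * p * q, q^2)
  chisq <- sum((c(n_aa, n_ab, n_bb) - expected)^2 / expected)
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' SNP-level quality control
#'
#' Removes SNPs with missingness above `max_missing`, Hardy-Weinberg
#' equilibrium p below `hwe_p`, non-autosomal chromosome labels, or minor
#' allele frequency below `min_maf`. A SNP failing several rules is counted
#' under each.
#'
#' @param gm a `genotype_matrix` (see [generate_snp_matrix()]).
#' @param max_missing,hwe_p,min_maf thresholds (defaults 0.05, 1e-4, 0.05).
#' @return List: `gm` (filtered matrix, same class), `report` (counts removed
#'   per rule and totals).
#' @export
snp_qc <- function(gm, max_missing = 0.05, hwe_p = 1e-4, min_maf = 0.05) {
  d <- gm$dosage
  if (is.null(d) || ncol(d) == 0) stop("empty genotype matrix", call. = FALSE)
  miss <- colMeans(is.na(d))
  freq <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  autosomal <- gm$chromosome %in% as.character(1:22)
  hwe_fail <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(TRUE)
    ht <- hwe_test(sum(x == 0), sum(x == 1), sum(x == 2))
    ht$p < hwe_p
  }, logical(1))
  fail_missing <- miss > max_missing
  fail_maf <- maf < min_maf
  keep <- !fail_missing & !hwe_fail & autosomal & !fail_maf
  if (!any(keep)) stop("all SNPs removed by QC", call. = FALSE)
  out <- gm
  out$dosage <- d[, keep, drop = FALSE]
  out$chromosome <- gm$chromosome[keep]
  list(gm = out,
       report = list(n_input = ncol(d), n_retained = sum(keep),
                     removed_missing = sum(fail_missing),
                     removed_hwe = sum(hwe_fail),
                     removed_nonautosomal = sum(!autosomal),
                     removed_maf = sum(fail_maf)))
}

#' Sample-level quality control
#'
#' Removes subjects with genotype missingness above `max_missing` and, when
#' reported sex and X-chromosome SNPs are available, subjects whose inferred
#' sex (X heterozygosity < `male_max` implies male, > `female_min` implies
#' female) contradicts the reported sex. Ambiguous heterozygosity is flagged
#' but not removed.
#'
#' @param gm a `genotype_matrix` with optional `sex` field.
#' @param max_missing per-subject missingness threshold (default 0.03).
#' @param male_max,female_min X-heterozygosity cutoffs (defaults 0.05, 0.15).
#' @return List: `gm` (subjects filtered), `report` (removals and ambiguous
#'   flags).
#' @export
sample_qc <- function(gm, max_missing = 0.03,
                      male_max = 0.05, female_min = 0.15) {
  d <- gm$dosage
  miss <- rowMeans(is.na(d))
  fail_missing <- miss > max_missing
  discordant <- rep(FALSE, nrow(d))
  ambiguous <- rep(FALSE, nrow(d))
  xcols <- gm$chromosome == "X"
  if (any(xcols) && !is.null(gm$sex)) {
    xhet <- rowMeans(d[, xcols, drop = FALSE] == 1, na.rm = TRUE)
    inferred <- ifelse(xhet < male_max, "male",
                       ifelse(xhet > female_min, "female", "ambiguous"))
    ambiguous <- inferred == "ambiguous"
    discordant <- !ambiguous & inferred != gm$sex
  }
  keep <- !fail_missing & !discordant
  out <- gm
  out$dosage <- d[keep, , drop = FALSE]
  out$population <- gm$population[keep]
  out$sex <- gm$sex[keep]
  list(gm = out,
       report = list(n_input = nrow(d), n_retained = sum(keep),
                     removed_missing = sum(fail_missing),
                     removed_sex_discordant = sum(discordant),
                     flagged_ambiguous_sex = sum(ambiguous)))
}

#' Frequency-standardized genotype principal components
#'
#' EIGENSTRAT-style PCA: missing dosages are mean-imputed per SNP, each SNP
#' is centered at twice its allele frequency and scaled by
#' `sqrt(p * (1 - p))`, and the top K left singular vectors of the
#' standardized matrix are returned as subject scores.
#'
#' @param gm a post-QC `genotype_matrix`.
#' @param k number of components (default 10; reduced with a warning if it
#'   exceeds the matrix rank).
#' @return List of class `pca_result`: `components` (subjects x K score
#'   matrix, columns `PC1..PCk`), `eigenvalues` (variances along components).
#' @export
eigenstrat_pca <- function(gm, k = 10) {
  d <- gm$dosage
  n <- nrow(d); m <- ncol(d)
  for (j in seq_len(m)) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  p <- colMeans(d) / 2
  sd_j <- sqrt(p * (1 - p))
  ok <- sd_j > 0
  x <- sweep(d[, ok, drop = FALSE], 2, 2 * p[ok])
  x <- sweep(x, 2, sd_j[ok], "/")
  maxk <- min(n - 1L, sum(ok))
  if (k > maxk) {
    warning("k reduced to matrix rank (", maxk, ")")
    k <- maxk
  }
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(d)
  structure(list(components = scores,
                 eigenvalues = sv$d[seq_len(k)]^2 / (n - 1)),
            class = "pca_result")
}

#' Genomic inflation factor
#'
#' Lambda is the median of the association chi-square statistics divided by
#' the median of the 1-df chi-square distribution (0.4549364); values near 1
#' indicate adequate stratification control.
#'
#' @param chisq vector of 1-df association chi-squares.
#' @return Numeric lambda.
#' @export
genomic_inflation <- function(chisq) {
  if (length(chisq) < 100) {
    warning("fewer than 100 statistics; lambda is unstable")
  }
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Per-SNP trend-test chi-squares for a quantitative trait
#'
#' Score-test style scan used for inflation diagnostics: the trait (and each
#' dosage column) is optionally residualized on covariates, and the per-SNP
#' chi-square is `n * r^2` for the trait-dosage correlation — the 1-df score
#' statistic of the linear trend test.
#'
#' @param gm a `genotype_matrix`.
#' @param trait numeric trait, one value per subject.
#' @param covariates optional numeric matrix to residualize on (e.g. PCs).
#' @return Vector of chi-squares, one per polymorphic SNP.
#' @export
trend_scan <- function(gm, trait, covariates = NULL) {
  d <- gm$dosage
  for (j in seq_len(ncol(d))) {
    nas <- is.na(d[, j])
    if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
  }
  y <- trait
  if (!is.null(covariates)) {
    q <- qr(cbind(1, covariates))
    y <- qr.resid(q, y)
    d <- qr.resid(q, d)
    k <- q$rank
  } else {
    y <- y - mean(y)
    d <- sweep(d, 2, colMeans(d))
    k <- 1L
  }
  sy <- sqrt(sum(y^2))
  sd_j <- sqrt(colSums(d^2))
  ok <- sd_j > 0 & sy > 0
  r <- colSums(d[, ok, drop = FALSE] * y) / (sd_j[ok] * sy)
  # squared t of the (partial) correlation at its residual df; without the
  # df correction lambda is biased upward by ~n / (n - k)
  df <- nrow(d) - k - 1L
  df * r^2 / (1 - r^2)
}
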