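#' Specification for a synthetic two-population SNP matrix
#'
#' Balding-Nichols model: each SNP has an ancestral allele frequency p drawn
#' uniformly from `ancestral_freq_range`; each population's frequency is a
#' Beta draw with mean p and variance `fst * p * (1 - p)`; genotypes are
#' binomial(2) dosages. Used to exercise the stratification-control stage.
#'
#' @param n_snps number of autosomal SNPs.
#' @param n_per_population integer vector of subjects per population.
#' @param fst divergence parameter in (0, 1).
#' @param ancestral_freq_range interval for ancestral frequencies.
#' @param n_x_snps number of X-chromosome SNPs appended (for the sex check).
#' @param seed integer seed.
#' @return An object of class `snp_spec`.
#' @export
snp_spec <- function(n_snps = 5000, n_per_population = c(100, 100),
                     fst = 0.1, ancestral_freq_range = c(0.1, 0.9),
                     n_x_snps = 0, seed = 1L) {
  if (!is.numeric(fst) || fst <= 0 || fst >= 1) {
    stop("`fst` must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(all(ancestral_freq_range > 0), all(ancestral_freq_range < 1),
            n_snps >= 1, all(n_per_population >= 1))
  structure(list(n_snps = as.integer(n_snps),
                 n_per_population = as.integer(n_per_population),
                 fst = fst, ancestral_freq_range = ancestral_freq_range,
                 n_x_snps = as.integer(n_x_snps), seed = as.integer(seed)),
            class = "snp_spec")
}

#' Generate a two-population genotype dosage matrix
#'
#' @param spec a [snp_spec()].
#' @return A list of class `genotype_matrix`: `dosage` (subjects x SNPs,
#'   values 0/1/2 or NA), `chromosome` (per-SNP label, `"1"`-`"22"` cycled,
#'   `"X"` for appended X SNPs), `population` (per-subject), `sex`
#'   (per-subject reported sex; X genotypes are hemizygous for males).
#' @export
generate_snp_matrix <- function(spec) {
  stopifnot(inherits(spec, "snp_spec"))
  set.seed(spec$seed)
  npop <- length(spec$n_per_population)
  n <- sum(spec$n_per_population)
  m <- spec$n_snps
  p_anc <- stats::runif(m, spec$ancestral_freq_range[1],
                        spec$ancestral_freq_range[2])
  a <- p_anc * (1 - spec$fst) / spec$fst
  b <- (1 - p_anc) * (1 - spec$fst) / spec$fst
  pop <- rep(seq_len(npop), spec$n_per_population)
  dosage <- matrix(0L, n, m)
  for (k in seq_len(npop)) {
    pk <- stats::rbeta(m, a, b)
    rows <- which(pop == k)
    dosage[rows, ] <- matrix(
      stats::rbinom(length(rows) * m, 2L, rep(pk, each = length(rows))),
      nrow = length(rows))
  }
  chromosome <- as.character(rep_len(1:22, m))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  if (spec$n_x_snps > 0) {
    px <- stats::runif(spec$n_x_snps, 0.2, 0.8)
    xmat <- matrix(0L, n, spec$n_x_snps)
    male <- sex == "male"
    # males hemizygous: dosage 0 or 2, no heterozygotes
    xmat[male, ] <- matrix(2L * stats::rbinom(sum(male) * spec$n_x_snps, 1L,
                                              rep(px, each = sum(male))),
                           nrow = sum(male))
    xmat[!male, ] <- matrix(stats::rbinom(sum(!male) * spec$n_x_snps, 2L,
                                          rep(px, each = sum(!male))),
                            nrow = sum(!male))
    dosage <- cbind(dosage, xmat)
    chromosome <- c(chromosome, rep("X", spec$n_x_snps))
  }
  rownames(dosage) <- sprintf("S%04d", seq_len(n))
  colnames(dosage) <- sprintf("rs%06d", seq_len(ncol(dosage)))
  structure(list(dosage = dosage, chromosome = chromosome,
                 population = pop, sex = sex),
            class = "genotype_matrix")
}
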