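#' Specification for a synthetic cohort
#'
#' Describes the study cohort the generator emulates: a three-group
#' comprehension-discrepancy cohort (UPC = unexpected poor, EAC = expected
#' average, UGC = unexpected good comprehension) in which the frequency of
#' READ1 RU2Short carriers depends on group, covariates have group-dependent
#' means, and a small fraction of covariate cells is missing completely at
#' random.
#'
#' Default carrier frequencies are 0.47 / 0.37 / 0.32 (UPC / EAC / UGC) and
#' default covariate means/SDs follow the demographic structure of the study
#' population the pipeline was designed for (age in months, receptive
#' vocabulary on a standard-score scale, maternal education in years, binary
#' low-SES, sex, Spanish-home and bilingual flags). Proportions for the
#' language flags are not published for that population and are set to
#' plausible values (0.30 / 0.35).
#'
#' @param n_subjects number of subjects (>= 3).
#' @param carrier_freq_by_group named probabilities for UPC, EAC, UGC.
#' @param group_probs named sampling probabilities of the three groups.
#' @param effect_sizes named list of generating coefficients for the
#'   comprehension score (intercept, age, piq, and one slope per word-level
#'   measure) plus `residual_sd`, the SD of the comprehension residual.
#' @param missing_rate MCAR missingness fraction in `[0, 1)` applied to
#'   `missing_cols`.
#' @param missing_cols covariate columns subject to missingness.
#' @param allele_freqs named READ1 allele frequency vector (IDs as in the
#'   functional-group table; "DEL" = microdeletion). Must sum to 1.
#' @param call_rate probability that a subject's READ1 call is non-missing.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 1000,
                        carrier_freq_by_group = c(UPC = 0.47, EAC = 0.37,
                                                  UGC = 0.32),
                        group_probs = c(UPC = 216, EAC = 530, UGC = 223) / 969,
                        effect_sizes = NULL,
                        missing_rate = 0.015,
                        missing_cols = c("vocabulary", "maternal_education",
                                         "ses", "spanish_home", "bilingual"),
                        allele_freqs = default_allele_freqs(),
                        call_rate = 0.987,
                        seed = 1L) {
  stopifnot(n_subjects >= 3)
  assert_prob(carrier_freq_by_group, "carrier_freq_by_group")
  assert_prob(group_probs, "group_probs")
  assert_prob(call_rate, "call_rate")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  grps <- c("UPC", "EAC", "UGC")
  if (!all(grps %in% names(carrier_freq_by_group))) {
    stop("`carrier_freq_by_group` needs entries named UPC, EAC, UGC",
         call. = FALSE)
  }
  if (abs(sum(allele_freqs) - 1) > 1e-8) {
    stop("`allele_freqs` must sum to 1", call. = FALSE)
  }
  effect_sizes <- effect_sizes %||% list(
    intercept = -5, age = 0.01, piq = 0.30,
    wj_word_attack = 0.04, towre_pde = 0.04,
    wj_letter_word = 0.05, towre_swe = 0.05, sri_word_rec = 0.05,
    residual_sd = 3
  )
  structure(list(
    n_subjects = as.integer(n_subjects),
    carrier_freq_by_group = carrier_freq_by_group[grps],
    group_probs = group_probs[grps] / sum(group_probs[grps]),
    effect_sizes = effect_sizes,
    missing_rate = missing_rate,
    missing_cols = missing_cols,
    allele_freqs = allele_freqs,
    call_rate = call_rate,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default READ1 allele frequency table
#'
#' Covers every allele in the functional-group table plus the microdeletion
#' ("DEL") and one ungrouped allele (7). Frequencies are invented but ordered
#' to make alleles 4/10 (RU2Short) and 5/6 (RU2Long) the common ones.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_allele_freqs <- function() {
  f <- c(`4` = 0.180, `10` = 0.100, `15` = 0.010, `16` = 0.010, `17` = 0.005,
         `21` = 0.005, `24` = 0.005, `26` = 0.005, `30` = 0.002, `37` = 0.002,
         `39` = 0.001,
         `5` = 0.220, `6` = 0.130, `13` = 0.010, `14` = 0.010, `19` = 0.005,
         `20` = 0.005, `22` = 0.005, `23` = 0.005,
         `2` = 0.120, `3` = 0.080, `8` = 0.010, `12` = 0.010, `25` = 0.005,
         `27` = 0.005,
         DEL = 0.030, `7` = 0.025)
  f / sum(f)
}

# truncated standard-normal sampler on [lo, hi] via inverse CDF
rtrunc_norm <- function(n, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo)
  phi <- stats::pnorm(hi)
  stats::qnorm(plo + stats::runif(n) * (phi - plo))
}

#' Generate a synthetic comprehension-discrepancy cohort
#'
#' Group labels are drawn first; READ1 carrier status is then drawn per group
#' at the spec's frequencies, and a genotype (unordered allele pair) is drawn
#' conditional on carrier status. Word-level reading scores, performance IQ
#' and demographic covariates get group-dependent means, and the comprehension
#' score is built from the generating linear model plus a residual whose
#' standardized value is confined to the group's regression band
#' (UPC: z <= -1; EAC: |z| <= 0.5; UGC: z >= +1). MCAR missingness is applied
#' last. Identical spec and seed give identical output.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `cohort` (data.frame, one row per subject) and
#'   `genotypes` (data.frame: subject_id, allele_a, allele_b; NA = no call).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  grps <- c("UPC", "EAC", "UGC")
  group <- sample(grps, n, replace = TRUE, prob = spec$group_probs)

  carrier <- stats::rbinom(n, 1L, spec$carrier_freq_by_group[group]) == 1L
  geno <- draw_read1_pairs(carrier, spec$allele_freqs, spec$call_rate)

  # group-dependent covariate means (age months; vocabulary standard score;
  # maternal education years; P(low SES); P(female))
  mu <- list(
    age  = c(UPC = 143.75, EAC = 131.19, UGC = 148.17),
    age_sd = c(UPC = 25.12, EAC = 24.30, UGC = 23.59),
    vocab = c(UPC = 87.2, EAC = 93.0, UGC = 105.0),
    vocab_sd = c(UPC = 12.7, EAC = 13.9, UGC = 16.2),
    medu = c(UPC = 13.30, EAC = 13.24, UGC = 14.44),
    medu_sd = c(UPC = 2.51, EAC = 2.94, UGC = 3.02),
    ses = c(UPC = 0.599, EAC = 0.535, UGC = 0.338),
    female = c(UPC = 0.484, EAC = 0.450, UGC = 0.449),
    ability = c(UPC = 96.6, EAC = 92.1, UGC = 98.7),
    ability_sd = c(UPC = 10.4, EAC = 13.5, UGC = 13.6)
  )
  age <- stats::rnorm(n, mu$age[group], mu$age_sd[group])
  vocabulary <- stats::rnorm(n, mu$vocab[group], mu$vocab_sd[group])
  maternal_education <- pmin(pmax(
    stats::rnorm(n, mu$medu[group], mu$medu_sd[group]), 6), 20)
  ses <- stats::rbinom(n, 1L, mu$ses[group])
  sex <- ifelse(stats::rbinom(n, 1L, mu$female[group]) == 1L,
                "female", "male")
  spanish_home <- stats::rbinom(n, 1L, 0.30)
  bilingual <- stats::rbinom(n, 1L, 0.35)
  piq <- stats::rnorm(n, 9.3, 2.8)

  # six word-level measures loading on one word-reading ability
  ability <- stats::rnorm(n, mu$ability[group], mu$ability_sd[group])
  word_score <- function() ability + stats::rnorm(n, 0, 6)
  wj_letter_word <- word_score(); wj_word_attack <- word_score()
  towre_swe <- word_score(); towre_pde <- word_score()
  sri_word_rec <- word_score()

  es <- spec$effect_sizes
  z_lo <- c(UPC = -Inf, EAC = -0.5, UGC = 1)[group]
  z_hi <- c(UPC = -1, EAC = 0.5, UGC = Inf)[group]
  resid_z <- rtrunc_norm(n, z_lo, z_hi)
  comprehension <- es$intercept + es$age * age + es$piq * piq +
    es$wj_word_attack * wj_word_attack + es$towre_pde * towre_pde +
    es$wj_letter_word * wj_letter_word + es$towre_swe * towre_swe +
    es$sri_word_rec * sri_word_rec + es$residual_sd * resid_z

  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group, carrier_ru2short = carrier,
    age = age, sex = sex, piq = piq, vocabulary = vocabulary,
    maternal_education = maternal_education, ses = ses,
    spanish_home = spanish_home, bilingual = bilingual,
    wj_letter_word = wj_letter_word, wj_word_attack = wj_word_attack,
    towre_swe = towre_swe, towre_pde = towre_pde,
    sri_word_rec = sri_word_rec, comprehension = comprehension,
    resid_z_true = resid_z,
    stringsAsFactors = FALSE
  )

  if (spec$missing_rate > 0) {
    for (col in spec$missing_cols) {
      miss <- stats::runif(n) < spec$missing_rate
      cohort[[col]][miss] <- NA
    }
  }
  geno$subject_id <- cohort$subject_id
  list(cohort = cohort,
       genotypes = geno[, c("subject_id", "allele_a", "allele_b")])
}

# draw unordered READ1 allele pairs conditional on planted carrier status;
# dual deletions cannot satisfy either carrier value and are redrawn
draw_read1_pairs <- function(carrier, freqs, call_rate) {
  n <- length(carrier)
  ids <- names(freqs)
  short <- intersect(ids, as.character(read1_groups()$ru2short))
  draw <- function(k) sample(ids, k, replace = TRUE, prob = freqs)
  a <- draw(n); b <- draw(n)
  repeat {
    eff_a <- ifelse(a == "DEL", b, a)
    eff_b <- ifelse(b == "DEL", a, b)
    is_car <- (eff_a %in% short) | (eff_b %in% short)
    dual <- a == "DEL" & b == "DEL"
    bad <- dual | (is_car != carrier)
    if (!any(bad)) break
    a[bad] <- draw(sum(bad)); b[bad] <- draw(sum(bad))
  }
  nocall <- stats::runif(n) >= call_rate
  a[nocall] <- NA; b[nocall] <- NA
  data.frame(allele_a = a, allele_b = b, stringsAsFactors = FALSE)
}
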