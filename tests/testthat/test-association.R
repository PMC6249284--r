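test_that("contingency table reproduces planted per-group proportions", {
  sim <- called_cohort(n = 10000, seed = 17, missing_rate = 0)
  ct <- carrier_contingency(sim$cohort$group, sim$cohort$carrier_called)
  expect_lt(abs(ct$proportions[["UPC"]] - 0.47), 0.02)
  expect_lt(abs(ct$proportions[["EAC"]] - 0.37), 0.02)
  expect_lt(abs(ct$proportions[["UGC"]] - 0.32), 0.02)
  # degenerate cases
  all_c <- carrier_contingency(rep(c("UPC", "EAC", "UGC"), 5), rep(TRUE, 15))
  expect_equal(unname(all_c$proportions), c(1, 1, 1))
  one <- carrier_contingency(c("UPC", "EAC", "UGC"), c(TRUE, FALSE, TRUE))
  expect_true(all(one$proportions %in% c(0, 1)))
  expect_error(carrier_contingency(c("UPC", "EAC"), c(TRUE, TRUE)), "UGC")
})

test_that("chi-square matches hand computation and the textbook oracle", {
  flat <- chi_square_independence(matrix(50, 3, 2))
  expect_equal(flat$chisq, 0)
  expect_equal(flat$df, 2)
  expect_equal(flat$p, 1)
  skewed <- chi_square_independence(rbind(c(30, 70), c(50, 50), c(70, 30)))
  expect_equal(skewed$chisq, 32)
  expect_equal(skewed$df, 2)
  set.seed(5)
  for (i in 1:200) {
    counts <- matrix(rpois(6, lambda = 40) + 1, 3, 2)
    got <- chi_square_independence(counts)
    expect_equal(got$chisq, brute_chisq(counts), tolerance = 1e-10)
    expect_equal(got$df, 2)
  }
  expect_error(chi_square_independence(rbind(c(0, 0), c(5, 5), c(5, 5))),
               "expected")
})

test_that("multinomial fit recovers a planted carrier odds ratio", {
  # carrier frequencies chosen so the UGC-vs-UPC carrier OR is exactly 0.60;
  # the estimate averaged over replicates must land inside one fit's Wald
  # half-width (a much tighter event than single-fit coverage)
  f_upc <- 0.47
  f_ugc <- plogis(qlogis(f_upc) + log(0.60))
  ests <- numeric(5)
  half_width <- NA
  for (i in 1:5) {
    sim <- generate_cohort(cohort_spec(
      n_subjects = 4000, missing_rate = 0,
      carrier_freq_by_group = c(UPC = f_upc, EAC = 0.40, UGC = f_ugc),
      seed = 22 + i))
    co <- sim$cohort
    co$carrier_ru2short <- as.numeric(co$carrier_ru2short)
    fit <- fit_multinomial(co, predictors = "carrier_ru2short")
    row <- fit$table[fit$table$contrast == "UGC" &
                       fit$table$term == "carrier_ru2short", ]
    ests[i] <- row$estimate
    half_width <- (log(row$ci_hi) - log(row$ci_lo)) / 2
  }
  expect_lt(abs(mean(ests) - log(0.60)), half_width)
  expect_gt(fit$nagelkerke_r2, 0)
})

test_that("intercept-only model has zero Nagelkerke R2", {
  expect_equal(nagelkerke_r2(100, 100, 50), 0)
  sim <- called_cohort(n = 300, seed = 31, missing_rate = 0)
  co <- sim$cohort
  co$noise <- rnorm(nrow(co))
  fit <- fit_multinomial(co, predictors = "noise")
  expect_lt(fit$nagelkerke_r2, 0.03)
})

test_that("carrier type-I error is near nominal under the null", {
  # null: carrier frequency identical across groups
  set.seed(71)
  reject <- vapply(1:200, function(i) {
    sim <- generate_cohort(cohort_spec(
      n_subjects = 1000, missing_rate = 0,
      carrier_freq_by_group = c(UPC = 0.4, EAC = 0.4, UGC = 0.4),
      seed = 4000 + i))
    co <- sim$cohort
    co$carrier_ru2short <- as.numeric(co$carrier_ru2short)
    fit <- fit_multinomial(co, predictors = c("carrier_ru2short", "age",
                                              "vocabulary"))
    any(fit$table$p[fit$table$term == "carrier_ru2short"] < 0.05)
  }, logical(1))
  # two contrasts tested per replicate; familywise null rate under
  # independence would be just under 0.10, per-contrast 0.05
  expect_lt(mean(reject), 0.14)
  expect_gt(mean(reject), 0.04)
})

test_that("pooling reduces to the single fit when nothing is missing", {
  sim <- called_cohort(n = 600, seed = 41, missing_rate = 0)
  co <- sim$cohort
  co$carrier_ru2short <- as.numeric(co$carrier_ru2short)
  co$sexf <- as.numeric(co$sex == "female")
  preds <- c("age", "sexf", "vocabulary", "carrier_ru2short")
  pooled <- impute_and_pool(co, predictors = preds, m = 3, seed = 1)
  single <- fit_multinomial(co, predictors = preds)
  expect_equal(pooled$table$estimate, unname(single$estimates),
               tolerance = 1e-10)
  expect_true(all(pooled$table$relative_efficiency == 1))
  expect_true(all(pooled$table$gamma == 0))
})

test_that("Rubin formulas obey their limits", {
  fake <- function(est) list(estimates = c(a = est, b = 1),
                             variances = c(a = 0.04, b = 0.01))
  # identical imputations: B = 0, T = W, gamma = 0, RE = 1
  p0 <- pool_rubin(list(fake(0.5), fake(0.5), fake(0.5)))
  expect_equal(p0$table$se[1], 0.2)
  expect_equal(p0$table$gamma[1], 0)
  expect_equal(p0$table$relative_efficiency[1], 1)
  # hand-check T = W + (1 + 1/m) B with m = 2
  p1 <- pool_rubin(list(fake(0), fake(1)))
  b <- stats::var(c(0, 1))
  expect_equal(p1$table$se[1]^2, 0.04 + (1 + 1 / 2) * b)
  expect_gte(p1$table$se[1]^2, 0.04)
})

test_that("imputation fills all cells and respects observed margins", {
  sim <- called_cohort(n = 500, seed = 53, missing_rate = 0.05)
  co <- sim$cohort
  co$carrier_ru2short <- as.numeric(co$carrier_ru2short)
  co <- co[!is.na(co$carrier_ru2short), ]
  vars <- c("group", "age", "vocabulary", "ses", "maternal_education",
            "carrier_ru2short")
  imp <- impute_chained(co, vars, m = 2, n_iter = 3, seed = 9)
  expect_length(imp, 2)
  for (d in imp) expect_false(anyNA(d[, vars]))
  # observed cells are untouched
  obs <- !is.na(co$vocabulary)
  expect_identical(imp[[1]]$vocabulary[obs], co$vocabulary[obs])
  # PMM draws come from observed values
  expect_true(all(imp[[1]]$vocabulary %in% co$vocabulary[obs]))
})

test_that("sensitivity modes behave as specified", {
  sim <- called_cohort(n = 1200, seed = 67, missing_rate = 0)
  co <- sim$cohort
  co$carrier_ru2short <- as.numeric(co$carrier_ru2short)
  co$sex <- as.numeric(co$sex == "female")
  fitm <- fit_residual_model(co)
  co$resid_z <- fitm$z
  preds <- c("age", "vocabulary", "carrier_ru2short")
  # linear mode: carriers sit lower on the residual scale by construction
  lin <- sensitivity_suite(co, "linear", predictors = preds)
  expect_lt(lin$focal$estimate[1], 0)
  expect_lt(lin$focal$p[1], 0.05)
  # no bilinguals: exclusion is a no-op
  co2 <- co
  co2$bilingual <- 0
  base <- fit_multinomial(co2, predictors = preds)
  excl <- sensitivity_suite(co2, "exclude_bilingual", predictors = preds)
  expect_equal(excl$fit$estimates, base$estimates, tolerance = 1e-8)
  # reclassification only grows the extreme bands
  rec <- sensitivity_suite(co, "reclassify", predictors = preds)
  expect_gte(rec$fit$n, base$n)
  expect_error(sensitivity_suite(co[co$bilingual == 1, ], "exclude_bilingual",
                                 predictors = preds), "empty")
})
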