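#' Carrier-by-group contingency table
#'
#' Cross-tabulates comprehension group against READ1 group-carrier status.
#' Missing calls and dual-deletion exclusions are dropped.
#'
#' @param labels group labels (`UPC`, `EAC`, `UGC`; others dropped).
#' @param carrier logical carrier flags (NA = no call / excluded).
#' @return List of class `contingency_table`: `counts` (3 x 2 matrix,
#'   columns carrier / non-carrier), `proportions` (per-group carrier
#'   proportion), `n`.
#' @export
carrier_contingency <- function(labels, carrier) {
  keep <- labels %in% c("UPC", "EAC", "UGC") & !is.na(carrier)
  labels <- factor(labels[keep], levels = c("UPC", "EAC", "UGC"))
  carrier <- carrier[keep]
  counts <- cbind(carrier = tapply(carrier, labels, sum),
                  non_carrier = tapply(!carrier, labels, sum))
  counts[is.na(counts)] <- 0
  empty <- rownames(counts)[rowSums(counts) == 0]
  if (length(empty)) {
    stop("empty group(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts,
                 proportions = counts[, "carrier"] / rowSums(counts),
                 n = sum(counts)),
            class = "contingency_table")
}

#' Pearson chi-square test of independence
#'
#' No continuity correction; df = (rows - 1)(cols - 1). For the 3 x 2
#' carrier table, df = 2.
#'
#' @param counts matrix of nonnegative counts, or a `contingency_table`.
#' @return List with `chisq`, `df`, `p`, and the `expected` counts.
#' @export
chi_square_independence <- function(counts) {
  if (inherits(counts, "contingency_table")) counts <- counts$counts
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) {
    stop("zero expected count; collapse sparse rows or columns",
         call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = expected)
}

#' Multinomial logistic regression for comprehension-group membership
#'
#' Maximum-likelihood multinomial logit with a configurable reference group
#' (UPC by default, so the two coefficient sets contrast EAC vs UPC and UGC
#' vs UPC). Reports odds ratios with symmetric-on-log Wald 95 percent
#' confidence intervals and the Nagelkerke pseudo R-squared.
#'
#' @param data data.frame with the outcome and predictors (complete cases
#'   used; impute first for missing data).
#' @param outcome outcome column (3-level).
#' @param predictors predictor column names.
#' @param reference reference outcome level.
#' @return List of class `multinomial_fit`: `table` (one row per contrast x
#'   term: estimate, se, or, ci_lo, ci_hi, p), `nagelkerke_r2`, `n`,
#'   `estimates`/`variances` (named vectors for pooling), `fit`.
#' @export
fit_multinomial <- function(data, outcome = "group",
                            predictors, reference = "UPC") {
  dat <- data[, c(outcome, predictors)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  y <- dat[[outcome]]
  if (length(unique(y)) != 3) stop("outcome must have 3 levels", call. = FALSE)
  dat[[outcome]] <- stats::relevel(factor(y), ref = reference)
  form <- stats::reformulate(predictors, response = outcome)
  fit <- nnet::multinom(form, data = dat, trace = FALSE, maxit = 500,
                        model = TRUE)
  cf <- stats::coef(fit)
  # scale-free divergence check for separation
  xsd <- vapply(predictors, function(p) {
    v <- dat[[p]]
    if (is.numeric(v)) stats::sd(v) else 1
  }, numeric(1))
  std <- abs(sweep(cf[, -1, drop = FALSE], 2, xsd, "*"))
  if (any(std > 15)) {
    bad <- colnames(std)[apply(std > 15, 2, any)]
    stop("possible separation; divergent coefficient for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vc <- stats::vcov(fit)
  est <- as.vector(t(cf))
  names(est) <- paste(rep(rownames(cf), each = ncol(cf)),
                      rep(colnames(cf), nrow(cf)), sep = ":")
  se <- sqrt(diag(vc))[names(est)]
  zst <- est / se
  p <- 2 * stats::pnorm(-abs(zst))
  tab <- data.frame(
    contrast = sub(":.*", "", names(est)),
    term = sub("^[^:]*:", "", names(est)),
    estimate = est, se = se, or = exp(est),
    ci_lo = exp(est - 1.96 * se), ci_hi = exp(est + 1.96 * se),
    p = p, row.names = NULL, stringsAsFactors = FALSE
  )
  n <- nrow(dat)
  null_fit <- nnet::multinom(stats::reformulate("1", response = outcome),
                             data = dat, trace = FALSE)
  r2 <- nagelkerke_r2(stats::deviance(null_fit), stats::deviance(fit), n)
  structure(list(table = tab, nagelkerke_r2 = r2, n = n,
                 estimates = est, variances = se^2, fit = fit),
            class = "multinomial_fit")
}

#' Nagelkerke pseudo R-squared from model deviances
#'
#' Cox-Snell R2 = 1 - exp((D1 - D0)/n), rescaled by its maximum
#' 1 - exp(-D0/n).
#'
#' @param dev0,dev1 null and fitted model deviances (-2 log L).
#' @param n sample size.
#' @return Numeric in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(dev0, dev1, n) {
  cs <- 1 - exp((dev1 - dev0) / n)
  denom <- 1 - exp(-dev0 / n)
  if (denom <= 0) return(0)
  max(0, cs / denom)
}

# one chained-equation pass over the incomplete columns (in place)
chained_pass <- function(dat, incomplete, miss_idx, rhs_terms, pmm_k = 5) {
  for (v in incomplete) {
    mi <- miss_idx[[v]]
    rhs <- setdiff(rhs_terms, v)
    form <- stats::reformulate(rhs, response = v)
    obs <- dat[-mi, , drop = FALSE]
    x_all <- stats::model.matrix(stats::reformulate(rhs), data = dat)
    x_obs <- x_all[-mi, , drop = FALSE]
    x_mis <- x_all[mi, , drop = FALSE]
    yv <- dat[[v]]
    if (is.numeric(yv) && length(unique(yv[-mi])) > 2) {
      fit <- stats::lm.fit(x_obs, yv[-mi])
      keep <- !is.na(fit$coefficients)
      cf <- fit$coefficients[keep]
      rss <- sum(fit$residuals^2)
      dfres <- length(fit$residuals) - fit$rank
      sig2 <- rss / stats::rchisq(1, dfres)
      r <- qr.R(qr(x_obs[, keep, drop = FALSE]))
      beta <- cf + sqrt(sig2) * backsolve(r, stats::rnorm(length(cf)))
      pred_obs <- drop(x_obs[, keep, drop = FALSE] %*% cf)
      pred_mis <- drop(x_mis[, keep, drop = FALSE] %*% beta)
      # predictive mean matching: draw among k nearest observed predictions
      donors <- vapply(pred_mis, function(pm) {
        nn <- order(abs(pred_obs - pm))[seq_len(min(pmm_k, length(pred_obs)))]
        sample(nn, 1L)
      }, integer(1))
      dat[[v]][mi] <- yv[-mi][donors]
    } else {
      yb <- as.numeric(factor(yv)) - 1
      fit <- suppressWarnings(
        stats::glm.fit(x_obs, yb[-mi], family = stats::binomial()))
      keep <- !is.na(fit$coefficients)
      cf <- fit$coefficients[keep]
      w <- fit$weights
      xw <- x_obs[, keep, drop = FALSE] * sqrt(w)
      r <- qr.R(qr(xw))
      beta <- tryCatch(cf + backsolve(r, stats::rnorm(length(cf))),
                       error = function(e) cf)
      pmis <- stats::plogis(drop(x_mis[, keep, drop = FALSE] %*% beta))
      draws <- stats::rbinom(length(mi), 1L, pmis)
      lev <- sort(unique(yv[-mi]))
      dat[[v]][mi] <- lev[draws + 1L]
    }
  }
  dat
}

#' Chained-equation multiple imputation
#'
#' Fills missing predictor cells by iterated conditional draws: predictive
#' mean matching (5 donors, Bayesian coefficient draws) for continuous
#' columns and Bayesian logistic draws for binary columns, each conditioned
#' on all other model variables including the outcome. Each of the `m`
#' imputations is an independent chain of `n_iter` passes from a random
#' starting fill.
#'
#' @param data data.frame; only `vars` may contain missing values.
#' @param vars columns entering the imputation model (outcome included).
#' @param m number of imputations (default 15).
#' @param n_iter burn-in passes per chain (default 10).
#' @param seed integer seed.
#' @return List of `m` completed data.frames.
#' @export
impute_chained <- function(data, vars, m = 15, n_iter = 10, seed = 1L) {
  set.seed(seed)
  dat0 <- data[, vars, drop = FALSE]
  miss_idx <- lapply(dat0, function(x) which(is.na(x)))
  incomplete <- names(miss_idx)[lengths(miss_idx) > 0]
  if (any(vapply(dat0[incomplete], function(x) mean(is.na(x)), 1) >= 0.5)) {
    stop("a column has >= 50% missingness", call. = FALSE)
  }
  if (!length(incomplete)) return(replicate(m, data, simplify = FALSE))
  out <- vector("list", m)
  for (im in seq_len(m)) {
    dat <- dat0
    for (v in incomplete) {  # random starting fill from observed margins
      mi <- miss_idx[[v]]
      dat[[v]][mi] <- sample(dat[[v]][-mi], length(mi), replace = TRUE)
    }
    for (it in seq_len(n_iter)) {
      dat <- chained_pass(dat, incomplete, miss_idx, rhs_terms = vars)
    }
    completed <- data
    completed[, vars] <- dat
    out[[im]] <- completed
  }
  out
}

#' Pool repeated-imputation fits by Rubin's rules
#'
#' For each coefficient: pooled estimate = mean of the m estimates; within
#' variance W = mean of squared SEs; between variance B = variance of the
#' estimates; total T = W + (1 + 1/m) B. The fraction of missing information
#' uses the large-sample form gamma = (1 + 1/m) B / T, and the relative
#' efficiency of m imputations is (1 + gamma/m)^-1. Wald tests use the
#' Barnard-Rubin small-sample degrees of freedom.
#'
#' @param fits list of `multinomial_fit` objects (or any objects with
#'   `estimates` and `variances` named vectors).
#' @return List of class `pooled_fit`: `table` (term, estimate, se, or, ci,
#'   p, gamma, relative_efficiency), `m`.
#' @export
pool_rubin <- function(fits) {
  m <- length(fits)
  est <- do.call(rbind, lapply(fits, `[[`, "estimates"))
  var_w <- do.call(rbind, lapply(fits, `[[`, "variances"))
  qbar <- colMeans(est)
  w <- colMeans(var_w)
  b <- if (m > 1) apply(est, 2, stats::var) else rep(0, ncol(est))
  tt <- w + (1 + 1 / m) * b
  gamma <- ifelse(tt > 0, (1 + 1 / m) * b / tt, 0)
  re <- 1 / (1 + gamma / m)
  df <- ifelse(gamma > 0, (m - 1) / gamma^2, Inf)
  se <- sqrt(tt)
  p <- 2 * stats::pt(-abs(qbar / se), df = pmax(df, 1))
  tab <- data.frame(
    term = colnames(est), estimate = qbar, se = se, or = exp(qbar),
    ci_lo = exp(qbar - 1.96 * se), ci_hi = exp(qbar + 1.96 * se),
    p = p, gamma = gamma, relative_efficiency = re,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = tab, m = m), class = "pooled_fit")
}

#' Impute, fit, and pool the group-membership model
#'
#' Runs [impute_chained()], fits the multinomial model on each completed
#' dataset, and pools by [pool_rubin()]. With no missing data this reduces
#' exactly to the single complete-data fit (relative efficiency 1).
#'
#' @inheritParams fit_multinomial
#' @inheritParams impute_chained
#' @return A `pooled_fit` (see [pool_rubin()]) with the per-imputation fits
#'   attached as `fits`.
#' @export
impute_and_pool <- function(data, outcome = "group", predictors,
                            reference = "UPC", m = 15, n_iter = 10,
                            seed = 1L) {
  completed <- impute_chained(data, vars = c(outcome, predictors),
                              m = m, n_iter = n_iter, seed = seed)
  fits <- lapply(completed, fit_multinomial, outcome = outcome,
                 predictors = predictors, reference = reference)
  pooled <- pool_rubin(fits)
  pooled$fits <- fits
  pooled
}

#' Sensitivity analyses for the carrier association
#'
#' Re-runs the focal model under one of four perturbations: `reclassify`
#' widens the EAC band to |z| < 1 (contiguous rule) and refits the
#' multinomial model; `linear` regresses the raw comprehension residual on
#' the same predictors by OLS; `exclude_bilingual` and
#' `exclude_spanish_home` drop the respective subgroup and refit.
#'
#' @param data cohort data.frame; must contain `resid_z` (standardized
#'   comprehension residual) for `reclassify`/`linear`.
#' @param mode one of `"reclassify"`, `"linear"`, `"exclude_bilingual"`,
#'   `"exclude_spanish_home"`.
#' @param predictors model predictors (must include `focal`).
#' @param focal focal predictor (default `"carrier_ru2short"`).
#' @param outcome group column for multinomial modes.
#' @return List: `mode`, `fit`, and `focal` (data.frame of focal-term
#'   estimates and p-values).
#' @export
sensitivity_suite <- function(data, mode, predictors,
                              focal = "carrier_ru2short",
                              outcome = "group") {
  mode <- match.arg(mode, c("reclassify", "linear", "exclude_bilingual",
                            "exclude_spanish_home"))
  if (mode == "linear") {
    dat <- data[stats::complete.cases(data[, c("resid_z", predictors)]), ]
    fit <- stats::lm(stats::reformulate(predictors, response = "resid_z"),
                     data = dat)
    sm <- summary(fit)$coefficients
    rows <- grep(focal, rownames(sm))
    focal_tab <- data.frame(term = rownames(sm)[rows],
                            estimate = sm[rows, 1], p = sm[rows, 4],
                            row.names = NULL)
    return(list(mode = mode, fit = fit, focal = focal_tab))
  }
  dat <- data
  if (mode == "reclassify") {
    dat[[outcome]] <- classify_groups(dat$resid_z, bands = "contiguous")
    dat <- dat[dat[[outcome]] %in% c("UPC", "EAC", "UGC"), ]
  } else if (mode == "exclude_bilingual") {
    dat <- dat[!is.na(dat$bilingual) & dat$bilingual == 0, ]
  } else {
    dat <- dat[!is.na(dat$spanish_home) & dat$spanish_home == 0, ]
  }
  if (nrow(dat) == 0) stop("empty subgroup after exclusion", call. = FALSE)
  preds <- predictors
  if (mode == "exclude_bilingual") preds <- setdiff(preds, "bilingual")
  if (mode == "exclude_spanish_home") preds <- setdiff(preds, "spanish_home")
  fit <- fit_multinomial(dat, outcome = outcome, predictors = preds)
  ft <- fit$table[grepl(focal, fit$table$term), c("contrast", "term",
                                                  "estimate", "or", "p")]
  list(mode = mode, fit = fit, focal = ft)
}
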