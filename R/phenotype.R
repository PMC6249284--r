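#' Fit the comprehension residualization model
#'
#' Reading comprehension is regressed by ordinary least squares onto age,
#' performance IQ, two word-decoding measures, and three word-recognition
#' measures. The residual of this regression is the comprehension phenotype:
#' how much better or worse a child comprehends than their word-level reading
#' predicts. For the imaging subsample the same model is used with raw
#' scores; the predictor set is configurable through `predictors`.
#'
#' @param cohort data.frame containing `outcome` and all `predictors`.
#' @param outcome outcome column name (default `"comprehension"`).
#' @param predictors predictor column names.
#' @return List of class `residual_model`: `fit` (the `lm`), `coefficients`,
#'   `residual_sd` (SD of in-sample residuals), `residuals`, `z`
#'   (residual / residual_sd), `n_fit`.
#' @export
fit_residual_model <- function(cohort,
                               outcome = "comprehension",
                               predictors = c("age", "piq",
                                              "wj_word_attack", "towre_pde",
                                              "wj_letter_word", "towre_swe",
                                              "sri_word_rec")) {
  missing_cols <- setdiff(c(outcome, predictors), names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- cohort[, c(outcome, predictors)]
  cc <- stats::complete.cases(dat)
  if (sum(cc) < length(predictors) + 2) {
    stop("need at least p + 2 complete cases", call. = FALSE)
  }
  form <- stats::reformulate(predictors, response = outcome)
  fit <- stats::lm(form, data = dat[cc, ])
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- rep(NA_real_, nrow(cohort))
  res[cc] <- stats::resid(fit)
  rsd <- stats::sd(stats::resid(fit))
  if (!is.finite(rsd) || rsd < 1e-10) {
    stop("degenerate fit: residual SD is zero", call. = FALSE)
  }
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 residual_sd = rsd, residuals = res, z = res / rsd,
                 n_fit = sum(cc)),
            class = "residual_model")
}

#' Classify subjects into comprehension groups from residual z scores
#'
#' Bands on the standardized regression residual: z <= -1 gives UPC
#' (unexpected poor comprehension), z >= +1 gives UGC (unexpected good),
#' |z| <= 0.5 gives EAC (expected average), and the gaps between bands are
#' UNCLASSIFIED. Boundary values are inclusive toward the labeled groups.
#' `bands = "contiguous"` widens EAC to |z| < 1 (used by the reclassification
#' sensitivity analysis); `bands = "split"` assigns the 0.5-1 gap to the
#' adjacent extreme group when |z| >= 0.75 and to EAC otherwise.
#'
#' @param z numeric standardized residuals.
#' @param bands `"default"`, `"contiguous"`, or `"split"`, or a list with
#'   numeric elements `upc`, `ugc`, `eac` giving the three cutoffs.
#' @return Character vector of labels in
#'   `{UPC, EAC, UGC, UNCLASSIFIED}`.
#' @export
classify_groups <- function(z, bands = "default") {
  if (is.character(bands)) {
    bands <- match.arg(bands, c("default", "contiguous", "split"))
    cfg <- switch(bands,
      default = list(upc = -1, ugc = 1, eac = 0.5),
      contiguous = list(upc = -1, ugc = 1, eac = 1),
      split = list(upc = -0.75, ugc = 0.75, eac = 0.75))
  } else {
    cfg <- bands
  }
  out <- rep("UNCLASSIFIED", length(z))
  out[!is.na(z) & z <= cfg$upc] <- "UPC"
  out[!is.na(z) & z >= cfg$ugc] <- "UGC"
  mid <- !is.na(z) & abs(z) <= cfg$eac & out == "UNCLASSIFIED"
  out[mid] <- "EAC"
  out[is.na(z)] <- NA_character_
  out
}
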