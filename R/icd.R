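#' Correlation survival curve for one voxel
#'
#' The intrinsic connectivity distribution summarizes a voxel's connectivity
#' as the survival function of its correlations to every other in-mask
#' voxel: S(tau) = fraction of other voxels with correlation r > tau, on the
#' positive tail only.
#'
#' @param voxel_ts numeric time series of the voxel.
#' @param all_ts voxels x time matrix including the voxel itself at row
#'   `self` (excluded from the curve), or other voxels only (`self = NULL`).
#' @param tau_grid correlation thresholds in `[0, 1)`.
#' @param self row index of `voxel_ts` within `all_ts`, or `NULL`.
#' @return Numeric survival values, one per threshold.
#' @export
correlation_survival <- function(voxel_ts, all_ts,
                                 tau_grid = seq(0, 0.99, by = 0.01),
                                 self = NULL) {
  stopifnot(all(tau_grid >= 0), all(tau_grid < 1))
  if (stats::sd(voxel_ts) == 0) {
    stop("zero-variance voxel", call. = FALSE)
  }
  r <- as.vector(stats::cor(voxel_ts, t(all_ts)))
  if (!is.null(self)) r <- r[-self]
  vapply(tau_grid, function(tau) mean(r > tau), numeric(1))
}

#' Survival curves for every voxel of a masked time-series matrix
#'
#' Matrix implementation of [correlation_survival()] over all voxel pairs;
#' equal to the per-voxel double loop up to floating-point rounding.
#'
#' @param ts voxels x time matrix (in-mask voxels only).
#' @param tau_grid correlation thresholds (sorted, in `[0, 1)`).
#' @return List: `s` (voxels x thresholds survival matrix), `tau_grid`,
#'   `zero_var` (logical flag per voxel; flagged rows are NA).
#' @export
survival_curves <- function(ts, tau_grid = seq(0, 0.99, by = 0.01)) {
  stopifnot(!is.unsorted(tau_grid))
  v <- nrow(ts)
  sds <- apply(ts, 1, stats::sd)
  zero_var <- sds == 0
  s <- matrix(NA_real_, v, length(tau_grid))
  ok <- which(!zero_var)
  if (length(ok) >= 2) {
    cm <- stats::cor(t(ts[ok, , drop = FALSE]))
    ntau <- length(tau_grid)
    for (a in seq_along(ok)) {
      r <- cm[a, -a]
      b <- findInterval(r, tau_grid)  # count of thresholds <= r
      tab <- tabulate(b + 1L, nbins = ntau + 1L)
      cum <- cumsum(tab)[seq_len(ntau)]
      s[ok[a], ] <- (length(r) - cum) / length(r)
    }
  }
  list(s = s, tau_grid = tau_grid, zero_var = zero_var)
}

# linearized estimate of (alpha, beta): log(-log S) = beta log alpha +
# beta log tau on interior points
se_linearized_init <- function(tau, s) {
  ok <- tau > 0 & s > 1e-6 & s < 1 - 1e-6
  if (sum(ok) < 2) return(c(alpha = 1, beta = 1))
  y <- log(-log(s[ok]))
  x <- log(tau[ok])
  cf <- stats::coef(stats::lm(y ~ x))
  beta <- max(min(cf[2], 50), 0.05)
  alpha <- exp(cf[1] / beta)
  c(alpha = max(min(alpha, 99), 1e-3), beta = beta)
}

#' Fit a stretched-exponential survival function
#'
#' Nonlinear least squares of S(tau) = exp(-(alpha * tau)^beta) with both
#' parameters bounded in (0, 100]. Alpha scales how quickly the correlation
#' density decays (smaller alpha = heavier tail = more extensive
#' connectivity); beta shapes the decay. Starting values come from the
#' log-log linearization, falling back to (1, 1).
#'
#' @param tau,s threshold grid and survival values.
#' @param init optional starting values `c(alpha, beta)`.
#' @return List: `alpha`, `beta`, `converged`, `resid_norm`.
#' @export
fit_stretched_exponential <- function(tau, s, init = NULL) {
  stopifnot(length(tau) >= 5, length(tau) == length(s))
  if (any(s < -1e-9) || any(s > 1 + 1e-9)) {
    stop("survival values must lie in [0, 1]", call. = FALSE)
  }
  start <- init %||% se_linearized_init(tau, s)
  dat <- data.frame(tau = tau, s = s)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ exp(-(alpha * tau)^beta), data = dat,
                      start = list(alpha = unname(start[1]),
                                   beta = unname(start[2])),
                      lower = c(1e-6, 1e-6), upper = c(100, 100),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(alpha = NA_real_, beta = NA_real_, converged = FALSE,
                resid_norm = NA_real_))
  }
  cf <- stats::coef(fit)
  list(alpha = unname(cf["alpha"]), beta = unname(cf["beta"]),
       converged = fit$convInfo$isConv %||% TRUE,
       resid_norm = sqrt(sum(stats::resid(fit)^2)))
}

#' Batch stretched-exponential fits (vectorized Levenberg-Marquardt)
#'
#' Fits S(tau) = exp(-(alpha * tau)^beta) independently to each row of a
#' survival matrix with a damped Gauss-Newton iteration carried out
#' elementwise across voxels (each step solves the per-voxel 2 x 2 normal
#' equations in closed form). Agrees with [fit_stretched_exponential()] to
#' high precision on well-conditioned curves and is orders of magnitude
#' faster for whole-brain maps.
#'
#' @param s voxels x thresholds survival matrix (NA rows skipped).
#' @param tau threshold grid.
#' @param max_iter iteration cap (default 60).
#' @param tol SSE improvement tolerance for convergence.
#' @return data.frame: `alpha`, `beta`, `converged`, `resid_norm` per row.
#' @export
fit_se_batch <- function(s, tau, max_iter = 60, tol = 1e-12) {
  v <- nrow(s)
  ok <- which(stats::complete.cases(s))
  alpha <- rep(NA_real_, v); beta <- rep(NA_real_, v)
  conv <- rep(FALSE, v); rnorm_out <- rep(NA_real_, v)
  if (!length(ok)) {
    return(data.frame(alpha = alpha, beta = beta, converged = conv,
                      resid_norm = rnorm_out))
  }
  sm <- s[ok, , drop = FALSE]
  init <- t(apply(sm, 1, se_linearized_init, tau = tau))
  a <- init[, 1]; b <- init[, 2]
  pos <- tau > 0
  ltau <- log(tau[pos])
  sp <- sm[, pos, drop = FALSE]
  sse_of <- function(a, b) {
    u <- exp(b * (log(a) + rep(ltau, each = length(a))))
    dim(u) <- c(length(a), length(ltau))
    rowSums((sp - exp(-u))^2) + (sm[, !pos, drop = FALSE] - 1)^2 %*%
      rep(1, sum(!pos))
  }
  lambda <- rep(1e-3, length(a))
  sse <- drop(sse_of(a, b))
  for (it in seq_len(max_iter)) {
    la <- log(a)
    u <- exp(outer(b, rep(1, sum(pos))) * (la + rep(ltau, each = length(a))))
    dim(u) <- c(length(a), sum(pos))
    e <- exp(-u)
    r <- sp - e
    da <- -e * u * (b / a)          # dE/dalpha
    db <- -e * u * (la + rep(ltau, each = length(a)))  # dE/dbeta
    # minimize ||s - E||^2: step solves (J'J + lambda I) d = J'r, J = dE/dtheta
    a11 <- rowSums(da * da); a12 <- rowSums(da * db); a22 <- rowSums(db * db)
    b1 <- rowSums(da * r); b2 <- rowSums(db * r)
    det <- (a11 + lambda) * (a22 + lambda) - a12^2
    det[det == 0] <- 1e-300
    step_a <- ((a22 + lambda) * b1 - a12 * b2) / det
    step_b <- ((a11 + lambda) * b2 - a12 * b1) / det
    a_new <- pmin(pmax(a + step_a, 1e-6), 100)
    b_new <- pmin(pmax(b + step_b, 1e-6), 100)
    sse_new <- drop(sse_of(a_new, b_new))
    better <- sse_new <= sse
    a[better] <- a_new[better]; b[better] <- b_new[better]
    lambda[better] <- pmax(lambda[better] / 3, 1e-10)
    lambda[!better] <- pmin(lambda[!better] * 10, 1e8)
    improved <- rep(0, length(sse))
    improved[better] <- sse[better] - sse_new[better]
    sse[better] <- sse_new[better]
    if (it > 5 && max(improved) < tol) break
  }
  alpha[ok] <- a; beta[ok] <- b
  conv[ok] <- TRUE
  rnorm_out[ok] <- sqrt(sse)
  data.frame(alpha = alpha, beta = beta, converged = conv,
             resid_norm = rnorm_out)
}

#' Intrinsic connectivity distribution maps for one subject
#'
#' Computes every gray-matter voxel's correlation survival curve from the
#' nuisance-regressed, censored residual run and fits the
#' stretched-exponential model, producing voxelwise alpha (scale) and beta
#' (shape) maps. Values are defined only inside the gray-matter mask;
#' zero-variance voxels are flagged and left NA.
#'
#' @param resid_run voxels x retained-volumes residual matrix (full grid,
#'   linear voxel order).
#' @param gm_mask logical gray-matter array.
#' @param tau_grid correlation thresholds.
#' @return List of class `icd_maps`: `alpha`, `beta` (3D arrays, NA outside
#'   the mask), `gm_mask`, `diagnostics` (per in-mask voxel: converged,
#'   resid_norm, zero_var).
#' @export
icd_subject <- function(resid_run, gm_mask,
                        tau_grid = seq(0, 0.99, by = 0.01)) {
  gm_idx <- which(gm_mask)
  ts <- resid_run[gm_idx, , drop = FALSE]
  sc <- survival_curves(ts, tau_grid)
  fits <- fit_se_batch(sc$s, tau_grid)
  shape <- dim(gm_mask)
  alpha <- array(NA_real_, shape); beta <- array(NA_real_, shape)
  alpha[gm_idx] <- fits$alpha
  beta[gm_idx] <- fits$beta
  structure(list(alpha = alpha, beta = beta, gm_mask = gm_mask,
                 diagnostics = data.frame(voxel = gm_idx,
                                          converged = fits$converged,
                                          resid_norm = fits$resid_norm,
                                          zero_var = sc$zero_var)),
            class = "icd_maps")
}

#' Voxelwise linear model over subject maps
#'
#' Fits, at every in-mask voxel, an ordinary least squares model of the map
#' value on a focal predictor plus covariates, and returns the t statistic
#' (and two-sided p) for the focal slope together with the residual maps
#' needed for smoothness estimation.
#'
#' @param maps subjects x voxels matrix of in-mask map values, or a list of
#'   3D arrays (stacked over `mask`).
#' @param design data.frame of subject-level variables.
#' @param focal focal predictor column name.
#' @param covariates covariate column names.
#' @param mask logical array (required when `maps` is a list).
#' @return List of class `voxelwise_fit`: `t`, `p` (3D arrays when a mask is
#'   given, else vectors), `df`, `residuals` (subjects x voxels), `mask`.
#' @export
voxelwise_model <- function(maps, design, focal, covariates = character(0),
                            mask = NULL) {
  if (is.list(maps) && !is.matrix(maps)) {
    stopifnot(!is.null(mask))
    idx <- which(mask)
    maps <- do.call(rbind, lapply(maps, function(m) m[idx]))
  }
  x <- stats::model.matrix(stats::reformulate(c(focal, covariates)),
                           data = design)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("more predictors than subjects", call. = FALSE)
  stopifnot(nrow(maps) == n)
  fcol <- which(colnames(x) == focal | startsWith(colnames(x), focal))[1]
  xtx_inv <- solve(crossprod(x))
  beta <- xtx_inv %*% crossprod(x, maps)
  res <- maps - x %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  tstat <- beta[fcol, ] / sqrt(xtx_inv[fcol, fcol] * sigma2)
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)
  if (!is.null(mask)) {
    tm <- array(NA_real_, dim(mask)); pm <- array(NA_real_, dim(mask))
    tm[which(mask)] <- tstat; pm[which(mask)] <- pval
    tstat <- tm; pval <- pm
  }
  structure(list(t = tstat, p = pval, df = n - p, residuals = res,
                 mask = mask),
            class = "voxelwise_fit")
}

#' Estimate per-axis Gaussian smoothness of residual maps
#'
#' Classic Gaussian autocorrelation estimator: along each axis, the variance
#' of first differences between in-mask neighbors gives the lag-1
#' autocorrelation, from which the FWHM of the equivalent Gaussian ACF
#' follows. Averaged across subjects.
#'
#' @param residuals subjects x in-mask-voxels matrix.
#' @param mask logical array.
#' @param grid a [make_grid()].
#' @return Length-3 FWHM vector in mm (floored at 1e-3).
#' @export
estimate_fwhm <- function(residuals, mask, grid) {
  idx <- which(mask)
  shape <- dim(mask)
  fwhm <- matrix(NA_real_, nrow(residuals), 3)
  full <- array(NA_real_, shape)
  strides <- c(1, shape[1], shape[1] * shape[2])
  arr_ind <- which(mask, arr.ind = TRUE)
  for (s in seq_len(nrow(residuals))) {
    full[idx] <- residuals[s, ]
    v <- stats::var(residuals[s, ])
    for (ax in 1:3) {
      ok <- arr_ind[, ax] < shape[ax]
      nb <- idx[ok] + strides[ax]
      pair_ok <- !is.na(full[nb])
      d <- full[nb[pair_ok]] - full[idx[ok][pair_ok]]
      if (length(d) < 10 || v <= 0) next
      rho <- 1 - stats::var(d) / (2 * v)
      if (rho <= 0 || rho >= 1) next
      sig <- sqrt(-1 / (2 * log(rho)))
      fwhm[s, ax] <- sig * 2 * sqrt(2 * log(2)) * grid$voxel_mm
    }
  }
  out <- colMeans(fwhm, na.rm = TRUE)
  out[!is.finite(out)] <- 1e-3
  pmax(out, 1e-3)
}

# kernel sd (voxels) whose discrete truncated autocorrelation reproduces
# the lag-1 correlation of a Gaussian-ACF field with the target FWHM; the
# continuum rule s_k = s_field / sqrt(2) is biased on a coarse lattice
kernel_sd_for_fwhm <- function(fwhm_mm, voxel_mm) {
  sig_field <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  rho_target <- exp(-1 / (2 * sig_field^2))
  lag1_ratio <- function(s) {
    i <- -ceiling(4 * s):ceiling(4 * s)
    k <- exp(-i^2 / (2 * s^2))
    sum(k[-1] * k[-length(k)]) / sum(k^2)
  }
  if (rho_target <= lag1_ratio(0.05)) return(0.02)  # essentially unsmoothed
  stats::uniroot(function(s) lag1_ratio(s) - rho_target,
                 c(0.05, 20), tol = 1e-8)$root
}

# smooth a batch of white-noise volumes to a target field FWHM (measured on
# the lattice); returns array (shape, B). With standardize = TRUE each voxel
# is scaled by its exact kernel-induced SD (edge voxels have less smoothing
# mass), giving unit marginal variance everywhere — the correct null for
# comparison with per-voxel studentized statistics.
simulate_smooth_fields <- function(fwhm_mm, grid, n_fields,
                                   standardize = FALSE) {
  sig_k <- vapply(fwhm_mm, kernel_sd_for_fwhm, numeric(1),
                  voxel_mm = grid$voxel_mm)
  d <- grid$shape
  kmats <- lapply(1:3, function(ax) gauss_kernel_matrix(d[ax], sig_k[ax]))
  x <- array(stats::rnorm(prod(d) * n_fields), c(d, n_fields))
  m <- kmats[[1]] %*% matrix(x, d[1])
  x <- array(m, c(d, n_fields))
  x <- aperm(x, c(2, 1, 3, 4))
  m <- kmats[[2]] %*% matrix(x, d[2])
  x <- aperm(array(m, c(d[2], d[1], d[3], n_fields)), c(2, 1, 3, 4))
  x <- aperm(x, c(3, 1, 2, 4))
  m <- kmats[[3]] %*% matrix(x, d[3])
  out <- aperm(array(m, c(d[3], d[1], d[2], n_fields)), c(2, 3, 1, 4))
  if (standardize) {
    rs <- lapply(kmats, function(k) rowSums(k^2))
    sdarr <- sqrt(outer(outer(rs[[1]], rs[[2]]), rs[[3]]))
    out <- out / as.vector(sdarr)  # recycles over the batch dimension
  }
  out
}

#' Cluster-extent correction by Monte-Carlo simulation
#'
#' Estimates the residual maps' spatial smoothness, simulates null Gaussian
#' random fields with that smoothness restricted to the search mask,
#' thresholds each at the voxelwise p, and takes the (1 - cluster_p)
#' quantile of the null maximum cluster size as the cluster-extent
#' threshold. Observed supra-threshold clusters at least that large are
#' significant.
#'
#' @param fit a `voxelwise_fit` (with 3D `t` and `mask`).
#' @param grid a [make_grid()].
#' @param voxel_p voxelwise two-sided threshold (default 0.001).
#' @param cluster_p familywise cluster threshold (default 0.05).
#' @param iters Monte-Carlo iterations (default 10000; < 100 warns).
#' @param connectivity cluster connectivity, 6 or 26 (default 6).
#' @param batch simulation batch size.
#' @return List of class `cluster_result`: `clusters` (data.frame: size,
#'   peak t, peak mm coordinates), `cluster_size_threshold`, `fwhm_mm`,
#'   `voxel_p`, `cluster_p`, `null_max_sizes`.
#' @export
cluster_correct <- function(fit, grid, voxel_p = 0.001, cluster_p = 0.05,
                            iters = 10000, connectivity = 6, batch = 250) {
  mask <- fit$mask
  if (is.null(mask) || !any(mask)) stop("empty mask", call. = FALSE)
  if (iters < 100) warning("fewer than 100 iterations; threshold unstable")
  fwhm <- estimate_fwhm(fit$residuals, mask, grid)
  zc <- stats::qnorm(1 - voxel_p / 2)
  midx <- which(mask)
  max_sizes <- integer(0)
  done <- 0
  while (done < iters) {
    b <- min(batch, iters - done)
    fields <- simulate_smooth_fields(fwhm, grid, b, standardize = TRUE)
    fl <- matrix(fields, ncol = b)[midx, , drop = FALSE]
    supra_any <- colSums(abs(fl) > zc) > 0
    sizes <- integer(b)
    for (ib in which(supra_any)) {
      sup <- array(FALSE, dim(mask))
      sup[midx[abs(fl[, ib]) > zc]] <- TRUE
      cc <- connected_components(sup, connectivity)
      sizes[ib] <- length(cc[[1]])
    }
    max_sizes <- c(max_sizes, sizes)
    done <- done + b
  }
  # smallest extent whose null exceedance probability is <= cluster_p
  cand <- sort(unique(c(1L, max_sizes + 1L)))
  exceed <- vapply(cand, function(s) mean(max_sizes >= s), numeric(1))
  thr <- cand[which(exceed <= cluster_p)[1]]
  tcrit <- stats::qt(1 - voxel_p / 2, df = fit$df)
  sup <- !is.na(fit$t) & abs(fit$t) > tcrit & mask
  comps <- connected_components(sup, connectivity)
  comps <- comps[lengths(comps) >= thr]
  xyz <- coords_mm(grid)
  clusters <- do.call(rbind, lapply(comps, function(ix) {
    pk <- ix[which.max(abs(fit$t[ix]))]
    data.frame(size = length(ix), peak_t = fit$t[pk],
               x = xyz[pk, 1], y = xyz[pk, 2], z = xyz[pk, 3],
               peak_index = pk)
  }))
  if (is.null(clusters)) {
    clusters <- data.frame(size = integer(0), peak_t = numeric(0),
                           x = numeric(0), y = numeric(0), z = numeric(0),
                           peak_index = integer(0))
  }
  structure(list(clusters = clusters, cluster_size_threshold = thr,
                 fwhm_mm = fwhm, voxel_p = voxel_p, cluster_p = cluster_p,
                 null_max_sizes = max_sizes),
            class = "cluster_result")
}

#' Influence diagnostics for a focal regression
#'
#' Fits `y ~ focal + covariates` by OLS, flags influential subjects by
#' Cook's distance (> 4/n) and standardized DFBETA of the focal slope
#' (|.| > 2/sqrt(n)), refits without the flagged subjects, and refits on the
#' subset with the focal phenotype inside `[-range_limit, range_limit]`.
#'
#' @param data data.frame with outcome, focal phenotype and covariates.
#' @param outcome,focal,covariates column names.
#' @param range_limit phenotype restriction bound (default 20).
#' @return List: `fit`, `flagged` (indices), `p_full`, `p_excluded`,
#'   `p_restricted`, and the two refits.
#' @export
influence_check <- function(data, outcome, focal,
                            covariates = character(0), range_limit = 20) {
  form <- stats::reformulate(c(focal, covariates), response = outcome)
  fit <- stats::lm(form, data = data)
  n <- nrow(data)
  focal_term <- grep(focal, names(stats::coef(fit)), value = TRUE)[1]
  cd <- stats::cooks.distance(fit)
  dfb <- stats::dfbetas(fit)[, focal_term]
  flagged <- which(cd > 4 / n | abs(dfb) > 2 / sqrt(n))
  p_of <- function(f) summary(f)$coefficients[focal_term, 4]
  fit_excl <- if (length(flagged)) {
    if (n - length(flagged) <= length(covariates) + 2) {
      stop("too few subjects after exclusion", call. = FALSE)
    }
    stats::lm(form, data = data[-flagged, ])
  } else {
    fit
  }
  keep <- abs(data[[focal]]) <= range_limit
  if (sum(keep) <= length(covariates) + 2) {
    stop("too few subjects after range restriction", call. = FALSE)
  }
  fit_rest <- stats::lm(form, data = data[keep, ])
  list(fit = fit, flagged = flagged,
       p_full = p_of(fit), p_excluded = p_of(fit_excl),
       p_restricted = p_of(fit_rest),
       fit_excluded = fit_excl, fit_restricted = fit_rest)
}
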