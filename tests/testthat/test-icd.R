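test_that("survival curves match the brute-force pairwise oracle", {
  set.seed(61)
  ts <- matrix(rnorm(50 * 40), 50, 40)
  tau <- seq(0, 0.9, by = 0.1)
  fast <- survival_curves(ts, tau)
  slow <- brute_survival(ts, tau)
  expect_lt(max(abs(fast$s - slow)), 1e-12)
  # monotone non-increasing, S(0) = fraction of positive correlations
  expect_true(all(apply(fast$s, 1, function(x) all(diff(x) <= 0))))
  cm <- cor(t(ts))
  expect_equal(fast$s[1, 1], mean(cm[1, -1] > 0))
})

test_that("survival handles perfect correlation and zero variance", {
  base <- sin(seq_len(30))
  ts <- rbind(base, 2 * base + 1, -base)
  s <- correlation_survival(ts[1, ], ts[2:3, , drop = FALSE],
                            tau_grid = seq(0, 0.99, 0.01))
  expect_equal(s[1], 0.5)   # one perfectly positive, one negative
  expect_true(all(s <= 1 & s >= 0))
  expect_error(correlation_survival(rep(1, 30), ts), "zero-variance")
  sc <- survival_curves(rbind(base, rep(1, 30), -base))
  expect_true(sc$zero_var[2])
  expect_true(all(is.na(sc$s[2, ])))
})

test_that("stretched-exponential fits recover noiseless parameters to 1e-6", {
  tau <- seq(0, 0.99, by = 0.01)
  for (truth in list(c(2, 1), c(1.5, 2), c(0.5, 0.8), c(10, 1.5))) {
    s <- exp(-(truth[1] * tau)^truth[2])
    f <- fit_stretched_exponential(tau, s)
    expect_lt(abs(f$alpha - truth[1]), 1e-6)
    expect_lt(abs(f$beta - truth[2]), 1e-6)
    expect_true(f$converged)
    fb <- fit_se_batch(matrix(s, 1), tau)
    expect_lt(abs(fb$alpha - truth[1]), 1e-6)
    expect_lt(abs(fb$beta - truth[2]), 1e-6)
  }
  # S(0) = 1 regardless of parameters; the fit is sane at the origin
  expect_equal(exp(-(5 * 0)^2), 1)
  f0 <- fit_stretched_exponential(tau, exp(-(2 * tau)^1))
  expect_equal(exp(-(f0$alpha * 0)^f0$beta), 1)
})

test_that("batch fitter agrees with the single-curve NLS on noisy curves", {
  set.seed(77)
  tau <- seq(0, 0.99, by = 0.01)
  truths <- cbind(runif(20, 0.5, 5), runif(20, 0.7, 3))
  s <- t(apply(truths, 1, function(th)
    pmin(pmax(exp(-(th[1] * tau)^th[2]) + rnorm(length(tau), 0, 0.01), 0), 1)))
  fb <- fit_se_batch(s, tau)
  for (i in 1:20) {
    fs <- fit_stretched_exponential(tau, s[i, ])
    expect_lt(abs(fb$alpha[i] - fs$alpha), 1e-3 * max(1, fs$alpha))
    expect_lt(abs(fb$beta[i] - fs$beta), 1e-3 * max(1, fs$beta))
  }
})

test_that("ICD maps separate planted nodes from background", {
  spec <- tiny_bold_spec(seed = 5, n_volumes_per_run = 180, n_runs = 1,
                         motion_spike_rate = 0)
  b <- generate_bold_subject(spec, FALSE, seed = 9)
  run <- b$runs[[1]][, -(1:6)]
  icd <- icd_subject(run, b$masks$gm)
  node_gm <- intersect(unlist(b$node_voxels), which(b$masks$gm))
  bg <- setdiff(which(b$masks$gm), node_gm)
  expect_lt(mean(icd$alpha[node_gm], na.rm = TRUE),
            mean(icd$alpha[bg], na.rm = TRUE))
  expect_true(all(icd$alpha[!b$masks$gm] %in% NA))
  # node voxels see a heavier positive tail at tau = 0.25
  gm_idx <- which(b$masks$gm)
  sc <- survival_curves(run[gm_idx, ], tau_grid = c(0, 0.25))
  in_node <- gm_idx %in% node_gm
  expect_gt(mean(sc$s[in_node, 2]), mean(sc$s[!in_node, 2]) + 0.02)
  # determinism
  icd2 <- icd_subject(run, b$masks$gm)
  expect_identical(icd$alpha, icd2$alpha)
})

test_that("Gaussian smoothing has the right kernel width and mask behavior", {
  g <- make_grid(c(15, 15, 15), 3)
  m <- array(0, c(15, 15, 15))
  m[8, 8, 8] <- 1
  expect_identical(smooth_map(m, 0), m)
  sm <- smooth_map(m, 6, 3)
  # value at half the FWHM from the peak equals half the peak
  expect_equal(sm[9, 8, 8] / sm[8, 8, 8],
               exp(-3^2 / (2 * (6 / 2.3548)^2)), tolerance = 1e-3)
  mid <- sm[7:9, 7:9, 7:9]
  expect_equal(sum(sm), 1, tolerance = 1e-6)  # kernel normalized
  # constant map unchanged inside an irregular mask
  mask <- ellipsoid_mask(g, c(18, 15, 12))
  const <- array(2, c(15, 15, 15))
  smc <- smooth_map(const, 6, 3, mask)
  expect_equal(smc[mask], rep(2, sum(mask)), tolerance = 1e-12)
  expect_true(all(smc[!mask] == 0))
})

test_that("voxelwise model is exact, location-invariant, and calibrated", {
  set.seed(91)
  n <- 24
  mask <- ellipsoid_mask(make_grid(c(10, 10, 10), 3), c(13, 13, 13))
  v <- sum(mask)
  maps <- matrix(rnorm(n * v), n, v)
  ph <- rnorm(n)
  cov1 <- rnorm(n)
  # plant a slope at 30 voxels
  idx <- 1:30
  maps[, idx] <- maps[, idx] + outer(ph, rep(1.5, 30))
  vw <- voxelwise_model(maps, data.frame(ph = ph, cov1 = cov1),
                        focal = "ph", covariates = "cov1")
  # agrees with lm at a planted and a null voxel
  for (j in c(3, 200)) {
    lmf <- summary(lm(maps[, j] ~ ph + cov1))$coefficients
    expect_equal(vw$t[j], lmf["ph", 3], tolerance = 1e-10)
  }
  expect_gt(min(vw$t[idx]), 2)
  expect_gt(mean(vw$t[idx]), 5)
  # shifting the phenotype leaves the t map unchanged
  vw2 <- voxelwise_model(maps, data.frame(ph = ph + 100, cov1 = cov1),
                         focal = "ph", covariates = "cov1")
  expect_equal(vw$t, vw2$t, tolerance = 1e-8)
  # null voxels reject at about the nominal rate
  expect_lt(abs(mean(vw$p[-idx] < 0.05) - 0.05), 0.03)
  expect_error(voxelwise_model(maps[1:2, ], data.frame(ph = ph[1:2]),
                               focal = "ph"), "predictors")
})

test_that("cluster correction recovers a planted cluster and scales with FWHM", {
  set.seed(101)
  grid <- make_grid(c(12, 14, 12), 3)
  mask <- ellipsoid_mask(grid, c(16, 19, 16))
  n <- 16
  idx <- which(mask)
  planted <- sphere_roi(c(6, 6, 0), 5, grid)
  planted <- intersect(planted, idx)
  ph <- rnorm(n)
  mk_maps <- function(fwhm) {
    fields <- readconn:::simulate_smooth_fields(rep(fwhm, 3), grid, n)
    mm <- t(matrix(fields, ncol = n)[idx, ])
    mm / sd(mm)
  }
  maps <- mk_maps(6)
  maps[, match(planted, idx)] <- maps[, match(planted, idx)] +
    outer(ph, rep(2, length(planted)))
  vw <- voxelwise_model(maps, data.frame(ph = ph), focal = "ph", mask = mask)
  cl <- cluster_correct(vw, grid, iters = 400)
  expect_gt(nrow(cl$clusters), 0)
  top <- cl$clusters[which.max(cl$clusters$size), ]
  d <- sqrt(sum((c(top$x, top$y, top$z) - c(6, 6, 0))^2))
  expect_lte(d, 2 * sqrt(3) * grid$voxel_mm)  # peak lands in the planted blob
  expect_true(all(cl$clusters$size >= cl$cluster_size_threshold))
  # extent threshold grows with smoothness
  thr <- sapply(c(3, 9), function(fw) {
    maps0 <- mk_maps(fw)
    vw0 <- voxelwise_model(maps0, data.frame(ph = ph), focal = "ph",
                           mask = mask)
    cluster_correct(vw0, grid, iters = 300)$cluster_size_threshold
  })
  expect_lte(thr[1], thr[2])
  expect_warning(cluster_correct(vw, grid, iters = 50), "100 iterations")
})

test_that("influence diagnostics flag a planted outlier and spare clean data", {
  set.seed(111)
  n <- 60
  d <- data.frame(ph = rnorm(n, 0, 5), s = rnorm(n))
  d$y <- -0.1 * d$ph + 0.2 * d$s + rnorm(n, 0, 0.4)
  clean <- influence_check(d, "y", "ph", "s")
  # 4/n-type cutoffs flag at most a handful of ordinary points
  expect_lte(length(clean$flagged), 0.15 * n)
  expect_equal(clean$p_restricted, clean$p_full)  # |ph| < 20 already
  # one gross outlier pulling against the true negative slope
  d2 <- d
  d2$ph[1] <- 60
  d2$y[1] <- 10
  out <- influence_check(d2, "y", "ph", "s", range_limit = 20)
  expect_true(1 %in% out$flagged)
  # the true (negative, significant) relationship survives exclusion
  expect_lt(coef(out$fit_excluded)["ph"], 0)
  expect_lt(out$p_excluded, 0.05)
  # the restriction refit drops the planted point
  expect_equal(nobs(out$fit_restricted), n - 1)
})
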