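test_that("Euclidean movement follows the point-to-point formula", {
  const <- matrix(0.5, 20, 6)
  expect_equal(euclidean_movement(const), rep(0, 20))
  tr <- matrix(0, 10, 6)
  tr[5:10, 1] <- 0.4
  expect_equal(euclidean_movement(tr)[5], 0.4)
  expect_equal(euclidean_movement(tr)[6], 0)
  tr2 <- matrix(0, 10, 6)
  tr2[5:10, 1] <- 0.3
  tr2[5:10, 2] <- 0.4
  expect_equal(euclidean_movement(tr2)[5], 0.5)  # 3-4-5
  expect_error(euclidean_movement(matrix(0, 1, 6)), "2 volumes")
})

test_that("outlier fraction detects planted spikes and stays in [0, 1]", {
  set.seed(12)
  v <- 400
  run <- matrix(rnorm(v * 60), v, 60)
  expect_equal(outlier_fraction(matrix(1, v, 60), rep(TRUE, v)),
               rep(0, 60), ignore_attr = TRUE)
  spiked <- run
  hit <- sample(v, 0.2 * v)
  spiked[hit, 30] <- spiked[hit, 30] + 10
  of <- outlier_fraction(spiked, rep(TRUE, v))
  expect_lt(abs(of[30] - 0.20), 0.03)
  expect_true(all(of >= 0 & of <= 1))
  expect_lt(max(of[-30]), 0.05)
  expect_error(outlier_fraction(run, integer(0)), "empty mask")
})

test_that("censoring applies strict thresholds and the 60% retention rule", {
  t_run <- 106  # 100 volumes after the initial drop
  clean <- list(matrix(0, t_run, 6), matrix(0, t_run, 6))
  cm <- censor(clean)
  expect_equal(cm$retention, 1)
  expect_false(cm$excluded)
  # exactly 0.3 mm is retained (strictly greater than)
  tr <- matrix(0, t_run, 6)
  tr[seq(10, t_run, by = 2), 1] <- 0.3  # every transition is exactly 0.3
  cm2 <- censor(list(tr, matrix(0, t_run, 6)))
  expect_equal(cm2$retention, 1)
  # 45% of volumes spiked: retention 0.55 -> excluded
  tr3 <- matrix(0, t_run, 6)
  spike_at <- 6 + which(seq_len(100) %% 20 < 9)  # 45 post-drop volumes
  tr3[spike_at, 1] <- rep(c(5, 0), length.out = length(spike_at)) +
    seq_along(spike_at)  # every spiked volume moves > 0.3 from its neighbor
  cm3 <- censor(list(tr3, tr3))
  expect_lt(cm3$retention, 0.60)
  expect_true(cm3$excluded)
  # outlier fractions alone can censor
  of <- list(c(rep(0, 50), 0.2, rep(0, t_run - 51)), rep(0, t_run))
  cm4 <- censor(clean, of)
  expect_equal(cm4$n_censored, 1)
  # exactly 0.10 outlier fraction is retained
  of10 <- list(rep(0.10, t_run), rep(0, t_run))
  expect_equal(censor(clean, of10)$retention, 1)
})

test_that("nuisance regression projects out its own span exactly", {
  set.seed(33)
  spec <- tiny_bold_spec(seed = 2, n_volumes_per_run = 60, n_runs = 1)
  b <- generate_bold_subject(spec, FALSE, seed = 5)
  run <- b$runs[[1]][, -(1:6)]
  tr <- b$motion[[1]][-(1:6), ]
  keep <- rep(TRUE, ncol(run))
  # construct data purely inside the regressor span: motion params + wm mean
  v <- nrow(run)
  wm_mean <- colMeans(run[which(b$masks$wm), ])
  fake <- outer(rnorm(v), tr[, 1]) + outer(rnorm(v), wm_mean)
  fake[which(b$masks$wm), ] <- run[which(b$masks$wm), ]  # keep wm signal
  # rank-2 fake data leaves degenerate ventricle PCs: the drop-with-warning
  # collinearity policy must engage rather than fail
  expect_warning(
    res <- nuisance_regress(fake, tr, keep, b$masks$wm, b$masks$vent,
                            spec$tr_s),
    "collinear")
  gm_idx <- which(b$masks$gm)
  expect_lt(max(abs(res[gm_idx, ])), 1e-8 * max(abs(fake)))
})

test_that("residuals are orthogonal to every nuisance regressor", {
  spec <- tiny_bold_spec(seed = 3, n_volumes_per_run = 80, n_runs = 1)
  b <- generate_bold_subject(spec, TRUE, seed = 6)
  run <- b$runs[[1]][, -(1:6)]
  tr <- b$motion[[1]][-(1:6), ]
  outl <- outlier_fraction(b$runs[[1]],
                           b$masks$gm | b$masks$wm | b$masks$vent)
  cm <- censor(b$motion, list(outl))
  res <- nuisance_regress(run, tr, cm$keep[[1]], b$masks$wm, b$masks$vent,
                          spec$tr_s)
  mt <- tr[cm$keep[[1]], ]
  for (j in 1:6) {
    r <- abs(stats::cor(res[5, ], mt[, j]))
    expect_lt(r, 1e-8)
  }
})

test_that("node correlations orthogonal to the nuisance span are preserved", {
  # plant signals made exactly orthogonal to the deterministic nuisance
  # block (motion, derivatives, drift); the data-driven tissue regressors
  # then overlap only at the 1/T finite-sample level
  set.seed(44)
  spec <- tiny_bold_spec(seed = 4, n_volumes_per_run = 240, n_runs = 1,
                         motion_spike_rate = 0)
  b <- generate_bold_subject(spec, FALSE, seed = 7)
  t_len <- spec$n_volumes_per_run - 6
  tr <- b$motion[[1]][-(1:6), ]
  z <- cbind(1, tr, rbind(0, diff(tr)),
             readconn:::dct_basis(t_len, spec$tr_s, 0.01))
  lat <- matrix(rnorm(t_len * 5), t_len, 5)
  lat <- qr.resid(qr(z), lat)
  cv <- crossprod(scale(lat, scale = FALSE)) / (t_len - 1)
  lat <- scale(lat, scale = FALSE) %*% solve(chol(cv)) %*%
    chol(readconn::default_base_corr(5))
  v <- prod(spec$grid$shape)
  y <- matrix(rnorm(v * t_len, sd = 1), v, t_len)
  for (i in 1:5) {
    y[b$node_voxels[[i]], ] <- y[b$node_voxels[[i]], , drop = FALSE] +
      matrix(lat[, i], length(b$node_voxels[[i]]), t_len, byrow = TRUE)
  }
  res <- nuisance_regress(y, tr, rep(TRUE, t_len), b$masks$wm,
                          b$masks$vent, spec$tr_s)
  node_mean <- function(mat, i) colMeans(mat[b$node_voxels[[i]], ])
  deltas <- sapply(utils::combn(5, 2, simplify = FALSE), function(pr) {
    abs(cor(node_mean(res, pr[1]), node_mean(res, pr[2])) -
          cor(node_mean(y, pr[1]), node_mean(y, pr[2])))
  })
  expect_lt(max(deltas), 0.02)
})
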