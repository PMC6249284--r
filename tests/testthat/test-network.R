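test_that("seed correlation map applies the Fisher transform exactly", {
  set.seed(121)
  t_len <- 80
  seed_ts <- rnorm(t_len)
  half <- sqrt(0.5)
  run <- rbind(seed_ts,                               # the seed voxel itself
               rnorm(t_len),                          # independent voxel
               seed_ts)                               # perfectly correlated
  out <- seed_corr_map(run, seed_voxels = 1)
  expect_equal(out$r[1], 1 - 1e-7)
  expect_true(all(c(1, 3) %in% out$clipped))
  expect_equal(out$z[3], atanh(1 - 1e-7))
  # closed-form spot checks of the transform
  expect_equal(atanh(0.5), log(3) / 2)
  expect_equal(atanh(0), 0)
  # constant voxel maps to z = 0
  run2 <- rbind(seed_ts, rep(1, t_len))
  expect_equal(seed_corr_map(run2, 1)$z[2], 0)
  expect_error(seed_corr_map(matrix(1, 2, t_len), 1), "constant seed")
})

test_that("group network test is calibrated and recovers planted nodes", {
  set.seed(131)
  # identical maps with nonzero mean: capped t, inside the mask
  zm <- matrix(rep(c(0.5, 0, -0.2), each = 10), nrow = 10)
  gn <- group_network(zm, p_thresh = 0.001)
  expect_equal(gn$t[1], 1e6)
  expect_true(gn$network[1])
  expect_false(gn$network[2])   # zero mean
  expect_false(gn$network[3])   # negative mean excluded from the network
  # null maps: supra-threshold fraction near the threshold
  null_z <- matrix(rnorm(30 * 4000, 0, 0.1), 30)
  gn0 <- group_network(null_z, p_thresh = 0.05)
  # one-sided network mask keeps about half of the two-sided rejections
  expect_lt(abs(mean(gn0$network) - 0.025), 0.01)
})

test_that("planted network is recovered end to end from the seed", {
  spec <- tiny_bold_spec(seed = 6, n_volumes_per_run = 200, n_runs = 1,
                         motion_spike_rate = 0)
  n <- 8
  z_maps <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- generate_bold_subject(spec, FALSE, seed = 200 + i)
    seed_corr_map(b$runs[[1]][, -(1:6)], b$node_voxels[[1]])$z
  }))
  b <- generate_bold_subject(spec, FALSE, seed = 201)
  gm_idx <- which(b$masks$gm)
  gn <- group_network(z_maps[, gm_idx], p_thresh = 1e-4, mask = b$masks$gm)
  # every planted node overlaps the recovered network mask
  for (i in 1:5) {
    nd <- intersect(b$node_voxels[[i]], gm_idx)
    expect_gt(mean(gn$network[nd]), 0.5)
  }
  pk <- find_peaks(gn$t, gn$network, spec$grid, min_sep_mm = 15)
  centers <- default_node_centers(spec$grid$shape, spec$grid$voxel_mm)
  for (i in 1:5) {
    d <- sqrt(rowSums(sweep(as.matrix(pk[, 1:3]), 2, centers[i, ])^2))
    expect_lte(min(d), 2 * sqrt(3) * spec$grid$voxel_mm)
  }
})

test_that("peak finding enforces the minimum separation greedily", {
  grid <- make_grid(c(20, 10, 10), 3)
  m <- array(0, c(20, 10, 10))
  mask <- array(TRUE, c(20, 10, 10))
  m[3, 5, 5] <- 2    # 3 mm voxels: 14 voxels apart = 42 mm
  m[17, 5, 5] <- 1
  pk <- find_peaks(m, mask, grid, min_sep_mm = 30)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$value, c(2, 1))  # sorted descending
  m2 <- array(0, c(20, 10, 10))
  m2[8, 5, 5] <- 1
  m2[14, 5, 5] <- 2  # 18 mm apart < 20
  pk2 <- find_peaks(m2, mask, grid, min_sep_mm = 20)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$value, 2)  # the larger peak wins
  expect_equal(nrow(find_peaks(m, array(FALSE, c(20, 10, 10)), grid)), 0)
})

test_that("sphere ROIs have the published voxel counts", {
  # odd grid so the origin is a voxel center (peaks always are)
  grid <- make_grid(c(21, 21, 21), 3)
  expect_length(sphere_roi(c(0, 0, 0), 6, grid), 33)
  expect_length(sphere_roi(c(0, 0, 0), 0, grid), 1)
  expect_length(sphere_roi(c(0, 0, 0), 3, grid), 7)
  # brute-force oracle over every voxel center
  xyz <- coords_mm(grid)
  manual <- which(sqrt(rowSums(sweep(xyz, 2, c(6, -3, 0))^2)) <= 6)
  got <- sphere_roi(c(6, -3, 0), 6, grid)
  expect_identical(sort(as.vector(got)), manual)
  expect_warning(sphere_roi(c(28.5, 0, 0), 6, grid), "clipped")
})

test_that("node means equal the brute-force voxel average", {
  set.seed(141)
  grid <- make_grid(c(10, 10, 10), 3)
  pk <- data.frame(x = c(-6, 9), y = c(0, -3), z = c(0, 6))
  ns <- node_set(pk, grid, radius_mm = 5)
  zm <- matrix(rnorm(4 * 1000), 4)
  nv <- node_values(zm, ns)
  for (i in 1:4) {
    for (j in 1:2) {
      acc <- 0
      for (vx in ns$voxels[[j]]) acc <- acc + zm[i, vx]
      expect_equal(unname(nv[i, j]), acc / length(ns$voxels[[j]]),
                   tolerance = 1e-12)
    }
  }
  # constant and two-valued maps
  zc <- matrix(3, 1, 1000)
  expect_equal(unname(node_values(zc, ns)[1, ]), c(3, 3))
  ztv <- matrix(0, 1, 1000)
  ztv[1, ns$voxels[[2]]] <- 7
  expect_equal(unname(node_values(ztv, ns)[1, ]), c(0, 7))
})

test_that("backward selection keeps signal and respects alpha", {
  set.seed(151)
  n <- 500
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  # strong covariate retained essentially always
  y <- 0.8 * d$a + rnorm(n)
  kept <- backward_select(y, d, c("a", "b", "c", "d"))
  expect_true("a" %in% kept)
  # alpha = 1 keeps everything
  expect_identical(backward_select(y, d, c("a", "b", "c", "d"), alpha = 1),
                   c("a", "b", "c", "d"))
  # pure noise: empty set most of the time, never a p > alpha survivor
  y0 <- rnorm(n)
  kept0 <- backward_select(y0, d, c("a", "b", "c", "d"))
  if (length(kept0)) {
    fit <- lm(reformulate(kept0, response = "y0"),
              data = cbind(y0 = y0, d))
    expect_true(all(summary(fit)$coefficients[-1, 4] <= 0.05))
  } else {
    expect_length(kept0, 0)
  }
})

test_that("node regression detects the planted carrier increment", {
  set.seed(161)
  spec <- tiny_bold_spec(seed = 7, n_volumes_per_run = 180, n_runs = 1,
                         motion_spike_rate = 0)
  n <- 30
  carrier <- rep(c(TRUE, FALSE), c(10, 20))
  b1 <- generate_bold_subject(spec, TRUE, seed = 301)
  centers <- default_node_centers(spec$grid$shape, spec$grid$voxel_mm)
  ns <- node_set(data.frame(x = centers[, 1], y = centers[, 2],
                            z = centers[, 3]), spec$grid, radius_mm = 6)
  zm <- do.call(rbind, lapply(seq_len(n), function(i) {
    b <- generate_bold_subject(spec, carrier[i], seed = 300 + i)
    seed_corr_map(b$runs[[1]][, -(1:6)], b$node_voxels[[1]])$z
  }))
  nv <- node_values(zm, ns)
  covd <- data.frame(x = rnorm(n))
  # the carrier-coupled node (r_smg, node 3) shows a positive carrier effect
  m3 <- node_regression(nv[, 3], carrier, covd)
  expect_gt(m3$table$estimate[m3$table$term == "carrier"], 0.05)
  expect_lt(m3$table$p[m3$table$term == "carrier"], 0.01)
  # an uncoupled node (l_ifg) does not
  m2 <- node_regression(nv[, 2], carrier, covd)
  expect_gt(m2$table$p[m2$table$term == "carrier"], 0.05)
  # invariances: shifting connectivity moves only the intercept
  m3b <- node_regression(nv[, 3] + 5, carrier, covd)
  expect_equal(m3$table$estimate[m3$table$term == "carrier"],
               m3b$table$estimate[m3b$table$term == "carrier"],
               tolerance = 1e-10)
  expect_error(node_regression(nv[, 1], rep(TRUE, n), covd), "constant")
})
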