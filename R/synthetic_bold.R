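#' Specification for synthetic resting-state BOLD runs
#'
#' Emulates a small-grid resting-state acquisition with a planted bilateral
#' frontal-parietal-like network of spherical nodes. Latent node signals are
#' Gaussian series band-limited to the resting-state band
#' (`highpass_hz`-`lowpass_hz`, default 0.01-0.1 Hz, keeping them outside
#' the drift band the nuisance model removes) whose realized correlation
#' matrix equals the target (empirical whitening followed by Cholesky
#' mixing), with the
#' designated node pair's correlation raised by `carrier_corr_increment` for
#' RU2Short carriers and, optionally, the `pheno_node`'s correlations tilted
#' by the subject's comprehension-residual z (`pheno_corr_slope`). Voxel
#' series are the containing node's signal plus white noise; white-matter and
#' ventricle voxels carry shared low-frequency nuisance drifts; motion traces
#' contain spikes exceeding the 0.3 mm censoring threshold at
#' `motion_spike_rate`, with matching intensity spikes in the data.
#'
#' Defaults follow the acquisition the pipeline targets: TR = 1.55 s, two
#' runs of 240 volumes, 3 mm isotropic voxels.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_size_mm isotropic voxel size.
#' @param tr_s repetition time in seconds.
#' @param n_volumes_per_run,n_runs volumes per run and number of runs.
#' @param node_centers_mm matrix (nodes x 3) of node centers, mm. Default: a
#'   5-node set (right and left insula/IFG-like, right and left SMG-like,
#'   midline ACC-like).
#' @param node_radius_mm node sphere radius.
#' @param base_corr node correlation matrix (symmetric, unit diagonal, PSD).
#' @param carrier_pair indices of the node pair whose correlation depends on
#'   carrier status.
#' @param carrier_corr_increment added to the pair's correlation in carriers.
#' @param pheno_node,pheno_corr_slope optional phenotype coupling: the
#'   correlations of `pheno_node` with all other nodes are shifted by
#'   `pheno_corr_slope * pheno_z` per subject (0 disables).
#' @param noise_sd voxel white-noise SD (latent signals have unit SD).
#' @param lowpass_hz,highpass_hz latent-signal band (defaults 0.1 / 0.01 Hz).
#' @param motion_spike_rate per-volume probability of a motion spike.
#' @param seed integer seed.
#' @return Object of class `bold_spec`.
#' @export
bold_spec <- function(grid_shape = c(20, 24, 20), voxel_size_mm = 3,
                      tr_s = 1.55, n_volumes_per_run = 240, n_runs = 2,
                      node_centers_mm = default_node_centers(grid_shape,
                                                             voxel_size_mm),
                      node_radius_mm = 6,
                      base_corr = default_base_corr(nrow(node_centers_mm)),
                      carrier_pair = c(1, 3), carrier_corr_increment = 0.2,
                      pheno_node = 1, pheno_corr_slope = 0,
                      noise_sd = 1, lowpass_hz = 0.1, highpass_hz = 0.01,
                      motion_spike_rate = 0.03, seed = 1L) {
  stopifnot(n_runs >= 1, n_volumes_per_run >= 8, tr_s > 0)
  k <- nrow(node_centers_mm)
  stopifnot(nrow(base_corr) == k, ncol(base_corr) == k)
  if (max(abs(base_corr - t(base_corr))) > 1e-12 ||
      any(abs(diag(base_corr) - 1) > 1e-12) || any(abs(base_corr) > 1)) {
    stop("base_corr must be symmetric with unit diagonal and |r| <= 1",
         call. = FALSE)
  }
  if (min(eigen(base_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("base_corr must be positive semidefinite", call. = FALSE)
  }
  target <- base_corr[carrier_pair[1], carrier_pair[2]] +
    carrier_corr_increment
  if (abs(target) >= 1) {
    stop("carrier increment pushes the target correlation outside (-1, 1)",
         call. = FALSE)
  }
  grid <- make_grid(grid_shape, voxel_size_mm)
  lo <- grid$origin_mm - voxel_size_mm / 2
  hi <- grid$origin_mm + (grid_shape - 0.5) * voxel_size_mm
  for (i in seq_len(k)) {
    c_i <- node_centers_mm[i, ]
    if (any(c_i - node_radius_mm < lo) || any(c_i + node_radius_mm > hi)) {
      stop("node ", i, " overlaps the grid boundary", call. = FALSE)
    }
  }
  structure(list(grid = grid, tr_s = tr_s,
                 n_volumes_per_run = as.integer(n_volumes_per_run),
                 n_runs = as.integer(n_runs),
                 node_centers_mm = node_centers_mm,
                 node_radius_mm = node_radius_mm,
                 base_corr = base_corr, carrier_pair = carrier_pair,
                 carrier_corr_increment = carrier_corr_increment,
                 pheno_node = pheno_node, pheno_corr_slope = pheno_corr_slope,
                 noise_sd = noise_sd, lowpass_hz = lowpass_hz,
                 highpass_hz = highpass_hz,
                 motion_spike_rate = motion_spike_rate,
                 seed = as.integer(seed)),
            class = "bold_spec")
}

#' Default planted network node centers
#'
#' Five nodes placed at fixed fractions of the grid extent: right and left
#' anterior-lateral (insula/IFG-like), right and left posterior-lateral
#' (SMG-like), and one superior midline (ACC-like). On the default
#' 60 x 72 x 60 mm grid this gives centers such as (21, 9, 0) mm for the
#' right anterior node.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_size_mm voxel size.
#' @return 5 x 3 matrix of mm coordinates with row names.
#' @export
default_node_centers <- function(grid_shape = c(20, 24, 20),
                                 voxel_size_mm = 3) {
  ext <- grid_shape * voxel_size_mm
  m <- rbind(r_ifg = c(0.35, 0.125, 0), l_ifg = c(-0.35, 0.125, 0),
             r_smg = c(0.35, -0.25, 0.15), l_smg = c(-0.35, -0.25, 0.15),
             acc = c(0, 0.17, 0.30))
  m <- sweep(m, 2, ext, "*")
  colnames(m) <- c("x", "y", "z")
  m
}

#' Default node correlation matrix (equicorrelated at 0.5)
#' @param k number of nodes.
#' @return k x k correlation matrix.
#' @export
default_base_corr <- function(k) {
  r <- matrix(0.5, k, k)
  diag(r) <- 1
  r
}

# band-pass filter columns to [low_hz, high_hz] via FFT truncation
bandpass_filter <- function(x, tr_s, low_hz, high_hz) {
  n <- nrow(x)
  freqs <- (seq_len(n) - 1) / (n * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # two-sided
  keep <- freqs <= high_hz & freqs >= low_hz
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / n
}

# latent node signals with the realized correlation matrix equal to `r`
latent_signals <- function(t_len, r, tr_s, cutoff_hz, highpass_hz = 0.01) {
  k <- nrow(r)
  x <- matrix(stats::rnorm(t_len * k), t_len, k)
  x <- bandpass_filter(x, tr_s, highpass_hz, cutoff_hz)
  x <- scale(x, center = TRUE, scale = FALSE)
  # empirical whitening, then impose target correlation exactly
  cv <- crossprod(x) / (t_len - 1)
  x <- x %*% solve(chol(cv))
  ev <- eigen(r, symmetric = TRUE)
  mix <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  s <- x %*% mix
  scale(s, center = FALSE, scale = apply(s, 2, stats::sd))
}

# per-subject node correlation matrix with planted effects
subject_corr <- function(spec, carrier, pheno_z) {
  r <- spec$base_corr
  if (isTRUE(carrier)) {
    i <- spec$carrier_pair[1]; j <- spec$carrier_pair[2]
    r[i, j] <- r[j, i] <- r[i, j] + spec$carrier_corr_increment
  }
  if (spec$pheno_corr_slope != 0 && !is.null(pheno_z) && !is.na(pheno_z)) {
    pn <- spec$pheno_node
    shift <- spec$pheno_corr_slope * pheno_z
    r[pn, -pn] <- pmin(pmax(r[pn, -pn] + shift, -0.95), 0.95)
    r[-pn, pn] <- r[pn, -pn]
  }
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("planted effects make the node correlation matrix indefinite",
         call. = FALSE)
  }
  r
}

#' Tissue masks for the synthetic anatomy
#'
#' Gray matter is a large central ellipsoid minus the deep white-matter
#' ellipsoid; lateral-ventricle and white-matter masks sit inside it.
#'
#' @param spec a [bold_spec()].
#' @return List of logical arrays: `gm`, `wm`, `vent`.
#' @export
bold_masks <- function(spec) {
  grid <- spec$grid
  ext <- grid$shape * grid$voxel_mm
  brain <- ellipsoid_mask(grid, 0.46 * ext)
  deep <- ellipsoid_mask(grid, 0.24 * ext)
  vent <- ellipsoid_mask(grid, 0.08 * ext)
  wm <- deep & !vent
  gm <- brain & !deep
  list(gm = gm, wm = wm, vent = vent)
}

#' Generate one subject's synthetic BOLD runs and motion traces
#'
#' @param spec a [bold_spec()].
#' @param carrier logical RU2Short carrier flag.
#' @param pheno_z subject's standardized comprehension residual (used only
#'   when the spec's `pheno_corr_slope` is nonzero).
#' @param seed integer seed for this subject.
#' @return List: `runs` (list of voxels x volumes matrices in linear voxel
#'   order), `motion` (list of volumes x 6 matrices: 3 translations mm, 3
#'   rotations degrees), `masks` (gm/wm/vent logical arrays), `node_voxels`
#'   (list of linear-index vectors), `grid`, `tr_s`.
#' @export
generate_bold_subject <- function(spec, carrier, pheno_z = 0, seed = 1L) {
  set.seed(seed)
  grid <- spec$grid
  v_total <- prod(grid$shape)
  t_run <- spec$n_volumes_per_run
  masks <- bold_masks(spec)
  node_voxels <- lapply(seq_len(nrow(spec$node_centers_mm)), function(i) {
    sphere_roi(spec$node_centers_mm[i, ], spec$node_radius_mm, grid)
  })
  r <- subject_corr(spec, carrier, pheno_z)
  wm_idx <- which(masks$wm)
  vent_idx <- which(masks$vent)
  runs <- vector("list", spec$n_runs)
  motion <- vector("list", spec$n_runs)
  tt <- seq_len(t_run)
  for (rr in seq_len(spec$n_runs)) {
    sig <- latent_signals(t_run, r, spec$tr_s, spec$lowpass_hz,
                          spec$highpass_hz)
    y <- matrix(stats::rnorm(v_total * t_run, sd = spec$noise_sd),
                v_total, t_run)
    for (i in seq_along(node_voxels)) {
      y[node_voxels[[i]], ] <- y[node_voxels[[i]], , drop = FALSE] +
        matrix(sig[, i], length(node_voxels[[i]]), t_run, byrow = TRUE)
    }
    # shared slow nuisance drifts in white matter and ventricles
    drift_wm <- 1.5 * sin(2 * pi * tt / (t_run * stats::runif(1, 1, 2)) +
                            stats::runif(1, 0, 2 * pi))
    y[wm_idx, ] <- y[wm_idx, , drop = FALSE] +
      matrix(drift_wm, length(wm_idx), t_run, byrow = TRUE)
    for (pc in 1:3) {
      dv <- 1.5 * sin(2 * pi * pc * tt / t_run + stats::runif(1, 0, 2 * pi))
      wts <- stats::rnorm(length(vent_idx), 1, 0.3)
      y[vent_idx, ] <- y[vent_idx, , drop = FALSE] + outer(wts, dv)
    }
    # motion: slow random walk + spikes above the 0.3 mm censoring threshold
    mt <- apply(matrix(stats::rnorm(t_run * 6, sd = 0.01), t_run, 6), 2,
                cumsum)
    spikes <- which(stats::runif(t_run) < spec$motion_spike_rate)
    for (s in spikes) {
      par <- sample(1:3, 1)
      mt[s:t_run, par] <- mt[s:t_run, par] +
        stats::runif(1, 0.4, 1.0) * sample(c(-1, 1), 1)
      bad_vox <- sample(v_total, round(0.15 * v_total))
      y[bad_vox, s] <- y[bad_vox, s] + 8 * spec$noise_sd
    }
    runs[[rr]] <- y
    motion[[rr]] <- mt
  }
  list(runs = runs, motion = motion, masks = masks,
       node_voxels = node_voxels, grid = grid, tr_s = spec$tr_s)
}

#' Generate a set of subjects' synthetic BOLD data
#'
#' Thin wrapper over [generate_bold_subject()]; note that holding many
#' subjects on a large grid in memory is costly — pipelines should generate
#' and process one subject at a time.
#'
#' @param spec a [bold_spec()].
#' @param carriers logical vector, one flag per subject.
#' @param pheno_z numeric vector of comprehension-residual z values.
#' @return List of per-subject objects (see [generate_bold_subject()]).
#' @export
generate_bold <- function(spec, carriers, pheno_z = NULL) {
  n <- length(carriers)
  pheno_z <- pheno_z %||% rep(0, n)
  lapply(seq_len(n), function(i) {
    generate_bold_subject(spec, carriers[i], pheno_z[i],
                          seed = derive_seed(spec$seed, paste0("subj", i)))
  })
}
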