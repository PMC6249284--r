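#' Seed-based connectivity z map
#'
#' Correlates the mean time course of a seed region with every voxel's time
#' course and applies the Fisher (arctanh) variance-stabilizing transform.
#' Correlations at exactly +/-1 (e.g. voxels inside a single-voxel seed) are
#' clipped to +/-(1 - 1e-7) before the transform and flagged.
#'
#' @param run voxels x volumes matrix (censored volumes already dropped).
#' @param seed_voxels linear indices of the seed region.
#' @return List: `z` (per-voxel Fisher z vector), `r` (correlations),
#'   `clipped` (indices clipped at |r| = 1).
#' @export
seed_corr_map <- function(run, seed_voxels) {
  seed_ts <- colMeans(run[seed_voxels, , drop = FALSE])
  if (stats::sd(seed_ts) == 0) stop("constant seed time course", call. = FALSE)
  sds <- sqrt(rowSums((run - rowMeans(run))^2))
  r <- suppressWarnings(as.vector(stats::cor(seed_ts, t(run))))
  r[sds == 0] <- 0  # constant voxels carry no connectivity
  clipped <- which(abs(r) >= 1 - 1e-12)
  r[clipped] <- sign(r[clipped]) * (1 - 1e-7)
  list(z = atanh(r), r = r, clipped = clipped)
}

#' Groupwise one-sample t-test over subject z maps
#'
#' Per-voxel one-sample t across subjects; the network mask keeps voxels
#' with positive mean connectivity whose two-sided p falls below the
#' threshold. Degenerate voxels (zero between-subject variance) get a
#' capped t of +/-1e6.
#'
#' @param z_maps subjects x voxels matrix of Fisher z values.
#' @param p_thresh network threshold (default 1e-6; the real-scale default
#'   of 1e-20 presumes much larger t values than desk-scale runs produce).
#' @param mask optional logical array to shape the outputs.
#' @return List: `t`, `p` (vectors or 3D arrays), `network` (logical mask of
#'   the thresholded network).
#' @export
group_network <- function(z_maps, p_thresh = 1e-6, mask = NULL) {
  n <- nrow(z_maps)
  stopifnot(n >= 3)
  mu <- colMeans(z_maps)
  sd_v <- apply(z_maps, 2, stats::sd)
  tstat <- ifelse(sd_v > 0, mu / (sd_v / sqrt(n)), sign(mu) * 1e6)
  tstat <- pmin(pmax(tstat, -1e6), 1e6)
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  network <- p < p_thresh & tstat > 0
  if (!is.null(mask)) {
    idx <- which(mask)
    stopifnot(length(idx) == ncol(z_maps))
    to_arr <- function(v, fill) {
      a <- array(fill, dim(mask)); a[idx] <- v; a
    }
    return(list(t = to_arr(tstat, NA_real_), p = to_arr(p, NA_real_),
                network = to_arr(network, FALSE)))
  }
  list(t = tstat, p = p, network = network)
}

#' Build a node set from network peaks
#'
#' Centers a fixed-radius sphere on each peak coordinate.
#'
#' @param peaks data.frame from [find_peaks()] (columns x, y, z).
#' @param grid a [make_grid()].
#' @param radius_mm sphere radius (default 6).
#' @param labels optional node labels.
#' @return List of class `node_set`: `nodes` (data.frame: label, x, y, z,
#'   size), `voxels` (list of index vectors), `radius_mm`.
#' @export
node_set <- function(peaks, grid, radius_mm = 6, labels = NULL) {
  labels <- labels %||% sprintf("node%02d", seq_len(nrow(peaks)))
  vox <- lapply(seq_len(nrow(peaks)), function(i) {
    sphere_roi(c(peaks$x[i], peaks$y[i], peaks$z[i]), radius_mm, grid)
  })
  structure(list(nodes = data.frame(label = labels, x = peaks$x,
                                    y = peaks$y, z = peaks$z,
                                    size = lengths(vox)),
                 voxels = vox, radius_mm = radius_mm),
            class = "node_set")
}

#' Mean connectivity z per subject and node
#'
#' @param z_maps subjects x voxels matrix of Fisher z values (full grid
#'   voxel order).
#' @param nodes a [node_set()].
#' @return subjects x nodes matrix of sphere-mean z values.
#' @export
node_values <- function(z_maps, nodes) {
  out <- sapply(nodes$voxels, function(ix) {
    rowMeans(z_maps[, ix, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(z_maps))
  colnames(out) <- nodes$nodes$label
  out
}

#' Backward covariate selection by p-value
#'
#' Starting from the full OLS model, repeatedly removes the covariate with
#' the largest p-value above `alpha` (ties broken by predictor order) and
#' refits, until every retained covariate has p <= alpha. May return an
#' empty set.
#'
#' @param y response vector.
#' @param data data.frame containing the covariate pool.
#' @param pool covariate column names.
#' @param alpha inclusion/exclusion criterion (default 0.05).
#' @return Character vector of retained covariates.
#' @export
backward_select <- function(y, data, pool, alpha = 0.05) {
  stopifnot(length(pool) >= 1, nrow(data) > length(pool) + 2)
  retained <- pool
  dat <- cbind(.y = y, data[, pool, drop = FALSE])
  repeat {
    if (!length(retained)) return(character(0))
    fit <- stats::lm(stats::reformulate(retained, response = ".y"),
                     data = dat)
    sm <- summary(fit)$coefficients
    pvals <- vapply(retained, function(v) {
      rows <- grep(paste0("^", v), rownames(sm))
      min(sm[rows, 4])
    }, numeric(1))
    if (all(pvals <= alpha)) return(retained)
    worst <- which(pvals == max(pvals))[1]  # predictor-order tie-break
    retained <- retained[-worst]
  }
}

#' Genotype-connectivity regression at one node
#'
#' OLS of a node's connectivity values on the carrier indicator (forced in)
#' plus the covariates retained by backward selection.
#'
#' @param y per-subject node connectivity (mean z).
#' @param carrier logical/0-1 carrier flags.
#' @param data data.frame of covariates.
#' @param covariates retained covariate names (possibly empty).
#' @return List of class `node_model`: `table` (term, estimate, se, p),
#'   `fit`.
#' @export
node_regression <- function(y, carrier, data, covariates = character(0)) {
  if (length(unique(carrier)) < 2) {
    stop("carrier indicator is constant", call. = FALSE)
  }
  dat <- cbind(.y = y, carrier = as.numeric(carrier),
               data[, covariates, drop = FALSE])
  fit <- stats::lm(stats::reformulate(c("carrier", covariates),
                                      response = ".y"), data = dat)
  sm <- summary(fit)$coefficients
  tab <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    p = sm[, 4], row.names = NULL)
  structure(list(table = tab, fit = fit), class = "node_model")
}
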