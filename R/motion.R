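#' Per-volume Euclidean movement from a motion trace
#'
#' The square root of the sum of squared point-to-point changes over the six
#' rigid-body parameters (3 translations mm, 3 rotations degrees). The first
#' volume has no predecessor and gets 0.
#'
#' @param trace volumes x 6 numeric matrix.
#' @return Numeric vector, one displacement per volume.
#' @export
euclidean_movement <- function(trace) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2) stop("need at least 2 volumes", call. = FALSE)
  d <- diff(trace)
  c(0, sqrt(rowSums(d^2)))
}

#' Per-volume outlier-voxel fraction
#'
#' After removing each in-mask voxel's linear trend, a voxel is an outlier
#' at a volume if its detrended value deviates from the voxel's run median
#' by more than `k` times the voxel's median absolute deviation (scaled
#' MAD). Returns the fraction of in-mask voxels flagged at each volume.
#'
#' @param run voxels x volumes matrix (linear voxel order).
#' @param mask logical array or integer indices of in-mask voxels.
#' @param k MAD multiplier (default 3.5).
#' @return Numeric vector in `[0, 1]`, one fraction per volume.
#' @export
outlier_fraction <- function(run, mask, k = 3.5) {
  idx <- if (is.logical(mask)) which(mask) else mask
  if (!length(idx)) stop("empty mask", call. = FALSE)
  y <- run[idx, , drop = FALSE]
  t_len <- ncol(y)
  tt <- seq_len(t_len)
  x <- cbind(1, tt - mean(tt))
  beta <- solve(crossprod(x), crossprod(x, t(y)))
  y <- y - t(x %*% beta)
  med <- apply(y, 1, stats::median)
  mad_v <- apply(y, 1, stats::mad)
  mad_v[mad_v == 0] <- Inf  # constant voxels can never be outliers
  out <- abs(y - med) > k * mad_v
  colMeans(out)
}

#' Volume censoring and subject retention decision
#'
#' The first `drop_initial` volumes of each run are removed outright
#' (scanner stabilization). A remaining volume is censored when its
#' Euclidean movement strictly exceeds `move_thresh` or its outlier-voxel
#' fraction strictly exceeds `outlier_thresh`. The subject is excluded when
#' the fraction of retained volumes across all runs falls below
#' `min_retention`.
#'
#' @param motion list of volumes x 6 motion traces, one per run.
#' @param outlier list of per-volume outlier fractions, one per run (same
#'   lengths as the traces), or `NULL` to censor on movement only.
#' @param drop_initial initial volumes dropped per run (default 6).
#' @param move_thresh movement threshold in mm (default 0.3).
#' @param outlier_thresh outlier-fraction threshold (default 0.10).
#' @param min_retention retention fraction below which the subject is
#'   excluded (default 0.60).
#' @return List of class `censor_mask`: `keep` (list of logical vectors over
#'   post-drop volumes), `retention`, `excluded`, `n_censored`.
#' @export
censor <- function(motion, outlier = NULL, drop_initial = 6,
                   move_thresh = 0.3, outlier_thresh = 0.10,
                   min_retention = 0.60) {
  keep <- vector("list", length(motion))
  for (rr in seq_along(motion)) {
    mt <- as.matrix(motion[[rr]])
    disp <- euclidean_movement(mt)
    bad <- disp > move_thresh
    if (!is.null(outlier)) {
      of <- outlier[[rr]]
      stopifnot(length(of) == nrow(mt))
      bad <- bad | (of > outlier_thresh)
    }
    keep[[rr]] <- !bad[-seq_len(drop_initial)]
  }
  total <- sum(lengths(keep))
  kept <- sum(unlist(keep))
  retention <- kept / total
  structure(list(keep = keep, retention = retention,
                 excluded = retention < min_retention,
                 n_censored = total - kept),
            class = "censor_mask")
}

# discrete-cosine drift basis for frequencies below cutoff_hz
dct_basis <- function(t_len, tr_s, cutoff_hz = 0.01) {
  kmax <- floor(2 * t_len * tr_s * cutoff_hz)
  if (kmax < 1) return(NULL)
  tt <- seq_len(t_len)
  sapply(seq_len(kmax), function(k) cos(pi * (tt - 0.5) * k / t_len))
}

#' Nuisance regression of motion, drift, and tissue signals
#'
#' Per-voxel ordinary least squares removal of: the six motion parameters
#' and their first derivatives, a discrete-cosine drift basis spanning
#' frequencies below `drift_hz`, the first three principal components of the
#' ventricle-mask signal, and the mean white-matter signal. The model is fit
#' on retained volumes only (censored volumes are excluded and dropped from
#' the output). Collinear regressors are dropped with a warning.
#'
#' @param run voxels x volumes matrix (pre-drop volumes already removed).
#' @param trace matching volumes x 6 motion trace (post-drop).
#' @param keep logical vector of retained volumes (from [censor()]).
#' @param wm_mask,vent_mask logical arrays or voxel indices.
#' @param tr_s repetition time, seconds.
#' @param drift_hz drift band upper edge (default 0.01 Hz).
#' @return voxels x sum(keep) residual matrix.
#' @export
nuisance_regress <- function(run, trace, keep, wm_mask, vent_mask,
                             tr_s, drift_hz = 0.01) {
  stopifnot(ncol(run) == nrow(trace), length(keep) == ncol(run))
  wm_idx <- if (is.logical(wm_mask)) which(wm_mask) else wm_mask
  vent_idx <- if (is.logical(vent_mask)) which(vent_mask) else vent_mask
  y <- run[, keep, drop = FALSE]
  mt <- as.matrix(trace)[keep, , drop = FALSE]
  dmt <- rbind(0, diff(mt))
  dct <- dct_basis(sum(keep), tr_s, drift_hz)
  wm_mean <- colMeans(run[wm_idx, keep, drop = FALSE])
  vent_ts <- t(run[vent_idx, keep, drop = FALSE])
  vent_pc <- stats::prcomp(vent_ts, center = TRUE, scale. = FALSE)
  npc <- min(3, ncol(vent_pc$x))
  x <- cbind(1, mt, dmt, dct, vent_pc$x[, seq_len(npc), drop = FALSE],
             wm_mean)
  q <- qr(x)
  if (q$rank < ncol(x)) {
    warning("dropped ", ncol(x) - q$rank, " collinear nuisance regressor(s)")
  }
  t(qr.resid(q, t(y)))
}
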