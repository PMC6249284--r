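#' Define an isotropic RAS voxel grid
#'
#' The grid is centered on the world origin: voxel centers run from
#' `-(dim - 1)/2 * voxel` to `+(dim - 1)/2 * voxel` mm along each axis.
#'
#' @param shape integer vector of voxel counts per axis (x, y, z).
#' @param voxel_mm isotropic voxel size in mm (default 3).
#' @return List of class `vox_grid`: `shape`, `voxel_mm`, `affine` (4 x 4
#'   voxel-to-mm, 1-based voxel indices), `origin_mm`.
#' @export
make_grid <- function(shape, voxel_mm = 3) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), voxel_mm > 0)
  origin <- -(shape - 1) / 2 * voxel_mm
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- origin - voxel_mm  # world = affine %*% (i, j, k, 1)
  structure(list(shape = shape, voxel_mm = voxel_mm, affine = affine,
                 origin_mm = origin), class = "vox_grid")
}

#' World-mm coordinates of every voxel center
#'
#' @param grid a [make_grid()].
#' @return `prod(shape)` x 3 matrix in the grid's linear voxel order.
#' @export
coords_mm <- function(grid) {
  s <- grid$shape
  i <- rep(seq_len(s[1]), times = s[2] * s[3])
  j <- rep(rep(seq_len(s[2]), each = s[1]), times = s[3])
  k <- rep(seq_len(s[3]), each = s[1] * s[2])
  cbind(x = (i - 1) * grid$voxel_mm + grid$origin_mm[1],
        y = (j - 1) * grid$voxel_mm + grid$origin_mm[2],
        z = (k - 1) * grid$voxel_mm + grid$origin_mm[3])
}

#' Sphere region of interest on a voxel grid
#'
#' Voxel-center inclusion: returns the linear indices of voxels whose
#' centers lie within `radius_mm` of the given world coordinate. On a 3 mm
#' grid a 6 mm radius covers 33 voxels (the continuous volume ratio is 33.5).
#'
#' @param center_mm length-3 world coordinate.
#' @param radius_mm sphere radius (>= 0).
#' @param grid a [make_grid()].
#' @param warn_clipped warn if the sphere extends past the grid edge.
#' @return Integer vector of linear voxel indices with attribute `clipped`.
#' @export
sphere_roi <- function(center_mm, radius_mm, grid, warn_clipped = TRUE) {
  stopifnot(radius_mm >= 0)
  xyz <- coords_mm(grid)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  idx <- which(d2 <= radius_mm^2 + 1e-9)
  if (!length(idx)) {
    # empty only if the center is off-grid; snap to nearest voxel center
    idx <- which.min(d2)
  }
  lo <- grid$origin_mm - grid$voxel_mm / 2
  hi <- grid$origin_mm + (grid$shape - 0.5) * grid$voxel_mm
  clipped <- any(center_mm - radius_mm < lo) || any(center_mm + radius_mm > hi)
  if (clipped && warn_clipped) {
    warning("sphere clipped at grid boundary", call. = FALSE)
  }
  attr(idx, "clipped") <- clipped
  idx
}

#' Ellipsoid mask (synthetic-anatomy helper)
#'
#' @param grid a [make_grid()].
#' @param semi_axes_mm length-3 semi-axes.
#' @param center_mm ellipsoid center (default origin).
#' @return Logical 3D array.
#' @export
ellipsoid_mask <- function(grid, semi_axes_mm, center_mm = c(0, 0, 0)) {
  xyz <- coords_mm(grid)
  inside <- ((xyz[, 1] - center_mm[1]) / semi_axes_mm[1])^2 +
    ((xyz[, 2] - center_mm[2]) / semi_axes_mm[2])^2 +
    ((xyz[, 3] - center_mm[3]) / semi_axes_mm[3])^2 <= 1
  array(inside, dim = grid$shape)
}

# separable 3D convolution by per-axis kernel matrices
conv3d_sep <- function(arr, kmats) {
  d <- dim(arr)
  x <- kmats[[1]] %*% matrix(arr, d[1], d[2] * d[3])
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- kmats[[2]] %*% matrix(x, d[2], d[1] * d[3])
  x <- aperm(array(x, d[c(2, 1, 3)]), c(2, 1, 3))
  x <- aperm(x, c(3, 1, 2))
  x <- kmats[[3]] %*% matrix(x, d[3], d[1] * d[2])
  aperm(array(x, d[c(3, 1, 2)]), c(2, 3, 1))
}

gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  i <- seq_len(n)
  k <- exp(-outer(i, i, "-")^2 / (2 * sigma_vox^2))
  k * (abs(outer(i, i, "-")) <= ceiling(4 * sigma_vox))
}

#' Gaussian smoothing of a 3D map with mask renormalization
#'
#' Separable Gaussian kernel of the given full width at half maximum.
#' Within a mask the kernel is renormalized by the smoothed mask so that a
#' constant map stays constant up to the mask edge; voxels outside the mask
#' are set to 0.
#'
#' @param map 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @param voxel_mm voxel size in mm.
#' @param mask optional logical array of the same shape.
#' @return Smoothed array.
#' @export
smooth_map <- function(map, fwhm_mm, voxel_mm = 3, mask = NULL) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) {
    if (!is.null(mask)) map[!mask] <- 0
    return(map)
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  kmats <- lapply(dim(map), gauss_kernel_matrix, sigma_vox = sigma)
  if (is.null(mask)) {
    kmats <- lapply(kmats, function(k) sweep(k, 1, rowSums(k), "/"))
    return(conv3d_sep(map, kmats))
  }
  m <- array(as.numeric(mask), dim = dim(map))
  map[!mask] <- 0  # out-of-mask values (often NA) must not leak in
  num <- conv3d_sep(map * m, kmats)
  den <- conv3d_sep(m, kmats)
  out <- array(0, dim(map))
  out[mask] <- num[mask] / den[mask]
  out
}

#' Connected components of a logical 3D array
#'
#' @param supra logical 3D array of supra-threshold voxels.
#' @param connectivity 6 (faces) or 26 (faces + edges + corners).
#' @return List of integer vectors of linear voxel indices, one per cluster,
#'   ordered by decreasing size.
#' @export
connected_components <- function(supra, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(supra)
  idx <- which(supra)
  if (!length(idx)) return(list())
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  lab <- array(0L, d)
  lab[idx] <- -1L
  comp <- list()
  nc <- 0L
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != -1L) next
    nc <- nc + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- nc
    members <- integer(0)
    while (top > 0L) {
      v <- stack[top]; top <- top - 1L
      members <- c(members, v)
      k0 <- (v - 1L) %/% (d[1] * d[2])
      j0 <- ((v - 1L) %% (d[1] * d[2])) %/% d[1]
      i0 <- (v - 1L) %% d[1]
      for (r in seq_len(nrow(offs))) {
        i <- i0 + offs[r, 1]; j <- j0 + offs[r, 2]; k <- k0 + offs[r, 3]
        if (i < 0 || i >= d[1] || j < 0 || j >= d[2] || k < 0 || k >= d[3])
          next
        w <- i + j * d[1] + k * d[1] * d[2] + 1
        if (lab[w] == -1L) {
          lab[w] <- nc
          top <- top + 1L
          stack[top] <- w
        }
      }
    }
    comp[[nc]] <- members
  }
  comp[order(-lengths(comp))]
}

#' Local maxima of a map with minimum peak separation
#'
#' A voxel is a candidate peak if it exceeds all of its face neighbors
#' inside the mask. Candidates are sorted by decreasing value and retained
#' greedily subject to a pairwise minimum world-distance.
#'
#' @param map 3D numeric array.
#' @param mask logical array (search region).
#' @param grid a [make_grid()] matching `map`.
#' @param min_sep_mm minimum separation between retained peaks (default 30).
#' @return data.frame: `x`, `y`, `z` (mm), `value`, `index` (linear voxel
#'   index), sorted by decreasing value. Empty mask gives zero rows.
#' @export
find_peaks <- function(map, mask, grid, min_sep_mm = 30) {
  stopifnot(min_sep_mm >= 0)
  d <- dim(map)
  mp <- map
  mp[!mask] <- -Inf
  cand <- integer(0)
  for (v in which(mask)) {
    k0 <- (v - 1) %/% (d[1] * d[2])
    j0 <- ((v - 1) %% (d[1] * d[2])) %/% d[1]
    i0 <- (v - 1) %% d[1]
    is_max <- TRUE
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                     c(0, 0, 1), c(0, 0, -1))) {
      i <- i0 + off[1]; j <- j0 + off[2]; k <- k0 + off[3]
      if (i < 0 || i >= d[1] || j < 0 || j >= d[2] || k < 0 || k >= d[3])
        next
      if (mp[i + j * d[1] + k * d[1] * d[2] + 1] >= mp[v]) {
        is_max <- FALSE
        break
      }
    }
    if (is_max) cand <- c(cand, v)
  }
  if (!length(cand)) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      value = numeric(0), index = integer(0)))
  }
  cand <- cand[order(-map[cand])]
  xyz <- coords_mm(grid)
  kept <- integer(0)
  for (v in cand) {
    if (!length(kept)) {
      kept <- v
    } else {
      dist <- sqrt(rowSums((xyz[kept, , drop = FALSE] -
                              matrix(xyz[v, ], length(kept), 3,
                                     byrow = TRUE))^2))
      if (all(dist >= min_sep_mm)) kept <- c(kept, v)
    }
  }
  data.frame(x = xyz[kept, 1], y = xyz[kept, 2], z = xyz[kept, 3],
             value = map[kept], index = kept)
}
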