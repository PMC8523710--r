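#' Build a spherical searchlight over a voxel grid
#'
#' Centres a sphere of `radius` voxels (Euclidean distance on the integer
#' grid) on every in-mask voxel (or a supplied subset of centres) and records
#' the in-mask member voxels of each sphere. A full interior sphere of radius
#' 3 contains exactly 123 voxels; radius 1 gives the centre plus its 6 face
#' neighbours. Spheres whose in-mask membership falls below `min_voxels` are
#' dropped (their count is reported in the object).
#'
#' @param dim Grid dimensions (integer triple).
#' @param mask Logical 3D array of analysable voxels.
#' @param radius Sphere radius in voxels (>= 1, default 3).
#' @param min_voxels Minimum sphere occupancy (default 10).
#' @param centers Optional restriction of centres: logical 3D array or vector
#'   of linear voxel indices (still intersected with the mask).
#' @return Object of class `searchlight`: list with `centers` (linear
#'   indices), `idx` (centres x offsets matrix of member indices), `valid`
#'   (logical matrix), `n_dropped`, `radius`, `dim`.
#' @export
build_searchlight <- function(dim, mask = NULL, radius = 3, min_voxels = 10,
                              centers = NULL) {
  mt_validate(radius >= 1, "`radius` must be at least 1")
  if (is.null(mask)) mask <- array(TRUE, dim)
  mt_validate(any(mask), "mask is empty")
  off <- sphere_offsets(radius)
  if (is.null(centers)) {
    ctr <- which(as.logical(mask))
  } else if (is.logical(centers) || is.array(centers)) {
    ctr <- which(as.logical(centers) & as.logical(mask))
  } else {
    ctr <- intersect(as.integer(centers), which(as.logical(mask)))
  }
  mt_validate(length(ctr) > 0, "no searchlight centres inside the mask")
  cc <- index_to_coord(ctr, dim)
  n_off <- nrow(off)
  idx <- matrix(1L, length(ctr), n_off)
  valid <- matrix(FALSE, length(ctr), n_off)
  mvec <- as.logical(mask)
  for (k in seq_len(n_off)) {
    x <- cc[, 1] + off[k, 1]
    y <- cc[, 2] + off[k, 2]
    z <- cc[, 3] + off[k, 3]
    ok <- x >= 1 & x <= dim[1] & y >= 1 & y <= dim[2] & z >= 1 & z <= dim[3]
    li <- rep(1L, length(ctr))
    li[ok] <- coord_to_index(cbind(x[ok], y[ok], z[ok]), dim)
    ok[ok] <- mvec[li[ok]]
    idx[, k] <- li
    valid[, k] <- ok
  }
  occupancy <- rowSums(valid)
  keep <- occupancy >= min_voxels
  n_dropped <- sum(!keep)
  mt_validate(any(keep), "all searchlight spheres fall below `min_voxels`")
  structure(list(centers = ctr[keep], idx = idx[keep, , drop = FALSE],
                 valid = valid[keep, , drop = FALSE],
                 n_dropped = n_dropped, radius = radius, dim = dim,
                 min_voxels = min_voxels),
            class = "searchlight")
}

# integer offsets with squared norm <= radius^2
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- as.matrix(expand.grid(x = -r:r, y = -r:r, z = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' @export
print.searchlight <- function(x, ...) {
  cat(sprintf("<searchlight> radius %g, %d centres (max %d voxels/sphere, %d dropped)\n",
              x$radius, length(x$centers), ncol(x$idx), x$n_dropped))
  invisible(x)
}

#' Fisher z-transform of correlations
#'
#' `atanh` of the correlation after clipping to `+/-(1 - 1e-7)`, so perfect
#' correlations map to a large finite value rather than infinity.
#'
#' @param r Numeric vector of correlations; `|r|` beyond `1 + 1e-8` errors.
#' @return Fisher z values.
#' @examples
#' fisher_z(c(0, 0.5, 1))
#' @export
fisher_z <- function(r) {
  mt_validate(all(is.na(r) | abs(r) <= 1 + 1e-8),
              "correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
}
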