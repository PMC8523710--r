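#' Gaussian spatial smoothing of volumes and maps
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 * sqrt(2 * log(2)))`
#' per axis, expressed in voxel units via `voxel_size_mm`. Smoothing is
#' mask-aware: the kernel is renormalised over in-mask support so values do
#' not leak across the mask edge or shrink at the boundary.
#'
#' @param x A [bold_run()], [stat_map()] or 3D array.
#' @param fwhm Full width at half maximum in millimetres (0 = identity).
#' @param voxel_size_mm Isotropic voxel size in millimetres.
#' @param mask Logical 3D array; defaults to the object's mask.
#' @return Same type as `x`.
#' @export
smooth_volume <- function(x, fwhm, voxel_size_mm = 1, mask = NULL) {
  mt_validate(fwhm >= 0, "`fwhm` must be non-negative")
  if (fwhm == 0) return(x)
  if (inherits(x, "bold_run")) {
    m <- mask %||% x$mask
    sm <- smooth_matrix(x$data, x$dim, fwhm / voxel_size_mm, m)
    out <- x
    out$data <- sm
    return(out)
  }
  if (inherits(x, "stat_map")) {
    m <- mask %||% attr(x, "mask")
    v <- as.numeric(x)
    v[is.na(v)] <- 0
    sm <- smooth_matrix(matrix(v, 1), dim(x), fwhm / voxel_size_mm, m)
    return(stat_map(as.numeric(sm), dim(x), attr(x, "kind"), m,
                    c(attr(x, "info"), list(fwhm_mm = fwhm))))
  }
  mt_validate(is.array(x) && length(dim(x)) == 3L,
              "`x` must be a bold_run, stat_map or 3D array")
  m <- mask %||% array(TRUE, dim(x))
  array(smooth_matrix(matrix(as.numeric(x), 1), dim(x),
                      fwhm / voxel_size_mm, m),
        dim(x))
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# banded 1D smoothing operator (n x n), truncated at the edges (renormalised
# later against the mask image)
smooth_operator <- function(n, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    S[i, j] <- k[j - i + r + 1L]
  }
  S
}

# smooth every row of a scans x voxels matrix over the 3D grid.
# numerator = smoothed (data * mask), denominator = smoothed mask.
smooth_matrix <- function(M, dim, fwhm_vox, mask) {
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  S <- lapply(dim, smooth_operator, sigma = sigma)
  mvec <- as.numeric(mask)
  M0 <- sweep(M, 2, mvec, "*")
  M0[is.na(M0)] <- 0
  num <- apply_separable(M0, dim, S)
  den <- drop(apply_separable(matrix(mvec, 1), dim, S))
  out <- sweep(num, 2, pmax(den, .Machine$double.eps), "/")
  out[, !as.logical(mvec)] <- NA_real_
  out
}

# apply per-axis operators to all rows at once via reshaped matrix products
apply_separable <- function(M, dim, S) {
  n_t <- nrow(M)
  A <- array(t(M), c(dim, n_t))
  # axis 1
  A <- array(S[[1]] %*% matrix(A, dim[1]), c(dim, n_t))
  # axis 2
  A <- aperm(A, c(2, 1, 3, 4))
  A <- array(S[[2]] %*% matrix(A, dim[2]), c(dim[2], dim[1], dim[3], n_t))
  A <- aperm(A, c(2, 1, 3, 4))
  # axis 3
  A <- aperm(A, c(3, 1, 2, 4))
  A <- array(S[[3]] %*% matrix(A, dim[3]), c(dim[3], dim[1], dim[2], n_t))
  A <- aperm(A, c(2, 3, 1, 4))
  t(matrix(A, prod(dim), n_t))
}
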