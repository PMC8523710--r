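#' BOLD run container
#'
#' A `bold_run` stores one run's scan-by-voxel time series as a
#' `scans x voxels` matrix over a regular 3D grid, together with the grid
#' dimensions, repetition time and an analysis mask.
#'
#' @param data `scans x voxels` numeric matrix (`voxels = prod(dim)`), or a
#'   4D array `(x, y, z, scans)`.
#' @param dim Integer triple of grid dimensions (taken from the array if 4D).
#' @param tr Repetition time, seconds.
#' @param mask Logical 3D array (default: all voxels).
#' @param run,phase Optional provenance labels.
#' @return Object of class `bold_run`.
#' @export
bold_run <- function(data, dim = NULL, tr, mask = NULL, run = NA_integer_,
                     phase = NA_character_) {
  if (is.array(data) && length(base::dim(data)) == 4L) {
    dim <- base::dim(data)[1:3]
    data <- t(matrix(data, prod(dim), base::dim(data)[4]))
  }
  mt_validate(is.matrix(data), "`data` must be a scans x voxels matrix or 4D array")
  mt_validate(!is.null(dim) && length(dim) == 3L, "`dim` must be a voxel triple")
  mt_validate(ncol(data) == prod(dim), "`ncol(data)` must equal `prod(dim)`")
  mt_validate(tr > 0, "`tr` must be positive")
  if (is.null(mask)) mask <- array(TRUE, dim)
  mt_validate(all(base::dim(mask) == dim), "mask and grid dimensions differ")
  structure(list(data = data, dim = as.integer(dim), tr = tr, mask = mask,
                 run = run, phase = phase), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d scans, grid %s, TR %.3g s (%s run %s)\n",
              nrow(x$data), paste(x$dim, collapse = "x"), x$tr,
              x$phase, x$run))
  invisible(x)
}

#' @rdname bold_run
#' @param x A `bold_run`.
#' @export
as.array.bold_run <- function(x, ...) {
  array(t(x$data), c(x$dim, nrow(x$data)))
}

# stack a list of bold_runs into one matrix, checking geometry agreement
bind_bold <- function(bold) {
  if (inherits(bold, "bold_run")) bold <- list(bold)
  mt_validate(all(vapply(bold, inherits, TRUE, "bold_run")),
              "`bold` must be a bold_run or list of bold_runs")
  d1 <- bold[[1]]$dim
  tr <- bold[[1]]$tr
  mt_validate(all(vapply(bold, function(b) all(b$dim == d1) && b$tr == tr, TRUE)),
              "all runs must share grid dimensions and TR")
  list(data = do.call(rbind, lapply(bold, `[[`, "data")),
       dim = d1, tr = tr, mask = bold[[1]]$mask,
       scans = vapply(bold, function(b) nrow(b$data), integer(1)))
}

#' Per-voxel statistic map on a 3D grid
#'
#' @param values Numeric vector over the full grid (or 3D array). Values
#'   outside the mask are set to `NA`.
#' @param dim Grid dimensions.
#' @param kind One of `"beta"`, `"t"`, `"F"`, `"fisher_z"`.
#' @param mask Logical 3D array.
#' @param info Optional provenance (contrast weights, similarity variant, ...).
#' @return Object of class `stat_map`: a 3D array with attributes.
#' @export
stat_map <- function(values, dim, kind, mask = NULL, info = list()) {
  if (is.array(values) && length(base::dim(values)) == 3L) {
    dim <- base::dim(values)
    values <- as.numeric(values)
  }
  mt_validate(length(values) == prod(dim), "value length must match grid")
  if (is.null(mask)) mask <- array(TRUE, dim)
  values[!mask] <- NA_real_
  structure(array(values, dim), class = "stat_map", kind = kind,
            mask = mask, info = info)
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x[attr(x, "mask")]
  cat(sprintf("<stat_map kind=%s> grid %s, %d in-mask voxels, range [%.3g, %.3g]\n",
              attr(x, "kind"), paste(dim(x), collapse = "x"), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

map_values <- function(map, mask = NULL) {
  v <- as.numeric(map)
  if (!is.null(mask)) v[as.logical(mask)] else v
}
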