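#' First eigenvariate of an ROI time course
#'
#' Returns the leading left singular vector of the column-centred
#' `scans x roi-voxels` matrix -- the dominant shared time course of the
#' region. The sign is fixed so the mean correlation with the ROI's voxel
#' series is positive, and the series is standardised to unit variance.
#'
#' @param bold A [bold_run()] or list of runs (concatenated).
#' @param roi Logical 3D array with at least 2 voxels.
#' @param roi_label Optional label carried into the result.
#' @return Object of class `seed_series`: list with `series`,
#'   `explained_variance`, `n_voxels`, `roi_label`.
#' @export
first_eigenvariate <- function(bold, roi, roi_label = NA_character_) {
  bb <- bind_bold(bold)
  vx <- which(as.logical(roi))
  mt_validate(length(vx) >= 2, "ROI must contain at least 2 voxels")
  Y <- bb$data[, vx, drop = FALSE]
  Y <- sweep(Y, 2, colMeans(Y))
  if (all(abs(Y) < 1e-12)) {
    mt_stop("constant ROI data: eigenvariate undefined",
            class = "memtrace_degenerate_error")
  }
  sv <- svd(Y, nu = 1, nv = 1)
  e <- sv$u[, 1]
  if (mean(crossprod(Y, e)) < 0) e <- -e
  e <- e / sd(e)
  structure(list(series = e,
                 explained_variance = sv$d[1]^2 / sum(sv$d^2),
                 n_voxels = length(vx), roi_label = roi_label,
                 scans = bb$scans, tr = bb$tr),
            class = "seed_series")
}

#' @export
print.seed_series <- function(x, ...) {
  cat(sprintf("<seed_series %s> %d scans, %d voxels, %.1f%% variance explained\n",
              x$roi_label, length(x$series), x$n_voxels,
              100 * x$explained_variance))
  invisible(x)
}

#' Build a psychophysiological-interaction design
#'
#' Columns are the seed time course, the psychological regressor (the
#' context-coded event train, old = +1 / new = -1 by default, convolved with
#' the canonical HRF) and their element-by-element product -- the PPI term --
#' followed by per-run drift and constant columns.
#'
#' @param seed A [first_eigenvariate()] result (or numeric vector of scan
#'   length).
#' @param events Recognition-phase event table.
#' @param n_scans Named scans-per-run vector (defaults to the events
#'   attribute).
#' @param tr Repetition time, seconds.
#' @param context Named numeric coding of the `oldness` column
#'   (default `c(old = 1, new = -1)`); every event's label must be covered.
#' @param hp_cutoff High-pass cutoff, seconds.
#' @return A `design_matrix` whose first three columns are `seed`, `psych`,
#'   `ppi`.
#' @export
build_ppi_design <- function(seed, events, n_scans = NULL, tr,
                             context = c(old = 1, new = -1),
                             hp_cutoff = 128) {
  if (inherits(seed, "seed_series")) seed <- seed$series
  if (is.null(n_scans)) n_scans <- attr(events, "n_scans")
  mt_validate(!is.null(n_scans), "`n_scans` required")
  mt_validate(length(seed) == sum(n_scans),
              "seed series length must equal total scan count")
  missing <- setdiff(unique(events$oldness), names(context))
  if (length(missing) > 0) {
    mt_stop(paste("no context coding for event label(s):",
                  paste(missing, collapse = ", ")),
            class = "memtrace_validation_error")
  }
  keys <- sprintf("%s:%s", events$phase, events$run)
  psych <- numeric(sum(n_scans))
  offset <- 0L
  for (rk in names(n_scans)) {
    ev <- events[keys == rk, , drop = FALSE]
    ns <- n_scans[[rk]]
    if (nrow(ev) > 0) {
      psych[offset + seq_len(ns)] <-
        convolve_events(ev$onset, ev$duration,
                        context[ev$oldness], ns, tr)
    }
    offset <- offset + ns
  }
  base <- build_design(events[0, ], n_scans = n_scans, tr = tr,
                       mode = "condition", hp_cutoff = hp_cutoff)
  X <- cbind(seed = seed, psych = psych, ppi = seed * psych, unclass(base))
  kinds <- c("task", "task", "task", attr(base, "kind"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    mt_stop(sprintf("PPI design is rank deficient; collinear columns: %s",
                    paste(bad, collapse = ", ")),
            class = "memtrace_design_error")
  }
  structure(X, class = c("design_matrix", "matrix"), kind = kinds,
            col_info = tibble::tibble(name = c("seed", "psych", "ppi"),
                                      item_id = NA_character_,
                                      phase = "recognition",
                                      run = NA_integer_,
                                      emotion = NA_character_,
                                      oldness = NA_character_),
            run_rows = attr(base, "run_rows"), tr = tr, mode = "ppi",
            hp_cutoff = hp_cutoff)
}

#' Psychophysiological-interaction map
#'
#' Fits the PPI design with [fit_glm()] and returns beta and t maps for the
#' interaction column.
#'
#' @param bold A [bold_run()] or list of runs.
#' @param design A [build_ppi_design()] matrix.
#' @param ar1 Passed to [fit_glm()].
#' @param mask Optional analysis mask.
#' @return List with `beta` and `t` [stat_map()]s for the `ppi` column, and
#'   the underlying `fit`.
#' @export
ppi_map <- function(bold, design, ar1 = "global", mask = NULL) {
  fit <- fit_glm(bold, design, ar1 = ar1, mask = mask)
  maps <- contrast_map(fit, c(ppi = 1))
  list(beta = maps$beta, t = maps$t, fit = fit)
}
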