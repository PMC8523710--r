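#' Tidy and glance methods
#'
#' Broom-style summaries: `tidy()` returns one row per estimated quantity,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name memtrace-tidiers
NULL

#' @rdname memtrace-tidiers
#' @export
tidy.glm_fit <- function(x, ...) {
  info <- attr(x$design, "col_info")
  kinds <- attr(x$design, "kind")
  nm <- colnames(x$design)
  b <- x$beta[, x$mask_idx, drop = FALSE]
  tibble::tibble(term = nm, kind = kinds,
                 mean_beta = rowMeans(b),
                 sd_beta = apply(b, 1, sd))
}

#' @rdname memtrace-tidiers
#' @export
glance.glm_fit <- function(x, ...) {
  tibble::tibble(n_scans = nrow(x$design), n_regressors = ncol(x$design),
                 n_voxels = length(x$mask_idx), dof = x$dof, rho = x$rho,
                 mean_sigma2 = mean(x$sigma2, na.rm = TRUE))
}

#' @rdname memtrace-tidiers
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname memtrace-tidiers
#' @export
tidy.ers_maps <- function(x, ...) {
  v <- function(m) as.numeric(m)[!is.na(as.numeric(m))]
  tibble::tibble(statistic = c("eos", "ens", "ers"),
                 mean = c(mean(v(x$eos)), mean(v(x$ens)), mean(v(x$ers))),
                 sd = c(sd(v(x$eos)), sd(v(x$ens)), sd(v(x$ers))),
                 n_centers = length(v(x$ers)))
}

#' @rdname memtrace-tidiers
#' @export
glance.pipeline_report <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$behavior$sdt),
                 behav_interaction_p = x$behavior$interaction$p,
                 behav_contrast = x$behavior$interaction$contrast,
                 mean_d_prime = mean(x$behavior$sdt$d_prime))
}
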