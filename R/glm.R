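#' Fit a first-level GLM with optional AR(1) prewhitening
#'
#' Ordinary least squares per voxel, optionally preceded by AR(1)
#' prewhitening: a single autocorrelation coefficient is estimated from the
#' pooled lag-1 autocorrelation of the in-mask OLS residuals (lags never cross
#' run boundaries), data and design are filtered by the AR(1) square-root
#' filter, and the model is refit on the whitened problem.
#'
#' @param bold A [bold_run()] or list of runs (concatenated in order; the
#'   design's run blocks must match).
#' @param design A [build_design()] matrix for the same scans.
#' @param ar1 `"global"` (estimate one rho from pooled residuals), `"off"`, or
#'   a fixed numeric coefficient in (-1, 1).
#' @param mask Logical 3D array restricting the fit (default: the run mask).
#' @return Object of class `glm_fit` with elements `beta`
#'   (regressors x voxels, `NA` outside mask), `sigma2`, `dof`, `rho`,
#'   `xtx_inv` (whitened), `design`, `dim`, `mask`.
#' @export
fit_glm <- function(bold, design, ar1 = c("global", "off"), mask = NULL) {
  bb <- bind_bold(bold)
  mt_validate(nrow(bb$data) == nrow(design),
              sprintf("scan count mismatch: %d scans vs %d design rows",
                      nrow(bb$data), nrow(design)))
  if (is.null(mask)) mask <- bb$mask
  mvox <- which(as.logical(mask))
  mt_validate(length(mvox) > 0, "analysis mask is empty")
  Y <- bb$data[, mvox, drop = FALSE]
  X <- unclass(design)
  for (a in c("kind", "col_info", "run_rows", "tr", "mode", "hp_cutoff")) {
    attr(X, a) <- NULL
  }

  run_rows <- attr(design, "run_rows") %||% list(seq_len(nrow(X)))

  if (is.numeric(ar1)) {
    mt_validate(abs(ar1) < 1, "fixed AR(1) coefficient must lie in (-1, 1)")
    rho <- ar1
  } else {
    ar1 <- match.arg(ar1)
    rho <- 0
  }

  ols <- qr_fit(X, Y)
  if (identical(ar1, "global")) {
    rho <- pooled_ar1(ols$resid, run_rows)
  }
  if (rho != 0) {
    Xw <- ar1_whiten(X, rho, run_rows)
    Yw <- ar1_whiten(Y, rho, run_rows)
    fit <- qr_fit(Xw, Yw)
  } else {
    Xw <- X
    fit <- ols
  }
  dof <- nrow(X) - fit$rank
  mt_validate(dof > 0, "no residual degrees of freedom")
  sigma2 <- colSums(fit$resid^2) / dof

  p <- ncol(X)
  beta <- matrix(NA_real_, p, prod(bb$dim))
  beta[, mvox] <- fit$beta
  rownames(beta) <- colnames(design)
  s2 <- rep(NA_real_, prod(bb$dim))
  s2[mvox] <- sigma2
  structure(list(beta = beta, sigma2 = s2, dof = dof, rho = rho,
                 xtx_inv = fit$xtx_inv,
                 design = design, dim = bb$dim, mask = mask,
                 mask_idx = mvox),
            class = "glm_fit")
}

qr_fit <- function(X, Y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    mt_stop(sprintf("singular (whitened) design; collinear columns: %s",
                    paste(bad, collapse = ", ")),
            class = "memtrace_design_error")
  }
  beta <- qr.coef(qrX, Y)
  fitted <- X %*% beta
  unpivot <- order(qrX$pivot)
  xtx_inv <- chol2inv(qr.R(qrX))[unpivot, unpivot, drop = FALSE]
  list(beta = beta, resid = Y - fitted, qr = qrX, rank = qrX$rank,
       xtx_inv = xtx_inv)
}

# pooled lag-1 autocorrelation of residuals, within-run lags only
pooled_ar1 <- function(resid, run_rows) {
  num <- 0
  den <- sum(resid^2)
  if (den < 1e-12) return(0)
  for (rows in run_rows) {
    r <- resid[rows, , drop = FALSE]
    num <- num + sum(r[-1, , drop = FALSE] * r[-nrow(r), , drop = FALSE])
  }
  rho <- num / den
  max(min(rho, 0.97), -0.97)
}

# AR(1) square-root (Cochrane-Orcutt/Prais-Winsten) filter per run block
ar1_whiten <- function(M, rho, run_rows) {
  out <- M
  for (rows in run_rows) {
    B <- M[rows, , drop = FALSE]
    W <- B
    W[1, ] <- sqrt(1 - rho^2) * B[1, ]
    if (nrow(B) > 1) {
      W[-1, ] <- B[-1, , drop = FALSE] - rho * B[-nrow(B), , drop = FALSE]
    }
    out[rows, ] <- W
  }
  out
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d regressors x %d voxels, dof=%d, rho=%.3f\n",
              nrow(x$beta), length(x$mask_idx), x$dof, x$rho))
  invisible(x)
}

#' Contrast and t-statistic maps from a GLM fit
#'
#' Computes `c = w' beta` per voxel and the corresponding t-statistic
#' `t = c / sqrt(sigma2 * w' (X'X)^-1 w)` with the whitened design.
#'
#' @param fit A [fit_glm()] result.
#' @param weights Numeric contrast vector, either of length `ncol(design)` or
#'   a named vector over a subset of column names (others zero).
#' @return List with elements `beta` and `t`, both [stat_map()]s.
#' @export
contrast_map <- function(fit, weights) {
  X <- fit$design
  w <- expand_weights(weights, colnames(X))
  mt_validate(any(w != 0), "all-zero contrast weights")
  kinds <- attr(X, "kind")
  if (any(w != 0 & kinds != "task")) {
    warning("contrast weights touch drift/constant columns", call. = FALSE)
  }
  cvec <- drop(crossprod(w, fit$beta))
  se <- sqrt(fit$sigma2 * drop(crossprod(w, fit$xtx_inv %*% w)))
  tvec <- cvec / se
  list(beta = stat_map(cvec, fit$dim, "beta", fit$mask, list(weights = w)),
       t = stat_map(tvec, fit$dim, "t", fit$mask,
                    list(weights = w, dof = fit$dof)))
}

expand_weights <- function(weights, cols) {
  if (!is.null(names(weights)) && any(nzchar(names(weights)))) {
    missing <- setdiff(names(weights), cols)
    mt_validate(length(missing) == 0,
                paste("unknown contrast columns:", paste(missing, collapse = ", ")))
    w <- setNames(numeric(length(cols)), cols)
    w[names(weights)] <- weights
  } else {
    mt_validate(length(weights) == length(cols),
                "contrast weight length must match regressor count")
    w <- as.numeric(weights)
  }
  w
}

#' Trialwise t-statistic activation patterns
#'
#' Converts the trial betas of a trialwise GLM into t-statistics
#' (`t = beta / SE(beta)`), the noise-normalised patterns used by the
#' similarity analysis. Rows are keyed by item, phase and run.
#'
#' @param fit A [fit_glm()] result for a `trialwise` design.
#' @param phase Optional phase filter (`"encoding"` / `"recognition"`).
#' @param runs Optional run filter (e.g. the final encoding run).
#' @return A `pattern_matrix`: trials x voxels matrix (`NA` outside mask)
#'   with attribute `info` (tibble: `item_id`, `phase`, `run`, `emotion`,
#'   `oldness`).
#' @export
trial_patterns <- function(fit, phase = NULL, runs = NULL) {
  X <- fit$design
  mt_validate(identical(attr(X, "mode"), "trialwise"),
              "`fit` must come from a trialwise design")
  info <- attr(X, "col_info")
  keep <- rep(TRUE, nrow(info))
  if (!is.null(phase)) keep <- keep & info$phase %in% phase
  if (!is.null(runs)) keep <- keep & info$run %in% runs
  info <- info[keep, , drop = FALSE]
  mt_validate(nrow(info) > 0, "no trials match the requested phase/run")
  cols <- match(info$name, colnames(X))
  dvar <- diag(fit$xtx_inv)[cols]
  beta <- fit$beta[cols, , drop = FALSE]
  se <- sqrt(outer(dvar, fit$sigma2))
  pat <- beta / se
  structure(pat, class = c("pattern_matrix", "matrix"), info = info,
            dim3 = fit$dim, mask = fit$mask)
}

#' @export
print.pattern_matrix <- function(x, ...) {
  info <- attr(x, "info")
  cat(sprintf("<pattern_matrix> %d trials x %d voxels (%s)\n",
              nrow(x), ncol(x),
              paste(unique(info$phase), collapse = "+")))
  invisible(x)
}
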