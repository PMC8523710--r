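#' Canonical double-gamma haemodynamic response function
#'
#' The canonical HRF is the difference of two gamma densities: a response
#' component peaking near 5 s (shape 6, scale 1) minus an undershoot
#' component (shape 16, scale 1) weighted 1/6. The kernel is sampled on a
#' regular grid and normalised to unit peak.
#'
#' @param tr Sampling interval in seconds (> 0).
#' @param length Kernel support in seconds (default 32).
#' @return Numeric vector of kernel values at `seq(0, length, by = tr)`.
#' @examples
#' h <- canonical_hrf(0.1)
#' seq(0, 32, by = 0.1)[which.max(h)]  # peak close to 5 s
#' @export
canonical_hrf <- function(tr, length = 32) {
  mt_validate(is.numeric(tr) && tr > 0, "`tr` must be positive")
  mt_validate(length >= tr, "`length` must be at least one sample (`tr`)")
  t <- seq(0, length, by = tr)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# BOLD response curve of a single boxcar event: causal convolution of a
# unit boxcar of `duration` seconds with the canonical HRF, on a fine grid.
# Returned as a lookup function of time-since-onset.
event_response_curve <- function(duration, dt, hrf_length = 32) {
  h <- canonical_hrf(dt, hrf_length)
  nb <- max(1L, round(duration / dt))
  u <- rep(1, nb)
  pad <- length(h) - 1L
  y <- stats::filter(c(numeric(pad), u, numeric(pad)), h,
                     method = "convolution", sides = 1)
  y <- as.numeric(y[(pad + 1L):(pad + nb + pad)]) * dt
  y[is.na(y)] <- 0
  list(values = y, dt = dt, support = length(y) * dt)
}

# scans x events matrix of unit-amplitude HRF-convolved responses.
# All events sharing one duration reuse a single response curve (fast path).
event_regressor_matrix <- function(onsets, durations, n_scans, tr) {
  mt_validate(all(onsets >= 0), "event onsets must be non-negative")
  mt_validate(all(onsets + durations <= n_scans * tr),
              "event beyond scan window")
  dt <- tr / 16
  frames <- (seq_len(n_scans) - 1L) * tr
  out <- matrix(0, n_scans, length(onsets))
  curves <- list()
  for (i in seq_along(onsets)) {
    key <- sprintf("%.6f", durations[i])
    if (is.null(curves[[key]])) {
      curves[[key]] <- event_response_curve(durations[i], dt)
    }
    cv <- curves[[key]]
    rel <- frames - onsets[i]
    sel <- rel >= 0 & rel < cv$support
    idx <- floor(rel[sel] / dt) + 1L
    out[sel, i] <- cv$values[idx]
  }
  out
}

# single regressor: amplitude-weighted sum of event responses
convolve_events <- function(onsets, durations, amplitudes, n_scans, tr) {
  if (length(onsets) == 0L) return(numeric(n_scans))
  drop(event_regressor_matrix(onsets, durations, n_scans, tr) %*% amplitudes)
}
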