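#' Simulate item activation patterns with planted reinstatement strength
#'
#' Draws, per ROI, a unit-norm Gaussian voxel pattern for every item at
#' encoding and constructs the recognition-phase pattern of an old item as
#' `r * encoding + sqrt(1 - r^2) * independent`, which has expected Pearson
#' correlation `r` with the encoding pattern. New items receive independent
#' patterns. Optional independent pattern noise is added afterwards.
#'
#' @param spec A [cohort_spec()].
#' @param effects An [effect_spec()].
#' @param rois Named list of logical ROI masks (see [roi_layout()]).
#' @param drug,delay Group cell of the subject.
#' @param seed Integer seed.
#' @return List per ROI: `enc`, `rec_old` (rows = old items), `rec_new`
#'   (rows = new items), each `items x roi-voxels`, plus `r` planted.
#' @export
sim_patterns <- function(spec, effects, rois, drug, delay, seed) {
  withr::with_seed(seed, {
    out <- lapply(names(rois), function(rn) {
      v <- sum(rois[[rn]])
      r_cell <- effect_lookup(effects$ers, drug, delay, roi = rn)$r
      if (effects$subject_sd_z > 0) {
        r_cell <- tanh(atanh(r_cell) + rnorm(1, 0, effects$subject_sd_z))
      }
      unit <- function(n) {
        m <- matrix(rnorm(n * v), n, v)
        m / sqrt(rowSums(m^2))
      }
      enc <- unit(spec$n_items_old)
      fresh <- unit(spec$n_items_old)
      rec_old <- r_cell * enc + sqrt(1 - r_cell^2) * fresh
      rec_new <- unit(spec$n_items_new)
      addnoise <- function(m) {
        if (effects$pattern_noise_sd > 0) {
          m + matrix(rnorm(length(m), 0, effects$pattern_noise_sd),
                     nrow(m), ncol(m))
        } else m
      }
      list(enc = addnoise(enc), rec_old = addnoise(rec_old),
           rec_new = addnoise(rec_new), r = r_cell)
    })
    names(out) <- names(rois)
    out
  })
}

#' Simulate a subject's BOLD runs from the forward model
#'
#' The signal in each voxel is the sum over trials of the item's pattern
#' weight (plus a uniform ROI amplitude) times the HRF-convolved event
#' boxcar. On top of the signal the generator adds two slow cosine drift
#' components per run (periods above the 128-s high-pass cutoff, per-voxel
#' random amplitude) and AR(1) Gaussian scan noise. During recognition runs a
#' seed fluctuation `s(t)` drives the PPI seed ROI, and the target ROI
#' receives `gain * s(t)` gated by the HRF-convolved old-trial train --
#' the planted context-dependent coupling.
#'
#' @param events Event table for the subject (both phases, see [sim_events()]).
#' @param spec,effects,rois As in [sim_patterns()].
#' @param drug,delay Group cell.
#' @param seed Integer seed.
#' @param ppi_seed_roi,ppi_target_roi ROI names for the planted coupling
#'   (defaults `"ifg"` -> `"hippocampus"`); `NULL` disables it.
#' @return List with `runs` (list of [bold_run()]s, encoding then
#'   recognition), and `truth` (planted parameters: per-ROI pattern sets and
#'   correlations, amplitudes, gain, noise settings, seed series).
#' @export
sim_subject_bold <- function(events, spec, effects, rois, drug, delay, seed,
                             ppi_seed_roi = "ifg",
                             ppi_target_roi = "hippocampus") {
  patterns <- sim_patterns(spec, effects, rois, drug, delay,
                           derive_seed(seed, 1))
  items <- item_table(spec)
  V <- prod(spec$grid_shape)
  ns <- run_scans(events)
  gain <- effect_lookup(effects$ppi, drug, delay)$gain
  roi_idx <- lapply(rois, function(m) which(as.logical(m)))

  amp_jitter <- withr::with_seed(derive_seed(seed, 2), {
    rnorm(length(rois), 0, effects$subject_sd_amp)
  })
  names(amp_jitter) <- names(rois)

  runs <- list()
  seed_series <- list()
  keys <- sprintf("%s:%s", events$phase, events$run)
  for (rk in names(ns)) {
    ev <- events[keys == rk, , drop = FALSE]
    n_scan <- ns[[rk]]
    phase <- ev$phase[1]
    R <- event_regressor_matrix(ev$onset, ev$duration, n_scan, spec$tr)
    W <- matrix(0, nrow(ev), V)
    for (rn in names(rois)) {
      vx <- roi_idx[[rn]]
      uv <- effect_lookup(effects$univariate, drug, delay, roi = rn)
      for (ti in seq_len(nrow(ev))) {
        it <- ev$item_id[ti]
        row_old <- match(it, items$item_id[items$oldness == "old"])
        row_new <- match(it, items$item_id[items$oldness == "new"])
        if (phase == "encoding") {
          amp <- effects$amp_encoding + amp_jitter[[rn]]
          pat <- patterns[[rn]]$enc[row_old, ]
        } else if (!is.na(row_old)) {
          amp <- uv$amp_old + amp_jitter[[rn]]
          pat <- patterns[[rn]]$rec_old[row_old, ]
        } else {
          amp <- uv$amp_new + amp_jitter[[rn]]
          pat <- patterns[[rn]]$rec_new[row_new, ]
        }
        W[ti, vx] <- W[ti, vx] + amp + effects$pattern_scale * pat
      }
    }
    sig <- R %*% W

    run_seed <- derive_seed(seed, 10 + match(rk, names(ns)))
    withr::with_seed(run_seed, {
      # PPI: seed fluctuation drives the seed ROI; context-gated copy in target
      if (phase == "recognition" && !is.null(ppi_seed_roi)) {
        s_t <- ar1_noise(n_scan, 1, effects$seed_ar1, effects$seed_sd)
        old_sel <- ev$oldness == "old"
        psych_old <- convolve_events(ev$onset[old_sel], ev$duration[old_sel],
                                     rep(1, sum(old_sel)), n_scan, spec$tr)
        sig[, roi_idx[[ppi_seed_roi]]] <-
          sig[, roi_idx[[ppi_seed_roi]], drop = FALSE] + drop(s_t)
        sig[, roi_idx[[ppi_target_roi]]] <-
          sig[, roi_idx[[ppi_target_roi]], drop = FALSE] +
          effects$ppi_baseline * drop(s_t) +
          gain * drop(s_t) * psych_old
        seed_series[[rk]] <- drop(s_t)
      }
      drift <- sim_drift(n_scan, V, effects$drift_sd, spec$tr)
      noise <- ar1_noise(n_scan, V, effects$ar1, effects$noise_sd)
    })
    runs[[rk]] <- bold_run(sig + drift + noise, spec$grid_shape, spec$tr,
                           run = ev$run[1], phase = phase)
  }
  truth <- list(drug = drug, delay = delay, patterns = patterns,
                gain = gain, amp_jitter = amp_jitter,
                noise = list(ar1 = effects$ar1, noise_sd = effects$noise_sd,
                             drift_sd = effects$drift_sd),
                seed_series = seed_series)
  list(runs = runs, truth = truth)
}

# AR(1) noise with marginal SD `sd_target`, independent across columns
ar1_noise <- function(n, p, rho, sd_target) {
  if (sd_target == 0) return(matrix(0, n, p))
  innov_sd <- sd_target * sqrt(1 - rho^2)
  e <- matrix(rnorm(n * p, 0, innov_sd), n, p)
  if (rho != 0) {
    for (t in 2:n) e[t, ] <- e[t, ] + rho * e[t - 1, ]
  }
  e
}

# up to two slow cosine components with per-voxel random amplitudes, drawn
# from the discrete-cosine components below the high-pass cutoff so the
# planted drift always lies in the filter's stop band
sim_drift <- function(n, p, drift_sd, tr, cutoff = 128) {
  k_max <- min(2L, floor(2 * n * tr / cutoff))
  if (drift_sd == 0 || k_max < 1) return(matrix(0, n, p))
  t <- seq_len(n) - 0.5
  basis <- vapply(seq_len(k_max), function(k) cos(pi * k * t / n),
                  numeric(n))
  amps <- matrix(rnorm(k_max * p, 0, drift_sd), k_max, p)
  basis %*% amps
}
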