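#' Define the design of a synthetic recognition-memory cohort
#'
#' A cohort specification fixes the experimental design that the simulator
#' reproduces: a fully crossed between-subjects drug (placebo vs. yohimbine)
#' by delay (1 vs. 28 days) design, encoding of old pictures repeated once per
#' encoding run, and a delayed recognition test mixing old with emotion-matched
#' new pictures, all acquired on a small regular voxel grid.
#'
#' Defaults mirror the study design the simulator emulates: 26 subjects per
#' cell, 60 old items (half negative, half neutral) shown once in each of
#' three encoding runs, 60 matched new items, 3-s picture events with a
#' jittered 4 +/- 1 s fixation interval, and a repetition time of 2 s.
#'
#' @param n_per_group Subjects per drug x delay cell.
#' @param grid_shape Integer triple, voxel grid dimensions.
#' @param tr Repetition time in seconds.
#' @param n_items_old,n_items_new Number of old/new items; must be equal and
#'   even (half "negative", half "neutral").
#' @param n_encoding_runs,n_recognition_runs Run counts per phase.
#' @param event_duration Picture duration in seconds.
#' @param iti_base,iti_jitter Mean and half-range of the uniform
#'   inter-trial interval, seconds.
#' @param voxel_size_mm Isotropic voxel size in millimetres (used by
#'   smoothing).
#' @param roi_size Edge length (voxels) of the cubic regions of interest laid
#'   out by [roi_layout()].
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_per_group = 2, grid_shape = c(12, 12, 12))
#' spec$n_items_old
#' @export
cohort_spec <- function(n_per_group = 26,
                        grid_shape = c(24, 24, 24),
                        tr = 2.0,
                        n_items_old = 60,
                        n_items_new = n_items_old,
                        n_encoding_runs = 3,
                        n_recognition_runs = 3,
                        event_duration = 3.0,
                        iti_base = 4.0,
                        iti_jitter = 1.0,
                        voxel_size_mm = 3,
                        roi_size = 4) {
  mt_validate(is_count(n_per_group), "`n_per_group` must be a positive integer")
  mt_validate(length(grid_shape) == 3 && all(vapply(grid_shape, is_count, TRUE)),
              "`grid_shape` must be a triple of positive integers")
  mt_validate(is_count(n_items_old) && n_items_old %% 2 == 0,
              "`n_items_old` must be a positive even integer")
  mt_validate(n_items_new == n_items_old,
              "`n_items_new` must equal `n_items_old` (pairwise matching)")
  mt_validate(is_count(n_encoding_runs) && is_count(n_recognition_runs),
              "run counts must be positive integers")
  mt_validate(tr > 0 && event_duration > 0 && iti_base > 0,
              "all durations must be positive")
  mt_validate(iti_jitter >= 0 && iti_jitter < iti_base,
              "`iti_jitter` must be non-negative and smaller than `iti_base`")
  structure(list(
    n_per_group = as.integer(n_per_group),
    grid_shape = as.integer(grid_shape),
    tr = tr,
    n_items_old = as.integer(n_items_old),
    n_items_new = as.integer(n_items_new),
    n_encoding_runs = as.integer(n_encoding_runs),
    n_recognition_runs = as.integer(n_recognition_runs),
    event_duration = event_duration,
    iti_base = iti_base,
    iti_jitter = iti_jitter,
    voxel_size_mm = voxel_size_mm,
    roi_size = as.integer(roi_size)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d subjects/cell (4 cells), grid %s, TR %.3g s\n",
              x$n_per_group, paste(x$grid_shape, collapse = "x"), x$tr))
  cat(sprintf("  %d old + %d new items, %d encoding + %d recognition runs\n",
              x$n_items_old, x$n_items_new, x$n_encoding_runs,
              x$n_recognition_runs))
  cat(sprintf("  events %.3g s, ITI %.3g +/- %.3g s\n",
              x$event_duration, x$iti_base, x$iti_jitter))
  invisible(x)
}

#' Item catalogue and old/new pairing for a cohort
#'
#' Old items are split half/half into negative and neutral emotion classes and
#' each old item is paired with exactly one new item of the same emotion
#' (matching is a design input of the similarity analysis, not computed from
#' stimulus content).
#'
#' @param spec A [cohort_spec()].
#' @return `item_table()`: a tibble with `item_id`, `oldness`, `emotion`,
#'   `pair`; `item_pairing()`: a tibble with `old_item`, `new_item`, `emotion`.
#' @export
item_table <- function(spec) {
  half <- spec$n_items_old / 2L
  emo <- rep(c("negative", "neutral"), each = half)
  old <- tibble::tibble(
    item_id = sprintf("old%03d", seq_len(spec$n_items_old)),
    oldness = "old", emotion = emo, pair = seq_len(spec$n_items_old))
  new <- tibble::tibble(
    item_id = sprintf("new%03d", seq_len(spec$n_items_new)),
    oldness = "new", emotion = emo, pair = seq_len(spec$n_items_new))
  dplyr::bind_rows(old, new)
}

#' @rdname item_table
#' @export
item_pairing <- function(spec) {
  it <- item_table(spec)
  old <- it[it$oldness == "old", ]
  new <- it[it$oldness == "new", ]
  tibble::tibble(old_item = old$item_id,
                 new_item = new$item_id[match(old$pair, new$pair)],
                 emotion = old$emotion)
}

#' Subject-to-group assignment table
#'
#' Builds the balanced 2x2 between-subjects allocation (drug: PLAC/YOH, delay:
#' 1d/28d) with sex balanced within each cell (13 men and 13 women per cell at
#' the default cell size of 26).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `subject`, `drug`, `delay`, `sex`.
#' @export
group_table <- function(spec) {
  cells <- expand.grid(drug = c("PLAC", "YOH"), delay = c("1d", "28d"),
                       stringsAsFactors = FALSE)
  n <- spec$n_per_group
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sex <- rep(c("f", "m"), length.out = n)
    data.frame(drug = cells$drug[i], delay = cells$delay[i], sex = sex,
               stringsAsFactors = FALSE)
  }))
  out$subject <- sprintf("sub-%03d", seq_len(nrow(out)))
  tibble::as_tibble(out[, c("subject", "drug", "delay", "sex")])
}

#' Lay out disjoint cubic ROI masks on the simulation grid
#'
#' Places up to three cubic regions of interest -- a hippocampus-like target
#' region, an IFG-like neocortical region (also the PPI seed), and a null
#' control region -- in disjoint octants of the grid, leaving room for a
#' 3-voxel searchlight around each.
#'
#' @param spec A [cohort_spec()].
#' @return Named list of logical 3D arrays (`hippocampus`, `ifg`, `control`).
#' @export
roi_layout <- function(spec) {
  dm <- spec$grid_shape
  sz <- spec$roi_size
  mt_validate(all(dm >= 2 * sz + 4),
              "grid too small for the requested ROI layout")
  cube <- function(origin) {
    m <- array(FALSE, dm)
    m[origin[1] + seq_len(sz) - 1L,
      origin[2] + seq_len(sz) - 1L,
      origin[3] + seq_len(sz) - 1L] <- TRUE
    m
  }
  lo <- pmax(2L, floor(dm / 5))
  hi <- dm - sz - lo + 1L
  list(hippocampus = cube(c(lo[1], lo[2], lo[3])),
       ifg = cube(c(hi[1], hi[2], lo[3])),
       control = cube(c(lo[1], hi[2], hi[3])))
}

#' Planted effect structure for a synthetic cohort
#'
#' An effect specification defines every quantity the simulator plants:
#' per-ROI, per-cell univariate amplitudes, encoding-to-recognition pattern
#' correlations (the reinstatement strength the similarity analysis should
#' recover), PPI coupling gains, behavioural signal-detection parameters, and
#' the noise model (AR(1) coefficient, drift, scan noise).
#'
#' Defaults encode the qualitative consolidation-reversal structure under
#' study: in the hippocampus-like ROI, old-item responses and
#' encoding-retrieval pattern similarity *decrease* from 1d to 28d under
#' placebo but *increase* under yohimbine; the IFG-like ROI shows the mirrored
#' pattern; the control ROI carries no group effect. Behavioural cell d-prime
#' values (3.15/3.15/1.71/2.35) reproduce a grand-mean d' of 2.59, a 1d-to-28d
#' decline of 1.12 and a drug x delay contrast of 0.64, with a decision
#' criterion of 0.35 giving roughly 85% hits and 4% false alarms.
#'
#' @param univariate Tibble `roi, drug, delay, amp_old, amp_new` (arbitrary
#'   BOLD amplitude units) for the recognition phase.
#' @param ers Tibble `roi, drug, delay, r`: target Pearson correlation between
#'   an item's encoding and recognition pattern inside the ROI.
#' @param ppi Tibble `drug, delay, gain`: multiplier on the seed-derived
#'   signal routed into the target ROI during old trials.
#' @param behavior Tibble `drug, delay, emotion, d_prime, criterion`.
#' @param amp_encoding Uniform ROI response amplitude during encoding trials.
#' @param pattern_scale Multiplier on the unit-norm item patterns.
#' @param pattern_noise_sd SD of independent noise added to each emitted
#'   pattern (0 = patterns carry exactly the planted correlation).
#' @param noise_sd Marginal SD of the AR(1) scan noise.
#' @param ar1 AR(1) coefficient of the scan noise, in (-1, 1).
#' @param drift_sd Per-voxel SD of the two slow cosine drift components.
#' @param subject_sd_dprime Between-subject SD of the latent d-prime.
#' @param subject_sd_criterion Between-subject SD of the decision criterion.
#' @param subject_sd_z Between-subject SD (Fisher-z scale) of the planted
#'   reinstatement correlation.
#' @param subject_sd_amp Between-subject SD of univariate amplitudes.
#' @param confidence_offset Distance of the two confidence criteria from the
#'   decision criterion, evidence units.
#' @param seed_ar1,seed_sd AR(1) coefficient and SD of the PPI seed
#'   fluctuation.
#' @param ppi_baseline Context-independent seed-to-target coupling.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(univariate = default_univariate(),
                        ers = default_ers(),
                        ppi = default_ppi(),
                        behavior = default_behavior(),
                        amp_encoding = 0.5,
                        pattern_scale = 3,
                        pattern_noise_sd = 0,
                        noise_sd = 0.3,
                        ar1 = 0.3,
                        drift_sd = 0.5,
                        subject_sd_dprime = 0.35,
                        subject_sd_criterion = 0.1,
                        subject_sd_z = 0.1,
                        subject_sd_amp = 0.1,
                        confidence_offset = 0.5,
                        seed_ar1 = 0.85,
                        seed_sd = 1,
                        ppi_baseline = 0.3) {
  mt_validate(all(abs(ers$r) < 1), "planted pattern correlations must lie in (-1, 1)")
  mt_validate(abs(ar1) < 1, "AR(1) coefficient must lie in (-1, 1)")
  mt_validate(all(is.finite(behavior$d_prime)), "cell d-prime values must be finite")
  mt_validate(noise_sd >= 0 && drift_sd >= 0 && pattern_noise_sd >= 0,
              "noise SDs must be non-negative")
  structure(list(
    univariate = tibble::as_tibble(univariate),
    ers = tibble::as_tibble(ers),
    ppi = tibble::as_tibble(ppi),
    behavior = tibble::as_tibble(behavior),
    amp_encoding = amp_encoding,
    pattern_scale = pattern_scale,
    pattern_noise_sd = pattern_noise_sd,
    noise_sd = noise_sd,
    ar1 = ar1,
    drift_sd = drift_sd,
    subject_sd_dprime = subject_sd_dprime,
    subject_sd_criterion = subject_sd_criterion,
    subject_sd_z = subject_sd_z,
    subject_sd_amp = subject_sd_amp,
    confidence_offset = confidence_offset,
    seed_ar1 = seed_ar1,
    seed_sd = seed_sd,
    ppi_baseline = ppi_baseline
  ), class = "effect_spec")
}

cell_grid <- function() {
  expand.grid(drug = c("PLAC", "YOH"), delay = c("1d", "28d"),
              stringsAsFactors = FALSE)
}

#' @rdname effect_spec
#' @export
default_univariate <- function() {
  g <- cell_grid()
  amp <- function(roi) {
    switch(roi,
      hippocampus = ifelse(g$drug == "PLAC",
                           ifelse(g$delay == "1d", 0.5, 0.2),
                           ifelse(g$delay == "1d", 0.2, 0.5)),
      ifg = ifelse(g$drug == "PLAC",
                   ifelse(g$delay == "1d", 0.2, 0.5),
                   ifelse(g$delay == "1d", 0.5, 0.2)),
      control = rep(0.2, nrow(g)))
  }
  dplyr::bind_rows(lapply(c("hippocampus", "ifg", "control"), function(rn) {
    a <- amp(rn)
    tibble::tibble(roi = rn, drug = g$drug, delay = g$delay,
                   amp_old = a, amp_new = 0.2)
  }))
}

#' @rdname effect_spec
#' @export
default_ers <- function() {
  g <- cell_grid()
  r_of <- function(roi) {
    switch(roi,
      hippocampus = ifelse(g$drug == "PLAC",
                           ifelse(g$delay == "1d", 0.35, 0.15),
                           ifelse(g$delay == "1d", 0.15, 0.35)),
      ifg = ifelse(g$drug == "PLAC",
                   ifelse(g$delay == "1d", 0.15, 0.35),
                   ifelse(g$delay == "1d", 0.35, 0.15)),
      control = rep(0, nrow(g)))
  }
  dplyr::bind_rows(lapply(c("hippocampus", "ifg", "control"), function(rn) {
    rr <- r_of(rn)
    tibble::tibble(roi = rn, drug = g$drug, delay = g$delay, r = rr)
  }))
}

#' @rdname effect_spec
#' @export
default_ppi <- function() {
  g <- cell_grid()
  tibble::tibble(drug = g$drug, delay = g$delay,
                 gain = ifelse(g$drug == "PLAC",
                               ifelse(g$delay == "1d", 0.2, 0.6),
                               ifelse(g$delay == "1d", 0.6, 0.2)))
}

#' @rdname effect_spec
#' @export
default_behavior <- function() {
  g <- cell_grid()
  base <- ifelse(g$drug == "PLAC",
                 ifelse(g$delay == "1d", 3.15, 1.71),
                 ifelse(g$delay == "1d", 3.15, 2.35))
  dplyr::bind_rows(lapply(c("negative", "neutral"), function(emo) {
    adj <- ifelse(g$delay == "28d", ifelse(emo == "negative", 0.21, -0.21), 0)
    tibble::tibble(drug = g$drug, delay = g$delay, emotion = emo,
                   d_prime = base + adj, criterion = 0.35)
  }))
}

#' Uniform effect tables
#'
#' Convenience builders that assign one value to every design cell; useful
#' for planting a single effect (or none) in validation simulations.
#'
#' @param r,amp_old,amp_new,gain,d,crit The uniform value(s).
#' @param rois ROI names covered.
#' @return A tibble in the corresponding [effect_spec()] slot format.
#' @export
uniform_ers <- function(r, rois = c("hippocampus", "ifg", "control")) {
  g <- expand.grid(roi = rois, drug = c("PLAC", "YOH"),
                   delay = c("1d", "28d"), stringsAsFactors = FALSE)
  tibble::tibble(roi = g$roi, drug = g$drug, delay = g$delay, r = r)
}

#' @rdname uniform_ers
#' @export
uniform_univariate <- function(amp_old, amp_new,
                               rois = c("hippocampus", "ifg", "control")) {
  g <- expand.grid(roi = rois, drug = c("PLAC", "YOH"),
                   delay = c("1d", "28d"), stringsAsFactors = FALSE)
  tibble::tibble(roi = g$roi, drug = g$drug, delay = g$delay,
                 amp_old = amp_old, amp_new = amp_new)
}

#' @rdname uniform_ers
#' @export
uniform_ppi <- function(gain) {
  g <- cell_grid()
  tibble::tibble(drug = g$drug, delay = g$delay, gain = gain)
}

#' @rdname uniform_ers
#' @export
uniform_behavior <- function(d, crit = 0) {
  g <- expand.grid(drug = c("PLAC", "YOH"), delay = c("1d", "28d"),
                   emotion = c("negative", "neutral"),
                   stringsAsFactors = FALSE)
  tibble::tibble(drug = g$drug, delay = g$delay, emotion = g$emotion,
                 d_prime = d, criterion = crit)
}

effect_lookup <- function(tbl, drug, delay, roi = NULL, emotion = NULL) {
  sel <- tbl$drug == drug & tbl$delay == delay
  if (!is.null(roi)) sel <- sel & tbl$roi == roi
  if (!is.null(emotion)) sel <- sel & tbl$emotion == emotion
  out <- tbl[sel, , drop = FALSE]
  mt_validate(nrow(out) == 1L,
              sprintf("effect table has %d rows for cell (%s, %s%s%s)",
                      nrow(out), drug, delay,
                      if (is.null(roi)) "" else paste0(", ", roi),
                      if (is.null(emotion)) "" else paste0(", ", emotion)))
  out
}
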