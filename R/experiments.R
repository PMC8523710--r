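#' Desk-scale validation experiments
#'
#' These functions run the pipeline's generator-estimator loops at reduced,
#' fixed problem sizes: they simulate cohorts with known planted effects and
#' measure what the analysis recovers. They back the package's acceptance
#' checks and are useful for power exploration.
#'
#' @name memtrace-experiments
NULL

# shared desk-scale cohort geometry for the imaging experiments
experiment_spec <- function(n_per_group = 8, grid = 16, n_items = 20,
                            n_encoding_runs = 3, n_recognition_runs = 3) {
  cohort_spec(n_per_group = n_per_group, grid_shape = rep(grid, 3),
              n_items_old = n_items, n_encoding_runs = n_encoding_runs,
              n_recognition_runs = n_recognition_runs, roi_size = 4)
}

# per-subject imaging analysis used by the experiments: trialwise GLMs on
# unsmoothed data -> ERS map at ROI centres; condition GLM on smoothed data
# -> old-minus-new beta map
analyse_subject <- function(sim, ev, spec, rois, sl, fwhm_mm = 8,
                            what = c("ers", "old_minus_new")) {
  runs <- sim$runs
  out <- list()
  ev_rec <- events_phase(ev, "recognition")
  rec_runs <- runs[grep("^recognition", names(runs))]
  if ("ers" %in% what) {
    fit_enc <- fit_glm(runs[grep("^encoding", names(runs))],
                       build_design(events_phase(ev, "encoding"),
                                    tr = spec$tr, mode = "trialwise"),
                       ar1 = "global")
    fit_rec <- fit_glm(rec_runs,
                       build_design(ev_rec, tr = spec$tr, mode = "trialwise"),
                       ar1 = "global")
    ers <- ers_map(trial_patterns(fit_enc, phase = "encoding",
                                  runs = spec$n_encoding_runs),
                   trial_patterns(fit_rec, phase = "recognition"),
                   item_pairing(spec), sl, variant = "trial_specific")
    out$ers <- ers
  }
  if ("old_minus_new" %in% what) {
    rec_sm <- lapply(rec_runs, smooth_volume, fwhm = fwhm_mm,
                     voxel_size_mm = spec$voxel_size_mm)
    X <- build_design(ev_rec, tr = spec$tr, mode = "condition")
    fit <- fit_glm(rec_sm, X, ar1 = "global")
    info <- attr(X, "col_info")
    w <- setNames(ifelse(info$oldness == "old", 1, -1) /
                    pmax(1, table(info$oldness)[info$oldness]), info$name)
    out$old_minus_new <- contrast_map(fit, w)$beta
  }
  out
}

#' Recovery of planted reinstatement strength
#'
#' Simulates small single-cell cohorts whose matched-item encoding-to-
#' recognition pattern correlation is planted at each value of `r_values`
#' (pattern noise zero, near-noiseless scans, no univariate amplitude so the
#' multivariate channel is isolated), runs the full trialwise-GLM ->
#' searchlight path, and reports the ROI-mean trial-specific ERS, which
#' should approximate `atanh(r)`.
#'
#' @param r_values Planted correlations (each in (-1, 1)).
#' @param n_subjects Subjects per condition.
#' @param seed Integer seed.
#' @return Tibble with `r_planted`, `ers_mean` (across subjects),
#'   `ers_expected = atanh(r_planted)`, `n_subjects`.
#' @export
ers_recovery_experiment <- function(r_values = c(0, 0.3, 0.6),
                                    n_subjects = 8, seed = 1) {
  spec <- experiment_spec(n_per_group = 2)
  rois <- roi_layout(spec)
  sl <- build_searchlight(spec$grid_shape, radius = 3,
                          centers = rois$hippocampus)
  rows <- lapply(r_values, function(r0) {
    eff <- effect_spec(ers = uniform_ers(r0),
                       univariate = uniform_univariate(0, 0),
                       ppi = uniform_ppi(0), ppi_baseline = 0,
                       amp_encoding = 0, pattern_noise_sd = 0,
                       noise_sd = 0.02, subject_sd_z = 0, subject_sd_amp = 0)
    vals <- vapply(seq_len(n_subjects), function(i) {
      sseed <- derive_seed(seed, round(1000 * r0) * 100 + i)
      ev <- sim_events(spec, derive_seed(sseed, 1))
      sim <- sim_subject_bold(ev, spec, eff, rois, "PLAC", "1d",
                              derive_seed(sseed, 2))
      res <- analyse_subject(sim, ev, spec, rois, sl, what = "ers")
      ers_roi_mean(res$ers, rois$hippocampus)$ers
    }, numeric(1))
    tibble::tibble(r_planted = r0, ers_mean = mean(vals),
                   ers_expected = atanh(r0), n_subjects = n_subjects)
  })
  dplyr::bind_rows(rows)
}

#' Detection of the planted consolidation-reversal interaction
#'
#' Simulates cohorts carrying the study's qualitative effect structure --
#' hippocampal reinstatement and old-vs-new amplitude rising from 1d to 28d
#' under yohimbine but falling under placebo, with the mirrored pattern in
#' the IFG-like ROI and nothing in the control ROI -- and runs the
#' ROI-restricted max-statistic permutation test on the drug-by-delay
#' interaction for both map kinds.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n_per_cell Subjects per drug-by-delay cell.
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return Tibble with one row per cohort x map kind x ROI: `p_corr`,
#'   `peak_t`, `significant` (corrected p <= 0.05), `sign_ok` (peak sign
#'   matches the planted direction; `NA` for the control ROI).
#' @export
reversal_experiment <- function(n_cohorts = 20, n_per_cell = 8,
                                n_perm = 500, seed = 1) {
  spec <- experiment_spec(n_per_group = n_per_cell)
  rois <- roi_layout(spec)
  sl <- build_searchlight(spec$grid_shape, radius = 3,
                          centers = Reduce(`|`, rois))
  eff <- effect_spec()
  group <- group_table(spec)
  # planted contrast (PLAC: 1d-28d) - (YOH: 1d-28d) is positive in the
  # hippocampus and negative in the IFG for both map kinds
  planted_sign <- c(hippocampus = 1, ifg = -1, control = NA)
  rows <- list()
  for (co in seq_len(n_cohorts)) {
    maps <- list(ers = vector("list", nrow(group)),
                 old_minus_new = vector("list", nrow(group)))
    for (i in seq_len(nrow(group))) {
      sseed <- derive_seed(seed, co * 1000 + i)
      ev <- sim_events(spec, derive_seed(sseed, 1))
      sim <- sim_subject_bold(ev, spec, eff, rois, group$drug[i],
                              group$delay[i], derive_seed(sseed, 2))
      res <- analyse_subject(sim, ev, spec, rois, sl)
      maps$ers[[i]] <- res$ers$ers
      maps$old_minus_new[[i]] <- res$old_minus_new
    }
    for (kind in names(maps)) {
      fwe <- permutation_fwe(maps[[kind]], group, rois, n_perm = n_perm,
                             seed = derive_seed(seed, co * 7 +
                                                  match(kind, names(maps))),
                             bonferroni = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cohort = co, map_kind = kind, roi = fwe$roi, p_corr = fwe$p_corr,
        peak_t = fwe$peak_t,
        significant = fwe$p_corr <= 0.05,
        sign_ok = sign(fwe$peak_t) == planted_sign[fwe$roi])
    }
  }
  dplyr::bind_rows(rows)
}

#' Familywise-error calibration of the ROI permutation test
#'
#' Generates fully null cohorts (independent Gaussian subject maps, no
#' planted effect) and measures how often the ROI-corrected peak p-value
#' falls at or below 0.05. A calibrated procedure stays near the nominal
#' rate.
#'
#' @param n_cohorts Number of null cohorts.
#' @param n_per_cell Subjects per cell.
#' @param n_perm Permutations per cohort.
#' @param grid Grid edge length (the ROI is a central 3x3x3 cube).
#' @param seed Integer seed.
#' @return Tibble with `n_cohorts`, `rejection_rate`, `mean_p`.
#' @export
fwe_null_experiment <- function(n_cohorts = 500, n_per_cell = 4,
                                n_perm = 200, grid = 8, seed = 1) {
  d <- rep(grid, 3)
  roi <- array(FALSE, d)
  mid <- floor(grid / 2) + (-1:1)
  roi[mid, mid, mid] <- TRUE
  g <- expand.grid(drug = c("PLAC", "YOH"), delay = c("1d", "28d"),
                   stringsAsFactors = FALSE)
  design <- tibble::tibble(subject = sprintf("s%02d", seq_len(4 * n_per_cell)),
                           drug = rep(g$drug, each = n_per_cell),
                           delay = rep(g$delay, each = n_per_cell))
  p_vals <- withr::with_seed(seed, {
    vapply(seq_len(n_cohorts), function(co) {
      maps <- lapply(seq_len(nrow(design)), function(i) {
        stat_map(array(rnorm(prod(d)), d), d, "beta")
      })
      permutation_fwe(maps, design, list(roi = roi), n_perm = n_perm,
                      seed = sample.int(2^30, 1),
                      bonferroni = FALSE)$p_corr
    }, numeric(1))
  })
  tibble::tibble(n_cohorts = n_cohorts,
                 rejection_rate = mean(p_vals <= 0.05),
                 mean_p = mean(p_vals))
}

#' Recovery of planted context-dependent coupling (PPI)
#'
#' Simulates recognition-phase cohorts whose target ROI receives
#' seed-derived signal multiplied by `gain` during old trials, runs the seed
#' eigenvariate -> PPI design -> interaction map path, and summarises the
#' group-mean interaction beta over the target ROI per cohort.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_subjects Subjects per cohort.
#' @param gain Planted coupling gain (0 = null calibration).
#' @param seed Integer seed.
#' @return Tibble per cohort: `gain`, `mean_beta` (group mean over target
#'   ROI), `t`, `p` (one-sample t-test across subjects).
#' @export
ppi_recovery_experiment <- function(n_cohorts = 20, n_subjects = 12,
                                    gain = 0.6, seed = 1) {
  spec <- cohort_spec(n_per_group = max(2, ceiling(n_subjects / 4)),
                      grid_shape = c(12, 12, 12), n_items_old = 12,
                      n_encoding_runs = 1, n_recognition_runs = 2,
                      roi_size = 3)
  rois <- roi_layout(spec)
  eff <- effect_spec(ppi = uniform_ppi(gain))
  fit_mask <- rois$hippocampus | rois$control
  rows <- lapply(seq_len(n_cohorts), function(co) {
    betas <- vapply(seq_len(n_subjects), function(i) {
      sseed <- derive_seed(seed, co * 500 + i)
      ev_all <- sim_events(spec, derive_seed(sseed, 1))
      ev <- events_phase(ev_all, "recognition")
      sim <- sim_subject_bold(ev, spec, eff, rois, "PLAC", "1d",
                              derive_seed(sseed, 2))
      seed_ts <- first_eigenvariate(sim$runs, rois$ifg, "ifg")
      X <- build_ppi_design(seed_ts, ev, tr = spec$tr)
      pm <- ppi_map(sim$runs, X, ar1 = "global", mask = fit_mask)
      mean(as.numeric(pm$beta)[as.logical(rois$hippocampus)])
    }, numeric(1))
    ht <- t.test(betas)
    tibble::tibble(cohort = co, gain = gain, mean_beta = mean(betas),
                   t = unname(ht$statistic), p = ht$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Calibration and power of the behavioural interaction test
#'
#' `behav_null_experiment` draws pure-noise 2x2 cohorts and reports the
#' type-I error of [factorial_interaction()] at alpha = 0.05.
#' `behav_power_experiment` simulates full recognition cohorts from the
#' default planted cell structure (the attenuated 1d-to-28d decline under
#' yohimbine) at `n_per_cell` subjects and reports detection power.
#'
#' @param n_reps Simulation replicates.
#' @param n_per_cell Subjects per cell.
#' @param seed Integer seed.
#' @return One-row tibble with the rejection rate.
#' @export
behav_null_experiment <- function(n_reps = 2000, n_per_cell = 26, seed = 1) {
  g <- expand.grid(drug = c("PLAC", "YOH"), delay = c("1d", "28d"),
                   stringsAsFactors = FALSE)
  design <- tibble::tibble(drug = rep(g$drug, each = n_per_cell),
                           delay = rep(g$delay, each = n_per_cell))
  p <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      design$value <- rnorm(nrow(design))
      factorial_interaction(design)$p
    }, numeric(1))
  })
  tibble::tibble(n_reps = n_reps, rejection_rate = mean(p <= 0.05))
}

#' @rdname behav_null_experiment
#' @export
behav_power_experiment <- function(n_reps = 400, n_per_cell = 26, seed = 1) {
  spec <- cohort_spec(n_per_group = n_per_cell, grid_shape = c(12, 12, 12),
                      roi_size = 3)
  eff <- effect_spec()
  group <- group_table(spec)
  hits <- vapply(seq_len(n_reps), function(i) {
    resp <- sim_responses(group, spec, eff, derive_seed(seed, i))
    sdt <- sdt_summary(resp)
    res <- factorial_interaction(dplyr::rename(sdt, value = "d_prime"))
    res$p <= 0.05
  }, logical(1))
  tibble::tibble(n_reps = n_reps, rejection_rate = mean(hits))
}
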