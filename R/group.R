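#' Per-subject condition difference map
#'
#' Collapses a 2-level within-subject factor (old vs. new, recognition vs.
#' encoding, EOS vs. ENS) to a voxel-wise difference, so the between-subjects
#' 2x2 ANOVA on the result tests the corresponding three-way pattern.
#'
#' @param a,b [stat_map()]s of the two conditions (`a - b`).
#' @return A [stat_map()].
#' @export
difference_map <- function(a, b) {
  mt_validate(all(dim(a) == dim(b)), "condition maps differ in geometry")
  stat_map(as.numeric(a) - as.numeric(b), dim(a), attr(a, "kind"),
           attr(a, "mask") & attr(b, "mask"),
           list(difference = TRUE))
}

# subjects x voxels matrix from a list of stat_maps (optionally ROI-restricted)
stack_maps <- function(maps, roi = NULL) {
  mt_validate(length(maps) >= 4, "need at least one map per design cell")
  d <- dim(maps[[1]])
  mt_validate(all(vapply(maps, function(m) all(dim(m) == d), TRUE)),
              "maps differ in geometry")
  sel <- if (is.null(roi)) seq_len(prod(d)) else which(as.logical(roi))
  Y <- do.call(rbind, lapply(maps, function(m) as.numeric(m)[sel]))
  attr(Y, "voxels") <- sel
  attr(Y, "dim3") <- d
  Y
}

# vectorised 2x2 interaction t over the columns of Y (subjects x voxels):
# contrast (PLAC: 1d - 28d) - (YOH: 1d - 28d) on cell means, pooled MSE
interaction_t_matrix <- function(Y, drug, delay) {
  g <- factor(paste(drug, delay, sep = "."),
              levels = c("PLAC.1d", "PLAC.28d", "YOH.1d", "YOH.28d"))
  n_g <- as.integer(table(g))
  mt_validate(all(n_g >= 2), "need at least 2 subjects per cell")
  means <- rowsum(Y, g) / n_g
  ss_within <- colSums(Y^2) - colSums(means^2 * n_g)
  df2 <- nrow(Y) - 4L
  mse <- ss_within / df2
  cvec <- means[1, ] - means[2, ] - (means[3, ] - means[4, ])
  se <- sqrt(mse * sum(1 / n_g))
  t <- ifelse(se < 1e-12, 0, cvec / se)
  list(t = t, contrast = cvec, df = df2)
}

#' Voxel-wise 2x2 drug-by-delay interaction map
#'
#' Per voxel, the two-way between-subjects ANOVA interaction on one map per
#' subject, reported as the signed t of the cell-mean contrast
#' `(PLAC: 1d - 28d) - (YOH: 1d - 28d)` and as `F = t^2`. Voxels with zero
#' residual variance get statistic 0 (guarding the infinite-statistic case).
#'
#' @param maps List of [stat_map()]s, one per subject, aligned with `design`.
#' @param design Tibble with `drug` (PLAC/YOH) and `delay` (1d/28d) per
#'   subject.
#' @return List with `t` and `F` [stat_map()]s and `df = c(1, n - 4)`.
#' @export
interaction_map <- function(maps, design) {
  mt_validate(length(maps) == nrow(design),
              "one map per design row required")
  Y <- stack_maps(maps)
  res <- interaction_t_matrix(Y, design$drug, design$delay)
  d <- attr(Y, "dim3")
  mask <- attr(maps[[1]], "mask")
  ok <- !apply(Y, 2, anyNA)
  tv <- ifelse(ok, res$t, NA_real_)
  list(t = stat_map(tv, d, "t", mask, list(dof = res$df)),
       F = stat_map(tv^2, d, "F", mask, list(df = c(1, res$df))),
       df = c(1, res$df))
}

#' Permutation familywise-error control within ROI masks
#'
#' The permutation analogue of small-volume correction: subject cell labels
#' are permuted (`n_perm` relabellings of the between-subjects assignment,
#' or exhaustive enumeration when fewer distinct relabellings exist, with a
#' warning), the maximum absolute interaction t inside the ROI is recorded
#' per permutation, and the observed ROI peak is ranked in that max-statistic
#' null distribution. Clusters are formed among ROI voxels exceeding the
#' two-sided `cluster_forming_p` threshold (6-connectivity); extent is
#' descriptive, peak-level inference is primary. An optional Bonferroni
#' correction across ROIs is reported alongside.
#'
#' @param maps List of per-subject [stat_map()]s.
#' @param design Tibble with `drug`, `delay` (and optionally `subject`).
#' @param rois Named list of logical ROI masks.
#' @param n_perm Number of permutations (>= 100).
#' @param cluster_forming_p Two-sided uncorrected threshold for cluster
#'   forming (default 0.005).
#' @param seed Integer seed for the permutation stream (mandatory).
#' @param bonferroni Multiply corrected p by the number of ROIs.
#' @return A `cluster_result` tibble: one row per ROI with `roi`, `peak_x`,
#'   `peak_y`, `peak_z` (1-based voxel coordinates), `peak_t`, `k` (extent of
#'   the peak's cluster at the forming threshold), `p_corr`, `p_bonf`,
#'   `n_perm_used`, `exhaustive`. Attribute `subject_means`: per-subject mean
#'   over each ROI's suprathreshold cluster (or peak voxel when no cluster
#'   forms), for post-hoc cell comparisons.
#' @export
permutation_fwe <- function(maps, design, rois, n_perm = 1000,
                            cluster_forming_p = 0.005, seed,
                            bonferroni = TRUE) {
  mt_validate(n_perm >= 100, "`n_perm` must be at least 100")
  mt_validate(!missing(seed), "`seed` is mandatory for permutation inference")
  mt_validate(length(rois) > 0 && !is.null(names(rois)), "named ROI list required")
  n <- length(maps)
  perms <- make_permutations(design$drug, design$delay, n_perm, seed)
  exhaustive <- perms$exhaustive

  rows <- list()
  means_list <- list()
  for (rn in names(rois)) {
    roi <- rois[[rn]]
    mt_validate(any(roi), sprintf("ROI %s is empty", rn))
    Y_all <- stack_maps(maps, roi)
    keep <- !apply(Y_all, 2, anyNA)
    mt_validate(any(keep), sprintf("ROI %s has no valid voxels", rn))
    Y <- Y_all[, keep, drop = FALSE]
    vox <- attr(Y_all, "voxels")[keep]
    obs <- interaction_t_matrix(Y, design$drug, design$delay)
    peak_i <- which.max(abs(obs$t))
    peak_t <- obs$t[peak_i]
    null_max <- vapply(seq_len(nrow(perms$drug)), function(b) {
      max(abs(interaction_t_matrix(Y, perms$drug[b, ], perms$delay[b, ])$t))
    }, numeric(1))
    if (exhaustive) {
      p_corr <- mean(null_max >= abs(peak_t))
    } else {
      p_corr <- (1 + sum(null_max >= abs(peak_t))) / (1 + length(null_max))
    }
    t_thr <- qt(1 - cluster_forming_p / 2, obs$df)
    supra <- abs(obs$t) >= t_thr
    k <- 0L
    cl_vox <- vox[peak_i]
    if (supra[peak_i]) {
      d3 <- attr(Y_all, "dim3")
      comp <- connected_components(vox[supra], d3)
      peak_comp <- comp[match(vox[peak_i], vox[supra])]
      cl_vox <- vox[supra][comp == peak_comp]
      k <- length(cl_vox)
    }
    d3 <- dim(maps[[1]])
    pc <- index_to_coord(vox[peak_i], d3)
    cluster_means <- rowMeans(Y[, match(cl_vox, vox), drop = FALSE])
    means_list[[rn]] <- tibble::tibble(
      subject = design$subject %||% seq_len(n),
      drug = design$drug, delay = design$delay,
      roi = rn, cluster_mean = cluster_means)
    rows[[rn]] <- tibble::tibble(
      roi = rn, peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
      peak_t = peak_t, k = k, p_corr = p_corr,
      p_bonf = if (bonferroni) min(1, p_corr * length(rois)) else p_corr,
      n_perm_used = length(null_max), exhaustive = exhaustive)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "subject_means") <- dplyr::bind_rows(means_list)
  class(out) <- c("cluster_result", class(out))
  out
}

# relabellings of the between-subjects assignment (rows = permutations),
# returned as aligned drug/delay matrices. When fewer distinct assignments
# than n_perm exist, all of them are enumerated (with a warning) and p-values
# gain resolution 1/#arrangements.
make_permutations <- function(drug, delay, n_perm, seed) {
  labels <- paste(drug, delay, sep = ".")
  n <- length(labels)
  counts <- table(labels)
  log_distinct <- lgamma(n + 1) - sum(lgamma(counts + 1))
  if (log_distinct <= log(n_perm)) {
    warning(sprintf("only %d distinct relabellings; enumerating exhaustively",
                    round(exp(log_distinct))), call. = FALSE)
    arr <- enumerate_assignments(names(counts), as.integer(counts))
    parts <- strsplit(arr, ".", fixed = TRUE)
    return(list(
      drug = matrix(vapply(parts, `[`, "", 1), nrow(arr), ncol(arr)),
      delay = matrix(vapply(parts, `[`, "", 2), nrow(arr), ncol(arr)),
      exhaustive = TRUE))
  }
  idx <- withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) sample.int(n), integer(n)))
  })
  list(drug = matrix(drug[idx], n_perm, n),
       delay = matrix(delay[idx], n_perm, n),
       exhaustive = FALSE)
}

# all distinct arrangements of a label multiset (small n only)
enumerate_assignments <- function(levels_, counts) {
  rec <- function(remaining) {
    n <- sum(remaining)
    if (n == 0) return(matrix(character(0), 1, 0))
    out <- list()
    for (i in seq_along(levels_)) {
      if (remaining[i] == 0) next
      rem <- remaining
      rem[i] <- rem[i] - 1L
      sub <- rec(rem)
      out[[length(out) + 1L]] <- cbind(rep(levels_[i], nrow(sub)), sub)
    }
    do.call(rbind, out)
  }
  rec(counts)
}

# 6-connectivity connected components over a set of linear voxel indices
connected_components <- function(vox, dim) {
  n <- length(vox)
  comp <- integer(n)
  coords <- index_to_coord(vox, dim)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(vox[i]), i, envir = lookup)
  neigh_off <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      for (k in 1:6) {
        cc <- coords[j, ] + neigh_off[k, ]
        if (any(cc < 1) || any(cc > dim)) next
        li <- coord_to_index(matrix(cc, 1), dim)
        m <- mget(as.character(li), envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(m) && comp[m] == 0) {
          comp[m] <- cur
          queue <- c(queue, m)
        }
      }
    }
  }
  comp
}

#' Post-hoc Welch comparisons for a significant cluster
#'
#' The four cell comparisons used to unpack a drug-by-delay interaction:
#' 1d vs. 28d within each drug and PLAC vs. YOH within each delay, each via
#' [welch_t()] on per-subject cluster means.
#'
#' @param values Numeric vector of per-subject cluster means (or a
#'   `subject_means` tibble row set from [permutation_fwe()] via
#'   `cluster_means()`).
#' @param design Tibble with `drug` and `delay` aligned with `values`.
#' @return Tibble with one row per comparison.
#' @export
posthoc_cells <- function(values, design) {
  cmp <- list(
    list(label = "1d vs 28d | PLAC", a = design$drug == "PLAC" & design$delay == "1d",
         b = design$drug == "PLAC" & design$delay == "28d"),
    list(label = "1d vs 28d | YOH", a = design$drug == "YOH" & design$delay == "1d",
         b = design$drug == "YOH" & design$delay == "28d"),
    list(label = "PLAC vs YOH | 1d", a = design$drug == "PLAC" & design$delay == "1d",
         b = design$drug == "YOH" & design$delay == "1d"),
    list(label = "PLAC vs YOH | 28d", a = design$drug == "PLAC" & design$delay == "28d",
         b = design$drug == "YOH" & design$delay == "28d"))
  dplyr::bind_rows(lapply(cmp, function(cc) {
    mt_validate(sum(cc$a) >= 2 && sum(cc$b) >= 2,
                paste("empty or singleton cell in comparison", cc$label))
    dplyr::bind_cols(tibble::tibble(comparison = cc$label),
                     welch_t(values[cc$a], values[cc$b]))
  }))
}

#' Per-subject cluster means from a permutation result
#'
#' @param x A [permutation_fwe()] result.
#' @param roi ROI name.
#' @return Tibble `subject`, `drug`, `delay`, `cluster_mean`.
#' @export
cluster_means <- function(x, roi) {
  sm <- attr(x, "subject_means")
  mt_validate(!is.null(sm), "no subject means attached")
  sm[sm$roi == roi, , drop = FALSE]
}
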