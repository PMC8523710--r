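rand_maps <- function(n, d, seed, effect = NULL, roi = NULL) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      v <- array(rnorm(prod(d)), d)
      if (!is.null(effect) && effect[i] != 0) v[roi] <- v[roi] + effect[i]
      stat_map(v, d, "beta")
    })
  })
}

cell_design <- function(n_per_cell) {
  g <- expand.grid(drug = c("PLAC", "YOH"), delay = c("1d", "28d"),
                   stringsAsFactors = FALSE)
  tibble::tibble(subject = sprintf("s%02d", seq_len(4 * n_per_cell)),
                 drug = rep(g$drug, each = n_per_cell),
                 delay = rep(g$delay, each = n_per_cell))
}

test_that("difference maps are voxel-wise linear", {
  d <- c(6, 6, 6)
  withr::with_seed(1, a <- stat_map(array(rnorm(216), d), d, "beta"))
  expect_equal(as.numeric(difference_map(a, a)), rep(0, 216))
  b <- stat_map(array(as.numeric(a) + 2, d), d, "beta")
  expect_equal(as.numeric(difference_map(b, a)), rep(2, 216))
})

test_that("voxel-wise interaction matches the aov oracle", {
  d <- c(4, 4, 2)
  design <- cell_design(5)
  maps <- rand_maps(20, d, seed = 2)
  res <- interaction_map(maps, design)
  Y <- do.call(rbind, lapply(maps, as.numeric))
  for (vox in c(1, 9, 30)) {
    df <- data.frame(value = Y[, vox], drug = design$drug,
                     delay = design$delay)
    sm <- summary(aov(value ~ drug * delay, data = df))[[1]]
    f_oracle <- sm[grep("drug:delay", rownames(sm)), "F value"]
    expect_equal(as.numeric(res$F)[vox], f_oracle, tolerance = 1e-8)
  }
  # the signed contrast follows the cell means
  cm <- tapply(Y[, 1], list(design$drug, design$delay), mean)
  expect_equal(sign(as.numeric(res$t)[1]),
               sign((cm["PLAC", "1d"] - cm["PLAC", "28d"]) -
                      (cm["YOH", "1d"] - cm["YOH", "28d"])))
})

test_that("planted crossed effects produce large interaction statistics", {
  d <- c(5, 5, 5)
  roi <- array(FALSE, d)
  roi[2:4, 2:4, 2:4] <- TRUE
  design <- cell_design(6)
  # PLAC declines 1d -> 28d, YOH rises: strongly crossed
  effect <- ifelse(design$drug == "PLAC",
                   ifelse(design$delay == "1d", 3, 0),
                   ifelse(design$delay == "1d", 0, 3))
  maps <- rand_maps(24, d, seed = 3, effect = effect, roi = roi)
  res <- interaction_map(maps, design)
  expect_gt(mean(as.numeric(res$t)[roi]), 3)
  expect_lt(mean(abs(as.numeric(res$t)[!roi])), 1.5)

  # permuting group labels destroys the planted effect
  withr::with_seed(4, perm <- sample.int(24))
  res_p <- interaction_map(maps, design[perm, ])
  expect_lt(mean(abs(as.numeric(res_p$t)[roi])), 2)
})

test_that("permutation FWE control flags planted effects inside the ROI only", {
  d <- c(6, 6, 6)
  roi_a <- array(FALSE, d); roi_a[1:3, 1:3, 1:3] <- TRUE
  roi_b <- array(FALSE, d); roi_b[4:6, 4:6, 4:6] <- TRUE
  design <- cell_design(6)
  effect <- ifelse(design$drug == "PLAC",
                   ifelse(design$delay == "1d", 2.5, 0),
                   ifelse(design$delay == "1d", 0, 2.5))
  maps <- rand_maps(24, d, seed = 5, effect = effect, roi = roi_a)
  res <- permutation_fwe(maps, design, list(target = roi_a, control = roi_b),
                         n_perm = 300, seed = 11)
  expect_s3_class(res, "cluster_result")
  expect_lte(res$p_corr[res$roi == "target"], 0.05)
  expect_gt(res$p_corr[res$roi == "control"], 0.1)
  expect_gt(res$k[res$roi == "target"], 0)
  # bonferroni across ROIs doubles the corrected p
  expect_equal(res$p_bonf, pmin(1, res$p_corr * 2))
  # peak coordinates fall inside the ROI
  pk <- res[res$roi == "target", ]
  expect_true(roi_a[pk$peak_x, pk$peak_y, pk$peak_z])

  # post-hoc cell comparisons recover the planted crossed pattern
  cm <- cluster_means(res, "target")
  ph <- posthoc_cells(cm$cluster_mean, cm)
  expect_gt(ph$t[ph$comparison == "1d vs 28d | PLAC"], 0)
  expect_lt(ph$t[ph$comparison == "1d vs 28d | YOH"], 0)

  # post-hoc tests are scale-free
  ph2 <- posthoc_cells(cm$cluster_mean * 2, cm)
  expect_equal(ph2$t, ph$t, tolerance = 1e-10)
})

test_that("small designs fall back to exhaustive enumeration", {
  d <- c(4, 4, 1)
  design <- cell_design(2)
  maps <- rand_maps(8, d, seed = 6)
  roi <- array(TRUE, d)
  expect_warning(
    res <- permutation_fwe(maps, design, list(all = roi), n_perm = 3000,
                           seed = 12),
    "exhaustively")
  n_arr <- factorial(8) / (factorial(2)^4)  # 2520 distinct relabellings
  expect_equal(res$n_perm_used, n_arr)
  expect_true(res$exhaustive)
  # p has resolution 1 / #arrangements
  expect_equal(res$p_corr * n_arr, round(res$p_corr * n_arr),
               tolerance = 1e-9)
  expect_gte(res$p_corr, 1 / n_arr)
})

test_that("identical groups give zero post-hoc statistics", {
  design <- cell_design(3)
  vals <- rep(1.7, 12)
  ph <- posthoc_cells(vals, design)
  expect_equal(ph$t, rep(0, 4))
})

test_that("connected components separate disjoint blobs", {
  d <- c(8, 8, 1)
  blob1 <- c(memtrace:::coord_to_index(cbind(1, 1, 1), d),
             memtrace:::coord_to_index(cbind(2, 1, 1), d))
  blob2 <- memtrace:::coord_to_index(cbind(5, 5, 1), d)
  comp <- memtrace:::connected_components(c(blob1, blob2), d)
  expect_equal(length(unique(comp)), 2)
  expect_equal(comp[1], comp[2])
  expect_false(comp[1] == comp[3])
})
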