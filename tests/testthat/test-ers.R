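single_sphere <- function(dim) {
  # one searchlight covering the whole (tiny) grid
  mask <- array(TRUE, dim)
  build_searchlight(dim, mask, radius = ceiling(sqrt(sum(dim^2))),
                    min_voxels = 1,
                    centers = memtrace:::coord_to_index(
                      cbind(1, 1, 1), dim))
}

test_that("hand-computed three-item example reproduces EOS and ENS", {
  d <- c(5, 1, 1)
  enc <- matrix(c(1, 2, 3, 4, 5,
                  2, 1, 4, 3, 5,
                  5, 4, 3, 2, 1), 3, 5, byrow = TRUE)
  rec_old <- matrix(c(1, 2, 3, 5, 4,
                      2, 2, 4, 3, 6,
                      5, 5, 2, 2, 1), 3, 5, byrow = TRUE)
  rec_new <- matrix(c(3, 1, 4, 1, 5,
                      2, 7, 1, 8, 2,
                      1, 1, 2, 2, 3), 3, 5, byrow = TRUE)
  old_ids <- paste0("old", 1:3)
  new_ids <- paste0("new", 1:3)
  enc_p <- make_pattern(enc, old_ids, "encoding", d)
  rec_p <- make_pattern(rbind(rec_old, rec_new), c(old_ids, new_ids),
                        "recognition", d,
                        oldness = rep(c("old", "new"), each = 3))
  pairing <- tibble::tibble(old_item = old_ids, new_item = new_ids)
  sl <- single_sphere(d)

  res <- ers_map(enc_p, rec_p, pairing, sl, variant = "trial_specific")
  eos_hand <- mean(atanh(sapply(1:3, function(i) cor(enc[i, ], rec_old[i, ]))))
  ens_hand <- mean(atanh(sapply(1:3, function(i) cor(enc[i, ], rec_new[i, ]))))
  v <- function(m) as.numeric(m)[1]
  expect_equal(v(res$eos), eos_hand, tolerance = 1e-10)
  expect_equal(v(res$ens), ens_hand, tolerance = 1e-10)
  expect_equal(v(res$ers), eos_hand - ens_hand, tolerance = 1e-10)

  # cross-trial variant: all non-corresponding old pairs / all new pairs
  res_x <- ers_map(enc_p, rec_p, pairing, sl, variant = "cross_trial")
  eos_x <- mean(atanh(c(sapply(1:3, function(i)
    sapply((1:3)[-i], function(j) cor(enc[i, ], rec_old[j, ]))))))
  ens_x <- mean(atanh(outer(1:3, 1:3, Vectorize(function(i, j)
    cor(enc[i, ], rec_new[j, ])))))
  expect_equal(v(res_x$eos), eos_x, tolerance = 1e-10)
  expect_equal(v(res_x$ens), ens_x, tolerance = 1e-10)
})

test_that("perfect reinstatement versus broken correspondence", {
  d <- c(4, 4, 1)
  withr::with_seed(5, {
    enc <- matrix(rnorm(6 * 16), 6, 16)
    rec_new <- matrix(rnorm(6 * 16), 6, 16)
  })
  old_ids <- paste0("old", 1:6)
  new_ids <- paste0("new", 1:6)
  pairing <- tibble::tibble(old_item = old_ids, new_item = new_ids)
  sl <- single_sphere(d)
  enc_p <- make_pattern(enc, old_ids, "encoding", d)

  # identical recognition patterns: EOS saturates, ERS strongly positive
  rec_same <- make_pattern(rbind(enc, rec_new), c(old_ids, new_ids),
                           "recognition", d,
                           oldness = rep(c("old", "new"), each = 6))
  res <- ers_map(enc_p, rec_same, pairing, sl)
  expect_gt(as.numeric(res$eos)[1], fisher_z(0.999))
  expect_gt(as.numeric(res$ers)[1], 2)

  # permuted correspondence: expected reinstatement vanishes
  perm <- c(2:6, 1)
  rec_perm <- make_pattern(rbind(enc[perm, ], rec_new),
                           c(old_ids, new_ids), "recognition", d,
                           oldness = rep(c("old", "new"), each = 6))
  res_p <- ers_map(enc_p, rec_perm, pairing, sl)
  expect_lt(abs(as.numeric(res_p$ers)[1]), 0.5)
})

test_that("ERS is invariant to affine rescaling of all patterns", {
  d <- c(4, 4, 1)
  withr::with_seed(6, {
    enc <- matrix(rnorm(5 * 16), 5, 16)
    rec <- matrix(rnorm(10 * 16), 10, 16)
  })
  old_ids <- paste0("old", 1:5)
  new_ids <- paste0("new", 1:5)
  pairing <- tibble::tibble(old_item = old_ids, new_item = new_ids)
  sl <- single_sphere(d)
  mk <- function(e, r) {
    list(enc = make_pattern(e, old_ids, "encoding", d),
         rec = make_pattern(r, c(old_ids, new_ids), "recognition", d,
                            oldness = rep(c("old", "new"), each = 5)))
  }
  p1 <- mk(enc, rec)
  p2 <- mk(enc * 3.7 - 2, rec * 3.7 - 2)
  r1 <- ers_map(p1$enc, p1$rec, pairing, sl)
  r2 <- ers_map(p2$enc, p2$rec, pairing, sl)
  expect_equal(as.numeric(r1$ers), as.numeric(r2$ers), tolerance = 1e-10)
})

test_that("variants coincide when all items share one pattern", {
  d <- c(4, 4, 1)
  withr::with_seed(7, base <- rnorm(16))
  enc <- matrix(rep(base, 4), 4, 16, byrow = TRUE)
  rec <- matrix(rep(base, 8), 8, 16, byrow = TRUE)
  old_ids <- paste0("old", 1:4)
  new_ids <- paste0("new", 1:4)
  pairing <- tibble::tibble(old_item = old_ids, new_item = new_ids)
  sl <- single_sphere(d)
  enc_p <- make_pattern(enc, old_ids, "encoding", d)
  rec_p <- make_pattern(rec, c(old_ids, new_ids), "recognition", d,
                        oldness = rep(c("old", "new"), each = 4))
  ts <- ers_map(enc_p, rec_p, pairing, sl, variant = "trial_specific")
  ct <- ers_map(enc_p, rec_p, pairing, sl, variant = "cross_trial")
  expect_equal(as.numeric(ts$ers)[1], as.numeric(ct$ers)[1], tolerance = 1e-10)
})

test_that("unmatched items are reported by id", {
  d <- c(4, 4, 1)
  withr::with_seed(8, enc <- matrix(rnorm(2 * 16), 2, 16))
  enc_p <- make_pattern(enc, c("old1", "old2"), "encoding", d)
  rec_p <- make_pattern(enc, c("old1", "new1"), "recognition", d,
                        oldness = c("old", "new"))
  pairing <- tibble::tibble(old_item = c("old1", "old2"),
                            new_item = c("new1", "new9"))
  expect_error(ers_map(enc_p, rec_p, pairing, single_sphere(d)),
               "old2.*new9|unmatched")
})

test_that("planted pattern correlation is recovered from emitted patterns", {
  spec <- tiny_spec(n_items_old = 40)
  rois <- roi_layout(spec)
  for (r0 in c(0, 0.6)) {
    eff <- effect_spec(ers = uniform_ers(r0), subject_sd_z = 0)
    pats <- sim_patterns(spec, eff, rois, "PLAC", "1d", seed = 21)
    emp <- mean(sapply(seq_len(spec$n_items_old), function(i) {
      cor(pats$hippocampus$enc[i, ], pats$hippocampus$rec_old[i, ])
    }))
    expect_equal(emp, r0, tolerance = 0.05)
    emp_new <- mean(sapply(seq_len(spec$n_items_old), function(i) {
      cor(pats$hippocampus$enc[i, ], pats$hippocampus$rec_new[i, ])
    }))
    expect_lt(abs(emp_new), 0.05)
  }
})
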