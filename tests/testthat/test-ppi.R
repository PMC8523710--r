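test_that("rank-one ROI data reproduce the shared time course", {
  d <- c(6, 6, 1)
  roi <- array(FALSE, d)
  roi[2:4, 2:4, 1] <- TRUE
  withr::with_seed(1, {
    s <- rnorm(80)
    loading <- runif(sum(roi), 0.5, 1.5)
    Y <- matrix(0, 80, prod(d))
    Y[, which(roi)] <- outer(s, loading)
    Y <- Y + matrix(rnorm(80 * prod(d), 0, 1e-4), 80)
  })
  b <- bold_run(Y, d, tr = 2)
  ev <- first_eigenvariate(b, roi)
  expect_gt(abs(cor(ev$series, s)), 0.9999)
  expect_gt(ev$explained_variance, 0.999)
  expect_gt(cor(ev$series, s), 0)  # sign convention: positive mean loading

  # negating the data negates the eigenvariate
  b2 <- bold_run(-Y, d, tr = 2)
  ev2 <- first_eigenvariate(b2, roi)
  expect_equal(ev2$series, -ev$series, tolerance = 1e-4)

  # SVD oracle on the centred ROI matrix
  Yc <- sweep(Y[, which(roi)], 2, colMeans(Y[, which(roi)]))
  u1 <- svd(Yc)$u[, 1]
  expect_gt(abs(cor(ev$series, u1)), 0.9999)
})

test_that("degenerate ROI data are rejected", {
  d <- c(4, 4, 1)
  roi <- array(TRUE, d)
  b <- bold_run(matrix(1, 20, 16), d, tr = 2)
  expect_error(first_eigenvariate(b, roi), "constant")
  roi1 <- array(FALSE, d)
  roi1[1, 1, 1] <- TRUE
  expect_error(first_eigenvariate(b, roi1), "2 voxels")
})

test_that("the PPI column is the literal element-by-element product", {
  spec <- tiny_spec(n_items_old = 4, n_recognition_runs = 1)
  ev <- events_phase(sim_events(spec, seed = 2), "recognition")
  ns <- run_scans(ev)
  withr::with_seed(3, seed_ts <- rnorm(sum(ns)))
  X <- build_ppi_design(seed_ts, ev, tr = spec$tr)
  expect_equal(unname(X[, "ppi"]), unname(X[, "seed"] * X[, "psych"]),
               tolerance = 1e-12)
  expect_equal(unname(X[, "seed"]), seed_ts)
  # context coding: old events push psych up, new events down
  expect_gt(max(X[, "psych"]), 0)
  expect_lt(min(X[, "psych"]), 0)
})

test_that("degenerate context vectors surface collinearity errors", {
  spec <- tiny_spec(n_items_old = 4, n_recognition_runs = 1)
  ev <- events_phase(sim_events(spec, seed = 4), "recognition")
  withr::with_seed(5, seed_ts <- rnorm(sum(run_scans(ev))))
  # zero context: psych and ppi identically zero
  expect_error(build_ppi_design(seed_ts, ev, tr = spec$tr,
                                context = c(old = 0, new = 0)),
               "collinear")
  # missing label
  expect_error(build_ppi_design(seed_ts, ev, tr = spec$tr,
                                context = c(old = 1)),
               "context")
})

test_that("planted coupling gain is recovered with the correct sign", {
  spec <- tiny_spec(n_items_old = 10, n_recognition_runs = 2,
                    grid_shape = c(12, 12, 12))
  rois <- roi_layout(spec)
  eff <- effect_spec(ppi = uniform_ppi(0.8), noise_sd = 0.3,
                     subject_sd_amp = 0)
  ev <- sim_events(spec, seed = 6)
  sim <- sim_subject_bold(ev, spec, eff, rois, "PLAC", "1d", seed = 7)
  rec <- sim$runs[grep("^recognition", names(sim$runs))]
  ev_rec <- events_phase(ev, "recognition")
  seed_ts <- first_eigenvariate(rec, rois$ifg)
  X <- build_ppi_design(seed_ts, ev_rec, tr = spec$tr)
  pm <- ppi_map(rec, X)
  target <- mean(as.numeric(pm$beta)[as.logical(rois$hippocampus)])
  control <- mean(as.numeric(pm$beta)[as.logical(rois$control)])
  expect_gt(target, 0.1)
  expect_lt(abs(control), 0.1)

  # flipping the context coding negates the interaction map
  X2 <- build_ppi_design(seed_ts, ev_rec, tr = spec$tr,
                         context = c(old = -1, new = 1))
  pm2 <- ppi_map(rec, X2)
  expect_equal(as.numeric(pm2$beta), -as.numeric(pm$beta), tolerance = 1e-6)
})

test_that("interaction estimate is invariant to added main effects", {
  spec <- tiny_spec(n_items_old = 6, n_recognition_runs = 1,
                    grid_shape = c(10, 10, 10))
  ev <- events_phase(sim_events(spec, seed = 8), "recognition")
  ns <- sum(run_scans(ev))
  withr::with_seed(9, {
    seed_ts <- rnorm(ns)
    Y <- matrix(rnorm(ns * 1000), ns, 1000)
  })
  X <- build_ppi_design(seed_ts, ev, tr = spec$tr)
  b1 <- ppi_map(bold_run(Y, c(10, 10, 10), spec$tr), X, ar1 = "off")
  # add arbitrary multiples of the seed and psych main effects
  Y2 <- Y + outer(X[, "seed"], rep(2, 1000)) - outer(X[, "psych"], rep(3, 1000))
  b2 <- ppi_map(bold_run(Y2, c(10, 10, 10), spec$tr), X, ar1 = "off")
  expect_equal(as.numeric(b1$beta), as.numeric(b2$beta), tolerance = 1e-8)
})
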