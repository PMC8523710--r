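glm_toy <- function(seed = 1, n = 50, p = 5, v = 20, noise = 1) {
  withr::with_seed(seed, {
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    colnames(X) <- c("const", paste0("task:x", seq_len(p - 1)))
    B <- matrix(rnorm(p * v), p, v)
    Y <- X %*% B + matrix(rnorm(n * v, 0, noise), n, v)
    list(X = X, B = B, Y = Y)
  })
}

# wrap a raw matrix as a design + bold pair on a fake 1D grid
as_fit_inputs <- function(X, Y) {
  dimg <- c(ncol(Y), 1, 1)
  design <- structure(X, class = c("design_matrix", "matrix"),
                      kind = c("run_constant",
                               rep("task", ncol(X) - 1)),
                      col_info = tibble::tibble(name = colnames(X)[-1]),
                      run_rows = list(seq_len(nrow(X))), tr = 2,
                      mode = "condition", hp_cutoff = Inf)
  bold <- bold_run(Y, dim = dimg, tr = 2)
  list(design = design, bold = bold)
}

test_that("noiseless data recover the generating coefficients exactly", {
  toy <- glm_toy(seed = 2, noise = 0)
  inp <- as_fit_inputs(toy$X, toy$Y)
  fit <- fit_glm(inp$bold, inp$design, ar1 = "off")
  expect_equal(max(abs(fit$beta - toy$B)), 0, tolerance = 1e-8)
  expect_lt(max(fit$sigma2), 1e-16)
})

test_that("OLS path equals the normal-equation oracle", {
  for (seed in 1:5) {
    toy <- glm_toy(seed = seed)
    inp <- as_fit_inputs(toy$X, toy$Y)
    fit <- fit_glm(inp$bold, inp$design, ar1 = "off")
    oracle <- solve(crossprod(toy$X), crossprod(toy$X, toy$Y))
    expect_equal(fit$beta, oracle, tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(fit$dof, nrow(toy$X) - ncol(toy$X))
  }
})

test_that("global AR(1) estimation recovers the generating coefficient", {
  withr::with_seed(3, {
    n <- 300
    v <- 200
    # smooth regressor: OLS mis-states its variance under AR(1) noise
    X <- cbind(1, drop(memtrace:::ar1_noise(n, 1, 0.9, 1)))
    colnames(X) <- c("const", "task:x")
    E <- memtrace:::ar1_noise(n, v, 0.5, 1)
    Y <- 5 + E  # null task effect: intercept plus correlated noise only
  })
  inp <- as_fit_inputs(X, Y)
  fit <- fit_glm(inp$bold, inp$design, ar1 = "global")
  expect_equal(fit$rho, 0.5, tolerance = 0.1)
  # whitening deflates the inflated null t variance of correlated noise
  fit_off <- fit_glm(inp$bold, inp$design, ar1 = "off")
  t_white <- as.numeric(contrast_map(fit, c("task:x" = 1))$t)
  t_off <- as.numeric(contrast_map(fit_off, c("task:x" = 1))$t)
  expect_lt(abs(sd(t_white) - 1), 0.25)
  expect_gt(sd(t_off), sd(t_white))
})

test_that("null t-statistics follow the reference Student-t distribution", {
  withr::with_seed(8, {
    n <- 60
    v <- 2000
    X <- cbind(1, rnorm(n), rnorm(n))
    colnames(X) <- c("const", "task:a", "task:b")
    Y <- matrix(rnorm(n * v), n, v)
  })
  inp <- as_fit_inputs(X, Y)
  fit <- fit_glm(inp$bold, inp$design, ar1 = "off")
  tv <- as.numeric(contrast_map(fit, c("task:a" = 1))$t)
  ks <- suppressWarnings(stats::ks.test(tv, "pt", df = fit$dof))
  expect_gt(ks$p.value, 0.01)
})

test_that("contrasts are linear and validate their weights", {
  toy <- glm_toy(seed = 4)
  inp <- as_fit_inputs(toy$X, toy$Y)
  fit <- fit_glm(inp$bold, inp$design, ar1 = "off")
  m1 <- contrast_map(fit, c("task:x1" = 1))
  m2 <- contrast_map(fit, c("task:x1" = -1))
  expect_equal(as.numeric(m1$t), -as.numeric(m2$t))
  expect_equal(as.numeric(m1$beta), -as.numeric(m2$beta))
  expect_error(contrast_map(fit, rep(0, 5)), "all-zero")
  expect_warning(contrast_map(fit, c(1, 1, 0, 0, 0)), "drift/constant")
  expect_error(contrast_map(fit, c("nonexistent" = 1)), "unknown")
})

test_that("trialwise t-patterns match the scalar regression oracle", {
  spec <- tiny_spec(n_items_old = 4, n_encoding_runs = 1,
                    n_recognition_runs = 1, grid_shape = c(10, 10, 10))
  ev <- events_phase(sim_events(spec, seed = 9), "encoding")
  X <- build_design(ev, tr = spec$tr, mode = "trialwise")
  withr::with_seed(10, {
    Y <- matrix(rnorm(nrow(X) * 6), nrow(X), 6)
  })
  fullY <- matrix(0, nrow(X), 1000)
  fullY[, 1:6] <- Y
  fit <- fit_glm(bold_run(fullY, c(10, 10, 10), spec$tr), X, ar1 = "off")
  pat <- trial_patterns(fit, phase = "encoding")
  # lm oracle, voxel by voxel
  for (vox in 1:3) {
    lmfit <- lm(Y[, vox] ~ unclass(X) - 1)
    tt <- summary(lmfit)$coefficients[, "t value"]
    expect_equal(unname(pat[, vox]),
                 unname(tt[seq_len(nrow(pat))]), tolerance = 1e-8)
  }
})

test_that("pattern extraction demands a trialwise design", {
  spec <- tiny_spec(n_items_old = 4)
  ev <- sim_events(spec, seed = 11)
  X <- build_design(ev, tr = spec$tr, mode = "condition")
  withr::with_seed(1, {
    bold <- bold_run(matrix(rnorm(nrow(X) * 8), nrow(X), 8),
                     c(2, 2, 2), spec$tr)
  })
  fit <- fit_glm(bold, X, ar1 = "off")
  expect_error(trial_patterns(fit), "trialwise")
})
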