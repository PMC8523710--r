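test_that("Welch test matches the textbook formulas", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(3, 4, 5, 6, 7)
  res <- welch_t(a, b)
  # hand computation: means 3 and 5, both variances 2.5
  se <- sqrt(2.5 / 5 + 2.5 / 5)
  expect_equal(res$t, (3 - 5) / se)
  expect_equal(res$df, (0.5 + 0.5)^2 / (0.5^2 / 4 + 0.5^2 / 4))
  expect_equal(res$p, 2 * pt(-abs(res$t), res$df))
  expect_equal(res$cohen_d, -2 / sqrt(2.5))

  # antisymmetry under sample swap
  rev <- welch_t(b, a)
  expect_equal(rev$t, -res$t)
  expect_equal(rev$p, res$p)

  # identical samples: zero statistic
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$cohen_d, 0)
})

test_that("Welch equals Student's t for equal sizes and variances", {
  withr::with_seed(4, {
    a <- rnorm(12)
    b <- rnorm(12) + 0.5
  })
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)  # force equal variance
  res <- welch_t(a, b)
  student <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(student$statistic), tolerance = 1e-10)
  expect_equal(res$df, unname(student$parameter), tolerance = 1e-10)
})

test_that("degenerate Welch inputs follow the zero-variance contract", {
  expect_equal(welch_t(rep(1, 3), rep(1, 4))$t, 0)
  expect_error(welch_t(rep(1, 3), rep(2, 4)), "constant")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Tukey fences flag exactly the extreme points", {
  x <- c(1:9, 100)
  expect_equal(which(tukey_outliers(x)), 10L)
  expect_false(any(tukey_outliers(rep(5, 6))))
  expect_false(any(tukey_outliers(c(-2, -1, 0, 1, 2))))
  expect_error(tukey_outliers(1:3), "at least 4")
})

test_that("Pearson test agrees with the covariance-formula oracle", {
  withr::with_seed(9, {
    x <- rnorm(10)
    y <- 0.5 * x + rnorm(10)
  })
  res <- pearson_cor_test(x, y)
  all_row <- res[res$subset == "all", ]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(all_row$r, r_hand, tolerance = 1e-12)
  expect_equal(all_row$t, r_hand * sqrt(8 / (1 - r_hand^2)), tolerance = 1e-10)
  expect_equal(all_row$df, 8)

  expect_equal(pearson_cor_test(x, x)$r[1], 1)
  expect_equal(pearson_cor_test(x, -2 * x)$r[1], -1)
  expect_error(pearson_cor_test(x, rep(1, 10)), "variance")
})

test_that("outlier-trimmed correlation removes flagged points", {
  x <- c(rnorm(12), 10)
  y <- c(rnorm(12), -10)
  res <- pearson_cor_test(x, y)
  trimmed <- res[res$subset == "tukey_trimmed", ]
  expect_lt(trimmed$n, 13)  # the planted extreme pair is gone
  expect_gt(trimmed$r, res$r[res$subset == "all"])  # it drove r negative
})

test_that("factorial interaction recovers flat and crossed cell patterns", {
  cells <- expand.grid(drug = c("PLAC", "YOH"), delay = c("1d", "28d"))
  flat <- tibble::tibble(drug = rep(cells$drug, each = 3),
                         delay = rep(cells$delay, each = 3),
                         value = 2)
  res <- factorial_interaction(flat)
  expect_equal(res$contrast, 0)
  expect_equal(res$F, 0)

  # crossed noiseless pattern: PLAC 3 -> 1, YOH 3 -> 3
  crossed <- tibble::tibble(
    drug = rep(cells$drug, each = 3),
    delay = rep(cells$delay, each = 3),
    value = rep(c(3, 3, 1, 3), each = 3))
  res2 <- factorial_interaction(crossed)
  expect_equal(res2$contrast, 2)
  expect_lt(res2$p, 1e-10)
  expect_equal(res2$partial_eta_sq, 1)
})

test_that("factorial interaction agrees with aov and rejects empty cells", {
  withr::with_seed(12, {
    d <- tibble::tibble(drug = rep(c("PLAC", "YOH"), each = 10),
                        delay = rep(rep(c("1d", "28d"), each = 5), 2),
                        value = rnorm(20))
  })
  res <- factorial_interaction(d)
  fit <- summary(aov(value ~ drug * delay, data = d))[[1]]
  int_row <- grep("drug:delay", rownames(fit))
  expect_equal(res$F, fit[int_row, "F value"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$p, fit[int_row, "Pr(>F)"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(factorial_interaction(d[d$drug == "PLAC" | d$delay == "1d", ]),
               "empty")
})
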