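test_that("chance performance gives zero sensitivity and neutral criterion", {
  res <- d_prime(30, 30, 60, 60, correction = "none")
  expect_equal(res$d_prime, 0)
  expect_equal(res$criterion, 0)
})

test_that("d-prime matches the inverse-normal definition at high precision", {
  # rates chosen so the true value is exactly 2 (H = pnorm(1), FA = pnorm(-1))
  res <- d_prime(0.8413447461 * 100, 0.1586552539 * 100, 100, 100,
                 correction = "none")
  expect_equal(res$d_prime, 2, tolerance = 1e-5)
  expect_equal(res$criterion, 0, tolerance = 1e-5)
})

test_that("log-linear correction reproduces the corrected-rate oracle", {
  res <- d_prime(58, 0, 60, 60, correction = "loglinear")
  expect_equal(res$hit_rate, 58.5 / 61)
  expect_equal(res$fa_rate, 0.5 / 61)
  expect_equal(res$d_prime, qnorm(58.5 / 61) - qnorm(0.5 / 61),
               tolerance = 1e-12)
  expect_equal(res$d_prime, 4.14, tolerance = 1e-3)
})

test_that("extreme rates error without correction and clamp otherwise", {
  expect_error(d_prime(60, 0, 60, 60, correction = "none"), "0 or 1")
  res <- d_prime(60, 0, 60, 60, correction = "clamp")
  expect_true(is.finite(res$d_prime))
  expect_equal(res$hit_rate, 1 - 1 / 120)
  expect_true(res$correction_applied)
})

test_that("d-prime is monotone in hits and antitone in false alarms, and
           rate-invariant to sample size", {
  base <- d_prime(40, 10, 60, 60, correction = "none")$d_prime
  expect_gt(d_prime(45, 10, 60, 60, correction = "none")$d_prime, base)
  expect_lt(d_prime(40, 15, 60, 60, correction = "none")$d_prime, base)
  doubled <- d_prime(80, 20, 120, 120, correction = "none")$d_prime
  expect_equal(doubled, base, tolerance = 1e-12)
})

test_that("confidence weighting scales hit counts as specified", {
  lv <- response_levels()
  # 8-trial toy table, hand-scored: old items answered rather_old (w 0.5),
  # definitely_old (w 1), rather_new, definitely_new; new items one FA
  resp <- tibble::tibble(
    subject = "s1",
    oldness = rep(c("old", "new"), each = 4),
    response = factor(c("rather_old", "definitely_old", "rather_new",
                        "definitely_new",
                        "definitely_new", "definitely_new", "rather_old",
                        "definitely_new"), levels = lv, ordered = TRUE))
  w <- c(definitely = 1, rather = 0.5)
  out <- weighted_d_prime(resp, w)
  # weighted hits = 0.5 + 1 = 1.5 of 4; weighted FA = 0.5 of 4
  expect_equal(out$hit_rate, (1.5 + 0.5) / 5)
  expect_equal(out$fa_rate, (0.5 + 0.5) / 5)
  expect_equal(out$d_prime, qnorm(2 / 5) - qnorm(1 / 5))

  # all-definite responding makes weighting a no-op
  resp2 <- resp
  resp2$response <- factor(ifelse(resp$oldness == "old", "definitely_old",
                                  "definitely_new"), levels = lv,
                           ordered = TRUE)
  expect_equal(weighted_d_prime(resp2, w)$d_prime,
               sdt_summary(resp2)$d_prime)

  # uniform rather_old responses on old items halve the weighted hit rate
  resp3 <- resp
  resp3$response <- factor(ifelse(resp$oldness == "old", "rather_old",
                                  "definitely_new"), levels = lv,
                           ordered = TRUE)
  out3 <- weighted_d_prime(resp3, w)
  raw_h <- 4 / 4
  expect_equal(out3$hit_rate, (0.5 * raw_h * 4 + 0.5) / 5)
})

test_that("count tabulation respects the hits + misses = n_old identity", {
  spec <- tiny_spec()
  eff <- effect_spec(behavior = uniform_behavior(1.5, 0.2))
  resp <- sim_responses(flat_group(6), spec, eff, seed = 2)
  cnt <- recognition_counts(resp)
  expect_equal(cnt$hits + cnt$misses, cnt$n_old)
  expect_equal(cnt$false_alarms + cnt$correct_rejections, cnt$n_new)
  expect_equal(cnt$n_old, rep(spec$n_items_old, 6))
})
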