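#' Welch's two-sample t-test with effect size
#'
#' Wraps `stats::t.test(var.equal = FALSE)` (Welch-Satterthwaite degrees of
#' freedom) and adds Cohen's d computed against the pooled standard
#' deviation. When both samples are constant with equal means the statistic
#' is defined as 0 (p = 1); constant samples with unequal means are an error.
#'
#' @param a,b Numeric samples (each of length >= 2, finite).
#' @return One-row tibble: `estimate` (mean difference a - b), `t`, `df`,
#'   `p`, `cohen_d`.
#' @export
welch_t <- function(a, b) {
  mt_validate(length(a) >= 2 && length(b) >= 2,
              "each sample needs at least 2 observations")
  mt_validate(all(is.finite(a)) && all(is.finite(b)),
              "samples must be finite")
  va <- var(a)
  vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(estimate = 0, t = 0,
                            df = length(a) + length(b) - 2, p = 1,
                            cohen_d = 0))
    }
    mt_stop("both samples are constant with different means",
            class = "memtrace_degenerate_error")
  }
  ht <- t.test(a, b, var.equal = FALSE)
  sp <- sqrt(((length(a) - 1) * va + (length(b) - 1) * vb) /
               (length(a) + length(b) - 2))
  tibble::tibble(estimate = mean(a) - mean(b),
                 t = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 cohen_d = (mean(a) - mean(b)) / sp)
}

#' Tukey's fence rule for outliers
#'
#' Flags observations outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#'
#' @param x Numeric sample of length >= 4.
#' @return Logical mask, `TRUE` for outliers.
#' @examples
#' tukey_outliers(c(1:9, 100))
#' @export
tukey_outliers <- function(x) {
  mt_validate(length(x) >= 4, "need at least 4 observations")
  q <- quantile(x, c(0.25, 0.75), names = FALSE, na.rm = FALSE)
  iqr <- q[2] - q[1]
  x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
}

#' Pearson correlation test, with and without Tukey-trimmed outliers
#'
#' Wraps `stats::cor.test` and repeats the test after removing observations
#' flagged by [tukey_outliers()] on either variable.
#'
#' @param x,y Numeric samples (n >= 3, finite, non-constant).
#' @return Tibble with rows `all` and `tukey_trimmed`: `subset`, `n`, `r`,
#'   `t`, `df`, `p`.
#' @export
pearson_cor_test <- function(x, y) {
  mt_validate(length(x) == length(y), "`x` and `y` must have equal length")
  mt_validate(length(x) >= 3, "need at least 3 observations")
  mt_validate(all(is.finite(x)) && all(is.finite(y)), "samples must be finite")
  mt_validate(var(x) > 0 && var(y) > 0, "zero variance in `x` or `y`")
  one <- function(x, y, label) {
    ht <- suppressWarnings(cor.test(x, y, method = "pearson"))
    tibble::tibble(subset = label, n = length(x),
                   r = unname(ht$estimate), t = unname(ht$statistic),
                   df = unname(ht$parameter), p = ht$p.value)
  }
  keep <- !(tukey_outliers(x) | tukey_outliers(y))
  out <- one(x, y, "all")
  if (sum(keep) >= 3 && var(x[keep]) > 0 && var(y[keep]) > 0) {
    out <- dplyr::bind_rows(out, one(x[keep], y[keep], "tukey_trimmed"))
  }
  out
}

#' Two-by-two between-subjects factorial interaction test
#'
#' Fits the two-way between-subjects ANOVA `value ~ drug * delay` (via
#' `stats::aov`) and reports the interaction together with the cell-mean
#' interaction contrast `(PLAC 1d - PLAC 28d) - (YOH 1d - YOH 28d)` and
#' partial eta squared `SS_int / (SS_int + SS_error)`.
#'
#' @param data Tibble with one row per subject.
#' @param value,drug,delay Column names (strings) of the response and the two
#'   factors; factor columns must contain exactly the levels PLAC/YOH and
#'   1d/28d.
#' @return One-row tibble: `contrast`, `F`, `df1`, `df2`, `p`,
#'   `partial_eta_sq`.
#' @export
factorial_interaction <- function(data, value = "value", drug = "drug",
                                  delay = "delay") {
  d <- data.frame(value = data[[value]],
                  drug = factor(data[[drug]], levels = c("PLAC", "YOH")),
                  delay = factor(data[[delay]], levels = c("1d", "28d")))
  mt_validate(!anyNA(d$drug) && !anyNA(d$delay),
              "drug must be PLAC/YOH and delay 1d/28d")
  tab <- table(d$drug, d$delay)
  if (any(tab == 0)) mt_stop("empty design cell", class = "memtrace_design_error")
  mt_validate(all(tab >= 2), "need at least 2 subjects per cell")
  fit <- aov(value ~ drug * delay, data = d,
             contrasts = list(drug = "contr.sum", delay = "contr.sum"))
  sm <- summary(fit)[[1]]
  row <- grep("drug:delay", rownames(sm))
  err <- grep("Residuals", rownames(sm))
  ss_int <- sm[row, "Sum Sq"]
  ss_err <- sm[err, "Sum Sq"]
  cm <- tapply(d$value, list(d$drug, d$delay), mean)
  contrast <- (cm["PLAC", "1d"] - cm["PLAC", "28d"]) -
    (cm["YOH", "1d"] - cm["YOH", "28d"])
  f_val <- sm[row, "F value"]
  p_val <- sm[row, "Pr(>F)"]
  flat <- (ss_int + ss_err) < 1e-12 * max(1, mean(d$value)^2)
  if (flat) {  # fully flat design: define F = 0
    f_val <- 0
    p_val <- 1
  }
  tibble::tibble(contrast = unname(contrast), F = unname(f_val),
                 df1 = sm[row, "Df"], df2 = sm[err, "Df"],
                 p = unname(p_val),
                 partial_eta_sq = if (flat) 0 else
                   unname(ss_int / (ss_int + ss_err)))
}
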