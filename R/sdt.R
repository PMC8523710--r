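#' Signal-detection sensitivity and bias from recognition counts
#'
#' Computes `d' = qnorm(H) - qnorm(FA)` and criterion
#' `c = -(qnorm(H) + qnorm(FA)) / 2` from hit and false-alarm counts, after
#' correcting extreme rates. The default log-linear correction adds 0.5 to
#' both counts and 1 to both totals regardless of extremity; `clamp` replaces
#' 0 and 1 rates with `1/(2n)` and `1 - 1/(2n)`; `none` leaves rates as they
#' are and errors on 0/1 rates (the statistic would be infinite).
#'
#' @param hits,false_alarms Counts (vectors allowed).
#' @param n_old,n_new Numbers of old and new trials.
#' @param correction `"loglinear"`, `"clamp"` or `"none"`.
#' @return Tibble with `hit_rate`, `fa_rate`, `d_prime`, `criterion`,
#'   `correction_applied`.
#' @examples
#' d_prime(51, 3, 60, 60)
#' @export
d_prime <- function(hits, false_alarms, n_old, n_new,
                    correction = c("loglinear", "clamp", "none")) {
  correction <- match.arg(correction)
  mt_validate(all(n_old > 0) && all(n_new > 0),
              "`n_old` and `n_new` must be positive")
  mt_validate(all(hits >= 0 & hits <= n_old),
              "`hits` must lie in [0, n_old]")
  mt_validate(all(false_alarms >= 0 & false_alarms <= n_new),
              "`false_alarms` must lie in [0, n_new]")
  rates <- correct_rates(hits, false_alarms, n_old, n_new, correction)
  zh <- qnorm(rates$h)
  zf <- qnorm(rates$f)
  if (any(!is.finite(zh) | !is.finite(zf))) {
    mt_stop("hit or false-alarm rate of 0 or 1 with `correction = \"none\"`",
            class = "memtrace_sdt_error")
  }
  tibble::tibble(hit_rate = rates$h, fa_rate = rates$f,
                 d_prime = zh - zf, criterion = -(zh + zf) / 2,
                 correction_applied = rates$applied)
}

correct_rates <- function(hits, fa, n_old, n_new, correction) {
  if (correction == "loglinear") {
    list(h = (hits + 0.5) / (n_old + 1), f = (fa + 0.5) / (n_new + 1),
         applied = rep(TRUE, length(hits)))
  } else if (correction == "clamp") {
    h <- hits / n_old
    f <- fa / n_new
    applied <- h %in% c(0, 1) | f %in% c(0, 1)
    h <- pmin(pmax(h, 1 / (2 * n_old)), 1 - 1 / (2 * n_old))
    f <- pmin(pmax(f, 1 / (2 * n_new)), 1 - 1 / (2 * n_new))
    list(h = h, f = f, applied = applied)
  } else {
    list(h = hits / n_old, f = fa / n_new,
         applied = rep(FALSE, length(hits)))
  }
}

#' Tabulate recognition counts per subject
#'
#' @param responses Trial table with `subject`, `oldness`, `response` (see
#'   [sim_responses()]); an optional `emotion` split is controlled by
#'   `by_emotion`.
#' @param by_emotion Split counts by emotion class.
#' @return Tibble with `subject` (, `emotion`), `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`, `n_old`, `n_new`.
#' @export
recognition_counts <- function(responses, by_emotion = FALSE) {
  old_resp <- responses$response %in% c("rather_old", "definitely_old")
  keys <- c("subject", if (by_emotion) "emotion")
  responses |>
    dplyr::mutate(.said_old = old_resp) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      hits = sum(.data$oldness == "old" & .data$.said_old),
      misses = sum(.data$oldness == "old" & !.data$.said_old),
      false_alarms = sum(.data$oldness == "new" & .data$.said_old),
      correct_rejections = sum(.data$oldness == "new" & !.data$.said_old),
      n_old = sum(.data$oldness == "old"),
      n_new = sum(.data$oldness == "new"),
      .groups = "drop")
}

#' Per-subject signal-detection summary, optionally confidence-weighted
#'
#' Unweighted: hit and false-alarm counts enter [d_prime()] directly. With
#' `weights`, each "old" response contributes its confidence weight (e.g.
#' `definitely = 1`, `rather = 0.5`) to a weighted hit / false-alarm count
#' before the same corrected d-prime computation.
#'
#' @inheritParams recognition_counts
#' @param weights `NULL` for unweighted counting, or a named numeric vector
#'   with entries `definitely` and `rather` in `[0, 1]`.
#' @param correction Passed to [d_prime()].
#' @return Tibble with one row per subject (x emotion) and the [d_prime()]
#'   columns, plus group labels if present in `responses`.
#' @export
sdt_summary <- function(responses, weights = NULL, by_emotion = FALSE,
                        correction = "loglinear") {
  keys <- c("subject", if (by_emotion) "emotion")
  if (is.null(weights)) {
    cnt <- recognition_counts(responses, by_emotion = by_emotion)
    res <- d_prime(cnt$hits, cnt$false_alarms, cnt$n_old, cnt$n_new,
                   correction = correction)
  } else {
    mt_validate(all(c("definitely", "rather") %in% names(weights)),
                "`weights` must name levels `definitely` and `rather`")
    w <- ifelse(responses$response == "definitely_old", weights[["definitely"]],
                ifelse(responses$response == "rather_old", weights[["rather"]], 0))
    cnt <- responses |>
      dplyr::mutate(.w = w) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(
        hits = sum(.data$.w[.data$oldness == "old"]),
        false_alarms = sum(.data$.w[.data$oldness == "new"]),
        n_old = sum(.data$oldness == "old"),
        n_new = sum(.data$oldness == "new"),
        .groups = "drop")
    res <- d_prime(cnt$hits, cnt$false_alarms, cnt$n_old, cnt$n_new,
                   correction = correction)
  }
  out <- dplyr::bind_cols(cnt[keys], res)
  lab <- unique(responses[intersect(c("subject", "drug", "delay"),
                                    names(responses))])
  if (ncol(lab) > 1) out <- dplyr::left_join(out, lab, by = "subject")
  out
}

#' @rdname sdt_summary
#' @export
weighted_d_prime <- function(responses, weights = c(definitely = 1, rather = 0.5),
                             by_emotion = FALSE, correction = "loglinear") {
  sdt_summary(responses, weights = weights, by_emotion = by_emotion,
              correction = correction)
}
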