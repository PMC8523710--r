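#' Simulate recognition responses from a signal-detection model
#'
#' For every recognition trial an internal evidence value is drawn from
#' `N(d', 1)` for old items and `N(0, 1)` for new items, where `d'` is the
#' subject's latent sensitivity for the item's emotion class (cell value plus
#' a between-subject trait deviation). The decision criterion sits at
#' `lambda = d'/2 + c` on the evidence axis (`c` = bias; `c = 0` is the
#' symmetric criterion) and two confidence criteria at
#' `lambda +/- confidence_offset` map evidence onto the four-point scale
#' "definitely new" / "rather new" / "rather old" / "definitely old".
#'
#' @param group A [group_table()] (or any tibble with `subject`, `drug`,
#'   `delay`).
#' @param spec A [cohort_spec()].
#' @param effects An [effect_spec()]; its `behavior` table supplies cell
#'   `d_prime` and `criterion`.
#' @param seed Integer seed.
#' @return Tibble with one row per subject x item: `subject`, `drug`,
#'   `delay`, `item_id`, `emotion`, `oldness`, `response` (ordered factor),
#'   plus the subject's latent `d_true` per emotion in attribute
#'   `latent` (a tibble, for generator-recovery checks).
#' @export
sim_responses <- function(group, spec, effects, seed) {
  items <- item_table(spec)
  lv <- response_levels()
  beh <- effects$behavior
  withr::with_seed(seed, {
    n_sub <- nrow(group)
    trait <- rnorm(n_sub, 0, effects$subject_sd_dprime)
    crit_dev <- rnorm(n_sub, 0, effects$subject_sd_criterion)

    # subject x emotion latent parameters from the planted cell table
    lat <- tidyr::crossing(group[, c("subject", "drug", "delay")],
                           emotion = unique(items$emotion))
    cell_key <- paste(beh$drug, beh$delay, beh$emotion)
    hit <- match(paste(lat$drug, lat$delay, lat$emotion), cell_key)
    mt_validate(!anyNA(hit), "behaviour table does not cover all cells")
    si <- match(lat$subject, group$subject)
    lat$d_true <- pmax(beh$d_prime[hit] + trait[si], 0)
    lat$criterion_true <- beh$criterion[hit] + crit_dev[si]

    # one row per subject x item; vectorised evidence draw
    out <- tidyr::crossing(group[, c("subject", "drug", "delay")], items)
    li <- match(paste(out$subject, out$emotion),
                paste(lat$subject, lat$emotion))
    d_true <- lat$d_true[li]
    lambda <- d_true / 2 + lat$criterion_true[li]
    ev <- rnorm(nrow(out), ifelse(out$oldness == "old", d_true, 0), 1)
    off <- effects$confidence_offset
    level_idx <- 1L + (ev > lambda - off) + (ev > lambda) + (ev > lambda + off)
    out <- out[, c("subject", "drug", "delay", "item_id", "emotion",
                   "oldness")]
    out$response <- factor(lv[level_idx], levels = lv, ordered = TRUE)
    attr(out, "latent") <- lat[, c("subject", "emotion", "d_true",
                                   "criterion_true")]
    out
  })
}

#' Four-point recognition response scale
#' @return Character vector of the ordered response levels.
#' @export
response_levels <- function() {
  c("definitely_new", "rather_new", "rather_old", "definitely_old")
}
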