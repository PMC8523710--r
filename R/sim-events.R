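#' Simulate event tables for encoding and recognition runs
#'
#' Encoding runs each present every old item exactly once in a fresh random
#' order; recognition runs jointly present all old and all new items exactly
#' once, interleaved at random (the allocation of items to recognition runs is
#' uniform). Each trial shows the picture for `spec$event_duration` seconds and
#' is followed by a fixation interval drawn uniformly from
#' `iti_base +/- iti_jitter`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give identical tables.
#' @param lead_in,lead_out Dead time (s) before the first onset and after the
#'   last event, used to size the scan window.
#' @return A tibble with columns `phase` ("encoding"/"recognition"), `run`,
#'   `onset`, `duration`, `item_id`, `emotion`, `oldness`. The attribute
#'   `n_scans` holds a named integer vector of scans per `phase:run`.
#' @examples
#' ev <- sim_events(cohort_spec(n_per_group = 2), seed = 1)
#' table(ev$phase, ev$run)
#' @export
sim_events <- function(spec, seed, lead_in = 6, lead_out = 16) {
  mt_validate(inherits(spec, "cohort_spec"), "`spec` must be a cohort_spec")
  items <- item_table(spec)
  old <- items[items$oldness == "old", ]
  withr::with_seed(seed, {
    enc <- lapply(seq_len(spec$n_encoding_runs), function(r) {
      ord <- sample.int(nrow(old))
      build_run(old[ord, ], "encoding", r, spec, lead_in)
    })
    rec_items <- items[sample.int(nrow(items)), ]
    splits <- sort(rep_len(seq_len(spec$n_recognition_runs), nrow(rec_items)))
    rec <- lapply(seq_len(spec$n_recognition_runs), function(r) {
      build_run(rec_items[splits == r, ], "recognition", r, spec, lead_in)
    })
    runs <- c(enc, rec)
  })
  out <- dplyr::bind_rows(lapply(runs, `[[`, "events"))
  ns <- vapply(runs, `[[`, integer(1), "n_scans")
  names(ns) <- vapply(runs, `[[`, character(1), "key")
  # final scan window check: every event ends inside its run
  attr(out, "n_scans") <- ns
  out
}

build_run <- function(rows, phase, run, spec, lead_in) {
  n <- nrow(rows)
  iti <- runif(n, spec$iti_base - spec$iti_jitter,
               spec$iti_base + spec$iti_jitter)
  onsets <- lead_in + cumsum(c(0, (spec$event_duration + iti)[-n]))
  dur_total <- onsets[n] + spec$event_duration + 16
  ev <- tibble::tibble(phase = phase, run = as.integer(run),
                       onset = onsets, duration = spec$event_duration,
                       item_id = rows$item_id, emotion = rows$emotion,
                       oldness = rows$oldness)
  list(events = ev, n_scans = as.integer(ceiling(dur_total / spec$tr)),
       key = paste0(phase, ":", run))
}

#' Scans per run of an event table
#'
#' @param events An event table from [sim_events()].
#' @param phase Optional phase to restrict to.
#' @return Named integer vector of scans per run.
#' @export
run_scans <- function(events, phase = NULL) {
  ns <- attr(events, "n_scans")
  mt_validate(!is.null(ns), "event table carries no `n_scans` attribute")
  if (!is.null(phase)) ns <- ns[startsWith(names(ns), paste0(phase, ":"))]
  ns
}

#' Restrict an event table to one phase, keeping scan metadata
#'
#' @inheritParams run_scans
#' @export
events_phase <- function(events, phase) {
  out <- events[events$phase == phase, , drop = FALSE]
  attr(out, "n_scans") <- run_scans(events, phase)
  out
}
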