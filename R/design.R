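#' Discrete-cosine drift basis for high-pass filtering
#'
#' Returns the DCT components with period longer than `cutoff` seconds
#' (frequencies below `1/cutoff` Hz), the standard drift model behind a
#' high-pass filter: component k has period `2 * n * tr / k`, and k runs to
#' `floor(2 * n * tr / cutoff)`.
#'
#' @param n_scans Number of scans.
#' @param tr Repetition time, seconds.
#' @param cutoff High-pass cutoff, seconds (default 128).
#' @return `n_scans x K` matrix (possibly zero columns), unit-normed columns.
#' @export
dct_basis <- function(n_scans, tr, cutoff = 128) {
  k_max <- floor(2 * n_scans * tr / cutoff)
  if (k_max < 1) return(matrix(numeric(0), n_scans, 0))
  t <- seq_len(n_scans) - 0.5
  out <- vapply(seq_len(k_max),
                function(k) cos(pi * k * t / n_scans), numeric(n_scans))
  sweep(out, 2, sqrt(colSums(out^2)), "/")
}

#' Build a first-level design matrix
#'
#' Constructs the scans x regressors matrix for one subject across
#' concatenated runs. In `condition` mode, encoding trials contribute one
#' regressor per run and emotion and recognition trials one regressor per
#' emotion and oldness category; in `trialwise` mode every trial is its own
#' regressor (the beta-series model behind pattern analyses). Task regressors
#' are event boxcars convolved with the canonical HRF. Each run additionally
#' receives a constant and a block of discrete-cosine drift regressors
#' implementing the high-pass filter.
#'
#' @param events Event table (see [sim_events()]); may span both phases or be
#'   restricted with [events_phase()].
#' @param n_scans Named integer vector of scans per `phase:run` (defaults to
#'   the table's `n_scans` attribute).
#' @param tr Repetition time, seconds.
#' @param mode `"condition"` or `"trialwise"`.
#' @param hp_cutoff High-pass cutoff in seconds (default 128); `Inf` disables
#'   drift regressors.
#' @param include_constants Add one constant per run (default TRUE).
#' @return A `design_matrix`: numeric matrix with attributes `kind` (one of
#'   `"task"`, `"drift"`, `"run_constant"` per column), `col_info` (tibble of
#'   task-column metadata), `run_rows`, `tr`.
#' @export
build_design <- function(events, n_scans = NULL, tr,
                         mode = c("condition", "trialwise"),
                         hp_cutoff = 128, include_constants = TRUE) {
  mode <- match.arg(mode)
  if (is.null(n_scans)) n_scans <- attr(events, "n_scans")
  mt_validate(!is.null(n_scans) && !is.null(names(n_scans)),
              "`n_scans` must be a named vector of scans per phase:run")
  keys <- sprintf("%s:%s", events$phase, events$run)
  mt_validate(all(keys %in% names(n_scans)),
              "every event's phase:run needs an `n_scans` entry")
  run_keys <- names(n_scans)
  offsets <- c(0, cumsum(n_scans))[seq_along(n_scans)]
  names(offsets) <- run_keys
  total <- sum(n_scans)

  blocks <- list()
  info <- list()
  for (rk in run_keys) {
    ev <- events[keys == rk, , drop = FALSE]
    ns <- n_scans[[rk]]
    mt_validate(all(ev$onset + ev$duration <= ns * tr),
                sprintf("event beyond scan window in run %s", rk))
    if (nrow(ev) == 0L) next
    if (mode == "trialwise") {
      X <- event_regressor_matrix(ev$onset, ev$duration, ns, tr)
      nm <- paste0("task:", ev$item_id, ":", ev$phase, ":run", ev$run)
      inf <- tibble::tibble(name = nm, item_id = ev$item_id,
                            phase = ev$phase, run = ev$run,
                            emotion = ev$emotion, oldness = ev$oldness)
    } else {
      if (ev$phase[1] == "encoding") {
        grp <- paste0("task:enc:run", ev$run, ":", ev$emotion)
      } else {
        grp <- paste0("task:rec:", ev$emotion, ":", ev$oldness)
      }
      levels_ <- unique(grp)
      X <- vapply(levels_, function(g) {
        sel <- grp == g
        convolve_events(ev$onset[sel], ev$duration[sel],
                        rep(1, sum(sel)), ns, tr)
      }, numeric(ns))
      nm <- levels_
      inf <- tibble::tibble(name = nm,
                            item_id = NA_character_,
                            phase = ev$phase[1],
                            run = if (ev$phase[1] == "encoding") {
                              as.integer(sub(".*run(\\d+).*", "\\1", nm))
                            } else NA_integer_,
                            emotion = sub(".*(negative|neutral).*", "\\1", nm),
                            oldness = ifelse(grepl(":old$", nm), "old",
                                             ifelse(grepl(":new$", nm), "new",
                                                    NA_character_)))
    }
    full <- matrix(0, total, ncol(X))
    full[offsets[[rk]] + seq_len(ns), ] <- X
    colnames(full) <- nm
    blocks[[rk]] <- full
    info[[rk]] <- inf
  }
  task <- do.call(cbind, blocks)
  if (is.null(task)) task <- matrix(numeric(0), total, 0)
  col_info <- dplyr::bind_rows(info)
  if (mode == "condition" && ncol(task) > 0) {
    # merge recognition condition columns that recur across runs
    dup <- duplicated(colnames(task))
    if (any(dup)) {
      merged <- vapply(unique(colnames(task)), function(nm) {
        rowSums(task[, colnames(task) == nm, drop = FALSE])
      }, numeric(total))
      task <- merged
      col_info <- col_info[!duplicated(col_info$name), , drop = FALSE]
    }
  }

  nuis <- list()
  kinds <- rep("task", ncol(task))
  for (rk in run_keys) {
    ns <- n_scans[[rk]]
    rows <- offsets[[rk]] + seq_len(ns)
    if (include_constants) {
      cst <- matrix(0, total, 1, dimnames = list(NULL, paste0("const:", rk)))
      cst[rows, 1] <- 1
      nuis[[paste0("c", rk)]] <- cst
      kinds <- c(kinds, "run_constant")
    }
    if (is.finite(hp_cutoff)) {
      D <- dct_basis(ns, tr, hp_cutoff)
      if (ncol(D) > 0) {
        full <- matrix(0, total, ncol(D))
        full[rows, ] <- D
        colnames(full) <- paste0("drift:", rk, ":k", seq_len(ncol(D)))
        nuis[[paste0("d", rk)]] <- full
        kinds <- c(kinds, rep("drift", ncol(D)))
      }
    }
  }
  X <- cbind(task, do.call(cbind, nuis))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    mt_stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                    paste(bad, collapse = ", ")),
            class = "memtrace_design_error")
  }
  run_rows <- lapply(run_keys, function(rk) offsets[[rk]] + seq_len(n_scans[[rk]]))
  names(run_rows) <- run_keys
  structure(X, class = c("design_matrix", "matrix"),
            kind = kinds, col_info = col_info, run_rows = run_rows,
            tr = tr, mode = mode, hp_cutoff = hp_cutoff)
}

#' @export
print.design_matrix <- function(x, ...) {
  k <- attr(x, "kind")
  cat(sprintf("<design_matrix> %d scans x %d regressors (%d task, %d drift, %d constant), mode=%s\n",
              nrow(x), ncol(x), sum(k == "task"), sum(k == "drift"),
              sum(k == "run_constant"), attr(x, "mode")))
  invisible(x)
}
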