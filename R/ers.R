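#' Searchlight encoding-retrieval similarity maps
#'
#' For every searchlight sphere, correlates each old item's encoding pattern
#' (final encoding run) with recognition patterns, Fisher z-transforms the
#' correlations, and averages over items:
#'
#' * `trial_specific`: EOS is the mean z-correlation between an item's
#'   encoding pattern and *its own* recognition pattern; ENS pairs each
#'   encoding pattern with its *matched new* item's recognition pattern.
#' * `cross_trial`: EOS averages all non-corresponding old pairings
#'   (encoding item i vs. recognition of old item j, i != j); ENS averages
#'   all encoding-by-new pairings.
#'
#' The reinstatement index is `ERS = EOS - ENS`, written at each sphere's
#' centre voxel.
#'
#' @param enc [trial_patterns()] of the final encoding run (old items).
#' @param rec [trial_patterns()] of the recognition phase (old + new items).
#' @param pairing Tibble with `old_item`, `new_item` (the supplied matching).
#' @param searchlight A [build_searchlight()].
#' @param variant `"trial_specific"` or `"cross_trial"`.
#' @return Object of class `ers_maps`: list of [stat_map()]s `eos`, `ens`,
#'   `ers` (all Fisher z), plus `variant` and `pairing`.
#' @export
ers_map <- function(enc, rec, pairing, searchlight,
                    variant = c("trial_specific", "cross_trial")) {
  variant <- match.arg(variant)
  enc_info <- attr(enc, "info")
  rec_info <- attr(rec, "info")
  miss_enc <- setdiff(pairing$old_item, enc_info$item_id)
  rec_old_ids <- rec_info$item_id[rec_info$oldness == "old"]
  rec_new_ids <- rec_info$item_id[rec_info$oldness == "new"]
  miss_old <- setdiff(pairing$old_item, rec_old_ids)
  miss_new <- setdiff(pairing$new_item, rec_new_ids)
  if (length(c(miss_enc, miss_old, miss_new)) > 0) {
    mt_stop(paste("unmatched items:",
                  paste(unique(c(miss_enc, miss_old, miss_new)), collapse = ", ")),
            class = "memtrace_pairing_error")
  }
  E <- enc[match(pairing$old_item, enc_info$item_id), , drop = FALSE]
  Ro <- rec[match(pairing$old_item, rec_info$item_id), , drop = FALSE]
  Rn <- rec[match(pairing$new_item, rec_info$item_id), , drop = FALSE]

  sl <- searchlight
  n_ctr <- length(sl$centers)
  eos <- ens <- rep(NA_real_, n_ctr)
  for (i in seq_len(n_ctr)) {
    vox <- sl$idx[i, sl$valid[i, ]]
    E0 <- std_rows(E[, vox, drop = FALSE])
    R0 <- std_rows(Ro[, vox, drop = FALSE])
    N0 <- std_rows(Rn[, vox, drop = FALSE])
    if (variant == "trial_specific") {
      eos[i] <- mean(fisher_z(rowSums(E0 * R0)))
      ens[i] <- mean(fisher_z(rowSums(E0 * N0)))
    } else {
      Ceo <- tcrossprod(E0, R0)
      diag(Ceo) <- NA
      eos[i] <- mean(fisher_z(Ceo[!is.na(Ceo)]))
      ens[i] <- mean(fisher_z(tcrossprod(E0, N0)))
    }
  }
  dim3 <- sl$dim
  center_mask <- array(FALSE, dim3)
  center_mask[sl$centers] <- TRUE
  put <- function(v, kind) {
    full <- rep(NA_real_, prod(dim3))
    full[sl$centers] <- v
    stat_map(full, dim3, kind, center_mask,
             list(variant = variant, radius = sl$radius))
  }
  structure(list(eos = put(eos, "fisher_z"), ens = put(ens, "fisher_z"),
                 ers = put(eos - ens, "fisher_z"),
                 variant = variant, pairing = pairing),
            class = "ers_maps")
}

# centre and scale rows to unit norm; constant rows become all-zero so they
# contribute a zero correlation rather than NaN
std_rows <- function(M) {
  M <- M - rowMeans(M)
  nrm <- sqrt(rowSums(M^2))
  nrm[nrm < 1e-12] <- Inf
  M / nrm
}

#' @export
print.ers_maps <- function(x, ...) {
  v <- as.numeric(x$ers)
  cat(sprintf("<ers_maps variant=%s> %d centres, mean ERS %.4f\n",
              x$variant, sum(!is.na(v)), mean(v, na.rm = TRUE)))
  invisible(x)
}

#' ROI summary of an ERS result
#'
#' Mean EOS, ENS and ERS over sphere centres inside a mask.
#'
#' @param x An [ers_map()] result.
#' @param roi Logical 3D array.
#' @return One-row tibble with `eos`, `ens`, `ers`, `n_centers`.
#' @export
ers_roi_mean <- function(x, roi) {
  sel <- as.logical(roi) & !is.na(as.numeric(x$ers))
  tibble::tibble(eos = mean(as.numeric(x$eos)[sel]),
                 ens = mean(as.numeric(x$ens)[sel]),
                 ers = mean(as.numeric(x$ers)[sel]),
                 n_centers = sum(sel))
}
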