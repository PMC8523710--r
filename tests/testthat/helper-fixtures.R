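# shared fixture builders; everything is generated in code at test time

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_per_group = 2, grid_shape = c(12, 12, 12), n_items_old = 8,
         n_encoding_runs = 3, n_recognition_runs = 2, roi_size = 3),
    list(...))
  do.call(cohort_spec, args)
}

# a hand-buildable pattern matrix (items x voxels over a small grid)
make_pattern <- function(mat, items, phase, dim, oldness = "old",
                         run = 1L) {
  structure(mat, class = c("pattern_matrix", "matrix"),
            info = tibble::tibble(
              name = sprintf("task:%s:%s:run%d", items, phase, run),
              item_id = items, phase = phase, run = run,
              emotion = "neutral", oldness = oldness),
            dim3 = dim, mask = array(TRUE, dim))
}

# single-cell group table for behavioural simulations
flat_group <- function(n, drug = "PLAC", delay = "1d") {
  tibble::tibble(subject = sprintf("sub-%03d", seq_len(n)),
                 drug = drug, delay = delay)
}
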