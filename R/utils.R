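# internal helpers shared across modules

# consistent error helper: all user-facing errors carry a memtrace_* class so
# callers (and tests) can distinguish validation from runtime failures
mt_stop <- function(msg, class = "memtrace_error") {
  rlang::abort(msg, class = c(class, "memtrace_error"))
}

mt_validate <- function(ok, msg) {
  if (!isTRUE(ok)) mt_stop(msg, class = "memtrace_validation_error")
  invisible(TRUE)
}

# stable sub-seed derivation: keeps every stage's stream distinct under one
# master seed while staying inside .Machine$integer.max
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483629L) + 1L
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# linear index <-> (i,j,k) helpers for 3D grids (1-based)
coord_to_index <- function(coords, dim) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  coords[, 1L] + (coords[, 2L] - 1L) * dim[1L] +
    (coords[, 3L] - 1L) * dim[1L] * dim[2L]
}

index_to_coord <- function(idx, dim) {
  arrayInd(idx, .dim = dim)
}
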