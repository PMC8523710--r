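#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti that attach/recover the pipeline's metadata:
#' 4D data become [bold_run()]s (TR from the header's time pixdim), 3D data
#' become plain arrays or masks.
#'
#' @param x A [bold_run()], [stat_map()] or numeric array.
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size written into the header.
#' @return `write_nifti` returns `path` invisibly; `read_bold_nifti` a
#'   [bold_run()]; `read_mask_nifti` a logical array; `read_map_nifti` a
#'   [stat_map()].
#' @export
write_nifti <- function(x, path, voxel_size_mm = 3) {
  if (inherits(x, "bold_run")) {
    img <- RNifti::asNifti(as.array(x))
    RNifti::pixdim(img) <- c(rep(voxel_size_mm, 3), x$tr)
  } else if (inherits(x, "stat_map")) {
    arr <- unclass(x)
    attributes(arr) <- list(dim = dim(x))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  } else {
    img <- RNifti::asNifti(x * 1)
    RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  mt_validate(length(d) == 4, "expected a 4D volume")
  tr <- RNifti::pixdim(img)[4]
  bold_run(array(as.numeric(img), d), tr = tr)
}

#' @rdname write_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  mt_validate(length(dim(img)) == 3, "expected a 3D mask")
  array(as.numeric(img) != 0, dim(img))
}

#' @rdname write_nifti
#' @param kind Statistic kind recorded on the map.
#' @export
read_map_nifti <- function(path, kind = "beta") {
  img <- RNifti::readNifti(path)
  mt_validate(length(dim(img)) == 3, "expected a 3D map")
  v <- as.numeric(img)
  stat_map(v, dim(img), kind, mask = array(is.finite(v), dim(img)))
}

#' Read and write tab-separated event / participants / response tables
#'
#' The on-disk dialect is tab-separated UTF-8 with `n/a` for missing values.
#' `read_events` validates the required columns and restores the `n_scans`
#' attribute from a JSON sidecar written by `write_events`.
#'
#' @param events,x Tibble to write.
#' @param path File path (`.tsv`).
#' @return Read functions return tibbles; write functions the path,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  write_tsv_na(events, path)
  ns <- attr(events, "n_scans")
  if (!is.null(ns)) {
    jsonlite::write_json(as.list(ns), paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- read_tsv_na(path)
  need <- c("phase", "run", "onset", "duration", "item_id", "emotion", "oldness")
  missing <- setdiff(need, names(out))
  mt_validate(length(missing) == 0,
              paste("events table lacks column(s):", paste(missing, collapse = ", ")))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    ns <- unlist(jsonlite::read_json(side))
    attr(out, "n_scans") <- setNames(as.integer(ns), names(ns))
  }
  out
}

#' @rdname write_events
#' @export
write_table_tsv <- function(x, path) {
  write_tsv_na(x, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_participants <- function(path) {
  out <- read_tsv_na(path)
  need <- c("subject", "drug", "delay")
  missing <- setdiff(need, names(out))
  mt_validate(length(missing) == 0,
              paste("participants table lacks column(s):",
                    paste(missing, collapse = ", ")))
  out
}

write_tsv_na <- function(x, path) {
  df <- as.data.frame(x)
  df[] <- lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "n/a"
    col
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

read_tsv_na <- function(path) {
  mt_validate(file.exists(path), paste("file not found:", path))
  out <- read.delim(path, sep = "\t", na.strings = "n/a",
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in intersect(c("onset", "duration"), names(out))) {
    out[[nm]] <- as.numeric(out[[nm]])
  }
  tibble::as_tibble(out)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (or accepts a list) and validates the fields
#' the pipeline needs: a cohort block, optional effect overrides, analysis
#' settings (smoothing FWHM in mm, high-pass cutoff in seconds, AR(1) mode,
#' searchlight radius in voxels, permutation count) and a seed for every
#' stochastic stage.
#'
#' @param x Path to a YAML file, or a list.
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  mt_validate(is.list(cfg), "config must be a list or YAML file")
  defaults <- list(fwhm_mm = 8, hp_cutoff = 128, ar1 = "global",
                   radius = 3, n_perm = 1000, variant = "trial_specific")
  cfg$analysis <- utils::modifyList(defaults, cfg$analysis %||% list())
  mt_validate(!is.null(cfg$seed), "config must set `seed`")
  mt_validate(is.numeric(cfg$seed) && cfg$seed == floor(cfg$seed),
              "`seed` must be an integer")
  cohort_args <- cfg$cohort %||% list()
  cfg$cohort_spec <- do.call(cohort_spec, cohort_args)
  effect_args <- cfg$effects %||% list()
  cfg$effect_spec <- do.call(effect_spec, effect_args)
  mt_validate(cfg$analysis$n_perm >= 100, "`n_perm` must be at least 100")
  structure(cfg, class = "run_config")
}
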