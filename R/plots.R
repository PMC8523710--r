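#' Plot an axial slice of a statistic map
#'
#' @param object A [stat_map()].
#' @param slice Axial (z) slice index; defaults to the slice with the
#'   largest absolute in-mask value.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stat_map <- function(object, slice = NULL, ...) {
  d <- dim(object)
  v <- array(as.numeric(object), d)
  if (is.null(slice)) {
    strength <- apply(abs(v), 3, max, na.rm = TRUE)
    strength[!is.finite(strength)] <- -Inf
    slice <- which.max(strength)
  }
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.numeric(v[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s map, z = %d", attr(object, "kind"),
                                  slice),
                  fill = attr(object, "kind")) +
    ggplot2::theme_minimal()
}

#' Cell-mean plot of per-subject d-prime by drug and delay
#'
#' @param sdt An [sdt_summary()] tibble carrying `drug` and `delay`.
#' @return A ggplot object.
#' @export
plot_sdt_cells <- function(sdt) {
  mt_validate(all(c("drug", "delay", "d_prime") %in% names(sdt)),
              "`sdt` must carry drug, delay and d_prime columns")
  cells <- sdt |>
    dplyr::group_by(.data$drug, .data$delay) |>
    dplyr::summarise(mean_d = mean(.data$d_prime),
                     se = sd(.data$d_prime) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$delay, y = .data$mean_d,
                                      group = .data$drug,
                                      colour = .data$drug)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_d - .data$se,
                                          ymax = .data$mean_d + .data$se)) +
    ggplot2::labs(x = "retention delay", y = "d'", colour = "drug") +
    ggplot2::theme_minimal()
}
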