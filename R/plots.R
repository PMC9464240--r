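#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Copy-number distribution of a target library
#'
#' Histogram of deduplicated targets by genome-wide copy number (log10 x
#' axis), the view used to spot high-copy barcode-like targets.
#'
#' @param object A `target_library`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot target_library
#' @export
autoplot.target_library <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$records, ggplot2::aes(x = .data$copy_number)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "copy number (log10)", y = "deduplicated targets",
                  title = "Target copy-number distribution") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.target_library
#' @param lib A `target_library`.
#' @export
plot_copy_number <- function(lib, bins = 30) autoplot(lib, bins = bins)

#' Mismatch-stratified hit profile of a specificity screen
#'
#' Bar chart of hit counts per mismatch stratum for the subject genome and
#' each adulterant genome.
#'
#' @param object A `specificity_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot specificity_report
#' @export
autoplot.specificity_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$mismatches), y = .data$n,
                                   fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~genome) +
    ggplot2::labs(x = "protospacer mismatches", y = "sites",
                  title = paste("Specificity screen:", object$protospacer),
                  subtitle = if (object$passes) {
                    "PASS: no adulterant site within tolerance"
                  } else {
                    paste("FAIL:", paste(object$failing_genomes, collapse = ", "))
                  }) +
    ggplot2::theme_minimal()
}

#' Fluorescence time courses by group
#'
#' Mean +/- SD curves over the measurement grid, one line per group — the
#' standard view of a Cas12a reporter dilution series.
#'
#' @param data Long assay tibble (`group`, `replicate`, `timepoint_min`,
#'   `reading`).
#' @return A ggplot.
#' @export
plot_fluorescence <- function(data) {
  s <- data |>
    dplyr::group_by(.data$group, .data$timepoint_min) |>
    dplyr::summarise(mean = mean(.data$reading), sd = stats::sd(.data$reading),
                     .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$timepoint_min, y = .data$mean,
                                  colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             size = 0.2) +
    ggplot2::labs(x = "time (min)", y = "fluorescence (a.u.)",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Detection calls across the dilution ladder
#'
#' p-values per concentration (log10 x axis) with the significance threshold
#' and the called limit of detection.
#'
#' @param object An `lod_result` from [lod_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lod_result
#' @export
autoplot.lod_result <- function(object, ...) {
  df <- object$calls
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration,
                                        y = .data$p_value,
                                        colour = .data$detected)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed") +
    ggplot2::labs(x = "concentration (ng/uL, log10)", y = "p-value (log10)",
                  title = paste("LOD:", if (object$lod_reached) object$lod
                                else "not reached")) +
    ggplot2::theme_minimal()
  if (object$lod_reached) {
    p <- p + ggplot2::geom_vline(xintercept = object$lod, linetype = "dotted")
  }
  p
}
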