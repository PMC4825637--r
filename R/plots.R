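# ggplot2 displays: schematic ideograms of karyotype maps and hit-count
# profiles of candidate oligos.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

CHANNEL_COLOURS <- c(green = "#2E9E4F", red = "#D6402D", blue = "#2C5FD0")

#' Ideogram-style plot of a karyotype map
#'
#' Chromosomes along the x axis, position classes stacked vertically,
#' one point per signal record coloured by imaging channel and sized by
#' intensity — a schematic rendering of the signal table.
#'
#' @param object a `kp_karyotype`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kp_karyotype <- function(object, ...) {
  dat <- object$records |>
    mutate(
      chrom = factor(.data$chrom, levels = object$chromosomes),
      position_class = factor(.data$position_class,
                              levels = rev(POSITION_CLASSES)),
      intensity = factor(.data$intensity, levels = INTENSITY_LEVELS)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chrom, y = .data$position_class,
                                    colour = .data$channel,
                                    size = .data$intensity)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6),
                        alpha = 0.9) +
    ggplot2::scale_colour_manual(values = CHANNEL_COLOURS) +
    ggplot2::scale_size_manual(values = c(none = 0, weak = 2, medium = 4,
                                          strong = 6), drop = FALSE) +
    ggplot2::labs(title = object$genotype, x = NULL, y = NULL,
                  colour = "channel", size = "intensity") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.kp_karyotype
#' @param map a `kp_karyotype`.
#' @export
plot_karyotype <- function(map, ...) autoplot.kp_karyotype(map, ...)

#' Bar plot of per-chromosome oligo hit counts
#'
#' @param counts named per-chromosome counts from [kp_oligo_hits()].
#' @param target_chroms optional chromosomes to highlight as on-target.
#' @return a ggplot object.
#' @export
plot_hit_counts <- function(counts, target_chroms = NULL) {
  dat <- tibble(chrom = factor(names(counts), levels = names(counts)),
                count = as.integer(counts),
                on_target = names(counts) %in% (target_chroms %||% character()))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chrom, y = .data$count,
                                    fill = .data$on_target)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2C5FD0", `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "binding sites (both strands)") +
    ggplot2::theme_minimal()
}
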