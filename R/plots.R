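#' Plot a micro-homology distribution
#'
#' Bar chart of junction counts by homology length, faceted by genotype, with
#' insertion-carrying events shown separately -- the summary view behind the
#' size/junction panels of MA structural-variant figures.
#'
#' @param object An `ma_homology_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ma_homology_distribution
#' @export
autoplot.ma_homology_distribution <- function(object, ...) {
  bins <- object$bins
  lv <- c(as.character(0:object$cap), paste0(">", object$cap))
  bins$hom_bin <- factor(bins$hom_bin, levels = lv)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$hom_bin, y = .data$n,
                                     fill = .data$has_insertion)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~genotype) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#4477aa",
                                          `TRUE` = "#cc3311"),
                               labels = c("no insertion", "with insertion"),
                               name = NULL) +
    ggplot2::labs(x = "junction micro-homology (nt)", y = "events") +
    ggplot2::theme_minimal()
}

#' Plot the null homology histogram against the analytic expectation
#'
#' @param object An `ma_null_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ma_null_result
#' @export
autoplot.ma_null_result <- function(object, ...) {
  h <- object$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = .data$hom_total, y = .data$n)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::labs(
      x = "junction micro-homology (nt)", y = "random deletions",
      subtitle = sprintf(
        "fraction with homology %.3f (i.i.d. expectation %.3f)",
        object$fraction_with_homology, object$analytic_expectation)) +
    ggplot2::theme_minimal()
}

#' Dot plot of per-line mutation rates by genotype
#'
#' One dot per MA line with the genotype mean and SEM error bar, mirroring
#' the rate panels of MA figures.
#'
#' @param line_summary Output of [summarize_lines()].
#' @param class Event class to show (default `"DELETION_ALL"`).
#' @return A ggplot object.
#' @export
plot_rate_dots <- function(line_summary, class = "DELETION_ALL") {
  sub <- filter(line_summary, .data$class == !!class)
  stats <- sub |>
    group_by(.data$genotype) |>
    summarise(mean = mean(.data$rate),
              sem = sd(.data$rate) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$genotype, y = .data$rate)) +
    ggplot2::geom_col(data = stats, ggplot2::aes(y = .data$mean),
                      fill = "grey80", width = 0.6) +
    ggplot2::geom_errorbar(
      data = stats,
      ggplot2::aes(y = .data$mean, ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.2) +
    ggplot2::geom_jitter(width = 0.08, colour = "#4477aa", size = 2) +
    ggplot2::labs(x = NULL, y = paste0(class, " rate (events / generation)")) +
    ggplot2::theme_minimal()
}

#' Stacked base-substitution spectrum per genotype
#'
#' @param spectrum Output of [substitution_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$genotype, y = .data$rate,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = NULL) +
    ggplot2::labs(x = NULL, y = "substitutions / generation") +
    ggplot2::theme_minimal()
}
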