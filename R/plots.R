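#' Plot per-category BGA time courses
#'
#' Trial-mean percent-change BGA per category with a 1 SEM ribbon, the
#' baseline window shaded and the d-prime analysis window marked.
#'
#' @param object A `bga_series` from [percent_change()] / [extract_bga()].
#' @param window Analysis window (s) marked with dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bga_series
#' @export
autoplot.bga_series <- function(object, window = c(0.1, 0.4), ...) {
  keep <- !object$rejected
  df <- tibble(
    time = rep(object$time, each = sum(keep)),
    category = rep(object$category[keep], times = length(object$time)),
    pct = as.vector(object$pct[keep, , drop = FALSE])
  ) |>
    group_by(.data$time, .data$category) |>
    summarise(mean = mean(.data$pct),
              sem = sd(.data$pct) / sqrt(n()), .groups = "drop")
  ggplot(df, aes(.data$time, .data$mean, colour = .data$category,
                 fill = .data$category)) +
    annotate("rect", xmin = object$baseline_window[1],
             xmax = object$baseline_window[2], ymin = -Inf, ymax = Inf,
             alpha = 0.08) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem),
                alpha = 0.25, colour = NA) +
    geom_line() +
    geom_vline(xintercept = window, linetype = "dashed", colour = "grey40") +
    labs(x = "time from stimulus onset (s)", y = "BGA (% change from baseline)",
         title = sprintf("Electrode %s", object$electrode)) +
    theme_minimal()
}

#' Plot a latency scan
#'
#' FDR-corrected p-values of the pointwise category contrast over time, with
#' the significance level and the detected onset (if any).
#'
#' @param object A `latency_scan` from [onset_latency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot latency_scan
#' @export
autoplot.latency_scan <- function(object, ...) {
  g <- ggplot(object$trace, aes(.data$time, -log10(pmax(.data$p_adj, 1e-16)))) +
    geom_line() +
    geom_hline(yintercept = -log10(object$alpha), linetype = "dashed") +
    labs(x = "time from stimulus onset (s)",
         y = expression(-log[10] ~ "adjusted p"),
         title = sprintf("Electrode %s, %s: onset %s", object$electrode,
                         object$category,
                         if (is.na(object$onset_s)) "none"
                         else sprintf("%.0f ms", 1000 * object$onset_s))) +
    theme_minimal()
  if (!is.na(object$onset_s)) {
    g <- g + geom_vline(xintercept = object$onset_s, colour = "red")
  }
  g
}

#' Scatter of d-prime against an electrode coordinate
#'
#' One panel per category: d-prime vs the chosen Talairach coordinate within a
#' region x hemisphere cell, with a least-squares trend line — the univariate
#' view of the topology gradients the mixed models quantify.
#'
#' @param selectivity Tibble from [selectivity_table()].
#' @param geometry Geometry tibble with raw coordinates.
#' @param axis Coordinate to plot against: `"x"`, `"y"` or `"z"`.
#' @param region,hemisphere Cell to display.
#' @return A ggplot object.
#' @export
plot_selectivity_gradient <- function(selectivity, geometry, axis = "x",
                                      region = "VTC", hemisphere = "L") {
  df <- selectivity |>
    filter(.data$region == !!region, .data$hemisphere == !!hemisphere) |>
    left_join(geometry |> select("electrode", "subject", all_of(axis)),
              by = c("electrode", "subject"))
  ggplot(df, aes(.data[[axis]], .data$d_prime)) +
    geom_point(aes(colour = .data$significant), alpha = 0.8) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "grey30",
                linewidth = 0.5) +
    facet_wrap(~category) +
    labs(x = sprintf("Talairach %s (mm)", axis), y = "d'",
         title = sprintf("%s, %s hemisphere", region, hemisphere)) +
    theme_minimal()
}

#' Forest plot of topology model coefficients
#'
#' Fixed-effect estimates with +/- 1.96 SE intervals for every fitted
#' category x region x hemisphere mixed model (intercepts omitted).
#'
#' @param object A `topology_report` from [topology_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot topology_report
#' @export
autoplot.topology_report <- function(object, ...) {
  df <- object$coefficients |>
    filter(.data$term != "(Intercept)") |>
    mutate(cell = paste(.data$region, .data$hemisphere))
  ggplot(df, aes(.data$estimate, .data$category, colour = .data$term)) +
    geom_vline(xintercept = 0, colour = "grey70") +
    geom_pointrange(aes(xmin = .data$estimate - 1.96 * .data$std.error,
                        xmax = .data$estimate + 1.96 * .data$std.error),
                    position = position_dodge(width = 0.5)) +
    facet_wrap(~cell, scales = "free_x") +
    labs(x = "coefficient (d' per mm)", y = NULL) +
    theme_minimal()
}
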