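#' Plot outcome means by situation and agent strategy
#'
#' Mean centred outcome with normal-approximation 95% confidence bars, per
#' situation cell and agent strategy — the standard picture for eyeballing
#' where a strategy helps and where it does not.
#'
#' @param data Trial data (e.g. from [generate_trial()]).
#' @param outcome Outcome column to plot (`"isr"`, `"icaa"` or `"fbh"`).
#' @return A ggplot object.
#' @examples
#' plot_strategy_effects(generate_trial(seed = 1), "isr")
#' @export
plot_strategy_effects <- function(data, outcome = "isr") {
  stopifnot(outcome %in% names(data))
  summ <- data |>
    dplyr::group_by(.data$situation, .data$strategy) |>
    dplyr::summarise(
      mean = mean(.data[[outcome]]),
      se = sd(.data[[outcome]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  summ$strategy <- factor(summ$strategy, levels = .mh_levels$strategy)
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = factor(.data$situation), y = .data$mean,
                               colour = .data$strategy,
                               group = .data$strategy)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                   ymax = .data$mean + 1.96 * .data$se),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "situation (stance x severity grid cell)",
                  y = sprintf("mean centred %s", toupper(outcome)),
                  colour = "agent strategy") +
    ggplot2::theme_minimal()
}

#' @rdname plot_strategy_effects
#' @param object,... Autoplot interface: `object` is an `mh_trial` tibble.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mh_trial <- function(object, outcome = "isr", ...) {
  plot_strategy_effects(object, outcome)
}

#' Plot the hypothesis-ladder results
#'
#' One point per likelihood-ratio comparison, positioned at its Cohen's w
#' with the comparison's p-value mapped to shape (below / above 0.05).
#'
#' @param object An `mh_ladders` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mh_ladders <- function(object, ...) {
  res <- tidy(object)
  res$label <- paste(res$hypothesis, res$outcome, res$comparison, sep = " / ")
  res$significant <- res$p.value < 0.05
  ggplot2::ggplot(res, ggplot2::aes(x = .data$cohens_w,
                                    y = stats::reorder(.data$label,
                                                       .data$cohens_w),
                                    shape = .data$significant)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Cohen's w", y = NULL,
                  shape = "p < 0.05") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
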