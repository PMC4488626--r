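#' @export
print.rt_evolution <- function(x, ...) {
  cond <- if (!is.null(x$condition)) {
    sprintf(" condition %s", x$condition$label)
  } else ""
  cat(sprintf(
    "<rt_evolution> %s task%s: %d populations x %d, %d generations\n",
    x$arch$task, cond, x$ga$n_populations, x$ga$pop_size, x$generations
  ))
  final <- dplyr::filter(x$history, .data$generation == x$generations)
  cat(sprintf("final best fitness: %s\n",
              paste(signif(final$best_fitness, 5), collapse = ", ")))
  cat(sprintf("final elite error rate: %s\n",
              paste(signif(final$error_rate, 3), collapse = ", ")))
  invisible(x)
}

#' Tidy an evolution run
#'
#' Returns the per-generation, per-island history: best fitness, the elite
#' individual's error rate, and its median RT per cue type.
#'
#' @param x an `rt_evolution` object.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.rt_evolution <- function(x, ...) {
  x$history
}

#' One-row summary of an evolution run
#'
#' Final-generation statistics: mean best fitness and elite error rate over
#' islands, and the pooled mean of individual median RTs per cue type.
#'
#' @inheritParams tidy.rt_evolution
#' @return A one-row tibble.
#' @export
glance.rt_evolution <- function(x, ...) {
  final <- dplyr::filter(x$history, .data$generation == x$generations)
  rts <- dplyr::filter(x$rt_summary, .data$generation == x$generations)
  get_rt <- function(ct) {
    v <- rts$mean_median_rt[rts$cue_type == ct]
    if (length(v) == 0L) NA_real_ else v
  }
  tibble(
    generations = x$generations,
    best_fitness = mean(final$best_fitness),
    elite_error_rate = mean(final$error_rate),
    rt_valid = get_rt("valid"),
    rt_neutral = get_rt("neutral"),
    rt_invalid = get_rt("invalid")
  )
}

#' Plot reaction-time evolution
#'
#' Pooled mean of individual median RTs per cue type against generation,
#' with a 95% confidence ribbon.
#'
#' @param object an `rt_evolution` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rt_evolution <- function(object, ...) {
  df <- dplyr::filter(object$rt_summary, !is.na(.data$mean_median_rt))
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$mean_median_rt,
                                   colour = .data$cue_type,
                                   fill = .data$cue_type)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_median_rt - .data$ci95_half_width,
                   ymax = .data$mean_median_rt + .data$ci95_half_width),
      alpha = 0.2, colour = NA, na.rm = TRUE
    ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "median RT (time units)",
                  colour = "cue", fill = "cue") +
    ggplot2::theme_minimal()
}

#' Plot the sensory-experiment summary
#'
#' Correct-trial mean RT by cue type, faceted by task and signal intensity,
#' one line per response threshold.
#'
#' @param exp1_summary a tibble from [run_exp1()].
#' @return A ggplot.
#' @export
plot_exp1_rt <- function(exp1_summary) {
  df <- dplyr::filter(exp1_summary, .data$cue_type != "all")
  df$cue_type <- factor(df$cue_type, c("valid", "neutral", "invalid"))
  ggplot2::ggplot(df, ggplot2::aes(.data$cue_type, .data$mean_rt,
                                   group = factor(.data$gamma),
                                   colour = factor(.data$gamma))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(ggplot2::vars(.data$s), ggplot2::vars(.data$task),
                        scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "cue type", y = "mean correct-trial RT (time units)",
                  colour = "gamma") +
    ggplot2::theme_minimal()
}
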