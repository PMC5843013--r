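#' Plot trajectory profiles of a latent class fit
#'
#' Per-class symptom probability against wave, the standard trajectory-class
#' display.
#'
#' @param object an [llca_fit()] object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot llca_fit
#' @export
autoplot.llca_fit <- function(object, ...) {
  d <- tidy(object)
  d$class <- factor(d$class, levels = object$class_labels)
  ggplot2::ggplot(d, ggplot2::aes(.data$wave, .data$item_prob,
                                  colour = .data$class, group = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "wave", y = "symptom probability",
      colour = "class",
      title = paste0("Trajectory classes",
                     if (!is.null(object$process)) paste0(" (", object$process, ")"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the joint class distribution
#'
#' Heatmap of the 4x4 joint class percentages with cell labels.
#'
#' @param object a [fit_parallel()] object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot parallel_llca
#' @export
autoplot.parallel_llca <- function(object, ...) {
  d <- tidy(object, "weights")
  d$constipation_class <- factor(d$constipation_class,
                                 levels = rev(rownames(object$joint_weights)))
  d$soiling_class <- factor(d$soiling_class, levels = colnames(object$joint_weights))
  ggplot2::ggplot(d, ggplot2::aes(.data$soiling_class, .data$constipation_class,
                                  fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$percent))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "soiling class", y = "constipation class",
                  fill = "% of cohort",
                  title = "Joint distribution of trajectory classes") +
    ggplot2::theme_minimal()
}

#' Forest plot of three-step odds ratios
#'
#' Odds ratios (log scale) with 95% Wald intervals for each non-reference
#' composite group; the intercept rows are omitted.
#'
#' @param object a [fit_threestep()] object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot threestep_fit
#' @export
autoplot.threestep_fit <- function(object, ...) {
  d <- dplyr::filter(wald_intervals(object), .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(.data$or, .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "odds ratio (vs normative, log scale)", y = NULL,
                  title = "Risk-factor associations with composite class") +
    ggplot2::theme_minimal()
}
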