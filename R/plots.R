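#' Plot female plumage-class distributions by species
#'
#' Histogram of ordinal female scores per species; bimodal panels are the
#' visual signature of female-limited polymorphism.
#'
#' @param records Specimen tibble (`species`, `sex`, `plumage_class`).
#' @return A ggplot object.
#' @export
plot_class_distribution <- function(records) {
  d <- dplyr::filter(records, .data$sex == "female")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$plumage_class,
                                             levels = 1:4))) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "Androchromy class", y = "Females") +
    ggplot2::theme_minimal()
}

#' @describeIn marginal_asr Stacked per-node state probabilities for the
#'   internal nodes, nodes ordered by number.
#' @param object,... An `mk_asr` object (unused dots).
#' @export
autoplot.mk_asr <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$type == "internal") |>
    tidyr::pivot_longer(dplyr::starts_with("p_"), names_to = "state",
                        names_prefix = "p_", values_to = "probability")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$node),
                                  y = .data$probability,
                                  fill = .data$state)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "Internal node", y = "Marginal probability",
                  fill = "State") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn pgls_fit Coefficient plot (estimates with ~95% intervals,
#'   intercept omitted).
#' @param object,... A `pgls_fit` object (unused dots).
#' @export
autoplot.pgls_fit <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error)) +
    ggplot2::labs(x = "PGLS estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-species androchromy slopes
#'
#' Point-range display of the relative-measurement ~ LD1 slopes from
#' [androchromy_slopes()], highlighting species significant at the
#' Bonferroni-corrected level.
#'
#' @param slopes Output of [androchromy_slopes()].
#' @return A ggplot object.
#' @export
plot_slopes <- function(slopes) {
  d <- dplyr::filter(slopes, .data$validated, is.finite(.data$slope))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$slope,
                                  y = stats::reorder(.data$species, .data$slope),
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$slope - 1.96 * .data$se,
                                          xmax = .data$slope + 1.96 * .data$se)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Relative measurement ~ LD1 slope", y = NULL,
                  colour = "Significant") +
    ggplot2::theme_minimal()
}
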