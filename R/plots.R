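#' Plot per-quantile odds ratios
#'
#' Odds ratio (with Woolf 95% CI) of endometriosis per PRS quantile bin
#' against the reference bin, plotted over the mean score of each bin.
#'
#' @param object An `endoprs_or_table` from [or_by_quantile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.endoprs_or_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_score, y = .data$odds_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                             size = 0.2) +
    ggplot2::labs(x = "Mean PRS of bin", y = "Odds ratio vs reference bin") +
    ggplot2::theme_minimal()
}

#' Plot prevalence by diagnosis burden
#'
#' @param object Output of [prevalence_by_burden()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_prevalence_by_burden <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$burden, y = .data$prevalence)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                             size = 0.2) +
    ggplot2::labs(x = "Unique diagnosis count", y = "Endometriosis prevalence") +
    ggplot2::theme_minimal()
}

#' Plot mean burden by PRS decile, stratified by status
#'
#' Visualizes the index-event signature: mean comorbidity count per PRS
#' decile, separately in cases and controls.
#'
#' @param cohort An `endoprs_cohort`.
#' @param profiles [count_burden()] output.
#' @param metric,resolution Burden column selectors.
#' @return A ggplot.
#' @export
plot_burden_by_decile <- function(cohort, profiles, metric = "comorbid",
                                  resolution = 3L) {
  col <- paste0(metric, "_", resolution, "char")
  asg <- assign_quantiles(cohort, k = 10L)
  dat <- tibble::tibble(
    decile = asg$quantile_bin[match(cohort$id, asg$id)],
    status = ifelse(cohort$endo_case, "case", "control"),
    burden = profiles[[col]][match(cohort$id, profiles$id)]
  )
  summ <- dplyr::summarise(
    dplyr::group_by(dat, .data$decile, .data$status),
    mean = mean(.data$burden),
    se = stats::sd(.data$burden) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$decile, y = .data$mean,
                                     colour = .data$status)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                          ymax = .data$mean + 1.96 * .data$se)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "PRS decile", y = "Mean comorbidity count", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the additive-scale interaction table
#'
#' Endometriosis prevalence per PRS decile in the with- and without-
#' comorbidity arms.
#'
#' @param object An `endoprs_additive` from [additive_interaction()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.endoprs_additive <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "decile",
                  with = "prevalence_with", without = "prevalence_without"),
    c("with", "without"), names_to = "arm", values_to = "prevalence"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$decile, y = .data$prevalence,
                                     colour = .data$arm)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "PRS decile", y = "Endometriosis prevalence",
                  colour = paste0(attr(object, "comorbidity"), " diagnosed")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
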