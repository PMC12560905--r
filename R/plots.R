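#' Histograms of the recorded milk traits
#'
#' One panel per trait present in the records (daily and shift yields,
#' fat and protein percentage), with free x scales.
#'
#' @param records Test-day records.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_trait_distributions <- function(records, bins = 40) {
  present <- .trait_columns[unname(.trait_columns) %in% names(records)]
  long <- tidyr::pivot_longer(records[, unname(present)],
                              dplyr::everything(),
                              names_to = "column", values_to = "value")
  long$trait <- names(present)[match(long$column, unname(present))]
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "grey30") +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = NULL, y = "records") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_lsm Plot least-squares means with SE bars and letter
#'   groups, one panel per factor.
#' @param object An `lsm_table`.
#' @param ... Unused.
#' @method autoplot lsm_table
#' @export
autoplot.lsm_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$lsm)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lsm - .data$se,
                                          ymax = .data$lsm + .data$se)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -1.2, size = 3) +
    ggplot2::facet_grid(trait ~ factor, scales = "free") +
    ggplot2::labs(x = NULL, y = "least-squares mean") +
    ggplot2::theme_minimal()
}

#' @describeIn clean_records Bar chart of surviving record counts after
#'   each cleaning stage.
#' @param object A `cleaning_report`.
#' @param ... Unused.
#' @method autoplot cleaning_report
#' @export
autoplot.cleaning_report <- function(object, ...) {
  df <- as_tibble(object)
  df$stage <- factor(df$stage, levels = df$stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$records_out)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("-", .data$records_removed)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "records remaining") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @describeIn reml_fit Stacked bar chart of the estimated variance
#'   components per trait.
#' @param object A `lactaqg_reml`.
#' @param ... Unused.
#' @method autoplot lactaqg_reml
#' @export
autoplot.lactaqg_reml <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$vc[, c("trait", "sigma2_a", "sigma2_m", "sigma2_pe", "sigma2_e")],
    -"trait", names_to = "component", values_to = "variance"
  )
  long$component <- factor(long$component,
                           levels = c("sigma2_e", "sigma2_pe", "sigma2_m", "sigma2_a"),
                           labels = c("residual", "permanent env.", "maternal", "additive"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trait, y = .data$variance,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues") +
    ggplot2::labs(x = NULL, y = "variance", fill = NULL) +
    ggplot2::theme_minimal()
}
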