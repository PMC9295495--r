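#' Plot a region census: classification counts and VUS rate per category
#'
#' Bars give the number of high-confidence pathogenic variants per region
#' category; points give the fraction of each category's records
#' classified as VUS.
#'
#' @param object An `ncv_audit` from [audit_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ncv_audit <- function(object, ...) {
  d <- object$by_category
  d$category <- factor(d$category, levels = d$category)
  scale <- max(d$n_hc_pathogenic, 1)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n_hc_pathogenic),
                      fill = "grey35") +
    ggplot2::geom_point(ggplot2::aes(y = .data$vus_rate * scale),
                        colour = "steelblue", size = 3, na.rm = TRUE) +
    ggplot2::scale_y_continuous(
      name = "high-confidence pathogenic variants",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "VUS rate")
    ) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot an in-trans scan summary: candidates per region class
#'
#' @param object An `ncv_scan_summary` from [summarize_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ncv_scan_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_region,
                  ggplot2::aes(x = .data$region_class,
                               y = .data$n_candidates)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "in-trans candidates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
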