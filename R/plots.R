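#' Plot a class distribution
#'
#' @param object An `ise_class_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ise_class_distribution <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass_tbl(object)),
                  ggplot2::aes(factor(class_k), frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "ISEs carried (genome-size class)",
                  y = "relative frequency")
}

#' Plot observed/expected ratios per genome-size class
#'
#' Horizontal reference at O/E = 1 (unbiased transmission); ratios above the
#' line mark overrepresented classes.
#'
#' @param oe An O/E table from [oe_ratios()] (optionally with a `clone_id`
#'   column for facetting).
#' @return A ggplot.
#' @export
plot_oe <- function(oe) {
  stopifnot(all(c("class_k", "oe_ratio") %in% names(oe)))
  p <- ggplot2::ggplot(oe, ggplot2::aes(factor(class_k), oe_ratio,
                                        group = 1)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "ISEs carried (genome-size class)", y = "O/E ratio")
  if ("clone_id" %in% names(oe)) {
    p <- p + ggplot2::facet_wrap(~clone_id)
  }
  p
}
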