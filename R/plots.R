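# Result graphics.

#' Volcano data for a query result
#'
#' @param results A query result tibble.
#' @return Tibble of (`refsetname`, `setscore`, `neglog10p`, `sig`), the
#'   standard volcano coordinates: enhancing compounds to the right,
#'   suppressing to the left, significant ones high.
#' @export
volcano_data <- function(results) {
  tibble(
    refsetname = results$refsetname,
    setscore = results$setscore,
    neglog10p = -log10(results$pvalue),
    sig = factor(results$sig, levels = c(0L, 1L),
                 labels = c("not significant", "significant"))
  )
}

#' Volcano plot of a connectivity query
#'
#' @param object A `connmap_query`.
#' @param ... Unused.
#' @return A ggplot: setscore against -log10 p per compound, with the
#'   Bonferroni threshold drawn as a horizontal line.
#' @export
autoplot.connmap_query <- function(object, ...) {
  v <- volcano_data(object)
  thr <- attr(object, "threshold")
  ggplot2::ggplot(v, ggplot2::aes(x = .data$setscore, y = .data$neglog10p,
                                  colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c("not significant" = "grey60", "significant" = "#c0392b"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "setscore (suppressing ← 0 → enhancing)",
      y = expression(-log[10] ~ p)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of perturbation stability
#'
#' @param report A [perturbation_stability()] report.
#' @return A ggplot of per-compound stability, sorted.
#' @export
plot_stability <- function(report) {
  d <- report |> arrange(desc(.data$stability))
  d$compound <- factor(d$compound, levels = rev(d$compound))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stability, y = .data$compound)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "perturbation stability", y = NULL) +
    ggplot2::theme_minimal()
}
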