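#' Plot a parameter-sweep report
#'
#' Mean Dice per grid point, faceted by iteration pair, with the winning
#' point highlighted.
#'
#' @param object a `sweep_report` from [parameter_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.sweep_report <- function(object, ...) {
  df <- as.data.frame(object)
  df$iters <- sprintf("%d x %d", df$inner, df$outer)
  best <- attr(object, "best")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = alpha, y = mean_dice,
                                        colour = factor(lam))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~iters) +
    ggplot2::labs(x = expression(alpha), y = "mean Dice",
                  colour = expression(lambda),
                  title = "DRLSE parameter sweep")
  if (!is.null(best))
    p <- p + ggplot2::annotate("point", x = best$alpha, y = best$mean_dice,
                               shape = 1, size = 4, colour = "black")
  p
}

#' Distribution of per-volume metrics
#'
#' Boxplots of the metric columns of one or more report tables, e.g. to
#' compare raw predictions against level-set-refined or border-stripped
#' variants side by side.
#'
#' @param ... named tibbles of [evaluate_pair()] rows; the names label the
#'   groups.
#' @param metrics which metric columns to show.
#' @return A ggplot object.
#' @export
plot_metric_distribution <- function(...,
                                     metrics = c("dice", "jaccard", "os",
                                                 "us", "hd95_mm")) {
  groups <- list(...)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  long <- do.call(rbind, lapply(names(groups), function(nm) {
    df <- as.data.frame(groups[[nm]])
    do.call(rbind, lapply(intersect(metrics, names(df)), function(mt)
      data.frame(group = nm, metric = mt, value = df[[mt]])))
  }))
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = group, y = value,
                                     fill = group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-volume metric distributions")
}
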