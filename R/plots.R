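# ggplot2 display helpers for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a respiratory signal trace
#'
#' @param object A \code{resp_signal}.
#' @param max_points Downsampling cap for long recordings.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot resp_signal
#' @export
autoplot.resp_signal <- function(object, max_points = 20000, ...) {
  rate <- signal_rate(object)
  idx <- if (length(object) > max_points) {
    round(seq(1, length(object), length.out = max_points))
  } else seq_along(object)
  df <- tibble::tibble(time_s = (idx - 1) / rate, value = as.numeric(object)[idx])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "belt signal [a.u.]")
}

#' Boxplots of the per-signal IQR criterion per mother wavelet
#'
#' @param ranking Result of \code{\link{rank_mother_wavelets}}.
#' @param top_n Number of best wavelets to show.
#' @return A ggplot.
#' @export
plot_wavelet_ranking <- function(ranking, top_n = 20) {
  per <- attr(ranking, "per_signal")
  abort_if(is.null(per), "ranking lacks the per-signal IQR attribute")
  keep <- ranking$wavelet[seq_len(min(top_n, nrow(ranking)))]
  df <- dplyr::filter(per, .data$wavelet %in% keep) |>
    dplyr::mutate(wavelet = factor(.data$wavelet, levels = keep))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelet, .data$iqr)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "scalogram IQR") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Boxplots of an anthropometric variable across pattern groups
#'
#' Median, quartile box and 1.5 IQR whiskers, outliers as points.
#'
#' @param cohort Cohort tibble.
#' @param variable Column to display (tidy-eval).
#' @return A ggplot.
#' @export
plot_cohort_boxplots <- function(cohort, variable) {
  grp <- factor(c("normal", "intermediate", "periodic-like")[cohort$expert_label],
                levels = c("normal", "intermediate", "periodic-like"))
  df <- tibble::tibble(group = grp,
                       value = rlang::eval_tidy(rlang::enquo(variable), cohort))
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$value)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 3,
                          outlier.colour = "red") +
    ggplot2::labs(x = NULL, y = rlang::as_label(rlang::enquo(variable)))
}

#' Accuracy boxplots of the explored configurations
#'
#' @param search A \code{respgran_grid} result.
#' @param top_n Configurations to show, sorted by decreasing median
#'   accuracy.
#' @return A ggplot.
#' @export
plot_search_results <- function(search, top_n = 20) {
  abort_if(!inherits(search, "respgran_grid"), "not a grid-search result")
  lab <- function(df) {
    sprintf("{%d-%d} %s %s %s c%d", df$d1, df$d2, substr(df$reduct, 1, 1),
            substr(df$discretize, 1, 1), df$rule, df$cuts)
  }
  med <- search$runs |>
    dplyr::summarise(med = stats::median(.data$accuracy),
                     .by = "config") |>
    dplyr::arrange(dplyr::desc(.data$med))
  keep <- med$config[seq_len(min(top_n, nrow(med)))]
  df <- dplyr::filter(search$runs, .data$config %in% keep) |>
    dplyr::mutate(label = lab(dplyr::pick(dplyr::everything())),
                  label = factor(.data$label,
                                 levels = unique(.data$label[order(match(.data$config, keep))])))
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "accuracy") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Scatter plot of a UMAP embedding
#'
#' @param embedding Result of \code{\link{umap_embed}} (with labels).
#' @return A ggplot.
#' @export
plot_umap <- function(embedding) {
  p <- ggplot2::ggplot(embedding, ggplot2::aes(.data$umap1, .data$umap2))
  if ("label" %in% names(embedding)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(x = "UMAP 1", y = "UMAP 2")
}
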