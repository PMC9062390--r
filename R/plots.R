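#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the training error trajectory of a fit
#'
#' Accepted-step `F(w) = e'e` against accepted-step index, on a log scale.
#'
#' @param object An `lmnet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lmnet_fit <- function(object, ...) {
  df <- tibble::tibble(step = seq_along(object$state$f_history) - 1L,
                       f = object$state$f_history)
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$f)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "accepted step", y = "F(w) = e'e",
                  title = "Levenberg-Marquardt training error") +
    ggplot2::theme_minimal()
}

#' Plot a target ranking as a scored bar chart
#'
#' @param object A `target_ranking` from [predict_targets()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.target_ranking <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$target <- stats::reorder(df$target, df$score)
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$target)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "network score", y = NULL,
                  title = paste("Target ranking:", attr(object, "query_id"))) +
    ggplot2::theme_minimal()
}

#' Plot a similarity hit list
#'
#' Lollipop chart of Tanimoto similarity (and network score when present)
#' for the ranked hits.
#'
#' @param object A `hit_list`.
#' @param top Show at most this many hits, default 25.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hit_list <- function(object, top = 25L, ...) {
  df <- tibble::as_tibble(object)[seq_len(min(top, nrow(object))), ]
  df$id <- factor(df$id, levels = rev(df$id))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$similarity, .data$id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$similarity,
                                       yend = .data$id), colour = "grey60") +
    ggplot2::labs(x = "Tanimoto similarity", y = NULL,
                  title = paste("Hits for", attr(object, "query_id"))) +
    ggplot2::theme_minimal()
  if ("nn_score" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$nn_score), size = 2) +
      ggplot2::scale_colour_viridis_c(name = "NN score")
  } else {
    p + ggplot2::geom_point(colour = "steelblue", size = 2)
  }
}

#' Plot per-atom RMSF
#'
#' @param fluct Numeric vector from [rmsf()].
#' @return A ggplot.
#' @export
plot_rmsf <- function(fluct) {
  df <- tibble::tibble(atom = seq_along(fluct), rmsf = fluct)
  ggplot2::ggplot(df, ggplot2::aes(.data$atom, .data$rmsf)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "atom index", y = "RMSF (Å)") +
    ggplot2::theme_minimal()
}
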