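#' Heatmap of a transition matrix
#'
#' @param model a `gaze_markov` model or a row-stochastic matrix with
#'   dimnames.
#' @param step which matrix to draw for a model: `"one"` or `"two"`.
#' @return a ggplot object: tile heatmap with probability labels, origin
#'   states on the y axis.
#' @export
plot_transition_matrix <- function(model, step = c("one", "two")) {
  step <- match.arg(step)
  P <- if (inherits(model, "gaze_markov")) {
    if (step == "one") model$P1 else model$P2_emp
  } else model
  if (is.null(P)) {
    stop_gazeflow("model has no two-step matrix (sequence shorter than 3).",
                  "gazeflow_data_error")
  }
  df <- tidyr::expand_grid(from = rownames(P), to = colnames(P)) |>
    dplyr::mutate(probability = P[cbind(.data$from, .data$to)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to,
                                   y = factor(.data$from, levels = rev(rownames(P))),
                                   fill = .data$probability)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$probability)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "to", y = "from",
                  title = sprintf("%s-step transition probabilities", step)) +
    ggplot2::theme_minimal()
}

#' @method autoplot gaze_markov
#' @export
autoplot.gaze_markov <- function(object, step = c("one", "two"), ...) {
  plot_transition_matrix(object, step = step)
}

#' Bar chart of per-area gaze occupancy
#'
#' @param summary a `fixation_summary` tibble.
#' @return a ggplot object.
#' @export
plot_fixation_summary <- function(summary) {
  ggplot2::ggplot(as_tibble(summary),
                  ggplot2::aes(x = .data$area, y = .data$p)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "AOI", y = "gaze-time share") +
    ggplot2::theme_minimal()
}

#' @method autoplot gaze_driver_report
#' @export
autoplot.gaze_driver_report <- function(object, ...) {
  df <- object$per_driver
  aes <- if (!is.null(object$group) && object$group %in% names(df)) {
    ggplot2::aes(x = factor(.data$driver), y = .data$E_n,
                 fill = .data[[object$group]])
  } else {
    ggplot2::aes(x = factor(.data$driver), y = .data$E_n)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$stats$mean, linetype = "dashed") +
    ggplot2::labs(x = "driver", y = expression(E[n]),
                  title = "Fixation entropy rate by driver") +
    ggplot2::theme_minimal()
}

#' @method autoplot gaze_entropy
#' @export
autoplot.gaze_entropy <- function(object, ...) {
  df <- object$areas[!object$areas$excluded, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "AOI", y = "contribution to E_n") +
    ggplot2::theme_minimal()
}
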