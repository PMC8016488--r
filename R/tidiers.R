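# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained model: per-epoch training history
#'
#' @param x An `og_model`.
#' @param ... Unused.
#' @return Tibble with epoch, learning_rate, train_loss, validation_accuracy.
#' @export
tidy.og_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), learning_rate = numeric(),
                          train_loss = numeric(),
                          validation_accuracy = numeric()))
  }
  x$history
}

#' One-row model summary
#'
#' @param x An `og_model`.
#' @param ... Unused.
#' @return Tibble with variant, group count, parameter count, best epoch and
#'   its validation accuracy.
#' @export
glance.og_model <- function(x, ...) {
  tibble::tibble(
    name = x$config$name,
    variant = x$config$variant,
    n_groups = x$config$n_groups,
    n_parameters = count_parameters(x$config),
    trained = x$trained,
    best_epoch = if (is.null(x$best_epoch)) NA_integer_ else x$best_epoch,
    best_validation_accuracy = if (is.null(x$history)) NA_real_
    else max(x$history$validation_accuracy)
  )
}

#' Tidy a score: per-group precision/recall table
#'
#' @param x An `og_score`.
#' @param ... Unused.
#' @export
tidy.og_score <- function(x, ...) x$per_group

#' One-row metrics summary
#'
#' @param x An `og_score`.
#' @param ... Unused.
#' @export
glance.og_score <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, n = x$n,
                 n_groups = nrow(x$per_group))
}

#' Training curves
#'
#' @param object A trained `og_model`.
#' @param ... Unused.
#' @return A ggplot of training loss and validation accuracy per epoch.
#' @export
autoplot.og_model <- function(object, ...) {
  h <- tidy.og_model(object)
  long <- tidyr::pivot_longer(
    h[, c("epoch", "train_loss", "validation_accuracy")],
    cols = c("train_loss", "validation_accuracy"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = object$config$name)
}

#' Confidence histogram plot
#'
#' @param object An `og_confhist`.
#' @param ... Unused.
#' @export
autoplot.og_confhist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lower + 0.005,
                                       y = .data$count)) +
    ggplot2::geom_col(width = 0.01) +
    ggplot2::labs(x = "assignment confidence", y = "sequences")
}

#' Overlayed in-model / out-model confidence histograms
#'
#' @param object An `og_inout`.
#' @param ... Unused.
#' @export
autoplot.og_inout <- function(object, ...) {
  both <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$in_hist), set = "in_model"),
    dplyr::mutate(tibble::as_tibble(object$out_hist), set = "out_model"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$lower + 0.005,
                                     y = .data$count, fill = .data$set)) +
    ggplot2::geom_col(width = 0.01, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "assignment confidence", y = "sequences", fill = NULL)
}

#' Per-group precision/recall plot
#'
#' @param object An `og_score`.
#' @param ... Unused.
#' @export
autoplot.og_score <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_group,
                              cols = c("precision", "recall"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL)
}
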