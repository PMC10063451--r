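#' Plot cluster sizes of a partition
#'
#' @param object A `dc_partition`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dc_partition
#' @export
autoplot.dc_partition <- function(object, ...) {
  df <- tidy(object) |> count(.data$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cluster", y = "cells",
                  title = sprintf("%d clusters, Q = %.3f",
                                  nrow(df), object$modularity)) +
    ggplot2::theme_minimal()
}

#' Plot connectivity-score distributions per signature
#'
#' @param object A `dc_scores` tibble.
#' @param ... Unused.
#' @return A ggplot of per-signature score distributions.
#' @method autoplot dc_scores
#' @export
autoplot.dc_scores <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$signature, y = .data$tau)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(tau)) +
    ggplot2::theme_minimal()
}

#' Plot annotated type and state composition
#'
#' @param object A `dc_annotation`.
#' @param ... Unused.
#' @return A ggplot: cells per consensus type, filled by activation state.
#' @method autoplot dc_annotation
#' @export
autoplot.dc_annotation <- function(object, ...) {
  df <- object$labels |>
    mutate(type = ifelse(is.na(.data$type), "NA", .data$type),
           state = ifelse(is.na(.data$state), "NA", .data$state))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, fill = .data$state)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "consensus type", y = "cells") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
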