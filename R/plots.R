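## ggplot2 visual summaries for the main result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed versus cross-validated predicted retention times
#'
#' @param object An `rt_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rt_model <- function(object, ...) {
  if (isTRUE(object$fallback)) stop("fallback RT model has no CV predictions",
                                    call. = FALSE)
  df <- tibble::tibble(
    observed = unlist(object$cv_stats$obs),
    predicted = unlist(object$cv_stats$pred)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "observed RT (s)", y = "predicted RT (s, held-out)",
                  title = "Retention-time model cross-validation") +
    ggplot2::theme_minimal()
}

#' Plot annotation counts per propagation round and level
#'
#' @param object A `propagation_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.propagation_result <- function(object, ...) {
  df <- object$annotations |>
    dplyr::count(.data$round, level = factor(.data$level))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$round), y = .data$n,
                                   fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "propagation round (0 = seeds)", y = "annotations",
                  fill = "level",
                  title = "Annotation propagation by round") +
    ggplot2::theme_minimal()
}

#' Plot the ion-form role composition of the peak correlation network
#'
#' @param object A `metanno_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metanno_result <- function(object, ...) {
  df <- dplyr::count(object$roles, .data$role)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$role, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::labs(x = NULL, y = "features",
                  title = "Recognized ion-form roles") +
    ggplot2::theme_minimal()
}

#' Bar chart of annotation evaluation outcomes
#'
#' @param evaluation Result of [evaluate_top_n()] or [evaluate_roles()].
#' @return A ggplot.
#' @export
plot_evaluation <- function(evaluation) {
  df <- tibble::enframe(evaluation$counts, name = "status", value = "n") |>
    dplyr::mutate(n = as.integer(.data$n))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data$n)) +
    ggplot2::geom_col(fill = "#66ccee") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3) +
    ggplot2::labs(x = NULL, y = "features", title = "Annotation evaluation") +
    ggplot2::theme_minimal()
}
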