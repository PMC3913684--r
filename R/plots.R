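# broom-style accessors and ggplot2 graphics for detection results.

#' @method tidy circ_detection
#' @export
tidy.circ_detection <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance circ_detection
#' @export
glance.circ_detection <- function(x, ...) {
  f <- attr(x, "funnel")
  out <- tidyr::pivot_wider(f, names_from = "stage", values_from = "count")
  out$platform <- attr(x, "platform")
  out
}

#' @export
print.circ_detection <- function(x, ...) {
  f <- attr(x, "funnel")
  cat(sprintf("<circ_detection: %s> %s\n", attr(x, "platform"),
              paste(sprintf("%s=%d", f$stage, f$count), collapse = " -> ")))
  NextMethod()
}

#' Plot the detection funnel
#'
#' Bar chart of per-stage candidate counts for one or more detection
#' results -- the shape of the filtering cascade from input contigs to
#' confirmed circular elements.
#'
#' @param ... One or more `circ_detection` results, or a single
#'   `circ_pipeline`.
#' @return A ggplot object.
#' @export
plot_funnel <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && inherits(xs[[1]], "circ_pipeline")) {
    df <- xs[[1]]$funnel
  } else {
    df <- bind_rows(lapply(xs, function(x) {
      mutate(attr(x, "funnel"), pipeline = attr(x, "platform"))
    }))
  }
  df$stage <- factor(df$stage, levels = unique(df$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count,
                                   fill = .data$pipeline)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "contigs", fill = "pipeline") +
    ggplot2::theme_minimal()
}

#' Length distribution of confirmed elements
#'
#' @param object A `circ_detection` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot circ_detection
#' @export
autoplot.circ_detection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "element length (nt)", y = "elements",
                  title = sprintf("%s circular elements", attr(object, "platform"))) +
    ggplot2::theme_minimal()
}
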