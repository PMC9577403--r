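#' Forest-style plot of a signal screen
#'
#' Point estimates with intervals per combination, faceted by method, on a
#' log scale for PRR/ROR and a linear scale for the IC; colour encodes
#' signal strength. MHRA, which has no interval, is omitted.
#'
#' @param object A `signal_screen`.
#' @param methods Methods to display (default PRR, ROR, BCPNN).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_screen
#' @export
autoplot.signal_screen <- function(object, methods = c("PRR", "ROR", "BCPNN"),
                                   ...) {
  long <- tidy(object) %>%
    filter(.data$method %in% methods, !is.na(.data$point)) %>%
    mutate(label = paste(.data$drug, .data$event_pt, sep = ": "))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$point, y = .data$label,
                                     colour = .data$strength)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_vline(
      data = tibble(method = factor(intersect(methods, c("PRR", "ROR", "BCPNN")),
                                    levels = methods_all)) %>%
        mutate(ref = ifelse(.data$method == "BCPNN", 0, 1)),
      ggplot2::aes(xintercept = .data$ref), linetype = 2, colour = "grey50"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$method), scales = "free_x") +
    ggplot2::labs(x = "statistic (PRR/ROR ratio scale; IC in bits)",
                  y = NULL, colour = "strength") +
    ggplot2::theme_minimal()
}

#' ROC plot of a method comparison
#'
#' Draws the anchored threshold-sweep ROC polyline of each compared
#' method, with the chance diagonal.
#'
#' @param object A `method_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  methods <- unique(as.character(object$method))
  pts <- bind_rows(lapply(methods, function(m) {
    tryCatch(roc_points(object, m) %>% mutate(method = m),
             error = function(e) NULL)
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  colour = "method") +
    ggplot2::theme_minimal()
}
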