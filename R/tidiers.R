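#' Tidy a GREML fit
#'
#' @param x A `greml_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.greml_fit <- function(x, ...) x$components

#' One-row summary of a GREML fit
#'
#' @param x A `greml_fit`.
#' @param ... Unused.
#' @return Tibble with `logL`, `n`, `iterations`, `converged`,
#'   `negative_components`.
#' @export
glance.greml_fit <- function(x, ...) {
  tibble(logL = x$logL, n = x$n, iterations = x$iterations,
         converged = x$converged,
         negative_components = x$negative_components)
}

#' Tidy a twin fit
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error` for every derived
#'   (standardized) quantity.
#' @export
tidy.twin_fit <- function(x, ...) {
  tibble(term = names(x$derived), estimate = unname(x$derived),
         std.error = unname(x$derived_se))
}

#' One-row summary of a twin fit
#'
#' @param x A `twin_fit`.
#' @param ... Unused.
#' @return Tibble with `minus2lnL`, pair counts, `model`, `se_available`.
#' @export
glance.twin_fit <- function(x, ...) {
  tibble(minus2lnL = x$minus2lnL, n_mz = unname(x$n_pairs["MZ"]),
         n_dz = unname(x$n_pairs["DZ"]), n_complete = x$n_complete,
         model = x$model, se_available = x$se_available)
}

#' Plot GREML variance components with standard-error bars
#'
#' @param object A `greml_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.greml_fit <- function(object, ...) {
  d <- object$components
  d <- d[grepl("^[VC]\\(", d$term) | d$term %in% c("r_G", "r_E"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std.error,
                   ymax = .data$estimate + .data$std.error),
      width = 0.25) +
    ggplot2::labs(x = NULL, y = "estimate",
                  title = "REML variance components") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot standardized twin-model components
#'
#' Stacked A/C/E shares of each trait's variance.
#'
#' @param object A `twin_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twin_fit <- function(object, ...) {
  s <- twin_standardized(object)
  d <- tidyr::pivot_longer(s[, c("component", "V_tr1", "V_tr2")],
                           cols = c("V_tr1", "V_tr2"),
                           names_to = "trait", values_to = "share")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trait, y = .data$share,
                                  fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "share of variance", x = NULL,
                  title = "ACE decomposition") +
    ggplot2::theme_minimal()
}

#' Scree plot with Tracy-Widom significance
#'
#' @param object A `pca_result`.
#' @param n_axes Number of leading eigenvalues to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_result <- function(object, n_axes = 20, ...) {
  k <- min(n_axes, length(object$eigenvalues))
  d <- tibble(axis = seq_len(k), eigenvalue = object$eigenvalues[seq_len(k)],
              significant = seq_len(k) %in% object$selected)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis, y = .data$eigenvalue,
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::labs(title = "GRM spectrum", colour = "TW p < alpha") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
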