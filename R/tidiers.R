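#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation: census with patterns
#'
#' @param x A `culture_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A tibble with one row per behaviour x site: `behaviour_id`,
#'   `category`, `subcategory`, `site`, `level`, `pattern`.
#' @method tidy culture_sim
#' @export
tidy.culture_sim <- function(x, ...) {
  x$census |>
    dplyr::left_join(x$space[, c("behaviour_id", "category", "subcategory")],
      by = "behaviour_id"
    ) |>
    dplyr::left_join(x$patterns, by = "behaviour_id") |>
    dplyr::select(
      "behaviour_id", "category", "subcategory", "site", "level", "pattern"
    )
}

#' One-row summary of a simulation
#'
#' @inheritParams tidy.culture_sim
#' @return A one-row tibble with the pattern counts, the cultural count, the
#'   number of locally restricted behaviours and the run parameters.
#' @method glance culture_sim
#' @export
glance.culture_sim <- function(x, ...) {
  pc <- table(x$patterns$pattern)
  tibble::tibble(
    n_cultural = unname(pc["D"]),
    n_pattern_a = unname(pc["A"]), n_pattern_b = unname(pc["B"]),
    n_pattern_c = unname(pc["C"]), n_pattern_d = unname(pc["D"]),
    n_locally_restricted = length(locally_restricted(x$census)),
    S = x$params$S, alpha_g = x$params$alpha_g, alpha_e = x$params$alpha_e,
    t_max = x$params$t_max,
    seed = if (is.null(x$params$seed)) NA_integer_ else x$params$seed
  )
}

#' @method tidy culture_correlation
#' @export
tidy.culture_correlation <- function(x, ...) x$pairs

#' @method glance culture_correlation
#' @export
glance.culture_correlation <- function(x, ...) x$estimate

#' @method tidy culture_s_effect
#' @export
tidy.culture_s_effect <- function(x, ...) x$rows

#' @method glance culture_s_effect
#' @export
glance.culture_s_effect <- function(x, ...) x$summary

#' Census grid plot
#'
#' Site-by-behaviour tile grid of classification levels, the text/graphic
#' analogue of the classic cultural-repertoire figure.
#'
#' @param object A `culture_sim`.
#' @param cultural_only Show only pattern-D behaviours (default `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot culture_sim
#' @export
autoplot.culture_sim <- function(object, cultural_only = FALSE, ...) {
  d <- tidy(object)
  if (cultural_only) d <- d[d$pattern == "D", ]
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$site, y = factor(.data$behaviour_id), fill = .data$level
  )) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c(
      customary = "#1b7837", habitual = "#7fbf7b", present = "#d9f0d3",
      absent = "white", ecological_explanation = "grey40"
    ), drop = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category), scales = "free_y", space = "free_y") +
    ggplot2::labs(x = NULL, y = "behaviour", fill = "level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Size-versus-culture scatter plot
#'
#' @param object A `culture_correlation` from [correlation_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot culture_correlation
#' @export
autoplot.culture_correlation <- function(object, ...) {
  e <- object$estimate
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$n, .data$n_cultural)) +
    ggplot2::geom_jitter(width = 0.8, height = 0.2, alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(
      x = "population size", y = "expressed cultural behaviours",
      subtitle = sprintf("%s rho = %.2f, p = %.2g, n = %d", e$method, e$rho, e$p_value, e$n)
    ) +
    ggplot2::theme_minimal()
}

#' Sweep heatmap
#'
#' Mean cultural count per (alpha_e, alpha_g) cell, coloured by whether the
#' mean lies above the benchmark threshold.
#'
#' @param sweep A tibble from [sweep_grid()].
#' @param threshold Threshold to colour around (default 38).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, threshold = 38) {
  d <- sweep |>
    dplyr::group_by(.data$alpha_e, .data$alpha_g) |>
    dplyr::summarise(mean_cultural = mean(.data$n_cultural), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(
    factor(.data$alpha_g), factor(.data$alpha_e), fill = .data$mean_cultural
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$mean_cultural, 1)), size = 3) +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", midpoint = threshold
    ) +
    ggplot2::labs(
      x = expression(alpha[g]), y = expression(alpha[e]),
      fill = "mean cultural\ncount"
    ) +
    ggplot2::theme_minimal()
}
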