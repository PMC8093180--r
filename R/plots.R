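#' Plot the approach to equilibrium
#'
#' Line plot of the derived quantities across iterations of the equilibrium
#' recursion (one iteration per generation). Requires
#' `equilibrium_state(..., keep_trajectory = TRUE)`.
#'
#' @param object an `equilibrium_state` with a stored trajectory.
#' @param quantities which quantities to draw.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.equilibrium_state <- function(object,
                                       quantities = c("V_Y", "V_F", "g", "w"),
                                       ...) {
  if (is.null(object$trajectory)) {
    abort("no trajectory stored; rerun equilibrium_state(keep_trajectory = TRUE)")
  }
  df <- tidyr::pivot_longer(
    object$trajectory,
    cols = -"iter",
    names_to = "quantity", values_to = "value"
  )
  df <- df[df$quantity %in% quantities, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$iter, .data$value, colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "generation (iteration)", y = "value",
      title = "Approach to equilibrium", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the ten g estimates
#'
#' Point-and-interval plot of the moment-based `g` estimates, colored by cis
#' (within-person) versus trans (across-mate) group; at AM equilibrium all
#' estimates share one mean.
#'
#' @param object a [g_estimates()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.g_estimates <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$estimate, y = .data$label, colour = .data$group
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 2 * .data$std.error,
      xmax = .data$estimate + 2 * .data$std.error
    )) +
    ggplot2::labs(
      x = "g estimate (+/- 2 SE)", y = NULL, colour = NULL,
      title = "Moment-based estimates of the AM-induced covariance g"
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted estimates with uncertainty
#'
#' Forest-style plot of the structural and derived estimates of a
#' [fit_model()] result with approximate 95% intervals.
#'
#' @param object a `nurture_fit`.
#' @param terms which terms to display.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.nurture_fit <- function(object,
                                 terms = c("delta", "a", "f", "r_mate", "V_F", "w", "v", "V_A"),
                                 ...) {
  df <- object$estimates[object$estimates$term %in% terms, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term, colour = .data$class)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(
      x = "estimate (95% interval)", y = NULL, colour = NULL,
      title = sprintf("Model %s estimates", sub("m", "", object$model))
    ) +
    ggplot2::theme_minimal()
}

#' Stacked variance-decomposition plot
#'
#' Shows the share of the phenotypic variance attributable to additive
#' genetics, vertical transmission, the genetic-nurture covariance, and the
#' residual, from an equilibrium state or fitted model.
#'
#' @param x an `equilibrium_state` or `nurture_fit`.
#' @return A ggplot.
#' @export
plot_variance_decomposition <- function(x) {
  if (inherits(x, "nurture_fit")) x <- x$state
  stopifnot(inherits(x, "equilibrium_state"))
  d <- decompose_variance(x)
  df <- tibble(
    component = factor(
      c("V_A", "V_F", "2(av + δw)", "V_eps"),
      levels = c("V_eps", "2(av + δw)", "V_F", "V_A")
    ),
    value = c(d$V_A, d$V_F, d$nurture_cov, d$V_eps)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = "V_Y", y = .data$value, fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "variance",
      title = "Phenotypic variance decomposition at equilibrium"
    ) +
    ggplot2::theme_minimal()
}
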