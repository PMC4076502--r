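#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the support of a joint pmf
#'
#' Draws the `(z1, z2)` lattice support colored by log10 probability mass,
#' which makes the translated-triangle pattern of the solution space
#' visible (one triangle per control configuration, overlapping at
#' multiples of `gcd(R_X, R_Y)`).
#'
#' @param object A `joint_pmf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' pr <- null_genotype_probs(mode = "fixed", p = c(1, 1, 1) / 3)
#' autoplot(joint_pmf_brute_force(19, 2, pr))
#' @method autoplot joint_pmf
#' @export
autoplot.joint_pmf <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$z1, y = .data$z2,
    colour = log10(.data$prob)
  )) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(name = "log10 mass") +
    ggplot2::labs(
      title = sprintf(
        "Joint pmf support (R_X = %d, R_Y = %d)",
        attr(object, "r_x"), attr(object, "r_y")
      ),
      x = expression(Z[1]), y = expression(Z[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot rejection rates from a simulation experiment
#'
#' Columns show the per-method Monte-Carlo rejection proportion with
#' +/- 2 SE error bars and a dashed line at the nominal level.
#'
#' @param object An `experiment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot experiment_result
#' @export
autoplot.experiment_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = pmax(0, .data$proportion - 2 * .data$se),
        ymax = pmin(1, .data$proportion + 2 * .data$se)
      ),
      width = 0.2
    ) +
    ggplot2::geom_hline(
      yintercept = object$config$alpha,
      linetype = "dashed"
    ) +
    ggplot2::labs(
      x = NULL, y = sprintf("rejection rate at alpha = %g", object$config$alpha)
    ) +
    ggplot2::theme_minimal()
}
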