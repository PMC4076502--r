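#' Asymptotic Cochran-Armitage trend test for one genetic model
#'
#' Standardizes the unnormalized trend statistic `W` by its null variance
#' `Var(W) = (R_X R_Y / N) (N sum(t_i^2 C_i) - (sum(t_i C_i))^2)` and reports
#' the two-sided normal p-value. The squared z-score equals the usual
#' chi-square(1) form of the trend statistic.
#'
#' A monomorphic weighting (all weighted column mass in one cell, so
#' `Var(W) = 0`) is not an error: the test is flagged degenerate and
#' `p_value = 1` is returned.
#'
#' @param table A [genotype_table()].
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return A `trend_result` object: list with `model`, `statistic`,
#'   `variance`, `z`, `p_value`, `degenerate`. Use [generics::tidy()] for a
#'   tibble.
#' @examples
#' gt <- genotype_table(167, 200, 54, 203, 185, 35)
#' ca_trend_test(gt, "additive")
#' @export
ca_trend_test <- function(table, model = c("additive", "dominant", "recessive")) {
  stopifnot(inherits(table, "genotype_table"))
  model <- match.arg(model)
  w <- trend_weights(model)
  stat <- trend_statistic(table, w)
  v <- with(table, (r_x * r_y / n) * (n * sum(w^2 * c) - sum(w * c)^2))
  degenerate <- v <= 0
  if (degenerate) {
    z <- 0
    p <- 1
  } else {
    z <- stat / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(
      model = model, statistic = stat, variance = v,
      z = z, p_value = p, degenerate = degenerate
    ),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "Cochran-Armitage trend test (%s model)\n  W = %d, Var(W) = %.6g, z = %.4f, two-sided p = %.4g%s\n",
    x$model, x$statistic, x$variance, x$z, x$p_value,
    if (x$degenerate) "  [degenerate]" else ""
  ))
  invisible(x)
}

#' Smallest per-model asymptotic p-value (uncorrected)
#'
#' Reports the minimum of the three single-model asymptotic p-values with no
#' multiplicity correction. This is not a valid test -- its type-1 error is
#' inflated roughly twofold because the three statistics are functionally
#' dependent -- and it is retained only as a comparison baseline.
#'
#' @param table A [genotype_table()].
#' @return The minimum p-value (a number in (0, 1]).
#' @export
min_p <- function(table) {
  min(vapply(
    genetic_models,
    function(m) ca_trend_test(table, m)$p_value,
    numeric(1)
  ))
}

#' Bonferroni-adjusted three-model p-value
#'
#' Scales the smallest single-model asymptotic p-value by the number of
#' models tested: `min(1, 3 * min_p)`. Equivalent to thresholding each test
#' at `alpha / 3`. Valid but conservative, since the three tests are highly
#' correlated.
#'
#' @param table A [genotype_table()].
#' @return The adjusted p-value in (0, 1].
#' @export
bonferroni_p <- function(table) {
  min(1, 3 * min_p(table))
}
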