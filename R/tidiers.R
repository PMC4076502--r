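#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-model trend test
#'
#' @param x A `trend_result` from [ca_trend_test()].
#' @param ... Unused.
#' @return One-row tibble: `model`, `statistic`, `variance`, `z`,
#'   `p.value`, `degenerate`.
#' @method tidy trend_result
#' @export
tidy.trend_result <- function(x, ...) {
  tibble::tibble(
    model = x$model, statistic = x$statistic, variance = x$variance,
    z = x$z, p.value = x$p_value, degenerate = x$degenerate
  )
}

#' @rdname tidy.trend_result
#' @method glance trend_result
#' @export
glance.trend_result <- function(x, ...) {
  tibble::tibble(p.value = x$p_value, model = x$model)
}

#' Tidy an exact joint-model test result
#'
#' @param x An `exact_result` from [exact_pvalue()].
#' @param ... Unused.
#' @return One-row tibble with the observed statistics, observed cell mass,
#'   p-value, scenario, and support-cell count.
#' @method tidy exact_result
#' @export
tidy.exact_result <- function(x, ...) {
  tibble::tibble(
    t1 = x$t1, t2 = x$t2, t3 = x$t3, z1 = x$z1, z2 = x$z2,
    f.obs = x$f_obs, p.value = x$p_value,
    scenario = x$scenario, cells = x$cells,
    probs_mode = x$probs$mode
  )
}

#' @rdname tidy.exact_result
#' @method glance exact_result
#' @export
glance.exact_result <- function(x, ...) {
  tibble::tibble(p.value = x$p_value, scenario = x$scenario)
}

#' Tidy a joint pmf
#'
#' @param x A `joint_pmf`.
#' @param ... Unused.
#' @return Tibble with `z1`, `z2`, `prob`.
#' @method tidy joint_pmf
#' @export
tidy.joint_pmf <- function(x, ...) {
  tibble::tibble(z1 = x$z1, z2 = x$z2, prob = x$prob)
}

#' @rdname tidy.joint_pmf
#' @method glance joint_pmf
#' @export
glance.joint_pmf <- function(x, ...) {
  tibble::tibble(
    r_x = attr(x, "r_x"), r_y = attr(x, "r_y"),
    method = attr(x, "method"), cells = nrow(x),
    total_mass = attr(x, "total_mass")
  )
}

#' Tidy an experiment result
#'
#' @param x An `experiment_result` from [run_experiment()].
#' @param ... Unused.
#' @return The per-method rejection-rate tibble (`method`, `rejections`,
#'   `n`, `proportion`, `se`).
#' @method tidy experiment_result
#' @export
tidy.experiment_result <- function(x, ...) {
  x$rates
}

#' @rdname tidy.experiment_result
#' @method glance experiment_result
#' @export
glance.experiment_result <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$config$n_replicates, alpha = x$config$alpha,
    maf = x$config$maf, beta1 = x$config$beta1, coding = x$config$coding
  )
}
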