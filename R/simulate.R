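#' Configuration for a case-control simulation experiment
#'
#' Replicate datasets are generated under a logistic disease model
#' `logit P(Z = 1) = beta0 + beta1 * X`, where `X` codes the genotype under
#' the generating genetic model (additive 0/1/2; dominant 0/1; recessive
#' 0/1) and genotypes are drawn from Hardy-Weinberg proportions at the given
#' minor allele frequency. Each replicate accrues individuals until the case
#' and control quotas are both met.
#'
#' @param maf Minor allele frequency, in (0, 0.5].
#' @param beta0 Logistic intercept (default -2.5, a rare-ish disease).
#' @param beta1 Log odds ratio for the coded genotype (default `log(1)`,
#'   the null).
#' @param coding Genotype coding of the generating model.
#' @param n_cases,n_controls Arm quotas per replicate.
#' @param n_replicates Number of replicate datasets.
#' @param alpha Nominal significance level for rejection counting.
#' @param seed Root seed for reproducibility (optional; integer).
#' @return A `simulation_config` object.
#' @examples
#' simulation_config(maf = 0.4, n_replicates = 10, seed = 1)
#' @export
simulation_config <- function(maf,
                              beta0 = -2.5,
                              beta1 = log(1),
                              coding = c("additive", "dominant", "recessive"),
                              n_cases = 1000,
                              n_controls = 1000,
                              n_replicates = 1000,
                              alpha = 0.05,
                              seed = NULL) {
  coding <- match.arg(coding)
  if (!is.numeric(maf) || length(maf) != 1 || is.na(maf) ||
    maf <= 0 || maf > 0.5) {
    stop("maf must be in (0, 0.5]", call. = FALSE)
  }
  if (!is.finite(beta0) || !is.finite(beta1)) {
    stop("beta0 and beta1 must be finite", call. = FALSE)
  }
  for (nm in c("n_cases", "n_controls", "n_replicates")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 ||
      abs(v - round(v)) > 1e-8) {
      stop(sprintf("%s must be a positive integer", nm), call. = FALSE)
    }
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
    alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(
      maf = maf, beta0 = beta0, beta1 = beta1, coding = coding,
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      n_replicates = as.integer(n_replicates), alpha = alpha, seed = seed
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: MAF %.2f, beta0 %.3g, beta1 %.4g (%s coding)\n  %d cases / %d controls, %d replicates, alpha %.3g, seed %s\n",
    x$maf, x$beta0, x$beta1, x$coding, x$n_cases, x$n_controls,
    x$n_replicates, x$alpha, if (is.null(x$seed)) "none" else x$seed
  ))
  invisible(x)
}

hwe_probs <- function(maf) {
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

model_coding <- function(coding) {
  switch(coding,
    additive = c(0, 1, 2),
    dominant = c(0, 1, 1),
    recessive = c(0, 0, 1)
  )
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Samples minor-allele counts 0/1/2 with probabilities
#' `((1 - m)^2, 2 m (1 - m), m^2)`.
#'
#' @param n Number of draws.
#' @param maf Minor allele frequency in (0, 0.5].
#' @return Integer vector of genotypes (0, 1, or 2).
#' @export
simulate_genotype <- function(n, maf) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]", call. = FALSE)
  sample.int(3L, n, replace = TRUE, prob = hwe_probs(maf)) - 1L
}

#' Simulate one replicate 2x3 genotype table
#'
#' Individuals carry a Hardy-Weinberg genotype and fall ill with probability
#' `expit(beta0 + beta1 * X)` under the configured genotype coding;
#' individuals are accrued until both arm quotas are met, with the excess of
#' a filled arm discarded. Conditional on arm membership the genotype of
#' each retained individual is an independent draw from
#' `P(g | case) = f_g pi_g / sum(f pi)` (and its control analogue with
#' `1 - pi_g`), so the arm counts are drawn directly from the corresponding
#' multinomials -- distributionally identical to the individual-level
#' accrual, and much faster.
#'
#' @param config A [simulation_config()]. If `config$seed` is set the
#'   replicate is reproducible; `run_experiment()` manages per-replicate
#'   seeds itself.
#' @return A [genotype_table()].
#' @export
simulate_replicate <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  f <- hwe_probs(config$maf)
  pi_g <- stats::plogis(config$beta0 + config$beta1 * model_coding(config$coding))
  p_case <- f * pi_g / sum(f * pi_g)
  p_ctrl <- f * (1 - pi_g) / sum(f * (1 - pi_g))
  x <- as.vector(stats::rmultinom(1, config$n_cases, p_case))
  y <- as.vector(stats::rmultinom(1, config$n_controls, p_ctrl))
  genotype_table(x[1], x[2], x[3], y[1], y[2], y[3])
}

experiment_methods <- c(
  "additive_only", "dominant_only", "recessive_only",
  "min_p", "bonferroni", "exact"
)

#' Run a type-1-error or power experiment
#'
#' Simulates `n_replicates` case-control datasets under `config`, computes
#' the requested per-replicate p-values, and reports the proportion of
#' replicates rejected at `config$alpha` with binomial Monte-Carlo standard
#' errors. One root seed spawns an independent sub-seed per replicate, so
#' any subset of replicates can be regenerated in isolation and runs are
#' bit-reproducible.
#'
#' The exact method is computationally heavy at large arm sizes; it can be
#' switched off (`exact_mode = "off"`), run on every replicate (`"on"`), or
#' run on the first `exact_subsample` replicates only (`"subsample"`), in
#' which case its rejection proportion is estimated from that subsample.
#'
#' @param config A [simulation_config()].
#' @param methods Character vector from `additive_only`, `dominant_only`,
#'   `recessive_only`, `min_p`, `bonferroni`, `exact`.
#' @param exact_mode `"off"`, `"on"`, or `"subsample"`.
#' @param exact_subsample Number of replicates for the exact method when
#'   `exact_mode = "subsample"`.
#' @param max_cells Passed to [exact_pvalue()].
#' @return An `experiment_result`: list with `rates` (tibble: method,
#'   rejections, n, proportion, se), `pvalues` (per-replicate tibble), and
#'   `config`.
#' @examples
#' cfg <- simulation_config(
#'   maf = 0.4, n_cases = 50, n_controls = 50,
#'   n_replicates = 20, seed = 7
#' )
#' run_experiment(cfg, methods = c("additive_only", "min_p"))
#' @export
run_experiment <- function(config,
                           methods = c(
                             "additive_only", "dominant_only",
                             "recessive_only", "min_p", "bonferroni"
                           ),
                           exact_mode = c("off", "on", "subsample"),
                           exact_subsample = NULL,
                           max_cells = 1e11) {
  stopifnot(inherits(config, "simulation_config"))
  exact_mode <- match.arg(exact_mode)
  methods <- match.arg(methods, experiment_methods, several.ok = TRUE)
  want_exact <- "exact" %in% methods
  if (want_exact && exact_mode == "off") {
    methods <- setdiff(methods, "exact")
    want_exact <- FALSE
  }
  if (want_exact && exact_mode == "subsample") {
    if (is.null(exact_subsample) || exact_subsample < 1) {
      stop("exact_mode = 'subsample' requires exact_subsample >= 1",
        call. = FALSE
      )
    }
    exact_subsample <- min(as.integer(exact_subsample), config$n_replicates)
  } else {
    exact_subsample <- config$n_replicates
  }

  if (!is.null(config$seed)) set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$n_replicates)

  rep_cfg <- config
  rep_cfg$seed <- NULL
  rows <- lapply(seq_len(config$n_replicates), function(i) {
    set.seed(rep_seeds[i])
    gt <- simulate_replicate(rep_cfg)
    p <- c(
      additive_only = ca_trend_test(gt, "additive")$p_value,
      dominant_only = ca_trend_test(gt, "dominant")$p_value,
      recessive_only = ca_trend_test(gt, "recessive")$p_value
    )
    p["min_p"] <- min(p[1:3])
    p["bonferroni"] <- min(1, 3 * p["min_p"])
    p["exact"] <- if (want_exact && i <= exact_subsample) {
      exact_pvalue(gt, probs = "pooled", max_cells = max_cells)$p_value
    } else {
      NA_real_
    }
    tibble::as_tibble_row(c(replicate = i, p))
  })
  pvals <- dplyr::bind_rows(rows)

  rates <- purrr::map_dfr(methods, function(m) {
    p <- pvals[[m]]
    p <- p[!is.na(p)]
    n <- length(p)
    rej <- sum(p <= config$alpha)
    prop <- rej / n
    tibble::tibble(
      method = m, rejections = rej, n = n,
      proportion = prop, se = sqrt(prop * (1 - prop) / n)
    )
  })
  structure(
    list(rates = rates, pvalues = pvals, config = config),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "experiment_result: %d replicates, alpha = %.3g\n",
    x$config$n_replicates, x$config$alpha
  ))
  print(as.data.frame(x$rates), row.names = FALSE)
  invisible(x)
}
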