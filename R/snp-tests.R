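#' Test SNPs in a counts data frame under all three genetic models
#'
#' Data-frame-first front end: takes a tibble with one SNP per row (columns
#' `snp`, `case_AA`, `case_Aa`, `case_aa`, `ctrl_AA`, `ctrl_Aa`, `ctrl_aa`,
#' as produced by [read_counts()]) and returns a tibble of results, one row
#' per SNP, ready for piping.
#'
#' @param counts A data frame of genotype counts (see [read_counts()]).
#' @param method Which p-values to compute: `"single"` (per-model
#'   asymptotic only), `"minp"`, `"bonferroni"`, `"exact"`, or `"all"`.
#' @param null_probs Null probability mode for the exact test (`"pooled"`
#'   or `"separate"`).
#' @param tie_tol,max_cells Passed to [exact_pvalue()].
#' @return A tibble with per-model statistics and z-scores, the requested
#'   p-values, a `degenerate` flag, and (when the exact test is run)
#'   `exact_scenario` and `exact_cells`.
#' @examples
#' counts <- tibble::tibble(
#'   snp = "eNOS_-786T>C",
#'   case_AA = 167, case_Aa = 200, case_aa = 54,
#'   ctrl_AA = 203, ctrl_Aa = 185, ctrl_aa = 35
#' )
#' snp_tests(counts, method = "all")
#' @export
snp_tests <- function(counts,
                      method = c("all", "single", "minp", "bonferroni", "exact"),
                      null_probs = c("pooled", "separate"),
                      tie_tol = 1e-12,
                      max_cells = 1e11) {
  method <- match.arg(method)
  null_probs <- match.arg(null_probs)
  counts <- validate_counts_df(counts)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    gt <- genotype_table(
      row$case_AA, row$case_Aa, row$case_aa,
      row$ctrl_AA, row$ctrl_Aa, row$ctrl_aa
    )
    fits <- lapply(genetic_models, function(m) ca_trend_test(gt, m))
    names(fits) <- genetic_models
    out <- tibble::tibble(
      snp = row$snp,
      n_cases = gt$r_x, n_controls = gt$r_y,
      w_additive = fits$additive$statistic,
      w_dominant = fits$dominant$statistic,
      w_recessive = fits$recessive$statistic,
      z_additive = fits$additive$z,
      z_dominant = fits$dominant$z,
      z_recessive = fits$recessive$z,
      p_additive = fits$additive$p_value,
      p_dominant = fits$dominant$p_value,
      p_recessive = fits$recessive$p_value,
      degenerate = any(vapply(fits, `[[`, logical(1), "degenerate"))
    )
    if (method %in% c("all", "minp", "bonferroni")) {
      out$min_p <- min(out$p_additive, out$p_dominant, out$p_recessive)
    }
    if (method %in% c("all", "bonferroni")) {
      out$bonferroni <- min(1, 3 * out$min_p)
    }
    if (method %in% c("all", "exact")) {
      ex <- exact_pvalue(gt,
        probs = null_probs, tie_tol = tie_tol,
        max_cells = max_cells
      )
      out$exact_p <- ex$p_value
      out$exact_scenario <- ex$scenario
      out$exact_cells <- ex$cells
    }
    out
  })
  dplyr::bind_rows(rows)
}

counts_cols <- c(
  "case_AA", "case_Aa", "case_aa",
  "ctrl_AA", "ctrl_Aa", "ctrl_aa"
)

validate_counts_df <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!"snp" %in% names(counts)) {
    counts$snp <- paste0("snp", seq_len(nrow(counts)))
  }
  missing <- setdiff(counts_cols, names(counts))
  if (length(missing)) {
    stop(
      "counts data frame lacks columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  counts
}
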