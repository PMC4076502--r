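# Shared fixtures built in code.

# Promoter-polymorphism breast-cancer table used as the worked example:
# cases 167/200/54, controls 203/185/35 (AA, Aa, aa).
enos_table <- function() {
  genotype_table(167, 200, 54, 203, 185, 35)
}

enos_counts_df <- function() {
  tibble::tibble(
    snp = "eNOS_-786T>C",
    case_AA = 167, case_Aa = 200, case_aa = 54,
    ctrl_AA = 203, ctrl_Aa = 185, ctrl_aa = 35
  )
}

# Random non-degenerate table with the given arm sizes.
random_table <- function(r_x, r_y, px = c(0.4, 0.4, 0.2), py = px) {
  x <- as.vector(stats::rmultinom(1, r_x, px))
  y <- as.vector(stats::rmultinom(1, r_y, py))
  genotype_table(x[1], x[2], x[3], y[1], y[2], y[3])
}

# Independent probability-ordering p-value read off a brute-force pmf:
# used to check the optimized scenario algorithms.
pmf_pvalue <- function(pmf, table, tie_tol = 1e-12) {
  z1o <- table$r_y * table$x[3] - table$r_x * table$y[3]
  z2o <- table$r_y * table$x[2] - table$r_x * table$y[2]
  f_obs <- pmf$prob[pmf$z1 == z1o & pmf$z2 == z2o]
  sum(pmf$prob[pmf$prob <= f_obs * (1 + tie_tol)])
}

counts_cols_for_tests <- function() {
  c("case_AA", "case_Aa", "case_aa", "ctrl_AA", "ctrl_Aa", "ctrl_aa")
}
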