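#' Build a 2x3 case-control genotype table
#'
#' A di-allelic SNP yields three genotypes. With `a` the minor (risk) allele,
#' the fixed column order is (AA, Aa, aa); map your input columns to this
#' order explicitly (the package never guesses allele orientation). Rows are
#' cases and controls.
#'
#' @param x1,x2,x3 Non-negative integer counts of cases with genotypes
#'   AA, Aa, aa.
#' @param y1,y2,y3 Non-negative integer counts of controls with genotypes
#'   AA, Aa, aa.
#'
#' @return An object of class `genotype_table`: a list with integer vectors
#'   `x` (cases) and `y` (controls), and margins `r_x` (cases), `r_y`
#'   (controls), `c` (column totals) and `n`.
#'
#' @examples
#' gt <- genotype_table(167, 200, 54, 203, 185, 35)
#' gt$n
#' @export
genotype_table <- function(x1, x2, x3, y1, y2, y3) {
  x <- c(x1, x2, x3)
  y <- c(y1, y2, y3)
  check_counts(x, "case")
  check_counts(y, "control")
  x <- as.integer(round(x))
  y <- as.integer(round(y))
  if (sum(x) < 1L) {
    stop("genotype table has an empty case arm (r_x = 0)", call. = FALSE)
  }
  if (sum(y) < 1L) {
    stop("genotype table has an empty control arm (r_y = 0)", call. = FALSE)
  }
  structure(
    list(
      x = x, y = y,
      r_x = sum(x), r_y = sum(y),
      c = x + y, n = sum(x) + sum(y)
    ),
    class = "genotype_table"
  )
}

check_counts <- function(v, arm) {
  if (length(v) != 3L || !is.numeric(v) || anyNA(v)) {
    stop(sprintf("%s counts must be three non-missing numbers", arm),
      call. = FALSE
    )
  }
  if (any(v < 0)) {
    stop(sprintf("%s counts must be non-negative", arm), call. = FALSE)
  }
  if (any(abs(v - round(v)) > 1e-8)) {
    stop(sprintf("%s counts must be integers", arm), call. = FALSE)
  }
  invisible(v)
}

#' @export
print.genotype_table <- function(x, ...) {
  m <- rbind(cases = x$x, controls = x$y, total = x$c)
  colnames(m) <- c("AA", "Aa", "aa")
  cat(sprintf(
    "2x3 genotype table: %d cases, %d controls (n = %d)\n",
    x$r_x, x$r_y, x$n
  ))
  print(m)
  invisible(x)
}

#' Genotype weights for a genetic model
#'
#' The trend test weights the three genotype columns (AA, Aa, aa) according
#' to the assumed mode of inheritance: additive (0, 1, 2), dominant
#' (0, 1, 1), or recessive (0, 0, 1). No other weight triples are
#' constructible; the model label is the only entry point.
#'
#' @param model One of `"additive"`, `"dominant"`, `"recessive"`.
#' @return Integer vector of length 3, named by genotype, with attribute
#'   `model`.
#' @examples
#' trend_weights("dominant")
#' @export
trend_weights <- function(model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  w <- switch(model,
    additive  = c(0L, 1L, 2L),
    dominant  = c(0L, 1L, 1L),
    recessive = c(0L, 0L, 1L)
  )
  names(w) <- c("AA", "Aa", "aa")
  attr(w, "model") <- model
  w
}

genetic_models <- c("additive", "dominant", "recessive")

#' Unnormalized Cochran-Armitage trend statistic
#'
#' Computes `W = sum_i t_i (R_Y X_i - R_X Y_i)` for the given model weights.
#' `W` is an exact integer; its magnitude is bounded by `2 * r_x * r_y`, so
#' double arithmetic is exact for any table R can hold.
#'
#' @param table A [genotype_table()].
#' @param model Genetic model label, or an explicit weight vector from
#'   [trend_weights()].
#' @return The statistic as a (signed) numeric integer.
#' @examples
#' gt <- genotype_table(167, 200, 54, 203, 185, 35)
#' trend_statistic(gt, "additive")
#' @export
trend_statistic <- function(table, model = "additive") {
  stopifnot(inherits(table, "genotype_table"))
  w <- if (is.character(model)) trend_weights(model) else as.numeric(model)
  sum(w * (as.numeric(table$r_y) * table$x - as.numeric(table$r_x) * table$y))
}

#' All three trend statistics and the symmetrized transform
#'
#' Returns the unnormalized statistics for the additive (`t1`), dominant
#' (`t2`) and recessive (`t3`) models, together with the lattice coordinates
#' `z1 = R_Y X_3 - R_X Y_3` and `z2 = R_Y X_2 - R_X Y_2`. The three
#' statistics are functionally dependent (`t3 = t1 - t2`), and `(t1, t2)`
#' and `(z1, z2)` are related by the invertible map `t1 = 2 z1 + z2`,
#' `t2 = z1 + z2`; the joint distribution machinery works in `(z1, z2)`.
#'
#' @param table A [genotype_table()].
#' @return A one-row tibble with columns `t1`, `t2`, `t3`, `z1`, `z2`.
#' @examples
#' trend_statistics(genotype_table(167, 200, 54, 203, 185, 35))
#' @export
trend_statistics <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  d <- as.numeric(table$r_y) * table$x - as.numeric(table$r_x) * table$y
  tibble::tibble(
    t1 = d[2] + 2 * d[3],
    t2 = d[2] + d[3],
    t3 = d[3],
    z1 = d[3],
    z2 = d[2]
  )
}

#' Convert between (t1, t2) and (z1, z2) lattice coordinates
#'
#' `zz_to_tt()` maps the symmetrized coordinates back to the additive and
#' dominant statistics (`t1 = 2 z1 + z2`, `t2 = z1 + z2`); `tt_to_zz()` is
#' its inverse (`z1 = t1 - t2`, `z2 = 2 t2 - t1`). Both accept vectors.
#'
#' @param z1,z2,t1,t2 Numeric vectors of lattice coordinates.
#' @return A tibble with the transformed coordinate pair.
#' @examples
#' tt_to_zz(22929, 14822)
#' @export
zz_to_tt <- function(z1, z2) {
  tibble::tibble(t1 = 2 * z1 + z2, t2 = z1 + z2)
}

#' @rdname zz_to_tt
#' @export
tt_to_zz <- function(t1, t2) {
  tibble::tibble(z1 = t1 - t2, z2 = 2 * t2 - t1)
}

#' Swap the case and control arms of a table
#'
#' Relabeling cases as controls negates all three trend statistics; the
#' exact p-value is invariant under the swap (with the probability triples
#' swapped accordingly).
#'
#' @param table A [genotype_table()].
#' @return A [genotype_table()] with arms exchanged.
#' @export
swap_arms <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  genotype_table(
    table$y[1], table$y[2], table$y[3],
    table$x[1], table$x[2], table$x[3]
  )
}
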