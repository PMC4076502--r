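#' Null genotype probability triples
#'
#' The joint null distribution of the trend statistics treats the case and
#' control genotype configurations as independent trinomials with
#' probability triples `p` (cases) and `q` (controls). Under the null the
#' two arms share a common genotype distribution, so the default estimate
#' pools both arms: `p_i = q_i = C_i / N`. The `separate` mode uses the
#' per-arm relative frequencies `X_i / R_X` and `Y_i / R_Y` (the unrestricted
#' maximum-likelihood estimates, which do not impose the null); `fixed`
#' accepts user-supplied triples.
#'
#' @param table A [genotype_table()].
#' @param mode `"pooled"` (default), `"separate"`, or `"fixed"`.
#' @param p,q Probability triples for `mode = "fixed"`; each must be
#'   non-negative and sum to 1 (tolerance 1e-9). If only `p` is given it is
#'   used for both arms.
#' @return A `null_genotype_probs` object: list with `p`, `q`, `mode`.
#' @examples
#' gt <- genotype_table(167, 200, 54, 203, 185, 35)
#' null_genotype_probs(gt)
#' @export
null_genotype_probs <- function(table,
                                mode = c("pooled", "separate", "fixed"),
                                p = NULL, q = NULL) {
  mode <- match.arg(mode)
  if (mode != "fixed") stopifnot(inherits(table, "genotype_table"))
  pq <- switch(mode,
    pooled = {
      pr <- table$c / table$n
      list(p = pr, q = pr)
    },
    separate = list(p = table$x / table$r_x, q = table$y / table$r_y),
    fixed = {
      if (is.null(p)) stop("mode = 'fixed' requires p", call. = FALSE)
      if (is.null(q)) q <- p
      check_prob_triple(p)
      check_prob_triple(q)
      list(p = p / sum(p), q = q / sum(q))
    }
  )
  structure(c(pq, list(mode = mode)), class = "null_genotype_probs")
}

check_prob_triple <- function(v) {
  if (length(v) != 3L || !is.numeric(v) || anyNA(v) || any(v < 0)) {
    stop("probability triple must be three non-negative numbers",
      call. = FALSE
    )
  }
  if (abs(sum(v) - 1) > 1e-9) {
    stop("probability triple must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  invisible(v)
}

resolve_probs <- function(table, probs) {
  if (inherits(probs, "null_genotype_probs")) {
    return(probs)
  }
  if (is.character(probs)) {
    return(null_genotype_probs(table, probs))
  }
  stop("probs must be 'pooled', 'separate', or a null_genotype_probs object",
    call. = FALSE
  )
}

#' Number of solution-space triangles
#'
#' The lattice support of the joint pmf is a union of translated triangles,
#' one per control configuration `(Y_2, Y_3)` with `Y_2 + Y_3 <= R_Y`; there
#' are `(R_Y + 1)(R_Y + 2) / 2` of them, each holding
#' `(R_X + 1)(R_X + 2) / 2` lattice points before overlap.
#'
#' @param r_y Number of controls (non-negative integer).
#' @return The triangle count as an integer-valued numeric.
#' @examples
#' triangle_count(5) # 21
#' @export
triangle_count <- function(r_y) {
  if (!is.numeric(r_y) || length(r_y) != 1L || is.na(r_y) || r_y < 0 ||
    abs(r_y - round(r_y)) > 1e-8) {
    stop("r_y must be a single non-negative integer", call. = FALSE)
  }
  (r_y + 1) * (r_y + 2) / 2
}

gcd2 <- function(a, b) {
  while (b != 0) {
    tmp <- a %% b
    a <- b
    b <- tmp
  }
  a
}

#' Classify the arm-size structure of the solution space
#'
#' How the support triangles overlap depends on `gcd(R_X, R_Y)`: for coprime
#' arm sizes the triangles meet only at the origin (three of them); for
#' equal arm sizes the support condenses to a sparse lattice spaced `R`
#' apart; otherwise overlaps occur at multiples of the gcd. The exact
#' p-value dispatcher selects its algorithm from this classification (equal
#' takes precedence: `r_x = r_y = 1` is classified `equal`).
#'
#' @param r_x,r_y Arm sizes (positive integers).
#' @return `"coprime"`, `"equal"`, or `"general"`.
#' @examples
#' gcd_scenario(19, 2)
#' gcd_scenario(5, 5)
#' gcd_scenario(10, 2)
#' @export
gcd_scenario <- function(r_x, r_y) {
  stopifnot(r_x >= 1, r_y >= 1)
  if (r_x == r_y) {
    return("equal")
  }
  if (gcd2(r_x, r_y) == 1) {
    return("coprime")
  }
  "general"
}

# Log trinomial masses over the triangle {(g2, g3): g2 + g3 <= r}.
# Zero-probability categories contribute log(0) = -Inf unless the
# corresponding count is zero (0 * log(0) treated as 0).
log_trinom_triangle <- function(r, pr) {
  g2 <- rep.int(0:r, r + 1L)
  g3 <- rep(0:r, each = r + 1L)
  keep <- g2 + g3 <= r
  g2 <- g2[keep]
  g3 <- g3[keep]
  g1 <- r - g2 - g3
  lp <- log(pr)
  term <- function(cnt, l) ifelse(cnt == 0, 0, cnt * l)
  lf <- lgamma(r + 1) - lgamma(g1 + 1) - lgamma(g2 + 1) - lgamma(g3 + 1) +
    term(g1, lp[1]) + term(g2, lp[2]) + term(g3, lp[3])
  list(g2 = g2, g3 = g3, lf = lf)
}

resource_error <- function(msg) {
  stop(errorCondition(msg, class = c(
    "exacttrend_resource_error",
    "error", "condition"
  )))
}

#' Joint pmf by full enumeration (testing oracle)
#'
#' Enumerates every case configuration `(X_2, X_3)` against every control
#' configuration `(Y_2, Y_3)` and accumulates trinomial-product mass at
#' `(z_1, z_2) = (R_Y X_3 - R_X Y_3, R_Y X_2 - R_X Y_2)`. This is the slow
#' reference against which the optimized scenario algorithms are verified;
#' it refuses tables beyond a small-enumeration guard.
#'
#' @param r_x,r_y Arm sizes.
#' @param probs A `null_genotype_probs` object (see
#'   [null_genotype_probs()]).
#' @param guard Maximum allowed value of `(r_x+1)^2 (r_y+1)^2 / 4`.
#' @return A `joint_pmf` object: tibble with columns `z1`, `z2`, `prob`,
#'   plus attributes `r_x`, `r_y`, `probs`, `method`, `total_mass`.
#' @examples
#' pr <- null_genotype_probs(mode = "fixed", p = c(1, 1, 1) / 3)
#' pmf <- joint_pmf_brute_force(5, 5, pr)
#' sum(pmf$prob)
#' @export
joint_pmf_brute_force <- function(r_x, r_y, probs, guard = 1e7) {
  stopifnot(inherits(probs, "null_genotype_probs"))
  if ((r_x + 1)^2 * (r_y + 1)^2 / 4 > guard) {
    resource_error(paste0(
      "full enumeration guard exceeded ((r_x+1)^2 (r_y+1)^2 / 4 > ",
      format(guard), "); use exact_pvalue(), which dispatches an ",
      "optimized scenario algorithm"
    ))
  }
  tx <- log_trinom_triangle(r_x, probs$p)
  ty <- log_trinom_triangle(r_y, probs$q)
  nx <- length(tx$lf)
  ny <- length(ty$lf)
  ix <- rep.int(seq_len(nx), ny)
  iy <- rep(seq_len(ny), each = nx)
  z1 <- r_y * tx$g3[ix] - r_x * ty$g3[iy]
  z2 <- r_y * tx$g2[ix] - r_x * ty$g2[iy]
  mass <- exp(tx$lf[ix] + ty$lf[iy])
  off <- r_x * r_y
  key <- (z1 + off) * (2 * off + 1) + (z2 + off)
  agg <- rowsum(mass, key)
  k <- as.numeric(rownames(agg))
  out <- tibble::tibble(
    z1 = k %/% (2 * off + 1) - off,
    z2 = k %% (2 * off + 1) - off,
    prob = unname(agg[, 1])
  )
  out <- out[out$prob > 0, ]
  new_joint_pmf(out, r_x, r_y, probs, "brute_force")
}

new_joint_pmf <- function(tbl, r_x, r_y, probs, method) {
  structure(
    tbl,
    r_x = r_x, r_y = r_y, probs = probs, method = method,
    total_mass = sum(tbl$prob),
    class = c("joint_pmf", class(tbl))
  )
}

#' Joint pmf of the symmetrized trend statistics
#'
#' Computes the pmf of `(Z_1, Z_2)` under the supplied null probability
#' triples. Equal arm sizes use the condensed-lattice algorithm (support
#' spaced `R` apart, compiled cross-correlation of the two trinomial
#' triangles); other sizes fall back to full enumeration within the guard.
#'
#' @inheritParams joint_pmf_brute_force
#' @return A `joint_pmf` tibble (columns `z1`, `z2`, `prob`).
#' @export
joint_pmf <- function(r_x, r_y, probs, guard = 1e7) {
  stopifnot(inherits(probs, "null_genotype_probs"))
  if (r_x == r_y) {
    m <- condensed_pmf_matrix(r_x, probs)
    idx <- which(m > 0, arr.ind = TRUE)
    out <- tibble::tibble(
      z1 = r_x * (idx[, 2] - r_x - 1),
      z2 = r_x * (idx[, 1] - r_x - 1),
      prob = m[idx]
    )
    return(new_joint_pmf(out, r_x, r_y, probs, "condensed"))
  }
  joint_pmf_brute_force(r_x, r_y, probs, guard = guard)
}

condensed_pmf_matrix <- function(r, probs) {
  tri_mat <- function(n, pr) {
    t3 <- log_trinom_triangle(n, pr)
    m <- matrix(-Inf, n + 1, n + 1)
    m[cbind(t3$g2 + 1L, t3$g3 + 1L)] <- t3$lf
    m
  }
  lfx <- tri_mat(r, probs$p)
  lfy <- tri_mat(r, probs$q)
  sym <- isTRUE(all.equal(probs$p, probs$q, tolerance = 0))
  condensed_pmf_cpp(r, lfx, lfy, sym)
}

#' Triangle contributors at each support point
#'
#' For each lattice point of the joint support, counts the number of
#' distinct control configurations `(Y_2, Y_3)` -- i.e. support triangles --
#' contributing mass there. With coprime arm sizes the only multi-triangle
#' point is the origin, where exactly three triangles meet; otherwise
#' overlaps occur at multiples of `gcd(R_X, R_Y)`.
#'
#' @inheritParams joint_pmf_brute_force
#' @return A tibble with columns `z1`, `z2`, `n_triangles`, and attribute
#'   `n_triangles_total` (the number of distinct triangles enumerated).
#' @examples
#' to <- triangle_overlap(5, 5)
#' attr(to, "n_triangles_total") # 21
#' @export
triangle_overlap <- function(r_x, r_y, guard = 1e7) {
  if ((r_x + 1)^2 * (r_y + 1)^2 / 4 > guard) {
    resource_error("triangle enumeration guard exceeded")
  }
  g2 <- rep.int(0:r_x, r_x + 1L)
  g3 <- rep(0:r_x, each = r_x + 1L)
  keep <- g2 + g3 <= r_x
  x2 <- g2[keep]
  x3 <- g3[keep]
  h2 <- rep.int(0:r_y, r_y + 1L)
  h3 <- rep(0:r_y, each = r_y + 1L)
  keep <- h2 + h3 <= r_y
  y2 <- h2[keep]
  y3 <- h3[keep]
  nx <- length(x2)
  ny <- length(y2)
  ix <- rep.int(seq_len(nx), ny)
  iy <- rep(seq_len(ny), each = nx)
  z1 <- r_y * x3[ix] - r_x * y3[iy]
  z2 <- r_y * x2[ix] - r_x * y2[iy]
  key <- paste(z1, z2, iy) # one row per (cell, triangle)
  cell <- paste(z1, z2)[!duplicated(key)]
  tab <- table(cell)
  zz <- do.call(rbind, strsplit(names(tab), " "))
  out <- tibble::tibble(
    z1 = as.numeric(zz[, 1]),
    z2 = as.numeric(zz[, 2]),
    n_triangles = as.integer(tab)
  )
  attr(out, "n_triangles_total") <- ny
  out
}

#' Exact joint-model p-value for a 2x3 genotype table
#'
#' Computes the probability-ordering exact p-value for testing one SNP under
#' the additive, dominant, and recessive trend models jointly: the sum of
#' joint-pmf masses over all lattice points whose probability does not
#' exceed that of the observed statistic pair,
#' `p = sum f_T over {(T_1, T_2): f_T <= f_T(obs)}`.
#' Because the three statistics are functionally dependent
#' (`T_3 = T_1 - T_2`), the bivariate joint distribution of `(T_1, T_2)` --
#' computed in the symmetrized coordinates `(Z_1, Z_2)` -- carries all three
#' models, so a single exact tail probability replaces any multiplicity
#' correction across models.
#'
#' The algorithm dispatches on [gcd_scenario()]: coprime arm sizes stream
#' over non-overlapping triangles with a sorted prefix-sum reduction (no
#' support is materialized); equal arm sizes use the condensed
#' `(2R+1) x (2R+1)` lattice via compiled cross-correlation; the general
#' case accumulates per-cell triangle contributions in chunks. All paths
#' agree with [joint_pmf_brute_force()] to high precision.
#'
#' Ties ("equally probable") are included with a relative tolerance:
#' a cell with mass `f` enters the sum when `f <= f_obs * (1 + tie_tol)`,
#' since symmetric cells carry masses equal only up to floating rounding.
#'
#' @param table A [genotype_table()].
#' @param probs `"pooled"` (default), `"separate"`, or a
#'   [null_genotype_probs()] object.
#' @param tie_tol Relative tolerance for probability ties.
#' @param max_cells Refuse when the estimated number of elementary terms
#'   `(r_x+1)(r_x+2)(r_y+1)(r_y+2)/4` exceeds this ceiling.
#' @param method Algorithm override (default `"auto"` dispatches on the
#'   scenario); `"brute_force"` forces full enumeration.
#' @return An `exact_result` object: list with `p_value`, `f_obs`,
#'   `z1`, `z2`, `t1`, `t2`, `t3`, `scenario`, `cells` (support cells
#'   enumerated), `probs`, `tie_tol`.
#' @examples
#' gt <- genotype_table(167, 200, 54, 203, 185, 35)
#' exact_pvalue(gt)
#' @export
exact_pvalue <- function(table, probs = "pooled", tie_tol = 1e-12,
                         max_cells = 1e11,
                         method = c(
                           "auto", "coprime", "equal", "general",
                           "brute_force"
                         )) {
  stopifnot(inherits(table, "genotype_table"))
  method <- match.arg(method)
  pr <- resolve_probs(table, probs)
  est <- (table$r_x + 1) * (table$r_x + 2) *
    (table$r_y + 1) * (table$r_y + 2) / 4
  if (est > max_cells) {
    resource_error(sprintf(
      "estimated %.3g elementary terms exceeds max_cells = %.3g; raise max_cells or reduce the table",
      est, max_cells
    ))
  }
  if (method == "auto") {
    method <- switch(gcd_scenario(table$r_x, table$r_y),
      equal = "equal",
      coprime = "coprime",
      general = "general"
    )
  }
  res <- switch(method,
    coprime = exact_p_coprime(table, pr, tie_tol),
    equal = exact_p_equal(table, pr, tie_tol),
    general = exact_p_general(table, pr, tie_tol),
    brute_force = exact_p_brute(table, pr, tie_tol)
  )
  st <- trend_statistics(table)
  structure(
    list(
      p_value = min(res$p, 1),
      f_obs = res$f_obs,
      z1 = st$z1, z2 = st$z2, t1 = st$t1, t2 = st$t2, t3 = st$t3,
      scenario = res$scenario, cells = res$cells,
      probs = pr, tie_tol = tie_tol
    ),
    class = "exact_result"
  )
}

#' @export
print.exact_result <- function(x, ...) {
  cat(sprintf(
    "Exact joint-model trend test\n  observed (z1, z2) = (%d, %d); f_obs = %.4g\n  exact p-value = %.4g  [%s scenario, %s support cells]\n",
    x$z1, x$z2, x$f_obs, x$p_value, x$scenario, format(x$cells, big.mark = ",")
  ))
  invisible(x)
}

check_f_obs <- function(f_obs) {
  if (!is.finite(f_obs) || f_obs <= 0) {
    stop(paste(
      "observed table has zero probability under the supplied",
      "null genotype probabilities"
    ), call. = FALSE)
  }
  f_obs
}

# Scenario 1 (coprime arm sizes): triangles are disjoint except at the
# origin, where exactly three meet, so each cell mass is a single trinomial
# product. The inclusion sum over {fx * fy <= threshold} is evaluated by
# sorting the control-triangle masses and prefix-summing: for each case
# configuration the admissible control mass is a prefix. The three origin
# products are removed from the generic sum and the pooled origin cell is
# handled once.
exact_p_coprime <- function(table, pr, tie_tol) {
  r_x <- table$r_x
  r_y <- table$r_y
  tx <- log_trinom_triangle(r_x, pr$p)
  ty <- log_trinom_triangle(r_y, pr$q)

  lf_at <- function(tr, a2, a3) {
    i <- which(tr$g2 == a2 & tr$g3 == a3)
    if (length(i)) tr$lf[i] else -Inf
  }
  # origin contributors: (X2,X3;Y2,Y3) = (0,0;0,0), (r_x,0;r_y,0), (0,r_x;0,r_y)
  lo <- c(
    lf_at(tx, 0, 0) + lf_at(ty, 0, 0),
    lf_at(tx, r_x, 0) + lf_at(ty, r_y, 0),
    lf_at(tx, 0, r_x) + lf_at(ty, 0, r_y)
  )
  m0 <- sum(exp(lo))

  at_origin <- table$x[3] * r_y == table$y[3] * r_x &&
    table$x[2] * r_y == table$y[2] * r_x
  f_obs <- if (at_origin) {
    m0
  } else {
    exp(lf_at(tx, table$x[2], table$x[3]) + lf_at(ty, table$y[2], table$y[3]))
  }
  check_f_obs(f_obs)
  lth <- log(f_obs) + log1p(tie_tol)

  lfx <- tx$lf[is.finite(tx$lf)]
  lfy <- ty$lf[is.finite(ty$lf)]
  sy <- sort(lfy)
  cs <- cumsum(exp(sy))
  idx <- findInterval(lth - lfx, sy)
  have <- idx > 0
  s <- sum(exp(lfx[have]) * cs[idx[have]])
  for (l in lo) {
    if (is.finite(l) && l <= lth) s <- s - exp(l)
  }
  if (m0 > 0 && log(m0) <= lth) s <- s + m0
  list(
    p = s, f_obs = f_obs, scenario = "coprime",
    cells = as.double(length(lfx)) * length(lfy) - 2
  )
}

# Scenario 2 (equal arm sizes R): support condenses to differences
# (d1, d2) = (X3 - Y3, X2 - Y2) on a (2R+1)^2 lattice; masses come from the
# compiled cross-correlation of the two trinomial triangles (half the grid
# when the probability triples coincide).
exact_p_equal <- function(table, pr, tie_tol) {
  r <- table$r_x
  m <- condensed_pmf_matrix(r, pr)
  d1 <- table$x[3] - table$y[3]
  d2 <- table$x[2] - table$y[2]
  f_obs <- m[d2 + r + 1, d1 + r + 1]
  check_f_obs(f_obs)
  thr <- f_obs * (1 + tie_tol)
  pos <- m > 0
  list(
    p = sum(m[pos & m <= thr]), f_obs = f_obs, scenario = "equal",
    cells = sum(pos)
  )
}

# Scenario 3 (general): per-cell accumulation of contributions from every
# triangle, chunked over control configurations and merged with rowsum so
# only the distinct support cells are ever held.
exact_p_general <- function(table, pr, tie_tol, pair_budget = 2e7) {
  r_x <- table$r_x
  r_y <- table$r_y
  tx <- log_trinom_triangle(r_x, pr$p)
  ty <- log_trinom_triangle(r_y, pr$q)
  fin_x <- is.finite(tx$lf)
  fin_y <- is.finite(ty$lf)
  x2 <- tx$g2[fin_x]
  x3 <- tx$g3[fin_x]
  efx <- exp(tx$lf[fin_x])
  y2 <- ty$g2[fin_y]
  y3 <- ty$g3[fin_y]
  efy <- exp(ty$lf[fin_y])
  nx <- length(efx)
  ny <- length(efy)
  if (as.double(nx) * ny > pair_budget) {
    resource_error(sprintf(
      "general-scenario path needs %.3g configuration pairs (budget %.3g)",
      as.double(nx) * ny, pair_budget
    ))
  }
  off <- r_x * r_y
  base <- 2 * off + 1
  chunk <- max(1L, as.integer(2e6 %/% nx))
  agg_v <- numeric(0)
  agg_k <- numeric(0)
  for (start in seq(1L, ny, by = chunk)) {
    j <- start:min(start + chunk - 1L, ny)
    m <- length(j)
    ix <- rep.int(seq_len(nx), m)
    iy <- rep(j, each = nx)
    z1 <- r_y * x3[ix] - r_x * y3[iy]
    z2 <- r_y * x2[ix] - r_x * y2[iy]
    key <- (z1 + off) * base + (z2 + off)
    part <- rowsum(c(agg_v, efx[ix] * efy[iy]), c(agg_k, key))
    agg_v <- part[, 1]
    agg_k <- as.numeric(rownames(part))
  }
  z1o <- r_y * table$x[3] - r_x * table$y[3]
  z2o <- r_y * table$x[2] - r_x * table$y[2]
  f_obs <- agg_v[match((z1o + off) * base + (z2o + off), agg_k)]
  check_f_obs(f_obs)
  thr <- f_obs * (1 + tie_tol)
  list(
    p = sum(agg_v[agg_v <= thr]), f_obs = unname(f_obs),
    scenario = "general", cells = length(agg_v)
  )
}

exact_p_brute <- function(table, pr, tie_tol) {
  pmf <- joint_pmf_brute_force(table$r_x, table$r_y, pr)
  z1o <- table$r_y * table$x[3] - table$r_x * table$y[3]
  z2o <- table$r_y * table$x[2] - table$r_x * table$y[2]
  f_obs <- pmf$prob[pmf$z1 == z1o & pmf$z2 == z2o]
  if (length(f_obs) == 0) f_obs <- 0
  check_f_obs(f_obs)
  thr <- f_obs * (1 + tie_tol)
  list(
    p = sum(pmf$prob[pmf$prob <= thr]), f_obs = f_obs,
    scenario = "brute_force", cells = nrow(pmf)
  )
}

#' Write a joint pmf to a delimited file
#'
#' Three tab-separated columns (`z1`, `z2`, `prob`), full double precision;
#' suitable for plotting the triangle-pattern support.
#'
#' @param pmf A `joint_pmf` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "joint_pmf"))
  df <- data.frame(
    z1 = pmf$z1, z2 = pmf$z2,
    prob = format(pmf$prob, digits = 17, trim = TRUE)
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}
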