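test_that("null probability triples are estimated and validated correctly", {
  gt <- enos_table()
  pooled <- null_genotype_probs(gt)
  expect_equal(pooled$p, c(370, 385, 89) / 844)
  expect_identical(pooled$p, pooled$q)

  sep <- null_genotype_probs(gt, "separate")
  expect_equal(sep$p, c(167, 200, 54) / 421)
  expect_equal(sep$q, c(203, 185, 35) / 423)

  fx <- null_genotype_probs(mode = "fixed", p = c(1, 1, 1) / 3)
  expect_equal(fx$p, rep(1 / 3, 3))
  expect_equal(fx$q, rep(1 / 3, 3))
  expect_error(null_genotype_probs(mode = "fixed", p = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(null_genotype_probs(mode = "fixed", p = c(-0.1, 0.6, 0.5)), "non-negative")
})

test_that("triangle count follows the closed form", {
  expect_equal(triangle_count(0), 1)
  expect_equal(triangle_count(2), 6)
  expect_equal(triangle_count(3), 10)
  expect_equal(triangle_count(5), 21)
  expect_error(triangle_count(-1))
})

test_that("gcd scenarios classify arm sizes as dispatched", {
  expect_equal(gcd_scenario(19, 2), "coprime")
  expect_equal(gcd_scenario(5, 5), "equal")
  expect_equal(gcd_scenario(10, 2), "general")
  expect_equal(gcd_scenario(1, 1), "equal")
  expect_equal(gcd_scenario(421, 423), "coprime")
  expect_equal(gcd_scenario(4, 6), "general")
})

test_that("brute-force pmf is normalized and matches a direct 3x3 enumeration", {
  pr <- null_genotype_probs(mode = "fixed", p = c(0.2, 0.5, 0.3))
  pmf <- joint_pmf_brute_force(1, 1, pr)
  # direct oracle: both arms have 3 configurations each
  conf <- expand.grid(gx = 1:3, gy = 1:3)
  p <- pr$p
  mass <- p[conf$gx] * p[conf$gy]
  z1 <- (conf$gx == 3) - (conf$gy == 3)
  z2 <- (conf$gx == 2) - (conf$gy == 2)
  ref <- rowsum(mass, paste(z1, z2))
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  expect_equal(nrow(pmf), nrow(ref))
  for (k in seq_len(nrow(pmf))) {
    expect_equal(
      pmf$prob[k],
      unname(ref[paste(pmf$z1[k], pmf$z2[k]), 1]),
      tolerance = 1e-12
    )
  }
})

test_that("brute-force enumeration guard refuses large tables", {
  pr <- null_genotype_probs(mode = "fixed", p = c(1, 1, 1) / 3)
  expect_error(
    joint_pmf_brute_force(500, 500, pr),
    class = "exacttrend_resource_error"
  )
})

test_that("optimized scenario paths equal the brute-force oracle", {
  set.seed(42)
  cases <- list(
    c(19, 2), c(3, 2), c(7, 5), c(9, 4), # coprime
    c(5, 5), c(8, 8), c(12, 12), # equal
    c(10, 2), c(4, 6), c(12, 9) # general
  )
  for (rr in cases) {
    pr <- null_genotype_probs(
      mode = "fixed",
      p = as.vector(prop.table(stats::runif(3, 0.1, 1)))
    )
    pmf <- joint_pmf_brute_force(rr[1], rr[2], pr)
    for (i in 1:8) {
      gt <- random_table(rr[1], rr[2])
      res <- exact_pvalue(gt, probs = pr)
      expect_equal(res$scenario, gcd_scenario(rr[1], rr[2]))
      expect_equal(res$p_value, pmf_pvalue(pmf, gt), tolerance = 1e-10)
      expect_gte(res$p_value, res$f_obs)
      expect_lte(res$p_value, 1)
    }
  }
})

test_that("pooled and separate probability modes agree with the oracle too", {
  set.seed(9)
  for (rr in list(c(11, 3), c(6, 6), c(8, 6))) {
    for (mode in c("pooled", "separate")) {
      gt <- random_table(rr[1], rr[2], c(0.5, 0.3, 0.2), c(0.3, 0.4, 0.3))
      pr <- null_genotype_probs(gt, mode)
      res <- exact_pvalue(gt, probs = pr)
      pmf <- joint_pmf_brute_force(rr[1], rr[2], pr)
      expect_equal(res$p_value, pmf_pvalue(pmf, gt), tolerance = 1e-10)
    }
  }
})

test_that("condensed equal-arms pmf matches brute force cell by cell", {
  gt <- random_table(5, 5)
  for (mode in c("pooled", "separate")) {
    pr <- null_genotype_probs(gt, mode)
    a <- joint_pmf(5, 5, pr) # condensed path
    b <- joint_pmf_brute_force(5, 5, pr)
    expect_equal(attr(a, "method"), "condensed")
    a <- a[order(a$z1, a$z2), ]
    b <- b[order(b$z1, b$z2), ]
    expect_equal(a$z1, b$z1)
    expect_equal(a$z2, b$z2)
    expect_equal(a$prob, b$prob, tolerance = 1e-12)
  }
})

test_that("equal-arms support lives on multiples of R and every condensed p-value matches", {
  r <- 5
  gt0 <- random_table(r, r)
  pr <- null_genotype_probs(gt0, "pooled")
  pmf <- joint_pmf_brute_force(r, r, pr)
  expect_true(all(pmf$z1 %% r == 0))
  expect_true(all(pmf$z2 %% r == 0))
  # every attainable observation: all (x2, x3) x (y2, y3) combinations
  tri <- subset(expand.grid(g2 = 0:r, g3 = 0:r), g2 + g3 <= r)
  for (i in seq_len(nrow(tri))) {
    for (j in seq_len(nrow(tri))) {
      gt <- genotype_table(
        r - tri$g2[i] - tri$g3[i], tri$g2[i], tri$g3[i],
        r - tri$g2[j] - tri$g3[j], tri$g2[j], tri$g3[j]
      )
      res <- exact_pvalue(gt, probs = pr)
      expect_equal(res$p_value, pmf_pvalue(pmf, gt), tolerance = 1e-10)
    }
  }
})

test_that("coprime triangles overlap only at the origin, where three meet", {
  for (rr in list(c(19, 2), c(5, 3), c(7, 4), c(9, 2))) {
    to <- triangle_overlap(rr[1], rr[2])
    expect_equal(attr(to, "n_triangles_total"), triangle_count(rr[2]))
    multi <- to[to$n_triangles > 1, ]
    expect_equal(nrow(multi), 1)
    expect_equal(multi$z1, 0)
    expect_equal(multi$z2, 0)
    expect_equal(multi$n_triangles, 3)
    # triangle points count: union + overlap bookkeeping is conservative
    expect_equal(
      sum(to$n_triangles),
      triangle_count(rr[2]) * (rr[1] + 1) * (rr[1] + 2) / 2
    )
  }
})

test_that("non-coprime overlaps occur away from the origin at gcd multiples", {
  to <- triangle_overlap(4, 2) # gcd 2
  multi <- to[to$n_triangles > 1 & !(to$z1 == 0 & to$z2 == 0), ]
  expect_gt(nrow(multi), 0)
  g <- 2
  expect_true(all(multi$z1 %% g == 0))
  expect_true(all(multi$z2 %% g == 0))
})

test_that("equal-arms condensed overlap pattern is symmetric and complete", {
  r <- 10
  to <- triangle_overlap(r, r)
  expect_equal(
    sum(to$n_triangles),
    triangle_count(r) * (r + 1) * (r + 2) / 2
  )
  # overlap count at (z1, z2) equals the count at (-z1, -z2)
  key <- paste(to$z1, to$z2)
  mirror <- paste(-to$z1, -to$z2)
  expect_setequal(key, mirror)
  cnt <- stats::setNames(to$n_triangles, key)
  expect_equal(unname(cnt[mirror]), to$n_triangles)
})

test_that("p-value ordering is monotone in the observed cell mass", {
  set.seed(13)
  gt0 <- random_table(7, 5)
  pr <- null_genotype_probs(gt0, "pooled")
  pmf <- joint_pmf_brute_force(7, 5, pr)
  ord <- order(pmf$prob)
  ps <- cumsum(pmf$prob[ord])
  expect_true(all(diff(ps) >= 0))
  expect_equal(ps[length(ps)], 1, tolerance = 1e-10)
})

test_that("case-control relabeling leaves the exact p-value unchanged", {
  set.seed(17)
  for (rr in list(c(9, 4), c(6, 6), c(10, 4))) {
    gt <- random_table(rr[1], rr[2], c(0.5, 0.3, 0.2), c(0.3, 0.4, 0.3))
    a <- exact_pvalue(gt, probs = "pooled")
    b <- exact_pvalue(swap_arms(gt), probs = "pooled")
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("observations in a zero-mass statistic cell are an error", {
  # coprime arms: each non-origin cell is a single configuration, so an
  # observation in a zero-probability category has a zero-mass cell
  gt <- genotype_table(1, 1, 1, 1, 1, 0)
  pr <- null_genotype_probs(mode = "fixed", p = c(0.5, 0.5, 0))
  expect_error(exact_pvalue(gt, probs = pr), "zero probability")
  # equal arms pool configurations per cell: the observed statistic value
  # remains attainable through positive-probability configurations, so the
  # p-value is defined
  gt2 <- genotype_table(1, 1, 1, 1, 1, 1)
  res <- exact_pvalue(gt2, probs = pr)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("zero-probability categories are excluded from the support", {
  # no aa anywhere: pooled p3 = 0, support collapses to the z2 axis
  gt <- genotype_table(2, 3, 0, 3, 2, 0)
  pr <- null_genotype_probs(gt, "pooled")
  pmf <- joint_pmf_brute_force(gt$r_x, gt$r_y, pr)
  expect_true(all(pmf$z1 == 0))
  expect_equal(sum(pmf$prob), 1, tolerance = 1e-12)
  res <- exact_pvalue(gt, probs = pr)
  expect_equal(res$p_value, pmf_pvalue(pmf, gt), tolerance = 1e-10)
})

test_that("the cell budget refuses oversized problems with a resource error", {
  gt <- enos_table()
  expect_error(
    exact_pvalue(gt, max_cells = 1e6),
    class = "exacttrend_resource_error"
  )
})

test_that("exact p-values are deterministic across repeated calls", {
  gt <- enos_table()
  p1 <- exact_pvalue(gt)$p_value
  p2 <- exact_pvalue(gt)$p_value
  expect_identical(p1, p2)
})

test_that("pmf export writes a readable three-column table", {
  pr <- null_genotype_probs(mode = "fixed", p = c(1, 1, 1) / 3)
  pmf <- joint_pmf_brute_force(5, 3, pr)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pmf(pmf, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(back), c("z1", "z2", "prob"))
  expect_equal(nrow(back), nrow(pmf))
  expect_equal(sum(back$prob), 1, tolerance = 1e-12)
})
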