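test_that("configuration validation catches bad parameters", {
  expect_error(simulation_config(maf = 0.6), "maf")
  expect_error(simulation_config(maf = 0), "maf")
  expect_error(simulation_config(maf = 0.4, beta1 = Inf), "finite")
  expect_error(simulation_config(maf = 0.4, n_replicates = 0), "positive integer")
  expect_error(simulation_config(maf = 0.4, alpha = 0), "alpha")
  cfg <- simulation_config(maf = 0.5, n_replicates = 3, seed = 1)
  expect_s3_class(cfg, "simulation_config")
})

test_that("genotype draws follow Hardy-Weinberg proportions", {
  set.seed(100)
  n <- 1e5
  for (maf in c(0.5, 0.4, 0.2)) {
    g <- simulate_genotype(n, maf)
    expected <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
    obs <- tabulate(g + 1L, 3L) / n
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(obs - expected) <= 3 * se + 1e-9))
  }
})

test_that("null replicates have proportional arms in expectation", {
  set.seed(101)
  cfg <- simulation_config(
    maf = 0.4, beta1 = log(1), n_cases = 2000,
    n_controls = 2000, n_replicates = 1
  )
  acc <- c(0, 0, 0)
  for (i in 1:50) acc <- acc + simulate_replicate(cfg)$x
  freq <- acc / sum(acc)
  hwe <- c(0.36, 0.48, 0.16)
  expect_true(all(abs(freq - hwe) < 0.01))
})

test_that("a huge effect saturates the at-risk genotype into cases", {
  set.seed(102)
  cfg <- simulation_config(
    maf = 0.4, beta1 = 30, coding = "recessive",
    n_cases = 200, n_controls = 200, n_replicates = 1
  )
  gt <- simulate_replicate(cfg)
  # aa carriers are certain cases, so the control arm holds no aa
  expect_equal(gt$y[3], 0)
})

test_that("replicates and experiments are bit-reproducible from the seed", {
  cfg <- simulation_config(
    maf = 0.4, n_cases = 300, n_controls = 300,
    n_replicates = 25, seed = 77
  )
  a <- simulate_replicate(cfg)
  b <- simulate_replicate(cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)

  r1 <- run_experiment(cfg, methods = c("additive_only", "min_p"))
  r2 <- run_experiment(cfg, methods = c("additive_only", "min_p"))
  expect_identical(r1$rates, r2$rates)
  expect_identical(r1$pvalues, r2$pvalues)
})

test_that("alpha = 1 rejects every replicate", {
  cfg <- simulation_config(
    maf = 0.4, n_cases = 100, n_controls = 100,
    n_replicates = 10, alpha = 1, seed = 3
  )
  res <- run_experiment(cfg, methods = c("additive_only", "bonferroni"))
  expect_true(all(res$rates$proportion == 1))
})

test_that("rejection proportions carry binomial Monte-Carlo standard errors", {
  cfg <- simulation_config(
    maf = 0.4, n_cases = 100, n_controls = 100,
    n_replicates = 40, seed = 9
  )
  res <- run_experiment(cfg)
  expect_setequal(
    res$rates$method,
    c("additive_only", "dominant_only", "recessive_only", "min_p", "bonferroni")
  )
  expect_equal(
    res$rates$se,
    sqrt(res$rates$proportion * (1 - res$rates$proportion) / res$rates$n)
  )
})

test_that("exact subsampling restricts the exact method to early replicates", {
  cfg <- simulation_config(
    maf = 0.4, n_cases = 20, n_controls = 20,
    n_replicates = 12, seed = 21
  )
  res <- run_experiment(cfg,
    methods = c("additive_only", "exact"),
    exact_mode = "subsample", exact_subsample = 5
  )
  expect_equal(sum(!is.na(res$pvalues$exact)), 5)
  expect_equal(res$rates$n[res$rates$method == "exact"], 5)
  expect_error(
    run_experiment(cfg, methods = "exact", exact_mode = "subsample"),
    "exact_subsample"
  )
})
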