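test_that("Gollob df rule matches the published IPCA rows and closes the budget", {
  expect_identical(gollob_df(4, 5, 1), 6L)
  expect_identical(gollob_df(4, 5, 2), 4L)
  expect_identical(gollob_df(6, 5, 1), 8L)
  expect_identical(gollob_df(6, 5, 2), 6L)
  expect_identical(gollob_df(2, 2, 1), 1L)
  expect_error(gollob_df(4, 5, 4), "out of range")
  expect_error(gollob_df(4, 5, 0), "out of range")
  for (g in 2:6) for (e in 2:6) {
    k <- min(g - 1, e - 1)
    expect_identical(sum(vapply(seq_len(k), function(n) gollob_df(g, e, n),
                                integer(1))),
                     (g - 1L) * (e - 1L))
  }
})

test_that("an additive table has zero interaction SS and null axes", {
  a <- array(0, dim = c(3, 4, 2))
  for (p in 1:2) a[, , p] <- outer(1:3, 5 * (1:4), `+`) + 10
  fit <- fit_ammi(at_from_array(a))
  expect_lt(fit$interaction_ss, 1e-16)
  expect_equal(fit$theta, rep(0, 2), tolerance = 1e-10)
})

test_that("a planted rank-1 interaction loads entirely on the first axis", {
  u <- c(1, -2, 1); u <- u / sqrt(sum(u^2))
  v <- c(2, -1, -1); v <- v / sqrt(sum(v^2))
  omega <- 3 * outer(u, v)
  a <- array(0, dim = c(3, 3, 2))
  for (p in 1:2) a[, , p] <- 5 + omega
  fit <- fit_ammi(at_from_array(a))
  expect_equal(fit$axis_ss[1], fit$interaction_ss, tolerance = 1e-10)
  expect_lt(fit$residual_ss, 1e-10)
  orc <- dc_oracle(at_from_array(a))
  expect_equal(fit$interaction_ss, orc$interaction_ss, tolerance = 1e-10)
})

test_that("the liver design reproduces the published df column exactly", {
  tab <- simulate_activity(sim_spec(g = 4, e = 5, r = 6), seed = 5)
  fit <- fit_ammi(tab)
  an <- fit$anova
  expect_identical(an$source,
                   c("total", "treatment", "genotype", "environment",
                     "interaction", "IPCA1", "IPCA2", "residual", "error"))
  expect_identical(an$df, c(119L, 19L, 3L, 4L, 12L, 6L, 4L, 2L, 100L))
  # treatment SS splits into its three components
  expect_equal(an$ss[an$source == "treatment"],
               sum(an$ss[an$source %in% c("genotype", "environment", "interaction")]),
               tolerance = 1e-8)
})

test_that("axis SS conserve the interaction SS and scores are orthonormal", {
  set.seed(31)
  for (i in 1:10) {
    g <- sample(3:6, 1); e <- sample(3:6, 1); r <- sample(2:4, 1)
    tab <- random_table(g, e, r, sd = 4, mu = 30)
    fit <- fit_ammi(tab)
    expect_equal(sum(fit$axis_ss), fit$interaction_ss,
                 tolerance = 1e-8 * max(1, fit$interaction_ss))
    expect_equal(fit$interaction_ss, dc_oracle(tab)$interaction_ss,
                 tolerance = 1e-8 * max(1, fit$interaction_ss))
    expect_equal(crossprod(fit$xi), diag(ncol(fit$xi)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(crossprod(fit$eta), diag(ncol(fit$eta)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(fit$theta) <= 1e-12))
    # sign convention: dominant environment score positive on each axis
    for (j in seq_along(fit$theta)) {
      if (fit$theta[j] == 0) next
      expect_gt(fit$eta[which.max(abs(fit$eta[, j])), j], 0)
    }
  }
})

test_that("percent-of-SS uses total for main rows and interaction for IPCA rows", {
  liver <- data.frame(
    source = c("total", "treatment", "genotype", "environment", "interaction",
               "IPCA1", "IPCA2", "residual", "error"),
    ss = c(68712.453, 65577.679, 64644.578, 215.4319, 717.6689,
           713.59043, 2.89303, 1.18546, 3134.7745))
  out <- pct_of_total(liver)
  pc <- setNames(out$pct_total, out$source)
  expect_equal(round(unname(pc["genotype"]), 4), 94.0799)
  expect_equal(round(unname(pc["environment"]), 4), 0.3135)
  expect_equal(round(unname(pc["IPCA1"]), 4), 99.4317)
  expect_true(all(is.na(pc[c("total", "treatment", "residual", "error")])))

  muscle <- data.frame(source = c("total", "interaction", "IPCA1"),
                       ss = c(1854.7651, 156.9203, 156.70159))
  expect_equal(round(pct_of_total(muscle)$pct_total[3], 4), 99.8606)

  degen <- data.frame(source = c("total", "interaction", "IPCA1"),
                      ss = c(10, 0, 0))
  expect_true(is.na(pct_of_total(degen)$pct_total[3]))
})

test_that("unreplicated designs are rejected", {
  expect_error(fit_ammi(random_table(3, 3, 1)), "r >= 2")
})
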