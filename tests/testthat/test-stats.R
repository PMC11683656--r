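test_that("summary statistics use the sample (n - 1) divisor", {
  expect_equal(summarize_rmse(c(1, 1, 1)), list(mean = 1, sd = 0, n = 3L))
  s <- summarize_rmse(c(0, 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, sqrt(0.5), tolerance = 1e-12)   # 0.7071
  expect_equal(s$n, 2L)
  expect_error(summarize_rmse(numeric(0)), "insufficient data")
  expect_error(summarize_rmse(5), "insufficient data")
})

test_that("one-sample t works from summaries and matches t.test on raw values", {
  # closed form on the published-style summaries
  r <- one_sample_t(mean = 0.28, sd = 0.06, n = 115, mu0 = 0)
  expect_equal(r$t, 0.28 / (0.06 / sqrt(115)), tolerance = 1e-12)
  expect_equal(r$t, 50.04, tolerance = 1e-3)
  expect_equal(r$df, 114)
  # symmetric sample around mu0
  r2 <- one_sample_t(c(1, 2, 3, 4), mu0 = 2.5)
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  # raw-value path agrees with the closed-form summary path
  set.seed(5)
  x <- rnorm(40, 1, 2)
  a <- one_sample_t(x, mu0 = 0.5)
  b <- one_sample_t(mean = mean(x), sd = sd(x), n = length(x), mu0 = 0.5)
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_equal(a$ci, b$ci, tolerance = 1e-10)
  expect_error(one_sample_t(rep(2, 10)), "degenerate variance")
})

test_that("TOST reproduces the closed-form bound statistics", {
  r <- tost_equivalence(mean = 0.28, sd = 0.06, n = 115,
                        low = 0, high = 0.30)
  expect_equal(r$t_upper, (0.28 - 0.30) / (0.06 / sqrt(115)),
               tolerance = 1e-12)
  expect_equal(r$t_upper, -3.574, tolerance = 1e-3)
  expect_equal(r$df, 114)
  expect_true(r$equivalent)
  # mean exactly at the upper margin: no evidence of equivalence
  r2 <- tost_equivalence(mean = 0.30, sd = 0.06, n = 115,
                         low = 0, high = 0.30)
  expect_equal(r2$t_upper, 0)
  expect_equal(r2$p_upper, 0.5)
  expect_false(r2$equivalent)
  # well inside the margins: both bounds rejected emphatically
  r3 <- tost_equivalence(mean = 0.15, sd = 0.06, n = 115,
                         low = 0, high = 0.30)
  expect_equal(r3$t_lower, 26.81, tolerance = 1e-3)
  expect_equal(r3$t_upper, -26.81, tolerance = 1e-3)
  expect_lt(max(r3$p_lower, r3$p_upper), 1e-10)
  expect_true(r3$equivalent)
  expect_error(tost_equivalence(mean = 1, sd = 1, n = 10, low = 2, high = 1),
               "low < high")
})

test_that("TOST decision coincides with the 90% CI lying inside the margins", {
  set.seed(77)
  for (rep in 1:500) {
    m <- runif(1, -0.2, 0.6); s <- runif(1, 0.01, 0.5)
    n <- sample(3:200, 1)
    r <- tost_equivalence(mean = m, sd = s, n = n, low = 0, high = 0.30)
    inside <- r$ci90[1] > 0 && r$ci90[2] < 0.30
    expect_identical(r$equivalent, inside)
  }
})

test_that("one-sided TOST tails match numerical integration of the t density", {
  set.seed(123)
  for (rep in 1:40) {
    m <- runif(1, -0.1, 0.5); s <- runif(1, 0.02, 0.3)
    n <- sample(5:150, 1)
    r <- tost_equivalence(mean = m, sd = s, n = n, low = 0, high = 0.30)
    expect_lt(abs(r$p_lower - oracle_t_tail(r$t_lower, r$df)), 1e-10)
    # lower tail of t_upper = upper tail of -t_upper (symmetry)
    expect_lt(abs(r$p_upper - oracle_t_tail(-r$t_upper, r$df)), 1e-10)
  }
})

test_that("Hedges g applies the small-sample correction and a sane CI", {
  g0 <- hedges_g(mean = 1, sd = 2, n = 30, mu0 = 1)
  expect_equal(g0$g, 0)
  g1 <- hedges_g(mean = 0.28, sd = 0.06, n = 115, mu0 = 0)
  expect_equal(g1$correction, 1 - 3 / (4 * 114 - 1), tolerance = 1e-12)
  expect_equal(g1$g, 4.636, tolerance = 1e-3)   # 4.667 * (1 - 3/455)
  expect_lt(g1$ci[1], g1$g)
  expect_gt(g1$ci[2], g1$g)
  # d = 1 at n = 5: J(4) = 1 - 3/15 = 0.8
  g2 <- hedges_g(mean = 1, sd = 1, n = 5, mu0 = 0)
  expect_equal(g2$g, 0.8, tolerance = 1e-12)
  # noncentral CI is consistent: lower bound of the null effect is ~0
  g3 <- hedges_g(mean = 0, sd = 1, n = 20, mu0 = 0)
  expect_equal(mean(g3$ci), 0, tolerance = 1e-6)
  # bootstrap path needs raw values and brackets the point estimate
  set.seed(8)
  x <- rnorm(50, 0.5, 1)
  g4 <- hedges_g(x, ci_method = "bootstrap", n_boot = 400L)
  expect_true(g4$ci[1] < g4$g && g4$g < g4$ci[2])
  expect_error(hedges_g(mean = 1, sd = 1, n = 10, ci_method = "bootstrap"),
               "raw values")
})

test_that("noncentral-t CI has nominal coverage of the true standardized effect", {
  set.seed(4242)
  d_true <- 0.8
  hits <- replicate(300, {
    x <- rnorm(25, mean = d_true, sd = 1)
    ci <- hedges_g(x, ci_level = 0.90)$ci
    J <- 1 - 3 / (4 * 24 - 1)
    ci[1] <= J * d_true && J * d_true <= ci[2]
  })
  expect_gt(mean(hits), 0.84)   # 90% nominal, Monte-Carlo slack
})

test_that("Welch t test reports fractional df and reduces to Student under equal variance", {
  r <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(3) / sqrt(2), tolerance = 1e-10)  # -1.2247
  expect_equal(r$df, 4, tolerance = 1e-10)
  a <- c(1, 2, 3, 4, 5); b <- a + 2   # identical variances
  r2 <- welch_t(a, b)
  expect_equal(r2$df, length(a) + length(b) - 2, tolerance = 1e-9)
  r3 <- welch_t(a, a)
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  # unequal variances shrink the df below n1 + n2 - 2
  set.seed(2)
  g1 <- rnorm(20, sd = 1); g2 <- rnorm(20, sd = 6)
  expect_lt(welch_t(g1, g2)$df, 38)
  expect_error(welch_t(rep(1, 5), rep(2, 5)), "degenerate variance")
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("under the null, one-sample t p-values are uniform", {
  set.seed(314)
  p <- replicate(2000, one_sample_t(rnorm(12), mu0 = 0)$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("frame-rate analysis mirrors the two-contrast Bonferroni design", {
  set.seed(55)
  rmse <- abs(rnorm(60, 0.25, 0.05))
  res <- data.frame(fps = rep(c(30, 60, 120), each = 20), rmse = rmse)
  fa <- framerate_analysis(res)
  expect_equal(nrow(fa$tests), 2L)
  expect_equal(fa$tests$p_adjusted, pmin(1, 2 * fa$tests$p),
               tolerance = 1e-12)
  expect_equal(fa$groups$n, rep(20L, 3))
  # identical distributions across groups: t = 0, adjusted p = 1
  same <- data.frame(fps = rep(c(30, 60, 120), each = 20),
                     rmse = rep(rmse[1:20], 3))
  fa2 <- framerate_analysis(same)
  expect_equal(fa2$tests$t, c(0, 0))
  expect_equal(fa2$tests$p_adjusted, c(1, 1))
  # a missing fps group is named in the error
  expect_error(framerate_analysis(data.frame(fps = rep(90, 10),
                                             rmse = runif(10))),
               "30, 60")
})
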