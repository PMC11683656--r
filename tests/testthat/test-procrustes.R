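test_that("rmse_points implements the point-count-divisor definition", {
  expect_equal(rmse_points(cbind(c(0, 1), c(0, 0)), cbind(c(0, 1), c(1, 1))),
               1.0)                         # sqrt((1 + 1) / 2)
  expect_equal(rmse_points(cbind(0, 0), cbind(3, 4)), 5.0)  # sqrt(25 / 1)
  A <- random_config(8); B <- random_config(8)
  expect_equal(rmse_points(A, A), 0)
  # invariant under a common permutation of both point sets
  set.seed(1)
  perm <- sample(8)
  expect_equal(rmse_points(A, B), rmse_points(A[perm, ], B[perm, ]))
  expect_error(rmse_points(A, B[1:5, ]), "point counts differ")
})

test_that("self-match gives the identity transform and zero RMSE", {
  X <- random_config(12)
  fit <- procrustes_fit(X, X)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_equal(fit$scale, 1, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(2), tolerance = 1e-12)
  expect_equal(fit$translation, c(0, 0), tolerance = 1e-10)
})

test_that("similarity transforms are removed exactly and the rotation stays orthogonal", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    X <- random_config(n)
    s <- runif(1, 0.2, 5); th <- runif(1, -pi, pi)
    Y <- apply_similarity(X, s, th, runif(1, -50, 50), runif(1, -50, 50))
    # fit recovers X from Y: the predicted stream is transformed back
    fit <- procrustes_fit(X, Y, allow_reflection = FALSE)
    expect_lt(fit$rmse, 1e-10)
    expect_equal(fit$scale, 1 / s, tolerance = 1e-8)
    R <- fit$rotation
    expect_lt(max(abs(crossprod(R) - diag(2))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
})

test_that("reflection handling matches its flag", {
  set.seed(11)
  X <- random_config(9)
  Xm <- X; Xm[, 1] <- -Xm[, 1]                 # mirrored configuration
  free <- procrustes_fit(X, Xm, allow_reflection = TRUE)
  expect_lt(free$rmse, 1e-10)
  expect_true(free$reflection_used)
  expect_equal(det(free$rotation), -1, tolerance = 1e-10)
  forced <- procrustes_fit(X, Xm, allow_reflection = FALSE)
  expect_equal(det(forced$rotation), 1, tolerance = 1e-10)
  expect_false(forced$reflection_used)
  expect_gt(forced$rmse, free$rmse)
})

test_that("closed-form RMSE matches the rotation-grid-search oracle", {
  # frozen expectation for the documented 3-point instance, computed with
  # the grid-search oracle (theta step refined below 1e-7 rad)
  X <- cbind(c(0, 1, 0), c(0, 0, 1))
  Y <- cbind(c(0, 1, 1), c(0, 0, 1))
  expect_equal(procrustes_fit(X, Y)$rmse, 0.2886751346, tolerance = 1e-9)
  expect_equal(oracle_procrustes_rmse(X, Y), 0.2886751346,
               tolerance = 1e-9)
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    A <- random_config(n); B <- random_config(n)
    for (refl in c(TRUE, FALSE)) {
      expect_equal(procrustes_fit(A, B, allow_reflection = refl)$rmse,
                   oracle_procrustes_rmse(A, B, allow_reflection = refl),
                   tolerance = 1e-5)
    }
  }
})

test_that("the fit agrees with an established Procrustes implementation", {
  skip_if_not_installed("vegan")
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    X <- random_config(n); Y <- random_config(n)
    fit <- procrustes_fit(X, Y, allow_reflection = TRUE)
    vg <- vegan::procrustes(X, Y, symmetric = FALSE)
    # vegan keeps Yrot in the centered frame; shift by the target centroid
    vg_fit <- sweep(vg$Yrot, 2, colMeans(X), "+")
    expect_equal(fit$transformed, unname(vg_fit), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(fit$rmse, sqrt(sum((X - vg_fit)^2) / n),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and mismatched inputs are refused", {
  X <- random_config(5)
  expect_error(procrustes_fit(X, X[1:4, ]), "point counts differ")
  expect_error(procrustes_fit(matrix(1, 5, 2), X), "degenerate")
  expect_error(procrustes_fit(X[1, , drop = FALSE], X[1, , drop = FALSE]),
               "degenerate")
})

test_that("procrustes methods expose the fit consistently", {
  set.seed(13)
  X <- random_config(20)
  Y <- apply_similarity(X, 1.5, 0.3, 2, -4) +
    matrix(rnorm(40, sd = 0.1), 20, 2)
  fit <- procrustes_fit(X, Y)
  cf <- coef(fit)
  expect_named(cf, c("scale", "theta_rad", "tx", "ty", "det_r"))
  expect_equal(unname(fitted(fit)), unname(predict(fit)), tolerance = 1e-12)
  res <- residuals(fit)
  expect_equal(unname(X - fitted(fit)), unname(res), tolerance = 1e-12)
  d <- residuals(fit, type = "distance")
  expect_equal(fit$rmse, sqrt(mean(d^2)), tolerance = 1e-12)
  # residual distances feed the same RMSE reported by summary/print
  s <- summary(fit)
  expect_equal(s$rmse, fit$rmse)
  expect_output(print(fit), "RMSE")
})

test_that("a lossless trial pair passes through the whole pipeline at ~zero RMSE", {
  pair <- make_pair(seed = 6L, jitter_sd = 0, dropout_prob = 0,
                    transform = list(scale = 1, theta = 0,
                                     translate = c(0, 0)))
  row <- compare_trial(pair)
  expect_lt(row$rmse, 1e-6)
  # axis-aligned similarity (no rotation) also survives the full pipeline:
  # min-max normalization alone removes pure scale + translation
  pair2 <- make_pair(seed = 6L, jitter_sd = 0, dropout_prob = 0,
                     transform = list(scale = 1.4, theta = 0,
                                      translate = c(90, -60)))
  expect_lt(compare_trial(pair2)$rmse, 1e-10)
})

test_that("comparing a full trial set yields one complete record per trial", {
  pairs <- generate_trial_set(speeds_ms = seq(500, 2500, by = 500),
                              fps = 60, n_reps = 3L, base_seed = 2L)
  tab <- compare_trials(pairs)
  expect_equal(nrow(tab), 15L)
  expect_false(anyNA(tab$rmse))
  expect_true(all(tab$rmse >= 0))
  expect_setequal(tab$trial_id,
                  vapply(pairs, function(p) p$meta$trial_id, character(1)))
})

test_that("added jitter on normalized coordinates is recovered as sigma * sqrt(2)", {
  # Procrustes removes only 4 of the 2n degrees of freedom, so the expected
  # RMSE under i.i.d. per-coordinate noise of sd sigma is ~ sigma * sqrt(2)
  pair <- make_pair(seed = 14L, jitter_sd = 0, dropout_prob = 0,
                    transform = list(scale = 1, theta = 0,
                                     translate = c(0, 0)))
  ref <- preprocess_trajectory(pair$reference)
  sigma <- 0.01
  set.seed(99)
  vals <- replicate(50, {
    noisy <- traj_coords(ref) + matrix(rnorm(2 * 1500, sd = sigma), 1500, 2)
    procrustes_fit(traj_coords(ref), noisy)$rmse
  })
  expect_equal(mean(vals), sigma * sqrt(2), tolerance = 0.05)
})
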