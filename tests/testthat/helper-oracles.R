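# Independent oracles used by the tests. These deliberately avoid the
# package's closed-form code paths.

# Procrustes RMSE by grid search over the rotation angle, with the
# least-squares scale and translation computed per angle; refines the grid
# until the angular step is below `tol_angle`. Searches the reflected
# branch too when allow_reflection is TRUE.
oracle_procrustes_rmse <- function(X, Y, allow_reflection = TRUE,
                                   tol_angle = 1e-7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  branch_best <- function(flip) {
    Yb <- Y
    if (flip) Yb[, 2] <- -Yb[, 2]
    Ybc <- sweep(Yb, 2, colMeans(Yb))
    ss_at <- function(theta) {
      R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      Yr <- Ybc %*% t(R)
      s <- sum(Xc * Yr) / sum(Ybc^2)
      sum((Xc - s * Yr)^2)
    }
    lo <- -pi; hi <- pi
    step <- (hi - lo) / 2000
    grid <- seq(lo, hi, by = step)
    vals <- vapply(grid, ss_at, numeric(1))
    best <- grid[which.min(vals)]
    while (step > tol_angle) {
      lo <- best - 2 * step; hi <- best + 2 * step
      step <- step / 20
      grid <- seq(lo, hi, by = step)
      vals <- vapply(grid, ss_at, numeric(1))
      best <- grid[which.min(vals)]
    }
    ss_at(best)
  }
  ss <- branch_best(FALSE)
  if (allow_reflection) ss <- min(ss, branch_best(TRUE))
  sqrt(ss / n)
}

# DTW cumulative cost by exhaustive enumeration of all admissible warping
# paths (steps (1,0), (0,1), (1,1)); tractable for n, m <= 6.
oracle_dtw_cost <- function(q, r) {
  q <- as.matrix(q); r <- as.matrix(r)
  d <- function(i, j) sqrt(sum((q[i, ] - r[j, ])^2))
  n <- nrow(q); m <- nrow(r)
  best <- Inf
  recurse <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n) recurse(i + 1, j, acc + d(i + 1, j))
    if (j < m) recurse(i, j + 1, acc + d(i, j + 1))
    if (i < n && j < m) recurse(i + 1, j + 1, acc + d(i + 1, j + 1))
  }
  recurse(1, 1, d(1, 1))
  best
}

# Upper-tail t probability by numerical integration of the density.
oracle_t_tail <- function(t_stat, df) {
  if (t_stat >= 0) {
    stats::integrate(function(x) stats::dt(x, df), t_stat, Inf,
                     rel.tol = 1e-13, abs.tol = 1e-14)$value
  } else {
    1 - stats::integrate(function(x) stats::dt(x, df), -Inf, t_stat,
                         rel.tol = 1e-13, abs.tol = 1e-14)$value
  }
}

# Small random point configuration (rows = points).
random_config <- function(n, scale = 10) {
  matrix(stats::runif(2 * n, -scale, scale), n, 2)
}

# Random similarity transform applied to a point matrix.
apply_similarity <- function(p, s, theta, tx, ty) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(s * p %*% t(R), 2, c(tx, ty), "+")
}

# A quick noiseless trial pair from the generator.
make_pair <- function(seed = 1L, ...) {
  cfg <- synthetic_config(seed = seed, ...)
  shape <- generate_shape(cfg)
  ref <- render_reference_trace(shape, cfg)
  attr(ref, "trial_id") <- sprintf("t%03d", seed)
  pred <- degrade_trace(ref, cfg)
  structure(list(reference = ref, predicted = pred,
                 meta = list(trial_id = sprintf("t%03d", seed),
                             speed_ms = cfg$duration_ms, fps = cfg$fps,
                             seed = seed)),
            class = "trial_pair")
}
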