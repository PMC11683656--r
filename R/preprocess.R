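#' Collapse duplicate time stamps
#'
#' Spline resampling needs strictly increasing abscissae. Samples sharing a
#' time stamp (touchscreen polling can emit coincident events) are collapsed
#' to their coordinate mean; samples are sorted by time first.
#'
#' @param traj a [trajectory()].
#' @return The cleaned trajectory with strictly increasing `t_ms`.
#' @export
clean_monotone <- function(traj) {
  assert_trajectory(traj)
  o <- order(traj$t_ms)
  t_ms <- traj$t_ms[o]; x <- traj$x[o]; y <- traj$y[o]
  if (anyDuplicated(t_ms)) {
    grp <- match(t_ms, unique(t_ms))
    t_ms <- unique(t_ms)
    x <- as.numeric(tapply(x, grp, mean))
    y <- as.numeric(tapply(y, grp, mean))
  }
  if (length(t_ms) < 4L) {
    stop(sprintf(paste("degenerate trajectory: %d point(s) after cleanup,",
                       "at least 4 required for cubic resampling"),
                 length(t_ms)), call. = FALSE)
  }
  traj_update(traj, t_ms = t_ms, x = x, y = y)
}

#' Resample a trajectory to a fixed point count
#'
#' Fits an interpolating cubic spline to each coordinate over a normalized
#' parameter s in [0, 1] and evaluates it at `n_out` equally spaced values.
#' The default parameter is the rescaled time stamp; the normalized sample
#' index or normalized cumulative arc length can be selected instead. The
#' first and last input points are reproduced exactly. The standard
#' analysis resamples every trial to 1500 points.
#'
#' @param traj a cleaned [trajectory()] with at least 4 points and strictly
#'   increasing time stamps.
#' @param n_out output point count (default 1500).
#' @param param abscissa for the spline: `"time"` (default), `"index"`, or
#'   `"arclength"`.
#' @return The resampled trajectory (`n_out` points).
#' @export
resample_trajectory <- function(traj, n_out = 1500L,
                                param = c("time", "index", "arclength")) {
  assert_trajectory(traj)
  param <- match.arg(param)
  if (n_out < 2L) stop("n_out must be at least 2", call. = FALSE)
  n <- nrow(traj)
  if (n < 4L) {
    stop("at least 4 points required for cubic resampling", call. = FALSE)
  }
  s <- switch(param,
    time = {
      if (any(diff(traj$t_ms) <= 0)) {
        stop("internal error: time stamps not strictly increasing; ",
             "apply clean_monotone() first", call. = FALSE)
      }
      (traj$t_ms - traj$t_ms[1]) / (traj$t_ms[n] - traj$t_ms[1])
    },
    index = (seq_len(n) - 1) / (n - 1),
    arclength = {
      arc <- c(0, cumsum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)))
      if (arc[n] <= 0) {
        stop("degenerate trajectory: zero total arc length", call. = FALSE)
      }
      # coincident consecutive points would duplicate abscissae
      arc <- arc + seq(0, 1e-12, length.out = n)
      arc / arc[n]
    })
  s_out <- seq(0, 1, length.out = n_out)
  x <- stats::spline(s, traj$x, xout = s_out, method = "fmm",
                     ties = "ordered")$y
  y <- stats::spline(s, traj$y, xout = s_out, method = "fmm",
                     ties = "ordered")$y
  t_out <- seq(traj$t_ms[1], traj$t_ms[n], length.out = n_out)
  traj_update(traj, t_ms = t_out, x = x, y = y)
}

#' Per-axis min-max normalization
#'
#' Maps each coordinate axis independently onto [0, 1] via
#' (v - min) / (max - min), the standard min-max scaling step that moves
#' both streams into a common unit-square reference space. The two axes
#' are scaled independently, so the aspect ratio is deliberately not
#' preserved (the downstream Procrustes scale absorbs part of this).
#' A degenerate axis (max = min) maps to all zeros with a warning.
#'
#' @param traj a [trajectory()].
#' @return The trajectory in `"normalized"` space.
#' @export
minmax_normalize <- function(traj) {
  assert_trajectory(traj)
  norm_axis <- function(v, label) {
    r <- range(v)
    if (r[1] == r[2]) {
      warning(sprintf("degenerate %s axis (constant): mapped to 0", label),
              call. = FALSE)
      return(rep(0, length(v)))
    }
    (v - r[1]) / (r[2] - r[1])
  }
  traj_update(traj, x = norm_axis(traj$x, "x"), y = norm_axis(traj$y, "y"),
              space = "normalized")
}

#' Dynamic time warping alignment of two trajectories
#'
#' Classic dynamic-programming DTW with Euclidean local cost on (x, y),
#' symmetric step set {(1,0), (0,1), (1,1)} and no global window. Used as
#' an optional behavioral-standardization stage to absorb natural variation
#' in movement speed; it is not part of the standard index-correspondence
#' Procrustes pipeline.
#'
#' @param query,reference [trajectory()] objects (or n x 2 matrices) in the
#'   same coordinate space.
#' @return An object of class `warp_path`: list with `pairs` (m x 2 matrix
#'   of aligned index couples, starting at (1,1) and ending at (n, m)) and
#'   `cumulative_cost` (summed local Euclidean distances along the optimal
#'   path).
#' @examples
#' a <- trajectory(0:3, c(0, 1, 2, 3), c(0, 0, 0, 0))
#' dtw_align(a, a)$cumulative_cost  # 0
#' @export
dtw_align <- function(query, reference) {
  as_pts <- function(z) {
    if (inherits(z, "trajectory")) traj_coords(z)
    else as.matrix(z)
  }
  if (inherits(query, "trajectory") && inherits(reference, "trajectory") &&
      traj_space(query) != traj_space(reference)) {
    stop("query and reference must be in the same coordinate space",
         call. = FALSE)
  }
  q <- as_pts(query); r <- as_pts(reference)
  n <- nrow(q); m <- nrow(r)
  if (n == 0L || m == 0L) stop("sequences must be non-empty", call. = FALSE)
  # local cost matrix, vectorized
  d <- sqrt(outer(q[, 1], r[, 1], "-")^2 + outer(q[, 2], r[, 2], "-")^2)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    Dm <- D[i, ]      # row i-1 in 0-based terms
    Di <- D[i + 1L, ]
    for (j in seq_len(m)) {
      Di[j + 1L] <- d[i, j] + min(Dm[j], Dm[j + 1L], Di[j])
    }
    D[i + 1L, ] <- Di
  }
  # backtrack
  path <- matrix(NA_integer_, n + m, 2L)
  i <- n; j <- m; k <- n + m
  while (i >= 1L && j >= 1L) {
    path[k, ] <- c(i, j)
    k <- k - 1L
    step <- which.min(c(D[i, j], D[i, j + 1L], D[i + 1L, j]))
    if (step == 1L) { i <- i - 1L; j <- j - 1L }
    else if (step == 2L) i <- i - 1L
    else j <- j - 1L
  }
  pairs <- path[(k + 1L):(n + m), , drop = FALSE]
  colnames(pairs) <- c("query", "reference")
  structure(list(pairs = pairs, cumulative_cost = D[n + 1L, m + 1L]),
            class = "warp_path")
}

#' @export
print.warp_path <- function(x, ...) {
  cat(sprintf("<warp_path> %d aligned couples, cumulative cost %.6g\n",
              nrow(x$pairs), x$cumulative_cost))
  invisible(x)
}

#' Standard preprocessing chain
#'
#' Applies the standard pipeline order clean -> resample -> normalize to a
#' single trajectory.
#'
#' @inheritParams resample_trajectory
#' @param flip_y mirror the y axis (for camera footage with an inverted
#'   vertical axis) before any other step.
#' @return The preprocessed, normalized trajectory with `n_out` points.
#' @export
preprocess_trajectory <- function(traj, n_out = 1500L,
                                  param = c("time", "index", "arclength"),
                                  flip_y = FALSE) {
  assert_trajectory(traj)
  if (flip_y) traj <- traj_update(traj, y = -traj$y)
  minmax_normalize(resample_trajectory(clean_monotone(traj),
                                       n_out = n_out,
                                       param = match.arg(param)))
}
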