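#' Root-mean-squared error between corresponding points
#'
#' The agreement statistic of the analysis:
#' sqrt( sum_i [ (Xo_i - Xt_i)^2 + (Yo_i - Yt_i)^2 ] / n ),
#' the root of the mean over the n points of the summed squared x and y
#' deviations. Note the divisor is n, the point count, not 2n (the number
#' of scalar coordinates); conventions differ across fields, and this
#' package follows the point-count form throughout.
#'
#' @param reference,transformed n x 2 coordinate matrices (or
#'   [trajectory()] objects) with row-wise point correspondence.
#' @return The RMSE (in the coordinate units of the inputs; "normalized
#'   px" after min-max scaling).
#' @examples
#' rmse_points(cbind(c(0, 1), c(0, 0)), cbind(c(0, 1), c(1, 1)))  # 1
#' rmse_points(cbind(0, 0), cbind(3, 4))                           # 5
#' @export
rmse_points <- function(reference, transformed) {
  a <- if (inherits(reference, "trajectory")) traj_coords(reference)
       else as.matrix(reference)
  b <- if (inherits(transformed, "trajectory")) traj_coords(transformed)
       else as.matrix(transformed)
  if (nrow(a) != nrow(b)) {
    stop(sprintf("point counts differ: %d vs %d", nrow(a), nrow(b)),
         call. = FALSE)
  }
  if (nrow(a) < 1L) stop("need at least one point", call. = FALSE)
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Procrustes superimposition of a predicted trajectory onto a reference
#'
#' Fits the similarity transform (uniform scale s, 2x2 orthogonal matrix R,
#' translation t) that minimizes the sum of squared distances between the
#' reference points and the transformed predicted points,
#' x_i ~ s * R %*% y_i + t, in closed form: both configurations are
#' centered, the optimal rotation comes from the singular value
#' decomposition of the cross-covariance matrix, and the scale is the
#' least-squares optimum given that rotation. Correspondence is by index
#' (both streams carry 1500 points after the standard preprocessing).
#'
#' By default the orthogonal factor may include a reflection (absorbing
#' mirrored camera footage); with `allow_reflection = FALSE` the solution
#' is constrained to a proper rotation (det R = +1) by sign-correcting the
#' smallest singular direction.
#'
#' @param reference,predicted [trajectory()] objects or n x 2 matrices
#'   with equal point counts (n >= 2 distinct points each).
#' @param allow_reflection may the fitted orthogonal matrix have
#'   determinant -1?
#' @param scale estimate the scale factor (default) or constrain it to 1.
#' @return An object of class `procrustes`: list with elements `rotation`
#'   (2x2 orthogonal), `scale`, `translation` (length 2), `transformed`
#'   (n x 2 matrix of predicted points after the fitted transform), `rmse`,
#'   `reflection_used`, plus the stored configurations for methods.
#'   Methods: [print.procrustes()], [summary.procrustes()],
#'   [coef.procrustes()], `fitted()`, `residuals()`, [predict.procrustes()]
#'   and [plot.procrustes()].
#' @examples
#' ref <- cbind(c(0, 1, 0), c(0, 0, 1))
#' th <- pi / 2
#' R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
#' pred <- 2 * ref %*% t(R) + matrix(c(5, 7), 3, 2, byrow = TRUE)
#' fit <- procrustes_fit(ref, pred)
#' fit$rmse          # ~0: the similarity transform is removed exactly
#' coef(fit)["scale"]
#' @export
procrustes_fit <- function(reference, predicted, allow_reflection = TRUE,
                           scale = TRUE) {
  as_pts <- function(z, what) {
    p <- if (inherits(z, "trajectory")) traj_coords(z) else as.matrix(z)
    if (ncol(p) != 2L) stop(what, " must have two coordinate columns",
                            call. = FALSE)
    storage.mode(p) <- "double"
    p
  }
  if (inherits(reference, "trajectory") && inherits(predicted, "trajectory") &&
      traj_space(reference) != traj_space(predicted)) {
    stop("reference and predicted must be in the same coordinate space",
         call. = FALSE)
  }
  X <- as_pts(reference, "reference")
  Y <- as_pts(predicted, "predicted")
  if (nrow(X) != nrow(Y)) {
    stop(sprintf("point counts differ: reference %d vs predicted %d",
                 nrow(X), nrow(Y)), call. = FALSE)
  }
  n <- nrow(X)
  if (n < 2L || nrow(unique(X)) < 2L || nrow(unique(Y)) < 2L) {
    stop("degenerate configuration: need at least 2 distinct points",
         call. = FALSE)
  }
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2, xbar); Yc <- sweep(Y, 2, ybar)
  A <- crossprod(Xc, Yc)          # 2x2 cross-covariance (unnormalized)
  sv <- svd(A)
  S <- diag(2)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) {
    S[2, 2] <- -1                 # flip the smallest singular direction
  }
  R <- sv$u %*% S %*% t(sv$v)     # transformed point: R %*% y
  s <- if (scale) sum(diag(S) * sv$d) / sum(Yc^2) else 1
  t_vec <- as.numeric(xbar - s * (R %*% ybar))
  transformed <- s * Y %*% t(R) + matrix(t_vec, n, 2, byrow = TRUE)
  colnames(transformed) <- c("x", "y")
  structure(list(rotation = R, scale = s, translation = t_vec,
                 transformed = transformed,
                 rmse = rmse_points(X, transformed),
                 reflection_used = det(R) < 0,
                 reference = X, predicted = Y,
                 allow_reflection = allow_reflection,
                 scale_estimated = scale,
                 call = match.call()),
            class = "procrustes")
}

#' @export
print.procrustes <- function(x, digits = 4, ...) {
  cat("Procrustes superimposition (predicted -> reference)\n")
  cat(sprintf("  n points : %d\n", nrow(x$reference)))
  cat(sprintf("  RMSE     : %s\n", format(x$rmse, digits = digits)))
  cat(sprintf("  scale    : %s%s\n", format(x$scale, digits = digits),
              if (!x$scale_estimated) " (fixed)" else ""))
  cat(sprintf("  rotation : %s rad%s\n",
              format(atan2(x$rotation[2, 1], x$rotation[1, 1]),
                     digits = digits),
              if (x$reflection_used) " (with reflection)" else ""))
  cat(sprintf("  shift    : (%s, %s)\n",
              format(x$translation[1], digits = digits),
              format(x$translation[2], digits = digits)))
  invisible(x)
}

#' Coefficients of a fitted Procrustes transform
#'
#' @param object a [procrustes_fit()] result.
#' @param ... unused.
#' @return Named vector: `scale`, `theta_rad` (rotation angle), `tx`, `ty`,
#'   `det_r` (+1 rotation, -1 reflection).
#' @export
coef.procrustes <- function(object, ...) {
  c(scale = object$scale,
    theta_rad = atan2(object$rotation[2, 1], object$rotation[1, 1]),
    tx = object$translation[1], ty = object$translation[2],
    det_r = det(object$rotation))
}

#' @export
fitted.procrustes <- function(object, ...) object$transformed

#' Residuals of a Procrustes fit
#'
#' @param object a [procrustes_fit()] result.
#' @param type `"matrix"` for the n x 2 coordinate residuals
#'   (reference - transformed), `"distance"` for per-point Euclidean
#'   residual distances.
#' @param ... unused.
#' @export
residuals.procrustes <- function(object, type = c("matrix", "distance"),
                                 ...) {
  type <- match.arg(type)
  res <- object$reference - object$transformed
  if (type == "distance") sqrt(rowSums(res^2)) else res
}

#' Apply a fitted Procrustes transform to new points
#'
#' @param object a [procrustes_fit()] result.
#' @param newdata n x 2 matrix or [trajectory()] in the predicted stream's
#'   space; default the stored predicted configuration.
#' @param ... unused.
#' @return The transformed n x 2 coordinate matrix.
#' @export
predict.procrustes <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$predicted
       else if (inherits(newdata, "trajectory")) traj_coords(newdata)
       else as.matrix(newdata)
  out <- object$scale * p %*% t(object$rotation) +
    matrix(object$translation, nrow(p), 2, byrow = TRUE)
  colnames(out) <- c("x", "y")
  out
}

#' @export
summary.procrustes <- function(object, ...) {
  d <- residuals(object, type = "distance")
  structure(list(fit = object,
                 coef = coef(object),
                 rmse = object$rmse,
                 n = nrow(object$reference),
                 residual_quantiles = stats::quantile(d)),
            class = "summary.procrustes")
}

#' @export
print.summary.procrustes <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("  per-point residual distance quantiles:\n")
  print(signif(x$residual_quantiles, digits))
  invisible(x)
}

#' Overlay plot of reference and superimposed predicted trajectories
#'
#' @param x a [procrustes_fit()] result.
#' @param ... passed to [plot()].
#' @export
plot.procrustes <- function(x, ...) {
  rng_x <- range(x$reference[, 1], x$transformed[, 1])
  rng_y <- range(x$reference[, 2], x$transformed[, 2])
  plot(x$reference, type = "l", col = "navy", asp = 1,
       xlim = rng_x, ylim = rng_y, xlab = "x", ylab = "y",
       main = sprintf("Procrustes overlay (RMSE %.4g)", x$rmse), ...)
  graphics::lines(x$transformed, col = "firebrick", lty = 2)
  graphics::legend("topright", legend = c("reference", "transformed"),
                   col = c("navy", "firebrick"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Compare one trial pair end to end
#'
#' Runs the standard pipeline on both streams of a trial pair —
#' clean -> resample to `n_points` -> per-axis min-max normalize — then
#' superimposes the predicted stream onto the reference by Procrustes and
#' reports the per-trial RMSE and transform parameters.
#'
#' @param pair a `trial_pair` (see [generate_trial_set()]) or a list with
#'   elements `reference` and `predicted`.
#' @param n_points resampled point count (default 1500).
#' @param allow_reflection passed to [procrustes_fit()].
#' @param param spline abscissa, see [resample_trajectory()].
#' @return One-row data frame: `trial_id`, `fps`, `speed_ms`, `rmse`,
#'   `scale`, `theta_rad`, `tx`, `ty`, `reflection`.
#' @export
compare_trial <- function(pair, n_points = 1500L, allow_reflection = TRUE,
                          param = "time") {
  meta <- if (!is.null(pair$meta)) pair$meta else {
    m <- traj_meta(pair$reference)
    list(trial_id = m$trial_id, speed_ms = m$speed_ms, fps = m$fps)
  }
  id <- if (is.null(meta$trial_id)) NA_character_ else meta$trial_id
  fit <- tryCatch({
    ref <- preprocess_trajectory(pair$reference, n_out = n_points,
                                 param = param)
    pred <- preprocess_trajectory(pair$predicted, n_out = n_points,
                                  param = param)
    procrustes_fit(ref, pred, allow_reflection = allow_reflection)
  }, error = function(e) {
    stop(sprintf("trial %s: %s", id, conditionMessage(e)), call. = FALSE)
  })
  cf <- coef(fit)
  data.frame(trial_id = id,
             fps = if (is.null(meta$fps)) NA_real_ else meta$fps,
             speed_ms = if (is.null(meta$speed_ms)) NA_real_
                        else meta$speed_ms,
             rmse = fit$rmse,
             scale = cf[["scale"]], theta_rad = cf[["theta_rad"]],
             tx = cf[["tx"]], ty = cf[["ty"]],
             reflection = fit$reflection_used,
             stringsAsFactors = FALSE)
}

#' Compare a set of trial pairs
#'
#' @param pairs list of trial pairs.
#' @inheritParams compare_trial
#' @return Data frame with one row per trial (class `trial_comparisons`),
#'   columns as in [compare_trial()].
#' @export
compare_trials <- function(pairs, n_points = 1500L, allow_reflection = TRUE,
                           param = "time") {
  rows <- lapply(pairs, compare_trial, n_points = n_points,
                 allow_reflection = allow_reflection, param = param)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_comparisons", "data.frame")
  out
}

#' @export
print.trial_comparisons <- function(x, digits = 4, ...) {
  cat(sprintf("<trial_comparisons> %d trials\n", nrow(x)))
  cat(sprintf("  RMSE: mean %.4g, sd %.4g, range [%.4g, %.4g]\n",
              mean(x$rmse), stats::sd(x$rmse), min(x$rmse), max(x$rmse)))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = digits)
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
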