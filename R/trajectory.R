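#' Construct a trajectory object
#'
#' A trajectory is an ordered, time-stamped sequence of 2D points with
#' coordinate-space metadata. It is the common currency of the package:
#' the touchscreen reference stream and the tracker-predicted stream are
#' both trajectories, in pixel space on ingest and in normalized
#' (min-max scaled, unit-square) space after preprocessing.
#'
#' @param t_ms numeric vector of time stamps in milliseconds.
#' @param x,y numeric coordinate vectors, same length as `t_ms`.
#' @param space coordinate space, `"pixel"` or `"normalized"`.
#' @param trial_id optional trial identifier.
#' @param source `"reference"` (touchscreen) or `"predicted"` (tracker).
#' @param fps frames per second of the stream, if known.
#' @param speed_ms animation duration condition in milliseconds, if known.
#' @return An object of class `trajectory`: a data frame with columns
#'   `t_ms`, `x`, `y` and metadata attributes.
#' @examples
#' tr <- trajectory(t_ms = c(0, 10, 20, 30), x = 1:4, y = (1:4)^2)
#' tr
#' @export
trajectory <- function(t_ms, x, y, space = c("pixel", "normalized"),
                       trial_id = NA_character_, source = NA_character_,
                       fps = NA_real_, speed_ms = NA_real_) {
  space <- match.arg(space)
  if (length(t_ms) != length(x) || length(x) != length(y)) {
    stop("t_ms, x and y must have equal length", call. = FALSE)
  }
  if (length(t_ms) == 0L) stop("trajectory must be non-empty", call. = FALSE)
  if (!is.numeric(t_ms) || !is.numeric(x) || !is.numeric(y)) {
    stop("t_ms, x and y must be numeric", call. = FALSE)
  }
  if (anyNA(t_ms) || anyNA(x) || anyNA(y)) {
    stop("trajectory coordinates must not contain NA", call. = FALSE)
  }
  out <- data.frame(t_ms = as.numeric(t_ms), x = as.numeric(x),
                    y = as.numeric(y))
  structure(out,
            class = c("trajectory", "data.frame"),
            space = space,
            trial_id = trial_id,
            source = source,
            fps = fps,
            speed_ms = speed_ms)
}

#' Trajectory metadata accessors
#'
#' @param traj a [trajectory()].
#' @return `traj_space()` returns the coordinate space string;
#'   `traj_meta()` a named list of the metadata attributes;
#'   `traj_coords()` the n x 2 coordinate matrix.
#' @export
traj_space <- function(traj) attr(traj, "space")

#' @rdname traj_space
#' @export
traj_meta <- function(traj) {
  list(trial_id = attr(traj, "trial_id"), source = attr(traj, "source"),
       fps = attr(traj, "fps"), speed_ms = attr(traj, "speed_ms"))
}

#' @rdname traj_space
#' @export
traj_coords <- function(traj) {
  cbind(x = traj$x, y = traj$y)
}

# rebuild a trajectory keeping metadata, optionally overriding some fields
traj_update <- function(traj, t_ms = traj$t_ms, x = traj$x, y = traj$y,
                        space = attr(traj, "space")) {
  trajectory(t_ms, x, y, space = space,
             trial_id = attr(traj, "trial_id"),
             source = attr(traj, "source"),
             fps = attr(traj, "fps"),
             speed_ms = attr(traj, "speed_ms"))
}

assert_trajectory <- function(traj, arg = deparse(substitute(traj))) {
  if (!inherits(traj, "trajectory")) {
    stop(sprintf("`%s` must be a trajectory object", arg), call. = FALSE)
  }
  invisible(traj)
}

#' @export
print.trajectory <- function(x, ...) {
  m <- traj_meta(x)
  cat(sprintf("<trajectory> %d points, %s space", nrow(x), traj_space(x)))
  if (!is.na(m$trial_id)) cat(sprintf(", trial %s", m$trial_id))
  if (!is.na(m$source)) cat(sprintf(" [%s]", m$source))
  cat("\n")
  if (!is.na(m$fps) || !is.na(m$speed_ms)) {
    cat(sprintf("  fps: %s, speed: %s ms\n",
                format(m$fps), format(m$speed_ms)))
  }
  cat(sprintf("  t: %.6g .. %.6g ms;  x: [%.6g, %.6g];  y: [%.6g, %.6g]\n",
              min(x$t_ms), max(x$t_ms), min(x$x), max(x$x),
              min(x$y), max(x$y)))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ..., asp = 1) {
  plot(x$x, x$y, type = "l", asp = asp, xlab = "x", ylab = "y",
       main = attr(x, "trial_id"), ...)
  graphics::points(x$x[1], x$y[1], pch = 16)
  invisible(x)
}
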