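#' Write a trial pair to CSV files
#'
#' Writes two CSV files per trial — `<id>_reference.csv` and
#' `<id>_predicted.csv`, each with header `trial_id,t_ms,x,y` — plus a
#' JSON sidecar `<id>_config.json` recording the generating configuration.
#'
#' @param pair a `trial_pair` (see [generate_trial_set()]).
#' @param dir output directory (created if needed).
#' @param config optional [synthetic_config()] to record in the sidecar.
#' @return Invisibly, the paths written.
#' @export
write_trial_pair <- function(pair, dir, config = NULL) {
  stopifnot(inherits(pair, "trial_pair") ||
              all(c("reference", "predicted") %in% names(pair)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- pair$meta$trial_id
  paths <- character(0)
  for (src in c("reference", "predicted")) {
    traj <- pair[[src]]
    df <- data.frame(trial_id = id, t_ms = traj$t_ms, x = traj$x,
                     y = traj$y)
    p <- file.path(dir, sprintf("%s_%s.csv", id, src))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  side <- file.path(dir, sprintf("%s_config.json", id))
  payload <- list(meta = pair$meta)
  if (!is.null(config)) payload$config <- unclass(config)
  jsonlite::write_json(payload, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, side))
}

#' Read a trial CSV into a trajectory
#'
#' Header-driven (column order free) reader for the trial CSV schema
#' `trial_id,t_ms,x,y`. Malformed numeric cells are reported with their
#' line numbers. A JSON sidecar `<id>_config.json` next to the file, when
#' present, supplies fps and speed metadata.
#'
#' @param path CSV file path.
#' @param source `"reference"` or `"predicted"`, recorded as metadata;
#'   guessed from the file name when omitted.
#' @return A pixel-space [trajectory()].
#' @export
read_trial_csv <- function(path, source = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("trial_id", "t_ms", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("degenerate trajectory: %s has no data rows", path),
         call. = FALSE)
  }
  num <- lapply(df[c("t_ms", "x", "y")], function(col) {
    suppressWarnings(as.numeric(col))
  })
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad) > 0) {
    stop(sprintf("parse error in %s: non-numeric cell(s) at data line(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(source)) {
    source <- if (grepl("predicted", basename(path))) "predicted"
              else "reference"
  }
  fps <- NA_real_; speed <- NA_real_
  sidecar <- file.path(dirname(path),
                       sprintf("%s_config.json", df$trial_id[1]))
  if (file.exists(sidecar)) {
    info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(info$meta$fps)) fps <- info$meta$fps
    if (!is.null(info$meta$speed_ms)) speed <- info$meta$speed_ms
  }
  trajectory(num$t_ms, num$x, num$y, space = "pixel",
             trial_id = df$trial_id[1], source = source,
             fps = fps, speed_ms = speed)
}

#' Read a trial pair from a directory
#'
#' @param dir directory holding `<id>_reference.csv` and
#'   `<id>_predicted.csv`.
#' @param trial_id the trial identifier.
#' @return A `trial_pair`.
#' @export
read_trial_pair <- function(dir, trial_id) {
  ref <- read_trial_csv(file.path(dir, sprintf("%s_reference.csv", trial_id)),
                        source = "reference")
  pred <- read_trial_csv(file.path(dir, sprintf("%s_predicted.csv", trial_id)),
                         source = "predicted")
  m <- traj_meta(ref)
  structure(list(reference = ref, predicted = pred,
                 meta = list(trial_id = trial_id, speed_ms = m$speed_ms,
                             fps = m$fps)),
            class = "trial_pair")
}
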