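#' Pipeline configuration
#'
#' Assembles all stage parameters of the end-to-end analysis in one
#' validated list. Defaults reproduce the paper-shaped study design:
#' five animation speeds (500-2500 ms), 23 replicates (115 trials), 1500
#' resampled points, equivalence margins (0, 0.30) normalized px at
#' alpha = .05, and Bonferroni multiplier m = 2 for the two frame-rate
#' contrasts.
#'
#' @param speeds_ms animation duration conditions.
#' @param fps frame-rate condition(s) of the simulated streams.
#' @param n_reps replicates per speed x fps cell.
#' @param seed base RNG seed for the whole run.
#' @param n_points resampled point count.
#' @param allow_reflection passed to [procrustes_fit()].
#' @param bounds equivalence margins `c(low, high)`.
#' @param alpha TOST significance level.
#' @param contrasts frame-rate contrasts (list of fps pairs), or NULL to
#'   skip the frame-rate analysis.
#' @param generator a [synthetic_config()] carrying the degradation model
#'   and canvas (its seed/duration/fps fields are overridden per trial).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(speeds_ms = seq(500, 2500, by = 500),
                            fps = 60, n_reps = 23L, seed = 1L,
                            n_points = 1500L, allow_reflection = TRUE,
                            bounds = c(0, 0.30), alpha = 0.05,
                            contrasts = NULL,
                            generator = synthetic_config(seed = 0L)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2],
            inherits(generator, "synthetic_config"))
  if (!is.null(contrasts)) {
    need <- unique(unlist(contrasts))
    miss <- setdiff(need, fps)
    if (length(miss) > 0) {
      stop(sprintf("contrasts name fps group(s) absent from the design: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(speeds_ms = speeds_ms, fps = fps,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 n_points = as.integer(n_points),
                 allow_reflection = allow_reflection,
                 bounds = bounds, alpha = alpha, contrasts = contrasts,
                 generator = generator),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `generator` may be a
#' nested map with [synthetic_config()] fields.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator
  if (is.null(gen_args)) gen_args <- list()
  if (is.null(gen_args$seed)) gen_args$seed <- 0L
  if (!is.null(gen_args$transform$translate)) {
    gen_args$transform$translate <- as.numeric(gen_args$transform$translate)
  }
  raw$generator <- do.call(synthetic_config, gen_args)
  if (!is.null(raw$contrasts)) {
    raw$contrasts <- lapply(raw$contrasts, as.numeric)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> compare -> stats on a synthetic
#' study: generates the trial grid, runs the per-trial pipeline
#' (clean, resample, per-axis min-max normalize, Procrustes
#' superimposition), then the statistical analysis (summary, one-sample t
#' against 0, TOST equivalence against the configured margins, Hedges g,
#' and — when contrasts are configured — the pairwise Welch frame-rate
#' analysis with Bonferroni correction). Trials whose comparison fails are
#' excluded and logged with their reason.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param out_dir optional directory: per-trial comparisons CSV, the JSON
#'   analysis report and a JSON run manifest are written there.
#' @return Object of class `pipeline_result`: `comparisons` (per-trial
#'   table), `analysis` (summary, one_sample, tost, effect_size,
#'   framerate), `excluded` (data frame of excluded trials and reasons)
#'   and `manifest`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(n_reps = 2, seed = 7))
#' res$analysis$tost$equivalent
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  pairs <- generate_trial_set(speeds_ms = config$speeds_ms,
                              fps = config$fps, n_reps = config$n_reps,
                              base_seed = config$seed,
                              config_base = config$generator)
  rows <- vector("list", length(pairs))
  excluded <- list()
  for (i in seq_along(pairs)) {
    rows[[i]] <- tryCatch(
      compare_trial(pairs[[i]], n_points = config$n_points,
                    allow_reflection = config$allow_reflection),
      error = function(e) {
        excluded[[length(excluded) + 1L]] <<- data.frame(
          trial_id = pairs[[i]]$meta$trial_id,
          reason = conditionMessage(e), stringsAsFactors = FALSE)
        NULL
      })
  }
  comparisons <- do.call(rbind, rows)
  rownames(comparisons) <- NULL
  class(comparisons) <- c("trial_comparisons", "data.frame")
  excluded <- if (length(excluded) > 0) do.call(rbind, excluded)
              else data.frame(trial_id = character(0),
                              reason = character(0))
  if (is.null(comparisons) || nrow(comparisons) < 2L) {
    stop("pipeline produced fewer than 2 usable trials", call. = FALSE)
  }
  smry <- summarize_rmse(comparisons$rmse)
  analysis <- list(
    summary = smry,
    one_sample = one_sample_t(comparisons$rmse, mu0 = 0),
    tost = tost_equivalence(comparisons$rmse, low = config$bounds[1],
                            high = config$bounds[2], alpha = config$alpha),
    effect_size = hedges_g(comparisons$rmse, mu0 = 0),
    framerate = if (!is.null(config$contrasts)) {
      framerate_analysis(comparisons, contrasts = config$contrasts)
    })
  manifest <- list(
    seed = config$seed,
    parameters = list(speeds_ms = config$speeds_ms, fps = config$fps,
                      n_reps = config$n_reps, n_points = config$n_points,
                      allow_reflection = config$allow_reflection,
                      bounds = config$bounds, alpha = config$alpha,
                      generator = unclass(config$generator)),
    counts = list(generated = length(pairs),
                  analyzed = nrow(comparisons),
                  excluded = nrow(excluded)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  res <- structure(list(comparisons = comparisons, analysis = analysis,
                        excluded = excluded, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(as.data.frame(comparisons),
                     file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    report <- list(
      summary = smry,
      one_sample = analysis$one_sample[c("t", "df", "p", "ci")],
      tost = analysis$tost[c("t_lower", "t_upper", "df", "p_lower",
                             "p_upper", "ci90", "equivalent", "bounds",
                             "alpha")],
      effect_size = analysis$effect_size[c("g", "ci", "ci_level")],
      framerate = if (!is.null(analysis$framerate)) {
        analysis$framerate[c("groups", "tests")]
      },
      excluded = excluded)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

#' @export
print.pipeline_result <- function(x, digits = 4, ...) {
  cat(sprintf("Shape-tracing agreement pipeline: %d trials analyzed",
              x$manifest$counts$analyzed))
  if (x$manifest$counts$excluded > 0) {
    cat(sprintf(" (%d excluded)", x$manifest$counts$excluded))
  }
  cat("\n\n")
  s <- x$analysis$summary
  cat(sprintf("Mean RMSE %s (SD %s) normalized px, n = %d\n",
              format(round(s$mean, 2), nsmall = 2),
              format(round(s$sd, 2), nsmall = 2), s$n))
  print(x$analysis$one_sample, digits = digits)
  print(x$analysis$tost, digits = digits)
  print(x$analysis$effect_size, digits = digits)
  if (!is.null(x$analysis$framerate)) {
    cat("\n"); print(x$analysis$framerate, digits = digits)
  }
  invisible(x)
}
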