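# Either raw values or (mean, sd, n) summaries drive every test below, so
# paper-style reported summaries can be re-analyzed without raw data.
resolve_summary <- function(values = NULL, mean = NULL, sd = NULL, n = NULL,
                            min_n = 2L) {
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
    n <- length(values)
    if (n < min_n) {
      stop(sprintf("insufficient data: n = %d, need at least %d", n, min_n),
           call. = FALSE)
    }
    list(mean = base::mean(values), sd = stats::sd(values), n = n,
         values = values)
  } else {
    if (is.null(mean) || is.null(sd) || is.null(n)) {
      stop("supply either raw values or all of mean, sd and n",
           call. = FALSE)
    }
    if (n < min_n) {
      stop(sprintf("insufficient data: n = %d, need at least %d", n, min_n),
           call. = FALSE)
    }
    list(mean = mean, sd = sd, n = as.integer(n), values = NULL)
  }
}

#' Summary statistics of per-trial RMSE values
#'
#' @param values numeric vector (n >= 2).
#' @return List with `mean`, `sd` (n - 1 divisor) and `n`.
#' @examples
#' summarize_rmse(c(0, 1))  # mean 0.5, sd 0.7071, n 2
#' @export
summarize_rmse <- function(values) {
  s <- resolve_summary(values)
  list(mean = s$mean, sd = s$sd, n = s$n)
}

#' One-sample t test (raw values or summary statistics)
#'
#' Tests whether the mean differs from `mu0`:
#' t = (mean - mu0) / (sd / sqrt(n)), df = n - 1, two-sided p. With raw
#' values the computation delegates to [stats::t.test()]; the closed form
#' is used when only (mean, sd, n) summaries are available.
#'
#' @param values numeric vector, or NULL when summaries are given.
#' @param mean,sd,n summary statistics (used when `values` is NULL).
#' @param mu0 null-hypothesis mean.
#' @param conf_level confidence level of the reported interval.
#' @return List of class `test_result`: `t`, `df`, `p`, `ci`, `method`.
#' @export
one_sample_t <- function(values = NULL, mean = NULL, sd = NULL, n = NULL,
                         mu0 = 0, conf_level = 0.95) {
  s <- resolve_summary(values, mean, sd, n)
  if (s$sd <= 0) stop("degenerate variance: sd must be > 0", call. = FALSE)
  if (!is.null(s$values)) {
    tt <- stats::t.test(s$values, mu = mu0, conf.level = conf_level)
    out <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, ci = as.numeric(tt$conf.int))
  } else {
    se <- s$sd / sqrt(s$n)
    t_stat <- (s$mean - mu0) / se
    df <- s$n - 1
    crit <- stats::qt(1 - (1 - conf_level) / 2, df)
    out <- list(t = t_stat, df = df,
                p = 2 * stats::pt(-abs(t_stat), df),
                ci = s$mean + c(-1, 1) * crit * se)
  }
  out$mean <- s$mean; out$mu0 <- mu0; out$conf_level <- conf_level
  out$method <- "one-sample"
  structure(out, class = "test_result")
}

#' @export
print.test_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s t test: t(%s) = %s, p = %s\n", x$method,
              format(x$df, digits = digits), format(x$t, digits = digits),
              format.pval(x$p, digits = digits)))
  cat(sprintf("  %g%% CI [%s, %s]\n", 100 * x$conf_level,
              format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits)))
  if (!is.null(x$p_adjusted)) {
    cat(sprintf("  adjusted p (%s, m = %d): %s\n", x$correction,
                x$m_comparisons, format.pval(x$p_adjusted, digits = digits)))
  }
  invisible(x)
}

#' TOST equivalence test for a mean
#'
#' Two one-sided t tests against the equivalence margins (`low`, `high`):
#' t_lower tests H0 mean <= low (rejected by the upper tail), t_upper tests
#' H0 mean >= high (rejected by the lower tail). Equivalence is declared at
#' level alpha when both one-sided tests reject, i.e.
#' max(p_lower, p_upper) < alpha — equivalently, when the (1 - 2 alpha)
#' two-sided confidence interval (90% at alpha = .05) lies inside the
#' margins. The analysis of tracker agreement uses margins (0, 0.30)
#' normalized px.
#'
#' @inheritParams one_sample_t
#' @param low,high equivalence margins (low < high).
#' @param alpha one-sided significance level (default 0.05).
#' @return Object of class `tost_result`: `t_lower`, `t_upper`, `df`,
#'   `p_lower`, `p_upper`, `ci90` (the (1 - 2 alpha) interval),
#'   `equivalent`, `alpha`, `bounds`, `mean`, `se`, `n`.
#' @examples
#' tost_equivalence(mean = 0.28, sd = 0.06, n = 115, low = 0, high = 0.30)
#' @export
tost_equivalence <- function(values = NULL, mean = NULL, sd = NULL, n = NULL,
                             low = 0, high = 0.30, alpha = 0.05) {
  if (low >= high) stop("equivalence margins require low < high",
                        call. = FALSE)
  if (alpha <= 0 || alpha >= 0.5) stop("alpha must lie in (0, 0.5)",
                                       call. = FALSE)
  s <- resolve_summary(values, mean, sd, n)
  if (s$sd <= 0) stop("degenerate variance: sd must be > 0", call. = FALSE)
  se <- s$sd / sqrt(s$n)
  df <- s$n - 1
  t_lower <- (s$mean - low) / se
  t_upper <- (s$mean - high) / se
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  crit <- stats::qt(1 - alpha, df)
  ci <- s$mean + c(-1, 1) * crit * se
  structure(list(t_lower = t_lower, t_upper = t_upper, df = df,
                 p_lower = p_lower, p_upper = p_upper,
                 ci90 = ci, equivalent = max(p_lower, p_upper) < alpha,
                 alpha = alpha, bounds = c(low = low, high = high),
                 mean = s$mean, se = se, n = s$n),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, digits = 4, ...) {
  cat("Equivalence test (two one-sided t tests)\n")
  cat(sprintf("  mean %s (n = %d), margins (%g, %g), alpha = %g\n",
              format(x$mean, digits = digits), x$n,
              x$bounds["low"], x$bounds["high"], x$alpha))
  cat(sprintf("  lower: t(%g) = %s, p = %s\n", x$df,
              format(x$t_lower, digits = digits),
              format.pval(x$p_lower, digits = digits)))
  cat(sprintf("  upper: t(%g) = %s, p = %s\n", x$df,
              format(x$t_upper, digits = digits),
              format.pval(x$p_upper, digits = digits)))
  cat(sprintf("  %g%% CI [%s, %s]\n", 100 * (1 - 2 * x$alpha),
              format(x$ci90[1], digits = digits),
              format(x$ci90[2], digits = digits)))
  cat(sprintf("  decision: %s\n",
              if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}

#' Hedges g effect size with confidence interval
#'
#' One-sample standardized mean difference with the small-sample bias
#' correction J(df) = 1 - 3 / (4 df - 1), df = n - 1:
#' g = J(df) * (mean - mu0) / sd. The confidence interval inverts the
#' noncentral t distribution of the observed statistic t = d * sqrt(n)
#' (pivot on the noncentrality parameter); with raw values a
#' percentile-bootstrap interval is available instead.
#'
#' @inheritParams one_sample_t
#' @param ci_level confidence level (default 0.90, matching the
#'   equivalence-test convention).
#' @param ci_method `"noncentral"` (default) or `"bootstrap"` (raw values
#'   only).
#' @param n_boot bootstrap replicates.
#' @return List of class `hedges_g`: `g`, `ci`, `ci_level`, `d`
#'   (uncorrected), `correction` (J), `df`.
#' @export
hedges_g <- function(values = NULL, mean = NULL, sd = NULL, n = NULL,
                     mu0 = 0, ci_level = 0.90,
                     ci_method = c("noncentral", "bootstrap"),
                     n_boot = 2000L) {
  ci_method <- match.arg(ci_method)
  s <- resolve_summary(values, mean, sd, n)
  if (s$sd <= 0) stop("degenerate variance: sd must be > 0", call. = FALSE)
  df <- s$n - 1
  J <- 1 - 3 / (4 * df - 1)
  d <- (s$mean - mu0) / s$sd
  g <- J * d
  a <- (1 - ci_level) / 2
  if (ci_method == "bootstrap") {
    if (is.null(s$values)) {
      stop("bootstrap CI requires raw values", call. = FALSE)
    }
    gs <- replicate(n_boot, {
      b <- sample(s$values, replace = TRUE)
      J * (base::mean(b) - mu0) / stats::sd(b)
    })
    ci <- stats::quantile(gs, c(a, 1 - a), names = FALSE)
  } else {
    t_obs <- d * sqrt(s$n)
    # ncp such that the observed t sits at a given tail quantile
    ncp_root <- function(prob) {
      # pt() warns about reduced precision at extreme noncentrality; the
      # residual error there is far below the CI's practical resolution
      f <- function(ncp) {
        suppressWarnings(stats::pt(t_obs, df, ncp = ncp)) - prob
      }
      lim <- abs(t_obs) + 50
      if (f(-lim) * f(lim) > 0) return(sign(t_obs) * lim)
      stats::uniroot(f, c(-lim, lim), tol = 1e-10)$root
    }
    ci <- c(ncp_root(1 - a), ncp_root(a)) / sqrt(s$n) * J
  }
  structure(list(g = g, ci = ci, ci_level = ci_level, d = d,
                 correction = J, df = df, method = ci_method),
            class = "hedges_g")
}

#' @export
print.hedges_g <- function(x, digits = 4, ...) {
  cat(sprintf("Hedges g = %s, %g%% CI [%s, %s] (%s)\n",
              format(x$g, digits = digits), 100 * x$ci_level,
              format(x$ci[1], digits = digits),
              format(x$ci[2], digits = digits), x$method))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite fractional degrees of
#' freedom (delegates to [stats::t.test()]); returned in the package's
#' `test_result` form so frame-rate contrasts can carry adjusted p values.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param conf_level confidence level of the mean-difference interval.
#' @return List of class `test_result`: `t`, `df` (fractional), `p`, `ci`.
#' @export
welch_t <- function(a, b, conf_level = 0.95) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("degenerate variance: both groups constant", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, ci = as.numeric(tt$conf.int),
                 mean = base::mean(a) - base::mean(b), mu0 = 0,
                 conf_level = conf_level, method = "welch"),
            class = "test_result")
}

#' Frame-rate sensitivity analysis
#'
#' Pairwise Welch t tests of per-trial RMSE between frame-rate groups
#' (default contrasts 30 vs 60 and 60 vs 120 fps), Bonferroni-corrected
#' with multiplier m = number of requested contrasts, plus a per-group
#' mean (SD) table.
#'
#' @param results a `trial_comparisons` data frame (columns `fps`, `rmse`)
#'   from [compare_trials()].
#' @param contrasts list of length-2 fps vectors to compare.
#' @param correction multiplicity correction, passed to
#'   [stats::p.adjust()] with `n = length(contrasts)`.
#' @return Object of class `framerate_analysis`: `groups` (per-fps n,
#'   mean, sd) and `tests` (one row per contrast with t, df, p,
#'   p_adjusted, ci).
#' @export
framerate_analysis <- function(results,
                               contrasts = list(c(30, 60), c(60, 120)),
                               correction = "bonferroni") {
  stopifnot(is.data.frame(results), all(c("fps", "rmse") %in% names(results)))
  need <- sort(unique(unlist(contrasts)))
  have <- unique(results$fps)
  missing_fps <- setdiff(need, have)
  if (length(missing_fps) > 0) {
    stop(sprintf("no trials for fps group(s): %s",
                 paste(missing_fps, collapse = ", ")), call. = FALSE)
  }
  grp <- split(results$rmse, results$fps)
  groups <- data.frame(fps = as.numeric(names(grp)),
                       n = vapply(grp, length, integer(1)),
                       mean_rmse = vapply(grp, mean, numeric(1)),
                       sd_rmse = vapply(grp, stats::sd, numeric(1)))
  rownames(groups) <- NULL
  tests <- lapply(contrasts, function(cc) {
    tt <- welch_t(grp[[as.character(cc[1])]], grp[[as.character(cc[2])]])
    data.frame(fps_a = cc[1], fps_b = cc[2], t = tt$t, df = tt$df,
               p = tt$p, ci_low = tt$ci[1], ci_high = tt$ci[2])
  })
  tests <- do.call(rbind, tests)
  tests$p_adjusted <- stats::p.adjust(tests$p, method = correction,
                                      n = length(contrasts))
  structure(list(groups = groups, tests = tests, correction = correction,
                 m_comparisons = length(contrasts)),
            class = "framerate_analysis")
}

#' @export
print.framerate_analysis <- function(x, digits = 4, ...) {
  cat("Frame-rate sensitivity of RMSE\n\nPer-group summary:\n")
  print(transform(x$groups, mean_rmse = signif(mean_rmse, digits),
                  sd_rmse = signif(sd_rmse, digits)))
  cat(sprintf("\nPairwise Welch contrasts (%s, m = %d):\n",
              x$correction, x$m_comparisons))
  tt <- x$tests
  tt[c("t", "df", "p", "p_adjusted", "ci_low", "ci_high")] <-
    lapply(tt[c("t", "df", "p", "p_adjusted", "ci_low", "ci_high")],
           signif, digits = digits)
  print(tt)
  invisible(x)
}
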