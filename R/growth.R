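## Growth-curve kinetics: exponential-phase regression on log10(OD600),
## doubling time, lag time, no-growth calls after a long observation
## horizon, and Welch's unequal-variance t-test for strain comparisons.

check_curve <- function(times, od) {
  if (length(times) != length(od) || length(times) < 3)
    stop("a growth curve needs matched times and OD with at least 3 points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od <= 0))
    stop("OD values must be positive (blank-subtract upstream)")
}

#' Fit the exponential phase of a growth curve
#'
#' Regresses log10(OD600) on time over every contiguous window of at least
#' `min_window` points and keeps windows with positive slope and
#' `R^2 >= r2_min`. Because a window spanning the whole of a lag /
#' exponential / plateau curve can still clear an `R^2` threshold, the
#' qualifying windows are anchored to the steepest one: only windows whose
#' slope is at least `slope_quota` times the steepest qualifying slope are
#' considered, and among those the longest wins (ties: steeper slope, then
#' earlier start). The doubling time is `T_D = log10(2) / slope`. When no
#' window qualifies the fit is `indeterminate` — the fate of curves that
#' grow linearly rather than exponentially.
#'
#' @param times sampling times in hours, strictly increasing.
#' @param od OD600 values, positive.
#' @param r2_min minimum coefficient of determination for a window to
#'   qualify (default 0.95).
#' @param min_window minimum number of points in a window (default 4).
#' @param slope_quota fraction of the steepest qualifying slope a window
#'   must reach to be selectable (default 0.95).
#' @return a `growth_fit`: `slope` (log10-OD/h), `intercept`, `r2`,
#'   `window` (start and end indices), `t_d` (hours), `status`
#'   (`"growth"` or `"indeterminate"`).
#' @export
fit_exponential <- function(times, od, r2_min = 0.95, min_window = 4,
                            slope_quota = 0.95) {
  check_curve(times, od)
  n <- length(times)
  y <- log10(od)
  cands <- list()
  for (i in seq_len(n)) {
    if (i + min_window - 1 > n) break
    for (j in seq(i + min_window - 1, n)) {
      x <- times[i:j]; yy <- y[i:j]
      sxx <- sum((x - mean(x))^2)
      syy <- sum((yy - mean(yy))^2)
      sxy <- sum((x - mean(x)) * (yy - mean(yy)))
      slope <- sxy / sxx
      if (slope <= 0 || syy == 0) next
      r2 <- sxy^2 / (sxx * syy)
      if (r2 < r2_min) next
      cands[[length(cands) + 1]] <-
        list(slope = slope, intercept = mean(yy) - slope * mean(x),
             r2 = r2, window = c(i, j), len = j - i + 1)
    }
  }
  best <- NULL
  if (length(cands)) {
    s_max <- max(vapply(cands, `[[`, numeric(1), "slope"))
    for (cand in cands) {
      if (cand$slope < slope_quota * s_max) next
      if (is.null(best) ||
          cand$len > best$len ||
          (cand$len == best$len && cand$slope > best$slope) ||
          (cand$len == best$len && cand$slope == best$slope &&
           cand$window[1] < best$window[1]))
        best <- cand
    }
  }
  if (is.null(best))
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r2 = NA_real_, window = c(NA_integer_, NA_integer_),
                          t_d = NA_real_, status = "indeterminate"),
                     class = "growth_fit"))
  structure(list(slope = best$slope, intercept = best$intercept,
                 r2 = best$r2, window = best$window,
                 t_d = log10(2) / best$slope, status = "growth"),
            class = "growth_fit")
}

#' Lag time from a growth fit
#'
#' The lag (acclimation) time is the time at which the exponential-phase
#' regression line intersects the log10 OD600 value observed at `t = 0`
#' (the earliest point stands in, with a message, when the curve does not
#' start at zero): `T_Lag = (log10(od[1]) - intercept) / slope`.
#'
#' @param fit a `growth_fit` with `status = "growth"`.
#' @param times,od the curve the fit came from.
#' @return lag time in hours.
#' @export
lag_time <- function(fit, times, od) {
  if (!identical(fit$status, "growth"))
    stop("lag time is defined only for fits with growth status")
  if (fit$slope <= 0) stop("lag time needs a positive slope")
  check_curve(times, od)
  if (times[1] != 0)
    message(sprintf("curve starts at t = %g h; using its first point as the t = 0 proxy",
                    times[1]))
  (log10(od[1]) - fit$intercept) / fit$slope
}

#' Growth status with the long-horizon no-growth rule
#'
#' A culture is called `no_growth` when the OD600 never rises by at least
#' `min_delta` above its initial value over an observation span of at least
#' `horizon` hours (default 4320 h, about six months). Curves observed for
#' less than the horizon, or showing a rise, defer to [fit_exponential()]:
#' `growth` when an exponential window qualifies, else `indeterminate`.
#'
#' @inheritParams fit_exponential
#' @param min_delta minimum OD600 rise counted as growth (default 0.05).
#' @param horizon minimum observation span in hours for a no-growth call.
#' @return `"no_growth"`, `"growth"`, or `"indeterminate"`.
#' @export
call_no_growth <- function(times, od, min_delta = 0.05, horizon = 4320,
                           r2_min = 0.95, min_window = 4) {
  check_curve(times, od)
  span <- max(times) - min(times)
  if ((max(od) - od[1]) < min_delta && span >= horizon) return("no_growth")
  fit_exponential(times, od, r2_min = r2_min, min_window = min_window)$status
}

#' Welch's unequal-variance t-test
#'
#' Two-sided t-test without the equal-variance assumption:
#' `t = (mean(x) - mean(y)) / sqrt(s2x/nx + s2y/ny)` with
#' Welch-Satterthwaite degrees of freedom. When both samples have zero
#' variance and equal means the p-value is 1 by convention (with a
#' warning).
#'
#' @param x,y numeric samples, each of size at least 2.
#' @return a `welch_result` list: `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    warning("both samples have zero variance")
    if (mean(x) == mean(y))
      return(structure(list(t = 0, df = nx + ny - 2, p = 1),
                       class = "welch_result"))
    return(structure(list(t = sign(mean(x) - mean(y)) * Inf,
                          df = nx + ny - 2, p = 0), class = "welch_result"))
  }
  a <- vx / nx; b <- vy / ny
  t <- (mean(x) - mean(y)) / sqrt(a + b)
  df <- (a + b)^2 / (a^2 / (nx - 1) + b^2 / (ny - 1))
  structure(list(t = t, df = df, p = 2 * pt(-abs(t), df)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sided t-test: t = %.4g, df = %.3f, p = %.4g\n",
              x$t, x$df, x$p))
  invisible(x)
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$status == "growth")
    cat(sprintf("growth fit: T_D = %.2f h, slope = %.4g log10-OD/h, R^2 = %.4f, window %d..%d\n",
                x$t_d, x$slope, x$r2, x$window[1], x$window[2]))
  else cat("growth fit: indeterminate (no qualifying exponential window)\n")
  invisible(x)
}

#' Analyse a table of growth curves
#'
#' Applies the no-growth rule and exponential fitting to every
#' strain-replicate curve of a tidy OD table and reports doubling and lag
#' times.
#'
#' @param curves data frame with columns `strain`, `replicate`, `time_h`,
#'   `od600`.
#' @inheritParams fit_exponential
#' @inheritParams call_no_growth
#' @return data frame with one row per strain-replicate: `slope`, `r2`,
#'   `window_start`, `window_end`, `t_d_h`, `t_lag_h`, `status`.
#' @export
analyze_growth <- function(curves, r2_min = 0.95, min_window = 4,
                           min_delta = 0.05, horizon = 4320) {
  stopifnot(all(c("strain", "replicate", "time_h", "od600") %in% names(curves)))
  groups <- unique(curves[, c("strain", "replicate")])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- curves[curves$strain == groups$strain[g] &
                  curves$replicate == groups$replicate[g], , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    status <- call_no_growth(sub$time_h, sub$od600, min_delta, horizon,
                             r2_min, min_window)
    fit <- fit_exponential(sub$time_h, sub$od600, r2_min, min_window)
    grows <- status == "growth" && fit$status == "growth"
    data.frame(strain = groups$strain[g], replicate = groups$replicate[g],
               slope = if (grows) fit$slope else NA_real_,
               r2 = if (grows) fit$r2 else NA_real_,
               window_start = if (grows) fit$window[1] else NA_integer_,
               window_end = if (grows) fit$window[2] else NA_integer_,
               t_d_h = if (grows) fit$t_d else NA_real_,
               t_lag_h = if (grows) lag_time(fit, sub$time_h, sub$od600)
                         else NA_real_,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two strains' growth parameters
#'
#' Welch's two-sided t-test on per-replicate doubling or lag times from
#' [analyze_growth()].
#'
#' @param results data frame from [analyze_growth()].
#' @param strain_a,strain_b strain names.
#' @param metric `"t_d_h"` or `"t_lag_h"`.
#' @return a `welch_result`.
#' @export
compare_strains <- function(results, strain_a, strain_b,
                            metric = c("t_d_h", "t_lag_h")) {
  metric <- match.arg(metric)
  a <- results[[metric]][results$strain == strain_a]
  b <- results[[metric]][results$strain == strain_b]
  if (anyNA(a) || anyNA(b))
    stop("both strains need growth fits on every replicate for this comparison")
  welch_t(a, b)
}
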