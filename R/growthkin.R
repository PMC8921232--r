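# Growth kinetics: log-phase doubling-time estimation from timed cell
# counts. The log phase is the run of 3 consecutive intervals with the
# steepest summed log-count slope; the doubling time between two counts is
# g = (T2 - T1) * log(2) / (log(N2) - log(N1)).

#' Construct a growth series from timed cell counts
#'
#' @param counts data.frame with columns `time_h`, `replicate`, `count`
#'   (as produced by [simulate_growth_counts()] or [read_growth_tsv()]).
#' @return Object of class `growth_series`: list with `times` (hours,
#'   strictly increasing), `mean_counts` (per-time replicate means) and
#'   the raw `counts` table.
#' @export
growth_series <- function(counts) {
  stopifnot(all(c("time_h", "count") %in% names(counts)))
  times <- sort(unique(counts$time_h))
  if (length(times) < 2L) stop_input("at least 2 time points are required")
  mean_counts <- vapply(times, function(t) {
    mean(counts$count[counts$time_h == t])
  }, numeric(1))
  structure(list(times = times, mean_counts = mean_counts, counts = counts),
            class = "growth_series")
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("growth_series: %d time points over %.1f h, mean counts %.3g to %.3g\n",
              length(x$times), diff(range(x$times)),
              x$mean_counts[1], x$mean_counts[length(x$mean_counts)]))
  invisible(x)
}

#' Doubling time between two timed counts
#'
#' `g = (T2 - T1) * log(2) / (log(N2) - log(N1))`. The log ratio is
#' base-invariant, so any log base gives the same result (natural log is
#' used). A declining interval yields a negative g, passed through with a
#' warning.
#'
#' @param T1,T2 Times in hours, `T2 > T1`.
#' @param N1,N2 Cell counts, positive; `N2 != N1`.
#' @return Doubling time in hours.
#' @examples
#' interval_doubling(0, 1000, 24, 2000)  # 24
#' interval_doubling(0, 1000, 24, 4000)  # 12
#' @export
interval_doubling <- function(T1, N1, T2, N2) {
  if (T2 <= T1) stop_input("T2 must be greater than T1")
  if (N1 <= 0 || N2 <= 0) stop_input("counts must be positive")
  if (N2 == N1) stop_input("N2 equals N1: doubling time undefined")
  g <- (T2 - T1) * log(2) / (log(N2) - log(N1))
  if (g < 0) warning("declining counts: negative doubling time", call. = FALSE)
  g
}

#' Locate the log-phase window (3 steepest consecutive slopes)
#'
#' Computes per-interval slopes of log(mean count) against time and
#' returns the run of 3 consecutive intervals with the largest summed
#' slope; ties are broken by the earliest start.
#'
#' @param series A [growth_series()] (or a counts data.frame).
#' @param n_intervals Window length in intervals (default 3).
#' @return Integer vector of interval indices (interval i spans times
#'   i..i+1), with attribute `slopes` of all per-interval slopes.
#' @export
log_phase_window <- function(series, n_intervals = 3L) {
  if (!inherits(series, "growth_series")) series <- growth_series(series)
  times <- series$times; mc <- series$mean_counts
  if (length(times) < n_intervals + 1L) {
    stop_input("series too short for log-phase rule: need >= %d time points",
               n_intervals + 1L)
  }
  if (any(mc <= 0)) stop_input("mean counts must be positive")
  slopes <- diff(log(mc)) / diff(times)
  sums <- vapply(seq_len(length(slopes) - n_intervals + 1L), function(s) {
    sum(slopes[s:(s + n_intervals - 1L)])
  }, numeric(1))
  s <- which.max(sums)     # which.max takes the first maximum: earliest start
  structure(seq.int(s, s + n_intervals - 1L), slopes = slopes)
}

#' Log-phase doubling time of a growth series
#'
#' Selects the log-phase window with [log_phase_window()] and averages the
#' per-interval doubling times over it, using per-time replicate mean
#' counts.
#'
#' @inheritParams log_phase_window
#' @return Object of class `doubling_estimate`: list with `g` (hours),
#'   `window` (interval indices), `interval_g`, `times`, `declining`.
#' @export
mean_doubling_time <- function(series, n_intervals = 3L) {
  if (!inherits(series, "growth_series")) series <- growth_series(series)
  win <- log_phase_window(series, n_intervals)
  t <- series$times; mc <- series$mean_counts
  gi <- vapply(win, function(i) {
    interval_doubling(t[i], mc[i], t[i + 1L], mc[i + 1L])
  }, numeric(1))
  structure(list(g = mean(gi), window = win, interval_g = gi,
                 times = t[c(win[1], win[length(win)] + 1L)],
                 declining = mean(gi) < 0),
            class = "doubling_estimate")
}

#' @export
print.doubling_estimate <- function(x, ...) {
  cat(sprintf("log-phase doubling time: %.2f h (window %.0f-%.0f h; per-interval g: %s)\n",
              x$g, x$times[1], x$times[2],
              paste(sprintf("%.2f", x$interval_g), collapse = ", ")))
  if (x$declining) cat("  warning: declining series, negative estimate\n")
  invisible(x)
}

#' Compare doubling times between two growth series
#'
#' Two-sample two-tailed t-test on the per-interval log-phase doubling
#' times of two series (e.g. early versus late passage).
#'
#' @param series_a,series_b Growth series (or counts data.frames).
#' @return `htest` object from [stats::t.test()].
#' @export
compare_doubling <- function(series_a, series_b) {
  ga <- mean_doubling_time(series_a)$interval_g
  gb <- mean_doubling_time(series_b)$interval_g
  t.test(ga, gb)
}

#' Plot a growth series with its log-phase window
#'
#' Log-scale mean counts over time; the fitted log-phase window is shaded
#' and the estimated doubling time annotated.
#'
#' @param x A `growth_series`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the `doubling_estimate`.
#' @importFrom graphics points rect mtext
#' @export
plot.growth_series <- function(x, ...) {
  est <- mean_doubling_time(x)
  plot(x$times, x$mean_counts, log = "y", type = "b", pch = 16,
       xlab = "time (h)", ylab = "mean cell count", ...)
  rect(est$times[1], min(x$mean_counts), est$times[2], max(x$mean_counts),
       col = grDevices::adjustcolor("steelblue", 0.15), border = NA)
  mtext(sprintf("log-phase g = %.1f h", est$g), side = 3, line = 0.2,
        cex = 0.9)
  invisible(est)
}
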