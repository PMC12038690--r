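#' Construct a trace
#'
#' A single-channel time series on a strictly increasing uniform time grid.
#' `kind` records where the trace sits in the processing chain (raw siemens,
#' smoothed, baseline-normalized dG/G0, endpoint-normalized, differential).
#'
#' @param time Time stamps in seconds (uniform grid, length >= 2).
#' @param values Trace values (same length as `time`).
#' @param kind One of `"raw"`, `"smoothed"`, `"baseline_norm"`,
#'   `"endpoint_norm"`, `"differential"`.
#' @return An object of class `pegs_trace`.
#' @export
new_trace <- function(time, values,
                      kind = c("raw", "smoothed", "baseline_norm",
                               "endpoint_norm", "differential")) {
  kind <- match.arg(kind)
  stop_if_not(is.numeric(time) && length(time) >= 2, "time must have length >= 2")
  stop_if_not(length(values) == length(time),
              "values must match time in length")
  dtv <- diff(time)
  stop_if_not(all(dtv > 0), "time must be strictly increasing")
  stop_if_not(max(dtv) - min(dtv) <= 1e-9 * max(dtv),
              "time must be a uniform grid")
  structure(list(time = as.numeric(time), values = as.numeric(values),
                 kind = kind), class = "pegs_trace")
}

#' @export
print.pegs_trace <- function(x, ...) {
  cat(sprintf("<pegs_trace> kind %s, %d samples over %.1f s, range [%.4g, %.4g]\n",
              x$kind, length(x$time), max(x$time) - min(x$time),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Extract one channel of a recording as a trace
#'
#' @param recording A `pegs_recording`.
#' @param channel Channel id (character) or column index.
#' @return A raw `pegs_trace`.
#' @export
recording_trace <- function(recording, channel) {
  stop_if_not(inherits(recording, "pegs_recording"),
              "recording must be a pegs_recording")
  if (is.character(channel)) {
    stop_if_not(channel %in% colnames(recording$traces),
                sprintf("no channel named \"%s\"", channel),
                class = "pegs_missing_channel")
  }
  new_trace(recording$time, recording$traces[, channel], "raw")
}

#' Centered moving-average filter
#'
#' The low-pass filter used on wearable recordings to remove the breathing
#' oscillation: a centered running mean over `window_points` samples (at the
#' default 10 Hz sampling, 1000 points spans 100 s, about eight breathing
#' cycles).  Windows shrink symmetrically at both edges so the output has the
#' same length as the input and the 15-min endpoint stays defined.
#'
#' @param trace A `pegs_trace`.
#' @param window_points Window length in samples (>= 1, <= trace length).
#' @return A `pegs_trace` of kind `"smoothed"`.
#' @export
moving_average <- function(trace, window_points = 1000) {
  stop_if_not(inherits(trace, "pegs_trace"), "trace must be a pegs_trace")
  n <- length(trace$values)
  stop_if_not(is.numeric(window_points) && window_points >= 1 &&
                window_points == round(window_points),
              "window_points must be a positive integer")
  stop_if_not(window_points <= n,
              "window_points must not exceed the trace length")
  hl <- floor((window_points - 1) / 2)
  hr <- window_points - 1 - hl
  cs <- cumsum(c(0, trace$values))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - hl)
  hi <- pmin(n, idx + hr)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  new_trace(trace$time, out, "smoothed")
}

#' Normalize a trace to its pre-exposure baseline
#'
#' Computes the relative conductance change dG/G0 where G0 is the mean over
#' the pre-exposure baseline window.  This removes the per-sensor baseline
#' spread caused by the intrinsic microstructural variability of paper.
#'
#' @param trace A `pegs_trace` (raw or smoothed).
#' @param baseline_window_s Length of the baseline window in seconds,
#'   measured from the start of the trace (must cover at least one sample
#'   and lie within the pre-exposure period).
#' @return A `pegs_trace` of kind `"baseline_norm"`; values are ~0 over the
#'   baseline window.
#' @export
normalize_baseline <- function(trace, baseline_window_s) {
  stop_if_not(inherits(trace, "pegs_trace"), "trace must be a pegs_trace")
  stop_if_not(is.numeric(baseline_window_s) && baseline_window_s > 0,
              "baseline_window_s must be > 0")
  t0 <- trace$time[1]
  sel <- trace$time <= t0 + baseline_window_s
  stop_if_not(any(sel), "baseline window contains no samples")
  g0 <- mean(trace$values[sel])
  if (g0 <= 0) pegs_error("baseline conductance G0 must be positive",
                          "pegs_invalid_data")
  new_trace(trace$time, (trace$values - g0) / g0, "baseline_norm")
}

#' Normalize a trace to its endpoint value
#'
#' Divides the trace by its value at `t_end` (the 15-min mark for wearable
#' recordings) so that channels with different absolute conductances become
#' comparable; the output equals 1 exactly at `t_end`.
#'
#' @param trace A `pegs_trace`.
#' @param t_end Endpoint time in seconds (default: last sample); must lie
#'   within the trace span and the trace value there must be positive.
#' @return A `pegs_trace` of kind `"endpoint_norm"`.
#' @export
normalize_endpoint <- function(trace, t_end = NULL) {
  stop_if_not(inherits(trace, "pegs_trace"), "trace must be a pegs_trace")
  if (is.null(t_end)) t_end <- trace$time[length(trace$time)]
  stop_if_not(t_end >= trace$time[1] &&
                t_end <= trace$time[length(trace$time)] + 1e-9,
              "t_end must lie within the trace span")
  i <- which.min(abs(trace$time - t_end))
  v <- trace$values[i]
  if (v <= 0) pegs_error("endpoint value must be positive", "pegs_invalid_data")
  new_trace(trace$time, trace$values / v, "endpoint_norm")
}

#' Differential signal of two traces
#'
#' The humidity-cancelling subtraction at the core of the array readout:
#' `S_NH3 = S_A - S_U`.  The untreated sensor responds only to humidity, the
#' acid sensor to both humidity and NH3, so the pointwise difference isolates
#' the neutralization response.
#'
#' @param s_a,s_u `pegs_trace` objects on the same time grid and of the same
#'   kind (conventionally the acid-treated and untreated signals).
#' @return A `pegs_trace` of kind `"differential"`.
#' @export
differential <- function(s_a, s_u) {
  stop_if_not(inherits(s_a, "pegs_trace") && inherits(s_u, "pegs_trace"),
              "inputs must be pegs_trace objects")
  if (length(s_a$time) != length(s_u$time) ||
      max(abs(s_a$time - s_u$time)) > 1e-9) {
    pegs_error("traces are on different time grids", "pegs_incompatible_traces")
  }
  if (!identical(s_a$kind, s_u$kind)) {
    pegs_error("traces have different kinds", "pegs_incompatible_traces")
  }
  new_trace(s_a$time, s_a$values - s_u$values, "differential")
}

#' Aggregate replicate channels of one functionalization
#'
#' The array carries replicate sensors of each functionalization; their
#' (optionally transformed) traces are combined by a pointwise mean.
#'
#' @param recording A `pegs_recording`.
#' @param functionalization `"U"`, `"A"` or `"B"`.
#' @param transform A function `pegs_trace -> pegs_trace` applied to every
#'   matching channel before averaging (e.g. smoothing plus normalization);
#'   defaults to the identity.
#' @return A `pegs_trace`: the pointwise mean of the matching channels.
#' @export
channel_aggregate <- function(recording, functionalization,
                              transform = identity) {
  stop_if_not(inherits(recording, "pegs_recording"),
              "recording must be a pegs_recording")
  sel <- which(recording$channels$functionalization == functionalization)
  if (length(sel) == 0) {
    pegs_error(sprintf("no channel with functionalization \"%s\"",
                       functionalization), "pegs_missing_channel")
  }
  traces <- lapply(sel, function(j) transform(recording_trace(recording, j)))
  vals <- rowMeans(do.call(cbind, lapply(traces, `[[`, "values")))
  new_trace(traces[[1]]$time, vals, traces[[1]]$kind)
}

slope_result <- function(slope, interval, r_squared, method) {
  structure(list(slope = slope, interval = interval, r_squared = r_squared,
                 method = method), class = "pegs_slope")
}

#' @export
print.pegs_slope <- function(x, ...) {
  cat(sprintf("<pegs_slope> %s: %.5g min^-1 on [%.1f, %.1f] s (R^2 %.4f)\n",
              x$method, x$slope, x$interval[1], x$interval[2], x$r_squared))
  invisible(x)
}

#' Post-peak slope of a trace
#'
#' The chamber-style slope readout: locate the trace maximum, skip a short
#' settling interval past it, and fit an ordinary least-squares line from
#' there to the end of the trace (or to `fit_end_s`).  The fitted slope, in
#' inverse minutes, is the concentration indicator: higher NH3 neutralizes
#' the acid faster and steepens the decline.
#'
#' @param trace A `pegs_trace`.
#' @param skip_after_peak_s Settling time skipped after the peak before the
#'   fit starts, s (default 30).
#' @param peak_search_end_s Restrict the peak search to times at or before
#'   this value (default `NULL`: whole trace).  Differential breathing traces
#'   end at zero by construction, so their concentration-bearing peak is the
#'   initial one; the breathing analysis passes half the recording here.
#' @param fit_start_s,fit_end_s Optional fit window bounds in seconds.  The
#'   fit runs from `max(t_peak + skip, fit_start_s)` to `fit_end_s` (trace
#'   end when `NULL`).  Chamber analyses pass the exposure window so neither
#'   the pre-exposure baseline nor the recovery phase dilutes the slope.
#' @return A `pegs_slope` with `method = "post_peak"`.
#' @export
post_peak_slope <- function(trace, skip_after_peak_s = 30,
                            peak_search_end_s = NULL, fit_start_s = NULL,
                            fit_end_s = NULL) {
  stop_if_not(inherits(trace, "pegs_trace"), "trace must be a pegs_trace")
  stop_if_not(is.numeric(skip_after_peak_s) && skip_after_peak_s >= 0,
              "skip_after_peak_s must be >= 0")
  tt <- trace$time; vv <- trace$values
  search <- if (is.null(peak_search_end_s)) seq_along(tt) else
    which(tt <= peak_search_end_s)
  stop_if_not(length(search) >= 1, "peak search window is empty")
  ipk <- search[which.max(vv[search])]
  if (ipk == length(tt)) {
    pegs_error("trace peaks at its final sample: no decline to fit",
               "pegs_no_decline")
  }
  t_fit_start <- tt[ipk] + skip_after_peak_s
  if (!is.null(fit_start_s)) t_fit_start <- max(t_fit_start, fit_start_s)
  t_fit_end <- if (is.null(fit_end_s)) tt[length(tt)] else fit_end_s
  sel <- tt >= t_fit_start & tt <= t_fit_end
  if (sum(sel) < 2) {
    pegs_error("fewer than two samples after the peak-skip window",
               "pegs_no_decline")
  }
  fit <- .ols(tt[sel] / 60, vv[sel])
  slope_result(fit$slope, c(min(tt[sel]), max(tt[sel])), fit$r_squared,
               "post_peak")
}

#' Peak-fraction slope of a trace
#'
#' The wearable-recording slope readout: locate the peak, take the interval
#' from the first crossing of `hi` x peak (after the peak) to the first
#' crossing of `lo` x peak (trace end if the low level is never reached), and
#' fit an ordinary least-squares line on it.  Defaults reproduce the
#' 90%-to-20% peak-height interval.
#'
#' @param trace A `pegs_trace`; its maximum must be positive.
#' @param hi,lo Upper and lower peak fractions, `0 < lo < hi <= 1`
#'   (defaults 0.90 and 0.20).
#' @return A `pegs_slope` with `method = "peak_fraction"`.
#' @export
peak_fraction_slope <- function(trace, hi = 0.90, lo = 0.20) {
  stop_if_not(inherits(trace, "pegs_trace"), "trace must be a pegs_trace")
  stop_if_not(is.numeric(hi) && is.numeric(lo) && lo > 0 && lo < hi && hi <= 1,
              "need 0 < lo < hi <= 1")
  tt <- trace$time; vv <- trace$values
  ipk <- which.max(vv)
  peak <- vv[ipk]
  if (peak <= 0) pegs_error("trace peak must be positive", "pegs_invalid_data")
  after <- if (ipk < length(vv)) seq(ipk + 1, length(vv)) else integer(0)
  i_hi <- after[which(vv[after] <= hi * peak)[1]]
  if (length(i_hi) == 0 || is.na(i_hi)) {
    pegs_error("trace never falls to the upper peak fraction: degenerate interval",
               "pegs_degenerate_interval")
  }
  later <- seq(i_hi, length(vv))
  i_lo <- later[which(vv[later] <= lo * peak)[1]]
  if (length(i_lo) == 0 || is.na(i_lo)) i_lo <- length(vv)
  if (i_lo <= i_hi) i_lo <- i_hi + 1L
  if (i_lo > length(vv)) {
    pegs_error("peak-fraction interval collapses to a point",
               "pegs_degenerate_interval")
  }
  sel <- seq(i_hi, i_lo)
  fit <- .ols(tt[sel] / 60, vv[sel])
  slope_result(fit$slope, c(tt[sel[1]], tt[sel[length(sel)]]), fit$r_squared,
               "peak_fraction")
}

#' Rescale a trace to unit maximum
#'
#' Divides by the trace maximum (which must be positive), as applied to the
#' differential signal before the peak-fraction slope so different subjects
#' and runs become comparable.
#'
#' @param trace A `pegs_trace`.
#' @return A `pegs_trace` of the same kind with maximum exactly 1.
#' @export
normalize_max <- function(trace) {
  stop_if_not(inherits(trace, "pegs_trace"), "trace must be a pegs_trace")
  mx <- max(trace$values)
  if (mx <= 0) pegs_error("trace maximum must be positive", "pegs_invalid_data")
  new_trace(trace$time, trace$values / mx, trace$kind)
}
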