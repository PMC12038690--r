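#' Analyze a constant-humidity chamber recording
#'
#' The chamber processing chain: each channel is normalized to its
#' pre-exposure baseline (dG/G0) and the post-peak slope is fitted within
#' the exposure window (the peak is searched within the pre-exposure
#' baseline, where a chamber-equilibrated sensor tops out before the
#' neutralization decline), giving one concentration-indicating slope per
#' channel.
#'
#' @param recording A `pegs_recording` from a [chamber_protocol()] run.
#' @param baseline_s Baseline window length in seconds (default 120,
#'   matching the default chamber protocol's pre-exposure segment).
#' @param exposure_end_s End of the exposure window in seconds from the
#'   start of the recording (default `NULL`: trace end).  Pass
#'   `baseline + exposure` duration to keep the recovery phase out of the
#'   fit.
#' @param skip_after_peak_s Settling time skipped after the peak (default 30).
#' @return A data frame with one row per channel: `id`, `functionalization`,
#'   `molarity`, `g0` (baseline conductance, S), `slope` (min^-1),
#'   `r_squared`, `t_start`, `t_end`.
#' @export
analyze_chamber <- function(recording, baseline_s = 120,
                            exposure_end_s = NULL, skip_after_peak_s = 30) {
  stop_if_not(inherits(recording, "pegs_recording"),
              "recording must be a pegs_recording")
  rows <- lapply(seq_len(ncol(recording$traces)), function(j) {
    tr <- recording_trace(recording, j)
    g0 <- mean(tr$values[tr$time <= tr$time[1] + baseline_s])
    nb <- normalize_baseline(tr, baseline_s)
    # channels that only rise (e.g. untreated sensors under NH3) have no
    # decline to fit; report NA rather than fail the whole array
    sl <- tryCatch(
      post_peak_slope(nb, skip_after_peak_s = skip_after_peak_s,
                      peak_search_end_s = baseline_s,
                      fit_start_s = baseline_s, fit_end_s = exposure_end_s),
      pegs_no_decline = function(e)
        slope_result(NA_real_, c(NA_real_, NA_real_), NA_real_, "post_peak")
    )
    data.frame(id = recording$channels$id[j],
               functionalization = recording$channels$functionalization[j],
               molarity = recording$channels$molarity[j],
               g0 = g0, slope = sl$slope, r_squared = sl$r_squared,
               t_start = sl$interval[1], t_end = sl$interval[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Analyze a breathing or wearable-mask recording
#'
#' The differential processing chain for recordings under cyclic humidity:
#' every channel is smoothed with the centered moving average and normalized
#' to its endpoint, replicate channels of each functionalization are
#' averaged, and the humidity-cancelling differential `S_A - S_U` is formed.
#' The slope is then extracted either as the post-peak fit used for the
#' bench respiratory-simulator calibration (`method = "post_peak"`; the
#' peak search is restricted to the first half of the recording, where the
#' initial moisture-equilibration peak lies) or as the 90%-to-20%
#' peak-fraction fit on the max-normalized differential used for human
#' recordings (`method = "peak_fraction"`).
#'
#' @param recording A `pegs_recording` containing at least one `"A"` and one
#'   `"U"` channel.
#' @param method `"post_peak"` or `"peak_fraction"`.
#' @param window_points Moving-average window in samples (default 1000).
#' @param t_end Endpoint-normalization time in seconds (default: last
#'   sample, i.e. the 15-min mark for standard recordings).
#' @param hi,lo Peak fractions for `method = "peak_fraction"` (defaults 0.90
#'   and 0.20).
#' @param skip_after_peak_s Post-peak settling skip for
#'   `method = "post_peak"` (default 30).
#' @return A list with `slope` (the `pegs_slope` result), `differential`
#'   (the differential `pegs_trace`; max-normalized for
#'   `"peak_fraction"`), `s_a` and `s_u` (the aggregated normalized traces).
#' @export
analyze_breath <- function(recording, method = c("post_peak", "peak_fraction"),
                           window_points = 1000, t_end = NULL,
                           hi = 0.90, lo = 0.20, skip_after_peak_s = 30) {
  method <- match.arg(method)
  stop_if_not(inherits(recording, "pegs_recording"),
              "recording must be a pegs_recording")
  prep <- function(tr) normalize_endpoint(moving_average(tr, window_points),
                                          t_end)
  s_a <- channel_aggregate(recording, "A", prep)
  s_u <- channel_aggregate(recording, "U", prep)
  dif <- differential(s_a, s_u)
  if (method == "post_peak") {
    half <- (dif$time[1] + dif$time[length(dif$time)]) / 2
    sl <- post_peak_slope(dif, skip_after_peak_s = skip_after_peak_s,
                          peak_search_end_s = half)
    list(slope = sl, differential = dif, s_a = s_a, s_u = s_u)
  } else {
    difn <- normalize_max(dif)
    sl <- peak_fraction_slope(difn, hi = hi, lo = lo)
    list(slope = sl, differential = difn, s_a = s_a, s_u = s_u)
  }
}
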