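#' Exposure protocol segment
#'
#' A piecewise-constant interval of the exposure schedule: fixed relative
#' humidity, gas levels and carrier flow for a given duration.
#'
#' @param duration Segment length in seconds (> 0).
#' @param rh Relative humidity in percent, in \[0, 100\].
#' @param nh3 NH3 concentration in ppm (>= 0).
#' @param co2 CO2 concentration in % v/v (>= 0).
#' @param flow Carrier flow in mL/min (>= 0).
#' @return A one-row data frame with the segment fields.
#' @export
protocol_segment <- function(duration, rh, nh3 = 0, co2 = 0, flow = 2000) {
  stop_if_not(is.numeric(duration) && length(duration) == 1 && duration > 0,
              "duration must be > 0")
  stop_if_not(is.numeric(rh) && rh >= 0 && rh <= 100, "rh must be in [0, 100]")
  stop_if_not(is.numeric(nh3) && nh3 >= 0, "nh3 must be >= 0")
  stop_if_not(is.numeric(co2) && co2 >= 0, "co2 must be >= 0")
  stop_if_not(is.numeric(flow) && flow >= 0, "flow must be >= 0")
  data.frame(duration = duration, rh = rh, nh3 = nh3, co2 = co2, flow = flow)
}

new_protocol <- function(segments, repeat_count = 1L, description = "") {
  stop_if_not(is.data.frame(segments) && nrow(segments) >= 1,
              "protocol needs at least one segment")
  stop_if_not(is.numeric(repeat_count) && repeat_count >= 1 &&
                repeat_count == round(repeat_count),
              "repeat_count must be a positive integer")
  p <- list(segments = segments, repeat_count = as.integer(repeat_count),
            description = description)
  class(p) <- "pegs_protocol"
  p
}

#' Total duration of an exposure protocol
#'
#' @param protocol A `pegs_protocol`.
#' @return Duration in seconds: `repeat_count * sum(segment durations)`.
#' @export
protocol_duration <- function(protocol) {
  protocol$repeat_count * sum(protocol$segments$duration)
}

#' @export
print.pegs_protocol <- function(x, ...) {
  cat(sprintf("<pegs_protocol> %s\n", x$description))
  cat(sprintf("  %d segment(s) x %d repeat(s), total %.1f min\n",
              nrow(x$segments), x$repeat_count, protocol_duration(x) / 60))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Constant-humidity chamber exposure protocol
#'
#' The characterization protocol: sensors rest in the chamber at constant RH,
#' then see a constant target-gas step, then recover in clean carrier gas.
#' Used for the fixed-65%-RH NH3 and CO2 characterization runs.
#'
#' @param gas `"NH3"` or `"CO2"`.
#' @param conc Exposure concentration: ppm for NH3, % v/v for CO2 (>= 0).
#' @param exposure_min Exposure duration in minutes (> 0).
#' @param rh Chamber relative humidity in percent (default 65).
#' @param baseline_min Pre-exposure baseline duration in minutes (default 2).
#' @param recovery_min Post-exposure recovery duration in minutes (default 5).
#' @param flow Carrier flow in mL/min (default 2000).
#' @return A `pegs_protocol` with three segments.
#' @examples
#' chamber_protocol("NH3", 5, 10)
#' @export
chamber_protocol <- function(gas, conc, exposure_min, rh = 65,
                             baseline_min = 2, recovery_min = 5, flow = 2000) {
  stop_if_not(is.character(gas) && length(gas) == 1 && gas %in% c("NH3", "CO2"),
              "gas must be \"NH3\" or \"CO2\"")
  stop_if_not(is.numeric(conc) && conc >= 0, "conc must be >= 0")
  stop_if_not(is.numeric(exposure_min) && exposure_min > 0,
              "exposure_min must be > 0")
  stop_if_not(baseline_min > 0 && recovery_min > 0,
              "baseline_min and recovery_min must be > 0")
  nh3 <- if (gas == "NH3") conc else 0
  co2 <- if (gas == "CO2") conc else 0
  segs <- rbind(
    protocol_segment(baseline_min * 60, rh, 0, 0, flow),
    protocol_segment(exposure_min * 60, rh, nh3, co2, flow),
    protocol_segment(recovery_min * 60, rh, 0, 0, flow)
  )
  new_protocol(segs, 1L,
               sprintf("chamber %s %g%s, %g min @ %g%% RH", gas, conc,
                       if (gas == "NH3") " ppm" else "% v/v", exposure_min, rh))
}

#' Simulated-breathing exposure protocol
#'
#' The bench respiratory schedule: repeated cycles of an 8 s humidified
#' exhalation segment (default 90% RH, 2000 mL/min, carrying the NH3 dose)
#' followed by a 4 s room-air inhalation segment (default 50% RH, NH3-free).
#' At 2000 mL/min the 8 s exhalation moves about 267 mL, matching the bench
#' simulator's ~270 mL tidal volume.
#'
#' @param nh3_ppm NH3 concentration in the exhalation stream, ppm (>= 0).
#' @param minutes Total protocol length in minutes (> 0); the cycle count is
#'   `ceiling(minutes * 60 / 12)`.
#' @param rh_exhale,rh_inhale Exhalation / inhalation RH in percent
#'   (defaults 90 and 50).
#' @param flow Flow in mL/min for both phases (default 2000).
#' @return A `pegs_protocol` with a two-segment cycle and the appropriate
#'   repeat count.
#' @examples
#' breathing_protocol(5, 15)   # 75 cycles of 8 s + 4 s
#' @export
breathing_protocol <- function(nh3_ppm, minutes, rh_exhale = 90,
                               rh_inhale = 50, flow = 2000) {
  stop_if_not(is.numeric(nh3_ppm) && nh3_ppm >= 0, "nh3_ppm must be >= 0")
  stop_if_not(is.numeric(minutes) && minutes > 0, "minutes must be > 0")
  segs <- rbind(
    protocol_segment(8, rh_exhale, nh3_ppm, 0, flow),
    protocol_segment(4, rh_inhale, 0, 0, flow)
  )
  new_protocol(segs, ceiling(minutes * 60 / 12),
               sprintf("breathing %g ppm NH3, %g min (8 s / 4 s)", nh3_ppm,
                       minutes))
}

# Expand a protocol into a per-step schedule on a uniform grid of step dt.
# Returns a data frame with one row per step: the segment conditions in
# force during [t, t + dt).
protocol_schedule <- function(protocol, dt) {
  stop_if_not(is.numeric(dt) && dt > 0, "dt must be > 0")
  segs <- protocol$segments[rep(seq_len(nrow(protocol$segments)),
                                protocol$repeat_count), , drop = FALSE]
  ends <- cumsum(segs$duration)
  total <- ends[length(ends)]
  n <- floor(total / dt + 1e-9)
  t0 <- (seq_len(n) - 1) * dt
  idx <- findInterval(t0, c(0, ends), rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx > nrow(segs)] <- nrow(segs)
  data.frame(time = t0, rh = segs$rh[idx], nh3 = segs$nh3[idx],
             co2 = segs$co2[idx], flow = segs$flow[idx])
}
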