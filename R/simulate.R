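#' Measurement-noise parameters for simulated recordings
#'
#' Defaults emulate the variability of the physical device: a per-sensor
#' multiplicative baseline factor (paper microstructure and pipetting
#' variability, lognormal with 15% CV), additive white measurement noise
#' (0.5% of each channel's baseline), a slow bounded environmental drift
#' shared by all co-located channels (up to 5% over a 15-min recording) with
#' a much smaller idiosyncratic per-channel component, and an optional
#' breathing-period oscillation used for wearable-mask recordings.
#'
#' @param baseline_cv Coefficient of variation of the lognormal per-channel
#'   baseline multiplier (default 0.15).
#' @param white_frac Additive white-noise SD as a fraction of the channel
#'   baseline (default 0.005).
#' @param drift_frac Peak amplitude of the slow common-mode drift as a
#'   fraction of the channel baseline (default 0.05).
#' @param drift_channel_frac Peak amplitude of the per-channel idiosyncratic
#'   drift (default 2e-4).  Co-located paper sensors share their environment,
#'   so almost all slow drift is common mode and cancels in the differential.
#' @param osc_frac Amplitude of an instrumental oscillation at the 12 s
#'   breathing period, as a fraction of baseline (default 0; the mask-wearing
#'   cohort uses 0.02).
#' @return An object of class `pegs_noise`.
#' @export
noise_params <- function(baseline_cv = 0.15, white_frac = 0.005,
                         drift_frac = 0.05, drift_channel_frac = 2e-4,
                         osc_frac = 0) {
  stop_if_not(baseline_cv >= 0 && white_frac >= 0 && drift_frac >= 0 &&
                drift_channel_frac >= 0 && osc_frac >= 0,
              "noise parameters must be non-negative")
  n <- list(baseline_cv = baseline_cv, white_frac = white_frac,
            drift_frac = drift_frac, drift_channel_frac = drift_channel_frac,
            osc_frac = osc_frac)
  class(n) <- "pegs_noise"
  n
}

#' Run a PEGS array through an exposure protocol
#'
#' Fixed-step operator-splitting integration of the sensor model: at each
#' step the water film relaxes toward the segment's humidity equilibrium,
#' the segment's gas delivery (via [gas_molar_rate()]) is absorbed, the
#' dissolved-gas pools relax, and the conductance of every channel is
#' recorded.  The film update uses the exact exponential solution within a
#' step, and gas delivery is linear in the step, so the integration is
#' accurate for piecewise-constant protocols at ordinary sample rates.
#'
#' With `noise = NULL` the simulation is fully deterministic.  Given a
#' [noise_params()] object and a seed, identical (sensors, protocol, seed)
#' always produce identical recordings, and the seed is stored in the
#' recording metadata.
#'
#' @param sensors A list of [make_sensor()] states (>= 1).  All sensors must
#'   share the same [physics_params()].
#' @param protocol A `pegs_protocol`.
#' @param sample_rate Sampling rate in Hz (default 10; one integration step
#'   per sample).
#' @param noise A [noise_params()] object, or `NULL` for a noise-free run.
#' @param seed Integer seed for the noise draws (ignored when `noise` is
#'   `NULL`); the caller's RNG state is left untouched.
#' @return An object of class `pegs_recording`: a list with `time` (s),
#'   `traces` (matrix, one column per channel, siemens), `channels` (data
#'   frame with `id`, `functionalization`, `molarity`), `sample_rate`, `meta`
#'   (protocol description, seed) and `final_states` (the sensor states at
#'   the end of the run).
#' @examples
#' arr <- list(make_sensor("A", 0.01), make_sensor("U"))
#' rec <- run_simulation(arr, chamber_protocol("NH3", 5, 2, recovery_min = 1))
#' dim(rec$traces)
#' @export
run_simulation <- function(sensors, protocol, sample_rate = 10,
                           noise = NULL, seed = NULL) {
  stop_if_not(is.list(sensors) && length(sensors) >= 1 &&
                all(vapply(sensors, inherits, logical(1), "pegs_sensor")),
              "sensors must be a non-empty list of pegs_sensor objects")
  stop_if_not(inherits(protocol, "pegs_protocol"), "protocol must be a pegs_protocol")
  stop_if_not(is.numeric(sample_rate) && sample_rate > 0,
              "sample_rate must be > 0")
  if (!is.null(noise)) stop_if_not(inherits(noise, "pegs_noise"),
                                   "noise must be a pegs_noise object or NULL")
  p <- sensors[[1]]$params
  same <- vapply(sensors, function(s) identical(s$params, p), logical(1))
  stop_if_not(all(same), "all sensors must share the same physics_params")

  dt <- 1 / sample_rate
  sched <- protocol_schedule(protocol, dt)
  nt <- nrow(sched)
  nc <- length(sensors)

  # unpack array state into per-channel vectors
  getm <- function(sp) vapply(sensors, function(s) s$ion_moles[[sp]], numeric(1))
  h3o <- getm("H3O+"); nh4 <- getm("NH4+"); oh <- getm("OH-")
  na_ <- getm("Na+"); hco3 <- getm("HCO3-"); so4 <- getm("SO4^2-")
  wf  <- vapply(sensors, `[[`, numeric(1), "water_film")
  vol <- vapply(sensors, `[[`, numeric(1), "deposit_volume")
  nh3_pool <- vapply(sensors, `[[`, numeric(1), "nh3_pool")
  co2_pool <- vapply(sensors, `[[`, numeric(1), "co2_pool")
  co2_pairs <- vapply(sensors, `[[`, numeric(1), "co2_pairs")

  ea <- exp(-dt / p$tau_adsorb); ed <- exp(-dt / p$tau_desorb)
  e_react <- 1 - exp(-dt / p$tau_co2_react)
  e_out <- exp(-dt / p$tau_co2_outgas)
  wbf <- p$weak_base_fraction; fr <- p$co2_react_fraction
  mu <- .ION_MOBILITY

  weq_all <- water_film_equilibrium(sched$rh, p)
  # gas_molar_rate is linear in conc and flow; scale its unit rate
  nh3_dose <- gas_molar_rate(1, 1, p, "NH3") * sched$nh3 * sched$flow * dt
  co2_dose <- gas_molar_rate(1, 1, p, "CO2") * (sched$co2 * 1e4) * sched$flow * dt

  traces <- matrix(NA_real_, nt, nc)
  for (i in seq_len(nt)) {
    weq <- weq_all[i]
    up <- weq > wf
    wf <- weq + (wf - weq) * ifelse(up, ea, ed)

    dn <- nh3_dose[i]
    if (dn > 0) {
      take <- pmin(dn, h3o)
      h3o <- h3o - take
      nh4 <- nh4 + take
      rem <- dn - take
      nh4 <- nh4 + wbf * rem
      oh  <- oh + wbf * rem
      nh3_pool <- nh3_pool + (1 - wbf) * rem
    }

    dc <- co2_dose[i]
    if (dc > 0) {
      immediate <- fr * dc
      take <- pmin(immediate, oh)
      oh <- oh - take
      hco3 <- hco3 + take
      left <- immediate - take
      if (any(left > 0)) {
        ph <- rep(7, nc)
        c_h <- pmax(h3o - co2_pairs, 0) / vol; c_oh <- oh / vol
        acid <- c_h > c_oh & c_h > 1e-7
        base <- c_oh > c_h & c_oh > 1e-7
        ph[acid] <- -log10(c_h[acid])
        ph[base] <- 14 + log10(c_oh[base])
        y <- co2_solubility_scale(ph, p)
        h3o <- h3o + y * left
        hco3 <- hco3 + y * left
        co2_pairs <- co2_pairs + y * left
        co2_pool <- co2_pool + (1 - y) * left
      }
      co2_pool <- co2_pool + (1 - fr) * dc
    }

    if (any(co2_pool > 0) || any(co2_pairs > 0)) {
      react <- pmin(co2_pool * e_react, oh)
      oh <- oh - react
      hco3 <- hco3 + react
      co2_pool <- (co2_pool - react) * e_out
      revert <- pmin(co2_pairs * (1 - e_out), h3o, hco3)
      h3o <- h3o - revert
      hco3 <- hco3 - revert
      co2_pairs <- co2_pairs - revert
    }

    ionic <- (mu[["H3O+"]] * h3o + mu[["NH4+"]] * nh4 + mu[["OH-"]] * oh +
                mu[["Na+"]] * na_ + mu[["HCO3-"]] * hco3 +
                2 * mu[["SO4^2-"]] * so4) / vol
    traces[i, ] <- p$background_leak +
      p$cell_factor * wf * (p$paper_ion_product + ionic)
  }

  time <- seq_len(nt) * dt

  if (!is.null(noise)) {
    traces <- with_seed(seed, {
      g0 <- traces[1, ]
      sdlog <- sqrt(log(1 + noise$baseline_cv^2))
      mult <- stats::rlnorm(nc, -sdlog^2 / 2, sdlog)
      total <- time[nt]
      # slow bounded wander: at most a quarter sine cycle per recording
      amp_c <- stats::runif(1, 0, noise$drift_frac / 2)
      ph_c <- stats::runif(1)
      drift_c <- amp_c * (sin(2 * pi * (time / (4 * total) + ph_c)) -
                            sin(2 * pi * ph_c))
      amp_i <- stats::runif(nc, 0, noise$drift_channel_frac)
      ph_i <- stats::runif(nc)
      osc_ph <- stats::runif(nc)
      rel <- matrix(0, nt, nc)
      for (j in seq_len(nc)) {
        rel[, j] <- drift_c +
          amp_i[j] * (sin(2 * pi * (time / (4 * total) + ph_i[j])) -
                        sin(2 * pi * ph_i[j]))
        if (noise$osc_frac > 0) {
          rel[, j] <- rel[, j] +
            noise$osc_frac * sin(2 * pi * (time / 12 + osc_ph[j]))
        }
      }
      white <- matrix(stats::rnorm(nt * nc), nt, nc)
      noisy <- sweep(traces * (1 + rel), 2, mult, `*`) +
        sweep(white, 2, noise$white_frac * mult * g0, `*`)
      pmax(noisy, .Machine$double.xmin)
    })
  }

  final <- sensors
  for (j in seq_len(nc)) {
    final[[j]]$ion_moles <- c("H3O+" = h3o[j], "NH4+" = nh4[j], "OH-" = oh[j],
                              "Na+" = na_[j], "HCO3-" = hco3[j],
                              "SO4^2-" = so4[j])
    final[[j]]$water_film <- wf[j]
    final[[j]]$nh3_pool <- nh3_pool[j]
    final[[j]]$co2_pool <- co2_pool[j]
    final[[j]]$co2_pairs <- co2_pairs[j]
  }

  ids <- vapply(seq_len(nc), function(j) {
    id <- sensors[[j]]$id
    if (is.null(id) || id %in% c("U", "A", "B"))
      sprintf("ch%d_%s", j, sensors[[j]]$functionalization) else id
  }, character(1))
  channels <- data.frame(
    id = ids,
    functionalization = vapply(sensors, `[[`, character(1), "functionalization"),
    molarity = vapply(sensors, `[[`, numeric(1), "deposit_molarity"),
    stringsAsFactors = FALSE
  )
  colnames(traces) <- ids

  rec <- list(
    time = time,
    traces = traces,
    channels = channels,
    sample_rate = sample_rate,
    meta = list(protocol = protocol$description,
                seed = if (is.null(noise)) NA_integer_ else
                  (if (is.null(seed)) NA_integer_ else as.integer(seed)),
                noise = !is.null(noise)),
    final_states = final
  )
  class(rec) <- "pegs_recording"
  rec
}

#' @export
print.pegs_recording <- function(x, ...) {
  cat(sprintf("<pegs_recording> %s\n", x$meta$protocol))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f min)%s\n",
              ncol(x$traces), nrow(x$traces), x$sample_rate,
              max(x$time) / 60,
              if (isTRUE(x$meta$noise)) sprintf(", noise seed %s", x$meta$seed)
              else ", noise-free"))
  print(x$channels, row.names = FALSE)
  invisible(x)
}
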