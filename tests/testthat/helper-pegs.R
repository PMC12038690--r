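# Shared fixtures: sensor arrays, short protocols, and an independent
# dense-grid explicit-Euler integrator used as the physics oracle.

make_array <- function(params = physics_params(), a_molarity = 0.01,
                       n_a = 3, n_u = 3, ambient_rh = params$ambient_rh) {
  c(
    lapply(seq_len(n_a), function(i)
      make_sensor("A", a_molarity, params = params, ambient_rh = ambient_rh,
                  id = sprintf("A%d", i))),
    lapply(seq_len(n_u), function(i)
      make_sensor("U", params = params, ambient_rh = ambient_rh,
                  id = sprintf("U%d", i)))
  )
}

# Independent physics oracle: plain forward-Euler integration of the same
# chemistry at a fine step, written from the model equations rather than the
# package's exact-exponential stepper.  Returns conductance sampled on the
# coarse grid (every `record_every` fine steps).
euler_oracle <- function(sensors, protocol, dt = 0.001, record_dt = 0.1) {
  p <- sensors[[1]]$params
  segs <- protocol$segments[rep(seq_len(nrow(protocol$segments)),
                                protocol$repeat_count), , drop = FALSE]
  ends <- cumsum(segs$duration)
  total <- ends[length(ends)]
  nfine <- floor(total / dt + 1e-9)
  every <- round(record_dt / dt)
  mu <- c(h = 36.23e-4, n = 7.63e-4, o = 20.5e-4, na = 5.19e-4,
          b = 4.61e-4, s = 8.29e-4)
  out <- list()
  for (si in seq_along(sensors)) {
    s0 <- sensors[[si]]
    h <- s0$ion_moles[["H3O+"]]; nh <- s0$ion_moles[["NH4+"]]
    oh <- s0$ion_moles[["OH-"]]; na <- s0$ion_moles[["Na+"]]
    hc <- s0$ion_moles[["HCO3-"]]; so <- s0$ion_moles[["SO4^2-"]]
    w <- s0$water_film; vol <- s0$deposit_volume
    pool <- 0; pairs <- 0
    g <- numeric(floor(nfine / every))
    k <- 0
    seg_i <- 1
    for (i in seq_len(nfine)) {
      t0 <- (i - 1) * dt
      while (t0 >= ends[seg_i]) seg_i <- seg_i + 1
      rh <- segs$rh[seg_i]
      weq <- 1 / (1 + exp(-(rh - p$weq_center) / p$weq_scale))
      tau <- if (weq > w) p$tau_adsorb else p$tau_desorb
      w <- w + (weq - w) * dt / tau
      dn <- p$capture_efficiency * (segs$flow[seg_i] / 1000 / 60) *
        (segs$nh3[seg_i] * 1e-6) / p$molar_volume * dt
      if (dn > 0) {
        take <- min(dn, h)
        h <- h - take; nh <- nh + take
        rem <- dn - take
        nh <- nh + p$weak_base_fraction * rem
        oh <- oh + p$weak_base_fraction * rem
      }
      dc <- p$capture_efficiency_co2 * (segs$flow[seg_i] / 1000 / 60) *
        (segs$co2[seg_i] * 1e4 * 1e-6) / p$molar_volume * dt
      if (dc > 0) {
        imm <- p$co2_react_fraction * dc
        take <- min(imm, oh)
        oh <- oh - take; hc <- hc + take
        left <- imm - take
        if (left > 0) {
          ch <- max(h - pairs, 0) / vol; coh <- oh / vol
          ph <- if (ch > coh && ch > 1e-7) -log10(ch) else
            if (coh > ch && coh > 1e-7) 14 + log10(coh) else 7
          y <- 1 / (1 + 10^(p$co2_ph_mid - ph))
          h <- h + y * left; hc <- hc + y * left
          pairs <- pairs + y * left
          pool <- pool + (1 - y) * left
        }
        pool <- pool + (1 - p$co2_react_fraction) * dc
      }
      if (pool > 0 && oh > 0) {
        react <- min(pool * dt / p$tau_co2_react, oh)
        oh <- oh - react; hc <- hc + react; pool <- pool - react
      }
      pool <- pool - pool * dt / p$tau_co2_outgas
      if (pairs > 0) {
        rv <- min(pairs * dt / p$tau_co2_outgas, h, hc)
        h <- h - rv; hc <- hc - rv; pairs <- pairs - rv
      }
      if (i %% every == 0) {
        k <- k + 1
        ionic <- (mu[["h"]] * h + mu[["n"]] * nh + mu[["o"]] * oh +
                    mu[["na"]] * na + mu[["b"]] * hc + 2 * mu[["s"]] * so) / vol
        g[k] <- p$background_leak +
          p$cell_factor * w * (p$paper_ion_product + ionic)
      }
    }
    out[[si]] <- g
  }
  out
}

expect_electroneutral <- function(state, tol = 1e-18) {
  expect_lt(abs(net_charge(state$ion_moles)), tol)
}
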