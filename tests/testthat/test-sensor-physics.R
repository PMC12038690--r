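test_that("functionalization stoichiometry and validation", {
  a <- make_sensor("A", 0.01, 10e-6)
  expect_equal(a$ion_moles[["H3O+"]], 2e-7)
  expect_equal(a$ion_moles[["SO4^2-"]], 1e-7)
  expect_electroneutral(a)

  b <- make_sensor("B", 0.1, 10e-6)
  expect_equal(b$ion_moles[["Na+"]], 1e-6)
  expect_equal(b$ion_moles[["OH-"]], 1e-6)
  expect_electroneutral(b)

  u <- make_sensor("U")
  expect_true(all(u$ion_moles == 0))
  expect_equal(conductance(u), background_conductance(u))
  expect_equal(u$water_film, water_film_equilibrium(45))

  expect_error(make_sensor("A", -0.01), class = "pegs_invalid_parameter")
  expect_error(make_sensor("A", 0.2), class = "pegs_invalid_parameter")
  expect_error(make_sensor("A", 0.01, volume = -1),
               class = "pegs_invalid_parameter")
  expect_error(make_sensor("X", 0.01), class = "pegs_invalid_parameter")
  expect_error(make_sensor("U", 0.01), class = "pegs_invalid_parameter")
})

test_that("conductance is the mobility-weighted ion sum", {
  a <- make_sensor("A", 0.01)
  # doubling every ion amount doubles the ionic part
  a2 <- a
  a2$ion_moles <- 2 * a$ion_moles
  bg <- background_conductance(a)
  expect_equal(conductance(a2) - bg, 2 * (conductance(a) - bg))

  # monotone in water film and in every ion amount
  wetter <- a
  wetter$water_film <- a$water_film * 1.1
  expect_gt(conductance(wetter), conductance(a))
  richer <- a
  richer$ion_moles[["Na+"]] <- 1e-8
  expect_gt(conductance(richer), conductance(a))

  # registry invariants
  reg <- ion_registry()
  expect_setequal(reg$species,
                  c("H3O+", "NH4+", "OH-", "Na+", "HCO3-", "SO4^2-"))
  expect_equal(reg$mobility[reg$species == "H3O+"], 36.23e-4)
  expect_equal(reg$mobility[reg$species == "NH4+"], 7.63e-4)
})

test_that("swapping hydronium for ammonium scales the cation term by the mobility ratio", {
  a <- make_sensor("A", 0.01)
  bg <- background_conductance(a)
  anion_only <- a
  anion_only$ion_moles[["H3O+"]] <- 0
  g_anion <- conductance(anion_only) - bg

  cation_h <- conductance(a) - bg - g_anion
  swapped <- a
  swapped$ion_moles[["H3O+"]] <- 0
  swapped$ion_moles[["NH4+"]] <- 2e-7
  cation_n <- conductance(swapped) - bg - g_anion
  expect_equal(cation_n / cation_h, 7.63 / 36.23, tolerance = 1e-12)
})

test_that("water film relaxes to equilibrium with slower desorption", {
  p <- physics_params()
  s <- make_sensor("U", params = p)
  # fixed point under constant humidity
  for (i in 1:400) s <- update_water_film(s, 80, 10)
  expect_equal(s$water_film, water_film_equilibrium(80, p), tolerance = 1e-6)

  # equal up/down steps leave a net film gain (desorption is slower)
  s0 <- make_sensor("U", params = p)
  up <- update_water_film(s0, 90, 8)
  updown <- update_water_film(up, 45, 8)
  expect_gt(updown$water_film, s0$water_film)

  expect_error(update_water_film(s0, 101, 1), class = "pegs_invalid_parameter")
  expect_error(update_water_film(s0, -1, 1), class = "pegs_invalid_parameter")
  expect_error(update_water_film(s0, 50, 0), class = "pegs_invalid_parameter")
})

test_that("8 s / 4 s humidity cycling reaches its stationary film in 7-8 minutes", {
  # independent fine-step integrator (dt = 10 ms)
  p <- physics_params()
  w <- water_film_equilibrium(45, p)
  dt <- 0.01
  cyc_means <- numeric(150)
  for (cyc in 1:150) {
    acc <- 0
    for (i in 1:1200) {
      rh <- if (i <= 800) 90 else 50
      weq <- water_film_equilibrium(rh, p)
      tau <- if (weq > w) p$tau_adsorb else p$tau_desorb
      w <- w + (weq - w) * dt / tau
      acc <- acc + w
    }
    cyc_means[cyc] <- acc / 1200
  }
  w_inf <- cyc_means[150]
  w0 <- cyc_means[1]
  t95 <- 12 * which(abs(cyc_means - w_inf) <= 0.05 * abs(w_inf - w0))[1] / 60
  expect_gte(t95, 7)
  expect_lte(t95, 8)
  # the cycle-averaged film rises monotonically
  expect_true(all(diff(cyc_means[1:100]) > 0))
})

test_that("ammonia uptake depletes acid stoichiometrically and conserves mass", {
  a <- make_sensor("A", 0.01)
  done <- absorb_nh3(a, 2e-7)
  expect_equal(done$ion_moles[["H3O+"]], 0)
  expect_equal(done$ion_moles[["NH4+"]], 2e-7)
  expect_equal(done$ion_moles[["SO4^2-"]], 1e-7)
  expect_electroneutral(done)

  expect_identical(absorb_nh3(a, 0), a)
  expect_error(absorb_nh3(a, -1e-9), class = "pegs_invalid_parameter")

  # untreated sensors respond to NH3 with a strict conductance rise
  u <- make_sensor("U")
  u2 <- absorb_nh3(u, 1e-9)
  expect_gt(conductance(u2), conductance(u))

  # property: electroneutrality and nitrogen conservation along a random
  # dosing sequence crossing the depletion point
  set.seed(7)
  s <- make_sensor("A", 0.005)
  delivered <- 0
  for (i in 1:50) {
    d <- runif(1, 0, 8e-9)
    s <- absorb_nh3(s, d)
    delivered <- delivered + d
    expect_electroneutral(s)
  }
  n_accounted <- s$ion_moles[["NH4+"]] + s$nh3_pool
  expect_equal(n_accounted, delivered, tolerance = 1e-12)
})

test_that("CO2 chemistry: hydroxide consumption, pH-limited dissolution, reversibility", {
  b <- make_sensor("B", 0.01)
  g0 <- conductance(b)
  b1 <- absorb_co2(b, 1e-8)
  expect_lt(conductance(b1), g0)    # OH- replaced by slower HCO3-
  expect_electroneutral(b1)

  # same dose produces a smaller conductance change on an acidified film
  u <- make_sensor("U")
  ua <- absorb_nh3(make_sensor("A", 0.01), 0)   # acidified
  du_neutral <- abs(conductance(absorb_co2(u, 5e-9)) - conductance(u))
  da_acid <- abs(conductance(absorb_co2(ua, 5e-9)) - conductance(ua))
  expect_lt(da_acid, du_neutral)

  expect_error(absorb_co2(u, -1), class = "pegs_invalid_parameter")

  # desorb: no-op without a pool, strict pool decay afterwards
  expect_equal(desorb_dissolved_gas(u, 1)$ion_moles, u$ion_moles)
  ud <- absorb_co2(u, 5e-9)
  pool0 <- ud$co2_pool
  expect_gt(pool0, 0)
  ud2 <- desorb_dissolved_gas(ud, 5)
  expect_lt(ud2$co2_pool, pool0)
  # ion pairs revert toward baseline as the gas leaves
  for (i in 1:400) ud <- desorb_dissolved_gas(ud, 5)
  expect_equal(conductance(ud), conductance(u), tolerance = 1e-6)
  expect_electroneutral(ud)
})

test_that("gas delivery rate follows the flow/concentration arithmetic", {
  p1 <- physics_params(capture_efficiency = 1)
  expect_equal(gas_molar_rate(5, 2000, p1), 6.8166e-9, tolerance = 1e-4)
  expect_equal(gas_molar_rate(0, 2000, p1), 0)
  # linear in concentration
  expect_equal(gas_molar_rate(4, 2000, p1), 2 * gas_molar_rate(2, 2000, p1))
  expect_error(gas_molar_rate(-1, 2000, p1), class = "pegs_invalid_parameter")
  expect_error(gas_molar_rate(1, 0, p1), class = "pegs_invalid_parameter")
})

test_that("impedance stays in the kilo-ohm to giga-ohm operating span across humidity", {
  p <- physics_params()
  for (rh in c(20, 45, 65, 90, 100)) {
    for (s in list(make_sensor("U", params = p, ambient_rh = rh),
                   make_sensor("A", 0.1, params = p, ambient_rh = rh),
                   make_sensor("B", 0.1, params = p, ambient_rh = rh))) {
      z <- 1 / conductance(s)
      expect_gte(z, 1e3)
      expect_lte(z, 1e9)
    }
  }
})
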