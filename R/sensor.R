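#' Construct a PEGS sensor state
#'
#' A sensor is a wax-confined region of chromatography paper carrying
#' screen-printed electrodes, functionalized with a 10 uL deposit of either
#' deionized water (untreated, `"U"`), sulfuric acid (`"A"`) or sodium
#' hydroxide (`"B"`).  The state tracks the full chemical inventory of the
#' water film (moles of each ionic species, dissolved neutral NH3 and CO2
#' pools), the humidity-driven water-film level and the constants needed to
#' turn all of that into a conductance.
#'
#' Functionalization stoichiometry: each mole of H2SO4 contributes two
#' hydronium and one sulfate ion; each mole of NaOH one sodium and one
#' hydroxide ion; the untreated sensor starts with an empty inventory.
#'
#' @param functionalization One of `"U"`, `"A"`, `"B"`.
#' @param molarity Deposit molarity in mol/L, in \[0, 0.1\] (0 for `"U"`).
#' @param volume Deposit volume in liters (default 10e-6, i.e. 10 uL).
#' @param params A [physics_params()] object.
#' @param ambient_rh Relative humidity (%) the sensor has equilibrated at
#'   before the recording starts; the water film is initialized at its
#'   equilibrium value for this RH.  Defaults to `params$ambient_rh`.
#' @param id Optional channel label.
#' @return An object of class `pegs_sensor`.
#' @examples
#' a <- make_sensor("A", 0.01)
#' a$ion_moles[["H3O+"]]   # 2e-7 mol
#' conductance(a)
#' @export
make_sensor <- function(functionalization, molarity = 0, volume = 10e-6,
                        params = physics_params(),
                        ambient_rh = params$ambient_rh,
                        id = NULL) {
  stop_if_not(is.character(functionalization) && length(functionalization) == 1 &&
                functionalization %in% c("U", "A", "B"),
              "functionalization must be one of \"U\", \"A\", \"B\"")
  stop_if_not(is.numeric(molarity) && length(molarity) == 1 && molarity >= 0,
              "molarity must be a non-negative number")
  stop_if_not(molarity <= 0.1, "molarity must be in [0, 0.1] mol/L")
  stop_if_not(is.numeric(volume) && length(volume) == 1 && volume > 0,
              "volume must be a positive number (liters)")
  if (functionalization == "U") {
    stop_if_not(molarity == 0, "untreated sensors must have molarity 0")
  }
  validate_physics_params(params)

  moles <- stats::setNames(numeric(length(.ION_SPECIES)), .ION_SPECIES)
  nv <- molarity * volume
  if (functionalization == "A") {
    moles[["H3O+"]]   <- 2 * nv
    moles[["SO4^2-"]] <- nv
  } else if (functionalization == "B") {
    moles[["Na+"]] <- nv
    moles[["OH-"]] <- nv
  }

  state <- list(
    id = if (is.null(id)) functionalization else id,
    functionalization = functionalization,
    deposit_molarity = molarity,
    deposit_volume = volume,
    ion_moles = moles,
    water_film = water_film_equilibrium(ambient_rh, params),
    nh3_pool = 0,
    co2_pool = 0,
    co2_pairs = 0,
    params = params
  )
  class(state) <- "pegs_sensor"
  state
}

#' @export
print.pegs_sensor <- function(x, ...) {
  cat(sprintf("<pegs_sensor %s> %s-PEGS, %.4g M x %.3g uL\n", x$id,
              x$functionalization, x$deposit_molarity, x$deposit_volume * 1e6))
  nz <- x$ion_moles[x$ion_moles > 0]
  if (length(nz)) {
    cat("  ions (mol): ",
        paste(sprintf("%s %.3g", names(nz), nz), collapse = ", "), "\n")
  } else {
    cat("  ions: none\n")
  }
  cat(sprintf("  water film %.3f, G = %.4g S\n", x$water_film, conductance(x)))
  invisible(x)
}

#' Sensor conductance readout
#'
#' Implements the electrolytic conductance model
#' `G = leak + cell_factor * water_film * (paper_ion_product + sum_i c_i |z_i| mu_i)`
#' where `c_i = ion_moles_i / deposit_volume` is the species concentration in
#' the film.  The background has a dry electronic leak plus an intrinsic
#' cellulose-impurity ion term that scales with the water film (this is what
#' makes untreated paper respond to humidity); the deposited/reacted ion
#' inventory contributes the remaining, chemistry-dependent term.
#'
#' `G` is strictly positive and monotone increasing in every ion amount and
#' in the water film.
#'
#' @param state A `pegs_sensor`.
#' @return Conductance in siemens.
#' @export
conductance <- function(state) {
  p <- state$params
  ionic <- sum(state$ion_moles * abs(.ION_CHARGE) * .ION_MOBILITY) /
    state$deposit_volume
  p$background_leak +
    p$cell_factor * state$water_film * (p$paper_ion_product + ionic)
}

#' Background conductance of a sensor state
#'
#' The conductance the sensor would show with an empty deposited-ion
#' inventory at its current water film: dry leak plus the intrinsic paper
#' ion term.
#'
#' @param state A `pegs_sensor`.
#' @return Conductance in siemens.
#' @export
background_conductance <- function(state) {
  p <- state$params
  p$background_leak + p$cell_factor * state$water_film * p$paper_ion_product
}

#' Update the water film toward its humidity equilibrium
#'
#' First-order relaxation of the film level toward `W_eq(rh)`, using the
#' adsorption time constant when the film is rising and the (longer)
#' desorption constant when it is falling: moisture leaves paper more slowly
#' than it is taken up.  The update is the exact exponential solution for a
#' constant-RH interval, so step size only matters where RH changes.
#'
#' @param state A `pegs_sensor`.
#' @param rh Relative humidity in percent, in \[0, 100\].
#' @param dt Time step in seconds (> 0).
#' @return The updated `pegs_sensor`.
#' @export
update_water_film <- function(state, rh, dt) {
  stop_if_not(is.numeric(rh) && length(rh) == 1 && rh >= 0 && rh <= 100,
              "rh must be in [0, 100]")
  stop_if_not(is.numeric(dt) && length(dt) == 1 && dt > 0, "dt must be > 0")
  p <- state$params
  weq <- water_film_equilibrium(rh, p)
  tau <- if (weq > state$water_film) p$tau_adsorb else p$tau_desorb
  state$water_film <- weq + (state$water_film - weq) * exp(-dt / tau)
  state
}

#' Absorb gaseous ammonia into the sensor film
#'
#' While hydronium remains, each mole of NH3 performs the neutralization
#' `NH3 + H3O+ -> NH4+ + H2O`: a high-mobility hydronium ion is replaced by a
#' low-mobility ammonium ion (net two NH3 per H2SO4), so the conductance of
#' an acid sensor falls.  Once the acid is exhausted, a small fraction
#' `weak_base_fraction` of further NH3 ionizes as `NH3 + H2O -> NH4+ + OH-`
#' (so untreated sensors respond with a conductance rise); the rest stays in
#' the dissolved neutral NH3 pool.  Electroneutrality and nitrogen mass are
#' conserved exactly.
#'
#' @param state A `pegs_sensor`.
#' @param mol_nh3 Moles of NH3 delivered (>= 0).
#' @return The updated `pegs_sensor`.
#' @export
absorb_nh3 <- function(state, mol_nh3) {
  stop_if_not(is.numeric(mol_nh3) && length(mol_nh3) == 1 && mol_nh3 >= 0,
              "mol_nh3 must be a non-negative number")
  if (mol_nh3 == 0) return(state)
  m <- state$ion_moles
  take <- min(mol_nh3, m[["H3O+"]])
  m[["H3O+"]] <- m[["H3O+"]] - take
  m[["NH4+"]] <- m[["NH4+"]] + take
  rem <- mol_nh3 - take
  if (rem > 0) {
    f <- state$params$weak_base_fraction
    m[["NH4+"]] <- m[["NH4+"]] + f * rem
    m[["OH-"]]  <- m[["OH-"]]  + f * rem
    state$nh3_pool <- state$nh3_pool + (1 - f) * rem
  }
  state$ion_moles <- m
  state
}

# Film pH governing CO2 dissolution, from the strong-ion inventory
# (concentrations in mol/L).  Hydronium contributed by dissolved CO2 itself
# is excluded: the carbonic-acid system buffers its own ionization, and what
# suppresses CO2 solubility is added strong acid.
film_ph <- function(state) {
  c_h  <- max(state$ion_moles[["H3O+"]] - state$co2_pairs, 0) /
    state$deposit_volume
  c_oh <- state$ion_moles[["OH-"]] / state$deposit_volume
  if (c_h > c_oh && c_h > 1e-7) return(-log10(c_h))
  if (c_oh > c_h && c_oh > 1e-7) return(14 + log10(c_oh))
  7
}

#' Absorb gaseous carbon dioxide into the sensor film
#'
#' A fraction `co2_react_fraction` of the delivered CO2 acts immediately:
#' while hydroxide remains it is consumed one-for-one
#' (`CO2 + OH- -> HCO3-`), replacing a high-mobility with a low-mobility
#' anion, which is why base sensors show a conductance drop under CO2.  Any
#' immediate CO2 beyond the available hydroxide dissolves and ionizes
#' (`CO2 + 2 H2O -> H3O+ + HCO3-`) with a yield scaled by
#' [co2_solubility_scale()] at the current film pH, so acidified films are
#' much less CO2-sensitive.  The remainder of the dose joins a physically
#' dissolved CO2 pool that later reacts or outgasses
#' ([desorb_dissolved_gas()]), which is what makes the response reversible.
#'
#' @param state A `pegs_sensor`.
#' @param mol_co2 Moles of CO2 delivered (>= 0).
#' @return The updated `pegs_sensor`.
#' @export
absorb_co2 <- function(state, mol_co2) {
  stop_if_not(is.numeric(mol_co2) && length(mol_co2) == 1 && mol_co2 >= 0,
              "mol_co2 must be a non-negative number")
  if (mol_co2 == 0) return(state)
  p <- state$params
  m <- state$ion_moles
  immediate <- p$co2_react_fraction * mol_co2
  take <- min(immediate, m[["OH-"]])
  m[["OH-"]]   <- m[["OH-"]] - take
  m[["HCO3-"]] <- m[["HCO3-"]] + take
  left <- immediate - take
  if (left > 0) {
    y <- co2_solubility_scale(film_ph(state), p)
    m[["H3O+"]]  <- m[["H3O+"]] + y * left
    m[["HCO3-"]] <- m[["HCO3-"]] + y * left
    state$co2_pairs <- state$co2_pairs + y * left
    state$co2_pool  <- state$co2_pool + (1 - y) * left
  }
  state$co2_pool <- state$co2_pool + (1 - p$co2_react_fraction) * mol_co2
  state$ion_moles <- m
  state
}

#' Relax dissolved gas pools (outgassing and delayed reaction)
#'
#' Two first-order processes act on the dissolved CO2 inventory:
#' the neutral pool reacts with any remaining hydroxide (time constant
#' `tau_co2_react`), continuing the `CO2 + OH- -> HCO3-` conversion even
#' after the gas supply stops (this produces the second conductance drop
#' seen on strongly base-treated sensors after exposure ends), and both the
#' neutral pool and the dissolution-derived H3O+/HCO3- ion pairs decay
#' toward the ambient (zero) level with time constant `tau_co2_outgas`,
#' returning untreated sensors toward their baseline.
#'
#' @param state A `pegs_sensor`.
#' @param dt Time step in seconds (> 0).
#' @return The updated `pegs_sensor`.
#' @export
desorb_dissolved_gas <- function(state, dt) {
  stop_if_not(is.numeric(dt) && length(dt) == 1 && dt > 0, "dt must be > 0")
  p <- state$params
  m <- state$ion_moles
  if (state$co2_pool > 0 && m[["OH-"]] > 0) {
    react <- min(state$co2_pool * (1 - exp(-dt / p$tau_co2_react)), m[["OH-"]])
    m[["OH-"]]   <- m[["OH-"]] - react
    m[["HCO3-"]] <- m[["HCO3-"]] + react
    state$co2_pool <- state$co2_pool - react
  }
  if (state$co2_pool > 0) {
    state$co2_pool <- state$co2_pool * exp(-dt / p$tau_co2_outgas)
  }
  if (state$co2_pairs > 0) {
    revert <- min(state$co2_pairs * (1 - exp(-dt / p$tau_co2_outgas)),
                  m[["H3O+"]], m[["HCO3-"]])
    m[["H3O+"]]  <- m[["H3O+"]] - revert
    m[["HCO3-"]] <- m[["HCO3-"]] - revert
    state$co2_pairs <- state$co2_pairs - revert
  }
  state$ion_moles <- m
  state
}

#' Molar delivery rate of a gas to the sensor
#'
#' Converts a protocol gas level into an uptake flux:
#' `rate = efficiency * (flow[L/min] / 60) * (ppm * 1e-6) / molar_volume`.
#'
#' @param conc_ppm Gas concentration in ppm (v/v), >= 0.
#' @param flow_mL_min Carrier flow in mL/min, > 0.
#' @param params A [physics_params()] object.
#' @param gas `"NH3"` (default) or `"CO2"`; selects the capture efficiency.
#' @return Molar uptake rate in mol/s.
#' @examples
#' gas_molar_rate(5, 2000, physics_params(capture_efficiency = 1))
#' # 6.82e-9 mol/s
#' @export
gas_molar_rate <- function(conc_ppm, flow_mL_min, params = physics_params(),
                           gas = c("NH3", "CO2")) {
  gas <- match.arg(gas)
  stop_if_not(is.numeric(conc_ppm) && length(conc_ppm) == 1 && conc_ppm >= 0,
              "conc_ppm must be a non-negative number")
  stop_if_not(is.numeric(flow_mL_min) && length(flow_mL_min) == 1 && flow_mL_min > 0,
              "flow_mL_min must be a positive number")
  eff <- if (gas == "NH3") params$capture_efficiency else params$capture_efficiency_co2
  eff * (flow_mL_min / 1000 / 60) * (conc_ppm * 1e-6) / params$molar_volume
}
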