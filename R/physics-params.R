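#' Physics parameters for the PEGS model
#'
#' Bundles every tunable constant of the mechanistic sensor model.  Defaults
#' are calibrated once against the qualitative and quantitative behaviour of
#' the physical device (see the methods vignette) and all can be overridden
#' here or through the `physics:` section of a YAML config ([load_config()]).
#'
#' @param capture_efficiency Fraction of the NH3 molar flow passing the
#'   sensor that is absorbed into its water film (dimensionless, default
#'   0.05; chosen so 5 ppm NH3 at 2000 mL/min depletes a 0.01 M acid sensor
#'   in roughly ten minutes).
#' @param capture_efficiency_co2 As above for CO2 (default 3e-5).  CO2 is
#'   orders of magnitude less soluble in water than NH3, so its effective
#'   uptake is far smaller; calibrated to the observed base-sensor
#'   neutralization times at 5% CO2.
#' @param tau_adsorb Water-film adsorption time constant, s (default 115).
#' @param tau_desorb Water-film desorption time constant, s (default 345).
#'   Desorption of moisture from paper is thermodynamically less favorable
#'   than adsorption, so `tau_desorb > tau_adsorb`; the pair is calibrated so
#'   that 8 s / 4 s humidity cycling reaches its stationary film level in
#'   7-8 minutes.
#' @param weak_base_fraction Ionization fraction for NH3 dissolved after the
#'   acid reservoir is exhausted (default 0.005).  NH3 is a weak base and its
#'   ionization is further suppressed by the ammonium already in the film.
#' @param co2_react_fraction Fraction of absorbed CO2 that reacts or ionizes
#'   immediately; the remainder enters a physically dissolved pool that
#'   reacts or outgasses later (default 0.5).
#' @param tau_co2_outgas First-order time constant for outgassing of the
#'   dissolved CO2 pool and relaxation of dissolution-derived ion pairs, s
#'   (default 60).
#' @param tau_co2_react First-order time constant for the reaction of the
#'   dissolved CO2 pool with remaining hydroxide, s (default 120).
#' @param molar_volume Molar volume of an ideal gas at operating conditions,
#'   L/mol (default 24.45; 25 C, 1 atm).
#' @param cell_factor Geometry factor converting film-weighted ionic strength
#'   (mol/L x cm^2 V^-1 s^-1) to siemens (default 0.02).
#' @param background_leak Dry-paper electronic leak conductance, S (default
#'   1e-9; ~GOhm impedance of dry paper).
#' @param paper_ion_product Intrinsic cellulose-impurity ion content of the
#'   paper, expressed as a concentration-mobility product (mol/L x
#'   cm^2 V^-1 s^-1, default 3e-4).  Gives untreated sensors their humidity
#'   response.
#' @param ambient_rh Ambient relative humidity used to initialize the water
#'   film, % (default 45).
#' @param weq_center,weq_scale Center (% RH) and scale (% RH) of the logistic
#'   equilibrium water-film map `W_eq(rh) = plogis((rh - center)/scale)`
#'   (defaults 55 and 12: near zero below 20% RH, near saturation above 90%).
#' @param co2_ph_mid,co2_ph_width Midpoint and width of the logistic pH map
#'   scaling the CO2 dissolution yield (defaults 5 and 1): acidified films
#'   dissolve much less CO2.
#'
#' @return An object of class `pegs_physics`: a validated named list of the
#'   above parameters.
#' @examples
#' physics_params()
#' physics_params(capture_efficiency = 0.02)
#' @export
physics_params <- function(capture_efficiency = 0.05,
                           capture_efficiency_co2 = 3e-5,
                           tau_adsorb = 115,
                           tau_desorb = 345,
                           weak_base_fraction = 0.005,
                           co2_react_fraction = 0.5,
                           tau_co2_outgas = 60,
                           tau_co2_react = 120,
                           molar_volume = 24.45,
                           cell_factor = 0.02,
                           background_leak = 1e-9,
                           paper_ion_product = 3e-4,
                           ambient_rh = 45,
                           weq_center = 55,
                           weq_scale = 12,
                           co2_ph_mid = 5,
                           co2_ph_width = 1) {
  p <- list(
    capture_efficiency = capture_efficiency,
    capture_efficiency_co2 = capture_efficiency_co2,
    tau_adsorb = tau_adsorb,
    tau_desorb = tau_desorb,
    weak_base_fraction = weak_base_fraction,
    co2_react_fraction = co2_react_fraction,
    tau_co2_outgas = tau_co2_outgas,
    tau_co2_react = tau_co2_react,
    molar_volume = molar_volume,
    cell_factor = cell_factor,
    background_leak = background_leak,
    paper_ion_product = paper_ion_product,
    ambient_rh = ambient_rh,
    weq_center = weq_center,
    weq_scale = weq_scale,
    co2_ph_mid = co2_ph_mid,
    co2_ph_width = co2_ph_width
  )
  validate_physics_params(p)
  class(p) <- "pegs_physics"
  p
}

validate_physics_params <- function(p) {
  stop_if_not(is.numeric(p$capture_efficiency) &&
                p$capture_efficiency > 0 && p$capture_efficiency <= 1,
              "capture_efficiency must be in (0, 1]")
  stop_if_not(p$capture_efficiency_co2 > 0 && p$capture_efficiency_co2 <= 1,
              "capture_efficiency_co2 must be in (0, 1]")
  stop_if_not(p$tau_adsorb > 0 && p$tau_desorb > p$tau_adsorb,
              "need tau_desorb > tau_adsorb > 0 (moisture desorption is slower than adsorption)")
  stop_if_not(p$weak_base_fraction >= 0 && p$weak_base_fraction <= 1,
              "weak_base_fraction must be in [0, 1]")
  stop_if_not(p$co2_react_fraction >= 0 && p$co2_react_fraction <= 1,
              "co2_react_fraction must be in [0, 1]")
  stop_if_not(p$tau_co2_outgas > 0 && p$tau_co2_react > 0,
              "CO2 pool time constants must be positive")
  stop_if_not(p$molar_volume > 0, "molar_volume must be positive")
  stop_if_not(p$cell_factor > 0, "cell_factor must be positive")
  stop_if_not(p$background_leak > 0, "background_leak must be positive")
  stop_if_not(p$paper_ion_product >= 0, "paper_ion_product must be >= 0")
  stop_if_not(p$ambient_rh >= 0 && p$ambient_rh <= 100,
              "ambient_rh must be in [0, 100]")
  stop_if_not(p$weq_scale > 0 && p$co2_ph_width > 0,
              "logistic scales must be positive")
  invisible(p)
}

#' Equilibrium water film at a given relative humidity
#'
#' Monotone logistic map from % RH to the dimensionless film level in (0, 1):
#' near zero below 20% RH (where paper sensing is known to fail) and close to
#' saturation above 90% RH (where adsorbed water behaves like bulk water).
#'
#' @param rh Relative humidity in percent, in \[0, 100\] (vectorized).
#' @param params A [physics_params()] object.
#' @return Equilibrium film level(s) in (0, 1).
#' @export
water_film_equilibrium <- function(rh, params = physics_params()) {
  stop_if_not(all(rh >= 0 & rh <= 100), "rh must be in [0, 100]")
  stats::plogis((rh - params$weq_center) / params$weq_scale)
}

#' CO2 dissolution yield as a function of film pH
#'
#' Monotone logistic map: acidified films (low pH) dissolve and ionize far
#' less CO2 than neutral films, reproducing the reduced CO2 sensitivity of
#' acid-treated sensors.
#'
#' @param ph Film pH (vectorized).
#' @param params A [physics_params()] object.
#' @return Dimensionless yield in (0, 1).
#' @export
co2_solubility_scale <- function(ph, params = physics_params()) {
  stats::plogis((ph - params$co2_ph_mid) / params$co2_ph_width * log(10))
}
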