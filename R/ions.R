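#' Ion species registry
#'
#' Charge and electrical mobility constants for the ionic species that can be
#' present in the water film of a PEGS.  Electrolytic conductivity follows
#' sigma = n_ion x Z_e x mu_ion summed over species, so these constants fully
#' determine the ionic part of the sensor conductance.
#'
#' Mobilities are limiting (infinite-dilution) values in cm^2 V^-1 s^-1 at
#' 25 C.  H3O+ (36.23e-4) and NH4+ (7.63e-4) are the values quoted for the
#' sensing mechanism; OH- (20.5e-4), Na+ (5.19e-4), HCO3- (4.61e-4) and
#' SO4^2- (8.29e-4) are standard literature values (CRC Handbook, limiting
#' ionic conductivities divided by |z|F).
#'
#' @return A data frame with columns `species`, `charge` (signed elementary
#'   charges) and `mobility` (cm^2 V^-1 s^-1), one row per species.
#' @examples
#' ion_registry()
#' @export
ion_registry <- function() {
  reg <- data.frame(
    species  = c("H3O+", "NH4+", "OH-", "Na+", "HCO3-", "SO4^2-"),
    charge   = c(1L, 1L, -1L, 1L, -1L, -2L),
    mobility = c(36.23e-4, 7.63e-4, 20.5e-4, 5.19e-4, 4.61e-4, 8.29e-4),
    stringsAsFactors = FALSE
  )
  stopifnot(all(reg$charge != 0L), all(reg$mobility > 0))
  reg
}

# Internal fast lookups (fixed species order shared with SensorState$ion_moles)
.ION_SPECIES  <- c("H3O+", "NH4+", "OH-", "Na+", "HCO3-", "SO4^2-")
.ION_CHARGE   <- c(1, 1, -1, 1, -1, -2)
.ION_MOBILITY <- c(36.23e-4, 7.63e-4, 20.5e-4, 5.19e-4, 4.61e-4, 8.29e-4)
names(.ION_CHARGE) <- names(.ION_MOBILITY) <- .ION_SPECIES

#' Net charge of an ion inventory
#'
#' Sum of z_i * n_i over species; zero for an electroneutral inventory.
#'
#' @param ion_moles Named numeric vector of moles per species (names from
#'   [ion_registry()]).
#' @return Net charge in mole-equivalents (mol of elementary charge).
#' @export
net_charge <- function(ion_moles) {
  if (length(ion_moles) == 0) return(0)
  sum(.ION_CHARGE[names(ion_moles)] * ion_moles)
}
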