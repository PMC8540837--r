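#' Closed-vessel geometry and incubation context
#'
#' A `bottle_spec` records the geometry and physical conditions of a sealed
#' serum bottle: total volume, liquid volume (0 for soil microcosms, where
#' the peat volume is treated as negligible), incubation temperature and
#' headspace pressure. It anchors every gas mass-balance computation.
#'
#' @param total_mL Total internal volume of the bottle (mL).
#' @param liquid_mL Liquid (medium) volume (mL); default 0 for soil bottles.
#' @param temp_C Incubation temperature (degrees Celsius).
#' @param pressure_atm Headspace pressure (atm); assumed 1 throughout.
#'
#' @return An object of class `bottle_spec` with fields `total_mL`,
#'   `liquid_mL`, `temp_C`, `pressure_atm` and derived `headspace_mL`.
#' @examples
#' bottle_spec(total_mL = 125, liquid_mL = 21.6, temp_C = 8)
#' @export
bottle_spec <- function(total_mL, liquid_mL = 0, temp_C, pressure_atm = 1) {
  stopifnot(is.numeric(total_mL), is.numeric(liquid_mL),
            is.numeric(temp_C), is.numeric(pressure_atm))
  if (liquid_mL < 0 || liquid_mL >= total_mL)
    stop("liquid_mL must satisfy 0 <= liquid_mL < total_mL")
  if (temp_C <= -273.15) stop("temperature below absolute zero")
  if (pressure_atm <= 0) stop("pressure must be positive")
  structure(
    list(total_mL = total_mL, liquid_mL = liquid_mL, temp_C = temp_C,
         pressure_atm = pressure_atm,
         headspace_mL = total_mL - liquid_mL),
    class = "bottle_spec"
  )
}

#' @export
print.bottle_spec <- function(x, ...) {
  cat(sprintf("<bottle_spec> %.1f mL total, %.1f mL liquid (%.1f mL headspace), %g degC, %g atm\n",
              x$total_mL, x$liquid_mL, x$headspace_mL, x$temp_C, x$pressure_atm))
  invisible(x)
}

#' Temperature-corrected Henry solubility parameters for CH4
#'
#' Henry's-law solubility \eqn{k_H(T) = k_{H,ref} \exp(B (1/T - 1/T_{ref}))}
#' in mol L\eqn{^{-1}} atm\eqn{^{-1}}, with the van 't Hoff coefficient `B`
#' in Kelvin. The defaults (1.4e-3 mol/L/atm at 298.15 K, B = 1750 K) are
#' mid-range literature values for methane in water.
#'
#' @param kH_ref Solubility at the reference temperature (mol/L/atm).
#' @param T_ref Reference temperature (K).
#' @param vant_hoff van 't Hoff temperature coefficient (K), >= 0.
#' @return An object of class `henry_params`.
#' @examples
#' h <- henry_params()
#' henry_kH(8, h)   # mol/L/atm at 8 degC
#' @export
henry_params <- function(kH_ref = 1.4e-3, T_ref = 298.15, vant_hoff = 1750) {
  if (kH_ref <= 0) stop("kH_ref must be positive")
  if (vant_hoff < 0) stop("vant_hoff must be non-negative")
  structure(list(kH_ref = kH_ref, T_ref = T_ref, vant_hoff = vant_hoff),
            class = "henry_params")
}

#' @rdname henry_params
#' @param temp_C Temperature (degrees Celsius).
#' @param henry A `henry_params` object.
#' @export
henry_kH <- function(temp_C, henry = henry_params()) {
  if (any(temp_C <= -273.15)) stop("temperature below absolute zero")
  TK <- temp_C + 273.15
  henry$kH_ref * exp(henry$vant_hoff * (1 / TK - 1 / henry$T_ref))
}

#' Gravimetric soil context
#'
#' Carries fresh mass and gravimetric water fraction of a soil aliquot and
#' derives the dry mass used to normalise oxidation rates and transcript
#' counts.
#'
#' @param fresh_g Fresh soil mass (g).
#' @param water_fraction Gravimetric water content as a fraction in [0, 1).
#' @return An object of class `soil_context` with derived `dry_g`.
#' @examples
#' soil_context(4, 0.8)$dry_g  # 0.8 g dry weight
#' @export
soil_context <- function(fresh_g, water_fraction) {
  if (fresh_g <= 0) stop("fresh mass must be positive")
  if (water_fraction < 0 || water_fraction >= 1)
    stop("water_fraction must be in [0, 1)")
  dry <- fresh_g * (1 - water_fraction)
  structure(list(fresh_g = fresh_g, water_fraction = water_fraction,
                 dry_g = dry),
            class = "soil_context")
}

#' Headspace CH4 time series for one bottle
#'
#' Timestamped headspace mixing ratios together with the per-measurement
#' sampling volumes (gas drawn for GC injection; liquid drawn for OD
#' measurements in the culture experiment) and the bottle context.
#'
#' @param times_h Measurement times (h), strictly increasing.
#' @param ch4_ppm Headspace CH4 mixing ratios (ppm v/v), non-negative.
#' @param bottle A [bottle_spec()].
#' @param gas_sample_mL Gas volume removed at each measurement (mL).
#' @param liquid_sample_mL Liquid volume removed at each measurement (mL);
#'   0 for soil microcosms.
#' @return An object of class `gas_timeseries`.
#' @export
gas_timeseries <- function(times_h, ch4_ppm, bottle,
                           gas_sample_mL = 0, liquid_sample_mL = 0) {
  stopifnot(inherits(bottle, "bottle_spec"))
  if (length(times_h) != length(ch4_ppm))
    stop("times and mixing ratios must have equal length")
  if (length(times_h) < 2) stop("need at least 2 time points")
  if (any(diff(times_h) <= 0)) stop("times must be strictly increasing")
  if (any(ch4_ppm < 0)) stop("mixing ratios must be non-negative")
  if (gas_sample_mL < 0 || liquid_sample_mL < 0)
    stop("sampling volumes must be non-negative")
  structure(
    list(times_h = as.numeric(times_h), ch4_ppm = as.numeric(ch4_ppm),
         bottle = bottle, gas_sample_mL = gas_sample_mL,
         liquid_sample_mL = liquid_sample_mL),
    class = "gas_timeseries"
  )
}
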