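# Gas constant, L atm / (mol K); CH4 molar mass, g/mol
.R_GAS <- 0.082057
.CH4_G_PER_MOL <- 16.04

#' Equilibrium dissolved CH4 concentration under a given headspace
#'
#' Henry's law with van 't Hoff temperature correction. The dissolved
#' concentration is \eqn{k_H(T) \times p_{CH4}} where the partial pressure is
#' `mixing_ratio * 1e-6 * pressure`. With `kH` in mol/L/atm and the partial
#' pressure in atm this conveniently equals `kH * ppm * pressure` in uM.
#'
#' @param mixing_ratio Headspace CH4 mixing ratio (ppm v/v), >= 0.
#' @param temp_C Temperature (degrees Celsius).
#' @param henry [henry_params()] solubility parameters.
#' @param pressure_atm Total headspace pressure (atm).
#' @return Dissolved CH4 concentration (uM). Vectorised over `mixing_ratio`
#'   and `temp_C`.
#' @examples
#' dissolved_ch4(1000, 8)    # ~2 uM: a 0.1% headspace at 8 degC
#' dissolved_ch4(10000, 15)  # ~17 uM: a 1% headspace at 15 degC
#' @export
dissolved_ch4 <- function(mixing_ratio, temp_C, henry = henry_params(),
                          pressure_atm = 1) {
  if (any(mixing_ratio < 0)) stop("mixing ratio must be non-negative")
  if (pressure_atm <= 0) stop("pressure must be positive")
  kH <- henry_kH(temp_C, henry)                # mol/L/atm
  p_ch4 <- mixing_ratio * 1e-6 * pressure_atm  # atm
  kH * p_ch4 * 1e6                             # mol/L -> uM
}

#' Headspace mixing ratio after injecting CH4 into a closed bottle
#'
#' Assumes the injected gas mixes ideally into the expanded gas phase
#' (headspace + injected volume); overpressure is otherwise ignored.
#'
#' @param bottle A [bottle_spec()].
#' @param injected_mL Volume of gas mixture injected (mL), >= 0.
#' @param ch4_purity CH4 fraction of the injected mixture in [0, 1].
#' @return Resulting headspace CH4 mixing ratio (ppm v/v).
#' @examples
#' b <- bottle_spec(125, 21.6, temp_C = 8)
#' headspace_after_injection(b, 0.2, 0.95)  # ~1900 ppm
#' @export
headspace_after_injection <- function(bottle, injected_mL, ch4_purity = 0.95) {
  stopifnot(inherits(bottle, "bottle_spec"))
  if (any(injected_mL < 0)) stop("injected volume must be non-negative")
  if (ch4_purity < 0 || ch4_purity > 1) stop("purity must be in [0, 1]")
  1e6 * (injected_mL * ch4_purity) / (bottle$headspace_mL + injected_mL)
}

#' Moles of CH4 in the headspace (ideal gas law)
#'
#' @param bottle A [bottle_spec()].
#' @param mixing_ratio CH4 mixing ratio (ppm v/v).
#' @return Amount of headspace CH4 (umol); linear in `mixing_ratio`.
#' @examples
#' b <- bottle_spec(50, 4, temp_C = 8)  # 46 mL headspace
#' headspace_moles(b, 10000)            # ~19.9 umol
#' @export
headspace_moles <- function(bottle, mixing_ratio) {
  stopifnot(inherits(bottle, "bottle_spec"))
  if (any(mixing_ratio < 0)) stop("mixing ratio must be non-negative")
  TK <- bottle$temp_C + 273.15
  x <- mixing_ratio * 1e-6
  n_mol <- bottle$pressure_atm * (bottle$headspace_mL / 1000) * x /
    (.R_GAS * TK)
  n_mol * 1e6
}

#' Total CH4 mass in a bottle: headspace plus dissolved
#'
#' @inheritParams headspace_moles
#' @param henry [henry_params()].
#' @return Total CH4 (umol). Equals [headspace_moles()] when the bottle has
#'   no liquid.
#' @export
total_ch4_mass <- function(bottle, mixing_ratio, henry = henry_params()) {
  gas <- headspace_moles(bottle, mixing_ratio)
  diss_uM <- dissolved_ch4(mixing_ratio, bottle$temp_C, henry,
                           bottle$pressure_atm)
  gas + diss_uM * (bottle$liquid_mL / 1000)   # uM * L = umol
}

#' Correct a measured CH4 series for gas and medium removal during sampling
#'
#' Drawing a gas sample at uniform mixing leaves the measured mixing ratio
#' unchanged but carries away the fraction `gas_sample_mL / headspace_mL`
#' of the headspace CH4 (the bottle's gas content decays by that factor per
#' sampling); drawing medium removes the corresponding fraction of dissolved
#' CH4 (and of cells) and shrinks the liquid volume. The phases are assumed
#' to re-equilibrate between measurements, so the gas/liquid split of the
#' remaining pool is fixed by geometry and temperature, and first-order
#' consumption scales the pool by the measured concentration ratio. The
#' function tracks the true pool under that accounting and reports, per time
#' point, the residual mass, the cumulative removed mass, and the cumulative
#' mass oxidized, defined by mass balance as initial - removed - residual.
#' Sampling losses are applied after each measurement except the last.
#'
#' With zero sampling volumes the oxidized-mass column reduces to
#' `initial - mass(t)`, and a constant-concentration series with sampling
#' yields zero oxidized mass at every point.
#'
#' @param series A [gas_timeseries()].
#' @param henry [henry_params()] for the dissolved fraction.
#' @return A data.frame with one row per measurement: `time_h`, `ch4_ppm`,
#'   `headspace_umol`, `dissolved_umol`, `residual_umol`,
#'   `removed_cum_umol`, `oxidized_cum_umol`, `liquid_mL`.
#' @export
apply_sampling_corrections <- function(series, henry = henry_params()) {
  stopifnot(inherits(series, "gas_timeseries"))
  b <- series$bottle
  n <- length(series$times_h)
  if (series$gas_sample_mL >= b$headspace_mL)
    stop("gas sample volume must be smaller than the headspace")
  if (series$liquid_sample_mL > 0 && b$liquid_mL == 0)
    stop("liquid sampling from a bottle with no liquid")
  if (series$liquid_sample_mL * (n - 1) >= b$liquid_mL && b$liquid_mL > 0)
    stop("liquid sampling would exhaust the liquid volume")
  if (any(series$ch4_ppm <= 0))
    stop("sampling correction requires positive mixing ratios")

  fg <- series$gas_sample_mL / b$headspace_mL
  # per-ppm phase loadings: both phases are linear in the mixing ratio, so
  # the gas/liquid split depends only on geometry and temperature
  head_per_ppm <- headspace_moles(b, 1)
  diss_per_ppm_mL <- dissolved_ch4(1, b$temp_C, henry, b$pressure_atm) / 1000

  liquid_mL <- b$liquid_mL
  removed_cum <- 0
  out <- data.frame(time_h = series$times_h, ch4_ppm = series$ch4_ppm,
                    headspace_umol = NA_real_, dissolved_umol = NA_real_,
                    residual_umol = NA_real_, removed_cum_umol = NA_real_,
                    oxidized_cum_umol = NA_real_, liquid_mL = NA_real_)
  total <- (head_per_ppm + diss_per_ppm_mL * liquid_mL) * series$ch4_ppm[1]
  initial <- total
  for (i in seq_len(n)) {
    share_gas <- head_per_ppm / (head_per_ppm + diss_per_ppm_mL * liquid_mL)
    out$headspace_umol[i] <- total * share_gas
    out$dissolved_umol[i] <- total * (1 - share_gas)
    out$residual_umol[i] <- total
    out$removed_cum_umol[i] <- removed_cum
    out$oxidized_cum_umol[i] <- initial - removed_cum - total
    out$liquid_mL[i] <- liquid_mL
    if (i < n) {
      # sampling losses after the measurement, then first-order consumption
      # scales the (re-equilibrated) pool by the measured concentration ratio
      rem_liq_frac <- if (liquid_mL > 0)
        series$liquid_sample_mL / liquid_mL else 0
      removed <- total * (fg * share_gas + rem_liq_frac * (1 - share_gas))
      removed_cum <- removed_cum + removed
      total <- (total - removed) *
        (series$ch4_ppm[i + 1] / series$ch4_ppm[i])
      liquid_mL <- liquid_mL - series$liquid_sample_mL
    }
  }
  attr(out, "initial_umol") <- initial
  out
}

#' Fit a first-order CH4 consumption rate constant
#'
#' Assuming first-order kinetics, log-transforms the headspace mixing ratios
#' and fits ordinary least squares of ln(ppm) on time; the rate constant is
#' minus the slope. Negative fitted k (net production) is reported as-is
#' with a warning rather than clamped. A constant series yields k = 0 with
#' R-squared reported as 0 and `degenerate = TRUE`.
#'
#' @param series A [gas_timeseries()], all mixing ratios strictly positive.
#' @return An object of class `rate_fit`: list with `k` (per h), `intercept`
#'   (ln ppm), `r_squared`, `n_points`, `k_se`, `k_ci95` (length-2),
#'   `degenerate`.
#' @examples
#' b <- bottle_spec(50, 0, temp_C = 8)
#' s <- gas_timeseries(c(0, 10, 20, 30), 1000 * exp(-0.1 * c(0, 10, 20, 30)), b)
#' fit_first_order(s)$k  # 0.1
#' @export
fit_first_order <- function(series) {
  stopifnot(inherits(series, "gas_timeseries"))
  if (any(series$ch4_ppm <= 0))
    stop("all mixing ratios must be positive for the log transform")
  y <- log(series$ch4_ppm)
  t <- series$times_h
  n <- length(t)
  fit <- stats::lm.fit(cbind(1, t), y)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  degenerate <- ss_tot < .Machine$double.eps * n
  r2 <- if (degenerate) 0 else 1 - ss_res / ss_tot
  k <- if (degenerate) 0 else -slope
  if (k < 0 && !degenerate)
    warning("negative rate constant: net CH4 production over the fit window")
  # slope standard error for CI coverage diagnostics
  se <- if (n > 2) {
    sigma2 <- ss_res / (n - 2)
    sqrt(sigma2 / sum((t - mean(t))^2))
  } else NA_real_
  ci <- if (is.finite(se)) {
    tq <- stats::qt(0.975, df = n - 2)
    c(k - tq * se, k + tq * se)
  } else c(NA_real_, NA_real_)
  structure(list(k = unname(k), intercept = unname(intercept),
                 r_squared = unname(max(0, min(1, r2))), n_points = n,
                 k_se = unname(se), k_ci95 = unname(ci),
                 degenerate = degenerate),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> k = %.5g /h, R2 = %.4f, n = %d%s\n",
              x$k, x$r_squared, x$n_points,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' First-order oxidation rate at a given concentration
#'
#' Multiplies the fitted rate constant by a concentration; used to compare
#' rates at CH4 levels giving equal dissolved concentrations across
#' temperatures.
#'
#' @param fit A `rate_fit` (or a bare numeric rate constant, per h).
#' @param concentration Concentration (uM or ppm; result in the same unit/h).
#' @return Rate in concentration units per hour.
#' @export
rate_at_concentration <- function(fit, concentration) {
  k <- if (inherits(fit, "rate_fit")) fit$k else fit
  if (!is.finite(k)) stop("rate constant must be finite")
  k * concentration
}

#' Headspace mixing ratio giving the same dissolved concentration at another
#' temperature
#'
#' For the equal-dissolved-CH4 rate comparison across temperatures: the ppm
#' at `to_temp_C` whose dissolved concentration matches `ppm_ref` at
#' `ref_temp_C`, i.e. `ppm_ref * kH(ref) / kH(to)`.
#'
#' @param ppm_ref Reference mixing ratio (ppm).
#' @param ref_temp_C,to_temp_C Temperatures (degC).
#' @param henry [henry_params()].
#' @return Equivalent mixing ratio (ppm).
#' @export
equivalent_ppm <- function(ppm_ref, ref_temp_C, to_temp_C,
                           henry = henry_params()) {
  ppm_ref * henry_kH(ref_temp_C, henry) / henry_kH(to_temp_C, henry)
}

#' Normalise a mass rate to soil dry weight
#'
#' Converts a CH4 consumption rate in umol/h into ug CH4 per g dry soil per
#' day (x16.04 g/mol, x24 h/d, / dry mass).
#'
#' @param mass_rate_umol_h CH4 consumption (umol/h).
#' @param soil A [soil_context()].
#' @return Rate in ug CH4 g^-1 dry soil d^-1.
#' @examples
#' rate_per_dry_weight(1, soil_context(4, 0.8))  # 481.2
#' @export
rate_per_dry_weight <- function(mass_rate_umol_h, soil) {
  stopifnot(inherits(soil, "soil_context"))
  if (soil$dry_g <= 0) stop("dry mass must be positive")
  mass_rate_umol_h * .CH4_G_PER_MOL * 24 / soil$dry_g
}

#' Fit an OD-to-cell-count standard
#'
#' Linear regression of microscopic cell counts on optical density (OD410),
#' used to convert culture OD readings into absolute cell numbers.
#'
#' @param od_values OD410 readings of the standard series.
#' @param cell_counts Cell counts (cells/mL) matching `od_values`.
#' @return An object of class `cell_standard` with `slope`, `intercept`,
#'   `r_squared` and the raw points.
#' @export
fit_cell_standard <- function(od_values, cell_counts) {
  if (length(od_values) != length(cell_counts))
    stop("od_values and cell_counts must have equal length")
  if (length(od_values) < 2) stop("need at least 2 standard points")
  fit <- stats::lm(cell_counts ~ od_values)
  sl <- unname(stats::coef(fit)[2])
  if (!is.finite(sl) || sl <= 0)
    stop("cell standard slope must be positive")
  structure(list(slope = sl, intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(od_values, cell_counts)^2,
                 od_values = od_values, cell_counts = cell_counts),
            class = "cell_standard")
}

#' Convert an OD reading to a cell density
#'
#' Applies the fitted linear standard; predictions below zero are clamped to
#' 0 with a warning (an OD below the regression's root has no physical cell
#' count).
#'
#' @param od OD410 reading(s).
#' @param standard A [fit_cell_standard()] object.
#' @return Cell density (cells/mL), >= 0.
#' @export
cells_from_od <- function(od, standard) {
  if (!inherits(standard, "cell_standard")) stop("unfitted cell standard")
  pred <- standard$intercept + standard$slope * od
  if (any(pred < 0)) {
    warning("OD below the standard's zero-count root; clamping to 0 cells")
    pred[pred < 0] <- 0
  }
  pred
}

#' Normalise a mass rate to cell numbers
#'
#' @param mass_rate_umol_h CH4 consumption (umol/h).
#' @param cells_per_mL Cell density in the medium (cells/mL), > 0.
#' @param liquid_mL Medium volume (mL).
#' @return Rate in umol CH4 per 1e8 cells per hour.
#' @examples
#' rate_per_cell(0.5, 5e7, 21.6)  # ~0.0463
#' @export
rate_per_cell <- function(mass_rate_umol_h, cells_per_mL, liquid_mL) {
  total_cells <- cells_per_mL * liquid_mL
  if (any(total_cells <= 0)) stop("total cell number must be positive")
  mass_rate_umol_h / total_cells * 1e8
}
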