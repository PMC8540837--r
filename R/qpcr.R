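#' qPCR dilution-series standard
#'
#' @param copies Template copies per reaction at each standard point (> 0).
#' @param cq Quantification cycles, same length (replicates allowed: repeat
#'   the copy number).
#' @return An object of class `dilution_standard`.
#' @export
dilution_standard <- function(copies, cq) {
  if (length(copies) != length(cq)) stop("copies and cq lengths differ")
  if (any(copies <= 0)) stop("copies must be positive")
  if (any(!is.finite(cq))) stop("cq values must be finite")
  if (length(unique(copies)) < 2) stop("need >= 2 distinct copy levels")
  structure(list(copies = as.numeric(copies), cq = as.numeric(cq)),
            class = "dilution_standard")
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10(copies). Replicate Cq values at the
#' same copy level are averaged before fitting (the fitted line is identical
#' either way for balanced replication; averaging matches how instrument
#' software reports the curve). Amplification efficiency is
#' \eqn{10^{-1/slope} - 1}; a slope of \eqn{-1/\log_{10} 2 \approx -3.32}
#' corresponds to perfect doubling (efficiency 1).
#'
#' @param standard A [dilution_standard()].
#' @return Object of class `standard_curve`: `slope` (Cq per log10 copies),
#'   `intercept` (Cq at 1 copy), `efficiency`, `r_squared`, `valid` (slope
#'   negative), and the standard's copy/Cq ranges for extrapolation flags.
#' @examples
#' std <- dilution_standard(10^(6:1), 38 - 1 / log10(2) * -1 * log10(10^(6:1)))
#' @export
fit_standard_curve <- function(standard) {
  stopifnot(inherits(standard, "dilution_standard"))
  lg <- log10(standard$copies)
  cqm <- tapply(standard$cq, lg, mean)
  x <- as.numeric(names(cqm))
  y <- as.numeric(cqm)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  valid <- is.finite(slope) && slope < 0
  if (!valid) warning("non-negative standard-curve slope; curve flagged invalid")
  eff <- if (valid) 10^(-1 / slope) - 1 else NA_real_
  structure(list(slope = slope, intercept = intercept, efficiency = eff,
                 r_squared = stats::cor(x, y)^2, valid = valid,
                 copies_range = range(standard$copies),
                 cq_range = range(standard$cq)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, intercept %.2f, efficiency %.1f%%, R2 %.4f%s\n",
              x$slope, x$intercept, 100 * x$efficiency, x$r_squared,
              if (!x$valid) " [INVALID]" else ""))
  invisible(x)
}

#' Screen qPCR negative controls for contamination
#'
#' Negative (no-template) controls must be non-detect (NA) or amplify at or
#' above a late-cycle cutoff; anything earlier indicates contamination.
#'
#' @param cq Cq values of the negative controls (NA = non-detect).
#' @param cq_cutoff Minimum acceptable Cq for a detected negative control.
#' @return Logical: TRUE if all controls are clean (invisibly); warns
#'   otherwise.
#' @export
check_negative_controls <- function(cq, cq_cutoff = 35) {
  bad <- !is.na(cq) & cq < cq_cutoff
  if (any(bad))
    warning(sprintf("%d negative control(s) amplified before Cq %.1f: possible contamination",
                    sum(bad), cq_cutoff))
  invisible(!any(bad))
}

#' Absolute quantification: transcript copies per gram dry soil
#'
#' Inverts the standard curve at the replicate-mean Cq, scales by the
#' user-supplied elution/dilution factor (the chain from reaction template
#' back to the nucleic-acid extract of the soil aliquot), and divides by the
#' aliquot's dry mass.
#'
#' @param cq Cq value(s) for one sample; replicates are averaged.
#' @param curve A [fit_standard_curve()] result; must be valid.
#' @param dilution_factor Combined elution-and-dilution factor mapping copies
#'   per reaction to copies in the whole extract (unitless, > 0).
#' @param soil A [soil_context()] for the extracted aliquot.
#' @return A list: `copies_per_reaction`, `copies_per_gdw`, `cq_mean`,
#'   `extrapolated` (TRUE when the Cq falls outside the standard range).
#' @export
quantify_copies <- function(cq, curve, dilution_factor = 1, soil) {
  stopifnot(inherits(curve, "standard_curve"), inherits(soil, "soil_context"))
  if (!curve$valid) stop("cannot quantify against an invalid standard curve")
  if (dilution_factor <= 0) stop("dilution factor must be positive")
  cqm <- mean(cq)
  copies_rxn <- 10^((cqm - curve$intercept) / curve$slope)
  extrap <- cqm < min(curve$cq_range) || cqm > max(curve$cq_range)
  if (extrap)
    warning("Cq outside the standard range; quantification extrapolated")
  list(copies_per_reaction = copies_rxn,
       copies_per_gdw = copies_rxn * dilution_factor / soil$dry_g,
       cq_mean = cqm, extrapolated = extrap)
}
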