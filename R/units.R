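#' Length/time/concentration scales of the model
#'
#' The simulations run on the unit square in dimensionless time; this object
#' records the physical scales used to map results back to skin: domain edge
#' \code{length_cm} (default 27.4 cm), time unit \code{time_s} (default 250 s)
#' and the concentration normalization \code{conc_ml_per_ug} linking the
#' dimensionless injection dose to micrograms per millilitre (default 0.03,
#' from u0 = 0.3 at a 10 ug/ml dose).
#'
#' @param length_cm domain edge length L, in cm.
#' @param time_s time unit T, in seconds.
#' @param conc_ml_per_ug concentration scale u_nd, in ml/ug.
#' @return An object of class \code{"scaleSet"}.
#' @export
scaleSet <- function(length_cm = 27.4, time_s = 250, conc_ml_per_ug = 0.03) {
  if (any(c(length_cm, time_s, conc_ml_per_ug) <= 0))
    stop("scaleSet: all scales must be positive")
  structure(list(length_cm = length_cm, time_s = time_s,
                 conc_ml_per_ug = conc_ml_per_ug),
            class = "scaleSet")
}

#' @export
print.scaleSet <- function(x, ...) {
  cat(sprintf("Scales: L = %g cm, T = %g s, u_nd = %g ml/ug\n",
              x$length_cm, x$time_s, x$conc_ml_per_ug))
  invisible(x)
}

#' Convert a dimensional diffusion coefficient to model units
#'
#' \code{d_nd = d_dim * T / L^2} with \code{d_dim} in cm^2/s.
#'
#' @param d_dim diffusion coefficient in cm^2/sec, positive.
#' @param s a \code{\link{scaleSet}}.
#' @return Dimensionless diffusivity.
#' @export
diffusionToDimensionless <- function(d_dim, s = scaleSet()) {
  stopifnot(inherits(s, "scaleSet"))
  if (any(d_dim <= 0)) stop("diffusionToDimensionless: d_dim must be positive")
  d_dim * s$time_s / s$length_cm^2
}

#' Convert a dimensionless diffusion coefficient to cm^2/sec
#'
#' Inverse of \code{\link{diffusionToDimensionless}}.
#'
#' @param d_nd dimensionless diffusivity, positive.
#' @param s a \code{\link{scaleSet}}.
#' @return Diffusion coefficient in cm^2/sec.
#' @export
diffusionToDimensional <- function(d_nd, s = scaleSet()) {
  stopifnot(inherits(s, "scaleSet"))
  if (any(d_nd <= 0)) stop("diffusionToDimensional: d_nd must be positive")
  d_nd * s$length_cm^2 / s$time_s
}

# factors to cm2/s
.diff_unit_factors <- c("cm2/s" = 1, "cm2/sec" = 1,
                        "mm2/min" = 6000, "mm2/s" = 100, "mm2/sec" = 100)

#' Convert a diffusion coefficient between unit systems
#'
#' Exact unit algebra between \code{"cm2/s"}, \code{"mm2/min"} and
#' \code{"mm2/s"} (100 mm^2 per cm^2, 60 s per min).
#'
#' @param d value to convert.
#' @param from,to unit tokens.
#' @return Converted value.
#' @examples
#' convertDiffusionUnits(0.08474977, "mm2/min", "cm2/s")  # 1.412e-5
#' @export
convertDiffusionUnits <- function(d, from, to) {
  if (!from %in% names(.diff_unit_factors))
    stop("convertDiffusionUnits: unknown unit '", from, "'")
  if (!to %in% names(.diff_unit_factors))
    stop("convertDiffusionUnits: unknown unit '", to, "'")
  d / .diff_unit_factors[[from]] * .diff_unit_factors[[to]]
}

#' Convert a dimensionless front speed to mm/hr
#'
#' A dimensionless speed is in domain edges per time unit; the dimensional
#' speed is \code{c_nd * (10 * L_cm) / (T_s / 3600)} mm/hr.
#'
#' @param c_nd dimensionless speed, nonnegative.
#' @param s a \code{\link{scaleSet}}.
#' @return Speed in mm/hr.
#' @export
speedToDimensional <- function(c_nd, s = scaleSet()) {
  stopifnot(inherits(s, "scaleSet"))
  if (any(c_nd < 0, na.rm = TRUE)) stop("speedToDimensional: c_nd must be >= 0")
  c_nd * (10 * s$length_cm) / (s$time_s / 3600)
}

#' Concentration scale from an injection dose
#'
#' The dimensionless initial histamine amount of the point-source injection
#' model is \code{u0 = u_nd * dose}; given \code{u0} and the dose this returns
#' \code{u_nd = u0 / dose} in ml/ug.
#'
#' @param u0_nd dimensionless initial amount.
#' @param dose injected concentration in ug/ml, positive.
#' @return Concentration scale in ml/ug.
#' @examples
#' concScaleFromInjection(0.3, 10)  # 0.03
#' @export
concScaleFromInjection <- function(u0_nd, dose) {
  if (any(dose <= 0)) stop("concScaleFromInjection: dose must be positive")
  u0_nd / dose
}
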