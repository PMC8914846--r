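#' Radiative conversion constants
#'
#' Constants for the one-directional radiometry stack: the Stefan-Boltzmann
#' constant, human-body emissivity, shortwave absorption coefficient, the
#' angular weighting factor `F` (0.167 for one direction of a sphere, 0.06
#' for radiation from above onto a standing person), and the light-to-
#' shortwave conversion (slope 0.03887 W m-2 lx-1 with saturation above
#' 15,000 lx, capped at 600 W m-2).
#'
#' @param sigma Stefan-Boltzmann constant (W m-2 K-4)
#' @param eps_p emissivity of the human body
#' @param alpha_k absorption coefficient for shortwave radiation
#' @param F_angular angular weighting factor; 0.167 (sphere) or 0.06
#'   (standing person) are the two standard variants, other positive values
#'   are accepted with a warning
#' @param lux_slope shortwave irradiance per lux (W m-2 lx-1)
#' @param lux_saturation_lx light level above which the sensor saturates (lx)
#' @param sw_cap shortwave irradiance assigned above saturation (W m-2)
#' @return a list of class `radiation_constants`
#' @export
radiation_constants <- function(sigma = 5.67e-8, eps_p = 0.97, alpha_k = 0.7,
                                F_angular = 0.167, lux_slope = 0.03887,
                                lux_saturation_lx = 15000, sw_cap = 600) {
  vals <- c(sigma, eps_p, alpha_k, F_angular, lux_slope, lux_saturation_lx,
            sw_cap)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all radiation constants must be strictly positive", call. = FALSE)
  }
  if (!isTRUE(all.equal(F_angular, 0.167)) && !isTRUE(all.equal(F_angular, 0.06))) {
    warning("F_angular = ", F_angular,
            " is neither 0.167 (sphere) nor 0.06 (standing person)")
  }
  structure(list(sigma = sigma, eps_p = eps_p, alpha_k = alpha_k,
                 F_angular = F_angular, lux_slope = lux_slope,
                 lux_saturation_lx = lux_saturation_lx, sw_cap = sw_cap),
            class = "radiation_constants")
}

#' Shortwave irradiance from a light-level reading
#'
#' Piecewise-linear surrogate for solar irradiance from an upward-pointing
#' lux sensor: `SW = 0.03887 * L` up to (and including) the 15,000 lx
#' saturation threshold, and a fixed 600 W m-2 above it. The cap is applied
#' exactly as calibrated, i.e. with a small discontinuity at the threshold
#' (583.05 -> 600 W m-2).
#'
#' @param light light level (lx), non-negative
#' @param constants a [radiation_constants()] list
#' @return shortwave irradiance (W m-2)
#' @export
#' @examples
#' lux_to_sw(10000) # 388.7
#' lux_to_sw(20000) # 600
lux_to_sw <- function(light, constants = radiation_constants()) {
  if (any(light < 0, na.rm = TRUE)) {
    stop("light level must be non-negative", call. = FALSE)
  }
  ifelse(light > constants$lux_saturation_lx, constants$sw_cap,
         constants$lux_slope * light)
}

#' Light level corresponding to a shortwave irradiance
#'
#' Inverse of the linear branch of [lux_to_sw()]; only defined below the
#' saturation cap.
#'
#' @param sw shortwave irradiance (W m-2), below the saturation cap
#' @param constants a [radiation_constants()] list
#' @return light level (lx)
#' @export
sw_to_lux <- function(sw, constants = radiation_constants()) {
  lim <- constants$lux_slope * constants$lux_saturation_lx
  if (any(sw < 0 | sw > lim, na.rm = TRUE)) {
    stop("sw must lie within the invertible linear branch [0, ",
         format(lim), "] W m-2", call. = FALSE)
  }
  sw / constants$lux_slope
}

#' Brightness temperature from longwave irradiance
#'
#' Blackbody inversion of the Stefan-Boltzmann law,
#' `T_IRT = (LW / sigma)^(1/4) - 273.15`.
#'
#' @param lw incident longwave irradiance (W m-2), non-negative
#' @param constants a [radiation_constants()] list
#' @return brightness temperature (degrees C)
#' @export
brightness_temperature <- function(lw, constants = radiation_constants()) {
  if (any(lw < 0, na.rm = TRUE)) {
    stop("longwave irradiance must be non-negative", call. = FALSE)
  }
  (lw / constants$sigma)^0.25 - 273.15
}

#' Longwave irradiance emitted by a blackbody at a given temperature
#'
#' Inverse of [brightness_temperature()]; the pair round-trips to float
#' precision.
#'
#' @param tirt brightness temperature (degrees C)
#' @param constants a [radiation_constants()] list
#' @return longwave irradiance (W m-2)
#' @export
lw_from_brightness <- function(tirt, constants = radiation_constants()) {
  constants$sigma * (tirt + 273.15)^4
}

#' One-directional mean radiant flux density
#'
#' Combines upward-measured shortwave and longwave irradiance into the mean
#' radiant flux density absorbed by the body,
#' `S_str = F * alpha_k * SW + eps_p * LW`, assuming isotropic longwave and
#' shortwave arriving from above.
#'
#' @param sw shortwave irradiance (W m-2)
#' @param lw longwave irradiance (W m-2)
#' @param constants a [radiation_constants()] list; `F_angular` selects the
#'   sphere (0.167) or standing-person (0.06) weighting
#' @return mean radiant flux density (W m-2)
#' @export
mean_radiant_flux <- function(sw, lw, constants = radiation_constants()) {
  if (any(sw < 0, na.rm = TRUE) || any(lw < 0, na.rm = TRUE)) {
    stop("irradiances must be non-negative", call. = FALSE)
  }
  constants$F_angular * constants$alpha_k * sw + constants$eps_p * lw
}

#' Mean radiant temperature from a mean radiant flux density
#'
#' `T_mrt = (S_str / (eps_p * sigma))^(1/4) - 273.15`.
#'
#' @param sstr mean radiant flux density (W m-2)
#' @param constants a [radiation_constants()] list
#' @return mean radiant temperature (degrees C)
#' @export
tmrt_from_flux <- function(sstr, constants = radiation_constants()) {
  (sstr / (constants$eps_p * constants$sigma))^0.25 - 273.15
}
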