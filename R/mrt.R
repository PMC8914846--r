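#' Black globe thermometer specification
#'
#' Geometry and heat-transfer constants of a black globe thermometer for the
#' forced-convection globe-to-mean-radiant-temperature conversion
#' (ISO 7726 form). Defaults describe a 0.05 m matte-black globe with
#' emissivity 0.95.
#'
#' @param diameter globe diameter (m), in (0, 0.2]
#' @param emissivity globe emissivity, in (0, 1]
#' @param convection_coefficient forced-convection constant (1.1e8)
#' @param v_exponent wind-speed exponent (0.6)
#' @param d_exponent diameter exponent (0.4)
#' @return a list of class `globe_spec`
#' @export
globe_spec <- function(diameter = 0.05, emissivity = 0.95,
                       convection_coefficient = 1.1e8,
                       v_exponent = 0.6, d_exponent = 0.4) {
  if (diameter <= 0 || diameter > 0.2) {
    stop("globe diameter must lie in (0, 0.2] m", call. = FALSE)
  }
  if (emissivity <= 0 || emissivity > 1) {
    stop("globe emissivity must lie in (0, 1]", call. = FALSE)
  }
  structure(list(diameter = diameter, emissivity = emissivity,
                 convection_coefficient = convection_coefficient,
                 v_exponent = v_exponent, d_exponent = d_exponent),
            class = "globe_spec")
}

#' The five mean radiant temperature estimation methods
#'
#' Stable identifiers for the five T_mrt estimation routes: black globe
#' thermometer (`globe`), one-directional radiometry with spherical
#' (`ir_l_sphere`) or standing-person (`ir_l_person`) weighting, brightness
#' temperature only (`ir_only`), and air temperature as a fallback
#' (`air_temperature`).
#'
#' @return character vector of the five method labels
#' @export
mrt_methods <- function() {
  c("globe", "ir_l_sphere", "ir_l_person", "ir_only", "air_temperature")
}

.globe_convective_coef <- function(v_eff, globe) {
  globe$convection_coefficient * v_eff^globe$v_exponent /
    (globe$emissivity * globe$diameter^globe$d_exponent)
}

#' Mean radiant temperature from globe temperature
#'
#' Forced-convection conversion of globe temperature to mean radiant
#' temperature:
#' `T_mrt = ((T_g + 273.15)^4 + C v^0.6 / (eps_g D^0.4) (T_g - T_a))^(1/4) - 273.15`
#' with `C = 1.1e8`. Under extreme inputs the convective term can drive the
#' bracket negative; it is then clamped at zero (absolute zero result) with a
#' warning.
#'
#' @param tg globe temperature (degrees C)
#' @param ta air temperature (degrees C)
#' @param v_eff effective wind speed (m/s), >= 0.1 (floor already applied)
#' @param globe a [globe_spec()]
#' @return mean radiant temperature (degrees C)
#' @export
mrt_from_globe <- function(tg, ta, v_eff = 0.1, globe = globe_spec()) {
  if (any(tg <= -273.15, na.rm = TRUE) || any(ta <= -273.15, na.rm = TRUE)) {
    stop("temperatures below absolute zero", call. = FALSE)
  }
  if (any(v_eff < 0.1, na.rm = TRUE)) {
    stop("v_eff must be >= 0.1 m/s (apply effective_wind() first)",
         call. = FALSE)
  }
  hcg <- .globe_convective_coef(v_eff, globe)
  bracket <- (tg + 273.15)^4 + hcg * (tg - ta)
  neg <- !is.na(bracket) & bracket < 0
  if (any(neg)) {
    warning("convective term drove the radiant bracket negative for ",
            sum(neg), " record(s); clamped at absolute zero")
    bracket[neg] <- 0
  }
  bracket^0.25 - 273.15
}

#' Globe temperature consistent with a mean radiant temperature
#'
#' Inverse of [mrt_from_globe()], solved by bracketed root finding of the
#' globe heat balance for `T_g` in [-60, 120] degrees C; used as a testing
#' oracle and by the synthetic scenario generator to manufacture globe
#' channels with known ground truth.
#'
#' @param tmrt mean radiant temperature (degrees C)
#' @param ta air temperature (degrees C)
#' @param v_eff effective wind speed (m/s), >= 0.1
#' @param globe a [globe_spec()]
#' @return globe temperature (degrees C)
#' @export
globe_from_mrt <- function(tmrt, ta, v_eff = 0.1, globe = globe_spec()) {
  n <- max(length(tmrt), length(ta), length(v_eff))
  tmrt <- rep_len(tmrt, n); ta <- rep_len(ta, n); v_eff <- rep_len(v_eff, n)
  vapply(seq_len(n), function(i) {
    if (is.na(tmrt[i]) || is.na(ta[i])) return(NA_real_)
    hcg <- .globe_convective_coef(v_eff[i], globe)
    target <- (tmrt[i] + 273.15)^4
    f <- function(tg) (tg + 273.15)^4 + hcg * (tg - ta[i]) - target
    lo <- -60; hi <- 120
    if (f(lo) > 0 || f(hi) < 0) {
      stop("no globe temperature in [-60, 120] C reproduces tmrt = ",
           tmrt[i], call. = FALSE)
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
}

.method_channels <- list(
  globe = c("tg", "ta"),
  ir_l_sphere = c("lw", "light"),
  ir_l_person = c("lw", "light"),
  ir_only = c("lw"),
  air_temperature = c("ta")
)

#' Estimate mean radiant temperature from a derived record
#'
#' Applies one of the five estimation methods (see [mrt_methods()]) to rows
#' of a derived records data frame. Each method requires specific channels
#' (globe: `tg`; `ir_l_*`: `lw` + `light`; `ir_only`: `lw`;
#' `air_temperature`: `ta`); a missing channel is an error, never a silent
#' fallback (use [estimate_mrt_fallback()] for preference-ordered selection).
#'
#' @param records a derived records `data.frame` (see [derive_records()])
#' @param method one of the labels of [mrt_methods()]
#' @param constants a [radiation_constants()] list
#' @param globe a [globe_spec()]
#' @return numeric vector of mean radiant temperature (degrees C) with
#'   attribute `method`
#' @export
estimate_mrt <- function(records, method = "globe",
                         constants = radiation_constants(),
                         globe = globe_spec()) {
  method <- match.arg(method, mrt_methods())
  need <- .method_channels[[method]]
  for (ch in need) {
    if (!ch %in% names(records) || anyNA(records[[ch]])) {
      stop("channel '", ch, "' missing for method '", method, "'",
           call. = FALSE)
    }
  }
  tmrt <- switch(
    method,
    globe = mrt_from_globe(records$tg, records$ta,
                           effective_wind(records$v), globe),
    ir_l_sphere = {
      cs <- constants; cs$F_angular <- 0.167
      tmrt_from_flux(mean_radiant_flux(lux_to_sw(records$light, cs),
                                       records$lw, cs), cs)
    },
    ir_l_person = {
      cs <- constants; cs$F_angular <- 0.06
      tmrt_from_flux(mean_radiant_flux(lux_to_sw(records$light, cs),
                                       records$lw, cs), cs)
    },
    ir_only = brightness_temperature(records$lw, constants),
    air_temperature = records$ta
  )
  structure(tmrt, method = method)
}

#' Estimate mean radiant temperature with a method preference order
#'
#' Per record, applies the first method in `preference` whose channels are
#' present; the method actually used is recorded alongside the estimate. The
#' air-temperature method always succeeds, so ending the preference order
#' with `"air_temperature"` guarantees an estimate for every record.
#'
#' @param records a derived records `data.frame`
#' @param preference character vector of method labels in decreasing
#'   preference
#' @inheritParams estimate_mrt
#' @return a `data.frame` with columns `tmrt` and `method`
#' @export
estimate_mrt_fallback <- function(records,
                                  preference = c("globe", "ir_l_sphere",
                                                 "air_temperature"),
                                  constants = radiation_constants(),
                                  globe = globe_spec()) {
  preference <- match.arg(preference, mrt_methods(), several.ok = TRUE)
  n <- nrow(records)
  tmrt <- rep(NA_real_, n)
  used <- rep(NA_character_, n)
  for (m in preference) {
    have <- rep(TRUE, n)
    for (ch in .method_channels[[m]]) {
      have <- have & ch %in% names(records) & !is.na(records[[ch]])
    }
    idx <- which(is.na(used) & have)
    if (length(idx)) {
      est <- estimate_mrt(records[idx, , drop = FALSE], m, constants, globe)
      tmrt[idx] <- as.numeric(est)
      used[idx] <- m
    }
  }
  if (anyNA(used)) {
    stop("no method in the preference order is applicable to ",
         sum(is.na(used)), " record(s)", call. = FALSE)
  }
  data.frame(tmrt = tmrt, method = used, stringsAsFactors = FALSE)
}
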