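# Synthetic diurnal workplace scenarios with known ground-truth mean
# radiant temperature. The generator manufactures the radiant field first
# (wall longwave + a window sun pulse), then derives every sensor channel
# from it, so the globe route is exactly invertible before noise.

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scenario configuration for the synthetic generator
#'
#' Describes a diurnal office or industrial scenario: a sinusoidal air
#' temperature cycle, a half-sine window sun pulse, a wall-temperature model
#' driving the longwave channel (damped air-temperature cycle plus an
#' optional waste-heat offset), per-channel Gaussian sensor noise, and the
#' site type (indoor sites carry no wind channel).
#'
#' @param seed integer seed making the generated streams reproducible
#' @param duration_days length of the scenario (days)
#' @param step_min sampling step (minutes); must divide 24 h
#' @param ta_mean,ta_amplitude,ta_peak_hour diurnal air temperature cycle:
#'   mean (degC), half-amplitude (K) and UTC hour of the maximum
#' @param vp_mean ambient vapor pressure (hPa), held constant
#' @param sun_window UTC hours `c(start, end)` during which direct sun
#'   reaches the sensor through the window
#' @param sw_peak peak shortwave irradiance of the sun pulse (W m-2); keep
#'   below 583 W m-2 for an invertible light channel
#' @param waste_heat_offset wall-temperature offset from nearby machinery (K)
#' @param wall_damping fraction of the air-temperature diurnal amplitude
#'   retained by the walls
#' @param noise per-channel Gaussian noise standard deviations:
#'   `ta`, `rh` (additive) `tg`, `lw` (additive), `light_rel`
#'   (multiplicative); defaults at low-cost-sensor datasheet scale
#' @param site `"indoor"` (no wind channel) or `"semi-outdoor"` (log-normal
#'   wind with the 0.5 m/s anemometer starting-speed deadband)
#' @param device_id device identifier written to the records
#' @return a list of class `scenario_config`
#' @export
scenario_config <- function(seed = 1L, duration_days = 2, step_min = 5,
                            ta_mean = 24, ta_amplitude = 3, ta_peak_hour = 15,
                            vp_mean = 12, sun_window = c(7, 11),
                            sw_peak = 450, waste_heat_offset = 0,
                            wall_damping = 0.7,
                            noise = list(ta = 0.3, rh = 2, tg = 0.3, lw = 5,
                                         light_rel = 0.05),
                            site = c("indoor", "semi-outdoor"),
                            device_id = "sim-01") {
  site <- match.arg(site)
  if ((24 * 60) %% step_min != 0) stop("step_min must divide 24 h",
                                       call. = FALSE)
  if (any(unlist(noise) < 0)) stop("noise sigmas must be >= 0", call. = FALSE)
  if (sun_window[1] < 0 || sun_window[2] > 24 ||
      sun_window[1] >= sun_window[2]) {
    stop("sun_window must satisfy 0 <= start < end <= 24", call. = FALSE)
  }
  defaults <- list(ta = 0.3, rh = 2, tg = 0.3, lw = 5, light_rel = 0.05)
  defaults[names(noise)] <- noise
  structure(list(seed = as.integer(seed), duration_days = duration_days,
                 step_min = step_min, ta_mean = ta_mean,
                 ta_amplitude = ta_amplitude, ta_peak_hour = ta_peak_hour,
                 vp_mean = vp_mean, sun_window = sun_window,
                 sw_peak = sw_peak, waste_heat_offset = waste_heat_offset,
                 wall_damping = wall_damping, noise = defaults, site = site,
                 device_id = device_id),
            class = "scenario_config")
}

#' Scenario presets
#'
#' Named presets mirroring typical deployments: an east-window office with a
#' morning sun pulse (`office_east`), a windowless hallway
#' (`office_hallway`), an industrial workplace near waste-heat-producing
#' machinery (`industrial_waste_heat`) and a semi-outdoor barn with a wind
#' channel (`semi_outdoor_barn`).
#'
#' @param name preset name
#' @param seed integer seed
#' @param ... overrides forwarded to [scenario_config()]
#' @return a [scenario_config()]
#' @export
scenario_preset <- function(name = c("office_east", "office_hallway",
                                     "industrial_waste_heat",
                                     "semi_outdoor_barn"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    office_east = list(ta_mean = 24, ta_amplitude = 3, sun_window = c(6, 11),
                       sw_peak = 450, device_id = "office-east"),
    office_hallway = list(ta_mean = 25, ta_amplitude = 1.2, sw_peak = 0,
                          device_id = "office-hallway"),
    industrial_waste_heat = list(ta_mean = 30, ta_amplitude = 2.5,
                                 sw_peak = 60, sun_window = c(10, 14),
                                 waste_heat_offset = 8,
                                 device_id = "industrial-1"),
    semi_outdoor_barn = list(ta_mean = 18, ta_amplitude = 6,
                             sun_window = c(8, 16), sw_peak = 300,
                             site = "semi-outdoor", device_id = "barn-1"))
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, c(list(seed = seed), args))
}

.scenario_truth <- function(config, constants, globe) {
  n_per_day <- 24 * 60 / config$step_min
  n <- n_per_day * config$duration_days
  t0 <- as.POSIXct("2021-09-02 00:00:00", tz = "UTC")
  timestamp <- t0 + (seq_len(n) - 1) * config$step_min * 60
  hour <- (as.numeric(timestamp - t0, units = "hours")) %% 24

  ta <- config$ta_mean + config$ta_amplitude *
    cos(2 * pi * (hour - config$ta_peak_hour) / 24)
  vp <- rep(config$vp_mean, n)
  rh <- pmin(pmax(100 * vp / saturation_vapor_pressure(ta), 1), 99)
  # walls follow the air cycle with damped amplitude, plus waste heat
  t_wall <- config$ta_mean + config$waste_heat_offset +
    config$wall_damping * (ta - config$ta_mean)
  lw <- lw_from_brightness(t_wall, constants)
  sw <- rep(0, n)
  sun <- hour >= config$sun_window[1] & hour <= config$sun_window[2]
  span <- diff(config$sun_window)
  sw[sun] <- config$sw_peak *
    sin(pi * (hour[sun] - config$sun_window[1]) / span)
  sw <- pmin(sw, constants$lux_slope * constants$lux_saturation_lx)
  light <- sw_to_lux(sw, constants)

  if (config$site == "semi-outdoor") {
    v_raw <- .with_seed(config$seed + 1L, stats::rlnorm(n, log(0.8), 0.6))
    v_raw[v_raw < 0.5] <- 0  # cup anemometer starting-speed deadband
  } else {
    v_raw <- rep(NA_real_, n)
  }
  v_eff <- effective_wind(v_raw)

  tmrt <- tmrt_from_flux(mean_radiant_flux(sw, lw, constants), constants)
  tg <- globe_from_mrt(tmrt, ta, v_eff, globe)

  data.frame(timestamp = timestamp, ta = ta, rh = rh, vp = vp, sw = sw,
             lw = lw, light = light, v = v_raw, v_eff = v_eff,
             t_wall = t_wall, tmrt = tmrt, tg = tg)
}

#' Generate a synthetic scenario with known ground truth
#'
#' Builds the noiseless physical truth of a diurnal workplace scenario (air
#' temperature, radiant field, light, wind), derives all sensor channels
#' from it -- the globe channel through the inverse globe equation, the
#' light channel through the inverse lux-to-shortwave conversion -- and then
#' overlays per-channel sensor noise. With noise switched off, the globe
#' pipeline reproduces the ground-truth mean radiant temperature exactly.
#'
#' @param config a [scenario_config()] or [scenario_preset()]
#' @param constants a [radiation_constants()] list
#' @param globe a [globe_spec()]
#' @return a list of class `comfort_scenario` with elements `truth` (exact
#'   per-step physical state incl. `tmrt`) and `records` (the noisy sensor
#'   stream in [read_records()] layout)
#' @export
generate_scenario <- function(config = scenario_config(),
                              constants = radiation_constants(),
                              globe = globe_spec()) {
  truth <- .scenario_truth(config, constants, globe)
  n <- nrow(truth)
  ns <- config$noise
  rec <- .with_seed(config$seed, {
    data.frame(
      timestamp = truth$timestamp,
      device_id = config$device_id,
      ta = truth$ta + stats::rnorm(n, 0, ns$ta),
      rh = pmin(pmax(truth$rh + stats::rnorm(n, 0, ns$rh), 0), 100),
      tg = truth$tg + stats::rnorm(n, 0, ns$tg),
      lw = pmax(truth$lw + stats::rnorm(n, 0, ns$lw), 0),
      tirt = NA_real_,
      light = pmax(truth$light * (1 + stats::rnorm(n, 0, ns$light_rel)), 0),
      v = truth$v,
      stringsAsFactors = FALSE
    )
  })
  structure(list(truth = truth, records = rec, config = config),
            class = "comfort_scenario")
}

#' @export
print.comfort_scenario <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Synthetic %s scenario '%s': %d steps of %d min ",
                     "(%.1f days), seed %d\n"),
              cfg$site, cfg$device_id, nrow(x$records), cfg$step_min,
              cfg$duration_days, cfg$seed))
  cat(sprintf("  ta %.1f +/- %.1f degC, sun %g-%g h UTC (peak %g W m-2)\n",
              cfg$ta_mean, cfg$ta_amplitude, cfg$sun_window[1],
              cfg$sun_window[2], cfg$sw_peak))
  invisible(x)
}

#' Generate a paired device / reference layout
#'
#' Emulates a side-by-side comparison of the low-cost device against a
#' mid-cost reference instrument: the device stream comes from
#' [generate_scenario()] at its native step, the reference reports the
#' ground truth (plus a configurable bias and noise) on a coarser grid.
#' With zero bias and zero noise every error metric is exactly zero.
#'
#' @param config a [scenario_config()]
#' @param reference_bias named list of constant biases added to the
#'   reference channels `ta`, `vp`, `tmrt` (K / hPa)
#' @param reference_step_min reference sampling step (minutes)
#' @param reference_noise named list of Gaussian noise sigmas for the same
#'   channels
#' @inheritParams generate_scenario
#' @return a list of class `reference_pair` with `device` (a
#'   `comfort_scenario`) and `reference` (a `data.frame` with `timestamp`,
#'   `ta`, `vp`, `tmrt`)
#' @export
generate_reference_pair <- function(config = scenario_config(),
                                    reference_bias = list(),
                                    reference_step_min = 10,
                                    reference_noise = list(),
                                    constants = radiation_constants(),
                                    globe = globe_spec()) {
  device <- generate_scenario(config, constants, globe)
  truth <- device$truth
  idx <- seq(1, nrow(truth), by = reference_step_min / config$step_min)
  bias <- function(ch) reference_bias[[ch]] %||% 0
  sig <- function(ch) reference_noise[[ch]] %||% 0
  m <- length(idx)
  ref <- .with_seed(config$seed + 2L, data.frame(
    timestamp = truth$timestamp[idx],
    ta = truth$ta[idx] + bias("ta") + stats::rnorm(m, 0, sig("ta")),
    vp = truth$vp[idx] + bias("vp") + stats::rnorm(m, 0, sig("vp")),
    tmrt = truth$tmrt[idx] + bias("tmrt") + stats::rnorm(m, 0, sig("tmrt"))
  ))
  structure(list(device = device, reference = ref, config = config),
            class = "reference_pair")
}
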