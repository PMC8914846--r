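# Three-node (core / skin / clothing) steady-state human energy balance and
# the PET equivalence search. Model constants follow the published
# steady-state PET formulation; saturation vapor pressure uses the same
# Magnus curve as the records module.

.memi <- list(
  sbc = 5.67e-8,    # Stefan-Boltzmann [W m-2 K-4]
  e_skin = 0.99,    # skin emissivity
  e_clo = 0.95,     # clothing emissivity
  h_vap = 2.42e6,   # latent heat of vaporisation [J kg-1]
  c_blood = 3640,   # blood specific heat [J kg-1 K-1]
  c_air = 1010,     # air specific heat [J kg-1 K-1]
  lewis = 1.67,     # Lewis ratio [K hPa-1]
  i_m = 0.38,       # Woodcock moisture permeability index
  p_atm = 1013.25,  # [hPa]
  tc_set = 36.6,    # core temperature set point [degC]
  tsk_set = 34      # skin temperature set point [degC]
)

#' Person, clothing and activity configuration for PET
#'
#' Defaults are the standardized person used for workplace monitoring: male,
#' 35 years, 1.75 m, 75 kg, wearing 0.9 clo and performing 80 W of work
#' metabolism (light activity in a business suit). Basal metabolism is added
#' internally from sex, age, height and weight.
#'
#' @param sex `"male"` or `"female"`
#' @param age age (years)
#' @param height body height (m), in (0.5, 2.5)
#' @param weight body mass (kg), in (20, 200)
#' @param clothing clothing insulation (clo); the clothing-layer geometry
#'   requires at least 0.1 clo
#' @param work_metabolism activity heat production above basal (W), >= 0
#' @return a list of class `person_config`
#' @export
person_config <- function(sex = c("male", "female"), age = 35, height = 1.75,
                          weight = 75, clothing = 0.9, work_metabolism = 80) {
  sex <- match.arg(sex)
  if (height <= 0.5 || height >= 2.5) stop("height must lie in (0.5, 2.5) m",
                                           call. = FALSE)
  if (weight <= 20 || weight >= 200) stop("weight must lie in (20, 200) kg",
                                          call. = FALSE)
  if (clothing < 0.1) stop("clothing must be >= 0.1 clo", call. = FALSE)
  if (work_metabolism < 0) stop("work_metabolism must be >= 0", call. = FALSE)
  structure(list(sex = sex, age = age, height = height, weight = weight,
                 clothing = clothing, work_metabolism = work_metabolism),
            class = "person_config")
}

.body_surface <- function(weight, height) 0.202 * weight^0.425 * height^0.725

.basal_metabolism <- function(person) {
  with(person, {
    if (sex == "female") {
      3.19 * weight^0.75 * (1 + 0.004 * (30 - age) +
                              0.018 * (height * 100 / weight^(1 / 3) - 42.1))
    } else {
      3.45 * weight^0.75 * (1 + 0.004 * (30 - age) +
                              0.010 * (height * 100 / weight^(1 / 3) - 43.4))
    }
  })
}

# Nodal energy balances [W m-2] for body state t_arr = (t_core, t_skin,
# t_clothing) in an environment (ta, vpa, tr, v) with clothing/activity
# (clo, work). Returns c(core, skin, clothing) residuals.
.memi_balance <- function(t_arr, ta, vpa, tr, v, clo, work, person) {
  k <- .memi
  t_cr <- t_arr[1]; t_sk <- t_arr[2]; t_clo <- t_arr[3]
  a_du <- .body_surface(person$weight, person$height)
  he <- (work + .basal_metabolism(person)) / a_du
  h <- he  # mechanical efficiency 0

  # respiratory heat losses
  t_exp <- 0.47 * ta + 21
  d_vent <- he * 1.44e-6
  c_res <- k$c_air * (ta - t_exp) * d_vent
  q_res <- 0.623 * k$h_vap / k$p_atm *
    (vpa - saturation_vapor_pressure(t_exp)) * d_vent
  ere <- c_res + q_res

  hc <- 2.67 + 6.5 * v^0.67  # convection coefficient, seated subject

  # clothing geometry: clothed fraction and cylindrical clothing layer
  fcl <- 1 + 0.31 * clo
  f_a_cl <- min((173.51 * clo - 2.36 - 100.76 * clo^2 + 19.28 * clo^3) / 100, 1)
  a_clo <- a_du * (f_a_cl + fcl - 1)
  f_eff <- 0.696  # effective radiative area factor, seated
  r_cl <- clo / 6.45
  y <- if (clo >= 2) 1 else if (clo > 0.6) (person$height - 0.2) / person$height
       else if (clo > 0.3) 0.5 else 0.1
  r2 <- a_du * (fcl - 1 + f_a_cl) / (6.28 * person$height * y)
  r1 <- f_a_cl * a_du / (6.28 * person$height * y)
  htcl <- 6.28 * person$height * y * (r2 - r1) / (r_cl * log(r2 / r1) * a_clo)

  # thermoregulation: skin blood flow and sweating
  sig_core <- max(t_cr - k$tc_set, 0)
  sig_skin <- max(k$tsk_set - t_sk, 0)
  m_blood <- min((6.3 + 75 * sig_core) / (1 + 0.5 * sig_skin), 90)
  alpha <- 0.0417737 + 0.7451833 / (m_blood + 0.585417)
  t_body <- alpha * t_sk + (1 - alpha) * t_cr
  t_body_set <- 0.1 * k$tsk_set + 0.9 * k$tc_set
  m_rsw <- min(304.94e-3 * max(t_body - t_body_set, 0), 500)  # [g m-2 h-1]
  esw <- k$h_vap / 1000 * m_rsw / 3600                        # [W m-2]

  # skin vapor diffusion and sweat evaporation
  e_sk <- saturation_vapor_pressure(t_sk)
  fecl <- 1 / (1 + 0.92 * hc * r_cl)
  e_max <- hc * k$lewis * fecl * (e_sk - vpa)
  if (e_max <= 0) {
    w <- 1; esw <- 0
  } else {
    w <- min(esw / e_max, 1); esw <- min(esw, e_max)
  }
  r_ecl <- (1 / (fcl * hc) + r_cl) / (k$lewis * k$i_m)
  ediff <- (1 - w) * (e_sk - vpa) / r_ecl
  evap <- -(esw + ediff)

  # radiative and convective exchange on bare and clothed fractions
  tr_k4 <- (tr + 273.15)^4
  r_bare <- f_eff * (1 - f_a_cl) * k$e_skin * k$sbc *
    (tr_k4 - (t_sk + 273.15)^4)
  r_clo <- f_eff * (a_clo / a_du) * k$e_clo * k$sbc *
    (tr_k4 - (t_clo + 273.15)^4)
  c_bare <- hc * (ta - t_sk) * (1 - f_a_cl)
  c_clo <- hc * (ta - t_clo) * a_clo / a_du

  cond <- 5.28 + k$c_blood * m_blood / 3600  # core-to-skin conductance
  c(core = h + ere - cond * (t_cr - t_sk),
    skin = r_bare + c_bare + evap + cond * (t_cr - t_sk) -
      htcl * (t_sk - t_clo),
    clothing = r_clo + c_clo + htcl * (t_sk - t_clo))
}

#' Solve the human energy balance for the body thermal state
#'
#' Finds the steady-state core, skin and clothing-surface temperatures that
#' zero the three nodal heat balances (metabolic heat, respiration,
#' radiation, convection, skin vapor diffusion and sweat evaporation) in the
#' given environment. Solved by damped Newton iteration with a numerical
#' Jacobian from the fixed initial state (37, 34, mean(ta, tmrt)) degrees C.
#'
#' @param ta air temperature (degrees C)
#' @param vp vapor pressure (hPa)
#' @param tmrt mean radiant temperature (degrees C)
#' @param v_eff effective wind speed (m/s), >= 0.1
#' @param person a [person_config()]
#' @param tol convergence tolerance on the balance residuals (W m-2)
#' @return a list of class `thermal_state` with elements `t_core`, `t_skin`,
#'   `t_clothing` (degrees C) and `residuals` (W m-2)
#' @export
solve_energy_balance <- function(ta, vp, tmrt, v_eff = 0.1,
                                 person = person_config(), tol = 1e-8) {
  if (v_eff < 0.1) stop("v_eff must be >= 0.1 m/s", call. = FALSE)
  clo <- person$clothing; work <- person$work_metabolism
  f <- function(x) .memi_balance(x, ta, vp, tmrt, v_eff, clo, work, person)
  x <- c(37, 34, mean(c(ta, tmrt)))
  fx <- f(x)
  for (iter in seq_len(60)) {
    if (max(abs(fx)) < tol) break
    jac <- matrix(0, 3, 3)
    hstep <- 1e-5
    for (j in 1:3) {
      xp <- x; xp[j] <- xp[j] + hstep
      xm <- x; xm[j] <- xm[j] - hstep
      jac[, j] <- (f(xp) - f(xm)) / (2 * hstep)
    }
    step <- tryCatch(solve(jac, fx), error = function(e) fx * 0.01)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- f(xn)
      if (sum(fn^2) < sum(fx^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn; fx <- fn
  }
  if (max(abs(fx)) >= 1e-3) {
    stop(sprintf(paste0("energy balance did not converge ",
                        "(residuals %.3g, %.3g, %.3g W m-2)"),
                 fx[1], fx[2], fx[3]), call. = FALSE)
  }
  structure(list(t_core = x[1], t_skin = x[2], t_clothing = x[3],
                 residuals = fx),
            class = "thermal_state")
}

#' Physiologically equivalent temperature (PET)
#'
#' PET is the air temperature of a reference indoor environment
#' (`tmrt = PET`, `v = 0.1` m/s, `vp = 12` hPa, 0.9 clo, 80 W work
#' metabolism) in which the body, held at the thermal state it attains in
#' the actual environment, is in overall energy balance. The actual-state
#' system is solved with [solve_energy_balance()]; the reference air
#' temperature is then found by bracketed root search over [-60, 90]
#' degrees C with 0.01 K tolerance.
#'
#' @inheritParams solve_energy_balance
#' @return PET (degrees C); vectorized over `ta`, `vp`, `tmrt`, `v_eff`
#' @export
#' @examples
#' pet(22, 12, 22, 0.1)  # ~22 by construction of the reference environment
pet <- function(ta, vp, tmrt, v_eff = 0.1, person = person_config()) {
  n <- max(length(ta), length(vp), length(tmrt), length(v_eff))
  ta <- rep_len(ta, n); vp <- rep_len(vp, n)
  tmrt <- rep_len(tmrt, n); v_eff <- rep_len(v_eff, n)
  ref_person <- person
  ref_person$clothing <- 0.9
  ref_person$work_metabolism <- 80
  vapply(seq_len(n), function(i) {
    if (is.na(ta[i]) || is.na(vp[i]) || is.na(tmrt[i])) return(NA_real_)
    st <- solve_energy_balance(ta[i], vp[i], tmrt[i], v_eff[i], person)
    state <- c(st$t_core, st$t_skin, st$t_clothing)
    ref_bal <- function(tx) {
      sum(.memi_balance(state, tx, 12, tx, 0.1, 0.9, 80, ref_person))
    }
    lo <- -60; hi <- 90
    if (ref_bal(lo) * ref_bal(hi) > 0) {
      stop("PET bracket [-60, 90] C failed; widen the search range",
           call. = FALSE)
    }
    stats::uniroot(ref_bal, c(lo, hi), tol = 1e-4)$root
  }, numeric(1))
}

.stress_breaks <- c(4, 8, 13, 18, 23, 29, 35, 41)

.stress_labels <- list(
  en = c("extreme cold stress", "strong cold stress", "moderate cold stress",
         "slight cold stress", "no thermal stress", "slight heat stress",
         "moderate heat stress", "strong heat stress", "extreme heat stress"),
  de = c("extremer Kältestress", "starker Kältestress",
         "mäßiger Kältestress", "leichter Kältestress",
         "kein thermischer Stress", "leichter Hitzestress",
         "mäßiger Hitzestress", "starker Hitzestress",
         "extremer Hitzestress"),
  fr = c("stress au froid extrême", "stress au froid fort",
         "stress au froid modéré", "stress au froid léger",
         "aucun stress thermique", "stress thermique léger",
         "stress thermique modéré", "stress thermique fort",
         "stress thermique extrême")
)

#' Thermophysiological stress level labels
#'
#' The nine ordered stress classes, from extreme cold stress to extreme heat
#' stress. English labels are the canonical serialized form; German and
#' French tables mirror the device display languages.
#'
#' @param lang `"en"`, `"de"` or `"fr"`
#' @return character vector of nine labels, cold to heat
#' @export
stress_levels <- function(lang = c("en", "de", "fr")) {
  .stress_labels[[match.arg(lang)]]
}

#' Classify PET into thermophysiological stress levels
#'
#' Assigns each PET value to one of nine stress classes with boundaries at
#' 4, 8, 13, 18, 23, 29, 35 and 41 degrees C. Intervals are left-closed,
#' right-open (e.g. no thermal stress is `[18, 23)`), the bottom class is
#' `(-Inf, 4)` and the top class `[41, Inf)`.
#'
#' @param pet PET values (degrees C)
#' @return ordered factor over the nine English labels
#' @export
#' @examples
#' classify_pet(c(20, 30, -5))
classify_pet <- function(pet) {
  idx <- findInterval(pet, .stress_breaks) + 1L
  factor(.stress_labels$en[idx], levels = .stress_labels$en, ordered = TRUE)
}

#' Compute thermal comfort for a stream of sensor records
#'
#' The device pipeline: derives vapor pressure, shortwave irradiance and
#' effective wind, estimates mean radiant temperature with the requested
#' method (or a preference order with fallback), solves the human energy
#' balance for PET, and classifies the result into stress levels. All
#' intermediate values are retained in the result.
#'
#' @param records a records `data.frame` (see [read_records()]); derived
#'   columns are added if absent
#' @param method a single method label (see [mrt_methods()]); ignored when
#'   `fallback` is given
#' @param person a [person_config()]
#' @param constants a [radiation_constants()] list
#' @param globe a [globe_spec()]
#' @param fallback optional character vector of method labels tried in order
#'   per record
#' @return an object of class `thermal_comfort`: a `data.frame` with the
#'   record channels plus `vp`, `sw`, `v_eff`, `tmrt`, `mrt_method`, `pet`
#'   and `stress`
#' @export
thermal_comfort <- function(records, method = "globe",
                            person = person_config(),
                            constants = radiation_constants(),
                            globe = globe_spec(), fallback = NULL) {
  if (!all(c("vp", "sw", "v_eff") %in% names(records))) {
    records <- derive_records(records, constants)
  }
  if (is.null(fallback)) {
    est <- data.frame(tmrt = as.numeric(estimate_mrt(records, method,
                                                     constants, globe)),
                      method = rep(match.arg(method, mrt_methods()),
                                   nrow(records)),
                      stringsAsFactors = FALSE)
  } else {
    est <- estimate_mrt_fallback(records, fallback, constants, globe)
  }
  out <- records
  out$tmrt <- est$tmrt
  out$mrt_method <- if (nrow(out)) est$method else character(0)
  out$pet <- pet(out$ta, out$vp, out$tmrt, out$v_eff, person)
  out$stress <- classify_pet(out$pet)
  structure(out, person = person,
            class = c("thermal_comfort", "data.frame"))
}

#' @export
print.thermal_comfort <- function(x, ...) {
  cat("Thermal comfort series: ", nrow(x), " records",
      if (nrow(x)) paste0(", ", format(min(x$timestamp)), " .. ",
                          format(max(x$timestamp)), " UTC"), "\n", sep = "")
  if (nrow(x)) {
    cat(sprintf("  PET %.1f .. %.1f degC (median %.1f); methods: %s\n",
                min(x$pet, na.rm = TRUE), max(x$pet, na.rm = TRUE),
                stats::median(x$pet, na.rm = TRUE),
                paste(unique(x$mrt_method), collapse = ", ")))
  }
  utils::head(as.data.frame(x), 5) |> print()
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}

#' @export
summary.thermal_comfort <- function(object, ...) {
  freq <- stress_frequency(object, window = "full-day")
  structure(list(n = nrow(object),
                 pet_range = range(object$pet, na.rm = TRUE),
                 frequency = freq),
            class = "summary.thermal_comfort")
}

#' @export
print.summary.thermal_comfort <- function(x, ...) {
  cat("Thermal comfort summary over", x$n, "records\n")
  cat(sprintf("PET range: %.1f .. %.1f degC\n",
              x$pet_range[1], x$pet_range[2]))
  print(x$frequency)
  invisible(x)
}

#' @export
plot.thermal_comfort <- function(x, ...) {
  pal <- grDevices::hcl.colors(9, "RdBu", rev = TRUE)
  graphics::plot(x$timestamp, x$pet, type = "l", xlab = "time (UTC)",
                 ylab = "PET (degC)", ...)
  graphics::points(x$timestamp, x$pet, col = pal[as.integer(x$stress)],
                   pch = 16, cex = 0.5)
  graphics::abline(h = .stress_breaks, col = "grey85", lty = 3)
  invisible(x)
}
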