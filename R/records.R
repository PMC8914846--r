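# Canonical CSV column names <-> internal names. Order matters: it is the
# declared output column order.
.record_columns <- c(
  timestamp = "timestamp", device_id = "device_id",
  ta = "ta_c", rh = "rh_pct", tg = "tg_c", lw = "lw_wm2", tirt = "tirt_c",
  light = "light_lx", v = "wind_ms"
)
.derived_columns <- c(vp = "vp_hpa", sw = "sw_wm2", v_eff = "v_eff_ms")

#' Saturation vapor pressure over water (Magnus formula)
#'
#' WMO Magnus form, `e_s(t) = 6.112 exp(17.62 t / (243.12 + t))`, valid for
#' meteorological temperatures over liquid water.
#'
#' @param t air temperature (degrees C)
#' @return saturation vapor pressure (hPa)
#' @export
#' @examples
#' saturation_vapor_pressure(20) # ~23.4 hPa
saturation_vapor_pressure <- function(t) {
  stopifnot(is.numeric(t))
  if (any(t <= -273.15, na.rm = TRUE)) {
    stop("temperature below absolute zero", call. = FALSE)
  }
  6.112 * exp(17.62 * t / (243.12 + t))
}

#' Vapor pressure from relative humidity
#'
#' Converts a relative-humidity reading to water vapor pressure using the
#' Magnus saturation curve: `vp = rh/100 * e_s(ta)`.
#'
#' @param ta air temperature (degrees C)
#' @param rh relative humidity (percent, 0-100)
#' @return vapor pressure (hPa)
#' @export
#' @examples
#' vapor_pressure(25, 50) # ~15.8 hPa
vapor_pressure <- function(ta, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("relative humidity must be within [0, 100] %", call. = FALSE)
  }
  (rh / 100) * saturation_vapor_pressure(ta)
}

#' Effective wind speed with the indoor floor rule
#'
#' Workplace devices often carry no anemometer (indoor sites) or a cup
#' anemometer whose reading can be zero; for the globe conversion and the
#' energy balance, wind speed is floored at 0.1 m/s. An absent channel (`NA`
#' or `NULL`) is replaced by 0.1 m/s.
#'
#' @param v measured wind speed (m/s), may be `NA` or `NULL` when the channel
#'   is absent
#' @return effective wind speed, always >= 0.1 m/s
#' @export
#' @examples
#' effective_wind(NA)  # 0.1
#' effective_wind(0)   # 0.1
#' effective_wind(1.7) # 1.7
effective_wind <- function(v = NULL) {
  if (is.null(v)) return(0.1)
  if (length(v) == 0L) return(numeric(0))
  if (any(v < 0, na.rm = TRUE)) {
    stop("wind speed must be non-negative", call. = FALSE)
  }
  out <- pmax(v, 0.1)
  out[is.na(out)] <- 0.1
  out
}

.parse_timestamp <- function(x) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in fmts) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], f, tz = "UTC"))
  }
  out
}

.validate_records <- function(df, file = "<records>") {
  bad_rh <- which(!is.na(df$rh) & (df$rh < 0 | df$rh > 100))
  if (length(bad_rh)) {
    stop(sprintf("%s: relative humidity outside [0, 100] %% in row(s) %s",
                 file, paste(bad_rh, collapse = ", ")), call. = FALSE)
  }
  for (ch in c("light", "lw", "v")) {
    bad <- which(!is.na(df[[ch]]) & df[[ch]] < 0)
    if (length(bad)) {
      stop(sprintf("%s: negative %s in row(s) %s", file, ch,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  for (ch in c("ta", "tg", "tirt")) {
    bad <- which(!is.na(df[[ch]]) & df[[ch]] <= -273.15)
    if (length(bad)) {
      stop(sprintf("%s: %s below absolute zero in row(s) %s", file, ch,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a sensor-record CSV
#'
#' Reads the canonical comma-separated dialect (header row, ISO-8601 UTC
#' timestamps, columns `timestamp, device_id, ta_c, rh_pct, tg_c, lw_wm2,
#' tirt_c, light_lx, wind_ms`). Optional channels may be missing entirely or
#' left as empty cells; they come back as `NA`, never as sentinel numbers.
#' Records are returned sorted by timestamp.
#'
#' @param path path to a CSV file
#' @param schema optional named character vector mapping internal channel
#'   names (`ta`, `rh`, `tg`, `lw`, `tirt`, `light`, `v`, `timestamp`,
#'   `device_id`) to the column names used in the file; defaults to the
#'   canonical names
#' @return a `data.frame` with columns `timestamp` (POSIXct UTC),
#'   `device_id`, `ta`, `rh`, `tg`, `lw`, `tirt`, `light`, `v`
#' @export
read_records <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- .record_columns
  if (!is.null(schema)) cols[names(schema)] <- schema
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!cols[["timestamp"]] %in% names(raw)) {
    stop(path, ": missing timestamp column '", cols[["timestamp"]], "'",
         call. = FALSE)
  }
  n <- nrow(raw)
  ts <- .parse_timestamp(raw[[cols[["timestamp"]]]])
  if (n > 0 && anyNA(ts)) {
    stop(sprintf("%s: malformed timestamp in row(s) %s", path,
                 paste(which(is.na(ts)), collapse = ", ")), call. = FALSE)
  }
  num <- function(nm) {
    col <- cols[[nm]]
    if (!col %in% names(raw)) return(rep(NA_real_, n))
    x <- raw[[col]]
    x[!nzchar(trimws(x))] <- NA
    suppressWarnings(as.numeric(x))
  }
  df <- data.frame(
    timestamp = ts,
    device_id = if (cols[["device_id"]] %in% names(raw))
      raw[[cols[["device_id"]]]] else rep(NA_character_, n),
    ta = num("ta"), rh = num("rh"), tg = num("tg"), lw = num("lw"),
    tirt = num("tirt"), light = num("light"), v = num("v"),
    stringsAsFactors = FALSE
  )
  .validate_records(df, path)
  df <- df[order(df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write sensor records to CSV
#'
#' Writes the canonical CSV dialect; numeric channels are rounded to three
#' decimals (the declared round-trip precision), absent channels become empty
#' cells. Derived columns (`vp_hpa`, `sw_wm2`, `v_eff_ms`) are appended after
#' the raw channels when present, followed by any additional columns in the
#' input, in their declared order.
#'
#' @param records a records `data.frame` as returned by [read_records()] or
#'   [derive_records()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_records <- function(records, path) {
  known <- c(.record_columns, .derived_columns)
  extra <- setdiff(names(records), names(known))
  out <- list()
  fmt <- function(x) {
    if (inherits(x, "POSIXct")) return(format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
    if (is.numeric(x)) {
      s <- formatC(round(x, 3), format = "fg", digits = 15)
      s <- trimws(s)
      s[is.na(x)] <- ""
      return(s)
    }
    x[is.na(x)] <- ""
    x
  }
  for (nm in names(known)) {
    if (nm %in% names(records)) out[[known[[nm]]]] <- fmt(records[[nm]])
  }
  for (nm in extra) out[[nm]] <- fmt(records[[nm]])
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  # preserve header even for empty collections
  if (nrow(records) == 0L) df <- df[0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive per-record quantities
#'
#' Adds the derived channels every downstream stage needs: vapor pressure
#' `vp` (hPa) from `ta` and `rh`, approximated shortwave irradiance `sw`
#' (W/m2) from the light channel, and the effective wind speed `v_eff` after
#' the 0.1 m/s floor rule. Exactly one of `lw` / `tirt` may be stored on a
#' record; the other is filled in via the Stefan-Boltzmann law.
#'
#' @param records a records `data.frame` (see [read_records()])
#' @param constants a [radiation_constants()] list
#' @return the input with columns `vp`, `sw`, `v_eff` appended and the
#'   `lw`/`tirt` complement filled in
#' @export
derive_records <- function(records, constants = radiation_constants()) {
  .validate_records(records)
  need_lw <- is.na(records$lw) & !is.na(records$tirt)
  records$lw[need_lw] <- lw_from_brightness(records$tirt[need_lw], constants)
  need_ti <- is.na(records$tirt) & !is.na(records$lw)
  records$tirt[need_ti] <- brightness_temperature(records$lw[need_ti], constants)
  records$vp <- vapor_pressure(records$ta, records$rh)
  records$sw <- ifelse(is.na(records$light), NA_real_,
                       lux_to_sw(records$light, constants))
  records$v_eff <- effective_wind(records$v)
  records
}

#' Align two time series by nearest timestamp
#'
#' Pairs every record of the reference series `b` with the nearest-in-time
#' record of the test series `a`, within `tolerance`; unmatched records are
#' dropped and each test record is used at most once (ties resolved in
#' reference time order). This supports comparing instruments sampling on
#' different grids, e.g. a 5-min device against a 10-min reference.
#'
#' @param a test-device records (`data.frame` with a `timestamp` column),
#'   time-sorted
#' @param b reference records, time-sorted
#' @param tolerance maximum timestamp separation in seconds (default 150 s,
#'   i.e. +/- 2.5 min)
#' @return a `data.frame` with columns `timestamp` (the reference time),
#'   `a` and `b` (integer row indices into the inputs)
#' @export
align_series <- function(a, b, tolerance = 150) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      a = integer(), b = integer()))
  }
  ta <- as.numeric(a$timestamp)
  tb <- as.numeric(b$timestamp)
  used <- logical(length(ta))
  ia <- integer(0); ib <- integer(0)
  for (j in seq_along(tb)) {
    d <- abs(ta - tb[j])
    d[used] <- Inf
    i <- which.min(d)
    if (is.finite(d[i]) && d[i] <= tolerance) {
      used[i] <- TRUE
      ia <- c(ia, i); ib <- c(ib, j)
    }
  }
  data.frame(timestamp = b$timestamp[ib], a = ia, b = ib)
}
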