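#' Fit a per-sensor linear calibration
#'
#' Ordinary least squares of reference readings on raw sensor readings,
#' optionally discarding pairs whose reference value is at or above a
#' saturation cutoff (sensors such as lux meters saturate at the top of
#' their range). The calibration maps raw values to the reference scale.
#'
#' @param raw raw sensor readings
#' @param reference paired reference-instrument readings
#' @param saturation_cutoff optional upper bound; pairs with
#'   `reference >= saturation_cutoff` are excluded from the fit
#' @return an object of class `sensor_calibration` with elements `slope`,
#'   `intercept`, `valid_range` (raw-value extent of the fit) and `n`
#' @export
#' @examples
#' cal <- fit_calibration(1:10, 2 * (1:10) + 1)
#' coef(cal) # intercept 1, slope 2
fit_calibration <- function(raw, reference, saturation_cutoff = NULL) {
  keep <- !is.na(raw) & !is.na(reference)
  if (!is.null(saturation_cutoff)) keep <- keep & reference < saturation_cutoff
  raw <- raw[keep]; reference <- reference[keep]
  if (length(raw) < 2L) {
    stop("need at least 2 usable (raw, reference) pairs", call. = FALSE)
  }
  fit <- stats::lm(reference ~ raw)
  # a perfect (noise-free) fit is a legitimate calibration input; silence
  # summary.lm's reliability warning for that case
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 valid_range = range(raw), n = length(raw),
                 sigma = sm$sigma,
                 se = sm$coefficients[, "Std. Error"]),
            class = "sensor_calibration")
}

#' @export
coef.sensor_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
print.sensor_calibration <- function(x, ...) {
  cat(sprintf("Linear sensor calibration (n = %d pairs)\n", x$n))
  cat(sprintf("  calibrated = %.6g * raw + %.6g\n", x$slope, x$intercept))
  cat(sprintf("  valid raw range: [%.6g, %.6g]\n",
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Apply a linear calibration to raw values
#'
#' Maps raw readings onto the reference scale. Values outside the
#' calibration's fitted range are calibrated anyway (linear extrapolation)
#' but flagged through the `extrapolated` attribute of the result.
#'
#' @param value raw values
#' @param cal a [fit_calibration()] object
#' @return calibrated values with a logical attribute `extrapolated`
#' @export
apply_calibration <- function(value, cal) {
  out <- cal$slope * value + cal$intercept
  attr(out, "extrapolated") <-
    !is.na(value) & (value < cal$valid_range[1] | value > cal$valid_range[2])
  out
}

#' @export
predict.sensor_calibration <- function(object, newdata, ...) {
  apply_calibration(newdata, object)
}

#' Apply a per-channel calibration table to records
#'
#' @param records a records `data.frame`
#' @param table a named list mapping channel names (`ta`, `rh`, `tg`, `lw`,
#'   `light`, `v`) to [fit_calibration()] objects or `list(slope, intercept)`
#'   pairs
#' @return the records with the listed channels calibrated
#' @export
apply_calibration_table <- function(records, table) {
  for (ch in names(table)) {
    if (!ch %in% names(records)) next
    cal <- table[[ch]]
    if (!inherits(cal, "sensor_calibration")) {
      cal <- structure(list(slope = cal$slope %||% 1,
                            intercept = cal$intercept %||% 0,
                            valid_range = c(-Inf, Inf), n = 0L),
                       class = "sensor_calibration")
    }
    records[[ch]] <- as.numeric(apply_calibration(records[[ch]], cal))
  }
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a
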