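#' Error metrics between a test and a reference series
#'
#' Computes the four standard comparison statistics on the differences
#' `d = test - reference`: root mean square error, mean bias error, mean
#' absolute error and mean squared error. With this sign convention a
#' negative MBE means the test device underestimates the reference.
#'
#' @param test values from the device under test
#' @param reference paired reference values
#' @return a list of class `evaluation_metrics` with `rmse`, `mbe`, `mae`,
#'   `mse` and `n`
#' @export
#' @examples
#' error_metrics(c(1, -1), c(0, 0)) # rmse 1, mbe 0, mae 1, mse 1
error_metrics <- function(test, reference) {
  if (length(test) != length(reference)) {
    stop("test and reference must have equal length", call. = FALSE)
  }
  keep <- !is.na(test) & !is.na(reference)
  d <- test[keep] - reference[keep]
  if (length(d) == 0L) stop("no usable pairs", call. = FALSE)
  structure(list(rmse = sqrt(mean(d^2)), mbe = mean(d), mae = mean(abs(d)),
                 mse = mean(d^2), n = length(d)),
            class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("n = %d: RMSE %.3f, MBE %.3f, MAE %.3f, MSE %.3f\n",
              x$n, x$rmse, x$mbe, x$mae, x$mse))
  invisible(x)
}

#' Light-level-binned difference summaries
#'
#' Splits test-minus-reference differences by the test device's own light
#' channel into the bins 0 lx (exactly dark), 1-500 lx and >500 lx, and
#' summarises each bin as a Tukey box: quartiles, median, whiskers at the
#' most extreme points within 1.5 IQR of the box, and count.
#'
#' @param diff differences, test minus reference
#' @param light light level of the test device (lx), same length
#' @return a `data.frame` with one row per non-empty bin: `bin`, `n`,
#'   `lower_whisker`, `q1`, `median`, `q3`, `upper_whisker`
#' @export
binned_differences <- function(diff, light) {
  if (length(diff) != length(light)) {
    stop("diff and light must have equal length", call. = FALSE)
  }
  keep <- !is.na(diff) & !is.na(light)
  diff <- diff[keep]; light <- light[keep]
  bin <- cut(light, breaks = c(-Inf, 0, 500, Inf),
             labels = c("0 lx", "1-500 lx", ">500 lx"), right = TRUE)
  out <- lapply(levels(bin), function(b) {
    d <- diff[bin == b]
    if (length(d) == 0L) return(NULL)
    st <- grDevices::boxplot.stats(d, coef = 1.5)
    data.frame(bin = b, n = length(d),
               lower_whisker = st$stats[1], q1 = st$stats[2],
               median = st$stats[3], q3 = st$stats[4],
               upper_whisker = st$stats[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Frequency of thermophysiological stress levels
#'
#' Fraction of records (percent) in each of the nine stress classes, over
#' the whole series or restricted to daytime working hours, the half-open
#' window [08:00, 18:00) UTC.
#'
#' @param results a [thermal_comfort()] object, or a `data.frame` with
#'   columns `timestamp` and `stress`
#' @param window `"full-day"` or `"working-hours"`
#' @return a `data.frame` with columns `stress`, `pct` (summing to 100) and
#'   `window`
#' @export
stress_frequency <- function(results, window = c("full-day", "working-hours")) {
  window <- match.arg(window)
  if (nrow(results) == 0L) stop("no records", call. = FALSE)
  keep <- rep(TRUE, nrow(results))
  if (window == "working-hours") {
    hr <- as.integer(format(results$timestamp, "%H", tz = "UTC"))
    keep <- hr >= 8 & hr < 18
    if (!any(keep)) stop("no records inside working hours", call. = FALSE)
  }
  stress <- factor(results$stress[keep], levels = stress_levels())
  tab <- table(stress)
  data.frame(stress = names(tab),
             pct = 100 * as.numeric(tab) / sum(tab),
             window = window, stringsAsFactors = FALSE)
}

#' Evaluate a device against a reference instrument
#'
#' Aligns a test-device comfort series with a reference series by nearest
#' timestamp and computes [error_metrics()] per channel, plus
#' light-binned mean-radiant-temperature differences where possible.
#'
#' @param device a [thermal_comfort()] object (or data.frame with
#'   `timestamp` and the compared channels)
#' @param reference a `data.frame` with `timestamp` and any of the channels
#'   `ta`, `vp`, `tmrt`, `pet`
#' @param tolerance alignment tolerance (seconds)
#' @return a list of class `comfort_evaluation`: per-channel metrics under
#'   `channels`, binned differences under `bins`, and the pair count `n`
#' @export
evaluate_against_reference <- function(device, reference, tolerance = 150) {
  pairs <- align_series(device, reference, tolerance)
  if (nrow(pairs) == 0L) {
    stop("no aligned pairs between device and reference series",
         call. = FALSE)
  }
  channels <- intersect(c("ta", "vp", "tmrt", "pet"),
                        intersect(names(device), names(reference)))
  mets <- lapply(channels, function(ch) {
    error_metrics(device[[ch]][pairs$a], reference[[ch]][pairs$b])
  })
  names(mets) <- channels
  bins <- NULL
  if ("tmrt" %in% channels && "light" %in% names(device)) {
    bins <- binned_differences(
      device$tmrt[pairs$a] - reference$tmrt[pairs$b],
      device$light[pairs$a])
  }
  structure(list(channels = mets, bins = bins, n = nrow(pairs)),
            class = "comfort_evaluation")
}

#' @export
print.comfort_evaluation <- function(x, ...) {
  cat("Device-vs-reference evaluation over", x$n, "aligned pairs\n")
  for (ch in names(x$channels)) {
    cat(sprintf("  %-5s ", ch)); print(x$channels[[ch]])
  }
  if (!is.null(x$bins)) {
    cat("T_mrt differences by light level:\n"); print(x$bins)
  }
  invisible(x)
}
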