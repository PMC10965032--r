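#' True thermal age at emergence of an individual insect
#'
#' The "true k" of an individual reared at a constant temperature: observed
#' development time multiplied by the temperature excess over the lower
#' developmental threshold.
#'
#' @param time_days Development time in days (> 0).
#' @param temp_c Constant rearing temperature, deg C; must exceed `d0`.
#' @param d0 Lower developmental threshold, deg C.
#' @param unit `"ADD"` (default) or `"ADH"` (degree-hours, 24 x ADD).
#' @return Thermal age in the requested unit.
#' @examples
#' true_k(3.5, 20, 8.5)        # 40.25 ADD
#' true_k(10, 25, 10, "ADH")   # 3600 ADH
#' @export
true_k <- function(time_days, temp_c, d0, unit = c("ADD", "ADH")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(time_days), all(time_days > 0))
  if (any(temp_c <= d0)) {
    stop("no development at or below the lower developmental threshold",
         call. = FALSE)
  }
  out <- time_days * (temp_c - d0)
  if (unit == "ADH") out <- out * 24
  out
}

#' Convert accumulated degree-days to days at a constant temperature
#'
#' @param add Accumulated degree-days.
#' @param temp_c Constant temperature, deg C; must exceed `d0`.
#' @param d0 Lower developmental threshold, deg C.
#' @return Equivalent time in days: `add / (temp_c - d0)`.
#' @examples
#' dd_to_days(25, 20, 11.7)  # ~3 days
#' dd_to_days(40, 20, 8.5)   # ~3.5 days
#' @export
dd_to_days <- function(add, temp_c, d0) {
  stopifnot(is.numeric(add), all(add >= 0))
  if (any(temp_c <= d0)) {
    stop("no development at or below the lower developmental threshold",
         call. = FALSE)
  }
  add / (temp_c - d0)
}

#' Temperature log
#'
#' An ordered series of temperature readings with a declared sampling step,
#' the raw material for degree-day accumulation during laboratory rearing or
#' at a scene.
#'
#' @param timestamp `POSIXct` vector (or numeric hours), strictly increasing.
#' @param temp_c Temperatures in deg C, one per timestamp.
#' @param step_hours Sampling step in hours; inferred from the median
#'   timestamp spacing when omitted.
#' @return A `"temp_log"` data frame with columns `timestamp`, `temp_c` and a
#'   `step_hours` attribute.
#' @export
temperature_log <- function(timestamp, temp_c, step_hours = NULL) {
  stopifnot(length(timestamp) == length(temp_c), is.numeric(temp_c))
  if (length(timestamp) > 1) {
    d <- diff(as.numeric(timestamp))
    if (any(d <= 0)) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
    if (is.null(step_hours)) {
      step_hours <- if (inherits(timestamp, "POSIXct")) {
        stats::median(d) / 3600
      } else {
        stats::median(d)
      }
    }
  }
  if (is.null(step_hours)) {
    stop("step_hours must be given for logs with fewer than 2 readings",
         call. = FALSE)
  }
  stopifnot(step_hours > 0)
  structure(
    data.frame(timestamp = timestamp, temp_c = temp_c),
    step_hours = step_hours,
    class = c("temp_log", "data.frame")
  )
}

#' Read a temperature log from CSV
#'
#' Expects columns `timestamp` (ISO-8601) and `temp_c`.
#'
#' @param path CSV file path.
#' @param tz Time zone for parsing timestamps.
#' @param step_hours Optional explicit sampling step (hours).
#' @return A `"temp_log"` object.
#' @export
read_temperature_log <- function(path, tz = "UTC", step_hours = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "temp_c") %in% names(df))) {
    stop("temperature log CSV needs columns 'timestamp' and 'temp_c'",
         call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  temperature_log(ts, df$temp_c, step_hours = step_hours)
}

#' Accumulate degree-days over a temperature log
#'
#' Rectangular integration with clamping at the threshold: each reading
#' contributes `max(temp - d0, 0) * step / 24` degree-days. Never negative,
#' additive over concatenated logs, and monotone non-decreasing in log
#' length. (At the constant temperatures used in development studies this
#' coincides with trapezoidal integration.)
#'
#' @param log A [temperature_log()].
#' @param d0 Lower developmental threshold, deg C.
#' @return Accumulated degree-days (ADD).
#' @examples
#' lg <- temperature_log(seq_len(84), rep(20, 84), step_hours = 1)
#' accumulate_dd(lg, 8.5)  # 40.25 ADD
#' @export
accumulate_dd <- function(log, d0) {
  stopifnot(inherits(log, "temp_log"))
  if (nrow(log) == 0) {
    warning("empty temperature log: 0 ADD accumulated", call. = FALSE)
    return(0)
  }
  step <- attr(log, "step_hours")
  sum(pmax(log$temp_c - d0, 0)) * step / 24
}

#' Physiological age at collection
#'
#' When live insects collected as evidence are reared to emergence in the
#' laboratory, their thermal age at the moment of collection is the
#' (calibrated) thermal summation value minus the thermal time accumulated
#' during rearing.
#'
#' @param k_c Thermal summation value (possibly calibrated), in `unit`.
#' @param rearing Thermal time accumulated during laboratory rearing, in
#'   `rearing_unit`.
#' @param unit,rearing_unit Units of the two quantities; must match.
#' @return `k_c - rearing`. A negative result cannot be a real collection
#'   age; it is returned with a warning and an `"inconsistent"` attribute so
#'   the input contradiction is visible to the caller.
#' @export
age_at_collection <- function(k_c, rearing, unit = "ADD",
                              rearing_unit = unit) {
  if (unit != rearing_unit) {
    stop(sprintf("unit mismatch: k_c in %s but rearing in %s",
                 unit, rearing_unit), call. = FALSE)
  }
  out <- k_c - rearing
  if (any(out < 0)) {
    warning("negative age at collection: rearing thermal time exceeds Kc; inputs are inconsistent",
            call. = FALSE)
    attr(out, "inconsistent") <- out < 0
  }
  out
}

#' Fit a linear thermal summation model from constant-temperature rearings
#'
#' The classical linear degree-day model: development rate `1/time` is
#' regressed on rearing temperature; then `k = 1/slope` and
#' `d0 = -intercept/slope`. The standard error of `k` follows by first-order
#' error propagation from the slope's standard error
#' (`se_k = se_slope / slope^2`); this propagation is a convention of this
#' fitter, since published thermal summation models do not always state how
#' their standard errors were obtained. `m` is the number of distinct
#' temperatures.
#'
#' @param temp_c Rearing temperature per individual (deg C).
#' @param dev_days Development time per individual (days, > 0).
#' @param unit Output unit for `k`.
#' @return A [thermal_summation_params()] object with `d0` filled in.
#' @examples
#' tt <- rep(c(14, 17, 20, 23, 26), each = 3)
#' fit_thermal_summation(tt, 400 / (tt - 10))  # recovers k = 400, d0 = 10
#' @export
fit_thermal_summation <- function(temp_c, dev_days, unit = c("ADD", "ADH")) {
  unit <- match.arg(unit)
  stopifnot(length(temp_c) == length(dev_days), all(dev_days > 0))
  m <- length(unique(temp_c))
  if (m < 3) {
    stop("thermal summation fit needs at least 3 distinct temperatures",
         call. = FALSE)
  }
  rate <- 1 / dev_days
  fit <- stats::lm(rate ~ temp_c)
  b <- unname(stats::coef(fit)[2])
  a <- unname(stats::coef(fit)[1])
  if (!is.finite(b) || b <= 0) {
    stop("non-positive rate-temperature slope: no thermal response",
         call. = FALSE)
  }
  # slope standard error from first principles (summary.lm warns on an
  # exactly collinear fit, which is a legitimate input here)
  rss <- sum(stats::residuals(fit)^2)
  sxx <- sum((temp_c - mean(temp_c))^2)
  se_b <- sqrt(rss / fit$df.residual / sxx)
  k <- 1 / b
  se_k <- se_b / b^2
  if (unit == "ADH") {
    k <- k * 24
    se_k <- se_k * 24
  }
  thermal_summation_params(k, se_k, m, unit = unit, d0 = -a / b)
}
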