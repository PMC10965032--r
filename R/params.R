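#' Thermal summation parameters for a species
#'
#' Bundles the species-level development constants of the linear thermal
#' summation model: the thermal summation constant `k` (mean physiological
#' age at adult emergence, in accumulated degree-days or degree-hours), its
#' standard error, and the number of constant rearing temperatures the model
#' was derived from.
#'
#' @param k Thermal summation constant (ADD or ADH). Must be positive.
#' @param se Standard error of `k`, in the same unit. Must be non-negative.
#' @param m Number of constant experimental temperatures used to derive `k`.
#'   A thermal summation regression needs at least two temperatures.
#' @param unit `"ADD"` (accumulated degree-days) or `"ADH"` (accumulated
#'   degree-hours).
#' @param d0 Optional lower developmental threshold (base temperature, deg C)
#'   below which no thermal time accumulates.
#'
#' @return An object of class `"ts_params"`.
#' @examples
#' thermal_summation_params(k = 469.89, se = 24.59, m = 8, unit = "ADD",
#'                          d0 = 8.5)
#' @export
thermal_summation_params <- function(k, se, m, unit = c("ADD", "ADH"),
                                     d0 = NULL) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0)
  stopifnot(is.numeric(se), length(se) == 1L, is.finite(se), se >= 0)
  stopifnot(is.numeric(m), length(m) == 1L, m >= 2, m == round(m))
  if (!is.null(d0)) {
    stopifnot(is.numeric(d0), length(d0) == 1L, is.finite(d0))
  }
  structure(
    list(k = k, se = se, m = as.integer(m), unit = unit, d0 = d0),
    class = "ts_params"
  )
}

#' @export
print.ts_params <- function(x, ...) {
  cat(sprintf("Thermal summation parameters: k = %g %s (SE %g), m = %d\n",
              x$k, x$unit, x$se, x$m))
  if (!is.null(x$d0)) cat(sprintf("  lower developmental threshold D0 = %g degC\n", x$d0))
  invisible(x)
}

#' Convert thermal summation parameters between ADD and ADH
#'
#' Degree-hours are degree-days times 24; `k` and its standard error scale
#' together, so the calibration line scales by exactly 24 at every length.
#'
#' @param params A [thermal_summation_params()] object.
#' @param to Target unit, `"ADD"` or `"ADH"`.
#' @return A `"ts_params"` object in the target unit.
#' @export
convert_unit <- function(params, to = c("ADD", "ADH")) {
  to <- match.arg(to)
  stopifnot(inherits(params, "ts_params"))
  if (params$unit == to) return(params)
  f <- if (to == "ADH") 24 else 1 / 24
  thermal_summation_params(params$k * f, params$se * f, params$m,
                           unit = to, d0 = params$d0)
}

#' Adult body-length range of a species
#'
#' The minimal and maximal adult body length (mm) reported for a species or
#' population, typically retrieved from the taxonomic literature. The range
#' stands in for the natural size variation of the population when no
#' individual-level size data are available.
#'
#' @param l_min,l_max Minimal and maximal length in mm; `0 < l_min < l_max`.
#' @param source Free-text citation label for the range.
#' @return An object of class `"size_range"`.
#' @examples
#' size_range(15, 25, source = "key to central European Silphidae")
#' @export
size_range <- function(l_min, l_max, source = NA_character_) {
  stopifnot(is.numeric(l_min), length(l_min) == 1L, is.finite(l_min))
  stopifnot(is.numeric(l_max), length(l_max) == 1L, is.finite(l_max))
  if (!(l_min > 0)) stop("l_min must be positive", call. = FALSE)
  if (!(l_max > l_min)) {
    stop("degenerate size range: l_max must exceed l_min", call. = FALSE)
  }
  structure(
    list(l_min = l_min, l_max = l_max, source = as.character(source)),
    class = "size_range"
  )
}

#' @export
print.size_range <- function(x, ...) {
  src <- if (is.na(x$source)) "" else sprintf(" [%s]", x$source)
  cat(sprintf("Size range: %g-%g mm%s\n", x$l_min, x$l_max, src))
  invisible(x)
}

range_width <- function(range) range$l_max - range$l_min
range_mid <- function(range) (range$l_max + range$l_min) / 2
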