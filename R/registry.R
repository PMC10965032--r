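#' Load the packaged species registry
#'
#' The registry holds, for eleven forensically important carrion insects of
#' central Europe, the published thermal summation constant `k` with its
#' standard error and unit, the number of experimental temperatures `m`
#' (recovered from the published calibration lines via [infer_m()]), the
#' adult size range used for calibration, the species' ecology, the assumed
#' sign of the length / true-k correlation (negative for necrophagous and
#' predatory species, positive for parasitoids), an optional lower
#' developmental threshold, and the published line coefficients kept for
#' cross-checking.
#'
#' The registry is a plain CSV (mirrored as JSON) so users can substitute
#' size ranges for the geographic population closest to their casework.
#'
#' @param path Path to a registry CSV or JSON; defaults to the packaged file.
#' @return A data frame of class `"species_registry"`.
#' @examples
#' species_registry()
#' @export
species_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "species_registry.csv", package = "kcalib")
  }
  reg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c("species", "family", "k", "se", "unit", "m", "l_min", "l_max",
              "range_source", "ecology", "corr_sign", "d0")
  missing <- setdiff(needed, names(reg))
  if (length(missing)) {
    stop("registry is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  class(reg) <- c("species_registry", "data.frame")
  reg
}

#' Packaged multi-source size ranges
#'
#' Adult body-length ranges reported by different literature sources for the
#' registry species, as a data frame with columns `species`, `l_min`,
#' `l_max`, `source`. Feed a species' rows to [choose_size_range()] to apply
#' the broadest-range rule.
#'
#' @param path Optional CSV path; defaults to the packaged file.
#' @return A data frame.
#' @export
species_size_ranges <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "size_ranges.csv", package = "kcalib")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Correlation sign implied by a species' ecology
#'
#' Age and size at maturity are usually negatively correlated in phytophagous
#' and predatory insects and positively correlated in parasitoids; carrion
#' entomology extends the negative sign to necrophagous species. The mapping
#' is an assumption (encoded as data, overridable per registry entry), not an
#' established law.
#'
#' @param ecology `"necrophagous"`, `"predatory"`, or `"parasitoid"`.
#' @return `"positive"` for parasitoids, `"negative"` otherwise.
#' @export
correlation_sign_for_ecology <- function(ecology) {
  ecology <- match.arg(ecology, c("necrophagous", "predatory", "parasitoid"))
  if (ecology == "parasitoid") "positive" else "negative"
}

#' Retrieve one species from the registry as a structured entry
#'
#' @param species Species name, matched exactly (case-insensitive).
#' @param registry A [species_registry()]; defaults to the packaged one.
#' @return A `"species_entry"` list with `species`, `family`, `params`
#'   ([thermal_summation_params()]), `range` ([size_range()]), `ecology`,
#'   `correlation_sign`, and `printed_line` (published coefficients, if any).
#' @export
species_entry <- function(species, registry = species_registry()) {
  i <- match(tolower(species), tolower(registry$species))
  if (is.na(i)) {
    stop(sprintf("species '%s' not found in the registry", species),
         call. = FALSE)
  }
  row <- registry[i, ]
  d0 <- if (is.na(row$d0)) NULL else row$d0
  printed <- NULL
  if (!is.null(row$printed_intercept) && !is.na(row$printed_intercept)) {
    printed <- list(intercept = row$printed_intercept,
                    slope = row$printed_slope)
  }
  structure(
    list(species = row$species,
         family = row$family,
         params = thermal_summation_params(row$k, row$se, row$m,
                                           unit = row$unit, d0 = d0),
         range = size_range(row$l_min, row$l_max, source = row$range_source),
         ecology = row$ecology,
         correlation_sign = row$corr_sign,
         printed_line = printed),
    class = "species_entry"
  )
}

#' @export
print.species_entry <- function(x, ...) {
  cat(sprintf("%s (%s), %s, %s correlation\n", x$species, x$family,
              x$ecology, x$correlation_sign))
  print(x$params)
  print(x$range)
  invisible(x)
}

#' Recover the number of experimental temperatures from a published line
#'
#' The calibration formula needs `m`, the number of temperatures behind the
#' thermal summation model, but published species tables print only the line
#' coefficients. Since `|slope| = se * sqrt(3 m) / (l_max - l_min)`, `m` is
#' recoverable by brute-force inversion over small integers.
#'
#' @param slope_magnitude Published absolute slope (thermal units per mm).
#' @param se Standard error of k.
#' @param range The [size_range()] the line was built on.
#' @param search_max Largest `m` considered.
#' @return A list with `m`, `fitted_slope` (slope implied by the recovered
#'   `m`), `residual`, and `rel_residual` (residual / published slope).
#'   A relative residual above 0.5% warns: the inversion is then suspect
#'   (wrong range, rounded inputs, or a different formula). A tie between two
#'   `m` values is an error listing both rather than a silent choice.
#' @examples
#' infer_m(12.05, 24.59, size_range(15, 25))  # m = 8
#' @export
infer_m <- function(slope_magnitude, se, range, search_max = 30) {
  stopifnot(slope_magnitude > 0, se > 0, inherits(range, "size_range"))
  m <- 2:search_max
  resid <- abs(slope_magnitude - se * sqrt(3 * m) / range_width(range))
  best <- which(resid == min(resid))
  if (length(best) > 1) {
    stop(sprintf("inversion tie between m = %s", paste(m[best], collapse = " and ")),
         call. = FALSE)
  }
  rel <- resid[best] / slope_magnitude
  if (rel > 0.005) {
    warning(sprintf(
      "poor m inversion: residual %.3g (%.2f%% of slope); inputs may not match the published line",
      resid[best], 100 * rel), call. = FALSE)
  }
  list(m = m[best],
       fitted_slope = se * sqrt(3 * m[best]) / range_width(range),
       residual = resid[best],
       rel_residual = rel)
}

#' Calibration line for a registry species
#'
#' Builds the size-calibration line for a species from its registry entry
#' (thermal constants, selected size range, ecology-derived correlation
#' sign). For all negative-correlation species the result matches the
#' published coefficients at printed precision. For *Nasonia vitripennis*
#' (positive correlation) only the published slope magnitude is reproduced:
#' the published intercept equals the negative-sign construction
#' `k + |slope| * midpoint` and is internally inconsistent with its positive
#' slope (the printed line never passes through `k` on the size range), so
#' the line is computed from first principles instead.
#'
#' @param entry A `"species_entry"` or a species name to look up.
#' @param registry Registry used when `entry` is a name.
#' @return A `"kc_line"` object.
#' @examples
#' species_formula("Necrodes littoralis")  # Kc(l) = 710.82 - 12.05 l
#' @export
species_formula <- function(entry, registry = species_registry()) {
  if (is.character(entry)) entry <- species_entry(entry, registry)
  stopifnot(inherits(entry, "species_entry"))
  calibration_line(entry$params, entry$range,
                   correlation_sign = entry$correlation_sign)
}

#' Choose a size range by the broadest-range rule
#'
#' When several literature sources give different size ranges for the same or
#' nearby populations, the broadest range should be used: it represents the
#' natural size variation with the highest probable accuracy. Ties on width
#' are broken toward the larger `l_max` (a convention of this package,
#' consistent with the published table's choices) with a warning.
#'
#' @param ranges A list of [size_range()] objects.
#' @return The selected `"size_range"`.
#' @examples
#' choose_size_range(list(size_range(15, 25), size_range(15, 23),
#'                        size_range(15, 24), size_range(12, 18)))
#' @export
choose_size_range <- function(ranges) {
  if (length(ranges) == 0) stop("no size ranges supplied", call. = FALSE)
  stopifnot(all(vapply(ranges, inherits, logical(1), "size_range")))
  widths <- vapply(ranges, range_width, numeric(1))
  cand <- which(widths == max(widths))
  if (length(cand) > 1) {
    warning("size-range width tie; preferring the range with the larger l_max",
            call. = FALSE)
    lmaxes <- vapply(ranges[cand], function(r) r$l_max, numeric(1))
    cand <- cand[which.max(lmaxes)]
  }
  ranges[[cand[1]]]
}
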