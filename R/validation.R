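#' Read individual insect records from CSV
#'
#' Expects columns `species`, `length_mm`, `true_k`, `unit`, and optionally
#' `sex`, `temp_c`, `dev_days`.
#'
#' @param path CSV file path.
#' @return A data frame of individual records.
#' @export
read_insect_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("species", "length_mm", "true_k", "unit")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("insect record CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Snap lengths to a measurement grid
#'
#' Development datasets record length with half-millimetre accuracy; lengths
#' are snapped to the nearest grid value before binning so that class
#' membership is deterministic. Ties at the bin midpoint round half up.
#'
#' @param l Lengths in mm.
#' @param grid Grid step in mm (default 0.5).
#' @return Snapped lengths.
#' @export
snap_length <- function(l, grid = 0.5) {
  floor(l / grid + 0.5) * grid
}

#' Bin individual records into length classes
#'
#' Groups individuals sharing one (grid-snapped) length value into a class
#' and summarizes each class by the median of its true-k values. Medians are
#' used because most individuals sit in classes near the mean length while
#' extreme classes are sparse; fitting to raw individuals would let the
#' crowded central classes dominate.
#'
#' @param records Data frame with `length_mm` and `true_k` columns.
#' @param grid Measurement grid step in mm.
#' @return A data frame of class `"length_classes"` with columns `length_mm`
#'   (ascending), `median_k`, `n`, and the per-class member values in the
#'   `"members"` attribute. Records with missing true-k are dropped with a
#'   warning.
#' @export
bin_by_length <- function(records, grid = 0.5) {
  stopifnot(is.data.frame(records),
            all(c("length_mm", "true_k") %in% names(records)))
  miss <- is.na(records$true_k)
  if (any(miss)) {
    warning(sprintf("excluding %d record(s) with missing true k", sum(miss)),
            call. = FALSE)
    records <- records[!miss, , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no usable records", call. = FALSE)
  len <- snap_length(records$length_mm, grid)
  members <- split(records$true_k, len)
  lengths <- as.numeric(names(members))
  ord <- order(lengths)
  members <- members[ord]
  classes <- data.frame(
    length_mm = lengths[ord],
    median_k = vapply(members, stats::median, numeric(1)),
    n = vapply(members, length, integer(1))
  )
  rownames(classes) <- NULL
  structure(classes, members = members,
            class = c("length_classes", "data.frame"))
}

#' Fit the three competing models to length-class medians
#'
#' The model comparison behind the formula's validation: (a) a reduced major
#' axis line fitted to the observed (class length, median true-k) pairs; (b)
#' the calibration line built from the species constants and the dataset's
#' own minimal and maximal lengths; (c) the "constant k" horizontal line.
#'
#' @param classes A [bin_by_length()] result (>= 3 classes).
#' @param params [thermal_summation_params()] for the species.
#' @param range Optional [size_range()]; by default the dataset's own
#'   min/max class lengths, matching how the validation was designed.
#' @param correlation_sign Passed to [calibration_line()].
#' @return A `"model_set"` list with elements `rma`, `kc`, `constant` (each
#'   with `intercept` and `slope`) and the `range` used.
#' @export
fit_three_models <- function(classes, params, range = NULL,
                             correlation_sign = c("negative", "positive")) {
  correlation_sign <- match.arg(correlation_sign)
  stopifnot(inherits(classes, "length_classes"))
  if (nrow(classes) < 3) {
    stop("need at least 3 length classes to compare models", call. = FALSE)
  }
  if (is.null(range)) {
    range <- size_range(min(classes$length_mm), max(classes$length_mm),
                        source = "dataset")
  }
  structure(
    list(rma = rma_fit(classes$length_mm, classes$median_k),
         kc = calibration_line(params, range, correlation_sign),
         constant = list(intercept = params$k, slope = 0),
         range = range),
    class = "model_set"
  )
}

#' @export
print.model_set <- function(x, ...) {
  cat("Model set:\n")
  cat(sprintf("  RMA:       y = %.4f %+.4f l\n", x$rma$intercept, x$rma$slope))
  cat(sprintf("  Kc:        y = %.4f %+.4f l\n", x$kc$intercept, x$kc$slope))
  cat(sprintf("  constant:  y = %.4f\n", x$constant$intercept))
  invisible(x)
}

#' Mean squared error of a line on length-class medians
#'
#' Unweighted by class size: weighting by membership would reintroduce the
#' central-class bias the medians were built to remove.
#'
#' @param classes A `"length_classes"` data frame.
#' @param model Any list with `intercept` and `slope`.
#' @return Mean over classes of `(median_k - model(length))^2`.
#' @export
mse <- function(classes, model) {
  stopifnot(nrow(classes) >= 1)
  pred <- model$intercept + model$slope * classes$length_mm
  mean((classes$median_k - pred)^2)
}

#' Per-class squared errors of every model in a set
#'
#' @param classes A `"length_classes"` data frame.
#' @param models A `"model_set"`.
#' @return Long data frame with columns `length_mm`, `model`, `sq_error`.
#' @export
squared_errors <- function(classes, models) {
  stopifnot(inherits(models, "model_set"))
  do.call(rbind, lapply(c("rma", "kc", "constant"), function(nm) {
    mod <- models[[nm]]
    data.frame(
      length_mm = classes$length_mm,
      model = nm,
      sq_error = (classes$median_k -
                    (mod$intercept + mod$slope * classes$length_mm))^2
    )
  }))
}

#' Keep only unusually small and large individuals
#'
#' Restricts a record set to the tails of the length distribution, where
#' calibration matters most: lengths strictly below the low percentile or
#' strictly above the high percentile. Percentiles use linear interpolation
#' between order statistics ([stats::quantile()] type 7); the realized
#' thresholds are attached so they can be checked against published cutoffs.
#'
#' @param records Data frame with a `length_mm` column.
#' @param low,high Percentiles in (0, 100), `low < high`. Defaults 33 and 66.
#' @return The subset, with a `"thresholds"` attribute `c(low =, high =)`.
#'   An empty subset (e.g. all lengths identical) is an error.
#' @export
extreme_subset <- function(records, low = 33, high = 66) {
  stopifnot(is.data.frame(records), "length_mm" %in% names(records))
  stopifnot(0 < low, low < high, high < 100)
  q <- stats::quantile(records$length_mm, c(low, high) / 100,
                       names = FALSE, type = 7)
  keep <- records$length_mm < q[1] | records$length_mm > q[2]
  if (!any(keep)) {
    stop("extreme subset is empty: no lengths beyond the percentile thresholds",
         call. = FALSE)
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "thresholds") <- c(low = q[1], high = q[2])
  out
}

#' Compare model squared errors by ANOVA with LSD post hoc tests
#'
#' One-way unpaired ANOVA on per-class squared errors with model as the
#' factor, followed by Fisher's Least Significant Difference post hoc test:
#' all pairwise two-sided t-tests using the pooled within-group variance
#' (the ANOVA residual mean square) on the residual degrees of freedom, with
#' Benjamini-Hochberg adjustment of the three pairwise p-values.
#'
#' @param errors Long data frame from [squared_errors()] (columns `model`,
#'   `sq_error`), three models with at least two classes each.
#' @return A `"model_comparison"` list: `mse` (named per-model means),
#'   `anova` (`F`, `p`, `df`), `pairwise` (data frame with `model_1`,
#'   `model_2`, `diff`, `t`, `p`, `p_adj`), and the input `errors`.
#' @export
compare_models_anova <- function(errors) {
  stopifnot(is.data.frame(errors),
            all(c("model", "sq_error") %in% names(errors)))
  errors$model <- factor(errors$model)
  groups <- split(errors$sq_error, errors$model)
  if (length(groups) != 3) {
    stop("expected exactly 3 models to compare", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each model needs at least 2 classes", call. = FALSE)
  }

  means <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, integer(1))
  nm <- names(groups)

  fit <- stats::aov(sq_error ~ model, data = errors)
  tab <- summary(fit)[[1]]
  msw <- tab["Residuals", "Mean Sq"]
  dfw <- tab["Residuals", "Df"]
  f_stat <- tab[1, "F value"]
  p_val <- tab[1, "Pr(>F)"]
  if (!is.finite(f_stat)) {  # zero variance everywhere
    f_stat <- 0; p_val <- 1
  }

  pairs <- utils::combn(nm, 2)
  pw <- vapply(seq_len(ncol(pairs)), function(j) {
    pr <- pairs[, j]
    d <- unname(means[pr[1]] - means[pr[2]])
    se <- sqrt(msw * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    t_stat <- if (se == 0) 0 else d / se
    c(d, t_stat, 2 * stats::pt(-abs(t_stat), dfw))
  }, numeric(3))
  pairwise <- data.frame(
    model_1 = pairs[1, ], model_2 = pairs[2, ],
    diff = pw[1, ], t = pw[2, ], p = pw[3, ]
  )
  pairwise$p_adj <- stats::p.adjust(pairwise$p, method = "BH")

  structure(
    list(mse = means, anova = list(F = f_stat, p = p_val,
                                   df = c(between = length(groups) - 1,
                                          within = dfw)),
         pairwise = pairwise, errors = errors),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison on per-class squared errors\n")
  cat("  MSE: ", paste(sprintf("%s = %.4g", names(x$mse), x$mse),
                       collapse = ", "), "\n")
  cat(sprintf("  ANOVA: F = %.4g on (%d, %d) df, p = %.4g\n",
              x$anova$F, x$anova$df["between"], x$anova$df["within"],
              x$anova$p))
  cat("  LSD pairwise (BH adjusted):\n")
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("    %s vs %s: diff = %.4g, p = %.4g, p_adj = %.4g\n",
                x$pairwise$model_1[i], x$pairwise$model_2[i],
                x$pairwise$diff[i], x$pairwise$p[i], x$pairwise$p_adj[i]))
  }
  invisible(x)
}

#' Run the full model-validation pipeline on individual records
#'
#' Optionally restricts to unusually small and large individuals, bins into
#' half-millimetre length classes, fits the RMA / calibration / constant-k
#' models, and compares their per-class squared errors by ANOVA with LSD
#' post hoc tests.
#'
#' @param records Data frame of individual records (`length_mm`, `true_k`).
#' @param params [thermal_summation_params()] for the species.
#' @param correlation_sign Passed to the calibration line.
#' @param extremes If `TRUE`, apply [extreme_subset()] first.
#' @param low,high Percentile cutoffs for the extreme subset.
#' @param range Optional fixed [size_range()] for the calibration line;
#'   defaults to the dataset's own min/max lengths.
#' @param grid Length grid step in mm.
#' @return A `"model_comparison"` with the fitted `models`, the `classes`,
#'   and (when `extremes`) the realized `thresholds` attached.
#' @examples
#' spec <- default_spec("N_littoralis")
#' rec <- generate_records(spec, seed = 1)
#' validate_models(rec, thermal_summation_params(469.89, 24.59, 8),
#'                 extremes = TRUE)
#' @export
validate_models <- function(records, params,
                            correlation_sign = c("negative", "positive"),
                            extremes = FALSE, low = 33, high = 66,
                            range = NULL, grid = 0.5) {
  correlation_sign <- match.arg(correlation_sign)
  thresholds <- NULL
  if (extremes) {
    records <- extreme_subset(records, low = low, high = high)
    thresholds <- attr(records, "thresholds")
  }
  classes <- bin_by_length(records, grid = grid)
  models <- fit_three_models(classes, params, range = range,
                             correlation_sign = correlation_sign)
  comp <- compare_models_anova(squared_errors(classes, models))
  comp$models <- models
  comp$classes <- classes
  comp$thresholds <- thresholds
  comp
}

#' Serialize a model comparison to JSON
#'
#' @param comparison A `"model_comparison"`.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
comparison_json <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "model_comparison"))
  obj <- list(
    mse = as.list(comparison$mse),
    anova = comparison$anova,
    pairwise = comparison$pairwise,
    thresholds = comparison$thresholds
  )
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
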