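#' Reduced major axis (model II) regression
#'
#' Fits the line `y = slope * x + intercept` by reduced major axis (RMA)
#' regression, the model II method appropriate when neither variable can be
#' singled out as the dependent one. The closed-form estimators are
#' `slope = sign(cor(x, y)) * sd(y) / sd(x)` and
#' `intercept = mean(y) - slope * mean(x)`; the fitted line minimizes the
#' summed unsigned product of vertical and horizontal residuals (see
#' [rma_loss()]). Standard deviations use the population (divide-by-n)
#' convention; the slope is unaffected (the n's cancel) and the convention
#' matches the sd/correlation algebra the calibration formula is built on.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return An object of class `"rma_fit"`: a list with `slope`, `intercept`,
#'   `n`, `correlation` (Pearson r), `sd_x`, `sd_y` (population sds),
#'   `mean_x`, `mean_y`.
#' @section Degenerate inputs:
#' `sd(x) = 0` (vertical line), `sd(y) = 0` (horizontal line) and
#' `cor(x, y) = 0` (the slope sign is indeterminate) are errors.
#' @examples
#' rma_fit(c(1, 2, 3, 4), c(2, 3, 5, 6))  # slope sqrt(2)
#' @export
rma_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 3) stop("RMA regression needs at least 3 points", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sdx <- sqrt(mean((x - mx)^2))
  sdy <- sqrt(mean((y - my)^2))
  if (sdx == 0) stop("sd(x) = 0: vertical degeneracy, RMA slope undefined",
                     call. = FALSE)
  if (sdy == 0) stop("sd(y) = 0: horizontal degeneracy, RMA slope undefined",
                     call. = FALSE)
  r <- mean((x - mx) * (y - my)) / (sdx * sdy)
  if (r == 0) stop("cor(x, y) = 0: slope sign indeterminate", call. = FALSE)
  slope <- sign(r) * sdy / sdx
  structure(
    list(slope = slope, intercept = my - slope * mx, n = n,
         correlation = r, sd_x = sdx, sd_y = sdy,
         mean_x = mx, mean_y = my),
    class = "rma_fit"
  )
}

#' @export
print.rma_fit <- function(x, digits = 4, ...) {
  cat(sprintf("RMA fit (n = %d): y = %s %s %s x   (r = %s)\n",
              x$n, format(round(x$intercept, digits)),
              if (x$slope < 0) "-" else "+",
              format(abs(round(x$slope, digits))),
              format(round(x$correlation, digits))))
  invisible(x)
}

#' @export
coef.rma_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' RMA product loss of a line on data
#'
#' The reduced major axis loss: the sum over points of the unsigned product
#' of the vertical residual `y - yhat` and the horizontal residual
#' `x - xhat`, where `yhat = slope * x + intercept` and
#' `xhat = (y - intercept) / slope`. Each term is the area of the rectangle
#' the point spans with the line, so the loss is non-negative and zero
#' exactly for collinear data. (The raw signed product has the constant sign
#' `-sign(slope)` for every point, since `x - xhat = -(y - yhat)/slope`.)
#' The closed-form [rma_fit()] minimizes this loss over all lines.
#'
#' @param x,y Numeric vectors.
#' @param line A `"rma_fit"`, `"kc_line"`, or any list with `slope` and
#'   `intercept`; `slope` must be non-zero.
#' @return The summed unsigned residual product.
#' @export
rma_loss <- function(x, y, line) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  slope <- line$slope; intercept <- line$intercept
  if (is.null(slope) || is.null(intercept)) {
    stop("line must have slope and intercept components", call. = FALSE)
  }
  if (slope == 0) stop("rma_loss undefined for a zero slope", call. = FALSE)
  yhat <- slope * x + intercept
  xhat <- (y - intercept) / slope
  sum(abs((y - yhat) * (x - xhat)))
}
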