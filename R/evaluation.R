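#' Agreement metrics between reference and pipeline measurements
#'
#' The three accuracy metrics used to benchmark CT trait extraction against
#' reference (threshing-machine or manual) measurements of the same
#' panicles: a coefficient of determination, the root mean square error and
#' the mean absolute percentage error. `x` holds the reference values and
#' `y` the CT pipeline values.
#'
#' `r_squared()` implements `1 - sum((x - y)^2) / sum((x - ybar)^2)` with
#' `ybar` the mean of the *pipeline* values `y` — the form in which the
#' statistic is defined for this benchmark (`center = "ct"`, the default).
#' The conventional coefficient, centering on `mean(x)`, is available with
#' `center = "reference"`; with it the statistic is invariant to common
#' shifts of both vectors, which the default form is not.
#'
#' @param x numeric reference measurements.
#' @param y numeric pipeline measurements, same length.
#' @param center `"ct"` (denominator centered on `mean(y)`) or
#'   `"reference"` (centered on `mean(x)`).
#' @return A single number; `mape()` is in percent.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))
#' rmse(c(0, 0), c(3, 4))
#' mape(c(50, 200), c(55, 180))
#' @export
r_squared <- function(x, y, center = c("ct", "reference")) {
  center <- match.arg(center)
  check_pairs(x, y)
  if (length(x) < 2L) stop("need at least 2 paired measurements")
  ctr <- if (center == "ct") mean(y) else mean(x)
  denom <- sum((x - ctr)^2)
  if (denom <= 0) stop("zero denominator: reference values equal the centering mean")
  1 - sum((x - y)^2) / denom
}

#' @rdname r_squared
#' @export
rmse <- function(x, y) {
  check_pairs(x, y)
  sqrt(sum((x - y)^2) / length(x))
}

#' @rdname r_squared
#' @export
mape <- function(x, y) {
  check_pairs(x, y)
  if (any(x == 0)) stop("MAPE undefined: reference contains zero values")
  100 * mean(abs(x - y) / x)
}

check_pairs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1L) stop("empty measurement vectors")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired measurements")
  invisible(TRUE)
}
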