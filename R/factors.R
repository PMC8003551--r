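#' Define an experimental factor
#'
#' A factor specification holds the natural (uncoded) range of one extraction
#' variable together with its units, and defines the linear map between
#' natural values and coded values: the centre of the range maps to 0 and the
#' half-range to one coded unit, so the low and high levels map to -1 and +1.
#' Coding is always ascending: the low natural level is -1 for every factor.
#'
#' @param name Human-readable factor name, e.g. `"temperature"`.
#' @param symbol Short symbol used in model terms, e.g. `"X1"`.
#' @param low,high Natural values of the low and high design levels
#'   (`low < high`).
#' @param units Measurement units, e.g. `"degC"`; must be non-empty.
#' @param center Natural value of the centre level. Defaults to the midpoint
#'   `(low + high) / 2`, which is the only centre consistent with symmetric
#'   three-level coding.
#'
#' @return An object of class `"factor_spec"`.
#' @seealso [code_value()], [decode_value()], [husk_factors()]
#' @examples
#' tempr <- factor_spec("temperature", "X1", 30, 100, "degC")
#' code_value(100, tempr)   # 1
#' decode_value(0.5, tempr) # 82.5
#' @export
factor_spec <- function(name, symbol, low, high, units,
                        center = (low + high) / 2) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(symbol), length(symbol) == 1L)
  if (!is.character(units) || length(units) != 1L || !nzchar(units))
    stop("'units' must be a non-empty string", call. = FALSE)
  low <- as.numeric(low); high <- as.numeric(high); center <- as.numeric(center)
  if (!(low < center && center < high))
    stop("factor levels must satisfy low < center < high", call. = FALSE)
  if (abs(center - (low + high) / 2) > 1e-9 * max(1, abs(high - low)))
    stop("'center' must be the midpoint of [low, high]", call. = FALSE)
  structure(list(name = name, symbol = symbol, low = low, center = center,
                 high = high, units = units),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s (%s): %g / %g / %g %s\n",
              x$symbol, x$name, x$low, x$center, x$high, x$units))
  invisible(x)
}

half_range <- function(factor) (factor$high - factor$low) / 2

#' Convert natural values to coded values
#'
#' Applies the coding transform `X = (x - x0) / dx`, where `x0` is the centre
#' of the factor's natural range and `dx` its half-range, so that the design
#' levels low/centre/high map to -1/0/+1.
#'
#' @param x Numeric vector of natural values.
#' @param factor A [factor_spec()].
#' @return Numeric vector of coded values.
#' @export
code_value <- function(x, factor) {
  stopifnot(inherits(factor, "factor_spec"))
  dx <- half_range(factor)
  if (dx <= 0) stop("invalid factor: zero half-range", call. = FALSE)
  (as.numeric(x) - factor$center) / dx
}

#' Convert coded values to natural values
#'
#' Inverse of [code_value()]: `x = x0 + X * dx`.
#'
#' @param X Numeric vector of coded values.
#' @param factor A [factor_spec()].
#' @return Numeric vector of natural values.
#' @export
decode_value <- function(X, factor) {
  stopifnot(inherits(factor, "factor_spec"))
  factor$center + as.numeric(X) * half_range(factor)
}

#' Factor set of the coffee-husk extraction study
#'
#' The four heat-assisted-extraction factors studied on the coffee husk:
#' temperature 30--100 degC, time 5--90 min, acidity 0--2 % citric acid and
#' solid-to-liquid ratio 0.02--0.05 g husk per mL water.
#'
#' @return A named list of four [factor_spec()] objects
#'   (`temperature`, `time`, `acidity`, `sl_ratio`).
#' @examples
#' fs <- husk_factors()
#' code_value(47.5, fs$time)  # 0
#' @export
husk_factors <- function() {
  list(
    temperature = factor_spec("temperature", "X1", 30, 100, "degC"),
    time        = factor_spec("time",        "X2", 5, 90, "min"),
    acidity     = factor_spec("acidity",     "X3", 0, 2, "% citric acid"),
    sl_ratio    = factor_spec("solid-to-liquid ratio", "X4", 0.02, 0.05,
                              "g/mL")
  )
}

check_factor_list <- function(factors) {
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop("'factors' must be a list of factor_spec objects", call. = FALSE)
  syms <- vapply(factors, `[[`, "", "symbol")
  if (anyDuplicated(syms)) stop("duplicated factor symbols", call. = FALSE)
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    names(factors) <- vapply(factors, `[[`, "", "name")
  factors
}
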