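#' Model-adequacy metrics
#'
#' Goodness-of-fit metrics comparing predicted with observed responses:
#' coefficient of determination (`r_squared`), root mean square error
#' (`rmse`, denominator `n`), and the absolute average deviation in percent
#' (`aad`). The default AAD is the mean absolute relative deviation with the
#' predicted value in the denominator,
#' \eqn{100 \cdot \frac{1}{n}\sum |Y_{pre} - Y_{exp}|/Y_{pre}};
#' `form = "squared"` instead averages the squared relative deviations
#' (no square root), a variant that appears in parts of the extraction
#' literature.
#'
#' @param pred Numeric vector of predictions.
#' @param obs Numeric vector of observations (same length).
#' @return A single number.
#' @examples
#' obs <- c(1, 2, 3); pred <- c(1.1, 1.9, 3.2)
#' r_squared(pred, obs)
#' rmse(pred, obs)
#' aad(pred, obs)
#' @export
r_squared <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("undefined metric: constant observations", call. = FALSE)
  1 - sum((pred - obs)^2) / sst
}

#' @rdname r_squared
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 1)
  sqrt(mean((pred - obs)^2))
}

#' @rdname r_squared
#' @param form `"mean"` (default, mean absolute relative deviation) or
#'   `"squared"` (mean of squared relative deviations).
#' @export
aad <- function(pred, obs, form = c("mean", "squared")) {
  form <- match.arg(form)
  stopifnot(length(pred) == length(obs))
  if (any(pred == 0)) stop("AAD undefined: zero prediction", call. = FALSE)
  rel <- abs(pred - obs) / pred
  100 * if (form == "mean") mean(rel) else mean(rel^2)
}

#' Compare response-surface and neural-network models
#'
#' Builds the model-comparison table: one row per response and method with
#' R-squared, RMSE and AAD computed from each model's predictions at the
#' design points.
#'
#' @param design A `design_table` with the response columns.
#' @param models Named list of lists: `models[[method]][[response]]` is a
#'   fitted model accepting `predict(model, newdata)`; for [rsm_quad()] fits
#'   the design's natural columns are used, for [mlp_surrogate()] fits
#'   likewise.
#' @return Data frame with columns `response`, `method`, `r2`, `rmse`, `aad`.
#' @examples
#' des <- coffee_husk_design()
#' full <- list(TPC = rsm_quad(des, "TPC"))
#' comparison_table(des, list(RSM = full))
#' @export
comparison_table <- function(design, models) {
  stopifnot(inherits(design, "design_table"), is.list(models))
  newdata <- as.data.frame(design)
  rows <- list()
  for (method in names(models)) {
    for (response in names(models[[method]])) {
      m <- models[[method]][[response]]
      if (is.null(m)) {
        warning("no ", method, " model for ", response, "; row omitted",
                call. = FALSE)
        next
      }
      if (!response %in% names(design)) {
        warning("response ", response, " not in design; row omitted",
                call. = FALSE)
        next
      }
      pred <- predict(m, newdata)
      obs <- design[[response]]
      rows[[length(rows) + 1L]] <-
        data.frame(response = response, method = method,
                   r2 = r_squared(pred, obs), rmse = rmse(pred, obs),
                   aad = aad(pred, obs), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
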