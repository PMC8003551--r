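#' One-sided (maximize) desirability transform
#'
#' Derringer-type ramp mapping a response value to \[0, 1\]: 0 at or below
#' the lower bound `L`, 1 at or above the target `T`, and
#' `((y - L) / (T - L))^weight` between.
#'
#' @param y Numeric response values.
#' @param L Lower bound (desirability 0).
#' @param T Target (desirability 1); must exceed `L`.
#' @param weight Positive exponent of the ramp (default 1, linear).
#' @return Numeric vector in \[0, 1\].
#' @examples
#' desirability(c(1, 1.5, 2), L = 1, T = 2)  # 0 0.5 1
#' @export
desirability <- function(y, L, T, weight = 1) {
  if (!(T > L)) stop("invalid bounds: need T > L", call. = FALSE)
  if (weight <= 0) stop("'weight' must be positive", call. = FALSE)
  d <- ((y - L) / (T - L))
  pmin(1, pmax(0, d))^weight
}

#' Maximize overall desirability over the factor space
#'
#' Multi-response optimization: each fitted model predicts its response over
#' the factor region, per-response desirabilities are combined as a
#' geometric mean (overall desirability D), and D is maximized by an
#' exhaustive grid search followed by a local quasi-Newton polish around the
#' best grid point. The search is deterministic for a fixed resolution.
#'
#' Unless goals are supplied, every response is maximized with `L` and `T`
#' set to its observed minimum and maximum in the design and weight 1.
#'
#' To expose near-tied optima (plateaus or twin peaks), the best grid point
#' at coded distance >= `separation` from the first optimum is polished as a
#' second candidate and reported alongside.
#'
#' @param models Named list of fitted models (one per response) accepting
#'   `predict(model, newdata)` with natural-unit columns.
#' @param design The `design_table` the models were fitted on (supplies the
#'   factor bounds and the default goal bounds).
#' @param goals Optional named list; each element a list with entries `L`,
#'   `T` and optionally `weight`, keyed by response.
#' @param resolution Grid points per axis (default 21).
#' @param separation Minimum coded Euclidean distance of the second
#'   optimum from the first (default 1).
#' @return Object of class `"desirability_opt"`: a data frame `optima` with
#'   the top-2 factor settings (natural units), their overall D, and
#'   per-response predictions; plus the goals used.
#' @examples
#' des <- coffee_husk_design()
#' fits <- lapply(c(TPC = "TPC", AC = "AC"), function(r) rsm_quad(des, r))
#' maximize_desirability(fits, des)
#' @export
maximize_desirability <- function(models, design, goals = NULL,
                                  resolution = 21, separation = 1) {
  stopifnot(length(models) >= 1, inherits(design, "design_table"))
  factors <- design_factors(design)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("'models' must be a named list keyed by response", call. = FALSE)
  if (is.null(goals)) {
    goals <- lapply(names(models), function(r) {
      y <- design[[r]]
      if (is.null(y)) stop("response ", r, " not in design", call. = FALSE)
      list(L = min(y), T = max(y), weight = 1)
    })
    names(goals) <- names(models)
  }
  for (g in goals) if (!(g$T > g$L)) stop("invalid goal bounds", call. = FALSE)

  k <- length(factors)
  grids <- lapply(factors, function(f) seq(f$low, f$high,
                                           length.out = resolution))
  grid <- do.call(expand.grid, grids)
  names(grid) <- names(factors)

  d_overall <- function(points) {
    dmat <- vapply(names(models), function(r) {
      g <- goals[[r]]
      w <- if (is.null(g$weight)) 1 else g$weight
      desirability(predict(models[[r]], points), g$L, g$T, w)
    }, numeric(nrow(points)))
    dmat <- matrix(dmat, nrow = nrow(points))
    exp(rowMeans(log(pmax(dmat, .Machine$double.xmin)))) *
      (apply(dmat > 0, 1, all))
  }
  D <- d_overall(grid)
  if (all(D == 0)) {
    warning("degenerate optimization: desirability is zero everywhere; ",
            "falling back to the sum of scaled predictions", call. = FALSE)
    score <- rowSums(vapply(names(models), function(r) {
      g <- goals[[r]]
      (predict(models[[r]], grid) - g$L) / (g$T - g$L)
    }, numeric(nrow(grid))))
    D <- score / max(abs(score))
  }

  codes <- function(points) {
    out <- vapply(seq_along(factors),
                  function(j) code_value(points[[names(factors)[j]]],
                                         factors[[j]]),
                  numeric(nrow(points)))
    matrix(out, nrow = nrow(points))
  }
  polish <- function(start_row) {
    x0 <- as.numeric(grid[start_row, ])
    lo <- vapply(factors, `[[`, 0, "low")
    hi <- vapply(factors, `[[`, 0, "high")
    step <- (hi - lo) / (resolution - 1)
    op <- stats::optim(x0, function(x) {
      pt <- as.data.frame(as.list(stats::setNames(x, names(factors))))
      -d_overall(pt)
    }, method = "L-BFGS-B",
       lower = pmax(lo, x0 - step), upper = pmin(hi, x0 + step))
    list(x = op$par, D = -op$value)
  }

  i1 <- which.max(D)
  o1 <- polish(i1)
  cd <- codes(grid)
  dist1 <- sqrt(rowSums((cd - matrix(cd[i1, ], nrow(grid), k,
                                     byrow = TRUE))^2))
  far <- which(dist1 >= separation)
  optima <- list(o1)
  if (length(far)) {
    i2 <- far[which.max(D[far])]
    optima <- c(optima, list(polish(i2)))
  }

  rows <- lapply(optima, function(o) {
    pt <- as.data.frame(as.list(stats::setNames(o$x, names(factors))))
    preds <- vapply(names(models), function(r) predict(models[[r]], pt), 0)
    cbind(pt, D = o$D, as.data.frame(as.list(preds)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- paste0("optimum_", seq_len(nrow(out)))
  structure(list(optima = out, goals = goals, factors = factors,
                 resolution = resolution),
            class = "desirability_opt")
}

#' @export
print.desirability_opt <- function(x, digits = 3, ...) {
  cat("Desirability optimization (grid", x$resolution, "points/axis + polish)\n")
  print(round(x$optima, digits))
  invisible(x)
}

#' Coefficient of variation of a predicted/experimental pair
#'
#' Model-validation statistic: `100 * sd / mean` of the two-value set
#' \{predicted, experimental\}, with the sample (n-1) standard deviation,
#' i.e. `100 * |pred - exp| / sqrt(2) / mean`.
#'
#' @param predicted,experimental Numeric scalars or equal-length vectors.
#' @return CV in percent (elementwise).
#' @examples
#' cv_percent(6.56, 6.89)  # 3.5
#' @export
cv_percent <- function(predicted, experimental) {
  m <- (predicted + experimental) / 2
  if (any(m == 0)) stop("CV undefined: zero mean", call. = FALSE)
  100 * abs(predicted - experimental) / sqrt(2) / m
}

#' Validation report at check conditions
#'
#' Predicts every response at the supplied conditions with the
#' response-surface models (and optionally the MLP surrogates), joins the
#' experimental check values, and computes the CV(%) between each prediction
#' and its experimental counterpart.
#'
#' @param models Named list of [rsm_quad()] fits keyed by response.
#' @param conditions Data frame of check conditions (natural factor
#'   columns); one row per condition.
#' @param experimental Data frame: one row per condition, one column per
#'   response, experimental values.
#' @param ann_models Optional named list of [mlp_surrogate()] fits.
#' @return Data frame with columns `condition`, `response`, `predicted_rsm`,
#'   (`predicted_ann`,) `experimental`, `cv_rsm` (, `cv_ann`).
#' @export
validation_report <- function(models, conditions, experimental,
                              ann_models = NULL) {
  stopifnot(nrow(conditions) == nrow(experimental))
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    for (r in names(models)) {
      pr <- predict(models[[r]], conditions[i, , drop = FALSE])
      ex <- experimental[[r]][i]
      row <- data.frame(condition = i, response = r, predicted_rsm = pr,
                        experimental = ex, cv_rsm = cv_percent(pr, ex),
                        stringsAsFactors = FALSE)
      if (!is.null(ann_models) && !is.null(ann_models[[r]])) {
        pa <- predict(ann_models[[r]], conditions[i, , drop = FALSE])
        row$predicted_ann <- pa
        row$cv_ann <- cv_percent(pa, ex)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
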