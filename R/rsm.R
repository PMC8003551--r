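#' Fit a coded second-order response-surface model
#'
#' Fits, by ordinary least squares in coded factor space, the polynomial
#'
#' \deqn{Y = \beta_0 + \sum_i \beta_i X_i + \sum_i \beta_{ii} X_i^2 +
#'       \sum_{i<j} \beta_{ij} X_i X_j}
#'
#' where the \eqn{X_i} are the coded factors (-1/0/+1 at the design levels).
#' The default term set is the full quadratic; any hierarchical or
#' non-hierarchical subset can be requested through `terms`.
#'
#' @param design A `design_table` containing the response column.
#' @param response Name of the response column.
#' @param terms Character vector of term labels (see [full_quadratic()]);
#'   default is the full quadratic set.
#' @return An object of class `"rsm_quad"` with coefficients, standard
#'   errors, the usual fit statistics (`r2`, `adj_r2`, `f_value`, `p_value`)
#'   and sums of squares (`sse`, `ssr`, `sst`). Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `anova()`, `plot()` and `simulate()`.
#' @examples
#' des <- coffee_husk_design()
#' fit <- rsm_quad(des, "TPC")
#' coef(fit)[c("(Intercept)", "X1")]
#' summary(fit)
#' @export
rsm_quad <- function(design, response, terms = NULL) {
  stopifnot(inherits(design, "design_table"))
  if (!response %in% names(design))
    stop("unknown response: ", response, call. = FALSE)
  factors <- design_factors(design)
  if (is.null(terms)) terms <- full_quadratic(factors)
  y <- design[[response]]
  X <- build_design_matrix(design, terms)
  n <- nrow(X); p <- length(terms)
  if (n <= p + 1)
    stop("too few runs (", n, ") for ", p, " model terms", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("singular design: model matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sse
  df_res <- n - p - 1
  sigma2 <- sse / df_res
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- names(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)
  r2 <- 1 - sse / sst
  f <- (ssr / p) / sigma2
  structure(list(
    coefficients = beta, se = se, t_value = tval, p_value_terms = pval,
    terms = terms, response = response, factors = factors,
    n = n, p = p, df_residual = df_res,
    r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / df_res,
    f_value = f,
    p_value = stats::pf(f, p, df_res, lower.tail = FALSE),
    sse = sse, ssr = ssr, sst = sst, sigma = sqrt(sigma2),
    fitted.values = drop(X %*% beta), residuals = res, y = y,
    design = design
  ), class = "rsm_quad")
}

#' @export
coef.rsm_quad <- function(object, ...) object$coefficients

#' @export
fitted.rsm_quad <- function(object, ...) object$fitted.values

#' @export
residuals.rsm_quad <- function(object, ...) object$residuals

#' @export
print.rsm_quad <- function(x, digits = 3, ...) {
  cat(sprintf("Second-order response-surface model: %s (%d runs, %d terms)\n",
              x$response, x$n, x$p))
  print(round(x$coefficients, digits))
  cat(sprintf("R2 = %.4f, Adj. R2 = %.4f, F = %.2f (p = %.3g)\n",
              x$r2, x$adj_r2, x$f_value, x$p_value))
  invisible(x)
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
summary.rsm_quad <- function(object, ...) {
  tab <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    t = object$t_value,
    p = object$p_value_terms,
    signif = signif_stars(object$p_value_terms),
    row.names = names(object$coefficients),
    check.names = FALSE
  )
  out <- list(response = object$response, coefficients = tab,
              r2 = object$r2, adj_r2 = object$adj_r2,
              f_value = object$f_value, p_value = object$p_value,
              sigma = object$sigma, n = object$n, p = object$p)
  class(out) <- "summary.rsm_quad"
  out
}

#' @export
print.summary.rsm_quad <- function(x, digits = 4, ...) {
  cat(sprintf("Response: %s\n", x$response))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$t <- round(tab$t, 2)
  tab$p <- signif(tab$p, 3)
  print(tab)
  cat(sprintf("\nR2 = %.4f, Adj. R2 = %.4f, F(%d, %d) = %.2f, p = %.3g\n",
              x$r2, x$adj_r2, x$p, x$n - x$p - 1, x$f_value, x$p_value))
  invisible(x)
}

coded_newdata <- function(object, newdata, warn_extrapolation = TRUE) {
  factors <- object$factors
  syms <- vapply(factors, `[[`, "", "symbol")
  newdata <- as.data.frame(newdata)
  if (all(syms %in% names(newdata))) {
    coded <- as.matrix(newdata[syms])
  } else if (all(names(factors) %in% names(newdata))) {
    coded <- vapply(seq_along(factors),
                    function(j) code_value(newdata[[names(factors)[j]]],
                                           factors[[j]]),
                    numeric(nrow(newdata)))
    coded <- matrix(coded, nrow = nrow(newdata))
    colnames(coded) <- syms
  } else {
    stop("newdata must contain either the factor columns (",
         paste(names(factors), collapse = ", "), ") or the coded columns (",
         paste(syms, collapse = ", "), ")", call. = FALSE)
  }
  if (warn_extrapolation && any(abs(coded) > 1 + 1e-8))
    warning("prediction outside the design region (|coded| > 1)",
            call. = FALSE)
  coded
}

#' Predict from a response-surface model
#'
#' @param object An [rsm_quad()] fit.
#' @param newdata Data frame of prediction points, either in natural units
#'   (columns named as the factors) or coded units (columns named by factor
#'   symbol). Missing `newdata` returns fitted values.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.rsm_quad <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  coded <- coded_newdata(object, newdata)
  X <- build_design_matrix(coded, object$terms)
  drop(X %*% object$coefficients)
}

#' Simulate responses from a fitted surface
#'
#' Draws response vectors at the design points from the fitted mean surface
#' plus i.i.d. Gaussian noise with the model's residual standard deviation.
#'
#' @param object An [rsm_quad()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns.
#' @export
simulate.rsm_quad <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Per-term ANOVA with contribution percentages
#'
#' Decomposes the model sum of squares term by term. The default
#' (`type = "partial"`) uses drop-one (Type III) sums of squares:
#' the increase in residual sum of squares when the term alone is removed.
#' Each term's contribution is its sum of squares as a percentage of the
#' total corrected sum of squares; group rows (linear, quadratic,
#' interaction) sum their members, and the model row carries
#' `100 * R2`. With `type = "sequential"` Type I sums of squares are used
#' instead (these sum exactly to the model sum of squares).
#'
#' @param object An [rsm_quad()] fit.
#' @param type `"partial"` (drop-one) or `"sequential"`.
#' @param ... Unused.
#' @return A data frame of class `"anova_rsm"` with columns `term`, `ss`,
#'   `df`, `f`, `p`, `contribution` and a `group` marker.
#' @examples
#' fit <- rsm_quad(coffee_husk_design(), "TPC")
#' anova(fit)
#' @export
anova.rsm_quad <- function(object, type = c("partial", "sequential"), ...) {
  type <- match.arg(type)
  design <- object$design
  y <- object$y
  terms <- object$terms
  X <- build_design_matrix(design, terms)
  mse <- object$sse / object$df_residual
  ss <- if (type == "partial") {
    vapply(seq_along(terms), function(j) {
      sub <- qr(X[, -(j + 1), drop = FALSE])
      sum(qr.resid(sub, y)^2) - object$sse
    }, 0)
  } else {
    vapply(seq_along(terms), function(j) {
      upto <- qr(X[, seq_len(j + 1), drop = FALSE])
      before <- qr(X[, seq_len(j), drop = FALSE])
      sum(qr.resid(before, y)^2) - sum(qr.resid(upto, y)^2)
    }, 0)
  }
  fval <- ss / mse
  pval <- stats::pf(fval, 1, object$df_residual, lower.tail = FALSE)
  contrib <- 100 * ss / object$sst
  kind <- ifelse(grepl("\\^2$", terms), "quadratic",
                 ifelse(grepl(":", terms), "interaction", "linear"))
  rows <- data.frame(term = terms, group = kind, ss = ss, df = 1,
                     f = fval, p = pval, contribution = contrib,
                     stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(c("linear", "quadratic", "interaction"),
    function(g) {
      sel <- rows$group == g
      if (!any(sel)) return(NULL)
      gss <- sum(rows$ss[sel]); gdf <- sum(rows$df[sel])
      gf <- (gss / gdf) / mse
      data.frame(term = g, group = "group", ss = gss, df = gdf, f = gf,
                 p = stats::pf(gf, gdf, object$df_residual,
                               lower.tail = FALSE),
                 contribution = sum(rows$contribution[sel]),
                 stringsAsFactors = FALSE)
    }))
  model <- data.frame(term = "model", group = "model", ss = object$ssr,
                      df = object$p, f = object$f_value, p = object$p_value,
                      contribution = 100 * object$r2,
                      stringsAsFactors = FALSE)
  out <- rbind(rows, groups, model)
  rownames(out) <- NULL
  attr(out, "type") <- type
  attr(out, "response") <- object$response
  class(out) <- c("anova_rsm", "data.frame")
  out
}

#' @export
`[.anova_rsm` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.anova_rsm <- function(x, digits = 3, ...) {
  cat(sprintf("ANOVA (%s SS) for response %s\n", attr(x, "type"),
              attr(x, "response")))
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, digits + 1)
  y$f <- round(y$f, 2)
  y$contribution <- round(y$contribution, 1)
  y$signif <- signif_stars(y$p)
  y$p <- signif(y$p, 3)
  print(y)
  invisible(x)
}

#' Reduce a model to its significant terms
#'
#' Single-pass model reduction: terms with full-model p-value below `alpha`
#' are retained, the set is closed under hierarchy (parents of retained
#' quadratic and interaction terms are added back) when `hierarchy = TRUE`,
#' and the model is refit on the retained set. No iterative elimination is
#' performed.
#'
#' @param object An [rsm_quad()] fit.
#' @param alpha Significance level for retention (default 0.05).
#' @param hierarchy Enforce model hierarchy (default `TRUE`).
#' @return A new [rsm_quad()] fit on the retained terms.
#' @examples
#' fit <- rsm_quad(coffee_husk_design(), "TF")
#' reduce_model(fit)$terms  # X1, X3, X4, X1^2
#' @export
reduce_model <- function(object, alpha = 0.05, hierarchy = TRUE) {
  stopifnot(inherits(object, "rsm_quad"))
  p <- object$p_value_terms[-1]
  keep <- names(p)[p < alpha]
  if (!length(keep)) {
    warning("no significant terms at alpha = ", alpha,
            "; returning intercept-only model", call. = FALSE)
    keep <- character()
  }
  syms <- vapply(object$factors, `[[`, "", "symbol")
  if (hierarchy && length(keep)) keep <- hierarchy_closure(keep, syms)
  if (!length(keep)) {
    y <- object$y
    n <- length(y)
    sst <- sum((y - mean(y))^2)
    out <- object
    out$terms <- character(); out$p <- 0L
    out$coefficients <- c("(Intercept)" = mean(y))
    out$fitted.values <- rep(mean(y), n)
    out$residuals <- y - mean(y)
    out$sse <- sst; out$ssr <- 0; out$r2 <- 0
    return(out)
  }
  rsm_quad(object$design, object$response, keep)
}

#' Express a coded model in natural units
#'
#' Substitutes the coding transform `X_i = (x_i - c_i) / h_i` into the coded
#' polynomial and collects coefficients on the natural monomials, so the
#' natural-unit equation predicts identically to the coded one.
#'
#' @param object An [rsm_quad()] fit.
#' @return Named numeric vector of natural-unit coefficients with labels
#'   `(Intercept)`, `x1`, `x1^2`, `x1:x3`, ... (lower-case symbols).
#' @examples
#' fit <- rsm_quad(coffee_husk_design(), "TPC")
#' natural_coef(fit)["x1^2"]  # ~ 3.8e-4 per degC^2
#' @export
natural_coef <- function(object) {
  stopifnot(inherits(object, "rsm_quad"))
  factors <- object$factors
  syms <- vapply(factors, `[[`, "", "symbol")
  centers <- vapply(factors, `[[`, 0, "center")
  halves <- vapply(factors, half_range, 0)
  names(centers) <- names(halves) <- syms
  lab <- function(s) tolower(s)
  acc <- new.env(parent = emptyenv())
  add <- function(key, val) {
    assign(key, (if (exists(key, acc)) get(key, acc) else 0) + val, acc)
  }
  add("(Intercept)", object$coefficients[["(Intercept)"]])
  for (tm in object$terms) {
    b <- object$coefficients[[tm]]
    if (grepl("\\^2$", tm)) {
      s <- sub("\\^2$", "", tm); c0 <- centers[s]; h <- halves[s]
      add(paste0(lab(s), "^2"), b / h^2)
      add(lab(s), -2 * b * c0 / h^2)
      add("(Intercept)", b * c0^2 / h^2)
    } else if (grepl(":", tm, fixed = TRUE)) {
      ss <- strsplit(tm, ":", fixed = TRUE)[[1]]
      ci <- centers[ss[1]]; cj <- centers[ss[2]]
      hi <- halves[ss[1]]; hj <- halves[ss[2]]
      add(paste0(lab(ss[1]), ":", lab(ss[2])), b / (hi * hj))
      add(lab(ss[1]), -b * cj / (hi * hj))
      add(lab(ss[2]), -b * ci / (hi * hj))
      add("(Intercept)", b * ci * cj / (hi * hj))
    } else {
      add(lab(tm), b / halves[tm])
      add("(Intercept)", -b * centers[tm] / halves[tm])
    }
  }
  keys <- ls(acc)
  order_key <- c("(Intercept)", lab(syms), paste0(lab(syms), "^2"),
                 if (length(syms) >= 2) {
                   idx <- utils::combn(length(syms), 2)
                   paste0(lab(syms)[idx[1, ]], ":", lab(syms)[idx[2, ]])
                 })
  keys <- order_key[order_key %in% keys]
  stats::setNames(vapply(keys, get, 0, envir = acc), keys)
}

#' Standardized model coefficients
#'
#' Scales each non-intercept coefficient by the ratio of its model-matrix
#' column standard deviation to the response standard deviation, giving
#' unitless effect sizes comparable across terms.
#'
#' @param object An [rsm_quad()] fit.
#' @return Named numeric vector (no intercept).
#' @export
standardized_coef <- function(object) {
  stopifnot(inherits(object, "rsm_quad"))
  sdy <- stats::sd(object$y)
  if (sdy == 0) stop("zero-variance response", call. = FALSE)
  X <- build_design_matrix(object$design, object$terms)
  sdx <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  object$coefficients[-1] * sdx / sdy
}

#' Contour plot of a fitted response surface
#'
#' Plots the predicted response over two factors, the remaining factors held
#' at their centre values.
#'
#' @param x An [rsm_quad()] fit.
#' @param which Character vector of two factor names (default: first two).
#' @param n Grid resolution per axis.
#' @param ... Passed to [graphics::contour()].
#' @return Invisibly, the prediction grid.
#' @export
plot.rsm_quad <- function(x, which = names(x$factors)[1:2], n = 40, ...) {
  factors <- x$factors
  stopifnot(length(which) == 2, all(which %in% names(factors)))
  f1 <- factors[[which[1]]]; f2 <- factors[[which[2]]]
  g1 <- seq(f1$low, f1$high, length.out = n)
  g2 <- seq(f2$low, f2$high, length.out = n)
  grid <- expand.grid(g1, g2)
  names(grid) <- which
  for (nm in setdiff(names(factors), which))
    grid[[nm]] <- factors[[nm]]$center
  z <- matrix(predict(x, grid), n, n)
  graphics::contour(g1, g2, z,
                    xlab = sprintf("%s (%s)", f1$name, f1$units),
                    ylab = sprintf("%s (%s)", f2$name, f2$units),
                    main = x$response, ...)
  invisible(list(x = g1, y = g2, z = z))
}
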