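#' Simulate a Box-Behnken experiment with known truth
#'
#' Generates a Box-Behnken design and a response column from a known coded
#' quadratic surface plus i.i.d. Gaussian noise, so that every modelling
#' stage can be exercised against ground truth.
#'
#' @param factors List of [factor_spec()] objects (default: the coffee-husk
#'   factor set).
#' @param beta Named coefficient vector in coded space; names are
#'   `(Intercept)` plus term labels as in [full_quadratic()]. Terms absent
#'   from the full quadratic are an error. Default: [tpc_truth()].
#' @param sigma Noise standard deviation in response units (default 0.16,
#'   the residual scatter of the TPC fit).
#' @param n_center Centre replicates (default 3).
#' @param seed Optional RNG seed; the same seed reproduces the same table.
#' @param response Name of the generated response column.
#' @return A `design_table` with the simulated response; the truth is
#'   attached as attributes `truth_beta` and `truth_sigma`.
#' @examples
#' des <- simulate_bbd(sigma = 0, seed = 1)
#' fit <- rsm_quad(des, "y")
#' max(abs(coef(fit) - tpc_truth()))  # ~1e-15
#' @export
simulate_bbd <- function(factors = husk_factors(), beta = tpc_truth(),
                         sigma = 0.16, n_center = 3, seed = NULL,
                         response = "y") {
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  if (!"(Intercept)" %in% names(beta))
    stop("'beta' must contain an (Intercept)", call. = FALSE)
  factors <- check_factor_list(factors)
  terms <- setdiff(names(beta), "(Intercept)")
  bad <- setdiff(terms, full_quadratic(factors))
  if (length(bad))
    stop("terms outside the full quadratic: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  des <- bbd_design(factors, n_center)
  X <- build_design_matrix(des, terms)
  mu <- drop(X %*% beta[c("(Intercept)", terms)])
  y <- mu + stats::rnorm(length(mu), sd = sigma)
  out <- as.data.frame(des)
  out[[response]] <- y
  out <- as_design_table(out, factors)
  attr(out, "truth_beta") <- beta
  attr(out, "truth_sigma") <- sigma
  out
}

#' Reference truth: the TPC full-model coefficient set
#'
#' The coded full-quadratic coefficients of the total-phenolic-compounds
#' model fitted to the 27-run coffee-husk experiment, used as the default
#' data-generating truth in simulations.
#'
#' @return Named numeric vector (15 coefficients).
#' @export
tpc_truth <- function() {
  c("(Intercept)" = 3.689,
    X1 = 0.592, X2 = 0.056, X3 = -0.001, X4 = -0.508,
    `X1^2` = 0.559, `X2^2` = 0.517, `X3^2` = 0.153, `X4^2` = 0.196,
    `X1:X2` = -0.060, `X1:X3` = 0.267, `X1:X4` = -0.390,
    `X2:X3` = -0.072, `X2:X4` = -0.357, `X3:X4` = 0.126)
}
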