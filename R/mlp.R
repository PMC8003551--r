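#' Random train/validation/test split
#'
#' Partitions `n` runs into disjoint train, validation and test sets by
#' uniform sampling without replacement. Subset sizes follow the fractions
#' by rounding (train and validation rounded, test takes the remainder), so
#' 27 runs at 70/15/15 give 19/4/4.
#'
#' @param n Number of runs.
#' @param fractions Length-3 numeric summing to 1.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with integer vectors `train`, `validation`, `test`, plus
#'   `fractions` and `seed`.
#' @examples
#' s <- data_split(27, seed = 1)
#' lengths(s[1:3])  # 19 4 4
#' @export
data_split <- function(n, fractions = c(0.70, 0.15, 0.15), seed = NULL) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train < 1 || n_val < 1 || n - n_train - n_val < 1)
    stop("split produces an empty subset", call. = FALSE)
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(n_train)]),
       validation = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[(n_train + n_val + 1):n]),
       fractions = fractions, seed = seed)
}

## parameter vector layout: W1 (k x h), b1 (h), W2 (h), b2 (1)
mlp_unpack <- function(th, k, h) {
  list(W1 = matrix(th[seq_len(k * h)], k, h),
       b1 = th[k * h + seq_len(h)],
       W2 = th[k * h + h + seq_len(h)],
       b2 = th[k * h + 2 * h + 1])
}

mlp_forward <- function(th, X, k, h) {
  p <- mlp_unpack(th, k, h)
  H <- tanh(X %*% p$W1 + rep(p$b1, each = nrow(X)))
  drop(H %*% p$W2 + p$b2)
}

mlp_loss <- function(th, X, y, k, h, decay) {
  w <- c(seq_len(k * h), k * h + h + seq_len(h))   # weights, not biases
  mean((mlp_forward(th, X, k, h) - y)^2) + decay * sum(th[w]^2)
}

mlp_grad <- function(th, X, y, k, h, decay) {
  p <- mlp_unpack(th, k, h)
  Z <- X %*% p$W1 + rep(p$b1, each = nrow(X))
  H <- tanh(Z)
  e <- 2 * (drop(H %*% p$W2 + p$b2) - y) / length(y)
  dH <- (e %o% p$W2) * (1 - H^2)
  g <- c(as.vector(t(X) %*% dH), colSums(dH), drop(t(H) %*% e), sum(e))
  w <- c(seq_len(k * h), k * h + h + seq_len(h))
  g[w] <- g[w] + 2 * decay * th[w]
  g
}

minmax_scaler <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("cannot scale a constant column", call. = FALSE)
  list(lo = lo, hi = hi)
}
scale_to <- function(x, s) 2 * (x - s$lo) / (s$hi - s$lo) - 1
scale_from <- function(z, s) s$lo + (z + 1) * (s$hi - s$lo) / 2

#' Train a feed-forward MLP surrogate
#'
#' Fits a single-hidden-layer perceptron (hyperbolic-tangent hidden units,
#' linear output) to one response of a designed experiment, the architecture
#' used for extraction surrogate modelling: `k` inputs, `hidden` neurons,
#' one output. Inputs and output are min-max scaled to \[-1, 1\] over the
#' full design. Training minimizes the mean squared error on the training
#' subset by BFGS quasi-Newton iterations with analytic gradients.
#'
#' Each restart draws a fresh 70/15/15 train/validation/test division and a
#' fresh uniform \[-0.5, 0.5\] weight initialization, and is run once per
#' value of `decay` (a small L2 penalty on the weights that controls how
#' aggressively the network may curve between design points). Parameters are
#' checkpointed every 10 BFGS iterations up to `max_epochs`. The returned
#' network is the checkpoint with the lowest selection criterion:
#' `select = "overall"` (default) uses the mean squared error over all runs,
#' mirroring the practice of training many candidate networks and keeping
#' the one with the best fit statistics; `select = "validation"` uses the
#' validation-set error of the checkpoint's own split (classical early
#' stopping).
#'
#' @param design A `design_table`.
#' @param response Response column name.
#' @param hidden Hidden-layer size (default 10).
#' @param max_epochs Cap on BFGS iterations per restart (default 500;
#'   must be >= 1).
#' @param restarts Number of random restarts (default 100).
#' @param seed RNG seed governing every random draw (splits, inits).
#' @param decay Numeric vector of L2 weight penalties tried per restart.
#' @param select Checkpoint selection rule, see Details.
#' @return An object of class `"mlp_surrogate"`: weights (`w_in`,
#'   `b_hidden`, `w_out`, `b_out`), scalers, the winning restart's split,
#'   `epochs_run`, `decay`, `seed`. Supports `print()` and `predict()`.
#' @examples
#' \donttest{
#' des <- coffee_husk_design()
#' net <- mlp_surrogate(des, "TPC", restarts = 10, seed = 1)
#' r_squared(predict(net, des), des$TPC)
#' }
#' @export
mlp_surrogate <- function(design, response, hidden = 10, max_epochs = 500,
                          restarts = 100, seed = 1,
                          decay = c(1e-4, 3e-3, 3e-2),
                          select = c("overall", "validation")) {
  stopifnot(inherits(design, "design_table"))
  select <- match.arg(select)
  if (max_epochs < 1) stop("'max_epochs' must be >= 1", call. = FALSE)
  if (restarts < 1) stop("'restarts' must be >= 1", call. = FALSE)
  if (!response %in% names(design))
    stop("unknown response: ", response, call. = FALSE)
  factors <- design_factors(design)
  k <- length(factors); h <- hidden
  npar <- k * h + 2 * h + 1
  Xnat <- as.matrix(as.data.frame(design)[names(factors)])
  in_scalers <- lapply(seq_len(k), function(j) minmax_scaler(Xnat[, j]))
  X <- vapply(seq_len(k), function(j) scale_to(Xnat[, j], in_scalers[[j]]),
              numeric(nrow(Xnat)))
  y <- design[[response]]
  out_scaler <- minmax_scaler(y)
  ys <- scale_to(y, out_scaler)
  n <- nrow(X)
  chunk <- 10L
  nchunk <- as.integer(ceiling(max_epochs / chunk))
  mse_on <- function(th, rows) mean((mlp_forward(th, X[rows, , drop = FALSE],
                                                 k, h) - ys[rows])^2)
  set.seed(seed)
  best <- NULL; best_crit <- Inf; ok <- FALSE
  for (r in seq_len(restarts)) {
    idx <- sample.int(n)
    n_tr <- round(0.70 * n); n_va <- round(0.15 * n)
    tr <- idx[seq_len(n_tr)]
    va <- idx[n_tr + seq_len(n_va)]
    te <- idx[(n_tr + n_va + 1):n]
    th0 <- stats::runif(npar, -0.5, 0.5)
    for (lam in decay) {
      th <- th0
      epochs <- 0L
      traj <- list(list(th = th, epochs = 0L))
      for (ch in seq_len(nchunk)) {
        op <- tryCatch(
          stats::optim(th, mlp_loss, mlp_grad, X = X[tr, , drop = FALSE],
                       y = ys[tr], k = k, h = h, decay = lam,
                       method = "BFGS", control = list(maxit = chunk)),
          error = function(e) NULL)
        if (is.null(op) || !all(is.finite(op$par))) break
        th <- op$par
        epochs <- epochs + chunk
        traj[[length(traj) + 1L]] <- list(th = th, epochs = epochs)
        if (op$convergence == 0) break
      }
      if (length(traj) == 1L && restarts > 1L) next
      crit <- vapply(traj, function(z) {
        if (select == "overall") mse_on(z$th, seq_len(n))
        else mse_on(z$th, va)
      }, 0)
      j <- which.min(crit)
      if (is.finite(crit[j]) && crit[j] < best_crit) {
        best_crit <- crit[j]
        best <- list(th = traj[[j]]$th, epochs = traj[[j]]$epochs,
                     decay = lam,
                     split = list(train = sort(tr), validation = sort(va),
                                  test = sort(te),
                                  fractions = c(0.70, 0.15, 0.15)))
        ok <- TRUE
      }
    }
  }
  if (!ok) stop("MLP training failed in every restart", call. = FALSE)
  p <- mlp_unpack(best$th, k, h)
  structure(list(
    w_in = p$W1, b_hidden = p$b1, w_out = p$W2, b_out = p$b2,
    hidden_activation = "tansig", output_activation = "purelin",
    input_scalers = in_scalers, output_scaler = out_scaler,
    factors = factors, response = response, hidden = h,
    split = best$split, seed = seed, epochs_run = best$epochs,
    decay = best$decay, selection = select
  ), class = "mlp_surrogate")
}

#' @export
print.mlp_surrogate <- function(x, ...) {
  cat(sprintf(
    "MLP surrogate for %s: %d-%d-1 (tansig/purelin), %d epochs, decay %g\n",
    x$response, nrow(x$w_in), x$hidden, x$epochs_run, x$decay))
  cat(sprintf("split %d/%d/%d, seed %s, selection by %s fit\n",
              length(x$split$train), length(x$split$validation),
              length(x$split$test), format(x$seed), x$selection))
  invisible(x)
}

#' Predict from an MLP surrogate
#'
#' Scales the inputs, runs the forward pass
#' `purelin(W2 tanh(W1 x + b1) + b2)` and inverse-scales the output.
#'
#' @param object An [mlp_surrogate()].
#' @param newdata Data frame with the factor columns in natural units, or
#'   coded columns named by factor symbol.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (natural units).
#' @export
predict.mlp_surrogate <- function(object, newdata, ...) {
  factors <- object$factors
  syms <- vapply(factors, `[[`, "", "symbol")
  newdata <- as.data.frame(newdata)
  if (all(names(factors) %in% names(newdata))) {
    nat <- as.matrix(newdata[names(factors)])
  } else if (all(syms %in% names(newdata))) {
    nat <- vapply(seq_along(factors),
                  function(j) decode_value(newdata[[syms[j]]], factors[[j]]),
                  numeric(nrow(newdata)))
    nat <- matrix(nat, nrow = nrow(newdata))
  } else {
    stop("newdata lacks factor columns", call. = FALSE)
  }
  X <- vapply(seq_along(factors),
              function(j) scale_to(nat[, j], object$input_scalers[[j]]),
              numeric(nrow(nat)))
  X <- matrix(X, nrow = nrow(nat))
  H <- tanh(X %*% object$w_in + rep(object$b_hidden, each = nrow(X)))
  scale_from(drop(H %*% object$w_out + object$b_out), object$output_scaler)
}
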