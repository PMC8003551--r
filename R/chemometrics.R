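#' Pearson correlation matrix with p-values
#'
#' Correlates every pair of panel variables, handling missing values
#' pairwise. p-values are two-sided, from the t distribution with n-2
#' degrees of freedom. Pairs with fewer than 3 complete observations are
#' flagged as not computed (NA).
#'
#' @param panel Data frame or matrix, samples in rows, variables in columns.
#' @return List of class `"pearson_matrix"` with matrices `r`, `p` and `n`
#'   (complete pairs per cell).
#' @examples
#' pm <- pearson_matrix(extract_panel())
#' pm$r["Chlorogenic acid", "TPC"]  # 0.8973
#' @export
pearson_matrix <- function(panel) {
  x <- as.matrix(panel)
  if (!is.numeric(x)) stop("panel must be numeric", call. = FALSE)
  v <- ncol(x)
  r <- p <- n <- matrix(NA_real_, v, v,
                        dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(v)) {
    for (j in i:v) {
      ok <- stats::complete.cases(x[, i], x[, j])
      m <- sum(ok)
      n[i, j] <- n[j, i] <- m
      if (m < 3) next
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0) next
      rij <- stats::cor(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- rij
      tt <- rij * sqrt((m - 2) / max(1 - rij^2, .Machine$double.eps))
      p[i, j] <- p[j, i] <- 2 * stats::pt(abs(tt), m - 2, lower.tail = FALSE)
    }
  }
  structure(list(r = r, p = p, n = n), class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (", ncol(x$r), "variables )\n")
  print(round(x$r, digits))
  invisible(x)
}

autoscale <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  if (any(sdv == 0)) stop("zero-variance variable(s): ",
                          paste(colnames(x)[sdv == 0], collapse = ", "),
                          call. = FALSE)
  list(z = sweep(sweep(x, 2, mu), 2, sdv, "/"), center = mu, scale = sdv)
}

canonical_signs <- function(loadings, scores) {
  for (a in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal component analysis of a sample panel
#'
#' Column-autoscaled (mean 0, SD 1) PCA via singular value decomposition.
#' Missing entries are imputed by the variable mean (with a message).
#' Component signs are canonicalized so the largest-magnitude loading of
#' each component is positive.
#'
#' @param panel Samples x variables data frame or matrix.
#' @param ncomp Number of components to report (default
#'   `min(n - 1, variables)`).
#' @return List of class `"panel_pca"`: `scores`, `loadings`,
#'   `explained_variance_pct`, `center`, `scale`.
#' @export
panel_pca <- function(panel, ncomp = NULL) {
  x <- as.matrix(panel)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(colSums(!is.na(x)) == 0))
    stop("variable with all values missing", call. = FALSE)
  if (anyNA(x)) {
    message("imputing ", sum(is.na(x)), " missing value(s) by variable mean")
    for (j in seq_len(ncol(x)))
      x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  }
  sc <- autoscale(x)
  maxcomp <- min(nrow(x) - 1, ncol(x))
  if (is.null(ncomp)) ncomp <- maxcomp
  ncomp <- min(ncomp, maxcomp)
  sv <- svd(sc$z)
  var_pct <- 100 * sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  loadings <- sv$v
  fix <- canonical_signs(loadings[, seq_len(ncomp), drop = FALSE],
                         scores[, seq_len(ncomp), drop = FALSE])
  dimnames(fix$scores) <- list(rownames(panel),
                               paste0("PC", seq_len(ncomp)))
  dimnames(fix$loadings) <- list(colnames(panel),
                                 paste0("PC", seq_len(ncomp)))
  structure(list(scores = fix$scores, loadings = fix$loadings,
                 explained_variance_pct = var_pct[seq_len(ncomp)],
                 center = sc$center, scale = sc$scale),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "variables\n")
  cat("explained variance (%):",
      paste(round(x$explained_variance_pct, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Partial least squares regression (NIPALS)
#'
#' Single-response PLS on autoscaled data by the NIPALS algorithm.
#' Regression coefficients are back-transformed to the original scale.
#'
#' @param X Samples x variables matrix or data frame.
#' @param y Numeric response vector.
#' @param ncomp Number of latent components
#'   (`<= min(n - 1, ncol(X))`).
#' @return List of class `"pls_model"`: `scores` (X-scores `T`), `weights`
#'   (`W`), `x_loadings` (`P`), `y_loadings` (`q`), `coefficients`
#'   (original scale, with intercept), `explained_y_variance` per component.
#' @export
pls_nipals <- function(X, y, ncomp) {
  Xs <- autoscale(X)
  if (stats::sd(y) == 0) stop("zero-variance response", call. = FALSE)
  ys <- (y - mean(y)) / stats::sd(y)
  n <- nrow(Xs$z); v <- ncol(Xs$z)
  if (ncomp > min(n - 1, v))
    stop("ncomp exceeds min(n - 1, #variables)", call. = FALSE)
  E <- Xs$z; f <- ys
  W <- P <- matrix(0, v, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ssy <- sum(ys^2)
  expl <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- qa
    expl[a] <- 100 * qa^2 * tt / ssy
  }
  Bs <- drop(W %*% solve(crossprod(P, W), q))
  b <- Bs * stats::sd(y) / Xs$scale
  intercept <- mean(y) - sum(b * Xs$center)
  vars <- colnames(as.data.frame(X))
  dimnames(W) <- dimnames(P) <- list(vars, paste0("comp", seq_len(ncomp)))
  structure(list(scores = Tm, weights = W, x_loadings = P, y_loadings = q,
                 coefficients = c("(Intercept)" = intercept,
                                  stats::setNames(b, vars)),
                 coefficients_std = stats::setNames(Bs, vars),
                 explained_y_variance = expl, ncomp = ncomp),
            class = "pls_model")
}

#' Variable importance in projection (VIP) scores
#'
#' Standard VIP from the PLS X-weights and the explained response variance
#' per component; the mean of the squared scores over variables is 1, so
#' values above 1 flag influential variables.
#'
#' @param pls A [pls_nipals()] model.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(pls) {
  stopifnot(inherits(pls, "pls_model"))
  W <- pls$weights
  ssycomp <- pls$y_loadings^2 * colSums(pls$scores^2)
  v <- nrow(W)
  w2 <- sweep(W^2, 2, colSums(W^2), "/")
  vip <- sqrt(v * drop(w2 %*% ssycomp) / sum(ssycomp))
  stats::setNames(vip, rownames(W))
}

#' Principal component regression coefficients
#'
#' Regresses the (autoscaled) response on the first `ncomp` PCA scores of
#' the autoscaled predictor panel and back-projects the fitted coefficients
#' onto the original variables and scale.
#'
#' @inheritParams pls_nipals
#' @param standardized If `TRUE`, return the autoscaled-space coefficients
#'   (no intercept), the scale on which variable importance is compared;
#'   default `FALSE` returns original-scale coefficients with intercept.
#' @return Named numeric vector of coefficients; first element
#'   `(Intercept)` unless `standardized`.
#' @export
pcr_coefficients <- function(X, y, ncomp, standardized = FALSE) {
  Xs <- autoscale(X)
  if (stats::sd(y) == 0) stop("zero-variance response", call. = FALSE)
  ys <- (y - mean(y)) / stats::sd(y)
  maxcomp <- min(nrow(Xs$z) - 1, ncol(Xs$z))
  if (ncomp > maxcomp) stop("ncomp exceeds available components",
                            call. = FALSE)
  sv <- svd(Xs$z)
  Tk <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  gam <- drop(solve(crossprod(Tk), crossprod(Tk, ys)))
  Bs <- drop(sv$v[, seq_len(ncomp), drop = FALSE] %*% gam)
  vars <- colnames(as.data.frame(X))
  if (standardized) return(stats::setNames(Bs, vars))
  b <- Bs * stats::sd(y) / Xs$scale
  intercept <- mean(y) - sum(b * Xs$center)
  c("(Intercept)" = intercept, stats::setNames(b, vars))
}

#' Agglomerative clustering of a sample panel
#'
#' Hierarchical clustering of the samples with Euclidean distance on the
#' autoscaled variables and, by default, average linkage. Missing values
#' are imputed by the variable mean.
#'
#' @param panel Samples x variables data frame or matrix.
#' @param method Linkage passed to [stats::hclust()] (default `"average"`).
#' @return An `hclust` object.
#' @export
cluster_panel <- function(panel, method = "average") {
  x <- as.matrix(panel)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(x))
    for (j in seq_len(ncol(x)))
      x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  stats::hclust(stats::dist(autoscale(x)$z), method = method)
}

#' Export a dendrogram as Newick text
#'
#' @param hc An `hclust` object.
#' @param digits Branch-length digits.
#' @return A single Newick string (heights as branch lengths).
#' @export
dendrogram_newick <- function(hc, digits = 4) {
  labs <- hc$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(hc$merge) + 1))
  node <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%s", gsub("[,;:()]", "_", labs[-i]),
              format(round(parent_h, digits)))
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%s", node(hc$merge[i, 1], h), node(hc$merge[i, 2], h),
              format(round(parent_h - h, digits)))
    }
  }
  n <- nrow(hc$merge)
  paste0("(", node(hc$merge[n, 1], hc$height[n]), ",",
         node(hc$merge[n, 2], hc$height[n]), ");")
}
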