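test_that("the correlation matrix is symmetric with unit diagonal", {
  pm <- pearson_matrix(extract_panel())
  expect_lt(max(abs(pm$r - t(pm$r)), na.rm = TRUE), 1e-12)
  expect_equal(unname(diag(pm$r)), rep(1, ncol(pm$r)))
  expect_true(all(abs(pm$r) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("correlation p-values agree with the cor.test oracle", {
  panel <- extract_panel()
  pm <- pearson_matrix(panel)
  ct <- stats::cor.test(panel[["Chlorogenic acid"]], panel$TPC)
  expect_equal(pm$r["Chlorogenic acid", "TPC"], unname(ct$estimate),
               tolerance = 1e-12)
  expect_equal(pm$p["Chlorogenic acid", "TPC"], ct$p.value,
               tolerance = 1e-12)
})

test_that("pairs with too few complete observations are not computed", {
  x <- data.frame(a = c(1, 2, NA, NA, NA), b = c(2, 1, 4, 4.5, NA),
                  c = 1:5)
  pm <- pearson_matrix(x)
  expect_true(is.na(pm$r["a", "b"]))
  expect_equal(pm$n["a", "b"], 2)
  expect_false(is.na(pm$r["b", "c"]))
})

test_that("PCA reconstructs the autoscaled panel from all components", {
  panel <- extract_panel()
  pp <- panel_pca(panel)
  z <- scale(as.matrix(panel))
  recon <- pp$scores %*% t(pp$loadings)
  expect_equal(unname(recon), unname(z[, ]), tolerance = 1e-9)
  expect_true(all(diff(pp$explained_variance_pct) <= 1e-9))
  expect_lte(sum(pp$explained_variance_pct), 100 + 1e-9)
})

test_that("duplicated samples receive identical PCA scores", {
  set.seed(8)
  x <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, letters[1:4]))
  x <- rbind(x, x[3, ])
  pp <- panel_pca(x)
  expect_equal(pp$scores[3, ], pp$scores[6, ], tolerance = 1e-9)
})

test_that("NIPALS X-scores are mutually orthogonal", {
  panel <- extract_panel()
  pl <- pls_nipals(panel[, 8:25], panel$AC, 3)
  g <- crossprod(pl$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("full-rank PLS and PCR collapse to ordinary least squares", {
  set.seed(12)
  X <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(8, sd = 0.1)
  ols <- coef(stats::lm(y ~ X))
  pl <- pls_nipals(X, y, 3)
  expect_equal(unname(pl$coefficients), unname(ols), tolerance = 1e-8)
  pc <- pcr_coefficients(X, y, 3)
  expect_equal(unname(pc), unname(ols), tolerance = 1e-8)
})

test_that("VIP scores are normalized and expose a single informative variable", {
  panel <- extract_panel()
  v <- vip_scores(pls_nipals(panel[, 8:25], panel$AC, 2))
  expect_equal(mean(v^2), 1, tolerance = 1e-6)

  set.seed(3)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, letters[1:5]))
  y <- 2 * X[, 2]
  v1 <- vip_scores(pls_nipals(X, y, 1))
  expect_equal(unname(v1["b"]), sqrt(5), tolerance = 0.2)
  expect_equal(which.max(v1), c(b = 2))
})

test_that("a PLS response proportional to one variable loads on it", {
  set.seed(6)
  X <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, letters[1:4]))
  y <- 3 * X[, 3]
  pl <- pls_nipals(X, y, 1)
  b <- abs(pl$coefficients[-1])
  expect_equal(names(which.max(b)), "c")
})

test_that("PCR coefficients of pure noise are indistinguishable from zero", {
  set.seed(31)
  devs <- replicate(200, {
    X <- matrix(rnorm(10 * 3), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(10)
    pcr_coefficients(X, y, 2, standardized = TRUE)
  })
  expect_lt(max(abs(rowMeans(devs))), 3 * max(apply(devs, 1, sd)) / sqrt(200))
})

test_that("ncomp limits are enforced", {
  panel <- extract_panel()
  expect_error(pls_nipals(panel[, 8:25], panel$AC, 7), "ncomp")
  expect_error(pcr_coefficients(panel[, 8:25], panel$AC, 7), "ncomp")
  expect_error(pls_nipals(panel[, 8:25], rep(1, 7), 2), "zero-variance")
})

test_that("clustering merges identical samples first and keeps all leaves", {
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9),
             d = c(4, 1, 0))
  hc <- cluster_panel(x)
  expect_equal(hc$height[1], 0)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
  expect_length(hc$order, 4)
  nwk <- dendrogram_newick(hc)
  expect_equal(lengths(regmatches(nwk, gregexpr("[abcd]:", nwk))), 4)
})

test_that("the extract panel reproduces its documented structure", {
  panel <- extract_panel()
  expect_equal(nrow(panel), 7)
  expect_equal(ncol(panel), 7 + 18 + 1)
  expect_equal(panel["Free", "Chlorogenic acid"], 1428.40)
  # below-detection entries as zero by default, NA on request
  expect_equal(panel["Bound", "Gallic acid"], 0)
  expect_true(is.na(extract_panel(missing = "na")["Bound", "Gallic acid"]))
})
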