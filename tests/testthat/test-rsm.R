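test_that("OLS coefficients match the brute-force normal-equations solution", {
  des <- tiny_design()
  terms <- c("X1", "X2", "X1:X2")
  fit <- rsm_quad(des, "y", terms)
  X <- build_design_matrix(des, terms)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% des$y)
  expect_equal(unname(coef(fit)), unname(drop(beta_oracle)),
               tolerance = 1e-10)
})

test_that("a noiseless quadratic surface is recovered exactly", {
  des <- simulate_bbd(sigma = 0, seed = 7)
  fit <- rsm_quad(des, "y")
  expect_equal(coef(fit)[names(tpc_truth())], tpc_truth(), tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("model matrix has the documented layout", {
  des <- coffee_husk_design()
  X <- build_design_matrix(des, full_quadratic(husk_factors()))
  expect_equal(ncol(X), 15)
  # centre run: all columns but the intercept vanish
  expect_equal(unname(X[27, ]), c(1, rep(0, 14)))
  # run 11 is coded (1, 0, 0, -1): X1:X4 product column is -1
  expect_equal(unname(X[11, "X1:X4"]), -1)
  expect_error(build_design_matrix(des, "X9"), "missing factor")
})

test_that("stored fit statistics satisfy their defining identities", {
  for (fit in husk_full_fits()) {
    expect_equal(fit$r2, 1 - fit$sse / fit$sst, tolerance = 1e-12)
    expect_equal(fit$adj_r2,
                 1 - (1 - fit$r2) * (fit$n - 1) / (fit$n - fit$p - 1),
                 tolerance = 1e-12)
    expect_equal(fit$f_value,
                 (fit$r2 / fit$p) / ((1 - fit$r2) / (fit$n - fit$p - 1)),
                 tolerance = 1e-9)
    expect_equal(r_squared(fitted(fit), fit$y), fit$r2, tolerance = 1e-9)
    expect_equal(mean(residuals(fit)), 0, tolerance = 1e-12)
  }
})

test_that("partial ANOVA F equals the squared coefficient t statistic", {
  fit <- husk_full_fits()$TPC
  a <- anova(fit)
  per_term <- a[a$group %in% c("linear", "quadratic", "interaction"), ]
  expect_equal(per_term$f,
               unname(fit$t_value[per_term$term]^2), tolerance = 1e-9)
})

test_that("ANOVA group rows sum their members and the model row carries R2", {
  for (fit in husk_full_fits()[c("TPC", "AC")]) {
    a <- anova(fit)
    for (g in c("linear", "quadratic", "interaction")) {
      members <- a$contribution[a$group == g]
      expect_equal(a$contribution[a$term == g], sum(members),
                   tolerance = 1e-9)
    }
    expect_equal(a$contribution[a$term == "model"], 100 * fit$r2,
                 tolerance = 1e-9)
  }
})

test_that("sequential sums of squares add up to the model sum of squares", {
  fit <- husk_full_fits()$TOD
  a <- anova(fit, type = "sequential")
  per_term <- a[a$group %in% c("linear", "quadratic", "interaction"), ]
  expect_equal(sum(per_term$ss), fit$ssr, tolerance = 1e-9)
})

test_that("temperature dominates time in the standardized TPC coefficients", {
  fit <- husk_full_fits()$TPC
  s <- standardized_coef(fit)
  expect_gt(abs(s["X1"]), abs(s["X2"]))
  # ranking of linear standardized coefficients agrees with partial SS
  a <- anova(fit)
  lin <- a[a$group == "linear", ]
  expect_equal(order(-abs(s[lin$term])), order(-lin$ss))
})

test_that("single-pass reduction retains the significant hierarchical sets", {
  fits <- husk_full_fits()
  expect_setequal(reduce_model(fits$TF)$terms, c("X1", "X3", "X4", "X1^2"))
  expect_setequal(reduce_model(fits$TFL)$terms,
                  c("X1", "X3", "X4", "X1^2", "X3^2", "X1:X4", "X3:X4"))
  expect_setequal(reduce_model(fits$AC)$terms,
                  c("X1", "X2", "X3", "X4", "X1^2", "X3^2", "X1:X4",
                    "X2:X3", "X3:X4"))
  # hierarchy: X2 enters TOD only as a parent of its significant interactions
  tod <- reduce_model(fits$TOD)
  expect_true("X2" %in% tod$terms)
  expect_false("X2" %in% names(which(fits$TOD$p_value_terms[-1] < 0.05)))
  # without hierarchy closure the parent is not added back
  expect_false("X2" %in% reduce_model(fits$TOD, hierarchy = FALSE)$terms)
})

test_that("reduction is the identity when every term is significant", {
  des <- simulate_bbd(beta = c("(Intercept)" = 1, X1 = 2, X2 = -2),
                      sigma = 0.01, seed = 3)
  fit <- rsm_quad(des, "y", c("X1", "X2"))
  expect_identical(reduce_model(fit)$terms, fit$terms)
})

test_that("reduction of a pure-noise response warns and returns intercept only", {
  des <- simulate_bbd(beta = c("(Intercept)" = 5), sigma = 1, seed = 9)
  fit <- rsm_quad(des, "y")
  expect_warning(red <- reduce_model(fit, alpha = 1e-12),
                 "intercept-only")
  expect_length(red$terms, 0)
  expect_equal(unname(coef(red)), mean(des$y))
})

test_that("natural-unit equations predict identically to coded equations", {
  des <- coffee_husk_design()
  for (fit in list(husk_full_fits()$TPC, reduce_model(husk_full_fits()$TPC))) {
    nc <- natural_coef(fit)
    nat <- as.data.frame(des)[c("temperature", "time", "acidity", "sl_ratio")]
    names(nat) <- c("x1", "x2", "x3", "x4")
    pred_nat <- rep(nc[["(Intercept)"]], nrow(nat))
    for (tm in setdiff(names(nc), "(Intercept)")) {
      val <- if (grepl("\\^2$", tm)) nat[[sub("\\^2$", "", tm)]]^2
             else if (grepl(":", tm)) {
               ss <- strsplit(tm, ":", fixed = TRUE)[[1]]
               nat[[ss[1]]] * nat[[ss[2]]]
             } else nat[[tm]]
      pred_nat <- pred_nat + nc[[tm]] * val
    }
    expect_equal(pred_nat, unname(predict(fit, des)), tolerance = 1e-9)
  }
})

test_that("a pure linear coded slope rescales by the half-range", {
  des <- simulate_bbd(beta = c("(Intercept)" = 2, X1 = 1.4), sigma = 0,
                      seed = 5)
  fit <- rsm_quad(des, "y", "X1")
  nc <- natural_coef(fit)
  expect_equal(unname(nc["x1"]), 1.4 / 35, tolerance = 1e-9)
})

test_that("predictions behave at the centre, the design points and beyond", {
  fit <- husk_full_fits()$TPC
  centre <- data.frame(temperature = 65, time = 47.5, acidity = 1,
                       sl_ratio = 0.035)
  expect_equal(unname(predict(fit, centre)),
               unname(coef(fit)["(Intercept)"]), tolerance = 1e-12)
  expect_equal(unname(predict(fit, coffee_husk_design())),
               unname(fitted(fit)), tolerance = 1e-12)
  expect_warning(predict(fit, data.frame(temperature = 120, time = 47.5,
                                         acidity = 1, sl_ratio = 0.035)),
                 "outside the design region")
  expect_error(predict(fit, data.frame(bogus = 1)), "factor")
})

test_that("degenerate fitting inputs are rejected", {
  des <- tiny_design()
  expect_error(rsm_quad(des, "nope"), "unknown response")
  expect_error(rsm_quad(des, "y"), "too few runs")
  dup <- as.data.frame(des)
  dup$X1X1 <- NULL
  d2 <- as_design_table(dup, toy_factors(3))
  expect_error(rsm_quad(d2, "y", c("X1", "X1")), "singular")
  flat <- as.data.frame(des); flat$y <- 1
  expect_error(standardized_coef(rsm_quad(as_design_table(flat,
                                                          toy_factors(3)),
                                          "y", "X1")),
               "zero-variance")
})
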