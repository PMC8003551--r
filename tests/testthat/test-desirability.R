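test_that("the desirability ramp hits its boundary values", {
  expect_equal(desirability(1, L = 1, T = 2), 0)
  expect_equal(desirability(2, L = 1, T = 2), 1)
  expect_equal(desirability(1.5, L = 1, T = 2), 0.5)
  expect_equal(desirability(0.2, L = 1, T = 2), 0)
  expect_equal(desirability(9, L = 1, T = 2), 1)
  expect_equal(desirability(1.5, L = 1, T = 2, weight = 2), 0.25)
  expect_error(desirability(1, L = 2, T = 2), "T > L")
  expect_error(desirability(1, L = 1, T = 2, weight = 0), "positive")
})

test_that("desirability is invariant to rescaling response and bounds", {
  y <- seq(0, 3, by = 0.1)
  expect_equal(desirability(y, 1, 2), desirability(10 * y, 10, 20))
})

test_that("a monotone single-response model is optimized at the corner", {
  des <- simulate_bbd(beta = c("(Intercept)" = 5, X1 = 1, X2 = 0.5),
                      sigma = 0, seed = 2)
  fit <- rsm_quad(des, "y", c("X1", "X2"))
  opt <- maximize_desirability(list(y = fit), des, resolution = 11)
  best <- opt$optima[1, ]
  expect_equal(best$temperature, 100, tolerance = 1e-6)
  expect_equal(best$time, 90, tolerance = 1e-6)
  expect_equal(best$D, 1, tolerance = 1e-6)
})

test_that("overall desirability is a reorder-invariant geometric mean", {
  des <- coffee_husk_design()
  fits <- husk_full_fits()[c("TPC", "AC", "TOD")]
  o1 <- maximize_desirability(fits, des, resolution = 9)
  o2 <- maximize_desirability(rev(fits), des, resolution = 9)
  expect_equal(o1$optima$D, o2$optima$D, tolerance = 1e-9)
  expect_equal(o1$optima$temperature, o2$optima$temperature,
               tolerance = 1e-9)
  # D is bounded and the reported optima are ranked
  expect_true(all(o1$optima$D >= 0 & o1$optima$D <= 1))
  expect_gte(o1$optima$D[1], o1$optima$D[2])
})

test_that("the second optimum is genuinely separated from the first", {
  des <- coffee_husk_design()
  opt <- maximize_desirability(husk_full_fits(), des, resolution = 11)
  expect_equal(nrow(opt$optima), 2)
  fs <- husk_factors()
  c1 <- vapply(names(fs), function(n)
    code_value(opt$optima[[n]][1], fs[[n]]), 0)
  c2 <- vapply(names(fs), function(n)
    code_value(opt$optima[[n]][2], fs[[n]]), 0)
  expect_gte(sqrt(sum((c1 - c2)^2)), 0.5)
})

test_that("CV of a predicted/experimental pair uses the sample SD", {
  expect_equal(round(cv_percent(6.56, 6.89), 1), 3.5)
  expect_equal(round(cv_percent(5.83, 6.89), 1), 11.8)
  expect_equal(cv_percent(4, 4), 0)
  expect_equal(cv_percent(c(4, 6.56), c(4, 6.89))[2],
               cv_percent(6.56, 6.89))
  expect_error(cv_percent(1, -1), "zero mean")
})

test_that("validation reports pair every response with every condition", {
  des <- coffee_husk_design()
  fits <- husk_full_fits()[c("TPC", "AC")]
  conds <- data.frame(temperature = c(100, 100), time = c(90, 5),
                      acidity = 0, sl_ratio = 0.02)
  exper <- data.frame(TPC = c(6.89, 5.59), AC = c(23.42, 21.36))
  rep <- validation_report(fits, conds, exper)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$cv_rsm,
               cv_percent(rep$predicted_rsm, rep$experimental))
})
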