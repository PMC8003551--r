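test_that("the 70/15/15 split partitions 27 runs into 19/4/4", {
  s <- data_split(27, seed = 11)
  expect_length(s$train, 19)
  expect_length(s$validation, 4)
  expect_length(s$test, 4)
  expect_setequal(c(s$train, s$validation, s$test), 1:27)
  expect_length(intersect(s$train, s$validation), 0)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(data_split(27, seed = 11), data_split(27, seed = 11))
  expect_error(data_split(3, c(0.9, 0.05, 0.05)), "empty subset")
  expect_error(data_split(27, c(0.5, 0.5, 0.5)), "sum")
})

test_that("every run appears in the test subset across many splits", {
  seen <- integer(0)
  for (s in 1:100) seen <- union(seen, data_split(27, seed = s)$test)
  expect_setequal(seen, 1:27)
})

test_that("training is reproducible and respects its preconditions", {
  des <- coffee_husk_design()
  a <- mlp_surrogate(des, "TPC", restarts = 2, max_epochs = 50, seed = 5,
                     decay = 1e-3)
  b <- mlp_surrogate(des, "TPC", restarts = 2, max_epochs = 50, seed = 5,
                     decay = 1e-3)
  expect_identical(a$w_in, b$w_in)
  expect_identical(a$split, b$split)
  expect_error(mlp_surrogate(des, "TPC", max_epochs = 0), "max_epochs")
  expect_error(mlp_surrogate(des, "TPC", restarts = 0), "restarts")
  expect_error(mlp_surrogate(des, "nope"), "unknown response")
})

test_that("a zeroed network predicts the response midrange", {
  des <- coffee_husk_design()
  net <- mlp_surrogate(des, "TPC", restarts = 1, max_epochs = 10, seed = 1,
                       decay = 1e-3)
  net$w_in[] <- 0; net$b_hidden[] <- 0; net$w_out[] <- 0; net$b_out <- 0
  centre <- data.frame(temperature = 65, time = 47.5, acidity = 1,
                       sl_ratio = 0.035)
  expect_equal(unname(predict(net, centre)),
               (min(des$TPC) + max(des$TPC)) / 2, tolerance = 1e-12)
})

test_that("network predictions are smooth in the inputs", {
  des <- coffee_husk_design()
  net <- mlp_surrogate(des, "TPC", restarts = 3, max_epochs = 200, seed = 2)
  p0 <- predict(net, data.frame(temperature = 80, time = 40, acidity = 1,
                                sl_ratio = 0.03))
  p1 <- predict(net, data.frame(temperature = 80 + 1e-6, time = 40,
                                acidity = 1, sl_ratio = 0.03))
  expect_lt(abs(p1 - p0), 1e-3)
})

test_that("a noiseless quadratic surface is learned to high accuracy", {
  des <- simulate_bbd(sigma = 0, seed = 21)
  net <- mlp_surrogate(des, "y", restarts = 6, max_epochs = 500, seed = 21)
  expect_gt(r_squared(predict(net, des), des$y), 0.99)
})

test_that("validation-based selection yields a usable early-stopped network", {
  des <- coffee_husk_design()
  net <- mlp_surrogate(des, "AC", restarts = 10, max_epochs = 300, seed = 4,
                       select = "validation")
  expect_identical(net$selection, "validation")
  pred <- predict(net, des)
  expect_true(all(is.finite(pred)))
  # the validation subset is predicted better than the trivial mean model
  va <- net$split$validation
  expect_lt(mean((pred[va] - des$AC[va])^2), stats::var(des$AC))
})
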