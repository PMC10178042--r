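test_that("hidden activations follow the logistic sigmoid", {
  expect_equal(hidden_activations(matrix(0, 3, 2), matrix(1, 2, 4), rep(0, 4)),
               matrix(0.5, 3, 4))
  expect_equal(as.numeric(hidden_activations(matrix(1), matrix(1), 0)),
               1 / (1 + exp(-1)))
  # monotone in the pre-activation
  z <- seq(-4, 4, length.out = 30)
  h <- hidden_activations(matrix(z), matrix(1), 0)
  expect_true(all(diff(as.numeric(h)) > 0))
  expect_error(hidden_activations(matrix(0, 2, 3), matrix(1, 2, 4), rep(0, 4)),
               "feature count")
})

test_that("output weights match an independent square-system oracle", {
  # 2 samples, 1 feature, 2 hidden neurons with hand-set parameters:
  # H is square and nonsingular, so beta must equal solve(H, T)
  x <- matrix(c(0.5, 1.5), 2, 1)
  labels <- c(0L, 1L)
  omega <- matrix(c(0.3, -0.5), 1, 2)
  bias <- c(0.1, 0.2)
  h <- 1 / (1 + exp(-(x %*% omega + rep(1, 2) %o% bias)))
  t_mat <- rbind(c(1, 0), c(0, 1))
  oracle_beta <- solve(h, t_mat)
  model <- elm_train(x, labels, elm_config(2), omega = omega, bias = bias)
  expect_equal(model$beta, oracle_beta, tolerance = 1e-8)
  oracle_pred <- c(0L, 1L)[max.col(h %*% oracle_beta, ties.method = "first")]
  expect_identical(elm_predict(model, x), oracle_pred)
})

test_that("least-squares beta beats random alternatives in Frobenius norm", {
  set.seed(21)
  x <- matrix(rnorm(12 * 4), 12, 4)
  labels <- rep(0:2, 4)
  omega <- matrix(runif(4 * 6, -1, 1), 4, 6)
  bias <- runif(6, -1, 1)
  model <- elm_train(x, labels, elm_config(6), omega = omega, bias = bias)
  h <- hidden_activations(x, omega, bias)
  t_mat <- outer(labels, 0:2, "==") + 0
  res <- norm(h %*% model$beta - t_mat, "F")
  for (i in 1:100) {
    b_alt <- matrix(rnorm(6 * 3), 6, 3)
    expect_lte(res, norm(h %*% b_alt - t_mat, "F") + 1e-10)
  }
})

test_that("with L = n the ELM interpolates its training set", {
  set.seed(5)
  n <- 25
  x <- matrix(rnorm(n * 5), n, 5)
  labels <- rep(0:4, 5)
  model <- elm_train(x, labels, elm_config(n, seed = 17))
  expect_equal(mean(elm_predict(model, x) == labels), 1, tolerance = 1e-6)
})

test_that("random hidden parameters are reproducible and bounded", {
  set.seed(1)
  x <- matrix(rnorm(20), 10, 2)
  labels <- rep(0:1, 5)
  m1 <- elm_train(x, labels, elm_config(8, seed = 33))
  m2 <- elm_train(x, labels, elm_config(8, seed = 33))
  expect_identical(m1, m2)
  expect_true(all(m1$omega >= -1 & m1$omega <= 1))
  expect_true(all(m1$bias >= -1 & m1$bias <= 1))
  lo <- elm_train(x, labels, elm_config(8, weight_low = -0.1,
                                        weight_high = 0.1, seed = 2))
  expect_true(all(abs(lo$omega) <= 0.1))
})

test_that("prediction argmax honours dominance and tie-breaking", {
  x <- matrix(c(0.5, 1.5), 2, 1)
  model <- elm_train(x, c(0L, 1L), elm_config(2),
                     omega = matrix(c(0.3, -0.5), 1, 2), bias = c(0.1, 0.2))
  # a dominant output column forces every prediction to that class
  model$beta <- cbind(rep(0, 2), rep(100, 2))
  expect_identical(elm_predict(model, x), c(1L, 1L))
  # exact ties go to the lowest class index
  model$beta <- cbind(rep(1, 2), rep(1, 2))
  expect_identical(elm_predict(model, x), c(0L, 0L))
  expect_error(elm_train(x, c(0L, 2L), elm_config(2), classes = 0:1),
               "absent")
})

test_that("position packing round-trips with the documented layout", {
  set.seed(6)
  omega <- matrix(rnorm(12), 3, 4)
  bias <- rnorm(4)
  v <- pack_position(omega, bias)
  expect_identical(length(pack_position(matrix(0, 233, 120), numeric(120))),
                   28080L)
  back <- unpack_position(v, 3, 4)
  expect_equal(back$omega, omega)
  expect_equal(back$bias, bias)
  expect_equal(unpack_position(c(0.5, -0.2), 1, 1),
               list(omega = matrix(0.5), bias = -0.2))
  expect_error(unpack_position(v, 3, 5), "does not match")
})

test_that("model JSON serialisation round-trips", {
  set.seed(2)
  x <- matrix(rnorm(30), 15, 2)
  labels <- rep(0:2, 5)
  model <- elm_train(x, labels, elm_config(6, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_elm_model(model, path)
  back <- read_elm_model(path)
  expect_equal(back$omega, model$omega)
  expect_equal(back$beta, model$beta)
  expect_identical(elm_predict(back, x), elm_predict(model, x))
})
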