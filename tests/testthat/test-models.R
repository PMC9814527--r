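# Regression model suite contracts.

test_that("fit_ols_single recovers an exact line and validates input", {
  # three collinear points generated from the published C-O relationship
  x <- c(1.41, 1.42, 1.43)
  y <- 93.381 * x - 127.71
  m <- fit_ols_single(x, y, bond = "ii")
  expect_equal(m$slope, 93.381, tolerance = 1e-9)
  expect_equal(m$intercept, -127.71, tolerance = 1e-9)
  expect_equal(m$r2_train, 1, tolerance = 1e-12)
  expect_equal(m$fitted_n, 3L)

  flat <- fit_ols_single(x, c(2, 2, 2))
  expect_true(flat$degenerate)
  expect_equal(predict_linear(flat, 1.5), 2)

  expect_error(fit_ols_single(x[1:2], y[1:2]), "at least 3")
  expect_error(fit_ols_single(c(1.4, 1.4, 1.4), y), "degenerate x")
})

test_that("the published C-O model predicts as printed", {
  m <- published_co_model()
  expect_equal(m$slope, 93.381)
  expect_equal(m$intercept, -127.71)
  expect_equal(m$bond, "ii")
  expect_equal(predict_linear(m, 1.4170), 4.610877, tolerance = 1e-9)
  # root of the affine map
  expect_equal(predict_linear(m, 127.71 / 93.381), 0, tolerance = 1e-9)
  expect_warning(predict_linear(m, 3.5), "extrapolat")
})

test_that("predict_linear is monotone with the slope sign", {
  up <- published_co_model()                      # positive slope (C-O)
  r <- seq(1.30, 1.36, length.out = 20)
  expect_true(all(diff(predict_linear(up, r)) > 0))
  down <- fit_ols_single(c(0.96, 0.99, 1.02), c(6, 4, 2), bond = "i")
  expect_true(down$slope < 0)
  expect_true(all(diff(predict_linear(down, r)) < 0))
})

test_that("PLS1 reduces to OLS at full rank and fits noise-free data", {
  d <- linear_xy(n = 30, p = 3)
  ols <- lm(d$y ~ d$X)
  full <- fit_pls(d$X, d$y, n_latent = 3)
  expect_equal(predict(full, d$X), unname(fitted(ols)), tolerance = 1e-9)
  expect_lt(max(abs(predict(full, d$X) - d$y)), 1e-9)

  # single feature, one latent variable = simple OLS
  x1 <- d$X[, 1, drop = FALSE]
  m1 <- fit_pls(x1, d$y, n_latent = 1)
  o1 <- lm(d$y ~ x1)
  expect_equal(predict(m1, x1), unname(fitted(o1)), tolerance = 1e-9)

  expect_error(fit_pls(d$X, d$y, n_latent = 4), "n_latent")
  expect_error(fit_pls(d$X[1:4, ], d$y[1:4], n_latent = 3), "samples")
})

test_that("SVR honors the epsilon tube and its kernel contract", {
  d <- linear_xy(n = 25, p = 2)
  # linear kernel, tight tube, large C: training MAE below epsilon
  m <- fit_svr(d$X, d$y, kernel = "linear", C = 1000, epsilon = 0.01)
  expect_lt(mae(d$y, predict(m, d$X)), 0.01 + 1e-6)
  # a tube wider than the response range swallows the data
  wide <- fit_svr(d$X, d$y, kernel = "rbf", C = 10,
                  epsilon = diff(range(d$y)) * 2, gamma = 1)
  expect_lt(diff(range(predict(wide, d$X))), 1e-6)
  expect_error(fit_svr(d$X, d$y, kernel = "rbf", C = 10, epsilon = 0.1),
               "gamma")
  expect_error(fit_svr(d$X, d$y, kernel = "banana"), "arg")
})

test_that("random forest regression is seeded and memorizes without bagging", {
  d <- linear_xy(n = 20, p = 2, seed = 5)
  one <- fit_rfr(d$X, d$y, n_estimators = 1, max_depth = NULL, seed = 1,
                 replace = FALSE, sample_fraction = 1)
  expect_equal(predict(one, d$X), d$y, tolerance = 1e-9)
  a <- fit_rfr(d$X, d$y, n_estimators = 25, max_depth = 6, seed = 3)
  b <- fit_rfr(d$X, d$y, n_estimators = 25, max_depth = 6, seed = 3)
  expect_identical(predict(a, d$X), predict(b, d$X))
  const <- fit_rfr(d$X, rep(4.2, 20), n_estimators = 5, seed = 0)
  expect_equal(unique(round(predict(const, d$X), 9)), 4.2)
})

test_that("kernel_se_ard matches its closed form and is a valid kernel", {
  expect_equal(kernel_se_ard(c(1, 2), c(1, 2), c(0, 0)), 1)
  # unit scaled distance in 1-D
  expect_equal(kernel_se_ard(0, 1, 0), exp(-0.5), tolerance = 1e-12)
  expect_equal(kernel_se_ard(0, exp(2.5), 2.5), exp(-0.5), tolerance = 1e-12)
  # huge length scales flatten the kernel to 1
  expect_equal(kernel_se_ard(c(0, 0), c(5, -3), c(30, 30)), 1,
               tolerance = 1e-9)
  expect_error(kernel_se_ard(c(1, 2), 1, c(0, 0)), "equal length")
  # symmetry, boundedness, PD Gram after jitter on random points
  set.seed(8)
  X <- matrix(rnorm(12), 6, 2)
  K <- outer(seq_len(6), seq_len(6),
             Vectorize(function(i, j)
               kernel_se_ard(X[i, ], X[j, ], c(-0.3, 0.4))))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_true(min(eigen(K + diag(1e-10, 6))$values) > 0)
})

test_that("GPR interpolates noiseless data and is restart-deterministic", {
  x <- matrix(seq(0, 3, length.out = 10))
  y <- sin(x[, 1])
  g1 <- fit_gpr(x, y, restarts = 5, seed = 4)
  expect_lt(max(abs(predict(g1, x) - y)), 1e-6)
  g2 <- fit_gpr(x, y, restarts = 5, seed = 4)
  expect_equal(g1$log_marginal_likelihood, g2$log_marginal_likelihood)
  expect_equal(g1$log_lengthscales, g2$log_lengthscales)
  expect_error(fit_gpr(x, y, restarts = 0), "restarts")
})

test_that("GPR log marginal likelihood matches a dense-matrix oracle", {
  set.seed(10)
  X <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  g <- fit_gpr(X, y, restarts = 3, seed = 2)
  # oracle: direct dense evaluation at the fitted hyperparameters using
  # base solve() and determinant(), built on the scalar kernel
  n <- 5
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- g$kernel_variance *
      kernel_se_ard(g$X_train[i, ], g$X_train[j, ], g$log_lengthscales)
  Ky <- K + diag(g$noise_jitter, n)
  yc <- g$y_train
  ll_oracle <- drop(-0.5 * t(yc) %*% solve(Ky, yc) -
                      0.5 * as.numeric(determinant(Ky)$modulus) - n / 2 * log(2 * pi))
  expect_equal(g$log_marginal_likelihood, ll_oracle, tolerance = 1e-8)
  # the optimum beats the fixed all-zero hyperparameter baseline
  K0 <- outer(1:n, 1:n, Vectorize(function(i, j)
    kernel_se_ard(g$X_train[i, ], g$X_train[j, ], c(0, 0)))) +
    diag(1e-10, n)
  ll0 <- drop(-0.5 * t(yc) %*% solve(K0, yc) -
                0.5 * as.numeric(determinant(K0)$modulus) - n / 2 * log(2 * pi))
  expect_gte(g$log_marginal_likelihood, ll0 - 1e-8)
})

test_that("every fitter reproduces a noise-free affine trend at training points", {
  set.seed(21)
  X <- matrix(runif(40), 20, 2)
  y <- drop(X %*% c(2, -1)) + 0.5
  for (method in c("OLS", "PLS", "GPR_rbf")) {
    fit <- aiblpka:::fit_method(method, X, y,
                                list(n_latent = 2, restarts = 3), seed = 1)
    expect_lt(max(abs(predict(fit, X) - y)), 1e-6)
  }
  sv <- fit_svr(X, y, kernel = "linear", C = 1000, epsilon = 0.01)
  expect_lt(max(abs(predict(sv, X) - y)), 0.011)
})

test_that("model JSON serialization round-trips the linear model", {
  p <- withr::local_tempfile(fileext = ".json")
  model_to_json(published_co_model(), p)
  back <- model_from_json(p)
  expect_equal(back$slope, 93.381)
  expect_equal(back$intercept, -127.71)
  expect_equal(predict_linear(back, 1.42), predict_linear(published_co_model(), 1.42))
  g <- fit_gpr(matrix(1:6 / 2), sin(1:6), restarts = 2, seed = 0)
  js <- model_to_json(g)
  expect_true(jsonlite::validate(js))
})
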