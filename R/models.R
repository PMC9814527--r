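# Regression model suite: single-bond OLS (incl. the published C-O model),
# PLS1, epsilon-SVR, random-forest regression, and a from-scratch Gaussian
# process with the squared-exponential ARD kernel.
#
# Multi-feature methods (PLS, SVR, GPR) z-score their features with
# train-set constants before fitting; single-bond OLS works in raw Angstrom
# so its slope/intercept stay directly interpretable (pKa per Angstrom).

#' Fit a single-bond OLS model
#'
#' Ordinary least squares of pKa on one bond length, the core of the AIBL
#' approach: pKa = slope * r + intercept.
#'
#' @param lengths bond lengths in Angstrom (>= 3 values, non-constant).
#' @param pkas experimental pKa values, same length.
#' @param bond which diagnostic bond the lengths belong to: one of
#'   \code{"i"}..\code{"v"}.
#' @return A \code{linear_bond_model} with \code{slope} (pKa/Angstrom),
#'   \code{intercept} (pKa), \code{r2_train} (coefficient of determination
#'   on the fit data), \code{fitted_n} and a \code{degenerate} flag (TRUE
#'   when the response is constant and the slope collapses to 0).
#' @export
fit_ols_single <- function(lengths, pkas, bond = "ii") {
  lengths <- check_numeric_vector(lengths, "lengths")
  pkas <- check_numeric_vector(pkas, "pkas")
  if (length(lengths) != length(pkas)) stop2("lengths and pkas differ in length")
  if (length(lengths) < 3L) stop2("need at least 3 points for a single-bond fit")
  if (var(lengths) == 0) stop2("degenerate x: bond lengths are all equal")
  bond <- match.arg(bond, BOND_LABELS)
  fit <- lm(pkas ~ lengths)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((pkas - mean(pkas))^2)
  structure(list(bond = bond, slope = slope, intercept = intercept,
                 r2_train = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 fitted_n = length(pkas),
                 degenerate = ss_tot == 0 || slope == 0),
            class = "linear_bond_model")
}

#' Predict pKa from a bond length
#'
#' Affine evaluation slope * length + intercept.  Lengths outside the
#' plausible (0.5, 3.0) Angstrom window trigger an extrapolation warning,
#' not an error.
#'
#' @param model a \code{linear_bond_model}.
#' @param length bond length(s) in Angstrom.
#' @return Predicted pKa value(s).
#' @export
predict_linear <- function(model, length) {
  stopifnot(inherits(model, "linear_bond_model"))
  length <- check_numeric_vector(length, "length")
  if (any(length <= LENGTH_RANGE[1] | length >= LENGTH_RANGE[2]))
    warning("bond length outside the plausible window; extrapolating",
            call. = FALSE)
  model$slope * length + model$intercept
}

#' @export
predict.linear_bond_model <- function(object, newdata, ...) {
  predict_linear(object, newdata)
}

#' The published C-O single-bond model
#'
#' The reported model for bond ii (the enol C-O bond):
#' pKa = 93.381 r(CO) - 127.71, with r in Angstrom.
#'
#' @return A \code{linear_bond_model} with the published coefficients.
#' @export
published_co_model <- function() {
  structure(list(bond = "ii", slope = 93.381, intercept = -127.71,
                 r2_train = NA_real_, fitted_n = NA_integer_,
                 degenerate = FALSE),
            class = "linear_bond_model")
}

#' @export
print.linear_bond_model <- function(x, ...) {
  cat(sprintf("<linear_bond_model> bond %s: pKa = %.4f * r %+.4f (n = %s, r2 = %s)\n",
              x$bond, x$slope, x$intercept,
              ifelse(is.na(x$fitted_n), "?", x$fitted_n),
              ifelse(is.na(x$r2_train), "?", sprintf("%.3f", x$r2_train))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# PLS1 (NIPALS).  Univariate response; deterministic.

#' Fit a PLS1 regression
#'
#' Partial least squares with a single response, fitted by the standard
#' iterative (NIPALS) algorithm on z-scored features and a centered
#' response.  With \code{n_latent} equal to the feature count on full-rank
#' data, PLS1 coincides with multiple OLS.
#'
#' @param X numeric feature matrix (rows = compounds).
#' @param y numeric response (pKa).
#' @param n_latent number of latent variables, at most \code{ncol(X)}.
#' @return A \code{pls_model} predictor; use \code{predict()}.
#' @export
fit_pls <- function(X, y, n_latent) {
  X <- as.matrix(X)
  y <- check_numeric_vector(y, "y")
  if (nrow(X) != length(y)) stop2("X and y differ in length")
  if (n_latent < 1L || n_latent > ncol(X))
    stop2("n_latent must lie in 1..%d (number of features)", ncol(X))
  if (nrow(X) < n_latent + 2L) stop2("need at least n_latent + 2 samples")
  scaler <- make_scaler(X)
  Xs <- apply_scaler(X, scaler)
  y_mean <- mean(y)
  E <- Xs
  f <- y - y_mean
  W <- P <- matrix(0, ncol(X), n_latent)
  q <- numeric(n_latent)
  for (a in seq_len(n_latent)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {  # response fully deflated; stop early
      W <- W[, seq_len(a - 1L), drop = FALSE]
      P <- P[, seq_len(a - 1L), drop = FALSE]
      q <- q[seq_len(a - 1L)]
      break
    }
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - t * qa
    W[, a] <- w; P[, a] <- p; q[a] <- qa
  }
  beta <- if (length(q)) drop(W %*% solve(crossprod(P, W), q)) else
    numeric(ncol(X))
  structure(list(method = "PLS", n_latent = length(q), beta = beta,
                 scaler = scaler, y_mean = y_mean),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  Xs <- apply_scaler(as.matrix(newdata), object$scaler)
  drop(Xs %*% object$beta) + object$y_mean
}

# ---------------------------------------------------------------------------
# SVR (epsilon-insensitive), via the libsvm binding.

#' Fit an epsilon-insensitive support vector regression
#'
#' Wraps \code{e1071::svm} (eps-regression) on z-scored features with a
#' frozen dual tolerance of 1e-6 for cross-run determinism.  \code{gamma}
#' is required for (and only valid with) the RBF kernel.
#'
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param kernel "linear" or "rbf".
#' @param C cost parameter, > 0.
#' @param epsilon width of the insensitivity tube, >= 0.
#' @param gamma RBF kernel width (on standardized features).
#' @return An \code{svr_model} predictor; use \code{predict()}.
#' @export
fit_svr <- function(X, y, kernel = c("linear", "rbf"), C = 1, epsilon = 0.1,
                    gamma = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- check_numeric_vector(y, "y")
  if (C <= 0) stop2("C must be positive")
  if (epsilon < 0) stop2("epsilon must be non-negative")
  if (kernel == "rbf" && is.null(gamma))
    stop2("gamma is required for the rbf kernel")
  if (kernel == "linear" && !is.null(gamma))
    stop2("gamma is only meaningful for the rbf kernel")
  scaler <- make_scaler(X)
  Xs <- apply_scaler(X, scaler)
  fit <- e1071::svm(x = Xs, y = y, type = "eps-regression",
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    cost = C, epsilon = epsilon,
                    gamma = if (kernel == "rbf") gamma else 1 / ncol(Xs),
                    scale = FALSE, tolerance = 1e-6, fitted = FALSE)
  structure(list(method = paste0("SVR_", kernel), fit = fit, scaler = scaler,
                 hyperparams = list(C = C, epsilon = epsilon,
                                    gamma = if (kernel == "rbf") gamma)),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  Xs <- apply_scaler(as.matrix(newdata), object$scaler)
  # with every residual inside the tube libsvm keeps no support vectors and
  # the solution is the constant -rho
  if (object$fit$tot.nSV == 0L) return(rep(-object$fit$rho, nrow(Xs)))
  unname(predict(object$fit, Xs))
}

# ---------------------------------------------------------------------------
# Random-forest regression.

#' Fit a random-forest regression
#'
#' Seeded, single-threaded \code{ranger} ensemble; the prediction is the
#' mean over trees.  \code{replace}/\code{sample_fraction} default to the
#' standard bootstrap; disable both (replace = FALSE, sample_fraction = 1)
#' to make a single unlimited-depth tree memorize its training set.
#'
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param n_estimators number of trees, >= 1.
#' @param max_depth maximum tree depth; NULL for unlimited.
#' @param seed integer seed.
#' @param replace bootstrap with replacement (default TRUE).
#' @param sample_fraction fraction of rows sampled per tree.
#' @return An \code{rfr_model} predictor; use \code{predict()}.
#' @export
fit_rfr <- function(X, y, n_estimators = 25, max_depth = NULL, seed = 0,
                    replace = TRUE, sample_fraction = 1) {
  X <- as.matrix(X)
  y <- check_numeric_vector(y, "y")
  if (n_estimators < 1L) stop2("n_estimators must be >= 1")
  df <- data.frame(X)
  df$.y <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = n_estimators,
    max.depth = if (is.null(max_depth)) 0 else max_depth,
    min.node.size = 1,
    replace = replace, sample.fraction = sample_fraction,
    seed = as.integer(seed), num.threads = 1)
  structure(list(method = "RFR", fit = fit, columns = colnames(df)[-ncol(df)],
                 hyperparams = list(n_estimators = n_estimators,
                                    max_depth = max_depth, seed = seed)),
            class = "rfr_model")
}

#' @export
predict.rfr_model <- function(object, newdata, ...) {
  df <- data.frame(as.matrix(newdata))
  names(df) <- object$columns
  predict(object$fit, data = df, num.threads = 1)$predictions
}

# ---------------------------------------------------------------------------
# Gaussian process with the SE-ARD kernel (written from scratch).

#' Squared-exponential ARD kernel
#'
#' k(x, x') = exp(-1/2 sum_d (x_d - x'_d)^2 / l_d^2), with one length scale
#' per dimension, l_d = exp(log_lengthscales[d]) (the optimizer works in
#' log space so length scales stay positive).  Unit value at x = x'.
#'
#' @param x,x_prime numeric vectors of equal length.
#' @param log_lengthscales numeric vector, one log length scale per
#'   dimension.
#' @return Kernel value in (0, 1].
#' @export
kernel_se_ard <- function(x, x_prime, log_lengthscales) {
  if (length(x) != length(x_prime) ||
      length(x) != length(log_lengthscales))
    stop2("x, x_prime and log_lengthscales must have equal length")
  ell <- exp(log_lengthscales)
  exp(-0.5 * sum(((x - x_prime) / ell)^2))
}

# Gram matrix of the SE-ARD kernel between row sets A and B.
se_ard_gram <- function(A, B, log_lengthscales) {
  ell <- exp(log_lengthscales)
  As <- sweep(as.matrix(A), 2, ell, "/")
  Bs <- sweep(as.matrix(B), 2, ell, "/")
  d2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  exp(-0.5 * pmax(d2, 0))
}

# Cholesky with jitter escalation: start at `jitter`, multiply by 10 up to
# 1e-4; fail with diagnostics beyond that.
chol_with_jitter <- function(K, jitter = 1e-10, max_jitter = 1e-4) {
  j <- jitter
  repeat {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
    if (j >= max_jitter)
      stop2(paste("kernel matrix not positive definite even at jitter %g;",
                  "check for duplicated inputs or degenerate length scales"),
            j)
    j <- j * 10
  }
}

# Log marginal likelihood of a zero-mean GP with covariance
# sigma2 * K_ard + jitter * I.
gp_log_marginal_likelihood <- function(X, y, log_lengthscales, log_variance,
                                       jitter = 1e-10) {
  n <- length(y)
  K <- exp(log_variance) * se_ard_gram(X, X, log_lengthscales)
  cj <- chol_with_jitter(K, jitter)
  L <- cj$L
  alpha <- backsolve(L, forwardsolve(t(L), y))
  -0.5 * sum(y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
}

#' Fit a Gaussian process regression with the SE-ARD kernel
#'
#' Maximizes the log marginal likelihood over the per-dimension log length
#' scales and the log kernel variance with L-BFGS-B, restarted from
#' \code{restarts} seeded random initializations (the first start is always
#' the all-zero point).  No noise variance is learned: a small jitter
#' (1e-10, escalated tenfold on Cholesky failure up to 1e-4) keeps the
#' kernel matrix positive definite, so the posterior mean interpolates the
#' training data.  Features are z-scored and the response centered with
#' train-set constants.
#'
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param restarts number of optimizer starts, >= 1.
#' @param seed integer seed for the random initializations.
#' @param jitter base diagonal jitter.
#' @return A \code{gpr_model} with \code{log_lengthscales} (on standardized
#'   features), \code{kernel_variance}, \code{noise_jitter},
#'   \code{log_marginal_likelihood} and the retained training set; use
#'   \code{predict()}.
#' @export
fit_gpr <- function(X, y, restarts = 10, seed = 0, jitter = 1e-10) {
  X <- as.matrix(X)
  y <- check_numeric_vector(y, "y")
  if (nrow(X) != length(y)) stop2("X and y differ in length")
  if (nrow(X) < 2L) stop2("need at least 2 samples")
  if (restarts < 1L) stop2("restarts must be >= 1")
  scaler <- make_scaler(X)
  Xs <- apply_scaler(X, scaler)
  y_mean <- mean(y)
  yc <- y - y_mean
  d <- ncol(Xs)

  inits <- with_seed(seed, {
    lapply(seq_len(restarts), function(r) {
      if (r == 1L) rep(0, d + 1L) else rnorm(d + 1L)
    })
  })
  neg_ll <- function(par) {
    val <- tryCatch(
      gp_log_marginal_likelihood(Xs, yc, par[seq_len(d)], par[d + 1L],
                                 jitter = jitter),
      error = function(e) -Inf)
    if (!is.finite(val)) 1e10 else -val
  }
  best <- NULL
  for (init in inits) {
    opt <- tryCatch(
      # box constraints keep the kernel matrix numerically full rank on
      # z-scored features: length scales above ~e^3 are indistinguishable
      # from flat and only degrade conditioning
      optim(init, neg_ll, method = "L-BFGS-B",
            lower = c(rep(-15, d), -15), upper = c(rep(3, d), 8),
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop2("GPR optimization failed from every restart")
  par <- best$par
  log_ls <- par[seq_len(d)]
  log_var <- par[d + 1L]
  K <- exp(log_var) * se_ard_gram(Xs, Xs, log_ls)
  cj <- chol_with_jitter(K, jitter)
  alpha <- backsolve(cj$L, forwardsolve(t(cj$L), yc))
  # iterative refinement against the jitter-free kernel: drives the
  # posterior mean back onto the training targets (noiseless model)
  res_prev <- Inf
  for (it in 1:5) {
    r <- yc - drop(K %*% alpha)
    if (max(abs(r)) < 1e-12 || max(abs(r)) >= res_prev) break
    res_prev <- max(abs(r))
    alpha <- alpha + backsolve(cj$L, forwardsolve(t(cj$L), r))
  }
  structure(list(method = "GPR_rbf",
                 log_lengthscales = log_ls,
                 kernel_variance = exp(log_var),
                 noise_jitter = cj$jitter,
                 restarts = restarts,
                 log_marginal_likelihood = -best$value,
                 X_train = Xs, y_train = yc, alpha = alpha,
                 scaler = scaler, y_mean = y_mean),
            class = "gpr_model")
}

#' @export
predict.gpr_model <- function(object, newdata, ...) {
  Xs <- apply_scaler(as.matrix(newdata), object$scaler)
  Kstar <- exp(log(object$kernel_variance)) *
    se_ard_gram(Xs, object$X_train, object$log_lengthscales)
  drop(Kstar %*% object$alpha) + object$y_mean
}

#' @export
print.gpr_model <- function(x, ...) {
  cat(sprintf(
    "<gpr_model> SE-ARD, %d dims; log length scales %s; variance %.4g; logML %.4f (%d restarts)\n",
    length(x$log_lengthscales),
    paste(sprintf("%.3f", x$log_lengthscales), collapse = ", "),
    x$kernel_variance, x$log_marginal_likelihood, x$restarts))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Multiple OLS (used by subset selection alongside the other methods).

fit_ols_multi <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- lm(y ~ ., data = data.frame(X, y = y))
  structure(list(method = "OLS", fit = fit, columns = colnames(X)),
            class = "olsm_model")
}

#' @export
predict.olsm_model <- function(object, newdata, ...) {
  df <- data.frame(as.matrix(newdata))
  names(df) <- object$columns
  unname(predict(object$fit, newdata = df))
}

# Unified fitting front-end used by cross-validation and selection.
# `hyperparams` is a named list; missing entries fall back to the reported
# optima (see default_grids()).
fit_method <- function(method, X, y, hyperparams = list(), seed = 0) {
  switch(method,
    OLS = fit_ols_multi(X, y),
    PLS = fit_pls(X, y,
                  n_latent = hyperparams$n_latent %||% min(3L, ncol(as.matrix(X)))),
    SVR_linear = fit_svr(X, y, kernel = "linear",
                         C = hyperparams$C %||% 1000,
                         epsilon = hyperparams$epsilon %||% 0.1),
    SVR_rbf = fit_svr(X, y, kernel = "rbf",
                      C = hyperparams$C %||% 1000,
                      epsilon = hyperparams$epsilon %||% 0.01,
                      gamma = hyperparams$gamma %||% 5),
    RFR = fit_rfr(X, y,
                  n_estimators = hyperparams$n_estimators %||% 25,
                  max_depth = hyperparams$max_depth %||% 6,
                  seed = seed),
    GPR_rbf = fit_gpr(X, y, restarts = hyperparams$restarts %||% 5,
                      seed = seed),
    stop2("unknown method '%s'", method))
}

MODEL_METHODS <- c("OLS", "PLS", "SVR_linear", "SVR_rbf", "RFR", "GPR_rbf")

#' Serialize a fitted model to JSON
#'
#' Writes the method name, hyperparameters, standardization constants and
#' coefficients/length scales, plus a simple checksum of the training data,
#' to a JSON string (or file when \code{path} is given).
#'
#' @param model a fitted model object from this package.
#' @param path optional output file.
#' @return The JSON string, invisibly when written to file.
#' @export
model_to_json <- function(model, path = NULL) {
  payload <- if (inherits(model, "linear_bond_model")) {
    list(type = "linear_bond_model", bond = model$bond, slope = model$slope,
         intercept = model$intercept, r2_train = model$r2_train,
         fitted_n = model$fitted_n)
  } else if (inherits(model, "pls_model")) {
    list(type = "pls_model", n_latent = model$n_latent, beta = model$beta,
         scaler = model$scaler, y_mean = model$y_mean)
  } else if (inherits(model, "gpr_model")) {
    list(type = "gpr_model", log_lengthscales = model$log_lengthscales,
         kernel_variance = model$kernel_variance,
         noise_jitter = model$noise_jitter,
         log_marginal_likelihood = model$log_marginal_likelihood,
         scaler = model$scaler, y_mean = model$y_mean,
         train_checksum = round(sum(model$X_train) + sum(model$alpha), 8))
  } else if (inherits(model, c("svr_model", "rfr_model"))) {
    list(type = class(model)[1], method = model$method,
         hyperparams = model$hyperparams, scaler = model$scaler)
  } else stop2("cannot serialize objects of class %s", class(model)[1])
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a linear bond model from JSON
#'
#' @param path JSON file produced by \code{\link{model_to_json}} for a
#'   \code{linear_bond_model}.
#' @return The reconstructed \code{linear_bond_model}.
#' @export
model_from_json <- function(path) {
  payload <- jsonlite::fromJSON(path)
  if (!identical(payload$type, "linear_bond_model"))
    stop2("only linear_bond_model JSON can be reloaded (got '%s')",
          payload$type %||% "?")
  structure(list(bond = payload$bond, slope = payload$slope,
                 intercept = payload$intercept,
                 r2_train = payload$r2_train %||% NA_real_,
                 fitted_n = payload$fitted_n %||% NA_integer_,
                 degenerate = FALSE),
            class = "linear_bond_model")
}
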