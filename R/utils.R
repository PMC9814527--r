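# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  All stochastic code in the package goes through
# this so that seeds are explicit and runs are reproducible.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# The five diagnostic bonds of the keto-enol fragment, in canonical order.
# Roman labels follow the field's convention: i = O-H, ii = C-O(enol),
# iii = C=C, iv = C-C, v = C=O(keto).
BOND_LABELS <- c("i", "ii", "iii", "iv", "v")
FEATURE_COLUMNS <- c(i = "r_OH", ii = "r_CO", iii = "r_CC_double",
                     iv = "r_CC_single", v = "r_CO_double")

# Plausible length window (Angstrom) shared by the feature-vector validity
# check and extrapolation warnings.
LENGTH_RANGE <- c(0.5, 3.0)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_numeric_vector <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop2("'%s' must be a finite numeric vector", name)
  x
}

# z-score standardization used (with train-set constants) by PLS, SVR and GPR.
make_scaler <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sig <- apply(X, 2, sd)
  sig[sig == 0 | !is.finite(sig)] <- 1
  list(mean = mu, sd = sig)
}

apply_scaler <- function(X, scaler) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}
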