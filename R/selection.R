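# Model-selection protocol: exhaustive feature-subset enumeration, seeded
# k-fold cross-validation, hyperparameter grid search, outlier flagging
# against the five single-bond models, and congeneric sub-series discovery.

#' Enumerate all non-empty feature subsets
#'
#' All 2^n - 1 subsets of n features in the canonical order: by size, then
#' lexicographically within a size.  For the five keto-enol bonds this
#' yields the 31 candidate models, with model_id 1..31.
#'
#' @param n_features number of features, 1..16.
#' @return A list of subsets; each element has \code{model_id} and
#'   \code{members} (sorted integer indices).
#' @export
enumerate_subsets <- function(n_features) {
  if (n_features < 1L || n_features > 16L)
    stop2("n_features must lie in 1..16")
  out <- list()
  for (size in seq_len(n_features)) {
    combos <- utils::combn(n_features, size, simplify = FALSE)
    out <- c(out, combos)
  }
  lapply(seq_along(out), function(i)
    list(model_id = i, members = out[[i]]))
}

# Feature-matrix columns for a subset of the five bonds.
subset_matrix <- function(ds, members) {
  cols <- unname(FEATURE_COLUMNS[members])
  as.matrix(as.data.frame(ds)[cols])
}

#' Subset members as bond labels
#' @param subset an element of \code{\link{enumerate_subsets}} output.
#' @return Character vector of roman bond labels.
#' @export
subset_bonds <- function(subset) BOND_LABELS[subset$members]

# Records a fold evaluation is run on: training split with complete
# features.
cv_records <- function(ds) {
  stopifnot(inherits(ds, "aibl_dataset"))
  keep <- ds$split == "train" & has_features(ds)
  if (!any(keep)) keep <- ds$split != "excluded" & has_features(ds)
  ds[keep, , drop = FALSE]
}

#' Seeded k-fold cross-validation
#'
#' Records are ordered canonically by id, shuffled with a seeded
#' Fisher-Yates permutation and cut into k contiguous folds whose sizes
#' differ by at most one; the model is refit k times and held-out
#' predictions pooled.  The headline \code{rmsee_cv} is the RMSE of the
#' pooled held-out residuals; the fold-averaged RMSE is also reported.
#'
#' @param ds an \code{\link{aibl_dataset}} (its training split is used).
#' @param subset a feature subset from \code{\link{enumerate_subsets}}.
#' @param method one of \code{"OLS"}, \code{"PLS"}, \code{"SVR_linear"},
#'   \code{"SVR_rbf"}, \code{"RFR"}, \code{"GPR_rbf"}.
#' @param hyperparams named list of hyperparameters for the method.
#' @param k number of folds, >= 2 and at most the training size.
#' @param seed integer seed controlling the fold assignment.
#' @return A \code{cv_result}: subset, method, hyperparams, per-fold RMSE,
#'   pooled \code{rmsee_cv} and \code{mae_cv}, fold-averaged
#'   \code{rmsee_foldmean}, pooled held-out predictions and \code{q2_cv}
#'   (squared Pearson correlation of observed vs pooled held-out
#'   predictions).
#' @export
kfold_cv <- function(ds, subset, method, hyperparams = list(), k = 7,
                     seed = 0) {
  method <- match.arg(method, MODEL_METHODS)
  rec <- cv_records(ds)
  n <- nrow(rec)
  if (k < 2L) stop2("k must be >= 2")
  if (n < k) stop2("training size %d smaller than k = %d", n, k)
  rec <- rec[order(rec$id), , drop = FALSE]   # invariant to input order
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold_of <- integer(n)
  fold_of[perm] <- rep(seq_len(k), sizes)
  X <- subset_matrix(rec, subset$members)
  y <- rec$pka_exp
  pred <- numeric(n)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    hold <- fold_of == f
    fit <- fit_method(method, X[!hold, , drop = FALSE], y[!hold],
                      hyperparams, seed = seed)
    pred[hold] <- predict(fit, X[hold, , drop = FALSE])
    per_fold[f] <- rmse(y[hold], pred[hold])
  }
  structure(list(subset = subset, method = method, hyperparams = hyperparams,
                 per_fold_rmse = per_fold,
                 rmsee_cv = rmse(y, pred),
                 mae_cv = mae(y, pred),
                 rmsee_foldmean = mean(per_fold),
                 q2_cv = if (sd(pred) > 0) r2_pearson_sq(y, pred) else NA_real_,
                 fold_seed = seed, n = n,
                 held_out = data.frame(id = rec$id, observed = y,
                                       predicted = pred, fold = fold_of,
                                       stringsAsFactors = FALSE)),
            class = "cv_result")
}

#' Default hyperparameter grids
#'
#' Grids bracketing the reported optima: C in \{1, 10, 100, 1000\},
#' epsilon in \{0.01, 0.1, 1\}, gamma in \{0.5, 1, 5, 10\} (RBF only),
#' n_estimators in \{10, 25, 50, 100\}, max_depth in \{2, 4, 6, 8\}, and
#' LV from 1 to the subset size.  OLS and GPR have no grid (GPR learns its
#' length scales by marginal-likelihood maximization).
#'
#' @param method a method name.
#' @param subset_size number of features in the candidate subset.
#' @return Named list of candidate value vectors (possibly empty).
#' @export
default_grids <- function(method, subset_size = 5L) {
  switch(method,
    OLS = list(),
    PLS = list(n_latent = seq_len(subset_size)),
    SVR_linear = list(C = c(1, 10, 100, 1000), epsilon = c(0.01, 0.1, 1)),
    SVR_rbf = list(C = c(1, 10, 100, 1000), epsilon = c(0.01, 0.1, 1),
                   gamma = c(0.5, 1, 5, 10)),
    RFR = list(n_estimators = c(10, 25, 50, 100), max_depth = c(2, 4, 6, 8)),
    GPR_rbf = list(),
    stop2("unknown method '%s'", method))
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every point of the grid by \code{\link{kfold_cv}} and returns
#' the first strict minimizer of the pooled cross-validated RMSE when the
#' grid values are sorted ascending -- so ties break toward smaller
#' hyperparameter magnitudes.
#'
#' @inheritParams kfold_cv
#' @param grid named list of candidate value vectors; must be non-empty.
#' @return A list with \code{hyperparams} (the winning point) and
#'   \code{cv} (its \code{cv_result}).
#' @export
grid_search <- function(ds, subset, method, grid, k = 7, seed = 0) {
  if (!length(grid)) stop2("empty grid")
  grid <- lapply(grid, sort)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  for (i in seq_len(nrow(pts))) {
    hp <- as.list(pts[i, , drop = FALSE])
    names(hp) <- names(pts)
    cv <- kfold_cv(ds, subset, method, hp, k = k, seed = seed)
    if (is.null(best) || cv$rmsee_cv < best$cv$rmsee_cv - 1e-12)
      best <- list(hyperparams = hp, cv = cv)
  }
  best
}

#' Select the best feature subset (and hyperparameters) per method
#'
#' For each method, evaluates all 2^5 - 1 = 31 bond subsets under seeded
#' k-fold cross-validation (with a per-subset grid search where the method
#' has tunable hyperparameters) and returns the configuration minimizing
#' the pooled cross-validated RMSE.  Subsets are visited in canonical
#' order (by size then lexicographic) and only strict improvements are
#' kept, so ties break toward fewer features, then smaller model_id, then
#' smaller hyperparameter magnitudes.  The full per-subset table is
#' retained for reporting.
#'
#' @inheritParams kfold_cv
#' @param methods character vector of method names.
#' @param grids optional named list (per method) overriding
#'   \code{\link{default_grids}}.
#' @return Named list (per method) with \code{subset}, \code{hyperparams},
#'   \code{cv} and a 31-row \code{table} (model_id, features, rmsee_cv,
#'   mae_cv).
#' @export
select_best_per_method <- function(ds, methods = c("OLS", "PLS"), k = 7,
                                   seed = 0, grids = NULL) {
  subsets <- enumerate_subsets(length(FEATURE_COLUMNS))
  out <- list()
  for (method in methods) {
    method <- match.arg(method, MODEL_METHODS)
    best <- NULL
    tab <- vector("list", length(subsets))
    for (s in subsets) {
      grid <- if (!is.null(grids) && !is.null(grids[[method]]))
        grids[[method]] else default_grids(method, length(s$members))
      res <- if (length(grid))
        grid_search(ds, s, method, grid, k = k, seed = seed)
      else
        list(hyperparams = list(),
             cv = kfold_cv(ds, s, method, list(), k = k, seed = seed))
      tab[[s$model_id]] <- data.frame(
        method = method, model_id = s$model_id,
        features = paste(BOND_LABELS[s$members], collapse = "+"),
        rmsee_cv = res$cv$rmsee_cv, mae_cv = res$cv$mae_cv,
        stringsAsFactors = FALSE)
      if (is.null(best) || res$cv$rmsee_cv < best$cv$rmsee_cv - 1e-12)
        best <- c(res, list(subset = s))
    }
    best$table <- do.call(rbind, tab)
    out[[method]] <- best
  }
  out
}

#' Flag outliers against the five single-bond models
#'
#' Fits all five single-bond OLS models on the full training data and
#' computes every compound's residual against each.  A compound is flagged
#' when at least \code{n_bonds_required} of its five absolute residuals
#' exceed \code{threshold} -- the "wrong for (almost) every bond" signature
#' of a record that does not belong to the modeled equilibrium.
#'
#' @param ds an \code{\link{aibl_dataset}} with complete features.
#' @param threshold residual threshold in pKa units; default 1.5.
#' @param n_bonds_required bonds that must exceed it; default 4.
#' @return A data frame with one row per compound: per-bond residuals
#'   (\code{res_i}..\code{res_v}), \code{n_bonds_exceeding},
#'   \code{threshold} and \code{flagged}.
#' @export
flag_outliers <- function(ds, threshold = 1.5, n_bonds_required = 4) {
  rec <- cv_records(ds)
  if (nrow(rec) < 3L) stop2("need at least 3 records with features")
  res <- matrix(NA_real_, nrow(rec), 5L,
                dimnames = list(NULL, paste0("res_", BOND_LABELS)))
  for (b in seq_along(BOND_LABELS)) {
    x <- rec[[FEATURE_COLUMNS[b]]]
    m <- fit_ols_single(x, rec$pka_exp, bond = BOND_LABELS[b])
    res[, b] <- predict_linear(m, x) - rec$pka_exp
  }
  n_exceed <- rowSums(abs(res) > threshold)
  data.frame(id = rec$id, res, n_bonds_exceeding = n_exceed,
             threshold = threshold,
             flagged = n_exceed >= n_bonds_required,
             stringsAsFactors = FALSE)
}

#' Fit a congeneric sub-series line
#'
#' OLS of pKa on the enol C-O length restricted to a motif-sharing subset
#' of compounds (e.g. the 5-C=O sub-series), reporting slope, intercept and
#' r-squared.  A near-unity r-squared indicates the members form their own
#' high-correlation congeneric series.
#'
#' @param ds an \code{\link{aibl_dataset}}.
#' @param motif_label free-text label for the shared structural motif.
#' @param member_ids ids of the member compounds (>= 3, all with features).
#' @return A list with \code{motif_label}, \code{n}, \code{slope},
#'   \code{intercept} and \code{r2}.
#' @export
discover_subseries <- function(ds, motif_label, member_ids) {
  stopifnot(inherits(ds, "aibl_dataset"))
  if (length(member_ids) < 3L) stop2("need at least 3 member ids")
  idx <- match(member_ids, ds$id)
  if (anyNA(idx))
    stop2("unknown id(s): %s", paste(member_ids[is.na(idx)], collapse = ", "))
  sub <- ds[idx, , drop = FALSE]
  if (!all(has_features(sub)))
    stop2("member(s) without features: %s",
          paste(sub$id[!has_features(sub)], collapse = ", "))
  m <- fit_ols_single(sub$r_CO, sub$pka_exp, bond = "ii")
  list(motif_label = motif_label, n = nrow(sub), slope = m$slope,
       intercept = m$intercept, r2 = m$r2_train)
}
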