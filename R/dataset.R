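# Dataset module: tabular compound records, CSV I/O, train/test splitting
# and the bundled 22-compound external test table.

#' Construct a compound dataset
#'
#' A data frame of compound records with columns \code{id}, \code{series},
#' \code{pka_exp}, the five feature columns \code{r_OH}, \code{r_CO},
#' \code{r_CC_double}, \code{r_CC_single}, \code{r_CO_double} (possibly NA),
#' \code{split} ("train", "test" or "excluded") and
#' \code{exclusion_reason}.  Ids must be unique and excluded records must
#' carry a reason.
#'
#' @param df data frame with at least \code{id} and \code{pka_exp}.
#' @param provenance free-text provenance note stored as an attribute.
#' @return The data frame, classed \code{aibl_dataset}.
#' @export
aibl_dataset <- function(df, provenance = "") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(c("id", "pka_exp") %in% names(df)))
    stop2("dataset needs 'id' and 'pka_exp' columns")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop2("duplicate compound id(s): %s",
          paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!is.numeric(df$pka_exp) || anyNA(df$pka_exp) || any(!is.finite(df$pka_exp)))
    stop2("pka_exp must be finite numeric for every record")
  if (is.null(df$series)) df$series <- ""
  for (col in FEATURE_COLUMNS)
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (is.null(df$split)) df$split <- "train"
  if (is.null(df$exclusion_reason)) df$exclusion_reason <- ""
  df$exclusion_reason[is.na(df$exclusion_reason)] <- ""
  bad <- setdiff(unique(df$split), c("train", "test", "excluded"))
  if (length(bad)) stop2("invalid split value(s): %s", paste(bad, collapse = ", "))
  if (any(df$split == "excluded" & !nzchar(df$exclusion_reason)))
    stop2("excluded records must carry a non-empty exclusion_reason")
  df <- df[c("id", "series", "pka_exp", unname(FEATURE_COLUMNS),
             "split", "exclusion_reason")]
  attr(df, "provenance") <- provenance
  class(df) <- c("aibl_dataset", "data.frame")
  df
}

has_features <- function(ds) {
  stats::complete.cases(as.data.frame(ds)[unname(FEATURE_COLUMNS)])
}

usable_records <- function(ds) ds[ds$split != "excluded", , drop = FALSE]

#' Read a feature table from CSV
#'
#' Expects a header with \code{id}, \code{pka} (or \code{pka_exp}) and
#' optionally the five feature columns, \code{series} and \code{split}.
#' Missing feature cells yield records without features.
#'
#' @param path path to a CSV file (comma-separated, "." decimal, UTF-8).
#' @return An \code{\link{aibl_dataset}}.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop2("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"pka_exp" %in% names(df) && "pka" %in% names(df))
    names(df)[names(df) == "pka"] <- "pka_exp"
  if (!all(c("id", "pka_exp") %in% names(df)))
    stop2("%s: header must contain 'id' and 'pka' columns", path)
  pk <- suppressWarnings(as.numeric(df$pka_exp))
  if (anyNA(pk))
    stop2("%s: non-numeric pKa for id(s): %s", path,
          paste(df$id[is.na(pk)], collapse = ", "))
  df$pka_exp <- pk
  aibl_dataset(df, provenance = path)
}

#' Write a feature table to CSV
#'
#' Inverse of \code{\link{read_feature_csv}} up to float formatting.
#'
#' @param ds an \code{\link{aibl_dataset}}.
#' @param path output CSV path.
#' @export
write_feature_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assign a random train/test split
#'
#' Deterministic seeded assignment over the usable (non-excluded) records.
#' The number of training records defaults to
#' \code{round(train_fraction * n)} but can be pinned with \code{n_train}
#' to reproduce an exact published count (e.g. 49:22 from 71 records, where
#' rounding 0.7 * 71 would give 50).  An explicit membership list can be
#' supplied instead via \code{train_ids}.
#'
#' @param ds an \code{\link{aibl_dataset}}.
#' @param train_fraction fraction of usable records to train on; default 0.7.
#' @param seed integer RNG seed.
#' @param n_train optional explicit training-set size, overriding the
#'   fraction.
#' @param train_ids optional character vector of ids to place in the
#'   training set (the explicit split-file interface); overrides both.
#' @return The dataset with its \code{split} column reassigned.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 0,
                          n_train = NULL, train_ids = NULL) {
  stopifnot(inherits(ds, "aibl_dataset"))
  usable <- which(ds$split != "excluded")
  if (length(usable) < 2L) stop2("need at least 2 usable records to split")
  if (!is.null(train_ids)) {
    unknown <- setdiff(train_ids, ds$id[usable])
    if (length(unknown))
      stop2("train_ids not in the usable records: %s",
            paste(unknown, collapse = ", "))
    ds$split[usable] <- ifelse(ds$id[usable] %in% train_ids, "train", "test")
    return(ds)
  }
  if (train_fraction <= 0 || train_fraction >= 1)
    stop2("train_fraction must lie strictly between 0 and 1")
  n <- length(usable)
  k <- if (is.null(n_train)) round(train_fraction * n) else as.integer(n_train)
  if (k < 1L || k >= n) stop2("training size %d leaves no test set", k)
  perm <- with_seed(seed, sample.int(n))
  ds$split[usable] <- "test"
  ds$split[usable[perm[seq_len(k)]]] <- "train"
  ds
}

#' Outlier exclusion list
#'
#' The two compounds removed from the training set before fitting the
#' single-bond models, shipped declaratively with their reasons: dk29
#' (second ionizable 2-pyridyl group, ambiguous dissociation) and tk3
#' (member of the high-correlation 5-C=O sub-series).
#'
#' @return A data frame with columns \code{id} and \code{reason}.
#' @export
outlier_exclusions <- function() {
  data.frame(
    id = c("dk29", "tk3"),
    reason = c("second ionizable 2-pyridyl group (dissociation ambiguity)",
               "member of the 5-C=O structural sub-series"),
    stringsAsFactors = FALSE)
}

#' Load the bundled 22-compound external test table
#'
#' The package ships a transcription of the published external test set:
#' experimental pKa for 22 cyclic 1,3-diketones (triketone, diketone, oxime
#' and tetracycline series) together with the predictions of eight methods
#' (single-bond C-O OLS, PLS, RFR, linear and RBF SVR, SE-ARD GPR, and the
#' Marvin program with and without tautomer consideration).
#'
#' @return A \code{prediction_table}: data frame with \code{id},
#'   \code{pka_exp} and one column per method (\code{co}, \code{pls},
#'   \code{rfr}, \code{svr_lin}, \code{svr_rbf}, \code{gpr_rbf},
#'   \code{marvin_taut}, \code{marvin_no_taut}).
#' @export
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_test_set.csv", package = "aiblpka",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 22L, !anyDuplicated(df$id), !anyNA(df$pka_exp))
  class(df) <- c("prediction_table", "data.frame")
  df
}

#' Method columns of a prediction table
#' @param table a \code{prediction_table}.
#' @return Character vector of prediction column names.
#' @export
prediction_methods <- function(table) {
  setdiff(names(table), c("id", "pka_exp"))
}

#' Invert the published C-O model over a prediction column
#'
#' The published single-bond model is pKa = 93.381 r(CO) - 127.71.  Applied
#' in reverse to the C-O prediction column, it recovers the bond length each
#' prediction implies: r = (prediction + 127.71) / 93.381.  This turns the
#' bundled test table into a regression-testable length fixture.
#'
#' @param table a \code{prediction_table} with a \code{co} column.
#' @return Named numeric vector, id -> implied r(CO) in Angstrom.
#' @export
implied_co_lengths <- function(table) {
  if (!"co" %in% names(table))
    stop2("prediction table has no C-O column")
  m <- published_co_model()
  setNames((table$co - m$intercept) / m$slope, table$id)
}
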