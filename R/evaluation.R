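#' Root-mean-square error for one drug
#'
#' `sqrt(mean((observed - predicted)^2))` over the cell lines with a
#' known response for that drug.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return non-negative scalar.
#' @export
drug_rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) == 0L) stop("empty vectors")
  sqrt(mean((observed - predicted)^2))
}

#' Pearson correlation for one drug
#'
#' Sample Pearson correlation between observed and predicted responses
#' over cell lines.  Undefined (returns `NA`) when fewer than 3 pairs
#' are available or either vector has zero variance; callers exclude
#' such drugs from drug-averaged metrics rather than imputing 0.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
drug_pcc <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted lengths differ")
  if (length(observed) < 3L) return(NA_real_)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) return(NA_real_)
  stats::cor(observed, predicted)
}

#' Split a drug's cell lines into sensitive and resistant quartiles
#'
#' Observed responses for the drug are split into quartiles (inclusive
#' linear-interpolation quantiles, R type 7); cell lines at or below Q1
#' form one extreme group and at or above Q3 the other.  Which extreme
#' is "sensitive" follows the response direction: the low quartile for
#' log-IC50 (`lower_is_sensitive`), the high quartile for activity area.
#'
#' @param R a [response_matrix()].
#' @param drug drug id (row name).
#' @return list with character vectors `sensitive` and `resistant`
#'   (cell ids).  When the drug has fewer than 8 observed cells or a
#'   degenerate (Q1 == Q3) spread it is excluded: an empty list of class
#'   `sr_split_excluded` is returned whose `reason` attribute names the
#'   cause.
#' @export
sensitive_resistant_split <- function(R, drug) {
  stopifnot(inherits(R, "response_matrix"))
  if (!drug %in% R$drug_ids) stop("unknown drug id: ", drug)
  vals <- R$values[drug, ]
  obs <- vals[R$mask[drug, ]]
  excluded <- function(why)
    structure(list(), class = "sr_split_excluded", reason = why)
  if (length(obs) < 8L)
    return(excluded("fewer than 8 observed cells"))
  q <- stats::quantile(obs, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] >= q[2])
    return(excluded("degenerate quartiles (Q1 >= Q3)"))
  low <- names(obs)[obs <= q[1]]
  high <- names(obs)[obs >= q[2]]
  if (R$direction == "lower_is_sensitive")
    list(sensitive = low, resistant = high)
  else
    list(sensitive = high, resistant = low)
}

as_entry_matrix <- function(heldout, dims) {
  if (is.logical(heldout) || (is.matrix(heldout) && all(dim(heldout) == dims) &&
                              all(heldout %in% c(0, 1, TRUE, FALSE)))) {
    which(heldout != 0, arr.ind = TRUE)
  } else if (is.matrix(heldout) && ncol(heldout) == 2L) {
    heldout
  } else stop("`heldout` must be a logical mask or a 2-column index matrix")
}

#' Per-drug prediction metrics with sensitive/resistant subsets
#'
#' Computes, for each drug, the Pearson correlation and RMSE between
#' observed and predicted responses over that drug's held-out entries,
#' plus the same two metrics restricted to held-out entries belonging to
#' the drug's sensitive or resistant cell lines
#' ([sensitive_resistant_split()], membership determined from the
#' observed values of the full matrix).  Drug-averaged metrics are the
#' arithmetic means over drugs with a defined value; drugs with
#' undefined metrics are excluded and counted, never imputed as 0.
#'
#' @param R a [response_matrix()] holding the observed truth.
#' @param predicted dense numeric matrix of the same dimensions.
#' @param heldout held-out entries to score: a logical mask or 2-column
#'   (drug index, cell index) matrix; must be a subset of the observed
#'   entries.  Defaults to all observed entries.
#' @return object of class `metrics_report`: list with `per_drug`
#'   (data frame: drug, n_used, pcc, rmse, n_sr_used, pcc_sr, rmse_sr),
#'   `drug_averaged` (named vector of the four means), and `excluded`
#'   (counts of drugs without a defined value per metric).
#' @export
evaluate_predictions <- function(R, predicted, heldout = NULL) {
  stopifnot(inherits(R, "response_matrix"))
  if (!all(dim(predicted) == dim(R$values)))
    stop("`predicted` dimensions do not match the response matrix")
  if (is.null(heldout)) heldout <- R$mask
  ent <- as_entry_matrix(heldout, dim(R$values))
  if (nrow(ent) == 0L) stop("no held-out entries to evaluate")
  if (any(!R$mask[ent]))
    stop("held-out entries must be observed entries of the response matrix")

  m <- nrow(R$values)
  per <- vector("list", m)
  for (i in seq_len(m)) {
    drug <- R$drug_ids[i]
    cols <- ent[ent[, 1] == i, 2]
    obs <- R$values[i, cols]
    pred <- predicted[i, cols]
    pcc <- if (length(cols) > 0L) drug_pcc(obs, pred) else NA_real_
    rmse <- if (length(cols) > 0L) drug_rmse(obs, pred) else NA_real_
    split <- sensitive_resistant_split(R, drug)
    if (length(split) == 0L) {
      n_sr <- 0L; pcc_sr <- NA_real_; rmse_sr <- NA_real_
    } else {
      sr_cells <- c(split$sensitive, split$resistant)
      keep <- R$cell_ids[cols] %in% sr_cells
      n_sr <- sum(keep)
      pcc_sr <- if (n_sr > 0L) drug_pcc(obs[keep], pred[keep]) else NA_real_
      rmse_sr <- if (n_sr > 0L) drug_rmse(obs[keep], pred[keep]) else NA_real_
    }
    per[[i]] <- data.frame(drug = drug, n_used = length(cols),
                           pcc = pcc, rmse = rmse, n_sr_used = n_sr,
                           pcc_sr = pcc_sr, rmse_sr = rmse_sr,
                           stringsAsFactors = FALSE)
  }
  per_drug <- do.call(rbind, per)
  cols <- c("pcc", "rmse", "pcc_sr", "rmse_sr")
  drug_averaged <- vapply(cols, function(cl)
    mean(per_drug[[cl]], na.rm = TRUE), numeric(1))
  excluded <- vapply(cols, function(cl) sum(is.na(per_drug[[cl]])),
                     integer(1))
  structure(list(per_drug = per_drug, drug_averaged = drug_averaged,
                 excluded = excluded, n_entries = nrow(ent)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report over %d held-out entries, %d drugs\n",
              x$n_entries, nrow(x$per_drug)))
  da <- x$drug_averaged
  cat(sprintf("  drug-averaged PCC %.4f | RMSE %.4f | PCC_S/R %.4f | RMSE_S/R %.4f\n",
              da["pcc"], da["rmse"], da["pcc_sr"], da["rmse_sr"]))
  if (any(x$excluded > 0))
    cat("  drugs excluded (undefined metric): ",
        paste(sprintf("%s=%d", names(x$excluded), x$excluded), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Randomly partition the observed entries into k folds
#'
#' Entry-wise cross-validation folds: individual observed matrix cells
#' (not whole rows or columns) are assigned fold labels uniformly at
#' random, with fold sizes differing by at most one.
#'
#' @param R a [response_matrix()].
#' @param k number of folds (>= 2, <= number of observed entries).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return object of class `fold_assignment`: list with `entries`
#'   (2-column index matrix over observed cells), `fold` (integer vector
#'   in `1..k`), `k`, `seed`.
#' @export
kfold_entries <- function(R, k, seed = 0L) {
  stopifnot(inherits(R, "response_matrix"))
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2")
  ent <- which(R$mask, arr.ind = TRUE)
  dimnames(ent) <- list(NULL, c("drug", "cell"))
  n <- nrow(ent)
  if (k > n) stop("`k` exceeds the number of observed entries (", n, ")")
  fold <- withr::with_seed(as.integer(seed),
                           sample(rep_len(seq_len(k), n)))
  structure(list(entries = ent, fold = fold, k = k,
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

# Mask one fold's entries out of the training response matrix.
mask_fold <- function(R, folds, j) {
  hold <- folds$entries[folds$fold == j, , drop = FALSE]
  mask <- R$mask
  mask[hold] <- FALSE
  vals <- R$values
  vals[!mask] <- NA_real_
  response_matrix(vals, direction = R$direction)
}

#' Entry-wise k-fold cross-validation of the factorization
#'
#' Splits the observed entries into `k` random folds; each fold in turn
#' is masked out of training, the model is fitted on the remaining
#' entries and the held-out cells are predicted.  The pooled out-of-fold
#' predictions are scored with [evaluate_predictions()] over all
#' observed entries.  The response is rescaled within each training fold
#' so no held-out information leaks into the scaling constant.
#'
#' @param R a [response_matrix()].
#' @param Sd,Sc similarity matrices (each may be `NULL` when its lambda
#'   is 0).
#' @param config an [srmf_config()].
#' @param k number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @return a `metrics_report` with attributes `folds` (the
#'   `fold_assignment`) and `predictions` (the pooled out-of-fold
#'   prediction matrix, `NA` where never held out).
#' @export
cross_validate <- function(R, Sd = NULL, Sc = NULL, config = srmf_config(),
                           k = 10L, seed = 0L) {
  folds <- kfold_entries(R, k, seed)
  pooled <- matrix(NA_real_, nrow(R$values), ncol(R$values),
                   dimnames = dimnames(R$values))
  for (j in seq_len(folds$k)) {
    train <- mask_fold(R, folds, j)
    fit <- srmf_fit(train, Sd = Sd, Sc = Sc, config = config)
    pred <- predict(fit)
    hold <- folds$entries[folds$fold == j, , drop = FALSE]
    pooled[hold] <- pred[hold]
  }
  report <- evaluate_predictions(R, ifelse(is.na(pooled), 0, pooled),
                                 heldout = folds$entries)
  attr(report, "folds") <- folds
  attr(report, "predictions") <- pooled
  report
}

#' Default regularization grid
#'
#' The conventional grid for the three penalty weights:
#' `lambda_l` in `2^-3 .. 2^2`, `lambda_d` and `lambda_c` in
#' `2^-5 .. 2^1` plus 0 — 6 x 8 x 8 = 384 configurations, enumerated in
#' lexicographic `(lambda_l, lambda_d, lambda_c)` order.
#'
#' @return data frame with columns `lambda_l`, `lambda_d`, `lambda_c`.
#' @export
default_lambda_grid <- function() {
  g <- expand.grid(lambda_c = c(2^(-5:1), 0),
                   lambda_d = c(2^(-5:1), 0),
                   lambda_l = 2^(-3:2),
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("lambda_l", "lambda_d", "lambda_c")]
}

#' Grid search over regularization weights by internal cross-validation
#'
#' Scores every `(lambda_l, lambda_d, lambda_c)` grid point by
#' entry-wise k-fold cross-validation on the supplied (training) data
#' and returns the configuration maximizing the selection metric
#' (drug-averaged PCC by default; RMSE-based metrics are minimized).
#' Ties break to the first grid point in enumeration order.  Call this
#' on training data only — running it on data later used for testing is
#' optimistic, and that nesting choice is the caller's.
#'
#' @param R training [response_matrix()].
#' @param Sd,Sc similarity matrices (optional per the lambdas).
#' @param grid data frame of candidate `lambda_l`, `lambda_d`,
#'   `lambda_c` rows; defaults to [default_lambda_grid()].
#' @param config base [srmf_config()] supplying K and the convergence
#'   controls.
#' @param k internal CV folds per grid point.
#' @param seed fold seed (shared across grid points so candidates see
#'   identical splits).
#' @param metric one of `"pcc"`, `"pcc_sr"` (maximized), `"rmse"`,
#'   `"rmse_sr"` (minimized).
#' @return list with `best_config` (an `srmf_config`), `best_score`,
#'   and `scores` (the grid with a `score` column).
#' @export
grid_search <- function(R, Sd = NULL, Sc = NULL, grid = default_lambda_grid(),
                        config = srmf_config(), k = 3L, seed = 0L,
                        metric = c("pcc", "pcc_sr", "rmse", "rmse_sr")) {
  metric <- match.arg(metric)
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("`grid` must be a non-empty data frame")
  need <- c("lambda_l", "lambda_d", "lambda_c")
  if (!all(need %in% colnames(grid)))
    stop("`grid` must have columns lambda_l, lambda_d, lambda_c")
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- config
    cfg$lambda_l <- grid$lambda_l[g]
    cfg$lambda_d <- grid$lambda_d[g]
    cfg$lambda_c <- grid$lambda_c[g]
    rep <- cross_validate(R, Sd = Sd, Sc = Sc, config = cfg,
                          k = k, seed = seed)
    score[g] <- rep$drug_averaged[[metric]]
  }
  ordered <- if (metric %in% c("pcc", "pcc_sr")) score else -score
  best <- which.max(ordered)          # first maximum in grid order
  best_config <- config
  best_config$lambda_l <- grid$lambda_l[best]
  best_config$lambda_d <- grid$lambda_d[best]
  best_config$lambda_c <- grid$lambda_c[best]
  list(best_config = best_config, best_score = score[best],
       scores = cbind(grid, score = score))
}
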