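# Scalar validation statistics used throughout: PRESS, SSY, LOO q2,
# external q2 variants, correlation-based R2, MSE/MAE/RMSE and k-fold Q2.

#' Predictive residual sum of squares
#'
#' `PRESS = sum (y_exp - y_calc)^2`.
#'
#' @param y_exp,y_calc numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
press <- function(y_exp, y_calc) {
  if (length(y_exp) != length(y_calc)) stop("length mismatch")
  if (length(y_exp) == 0L) stop("empty vectors")
  sum((y_exp - y_calc)^2)
}

#' Cross-validated q2 from leave-one-out predictions
#'
#' `q2 = 1 - PRESS / SSY` with `SSY = sum (y_exp - mean(y_exp))^2`.
#'
#' @param y_exp experimental values.
#' @param y_calc_loo leave-one-out predictions.
#' @return scalar `<= 1`.
#' @export
q2_loo <- function(y_exp, y_calc_loo) {
  if (length(y_exp) < 2L) stop("need at least 2 observations")
  ssy <- sum((y_exp - mean(y_exp))^2)
  if (ssy == 0) stop("degenerate target: zero variance in y_exp")
  1 - press(y_exp, y_calc_loo) / ssy
}

#' External-set q2 variants
#'
#' Both variants put the test-set PRESS in the numerator. `ext1` divides by
#' `sum (y_test - train_mean)^2` (deviation from the training mean); `ext2`
#' divides by `sum (y_test - mean(y_test))^2` (the test set's own spread).
#' The two coincide when the training mean equals the test mean.
#'
#' @param y_test experimental test values.
#' @param y_calc predicted test values.
#' @param train_mean mean of the training-set response (used by `ext1`).
#' @param variant `"ext1"` or `"ext2"`.
#' @return scalar.
#' @export
q2_external <- function(y_test, y_calc, train_mean, variant = c("ext1", "ext2")) {
  variant <- match.arg(variant)
  pr <- press(y_test, y_calc)
  denom <- if (variant == "ext1") {
    sum((y_test - train_mean)^2)
  } else {
    if (length(y_test) < 2L) stop("ext2 needs at least 2 test observations")
    sum((y_test - mean(y_test))^2)
  }
  if (denom == 0) stop("degenerate denominator in external q2")
  1 - pr / denom
}

#' Standard regression metrics
#'
#' `r2` is the squared Pearson correlation between `y` and `yhat` (NA when
#' either vector is constant); `mse`, `mae`, `rmse` have their usual
#' definitions.
#'
#' @param y,yhat numeric vectors.
#' @return named list `(r2, mse, mae, rmse)`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least 2 observations")
  res <- y - yhat
  r2 <- if (stats::sd(y) == 0 || stats::sd(yhat) == 0) NA_real_ else
    stats::cor(y, yhat)^2
  list(r2 = r2, mse = mean(res^2), mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)))
}

#' k-fold cross-validated Q2
#'
#' Splits the rows into `folds` shuffled folds (seeded), assembles
#' out-of-fold predictions, and returns
#' `Q2 = 1 - sum (y - yhat_oof)^2 / SSY` with SSY against the full-sample
#' mean, averaged over `repeats` repetitions.
#'
#' @param model_spec list with elements `fit(X, y) -> model` and
#'   `predict(model, X) -> yhat`.
#' @param X numeric matrix of features.
#' @param y numeric response.
#' @param folds number of folds (default 5).
#' @param repeats repetitions with fresh shuffles (default 1).
#' @param seed integer seed controlling the shuffles.
#' @return scalar Q2.
#' @export
q2_kfold <- function(model_spec, X, y, folds = 5, repeats = 1, seed = 1) {
  n <- length(y)
  if (folds < 2L || n < folds) stop("need n >= folds >= 2")
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) stop("degenerate target: zero variance in y")
  q2s <- vapply(seq_len(repeats), function(r) {
    set.seed((seed + 1000L * (r - 1L)) %% .Machine$integer.max)
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    yhat <- numeric(n)
    for (f in seq_len(folds)) {
      te <- which(fold_id == f); tr <- which(fold_id != f)
      m <- model_spec$fit(X[tr, , drop = FALSE], y[tr])
      yhat[te] <- model_spec$predict(m, X[te, , drop = FALSE])
    }
    1 - sum((y - yhat)^2) / ssy
  }, 0)
  mean(q2s)
}

#' Bundle the validation statistics of a model run
#'
#' @param y_train,yhat_loo training response and LOO predictions (optional).
#' @param y_test,yhat_test test response/predictions (optional).
#' @param train_mean training-set mean (defaults to `mean(y_train)`).
#' @return list of class `validation_report`.
#' @export
validation_report <- function(y_train = NULL, yhat_loo = NULL,
                              y_test = NULL, yhat_test = NULL,
                              train_mean = NULL) {
  out <- list(press = NA_real_, ssy = NA_real_, q2 = NA_real_,
              q2_ext1 = NA_real_, q2_ext2 = NA_real_,
              r2 = NA_real_, mse = NA_real_, mae = NA_real_, rmse = NA_real_,
              n_train = length(y_train), n_test = length(y_test))
  if (!is.null(y_train) && !is.null(yhat_loo)) {
    out$press <- press(y_train, yhat_loo)
    out$ssy <- sum((y_train - mean(y_train))^2)
    out$q2 <- q2_loo(y_train, yhat_loo)
    rm_ <- regression_metrics(y_train, yhat_loo)
    out[c("r2", "mse", "mae", "rmse")] <- rm_
  }
  if (!is.null(y_test) && !is.null(yhat_test)) {
    tm <- if (is.null(train_mean)) mean(y_train) else train_mean
    out$q2_ext1 <- q2_external(y_test, yhat_test, tm, "ext1")
    if (length(y_test) >= 2L) {
      out$q2_ext2 <- q2_external(y_test, yhat_test, tm, "ext2")
    }
  }
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  for (nm in c("press", "q2", "q2_ext1", "q2_ext2", "r2", "rmse")) {
    if (is.finite(x[[nm]])) cat(sprintf("  %-8s %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}
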