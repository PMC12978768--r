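# The Boltzmann-weighted conformer-ensemble activity model with an
# antipharmacophore shielding term:
#
#   A_n = A0 * sum_i delta_ni exp(-S_ni) exp(-E_ni/RT) / sum_i exp(-E_ni/RT)
#   S_ni = sum_j kappa_j a_ni^(j)
#
# where the sums run over the m_n retained conformers of compound n, delta
# gates the numerator only (a compound with no matching conformer predicts
# 0), E_ni are relative conformer energies (kcal/mol), and the kappa_j are
# adjustable constants fitted by nonlinear least squares. A0 is fixed to the
# reference compound's experimental pIC50, not fitted.

#' Shielding function S for one conformer
#'
#' `S = sum_j kappa_j * a^(j)` over the selected descriptor subset.
#'
#' @param a named (or positionally indexed) numeric descriptor vector for
#'   one conformer.
#' @param kappa numeric coefficients, one per selected descriptor.
#' @param descriptor_indices positions (or names) of the selected
#'   descriptors in `a`.
#' @return numeric scalar S.
#' @export
shielding <- function(a, kappa, descriptor_indices) {
  if (length(kappa) != length(descriptor_indices)) {
    stop("kappa and descriptor_indices must have equal length")
  }
  vals <- a[descriptor_indices]
  if (any(is.na(vals))) stop("descriptor missing from the vector")
  sum(kappa * vals)
}

#' Predict the activity of one compound from its conformer ensemble
#'
#' Evaluates the Boltzmann-weighted activity formula. The denominator sums
#' the Boltzmann factors of all retained conformers; the numerator is gated
#' by the pharmacophore indicator delta, so a compound in which no conformer
#' carries the pharmacophore predicts 0.
#'
#' @param delta 0/1 (or logical) pharmacophore flags, one per conformer.
#' @param rel_energies relative conformer energies, kcal/mol.
#' @param S shielding values, one per conformer.
#' @param A0 activity of the reference compound (pIC50).
#' @param T temperature in Kelvin (default 298.15).
#' @return predicted activity A_n (pIC50 scale).
#' @export
predict_one <- function(delta, rel_energies, S, A0, T = 298.15) {
  m <- length(rel_energies)
  if (m == 0L) stop("compound has no conformers")
  if (length(delta) != m || length(S) != m) {
    stop("delta, rel_energies and S must be aligned over conformers")
  }
  w <- exp(-(rel_energies - min(rel_energies)) / (R_GAS * T))
  A0 * sum(as.numeric(delta) * exp(-S) * w) / sum(w)
}

## ---- model data container --------------------------------------------------

#' Assemble per-compound model data for activity fitting
#'
#' Joins a descriptor panel, a conformer match table, an activity table and
#' the per-conformer relative energies into the per-compound structure the
#' fitting routines consume.
#'
#' @param panel a [descriptor_panel()].
#' @param match_table a `match_table` from [screen()] (or any data.frame
#'   with `compound_id`, `conformer_id`, `delta`).
#' @param activities an [activity_table()].
#' @param ensembles named list of [conformer_ensemble()] supplying
#'   `rel_energy` per conformer.
#' @return object of class `ecga_data`: a list of per-compound records
#'   (`compound_id`, `A_exp`, `split`, `rel_energies`, `delta`, `A` the
#'   m x p conformer-by-descriptor matrix).
#' @export
assemble_model_data <- function(panel, match_table, activities, ensembles) {
  stopifnot(inherits(panel, "descriptor_panel"), inherits(activities, "activity_table"))
  dnames <- descriptor_names(panel)
  key_mt <- paste(match_table$compound_id, match_table$conformer_id, sep = "/")
  delta_by_key <- stats::setNames(match_table$delta, key_mt)
  out <- lapply(activities$compound_id, function(id) {
    ens <- ensembles[[id]]
    if (is.null(ens)) stop(sprintf("no ensemble for compound %s", id))
    cids <- conformer_ids(ens)
    rows <- match(paste(id, cids, sep = "/"),
                  paste(panel$compound_id, panel$conformer_id, sep = "/"))
    if (any(is.na(rows))) stop(sprintf("descriptor rows missing for compound %s", id))
    dl <- delta_by_key[paste(id, cids, sep = "/")]
    if (any(is.na(dl))) stop(sprintf("match flags missing for compound %s", id))
    list(compound_id = id,
         A_exp = activities$pic50[activities$compound_id == id],
         split = activities$split[activities$compound_id == id],
         rel_energies = rel_energies(ens),
         delta = as.numeric(dl),
         A = as.matrix(panel[rows, dnames, drop = FALSE]))
  })
  names(out) <- activities$compound_id
  structure(out, class = "ecga_data", descriptor_names = dnames)
}

#' @export
print.ecga_data <- function(x, ...) {
  p <- length(attr(x, "descriptor_names"))
  cat(sprintf("<ecga_data> %d compounds, %d descriptors\n", length(x), p))
  invisible(x)
}

# predicted activities for all compounds at given kappa
predict_all <- function(data, kappa, descriptor_indices, A0, T) {
  vapply(data, function(cp) {
    S <- as.numeric(cp$A[, descriptor_indices, drop = FALSE] %*% kappa)
    predict_one(cp$delta, cp$rel_energies, S, A0, T)
  }, 0)
}

## ---- fitting ---------------------------------------------------------------

#' Fit the shielding coefficients kappa by nonlinear least squares
#'
#' Minimizes `sum_n (A_n^exp - A_n^calc(kappa))^2` over the training
#' compounds with the Levenberg-Marquardt algorithm (analytic Jacobian),
#' starting from `kappa = 0`. Optional seeded multistart adds random
#' restarts and keeps the best objective. Compounds in which no conformer
#' carries the pharmacophore predict 0 regardless of kappa; by default they
#' stay in the objective (contributing `A_exp^2`), since the model treats
#' the pharmacophore as necessary for activity; set
#' `include_nonmatching = FALSE` to drop them. A warning is emitted either
#' way when such compounds are present.
#'
#' @param data an `ecga_data` (see [assemble_model_data()]).
#' @param descriptor_indices positions of the selected descriptors
#'   (length N).
#' @param A0 reference activity; `"auto"` uses the maximum experimental
#'   pIC50 in `data`.
#' @param T temperature, Kelvin.
#' @param include_nonmatching keep all-delta-zero compounds in the
#'   objective (default TRUE).
#' @param n_starts number of optimizer starts (first is always kappa = 0).
#' @param seed integer seed for the extra random starts.
#' @param ftol convergence tolerance on the relative objective change.
#' @return object of class `ecga_model`.
#' @export
fit_kappa <- function(data, descriptor_indices, A0 = "auto", T = 298.15,
                      include_nonmatching = TRUE, n_starts = 1L, seed = 1L,
                      ftol = 1e-10) {
  stopifnot(inherits(data, "ecga_data"))
  N <- length(descriptor_indices)
  if (anyDuplicated(descriptor_indices)) stop("duplicate descriptor indices")
  A_exp_all <- vapply(data, `[[`, 0, "A_exp")
  if (identical(A0, "auto")) A0 <- max(A_exp_all)
  nonmatch <- vapply(data, function(cp) all(cp$delta == 0), TRUE)
  if (all(nonmatch)) stop("no compound has a matching conformer")
  if (any(nonmatch)) {
    warning(sprintf("%d compound(s) have no matching conformer and predict 0%s",
                    sum(nonmatch),
                    if (include_nonmatching) "" else " (excluded from the objective)"))
  }
  fit_data <- if (include_nonmatching) data else data[!nonmatch]
  A_exp <- vapply(fit_data, `[[`, 0, "A_exp")
  if (length(fit_data) < N + 1L) {
    warning("fewer training compounds than descriptors + 1")
  }

  # cache per-compound pieces: Boltzmann factors and gated descriptor rows
  pieces <- lapply(fit_data, function(cp) {
    w <- exp(-(cp$rel_energies - min(cp$rel_energies)) / (R_GAS * T))
    list(Asel = cp$A[, descriptor_indices, drop = FALSE],
         dw = cp$delta * w, wsum = sum(w))
  })
  calc <- function(kappa) {
    vapply(pieces, function(pc) {
      A0 * sum(pc$dw * exp(-as.numeric(pc$Asel %*% kappa))) / pc$wsum
    }, 0)
  }
  resid_fn <- function(kappa) A_exp - calc(kappa)
  jac_fn <- function(kappa) {
    # d resid_n / d kappa_j = + A0 * sum_i dw_i a_ij exp(-S_i) / wsum
    t(vapply(pieces, function(pc) {
      g <- pc$dw * exp(-as.numeric(pc$Asel %*% kappa))
      A0 * as.numeric(crossprod(pc$Asel, g)) / pc$wsum
    }, numeric(N)))
  }

  run_start <- function(k0) {
    minpack.lm::nls.lm(par = k0, fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         ftol = ftol, ptol = 1e-12, maxiter = 500))
  }
  starts <- list(rep(0, N))
  if (n_starts > 1L) {
    rs <- local_seed_runs(seed, n_starts - 1L, function() stats::runif(N, -1, 1))
    starts <- c(starts, rs)
  }
  fits <- lapply(starts, run_start)
  obj <- vapply(fits, function(f) sum(f$fvec^2), 0)
  best <- fits[[which.min(obj)]]
  kappa <- stats::setNames(as.numeric(best$par),
                           attr(data, "descriptor_names")[descriptor_indices])
  converged <- best$info %in% 1:4
  if (!converged) warning("optimizer did not converge; best iterate returned")

  model <- structure(
    list(A0 = A0, T = T,
         descriptor_indices = descriptor_indices,
         kappa = kappa,
         fit_report = list(objective = min(obj), iterations = best$niter,
                           converged = converged, seed = seed,
                           n_starts = n_starts),
         include_nonmatching = include_nonmatching,
         training_ids = names(fit_data)),
    class = "ecga_model")
  model$fitted_values <- predict_all(data, as.numeric(kappa),
                                     descriptor_indices, A0, T)
  model$residuals <- A_exp_all - model$fitted_values
  model
}

#' Fit the electron-conformational activity model
#'
#' High-level fitting interface: assembles the model data (if given raw
#' components) and fits the shielding coefficients. This is the package's
#' central model constructor; the returned `ecga_model` supports `print`,
#' `summary`, `coef`, `predict`, `fitted` and `residuals`.
#'
#' @inheritParams fit_kappa
#' @param ... passed through to [fit_kappa()].
#' @return an `ecga_model`.
#' @export
ecga_fit <- function(data, descriptor_indices, A0 = "auto", T = 298.15, ...) {
  fit_kappa(data, descriptor_indices, A0 = A0, T = T, ...)
}

#' @export
print.ecga_model <- function(x, ...) {
  cat(sprintf("Electron-conformational activity model (A0 = %.3f, T = %.2f K)\n",
              x$A0, x$T))
  cat(sprintf("  %d descriptors; objective (RSS) = %.6g; converged: %s\n",
              length(x$kappa), x$fit_report$objective, x$fit_report$converged))
  cat("  kappa:\n")
  print(round(x$kappa, 4))
  invisible(x)
}

#' @export
coef.ecga_model <- function(object, ...) object$kappa

#' @export
fitted.ecga_model <- function(object, ...) object$fitted_values

#' @export
residuals.ecga_model <- function(object, ...) object$residuals

#' @export
summary.ecga_model <- function(object, ...) {
  res <- object$residuals
  out <- list(model = object,
              rss = sum(res^2),
              rmse = sqrt(mean(res^2)),
              n = length(res))
  class(out) <- "summary.ecga_model"
  out
}

#' @export
print.summary.ecga_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  n = %d; training RMSE = %.4f pIC50\n", x$n, x$rmse))
  invisible(x)
}

#' Predict activities for compounds from a fitted model
#'
#' @param object an `ecga_model`.
#' @param newdata an `ecga_data` (defaults to nothing: use [fitted()] for
#'   training predictions).
#' @param ... unused.
#' @return named numeric vector of predicted pIC50 values.
#' @export
predict.ecga_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "ecga_data"))
  predict_all(newdata, as.numeric(object$kappa), object$descriptor_indices,
              object$A0, object$T)
}

#' @export
plot.ecga_model <- function(x, ...) {
  obs <- x$fitted_values + x$residuals
  plot(obs, x$fitted_values, xlab = "experimental pIC50",
       ylab = "calculated pIC50", main = "Activity model fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

## ---- leave-one-out and E statistics ----------------------------------------

#' Leave-one-out predictions of the activity model
#'
#' For each compound the kappa vector is refit on the remaining n - 1
#' compounds and the held-out compound's activity predicted. Feeds
#' [press()] and [q2_loo()].
#'
#' @inheritParams fit_kappa
#' @return data.frame of class `prediction_table` with columns
#'   `compound_id`, `A_exp`, `A_calc`, `split`.
#' @export
loo_predictions <- function(data, descriptor_indices, A0 = "auto",
                            T = 298.15, ...) {
  stopifnot(inherits(data, "ecga_data"))
  n <- length(data)
  if (n < 3L) stop("leave-one-out needs at least 3 compounds")
  if (identical(A0, "auto")) A0 <- max(vapply(data, `[[`, 0, "A_exp"))
  preds <- vapply(seq_len(n), function(i) {
    train <- data[-i]
    class(train) <- "ecga_data"
    attr(train, "descriptor_names") <- attr(data, "descriptor_names")
    m <- suppressWarnings(fit_kappa(train, descriptor_indices, A0 = A0, T = T, ...))
    ho <- data[i]
    class(ho) <- "ecga_data"
    attr(ho, "descriptor_names") <- attr(data, "descriptor_names")
    unname(predict(m, ho))
  }, 0)
  out <- data.frame(compound_id = names(data),
                    A_exp = vapply(data, `[[`, 0, "A_exp"),
                    A_calc = preds,
                    split = vapply(data, `[[`, "", "split"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Per-descriptor E statistics
#'
#' For each selected descriptor j, `E_j = PRESS(full model) /
#' PRESS(model with j eliminated)`, both from leave-one-out prediction.
#' Lower E marks a more influential descriptor (eliminating it hurts more).
#'
#' @inheritParams fit_kappa
#' @return named numeric vector of E values (NA where the reduced-model
#'   PRESS is 0).
#' @export
e_statistics <- function(data, descriptor_indices, A0 = "auto", T = 298.15,
                         ...) {
  N <- length(descriptor_indices)
  if (N < 2L) stop("E statistics need at least 2 descriptors")
  full <- loo_predictions(data, descriptor_indices, A0 = A0, T = T, ...)
  press_full <- press(full$A_exp, full$A_calc)
  E <- vapply(seq_len(N), function(j) {
    red <- loo_predictions(data, descriptor_indices[-j], A0 = A0, T = T, ...)
    pr <- press(red$A_exp, red$A_calc)
    if (pr == 0) NA_real_ else press_full / pr
  }, 0)
  nm <- attr(data, "descriptor_names")[descriptor_indices]
  stats::setNames(E, nm)
}

# run fn under n successive seeds derived from seed (restores RNG state)
local_seed_runs <- function(seed, n, fn) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  })
  lapply(seq_len(n), function(i) {
    set.seed((seed + i) %% .Machine$integer.max)
    fn()
  })
}
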