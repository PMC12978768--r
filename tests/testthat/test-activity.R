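test_that("shielding is the kappa-weighted descriptor sum and is homogeneous", {
  expect_equal(shielding(c(0.5, 0.1), c(0, 0), 1:2), 0)
  expect_equal(shielding(c(0.5, 0.1), c(1, -2), 1:2), 0.3)
  a <- stats::rnorm(5)
  expect_equal(shielding(2 * a, c(0.3, -1.1), c(2, 4)),
               2 * shielding(a, c(0.3, -1.1), c(2, 4)))
  expect_error(shielding(c(x = 1), c(1, 1), c("x", "y")), "missing")
})

test_that("the activity formula collapses correctly in degenerate ensembles", {
  A0 <- max(load_fixture("table1")$pic50)      # the reference compound row
  expect_equal(A0, 9.301)
  # all conformers carry the pharmacophore with zero shielding
  expect_equal(predict_one(c(1, 1, 1), c(0, 0.3, 0.7), c(0, 0, 0), A0), A0)
  # no conformer matches
  expect_equal(predict_one(c(0, 0), c(0, 0.4), c(0, 0), A0), 0)
  # equal energies, one of two matching
  expect_equal(predict_one(c(1, 0), c(0.2, 0.2), c(0, 0), A0), A0 / 2)
  expect_error(predict_one(numeric(0), numeric(0), numeric(0), A0), "no conformers")
})

test_that("activity predictions are shift-invariant, bounded and continuous in the tail", {
  set.seed(14)
  for (r in 1:20) {
    m <- sample(2:5, 1)
    delta <- stats::rbinom(m, 1, 0.7)
    E <- stats::runif(m, 0, 3)
    S <- stats::rnorm(m)
    A <- predict_one(delta, E, S, 9.3)
    expect_equal(A, predict_one(delta, E + 2.5, S, 9.3), tolerance = 1e-12)
    expect_true(A >= 0)
    if (all(S >= 0)) expect_true(A <= 9.3)
    # appending a non-matching, very high-energy conformer barely moves A
    A2 <- predict_one(c(delta, 0), c(E, 40), c(S, 0), 9.3)
    expect_equal(A, A2, tolerance = 1e-8)
  }
  expect_true(predict_one(1, 0, -1, 9.3) <= 9.3 * exp(1))
})

test_that("kappa is recovered exactly from noiseless forward data", {
  g <- gen_activity_data(synthetic_spec(seed = 3, n_active = 20, n_inactive = 20,
                                        noise_sd = 0, p_descriptors = 8,
                                        signal_indices = 1:4))
  m <- fit_kappa(g$data, g$signal_indices, A0 = g$A0)
  expect_lt(max(abs(as.numeric(coef(m)) - as.numeric(g$kappa_true))), 1e-3)
  expect_true(m$fit_report$converged)
  # descent: never worse than the kappa = 0 start
  obj0 <- sum((vapply(g$data, `[[`, 0, "A_exp") -
                 ecga4d:::predict_all(g$data, rep(0, 4), 1:4, g$A0, 298.15))^2)
  expect_lte(m$fit_report$objective, obj0)
})

test_that("the single-descriptor fit matches a golden-section oracle", {
  g <- gen_activity_data(synthetic_spec(seed = 5, n_active = 4, n_inactive = 4,
                                        noise_sd = 0.1, p_descriptors = 2,
                                        signal_indices = 1, kappa_true = 0.5))
  obj <- function(k) {
    sum((vapply(g$data, `[[`, 0, "A_exp") -
           ecga4d:::predict_all(g$data, k, 1L, g$A0, 298.15))^2)
  }
  gold <- stats::optimize(obj, c(-3, 3), tol = 1e-10)
  m <- fit_kappa(g$data, 1L, A0 = g$A0)
  expect_equal(unname(as.numeric(coef(m))), gold$minimum, tolerance = 1e-5)
  expect_equal(m$fit_report$objective, gold$objective, tolerance = 1e-8)
})

test_that("model methods expose coefficients, fits, residuals and predictions", {
  g <- gen_activity_data(synthetic_spec(seed = 19, n_active = 10, n_inactive = 10,
                                        noise_sd = 0.05))
  m <- ecga_fit(g$data, g$signal_indices, A0 = g$A0)
  expect_s3_class(m, "ecga_model")
  expect_length(coef(m), 4)
  expect_equal(fitted(m) + residuals(m),
               vapply(g$data, `[[`, 0, "A_exp"), tolerance = 1e-12)
  expect_equal(unname(predict(m, g$data)), unname(fitted(m)))
  expect_output(print(m), "kappa")
  expect_output(print(summary(m)), "RMSE")
})

test_that("compounds with no matching conformer are handled with a warning", {
  g <- gen_activity_data(synthetic_spec(seed = 23, n_active = 8, n_inactive = 8,
                                        noise_sd = 0, zero_delta_compounds = 2))
  expect_equal(g$data[[1]]$delta, rep(0, 3))
  expect_warning(m <- fit_kappa(g$data, g$signal_indices, A0 = g$A0),
                 "no matching conformer")
  expect_equal(unname(fitted(m)[1]), 0)
})

test_that("leave-one-out predictions equal naive refits and vanish on clean data", {
  g <- gen_activity_data(synthetic_spec(seed = 7, n_active = 10, n_inactive = 10,
                                        noise_sd = 0))
  lp <- loo_predictions(g$data, g$signal_indices, A0 = g$A0)
  expect_lte(press(lp$A_exp, lp$A_calc), 1e-6)
  expect_equal(q2_loo(lp$A_exp, lp$A_calc), 1, tolerance = 1e-6)

  g2 <- gen_activity_data(synthetic_spec(seed = 9, n_active = 3, n_inactive = 3,
                                         noise_sd = 0.2))
  lp2 <- loo_predictions(g2$data, g2$signal_indices, A0 = g2$A0)
  for (i in seq_along(g2$data)) {
    train <- g2$data[-i]
    class(train) <- "ecga_data"
    attr(train, "descriptor_names") <- attr(g2$data, "descriptor_names")
    mi <- fit_kappa(train, g2$signal_indices, A0 = g2$A0)
    ho <- g2$data[i]; class(ho) <- "ecga_data"
    attr(ho, "descriptor_names") <- attr(g2$data, "descriptor_names")
    expect_equal(lp2$A_calc[i], unname(predict(mi, ho)), tolerance = 1e-8)
  }

  tiny <- g2$data[1:2]; class(tiny) <- "ecga_data"
  attr(tiny, "descriptor_names") <- attr(g2$data, "descriptor_names")
  expect_error(loo_predictions(tiny, g2$signal_indices, A0 = g2$A0), "at least 3")
})

test_that("E statistics rank signal above noise and flag degenerate reductions", {
  g <- gen_activity_data(synthetic_spec(seed = 7, n_active = 30, n_inactive = 30,
                                        noise_sd = 0.05, p_descriptors = 6,
                                        signal_indices = 1:2,
                                        kappa_true = c(0.9, -0.7)))
  # fit over the two signal columns plus two pure-noise columns
  E <- e_statistics(g$data, c(1:2, 5:6), A0 = g$A0)
  expect_length(E, 4)
  # eliminating pure noise barely changes PRESS
  expect_true(all(E[3:4] > 0.8 & E[3:4] < 1.2))
  # eliminating true signal hurts most (smallest E)
  expect_lt(max(E[1:2]), min(E[3:4]))
})
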