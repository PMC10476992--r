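# Baseline MLR, OLS fitting, model selection/tuning, tolerance accuracy.

test_that("baseline regressions evaluate the coded-predictor equations", {
  pt <- default_pt_coefficients()
  tt <- default_tt_coefficients()
  zeros <- data.frame(X1 = 0, X2 = 0, X3 = 0, X4 = 0)
  expect_identical(mlr_predict_pt(pt, zeros), 3.551)
  expect_identical(mlr_predict_tt(tt, zeros), 3.5518)
  # hand arithmetic on the shipped coefficients
  expect_equal(mlr_predict_pt(pt, data.frame(X1 = 1, X2 = 0, X3 = 0)),
               3.551 - 0.0154)
  expect_equal(mlr_predict_tt(tt, data.frame(X1 = 0, X2 = 0, X3 = 0, X4 = 1)),
               3.5518 + 0.496)
  zero_c <- mlr_coefficients(0, c(0, 0, 0))
  expect_equal(mlr_predict_pt(zero_c, data.frame(X1 = 5, X2 = -2, X3 = 7)), 0)
  # weight-count contract: 3 for PT, 4 for TT
  expect_error(mlr_predict_pt(tt, zeros), "3 weights")
  expect_error(mlr_predict_tt(pt, zeros), "4 weights")
  expect_equal(minutes_to_seconds(3.551), 213.06)
})

test_that("predictor encoding follows the documented coding map", {
  co <- generate_cohort(cohort_config(200, seed = 3))
  enc <- encode_predictors(co)
  cm <- predictor_coding_map()
  expect_equal(enc$X1, unname(cm$X1_treatment_site[co$treatment_site]))
  expect_equal(enc$X2, as.integer(co$first_fraction))
  expect_true(all(enc$X4[co$irradiation_technology %in%
                           c("IMRT", "VMAT", "SBRT")] == 1))
  expect_true(all(enc$X4[co$irradiation_technology %in%
                           c("2D", "3D-CRT")] == 0))
})

test_that("OLS recovers noiseless generating coefficients exactly", {
  set.seed(10)
  x <- data.frame(a = rnorm(50), b = runif(50), c = rnorm(50))
  truth <- c(2.5, -1.2, 0.7)
  y <- 4.2 + as.matrix(x) %*% truth
  fit <- fit_mlr(x, y)
  expect_equal(fit$intercept, 4.2, tolerance = 1e-8)
  expect_equal(unname(fit$weights), truth, tolerance = 1e-8)
  # residual orthogonality to the design
  resid <- y - (fit$intercept + as.matrix(x) %*% fit$weights)
  expect_lt(max(abs(crossprod(as.matrix(x), resid))), 1e-8)
  # duplicated column -> rank error naming the column
  xdup <- cbind(x, a2 = x$a)
  expect_error(fit_mlr(xdup, y), "collinear.*a2")
})

test_that("OLS coefficient bias is within 3 SE under Gaussian noise", {
  set.seed(77)
  truth <- c(intercept = 600, a = 30, b = -12, c = 5)
  reps <- 200
  n <- 1000
  est <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    x <- cbind(a = stats::rnorm(n), b = stats::runif(n, 0, 4),
               c = sample(0:4, n, replace = TRUE))
    y <- truth[1] + x %*% truth[-1] + stats::rnorm(n, 0, 30)
    f <- fit_mlr(x, y)
    est[r, ] <- c(f$intercept, f$weights)
  }
  bias <- colMeans(est) - truth
  se <- apply(est, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(bias) < 3 * se))
})

constant_candidate <- function() {
  model_candidate("const",
                  fit = function(x, y, hyper, seed) list(mu = mean(y)),
                  predict = function(object, x) rep(object$mu, nrow(x)))
}

linear_candidate <- function() default_candidates()[[1]]

test_that("model selection picks the generating model and breaks ties first", {
  set.seed(5)
  x <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 100 + x %*% c(20, -10, 5) + rnorm(500, 0, 2)
  cfg <- model_selection_config(list(constant_candidate(), linear_candidate()),
                                k_folds = 5, seed = 42)
  sel <- select_model(x, y, cfg)
  expect_equal(sel$chosen, "linear")
  expect_lt(sel$cv_losses["linear"], sel$cv_losses["const"])

  single <- model_selection_config(list(constant_candidate()), k_folds = 3,
                                   seed = 1)
  expect_equal(select_model(x, y, single)$chosen, "const")

  # identical candidates under different names: first declared wins
  tie <- model_selection_config(list(
    model_candidate("first", linear_candidate()$fit, linear_candidate()$predict),
    model_candidate("second", linear_candidate()$fit, linear_candidate()$predict)),
    k_folds = 4, seed = 7)
  expect_equal(select_model(x, y, tie)$chosen, "first")

  tiny <- x[1:3, , drop = FALSE]
  expect_error(select_model(tiny, y[1:3], cfg), "fewer rows")
})

test_that("tuning minimizes CV loss over the grid with exact accounting", {
  set.seed(6)
  x <- matrix(rnorm(120 * 4), 120, 4)
  y <- drop(x %*% c(3, -2, 1, 0.5))  # noiseless linear truth

  # regularization can only hurt a noiseless linear fit
  ridge <- default_candidates()[[2]]
  ridge$space <- list(lambda = c(1e-8, 1e4))
  cfg <- model_selection_config(list(ridge), k_folds = 4, seed = 11)
  tuned <- tune_hyperparameters(ridge, x, y, cfg)
  expect_equal(tuned$hyper$lambda, 1e-8)

  # a 3-point grid triggers exactly 3*K fits
  calls <- new.env(); calls$n <- 0L
  counted <- model_candidate(
    "counted",
    fit = function(x, y, hyper, seed) { calls$n <- calls$n + 1L
                                        list(mu = mean(y) + hyper$shift) },
    predict = function(object, x) rep(object$mu, nrow(x)),
    default_hyper = list(shift = 0),
    space = list(shift = c(-1, 0, 1)))
  cfg2 <- model_selection_config(list(counted), k_folds = 5, seed = 2)
  tuned2 <- tune_hyperparameters(counted, x, y, cfg2)
  expect_equal(calls$n, 3L * 5L)
  expect_equal(tuned2$n_evaluations, 15L)
  expect_equal(tuned2$hyper$shift, 0)

  # empty space: defaults returned untouched, nothing evaluated
  none <- tune_hyperparameters(linear_candidate(), x, y, cfg2)
  expect_equal(none$strategy, "none")
  expect_equal(none$n_evaluations, 0L)
})

test_that("CV losses equal an independent fold-loop oracle", {
  set.seed(8)
  x <- matrix(rnorm(200 * 3), 200, 3)
  y <- 50 + drop(x %*% c(5, -3, 2)) + rnorm(200, 0, 4)
  cfg <- model_selection_config(list(linear_candidate()), k_folds = 5,
                                seed = 31)
  got <- cv_loss(linear_candidate(), list(), x, y, cfg)
  folds <- cv_folds(200, 5, 31)
  expect_equal(got, oracle_cv_mae_lm(x, y, folds), tolerance = 1e-10)
})

test_that("tolerance accuracy is a brute-force indicator mean", {
  p <- c(100, 200, 300, 400)
  expect_equal(tolerance_accuracy(p, p, 0), 1)
  # inclusive boundary at exactly T
  expect_equal(tolerance_accuracy(p + 60, p, 60), 1)
  expect_equal(tolerance_accuracy(p + 60, p, 59), 0)
  # errors {10, 50, 70, 100}, T = 60 -> 2 of 4 inside
  expect_equal(tolerance_accuracy(p + c(10, 50, 70, 100), p, 60), 0.5)
  expect_error(tolerance_accuracy(1:3, 1:4, 10), "equal length")
  expect_error(tolerance_accuracy(numeric(0), numeric(0), 10), "empty")
  expect_error(tolerance_accuracy(1:3, 1:3, -5), "non-negative")
})

test_that("accuracy tables are monotone and match hand counts", {
  actual <- c(0, 0, 0, 0)
  pred <- c(20, 40, 65, 95)
  tab <- accuracy_table(pred, actual)
  expect_equal(tab$threshold_s, c(30, 45, 60, 75, 90, 105))
  # hand count: errors {20,40,65,95}; 95 first enters the band at T = 105
  expect_equal(tab$accuracy, c(0.25, 0.50, 0.50, 0.75, 0.75, 1.0))
  expect_equal(attr(tab, "n"), 4)

  perfect <- accuracy_table(actual, actual)
  expect_true(all(perfect$accuracy == 1))

  set.seed(9)
  for (i in 1:20) {
    a <- runif(50, 0, 1000)
    p <- a + rnorm(50, 0, 80)
    acc <- accuracy_table(p, a)$accuracy
    expect_true(all(diff(acc) >= 0))
    expect_true(all(acc >= 0 & acc <= 1))
  }
})

test_that("total duration is the sum of independent PT and TT predictions", {
  const <- function(v) fit_predictor(
    model_candidate(paste0("const", v),
                    fit = function(x, y, hyper, seed) list(v = v),
                    predict = function(object, x) rep(object$v, nrow(x))),
    list(), matrix(0, 2, 1), c(0, 0))
  expect_equal(predict_total_duration(const(300), const(600),
                                      matrix(0, 3, 1)), rep(900, 3))
  # degenerate guard: negative model output clamps to the floor
  expect_equal(predict_total_duration(const(-500), const(100),
                                      matrix(0, 1, 1)), 120)
  expect_error(predict_total_duration(list(), const(1), matrix(0, 1, 1)),
               "fitted predictors")
})

test_that("noise-free cohorts are predicted exactly by the linear model", {
  co <- generate_cohort(cohort_config(
    300, seed = 17, duration_model = duration_model(noise_sd = 0)))
  fm <- make_features(cohort_entity_set(co))
  x <- feature_design(fm)
  pt <- fit_predictor(linear_candidate(), list(), x, co$true_pt)
  tt <- fit_predictor(linear_candidate(), list(), x, co$true_tt)
  total <- predict_total_duration(pt, tt, x)
  # truth is additive in the one-hot features, so OLS represents it exactly
  # (up to the integer rounding of the stored durations)
  expect_lt(max(abs(total - (co$true_pt + co$true_tt))), 1.5)
  expect_lt(mean(abs(predict(pt, x) - co$true_pt)), 0.6)
})

test_that("auto-ML beats the coded-predictor baseline within 60 s", {
  for (seed in c(101, 202)) {
    co <- generate_cohort(cohort_config(900, seed = seed))
    sp <- split_cohort(co, 600, seed = seed)
    fm <- make_features(cohort_entity_set(co))
    x <- feature_design(fm)
    tr <- match(sp$train$patient_id, co$patient_id)
    te <- match(sp$test$patient_id, co$patient_id)
    cfg <- model_selection_config(
      list(default_candidates()[[1]], default_candidates()[[3]]),
      k_folds = 5, seed = seed)
    pt_m <- train_predictor(x[tr, ], sp$train$true_pt, cfg)
    tt_m <- train_predictor(x[tr, ], sp$train$true_tt, cfg)

    enc_tr <- encode_predictors(sp$train)
    enc_te <- encode_predictors(sp$test)
    base_pt <- mlr_predict_pt(fit_mlr(enc_tr[, 1:3], sp$train$true_pt),
                              enc_te)
    base_tt <- mlr_predict_tt(fit_mlr(enc_tr, sp$train$true_tt), enc_te)

    acc60 <- function(p, a) tolerance_accuracy(p, a, 60)
    expect_gt(acc60(predict(pt_m, x[te, ]), sp$test$true_pt),
              acc60(base_pt, sp$test$true_pt))
    expect_gt(acc60(predict(tt_m, x[te, ]), sp$test$true_tt),
              acc60(base_tt, sp$test$true_tt))
  }
})
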