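# Auto-ML duration modeling: a small candidate family, K-fold
# cross-validated model selection, hyperparameter tuning over each
# candidate's search space, and deterministic final fits.

#' Construct a model candidate
#'
#' @param name Identifier (ties in selection break by declaration order).
#' @param fit `function(x, y, hyper, seed)` returning a fitted object;
#'   `x` is a numeric matrix.
#' @param predict `function(object, x)` returning numeric predictions.
#' @param default_hyper Named list of hyperparameters used during model
#'   selection (before tuning).
#' @param space Named list of hyperparameter grids, each a vector of values
#'   to try during tuning; empty means nothing to tune.
#' @return An object of class `model_candidate`.
#' @export
model_candidate <- function(name, fit, predict, default_hyper = list(),
                            space = list()) {
  structure(list(name = name, fit = fit, predict = predict,
                 default_hyper = default_hyper, space = space),
            class = "model_candidate")
}

# rpart/ranger need a data.frame with syntactic names; feature names carry
# "(", "=" etc., so columns are renamed positionally.
.model_frame <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_along(df))
  df
}

# glmnet requires >= 2 columns; pad single-column designs with a constant.
.glmnet_x <- function(x) {
  if (ncol(x) >= 2) return(x)
  cbind(x, .pad = 0)
}

#' Default candidate family
#'
#' Linear regression (QR least squares, aliased columns dropped), ridge
#' regression (glmnet, alpha = 0, lambda tuned), a decision tree (rpart,
#' complexity parameter tuned) and a random forest (ranger, 100 trees,
#' minimum node size tuned). An optional gradient-boosted tree candidate
#' (xgboost) can be appended with `include_gbt = TRUE`; it is off by default
#' to keep routine runs light.
#'
#' @param include_gbt Append the gradient-boosted tree candidate (requires
#'   the xgboost package).
#' @return List of [model_candidate()] objects in declaration order.
#' @export
default_candidates <- function(include_gbt = FALSE) {
  cands <- list(
    model_candidate(
      "linear",
      fit = function(x, y, hyper, seed) {
        design <- cbind(1, as.matrix(x))
        qr_d <- qr(design)
        beta <- qr.coef(qr_d, y)
        beta[is.na(beta)] <- 0  # aliased columns contribute nothing
        list(beta = beta)
      },
      predict = function(object, x) {
        drop(cbind(1, as.matrix(x)) %*% object$beta)
      }
    ),
    model_candidate(
      "ridge",
      fit = function(x, y, hyper, seed) {
        glmnet::glmnet(.glmnet_x(as.matrix(x)), y, alpha = 0,
                       lambda = hyper$lambda)
      },
      predict = function(object, x) {
        drop(glmnet::predict.glmnet(object, newx = .glmnet_x(as.matrix(x))))
      },
      default_hyper = list(lambda = 0.1),
      space = list(lambda = c(0.01, 0.1, 1))
    ),
    model_candidate(
      "tree",
      fit = function(x, y, hyper, seed) {
        df <- .model_frame(x)
        df$.y <- y
        rpart::rpart(.y ~ ., data = df,
                     control = rpart::rpart.control(cp = hyper$cp,
                                                    xval = 0L))
      },
      predict = function(object, x) {
        unname(stats::predict(object, newdata = .model_frame(x)))
      },
      default_hyper = list(cp = 0.01),
      space = list(cp = c(0.001, 0.01, 0.05))
    ),
    model_candidate(
      "forest",
      fit = function(x, y, hyper, seed) {
        ranger::ranger(x = .model_frame(x), y = y, num.trees = 100,
                       min.node.size = hyper$min.node.size,
                       seed = seed, num.threads = 1)
      },
      predict = function(object, x) {
        stats::predict(object, data = .model_frame(x),
                       num.threads = 1)$predictions
      },
      default_hyper = list(min.node.size = 5),
      space = list(min.node.size = c(5, 20))
    )
  )
  if (include_gbt) {
    cands <- c(cands, list(model_candidate(
      "gbt",
      fit = function(x, y, hyper, seed) {
        xgboost::xgboost(data = as.matrix(x), label = y,
                         nrounds = hyper$nrounds, max_depth = hyper$max_depth,
                         eta = 0.1, nthread = 1, verbose = 0,
                         seed = seed)
      },
      predict = function(object, x) {
        stats::predict(object, newdata = as.matrix(x))
      },
      default_hyper = list(nrounds = 100, max_depth = 4),
      space = list(max_depth = c(2, 4, 6))
    )))
  }
  cands
}

#' Loss functions for cross-validation
#'
#' Mean absolute error (the default, aligned with the tolerance-band
#' evaluation) and mean squared error.
#'
#' @param predicted,actual Numeric vectors of equal length.
#' @return Scalar loss.
#' @export
loss_mae <- function(predicted, actual) mean(abs(predicted - actual))

#' @rdname loss_mae
#' @export
loss_mse <- function(predicted, actual) mean((predicted - actual)^2)

#' Model selection and tuning configuration
#'
#' @param candidates Candidate family, a list of [model_candidate()]s.
#' @param k_folds Number of cross-validation folds K (>= 2).
#' @param loss `"mae"` or `"mse"`, or a `function(predicted, actual)`.
#' @param seed Integer seed governing fold assignment, stochastic fits and
#'   any random search.
#' @param budget Maximum hyperparameter evaluations per candidate; grids
#'   larger than the budget are subsampled at random (deterministically).
#' @return An object of class `model_selection_config`.
#' @export
model_selection_config <- function(candidates = default_candidates(),
                                   k_folds = 5L, loss = "mae", seed = 1L,
                                   budget = 50L) {
  if (length(candidates) < 1) stop("candidate family is empty", call. = FALSE)
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  loss_fn <- if (is.function(loss)) loss else
    switch(loss, mae = loss_mae, mse = loss_mse,
           stop("unknown loss '", loss, "'", call. = FALSE))
  structure(list(candidates = candidates, k_folds = as.integer(k_folds),
                 loss = loss, loss_fn = loss_fn, seed = as.integer(seed),
                 budget = budget),
            class = "model_selection_config")
}

#' Deterministic K-fold assignment
#'
#' @param n Number of rows.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`, one per row.
#' @export
cv_folds <- function(n, k, seed) {
  if (n < k) stop("fewer rows (", n, ") than folds (", k, ")", call. = FALSE)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Mean K-fold cross-validation loss of one candidate/hyperparameter pair
#'
#' For each fold i the candidate is fitted on the training part and its loss
#' is measured on the held-out part; the returned value is the mean over
#' folds — the objective minimized by both model selection and tuning.
#'
#' @param candidate A [model_candidate()].
#' @param hyper Named list of hyperparameters.
#' @param x Numeric matrix (or coercible) of features.
#' @param y Numeric response.
#' @param config A [model_selection_config()].
#' @return Scalar mean CV loss.
#' @export
cv_loss <- function(candidate, hyper, x, y, config) {
  x <- as.matrix(x)
  folds <- cv_folds(nrow(x), config$k_folds, config$seed)
  losses <- vapply(seq_len(config$k_folds), function(i) {
    tr <- folds != i
    fit <- candidate$fit(x[tr, , drop = FALSE], y[tr], hyper, config$seed)
    config$loss_fn(candidate$predict(fit, x[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1))
  mean(losses)
}

#' Select the best model candidate by cross-validation
#'
#' Evaluates every candidate (at its default hyperparameters) with the mean
#' K-fold CV loss and returns the argmin; ties break by declaration order.
#' Fold assignment is deterministic given the config seed.
#'
#' @inheritParams cv_loss
#' @return List with `candidate` (the chosen [model_candidate()]),
#'   `cv_losses` (named numeric, one per candidate) and `chosen` (its name).
#' @export
select_model <- function(x, y, config) {
  x <- as.matrix(x)
  if (nrow(x) < config$k_folds) {
    stop("fewer rows (", nrow(x), ") than folds (", config$k_folds, ")",
         call. = FALSE)
  }
  losses <- vapply(config$candidates, function(cand) {
    cv_loss(cand, cand$default_hyper, x, y, config)
  }, numeric(1))
  names(losses) <- vapply(config$candidates, `[[`, character(1), "name")
  best <- which.min(losses)  # first minimum: declaration-order tie-break
  list(candidate = config$candidates[[best]], cv_losses = losses,
       chosen = names(losses)[best])
}

#' Tune a candidate's hyperparameters by cross-validation
#'
#' Expands the candidate's search space into a grid, subsamples it at random
#' (deterministically) if it exceeds the budget, evaluates the mean K-fold
#' CV loss for each point and returns the argmin. An empty space returns the
#' default hyperparameters untouched.
#'
#' @param candidate A [model_candidate()].
#' @inheritParams cv_loss
#' @return List with `hyper` (best hyperparameters), `cv_loss`, `evaluated`
#'   (data frame of grid points and losses), `strategy` and `n_evaluations`
#'   (grid points times folds).
#' @export
tune_hyperparameters <- function(candidate, x, y, config) {
  if (length(candidate$space) == 0) {
    if (isTRUE(getOption("linacsched.verbose", FALSE))) {
      message("[tune] '", candidate$name, "' has no hyperparameter space; ",
              "returning defaults")
    }
    return(list(hyper = candidate$default_hyper, cv_loss = NA_real_,
                evaluated = data.frame(), strategy = "none",
                n_evaluations = 0L))
  }
  grid <- expand.grid(candidate$space, KEEP.OUT.ATTRS = FALSE)
  strategy <- "grid"
  if (nrow(grid) > config$budget) {
    set.seed(config$seed)
    grid <- grid[sort(sample.int(nrow(grid), config$budget)), , drop = FALSE]
    strategy <- "random"
  }
  losses <- vapply(seq_len(nrow(grid)), function(i) {
    hyper <- as.list(grid[i, , drop = FALSE])
    cv_loss(candidate, hyper, x, y, config)
  }, numeric(1))
  best <- which.min(losses)
  evaluated <- cbind(grid, cv_loss = losses)
  list(hyper = as.list(grid[best, , drop = FALSE]), cv_loss = losses[best],
       evaluated = evaluated, strategy = strategy,
       n_evaluations = nrow(grid) * config$k_folds)
}

#' Select, tune and fit a duration predictor
#'
#' Runs [select_model()], then [tune_hyperparameters()] on the winner, then
#' fits it on the full data. The returned predictor predicts
#' deterministically.
#'
#' @inheritParams cv_loss
#' @return An object of class `fitted_predictor` with the fitted model and
#'   training metadata (chosen candidate, hyperparameters, CV losses, seed,
#'   folds, feature names).
#' @export
train_predictor <- function(x, y, config = model_selection_config()) {
  x <- as.matrix(x)
  sel <- select_model(x, y, config)
  tuned <- tune_hyperparameters(sel$candidate, x, y, config)
  fit_predictor(sel$candidate, tuned$hyper, x, y, config$seed,
                metadata = list(selection_losses = sel$cv_losses,
                                tuning = tuned$evaluated,
                                tuning_strategy = tuned$strategy,
                                k_folds = config$k_folds, loss = config$loss))
}

#' Fit a candidate with fixed hyperparameters
#'
#' @param candidate A [model_candidate()].
#' @param hyper Named list of hyperparameters.
#' @param x Numeric matrix of features.
#' @param y Numeric response.
#' @param seed Integer seed for stochastic fits.
#' @param metadata Optional extra training metadata.
#' @return An object of class `fitted_predictor`.
#' @export
fit_predictor <- function(candidate, hyper, x, y, seed = 1L,
                          metadata = list()) {
  x <- as.matrix(x)
  object <- candidate$fit(x, y, hyper, seed)
  structure(list(candidate_name = candidate$name,
                 predict_fn = candidate$predict, object = object,
                 hyper = hyper, seed = seed,
                 feature_names = colnames(x), metadata = metadata),
            class = "fitted_predictor")
}

#' @export
predict.fitted_predictor <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata))
  if (!is.null(object$feature_names)) {
    missing_f <- setdiff(object$feature_names, colnames(x))
    if (length(missing_f) > 0) {
      stop("newdata lacks feature columns: ",
           paste(missing_f, collapse = ", "), call. = FALSE)
    }
    x <- x[, object$feature_names, drop = FALSE]
  }
  object$predict_fn(object$object, x)
}

#' @export
print.fitted_predictor <- function(x, ...) {
  cat("<fitted_predictor>", x$candidate_name, "\n")
  if (length(x$hyper) > 0) {
    cat("  hyperparameters:",
        paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", "),
        "\n")
  }
  cat("  features:", length(x$feature_names), " seed:", x$seed, "\n")
  invisible(x)
}
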