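# End-to-end orchestration: cohort -> features -> train/predict ->
# accuracy -> schedule -> comparison, driven by a single nested run
# configuration with one governing seed.

#' Default run configuration
#'
#' The documented default run: a 1665-record cohort split 1165/500,
#' depth-2 feature synthesis with the full default primitive vocabulary,
#' 5-fold model selection over the default candidate family with mean
#' absolute error loss, the 30--105 s accuracy grid, and a 08:00--18:00 day
#' of 1-h blocks with a 20-min daily QA reservation.
#'
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "linacsched-output",
    cohort = list(n_patients = 1665L, first_fraction_rate = 0.04),
    split = list(n_train = 1165L),
    dfs = list(primitives = c("count", "sum", "mean", "min", "max", "std",
                              "identity", "zscore"),
               max_depth = 2L),
    model = list(candidates = c("linear", "ridge", "tree", "forest"),
                 k_folds = 5L, loss = "mae", budget = 50L),
    predict = list(floor_s = 120L),
    evaluate = list(thresholds = c(30, 45, 60, 75, 90, 105)),
    schedule = list(open = "08:00", close = "18:00", slot_l_length = 60L,
                    daily_qa_minutes = 20L, state_thresholds = c(20, 10, 5),
                    section_length = 60L, slots_per_section = 4L)
  ), class = "run_config")
}

# Fill gaps in a user config with defaults, recursively.
.merge_config <- function(user, default) {
  for (nm in names(default)) {
    if (is.null(user[[nm]])) {
      user[[nm]] <- default[[nm]]
    } else if (is.list(default[[nm]]) && is.list(user[[nm]])) {
      user[[nm]] <- .merge_config(user[[nm]], default[[nm]])
    }
  }
  user
}

#' List every violation in a run configuration
#'
#' Checks the full configuration and returns all violations found (not just
#' the first), each naming the offending field.
#'
#' @param config Nested configuration list.
#' @return Character vector of violations; empty when valid.
#' @export
config_violations <- function(config) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  num1 <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x)
  if (!num1(config$seed)) add("seed: must be a single integer")
  n <- config$cohort$n_patients
  if (!num1(n) || n <= 0 || n != round(n)) {
    add("cohort.n_patients: must be a positive integer")
  }
  ffr <- config$cohort$first_fraction_rate
  if (!num1(ffr) || ffr < 0 || ffr > 1) {
    add("cohort.first_fraction_rate: must lie in [0, 1]")
  }
  nt <- config$split$n_train
  if (!num1(nt) || nt <= 0 || (num1(n) && nt >= n)) {
    add("split.n_train: must satisfy 0 < n_train < cohort.n_patients")
  }
  if (!num1(config$dfs$max_depth) || config$dfs$max_depth < 1) {
    add("dfs.max_depth: must be >= 1")
  }
  known_prims <- vapply(default_primitives(), `[[`, character(1), "name")
  bad <- setdiff(config$dfs$primitives, known_prims)
  if (length(bad) > 0) {
    add(paste0("dfs.primitives: unknown primitive(s) ",
               paste(bad, collapse = ", ")))
  }
  if (!num1(config$model$k_folds) || config$model$k_folds < 2) {
    add("model.k_folds: must be >= 2")
  }
  if (!config$model$loss %in% c("mae", "mse")) {
    add("model.loss: must be 'mae' or 'mse'")
  }
  known_cand <- c("linear", "ridge", "tree", "forest", "gbt")
  bad <- setdiff(config$model$candidates, known_cand)
  if (length(bad) > 0) {
    add(paste0("model.candidates: unknown candidate(s) ",
               paste(bad, collapse = ", ")))
  }
  if (length(config$model$candidates) == 0) {
    add("model.candidates: must be non-empty")
  }
  th <- config$evaluate$thresholds
  if (length(th) == 0 || any(th < 0)) {
    add("evaluate.thresholds: must be non-negative")
  }
  st <- config$schedule$state_thresholds
  if (length(st) != 3 || !(st[1] > st[2] && st[2] > st[3])) {
    add("schedule.state_thresholds: must be three strictly decreasing values")
  }
  qa <- config$schedule$daily_qa_minutes
  if (!num1(qa) || (qa != 0 && (qa < 10 || qa > 20))) {
    add("schedule.daily_qa_minutes: must be 0 or within [10, 20]")
  }
  open <- tryCatch(.parse_clock(config$schedule$open), error = function(e) NA)
  close <- tryCatch(.parse_clock(config$schedule$close), error = function(e) NA)
  if (is.na(open) || is.na(close) || close <= open) {
    add("schedule.open/close: close must be after open")
  }
  if (!num1(config$schedule$slot_l_length) ||
      config$schedule$slot_l_length < 1) {
    add("schedule.slot_l_length: must be >= 1")
  }
  sec <- config$schedule$section_length
  sps <- config$schedule$slots_per_section
  if (!num1(sec) || !num1(sps) || sps < 1 || sec %% sps != 0) {
    add("schedule.section_length: must be divisible by slots_per_section")
  }
  v
}

#' Load and validate a run configuration file
#'
#' Reads a YAML configuration, fills unspecified fields from
#' [default_run_config()] and validates it. On failure every violation is
#' reported, not only the first.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config file '", path, "'",
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  config <- .merge_config(raw, unclass(default_run_config()))
  v <- config_violations(config)
  if (length(v) > 0) {
    stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(config, class = "run_config")
}

.primitives_by_name <- function(names) {
  prims <- default_primitives()
  prims[vapply(prims, `[[`, character(1), "name") %in% names]
}

.candidates_by_name <- function(names) {
  cands <- default_candidates(include_gbt = "gbt" %in% names)
  cands[vapply(cands, `[[`, character(1), "name") %in% names]
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Generates the cohort, synthesizes features, splits, selects/tunes/fits
#' the PT and TT predictors, evaluates tolerance-band accuracy for both the
#' auto-ML models and the coded-predictor regression baseline on the test
#' split, packs the predicted totals into a minute-granular day, builds the
#' fixed-block baseline schedule on the same appointments, and writes every
#' artifact plus a manifest. One seed governs all stochastic stages; a rerun
#' with the same configuration reproduces identical artifacts.
#'
#' @param config A `run_config` list, or the path to a YAML config file.
#' @param output_dir Output directory (overrides `config$output_dir`).
#' @return Invisibly, a list with the in-memory results (cohort, features,
#'   models, predictions, accuracy, schedules, comparison, manifest).
#' @export
run_pipeline <- function(config = default_run_config(), output_dir = NULL) {
  if (is.character(config)) config <- validate_config(config)
  config <- .merge_config(config, unclass(default_run_config()))
  v <- config_violations(config)
  if (length(v) > 0) {
    stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  }
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  artifact <- function(f) file.path(out_dir, f)

  cohort <- .stage("cohort", {
    cc <- cohort_config(config$cohort$n_patients, seed = seed,
                        first_fraction_rate = config$cohort$first_fraction_rate)
    generate_cohort(cc)
  })
  write_cohort_csv(cohort, artifact("cohort.csv"))

  features <- .stage("features", {
    make_features(cohort_entity_set(cohort),
                  primitives = .primitives_by_name(config$dfs$primitives),
                  max_depth = config$dfs$max_depth)
  })
  write_feature_matrix(features, artifact("features.csv"))

  sp <- .stage("split", split_cohort(cohort, config$split$n_train,
                                     seed = seed + 1L))
  tr_idx <- match(sp$train$patient_id, cohort$patient_id)
  te_idx <- match(sp$test$patient_id, cohort$patient_id)
  x <- feature_design(features)

  msc <- model_selection_config(
    candidates = .candidates_by_name(config$model$candidates),
    k_folds = config$model$k_folds, loss = config$model$loss,
    seed = seed + 2L, budget = config$model$budget)
  pt_model <- .stage("train_pt",
                     train_predictor(x[tr_idx, , drop = FALSE],
                                     sp$train$true_pt, msc))
  tt_model <- .stage("train_tt",
                     train_predictor(x[tr_idx, , drop = FALSE],
                                     sp$train$true_tt, msc))

  x_test <- x[te_idx, , drop = FALSE]
  predictions <- .stage("predict", data.frame(
    patient_id = sp$test$patient_id,
    predicted_pt_s = predict(pt_model, x_test),
    predicted_tt_s = predict(tt_model, x_test),
    predicted_total_s = predict_total_duration(pt_model, tt_model, x_test,
                                               floor_s = config$predict$floor_s),
    stringsAsFactors = FALSE
  ))
  utils::write.csv(predictions, artifact("predictions.csv"),
                   row.names = FALSE)

  # Coded predictors can be constant in a small training split (e.g. no
  # first fractions drawn); fit on the varying ones and give the rest zero
  # weight so the baseline still evaluates.
  fit_baseline <- function(x, y) {
    x <- as.data.frame(x)
    keep <- vapply(x, function(col) length(unique(col)) > 1, logical(1))
    fit <- fit_mlr(x[, keep, drop = FALSE], y)
    w <- numeric(ncol(x))
    w[keep] <- fit$weights
    mlr_coefficients(fit$intercept, w)
  }

  accuracy <- .stage("evaluate", {
    enc_tr <- encode_predictors(sp$train)
    enc_te <- encode_predictors(sp$test)
    base_pt <- fit_baseline(enc_tr[, c("X1", "X2", "X3")], sp$train$true_pt)
    base_tt <- fit_baseline(enc_tr, sp$train$true_tt)
    th <- config$evaluate$thresholds
    bp <- mlr_predict_pt(base_pt, enc_te)
    bt <- mlr_predict_tt(base_tt, enc_te)
    list(
      automl = list(
        pt = accuracy_table(predictions$predicted_pt_s, sp$test$true_pt, th),
        tt = accuracy_table(predictions$predicted_tt_s, sp$test$true_tt, th),
        total = accuracy_table(predictions$predicted_total_s,
                               sp$test$true_pt + sp$test$true_tt, th)),
      mlr_baseline = list(
        pt = accuracy_table(bp, sp$test$true_pt, th),
        tt = accuracy_table(bt, sp$test$true_tt, th),
        total = accuracy_table(bp + bt, sp$test$true_pt + sp$test$true_tt, th))
    )
  })
  write_accuracy_json(accuracy, artifact("accuracy.json"))

  sched <- config$schedule
  appointments <- data.frame(patient_id = predictions$patient_id,
                             duration_s = predictions$predicted_total_s,
                             stringsAsFactors = FALSE)
  minute_day <- .stage("schedule", {
    day <- build_day(sched$open, sched$close, sched$slot_l_length)
    day <- reserve_daily_qa(day, sched$daily_qa_minutes)
    schedule_cohort(day, appointments)
  })
  write_schedule_json(minute_day, artifact("schedule.json"),
                      thresholds = sched$state_thresholds)

  comparison <- .stage("compare", {
    base_day <- build_day(sched$open, sched$close, sched$slot_l_length)
    base_day <- reserve_daily_qa(base_day, sched$daily_qa_minutes)
    block_day <- block_baseline_schedule(base_day, appointments,
                                         section_length = sched$section_length,
                                         slots_per_section = sched$slots_per_section)
    utilization_report(minute_day, block_day,
                       thresholds = sched$state_thresholds)
  })
  jsonlite::write_json(unclass(comparison), artifact("comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  manifest <- list(
    package = "linacsched",
    version = as.character(utils::packageVersion("linacsched")),
    seed = seed,
    config_hash = rlang::hash(config),
    record_counts = list(cohort = nrow(cohort),
                         train = nrow(sp$train), test = nrow(sp$test)),
    models = list(pt = pt_model$candidate_name, tt = tt_model$candidate_name),
    artifacts = c("cohort.csv", "features.csv", "predictions.csv",
                  "accuracy.json", "schedule.json", "comparison.json")
  )
  jsonlite::write_json(manifest, artifact("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = config, cohort = cohort, features = features,
                 split = sp, pt_model = pt_model, tt_model = tt_model,
                 predictions = predictions, accuracy = accuracy,
                 minute_day = minute_day, comparison = comparison,
                 manifest = manifest))
}
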