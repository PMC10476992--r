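# Synthetic patient cohorts: feature domains, generative duration model,
# generation, splitting, CSV round-trip.

#' Categorical feature domains of a treatment record
#'
#' The closed value domains for every categorical feature of a per-fraction
#' treatment record: anatomical sites, immobilization boards and irradiation
#' techniques. All generated and parsed cohorts are validated against these
#' domains.
#'
#' @return Named list of character vectors (`site`, `immobilization_method`,
#'   `irradiation_technology`) plus numeric bounds `prescription_dose` (Gy per
#'   fraction) and `control_points` (plan segments).
#' @export
cohort_domains <- function() {
  sites <- c("head", "head&neck", "thorax", "breast", "pelvic")
  list(
    site = sites,
    immobilization_method = c(sites, "SBRT"),
    irradiation_technology = c("2D", "3D-CRT", "IMRT", "VMAT", "SBRT"),
    prescription_dose = c(2, 12),
    control_points = c(0L, 1024L)
  )
}

#' Field order of the cohort CSV / record data frame
#' @return Character vector of column names in canonical declaration order.
#' @export
cohort_fields <- function() {
  c("patient_id", "immobilization_site", "immobilization_method",
    "six_dimension_table", "vacuum_cushion", "metallic_implant", "igrt",
    "treatment_site", "irradiation_technology", "prescription_dose",
    "control_points", "first_fraction", "true_pt", "true_tt")
}

.boolean_fields <- c("six_dimension_table", "vacuum_cushion",
                     "metallic_implant", "igrt", "first_fraction")

#' Additive generative model for positioning and treatment durations
#'
#' Per-record positioning time (PT) and treatment time (TT), in seconds, are
#' each a base duration plus additive per-level effects (plus per-Gy and
#' per-control-point slopes for TT), Gaussian noise, a first-fraction
#' positioning surcharge, rounding to whole seconds and truncation below at
#' 60 s. Defaults place deterministic non-first totals (PT+TT) at roughly
#' 18.4--21.1 min and first-fraction totals at 25.9--28.6 min, so that with
#' the default noise the realized totals fall inside the 15--22 min
#' (non-first) and 25--30 min (first fraction) operational windows with
#' probability well above 0.95.
#'
#' @param pt_base,tt_base Base durations, seconds.
#' @param pt_effects Named list: per-feature additive seconds. Categorical
#'   entries are named vectors over the feature's levels; boolean entries are
#'   single numbers applied when the flag is true.
#' @param tt_effects As `pt_effects`, plus scalar slopes `per_gy`
#'   (seconds per Gy of prescription dose) and `per_control_point`.
#' @param noise_sd Gaussian noise standard deviation, seconds, applied
#'   independently to PT and TT. Must be >= 0.
#' @param first_fraction_extra Extra positioning seconds for a course's first
#'   fraction.
#' @return An object of class `duration_model`.
#' @export
duration_model <- function(pt_base = 480,
                           pt_effects = list(
                             immobilization_site = c("head" = 0, "head&neck" = 10,
                                                     "thorax" = 6, "breast" = 4,
                                                     "pelvic" = 8),
                             immobilization_method = c("head" = 0, "head&neck" = 8,
                                                       "thorax" = 5, "breast" = 4,
                                                       "pelvic" = 6, "SBRT" = 15),
                             six_dimension_table = 12,
                             vacuum_cushion = 10,
                             metallic_implant = 8,
                             igrt = 25
                           ),
                           tt_base = 620,
                           tt_effects = list(
                             treatment_site = c("head" = 0, "head&neck" = 8,
                                                "thorax" = 5, "breast" = 3,
                                                "pelvic" = 6),
                             irradiation_technology = c("2D" = 0, "3D-CRT" = 8,
                                                        "IMRT" = 20, "VMAT" = 16,
                                                        "SBRT" = 30),
                             per_gy = 3,
                             per_control_point = 0.03
                           ),
                           noise_sd = 20,
                           first_fraction_extra = 450) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(pt_base = pt_base, pt_effects = pt_effects,
                 tt_base = tt_base, tt_effects = tt_effects,
                 noise_sd = noise_sd,
                 first_fraction_extra = first_fraction_extra),
            class = "duration_model")
}

#' Deterministic (noise-free) PT and TT for records under a duration model
#'
#' @param model A [duration_model()].
#' @param records Data frame of treatment records (durations ignored).
#' @return Data frame with columns `pt` and `tt`, seconds, before rounding.
#' @export
deterministic_duration <- function(model, records) {
  lvl <- function(effects, feature, values) {
    e <- effects[[feature]]
    if (is.null(e)) return(rep(0, length(values)))
    unname(e[as.character(values)])
  }
  flag <- function(effects, feature, values) {
    e <- effects[[feature]]
    if (is.null(e)) return(rep(0, length(values)))
    ifelse(values, e, 0)
  }
  pt <- model$pt_base +
    lvl(model$pt_effects, "immobilization_site", records$immobilization_site) +
    lvl(model$pt_effects, "immobilization_method", records$immobilization_method) +
    flag(model$pt_effects, "six_dimension_table", records$six_dimension_table) +
    flag(model$pt_effects, "vacuum_cushion", records$vacuum_cushion) +
    flag(model$pt_effects, "metallic_implant", records$metallic_implant) +
    flag(model$pt_effects, "igrt", records$igrt) +
    ifelse(records$first_fraction, model$first_fraction_extra, 0)
  tt <- model$tt_base +
    lvl(model$tt_effects, "treatment_site", records$treatment_site) +
    lvl(model$tt_effects, "irradiation_technology", records$irradiation_technology) +
    (model$tt_effects$per_gy %||% 0) * records$prescription_dose +
    (model$tt_effects$per_control_point %||% 0) * records$control_points
  data.frame(pt = pt, tt = tt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort generation configuration
#'
#' @param n_patients Number of records to generate (one per patient-fraction).
#' @param seed Integer seed; identical `(config, seed)` pairs yield identical
#'   cohorts.
#' @param category_probabilities Named list of per-feature categorical
#'   distributions. Categorical features take a named probability vector over
#'   their levels (must sum to 1); boolean features take a single probability
#'   of "yes". Features omitted default to uniform (booleans to 0.5).
#'   `immobilization_site` defaults to mirroring `treatment_site`
#'   (clinically the irradiated site is the immobilized site);
#'   `immobilization_method` defaults to the site's board, or the SBRT board
#'   when the irradiation technology is SBRT. Supplying explicit
#'   probabilities for either overrides the mirroring.
#' @param duration_model A [duration_model()].
#' @param first_fraction_rate Probability a record is a course's first
#'   fraction. Default 0.04: courses run 25--33 fractions, so about 1 record
#'   in 28 is a first fraction.
#' @param control_point_ranges Named list of `c(lo, hi)` integer ranges per
#'   irradiation technology; control points are drawn uniformly within the
#'   technology's range (low for 2D/3D-CRT, high for modulated deliveries).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients,
                          seed = 1L,
                          category_probabilities = list(),
                          duration_model = linacsched::duration_model(),
                          first_fraction_rate = 0.04,
                          control_point_ranges = list(
                            "2D" = c(0L, 50L), "3D-CRT" = c(10L, 100L),
                            "IMRT" = c(80L, 300L), "VMAT" = c(60L, 200L),
                            "SBRT" = c(80L, 360L))) {
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients <= 0 ||
      n_patients != round(n_patients)) {
    stop("configuration error: n_patients must be a positive integer",
         call. = FALSE)
  }
  for (feat in names(category_probabilities)) {
    p <- category_probabilities[[feat]]
    if (length(p) > 1 && abs(sum(p) - 1) > 1e-8) {
      stop("configuration error: probabilities for '", feat,
           "' must sum to 1", call. = FALSE)
    }
    if (any(p < 0 | p > 1)) {
      stop("configuration error: probabilities for '", feat,
           "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (first_fraction_rate < 0 || first_fraction_rate > 1) {
    stop("configuration error: first_fraction_rate must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 category_probabilities = category_probabilities,
                 duration_model = duration_model,
                 first_fraction_rate = first_fraction_rate,
                 control_point_ranges = control_point_ranges),
            class = "cohort_config")
}

.sample_levels <- function(n, levels, prob) {
  if (is.null(prob)) prob <- rep(1 / length(levels), length(levels))
  if (!is.null(names(prob))) prob <- prob[levels]
  sample(levels, n, replace = TRUE, prob = prob)
}

.sample_flag <- function(n, p) {
  if (is.null(p)) p <- 0.5
  stats::runif(n) < p
}

#' Generate a synthetic cohort of treatment records
#'
#' Draws categorical positioning and plan-complexity features from the
#' configured distributions, then realizes integer-second PT and TT from the
#' additive duration model (Gaussian noise, rounded, floored at 60 s).
#'
#' @param config A [cohort_config()].
#' @return Data frame of treatment records, one row per record, columns as
#'   [cohort_fields()].
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("configuration error: config must be a cohort_config", call. = FALSE)
  }
  dom <- cohort_domains()
  cp <- config$category_probabilities
  n <- config$n_patients
  set.seed(config$seed)

  treatment_site <- .sample_levels(n, dom$site, cp$treatment_site)
  irradiation_technology <- .sample_levels(n, dom$irradiation_technology,
                                           cp$irradiation_technology)
  immobilization_site <- if (is.null(cp$immobilization_site)) {
    treatment_site
  } else {
    .sample_levels(n, dom$site, cp$immobilization_site)
  }
  immobilization_method <- if (is.null(cp$immobilization_method)) {
    ifelse(irradiation_technology == "SBRT", "SBRT", immobilization_site)
  } else {
    .sample_levels(n, dom$immobilization_method, cp$immobilization_method)
  }

  records <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    immobilization_site = immobilization_site,
    immobilization_method = immobilization_method,
    six_dimension_table = .sample_flag(n, cp$six_dimension_table),
    vacuum_cushion = .sample_flag(n, cp$vacuum_cushion),
    metallic_implant = .sample_flag(n, cp$metallic_implant),
    igrt = .sample_flag(n, cp$igrt),
    treatment_site = treatment_site,
    irradiation_technology = irradiation_technology,
    prescription_dose = round(stats::runif(n, dom$prescription_dose[1],
                                           dom$prescription_dose[2]), 1),
    control_points = 0L,
    first_fraction = stats::runif(n) < config$first_fraction_rate,
    stringsAsFactors = FALSE
  )
  for (tech in names(config$control_point_ranges)) {
    idx <- records$irradiation_technology == tech
    r <- config$control_point_ranges[[tech]]
    vals <- seq.int(r[1], r[2])
    records$control_points[idx] <- if (length(vals) == 1) {
      rep.int(vals, sum(idx))  # sample(n, ...) would draw from 1:n
    } else {
      sample(vals, sum(idx), replace = TRUE)
    }
  }

  det <- deterministic_duration(config$duration_model, records)
  sd <- config$duration_model$noise_sd
  records$true_pt <- as.integer(pmax(60, round(det$pt + stats::rnorm(n, 0, sd))))
  records$true_tt <- as.integer(pmax(60, round(det$tt + stats::rnorm(n, 0, sd))))
  validate_cohort(records)
  records[, cohort_fields()]
}

#' Validate a cohort data frame against the record contract
#'
#' Checks column presence, categorical domain closure, dose and control-point
#' bounds, and integer positive durations. Errors name the offending row and
#' field.
#'
#' @param records Data frame of treatment records.
#' @return The validated records, invisibly.
#' @export
validate_cohort <- function(records) {
  dom <- cohort_domains()
  missing_cols <- setdiff(cohort_fields(), names(records))
  if (length(missing_cols) > 0) {
    stop("parse error: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- function(field, ok) {
    i <- which(!ok)
    if (length(i) > 0) {
      stop(sprintf("parse error: row %d, field %s: value '%s' out of domain",
                   i[1], field, records[[field]][i[1]]), call. = FALSE)
    }
  }
  bad("immobilization_site", records$immobilization_site %in% dom$site)
  bad("immobilization_method",
      records$immobilization_method %in% dom$immobilization_method)
  bad("treatment_site", records$treatment_site %in% dom$site)
  bad("irradiation_technology",
      records$irradiation_technology %in% dom$irradiation_technology)
  for (f in .boolean_fields) bad(f, records[[f]] %in% c(TRUE, FALSE))
  bad("prescription_dose",
      records$prescription_dose >= dom$prescription_dose[1] &
        records$prescription_dose <= dom$prescription_dose[2])
  bad("control_points",
      records$control_points >= dom$control_points[1] &
        records$control_points <= dom$control_points[2] &
        records$control_points == round(records$control_points))
  for (f in c("true_pt", "true_tt")) {
    bad(f, records[[f]] > 0 & records[[f]] == round(records[[f]]))
  }
  invisible(records)
}

#' Split a cohort into training and testing sets
#'
#' Random disjoint partition, deterministic for a fixed seed; the union of
#' the two parts equals the input.
#'
#' @param records Cohort data frame.
#' @param n_train Number of training records; must satisfy
#'   `0 < n_train < nrow(records)`.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_cohort <- function(records, n_train, seed = 1L) {
  n <- nrow(records)
  if (n_train <= 0 || n_train >= n) {
    stop("n_train must satisfy 0 < n_train < ", n, call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(n, n_train)
  list(train = records[sort(idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Write / read a cohort CSV
#'
#' One header row; columns exactly the record fields in declaration order;
#' booleans serialized as `"yes"`/`"no"`; durations as integer seconds.
#' `read_cohort_csv()` validates every row and fails with a parse error
#' naming the first offending row and field.
#'
#' @param records Cohort data frame.
#' @param path File path.
#' @return `read_cohort_csv()` returns the validated cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  out <- records[, cohort_fields()]
  for (f in .boolean_fields) out[[f]] <- ifelse(out[[f]], "yes", "no")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(cohort_fields(), names(raw))
  if (length(missing_cols) > 0) {
    stop("parse error: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num <- function(field, integer = FALSE) {
    v <- suppressWarnings(as.numeric(raw[[field]]))
    i <- which(is.na(v) | (integer & v != round(v)))
    if (length(i) > 0) {
      stop(sprintf("parse error: row %d, field %s: '%s' is not a valid %s",
                   i[1], field, raw[[field]][i[1]],
                   if (integer) "integer" else "number"), call. = FALSE)
    }
    if (integer) as.integer(v) else v
  }
  yn <- function(field) {
    i <- which(!raw[[field]] %in% c("yes", "no"))
    if (length(i) > 0) {
      stop(sprintf("parse error: row %d, field %s: expected yes/no, got '%s'",
                   i[1], field, raw[[field]][i[1]]), call. = FALSE)
    }
    raw[[field]] == "yes"
  }
  records <- data.frame(
    patient_id = raw$patient_id,
    immobilization_site = raw$immobilization_site,
    immobilization_method = raw$immobilization_method,
    six_dimension_table = yn("six_dimension_table"),
    vacuum_cushion = yn("vacuum_cushion"),
    metallic_implant = yn("metallic_implant"),
    igrt = yn("igrt"),
    treatment_site = raw$treatment_site,
    irradiation_technology = raw$irradiation_technology,
    prescription_dose = num("prescription_dose"),
    control_points = num("control_points", integer = TRUE),
    first_fraction = yn("first_fraction"),
    true_pt = num("true_pt", integer = TRUE),
    true_tt = num("true_tt", integer = TRUE),
    stringsAsFactors = FALSE
  )
  validate_cohort(records)
  records
}
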