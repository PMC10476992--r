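# Multiple-linear-regression baseline for PT and TT, with the reference
# coefficient sets commonly fitted on hospital records, plus the integer
# coding of the categorical predictors it consumes.

#' Integer coding map for the baseline predictors
#'
#' The baseline regressions consume coded predictors: `X1` the treatment
#' site, `X2` the first-fraction flag, `X3` the irradiation technique and
#' `X4` machine modulation. Codes follow feature declaration order; `X4` is
#' a binary modulated-delivery indicator (IMRT/VMAT/SBRT use modulated
#' beams, 2D/3D-CRT do not).
#'
#' @return Named list of named integer vectors.
#' @export
predictor_coding_map <- function() {
  dom <- cohort_domains()
  list(
    X1_treatment_site = stats::setNames(seq_along(dom$site) - 1L, dom$site),
    X2_first_fraction = c("no" = 0L, "yes" = 1L),
    X3_irradiation_technology = stats::setNames(
      seq_along(dom$irradiation_technology) - 1L, dom$irradiation_technology),
    X4_modulation = c("2D" = 0L, "3D-CRT" = 0L, "IMRT" = 1L, "VMAT" = 1L,
                      "SBRT" = 1L)
  )
}

#' Encode cohort records into the baseline's coded predictors
#'
#' @param records Cohort data frame.
#' @return Data frame with integer columns `X1`, `X2`, `X3`, `X4` per
#'   [predictor_coding_map()].
#' @export
encode_predictors <- function(records) {
  cm <- predictor_coding_map()
  data.frame(
    X1 = unname(cm$X1_treatment_site[records$treatment_site]),
    X2 = as.integer(records$first_fraction),
    X3 = unname(cm$X3_irradiation_technology[records$irradiation_technology]),
    X4 = unname(cm$X4_modulation[records$irradiation_technology])
  )
}

#' Baseline regression coefficient sets
#'
#' `mlr_coefficients()` bundles an intercept with ordered weights. The
#' default PT set (intercept 3.551; weights -0.0154, 0.18287, 0.3846 on
#' X1..X3) and TT set (intercept 3.5518; weights -0.0569, 0.3962, 0.0014,
#' 0.496 on X1..X4) are the reference values fitted on hospital treatment
#' records for this baseline. Model outputs are in minutes; convert at the
#' boundary with [minutes_to_seconds()].
#'
#' @param intercept Intercept term.
#' @param weights Ordered numeric weights (3 for the PT model, 4 for TT).
#' @return An object of class `mlr_coefficients`.
#' @export
mlr_coefficients <- function(intercept, weights) {
  structure(list(intercept = as.numeric(intercept),
                 weights = as.numeric(weights)),
            class = "mlr_coefficients")
}

#' @rdname mlr_coefficients
#' @export
default_pt_coefficients <- function() {
  mlr_coefficients(3.551, c(-0.0154, 0.18287, 0.3846))
}

#' @rdname mlr_coefficients
#' @export
default_tt_coefficients <- function() {
  mlr_coefficients(3.5518, c(-0.0569, 0.3962, 0.0014, 0.496))
}

.mlr_eval <- function(coeffs, x, p) {
  if (!inherits(coeffs, "mlr_coefficients")) {
    stop("coeffs must be an mlr_coefficients object", call. = FALSE)
  }
  if (length(coeffs$weights) != p) {
    stop("expected ", p, " weights, got ", length(coeffs$weights),
         call. = FALSE)
  }
  x <- as.data.frame(x)
  need <- paste0("X", seq_len(p))
  if (!all(need %in% names(x))) {
    stop("predictors must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  xm <- as.matrix(x[, need, drop = FALSE])
  if (any(!is.finite(xm))) stop("predictors must be finite", call. = FALSE)
  drop(coeffs$intercept + xm %*% coeffs$weights)
}

#' Baseline PT and TT predictions
#'
#' `mlr_predict_pt()` evaluates `Yp = C1 + a1*X1 + a2*X2 + a3*X3`;
#' `mlr_predict_tt()` evaluates `Yt = C2 + b1*X1 + b2*X2 + b3*X3 + b4*X4`.
#' Outputs are in the model's native units (minutes for the default
#' coefficient sets).
#'
#' @param coeffs An [mlr_coefficients()] with 3 (PT) or 4 (TT) weights.
#' @param x Data frame (or coercible) with columns `X1..X3` / `X1..X4`.
#' @return Numeric vector of predictions.
#' @export
mlr_predict_pt <- function(coeffs, x) .mlr_eval(coeffs, x, 3L)

#' @rdname mlr_predict_pt
#' @export
mlr_predict_tt <- function(coeffs, x) .mlr_eval(coeffs, x, 4L)

#' Convert model-unit minutes to seconds
#'
#' @param x Numeric vector in minutes.
#' @param factor Seconds per model unit (default 60).
#' @return Numeric vector in seconds.
#' @export
minutes_to_seconds <- function(x, factor = 60) x * factor

#' Fit a multiple linear regression by ordinary least squares
#'
#' QR-based OLS with an intercept. The design must be full rank; a
#' rank-deficient design raises an error naming the aliased (collinear)
#' columns.
#'
#' @param x Data frame or matrix of predictors.
#' @param y Numeric response.
#' @return An [mlr_coefficients()] with one weight per predictor column, in
#'   column order.
#' @export
fit_mlr <- function(x, y) {
  xm <- as.matrix(as.data.frame(x))
  storage.mode(xm) <- "double"
  if (nrow(xm) != length(y)) stop("x and y sizes differ", call. = FALSE)
  if (nrow(xm) < ncol(xm) + 1) {
    stop("need at least ", ncol(xm) + 1, " rows to fit ", ncol(xm),
         " coefficients plus intercept", call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, xm)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    aliased <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qr_d, as.numeric(y))
  mlr_coefficients(beta[1], beta[-1])
}
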