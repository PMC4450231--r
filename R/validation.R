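#' Prediction-error report for a predicted plasma profile
#'
#' Computes the two regulatory prediction errors,
#' Cmax_PE = |Cmax,obs - Cmax,pred| / Cmax,obs x 100 and
#' pAUC_PE = |pAUC,obs - pAUC,pred| / pAUC,obs x 100 (trapezoidal partial
#' AUC over the window), and assigns a verdict. The predicted profile is
#' resampled onto the observed grid before comparison (the observed grid is
#' the ground truth).
#'
#' @param observed,predicted plasma [ts_profile()]s (hours).
#' @param pauc_window length-2 numeric `(t_start, t_end)` (h); default the
#'   full common observation window.
#' @param mode `"internal"` (test formulation included in model building) or
#'   `"external"` (held out); controls the verdict thresholds, see
#'   [classify_prediction()].
#' @return A list of class `prediction_error_report` with the PEs, the
#'   window, the observed/predicted Cmax and pAUC, `mode` and `verdict`.
#' @export
prediction_error <- function(observed, predicted, pauc_window = NULL,
                             mode = c("external", "internal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(observed, "ts_profile"), inherits(predicted, "ts_profile"))
  lo <- max(observed$times[1], predicted$times[1])
  hi <- min(observed$times[length(observed$times)],
            predicted$times[length(predicted$times)])
  keep <- observed$times >= lo & observed$times <= hi
  if (sum(keep) < 2)
    stop("observed and predicted profiles share fewer than 2 time points", call. = FALSE)
  obs_common <- ts_profile(observed$times[keep], observed$values[keep],
                           observed$time_unit, observed$value_unit, observed$kind)
  lo <- obs_common$times[1]
  hi <- obs_common$times[length(obs_common$times)]
  if (is.null(pauc_window)) pauc_window <- c(lo, hi)
  if (pauc_window[1] < lo - 1e-9 || pauc_window[2] > hi + 1e-9)
    stop(sprintf("pAUC window outside the common observation window [%g, %g]", lo, hi),
         call. = FALSE)
  pred_common <- resample_linear(predicted, obs_common$times)

  cmax_obs <- cmax_tmax(obs_common)$cmax
  cmax_pred <- cmax_tmax(pred_common)$cmax
  if (cmax_obs <= 0) stop("observed Cmax is zero; prediction error undefined", call. = FALSE)
  pauc_obs <- auc_trapezoid(obs_common, pauc_window[1], pauc_window[2])
  pauc_pred <- auc_trapezoid(pred_common, pauc_window[1], pauc_window[2])
  if (pauc_obs <= 0) stop("observed pAUC is zero; prediction error undefined", call. = FALSE)

  rep <- structure(list(
    cmax_pe_percent = abs(cmax_obs - cmax_pred) / cmax_obs * 100,
    pauc_pe_percent = abs(pauc_obs - pauc_pred) / pauc_obs * 100,
    pauc_window = pauc_window,
    cmax_observed = cmax_obs, cmax_predicted = cmax_pred,
    pauc_observed = pauc_obs, pauc_predicted = pauc_pred,
    mode = mode), class = "prediction_error_report")
  rep$verdict <- classify_prediction(rep, mode)
  rep
}

#' FDA-style verdict for a prediction-error report
#'
#' External (held-out) predictions: both PEs <= 10% is a pass; both <= 20%
#' (but not both <= 10%) is inconclusive -- the model is not to be rejected
#' but additional data should be provided; any PE > 20% fails. Internal
#' validation: average absolute PE <= 10% with no individual PE above 15%
#' passes, anything else fails.
#'
#' @param report a [prediction_error()] report.
#' @param mode `"internal"` or `"external"`.
#' @return `"pass"`, `"inconclusive"` or `"fail"`.
#' @export
classify_prediction <- function(report, mode = c("external", "internal")) {
  mode <- match.arg(mode)
  pes <- c(report$cmax_pe_percent, report$pauc_pe_percent)
  if (mode == "external") {
    if (all(pes <= 10)) "pass"
    else if (all(pes <= 20)) "inconclusive"
    else "fail"
  } else {
    if (mean(pes) <= 10 && all(pes <= 15)) "pass" else "fail"
  }
}

#' @export
print.prediction_error_report <- function(x, ...) {
  cat(sprintf("<prediction_error_report> Cmax PE %.2f%%, pAUC PE %.2f%% on [%g, %g] h (%s): %s\n",
              x$cmax_pe_percent, x$pauc_pe_percent, x$pauc_window[1],
              x$pauc_window[2], x$mode, x$verdict))
  invisible(x)
}

#' Dissolution difference and similarity factors f1 / f2
#'
#' f1 = 100 sum|R - T| / sum R and
#' f2 = 50 log10(100 / sqrt(1 + mean((R - T)^2))), computed point-wise on the
#' reference grid (the test profile is interpolated there if the grids
#' differ). Profiles are expected as percent dissolved; fraction-kind
#' profiles are converted to percent automatically. f2 >= 50 conventionally
#' indicates similarity.
#'
#' @param reference,test dissolution [ts_profile()]s with at least 3 common
#'   time points.
#' @return A named list with `f1` and `f2`.
#' @export
similarity_factors <- function(reference, test) {
  stopifnot(inherits(reference, "ts_profile"), inherits(test, "ts_profile"))
  lo <- max(reference$times[1], test$times[1])
  hi <- min(reference$times[length(reference$times)], test$times[length(test$times)])
  tt <- reference$times[reference$times >= lo & reference$times <= hi]
  if (length(tt) < 3)
    stop("need at least 3 common time points for f1/f2", call. = FALSE)
  R <- profile_at(reference, tt)
  T_ <- profile_at(test, tt)
  if (reference$kind == "fraction") R <- R * 100
  if (test$kind == "fraction") T_ <- T_ * 100
  if (sum(R) <= 0) stop("reference profile sums to zero; f1 undefined", call. = FALSE)
  list(f1 = 100 * sum(abs(R - T_)) / sum(R),
       f2 = 50 * log10(100 / sqrt(1 + mean((R - T_)^2))))
}
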