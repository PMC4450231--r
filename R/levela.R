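#' Time-matched pairing of dissolution and absorption fractions
#'
#' Interpolates the cumulative fraction dissolved (in vitro, minutes) and the
#' cumulative fraction absorbed (in vivo, hours) at common times, the
#' point-to-point pairing underlying a level-A correlation. Dissolution
#' minutes are converted to hours explicitly here.
#'
#' @param fabs cumulative fraction-absorbed [ts_profile()] (hours).
#' @param fdiss cumulative fraction-dissolved [ts_profile()] (minutes or
#'   hours; minutes are converted).
#' @param pairing_times_h times (h) at which both curves are read; defaults
#'   to the dissolution sampling grid converted to hours, truncated to the
#'   overlap with the FABS observation window.
#' @return A data frame with columns `time_h`, `fdiss`, `fabs` in time order.
#' @export
pair_profiles <- function(fabs, fdiss, pairing_times_h = NULL) {
  stopifnot(inherits(fabs, "ts_profile"), inherits(fdiss, "ts_profile"))
  fdiss_h <- if (fdiss$time_unit == "min")
    ts_profile(fdiss$times / 60, fdiss$values, "h", fdiss$value_unit, fdiss$kind)
  else fdiss
  lo <- max(fabs$times[1], fdiss_h$times[1])
  hi <- min(fabs$times[length(fabs$times)], fdiss_h$times[length(fdiss_h$times)])
  if (lo >= hi)
    stop("dissolution and absorption profiles do not overlap in time", call. = FALSE)
  if (is.null(pairing_times_h))
    pairing_times_h <- fdiss_h$times[fdiss_h$times >= lo & fdiss_h$times <= hi]
  if (any(pairing_times_h < lo - 1e-9) || any(pairing_times_h > hi + 1e-9))
    stop(sprintf("pairing times outside the common window [%g, %g] h", lo, hi),
         call. = FALSE)
  pairing_times_h <- sort(pairing_times_h)
  data.frame(time_h = pairing_times_h,
             fdiss = profile_at(fdiss_h, pairing_times_h),
             fabs = profile_at(fabs, pairing_times_h))
}

#' Fit a level-A in vitro-in vivo correlation
#'
#' Ordinary least squares fit of
#' FABS = B0 + B1 FDISS + B2 FDISS^2 + E
#' (B2 fixed at 0 for `degree = 1`), via `stats::lm()`.
#'
#' @param pairs data frame from [pair_profiles()] (or with columns `fdiss`,
#'   `fabs`), possibly pooled over several formulations.
#' @param degree 1 (linear) or 2 (quadratic).
#' @param formulations_used optional character labels recorded in the model.
#' @return An object of class `levela_model` with coefficients `B0`, `B1`,
#'   `B2`, `r_squared`, `residuals`, the pairs used and the fitted `lm`.
#' @export
fit_levela <- function(pairs, degree = 2, formulations_used = character(0)) {
  stopifnot(degree %in% c(1, 2), all(c("fdiss", "fabs") %in% names(pairs)))
  if (nrow(pairs) < degree + 2)
    stop(sprintf("need at least %d pairs for degree %d", degree + 2, degree), call. = FALSE)
  if (stats::sd(pairs$fdiss) < 1e-12)
    stop("rank deficiency: FDISS is constant across all pairs", call. = FALSE)
  fml <- if (degree == 2) fabs ~ fdiss + I(fdiss^2) else fabs ~ fdiss
  fit <- stats::lm(fml, data = pairs)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank deficiency: degenerate regressor ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  co <- stats::coef(fit)
  # summary.lm warns on an essentially perfect fit; exact recovery is a
  # legitimate use here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(B0 = unname(co[1]), B1 = unname(co[2]),
                 B2 = if (degree == 2) unname(co[3]) else 0,
                 degree = degree,
                 r_squared = r2,
                 residuals = unname(stats::residuals(fit)),
                 pairs = pairs, formulations_used = formulations_used,
                 lm_fit = fit),
            class = "levela_model")
}

#' @export
print.levela_model <- function(x, ...) {
  cat(sprintf("<levela_model> FABS = %.4g + %.4g FDISS%s; R^2 = %.4f (%d pairs)\n",
              x$B0, x$B1,
              if (x$degree == 2) sprintf(" + %.4g FDISS^2", x$B2) else "",
              x$r_squared, nrow(x$pairs)))
  invisible(x)
}

#' Predict FABS from a dissolution profile with a level-A model
#'
#' Applies the fitted polynomial to FDISS(t), clips the result to \[0, 1\]
#' and enforces monotonicity by a running maximum (convolution requires a
#' nondecreasing cumulative input; an already-monotone prediction is left
#' untouched).
#'
#' @param model a [fit_levela()] model.
#' @param fdiss cumulative fraction-dissolved [ts_profile()].
#' @return A fraction-kind [ts_profile()] on the dissolution grid in hours.
#' @export
predict_fabs <- function(model, fdiss) {
  stopifnot(inherits(model, "levela_model"), inherits(fdiss, "ts_profile"))
  tt_h <- if (fdiss$time_unit == "min") fdiss$times / 60 else fdiss$times
  raw <- model$B0 + model$B1 * fdiss$values + model$B2 * fdiss$values^2
  clipped <- pmin(pmax(raw, 0), 1)
  n_clip <- sum(abs(clipped - raw) > 1e-12)
  if (n_clip > 0.2 * length(raw))
    warning(sprintf("level-A prediction clipped at %d of %d points; model extrapolating badly",
                    n_clip, length(raw)))
  ts_profile(tt_h, cummax(clipped), "h", "fraction", "fraction")
}

#' Classical plasma prediction: level-A model plus convolution
#'
#' Predicts the fraction absorbed from the dissolution curve with the fitted
#' level-A polynomial, then convolves it with the unit impulse response to
#' obtain the predicted plasma concentration curve.
#'
#' @inheritParams predict_fabs
#' @param uir a [uir_spec()].
#' @param dose_mg administered dose (mg).
#' @param times_h output grid (h); defaults to the predicted FABS grid.
#' @param F_bio fraction bioavailable (default 1).
#' @return A concentration-kind [ts_profile()].
#' @export
predict_plasma_classical <- function(model, fdiss, uir, dose_mg,
                                     times_h = NULL, F_bio = 1) {
  fabs_pred <- predict_fabs(model, fdiss)
  if (is.null(times_h)) times_h <- fabs_pred$times
  convolve_plasma(fabs_pred, uir, dose_mg, F_bio = F_bio, times_h = times_h)
}
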