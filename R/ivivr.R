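#' Triexponential dissolution-curve model
#'
#' f(t) = A exp(-k1 t) + B exp(-k2 t) + C exp(-k3 t), the empirical form used
#' to describe the rise-and-fall concentration curve of a single apparatus
#' compartment (a rise requires one negative coefficient). Exponential sums
#' are notoriously non-identifiable, so fits are judged by curve agreement
#' (RMSE), never by parameter equality.
#'
#' @param A,B,C coefficients (concentration scale, any sign).
#' @param k1,k2,k3 positive rate constants (1/min on the in vitro scale).
#' @param fit_rmse root-mean-square residual of the fit (NA if constructed
#'   directly).
#' @param t_end end of the fitted/valid window (min), used to read the
#'   terminal log-slope for profile extension.
#' @param converged optional optimizer convergence flag.
#' @return An object of class `triexp_model`.
#' @export
triexp_model <- function(A, B, C, k1, k2, k3, fit_rmse = NA_real_,
                         t_end = NA_real_, converged = NA) {
  if (any(c(k1, k2, k3) <= 0)) stop("rate constants must be positive", call. = FALSE)
  structure(list(A = A, B = B, C = C, k1 = k1, k2 = k2, k3 = k3,
                 fit_rmse = fit_rmse, t_end = t_end, converged = converged),
            class = "triexp_model")
}

#' Evaluate a triexponential model
#' @param model a [triexp_model()].
#' @param t times (min).
#' @return Numeric vector f(t).
#' @export
triexp_value <- function(model, t) {
  model$A * exp(-model$k1 * t) + model$B * exp(-model$k2 * t) +
    model$C * exp(-model$k3 * t)
}

#' @export
print.triexp_model <- function(x, ...) {
  cat(sprintf("<triexp_model> A=%.4g B=%.4g C=%.4g; k=(%.4g, %.4g, %.4g)/min; RMSE=%.4g\n",
              x$A, x$B, x$C, x$k1, x$k2, x$k3, x$fit_rmse))
  invisible(x)
}

#' Fit a triexponential to a compartment concentration curve
#'
#' Minimizes the sum of squared residuals of the triexponential form with
#' the DEPS hybrid optimizer. For dissolution curves the constraint
#' f(0) = 0 (A + B + C = 0) is on by default, which removes one coefficient
#' from the search. Non-convergence is flagged on the returned model, not
#' raised, so pipelines always complete.
#'
#' @param profile a [ts_profile()] (minutes) with at least 6 points.
#' @param deps a [deps_config()] or `NULL` for defaults; its `bounds` field
#'   is ignored (bounds are set from the data scale: coefficients within
#'   +/- 20x the curve maximum, rates in \[1e-4, 2\] per min).
#' @param constrain_origin force f(0) = 0 (default `TRUE`).
#' @param seed optimizer seed when `deps` is `NULL`.
#' @return A [triexp_model()] with `fit_rmse`, `t_end` and `converged` set.
#' @export
fit_triexponential <- function(profile, deps = NULL, constrain_origin = TRUE,
                               seed = 1L) {
  stopifnot(inherits(profile, "ts_profile"))
  if (length(profile$times) < 6)
    stop("need at least 6 points to fit a triexponential", call. = FALSE)
  if (any(profile$times < 0)) stop("times must be nonnegative", call. = FALSE)
  tt <- profile$times; yy <- profile$values
  peak <- max(abs(yy))

  if (peak < 1e-12) {  # constant-zero profile: A = B = C = 0 is exact
    return(triexp_model(0, 0, 0, 1e-3, 1e-2, 1e-1, fit_rmse = 0,
                        t_end = max(tt), converged = TRUE))
  }

  cb <- 20 * peak
  # rate constants span orders of magnitude; search them on a log10 scale so
  # slow terminal phases are as reachable as fast initial ones
  kb <- c(-4, log10(2))
  if (constrain_origin) {
    bounds <- rbind(c(-cb, cb), c(-cb, cb), kb, kb, kb)
    make_par <- function(th) list(A = th[1], B = th[2], C = -(th[1] + th[2]),
                                  k1 = 10^th[3], k2 = 10^th[4], k3 = 10^th[5])
  } else {
    bounds <- rbind(c(-cb, cb), c(-cb, cb), c(-cb, cb), kb, kb, kb)
    make_par <- function(th) list(A = th[1], B = th[2], C = th[3],
                                  k1 = 10^th[4], k2 = 10^th[5], k3 = 10^th[6])
  }
  # the fitted curve must stay nonnegative over the fitted window; penalize
  # negative excursions on a dense grid (they occur between samples when a
  # steep negative term overshoots)
  tg <- seq(0, max(tt), length.out = 100)
  obj <- function(th) {
    p <- make_par(th)
    r <- yy - (p$A * exp(-p$k1 * tt) + p$B * exp(-p$k2 * tt) + p$C * exp(-p$k3 * tt))
    fg <- p$A * exp(-p$k1 * tg) + p$B * exp(-p$k2 * tg) + p$C * exp(-p$k3 * tg)
    sum(r * r) + 10 * sum(pmin(fg, 0)^2)
  }
  if (is.null(deps)) {
    # exponential-sum fits converge slowly near the optimum; allow a longer
    # stagnation window than the general-purpose default
    deps <- deps_config(bounds, seed = seed, population_size = 80L,
                        max_generations = 4000L, stagnation_window = 400L,
                        tolerance = 1e-12)
  } else {
    deps$bounds <- bounds
  }
  res <- deps_minimize(obj, deps)
  p <- make_par(res$best_params)
  m <- triexp_model(p$A, p$B, p$C, p$k1, p$k2, p$k3, t_end = max(tt),
                    converged = res$converged)
  m$fit_rmse <- sqrt(mean((yy - triexp_value(m, tt))^2))
  if (min(triexp_value(m, tg)) < -0.02 * peak) m$converged <- FALSE
  m
}

# terminal log-slope (decay rate, 1/min) of a triexponential at its window end
terminal_log_slope <- function(model) {
  t_end <- model$t_end
  if (!is.finite(t_end)) stop("reference model has no fitted window", call. = FALSE)
  f <- triexp_value(model, t_end)
  if (f <= 0) stop("reference model is nonpositive at its window end", call. = FALSE)
  df <- -(model$A * model$k1 * exp(-model$k1 * t_end) +
            model$B * model$k2 * exp(-model$k2 * t_end) +
            model$C * model$k3 * exp(-model$k3 * t_end))
  slope <- -df / f
  if (slope <= 0) stop("reference model is not decaying at its window end", call. = FALSE)
  slope
}

#' Extend a truncated compartment profile with a reference descent
#'
#' Truncated runs stop near the curve maximum and lack the descending limb
#' needed for time scaling. This appends `n_points` synthetic points whose
#' spacing is one half-life of the reference model's terminal decay and whose
#' values fall from the last observed value at the reference's terminal
#' log-slope. The observed points are left untouched.
#'
#' @param profile truncated compartment [ts_profile()] (minutes).
#' @param reference a [triexp_model()] fitted on a full-length profile.
#' @param n_points number of points appended (default 2).
#' @return A [ts_profile()] with `n_points` extra points.
#' @export
extend_profile <- function(profile, reference, n_points = 2) {
  stopifnot(inherits(profile, "ts_profile"))
  if (n_points == 0) return(profile)
  if (!inherits(reference, "triexp_model"))
    stop("profile extension requires a reference triexponential fitted on a full profile",
         call. = FALSE)
  s <- terminal_log_slope(reference)
  t_last <- profile$times[length(profile$times)]
  v_last <- profile$values[length(profile$values)]
  dt <- log(2) / s
  new_t <- t_last + dt * seq_len(n_points)
  new_v <- v_last * exp(-s * (new_t - t_last))
  ts_profile(c(profile$times, new_t), c(profile$values, new_v),
             profile$time_unit, profile$value_unit, profile$kind)
}

#' Logarithmic in vivo to in vitro time scaling
#'
#' The map t_vitro = alpha log(1 + beta t_vivo), a simple, strictly
#' increasing and analytically invertible function. `alpha` and `beta` are
#' solved so the map sends two anchors -- by default (in vivo Tmax -> in
#' vitro peak time) and (in vivo end -> in vitro end) -- exactly.
#'
#' @param invitro_peak_time_min in vitro peak time (min).
#' @param invivo_tmax_h in vivo Tmax (h).
#' @param invitro_end_min in vitro last observation (min).
#' @param invivo_end_h in vivo last observation (h).
#' @return An object of class `time_scaling` with fields `alpha`, `beta`.
#' @export
fit_time_scaling <- function(invitro_peak_time_min, invivo_tmax_h,
                             invitro_end_min, invivo_end_h) {
  stopifnot(invitro_peak_time_min > 0, invivo_tmax_h > 0)
  if (invitro_end_min <= invitro_peak_time_min || invivo_end_h <= invivo_tmax_h)
    stop("unsolvable anchors: the peak anchor must precede the end anchor on both scales",
         call. = FALSE)
  a <- invivo_tmax_h; b <- invivo_end_h
  r <- invitro_peak_time_min / invitro_end_min
  # g(beta) = log1p(beta a)/log1p(beta b) rises from a/b (beta -> 0) to 1
  g <- function(beta) log1p(beta * a) / log1p(beta * b)
  if (r >= 1) stop("unsolvable anchors: in vitro peak must precede the end", call. = FALSE)
  if (r <= a / b + 1e-12) {
    # linear-compatible anchors: beta -> 0 limit, alpha from the series
    beta <- 1e-8
  } else {
    beta <- stats::uniroot(function(x) g(x) - r, lower = 1e-10, upper = 1e10,
                           tol = 1e-14)$root
  }
  alpha <- invitro_peak_time_min / log1p(beta * a)
  structure(list(alpha = alpha, beta = beta,
                 anchors = c(peak_min = invitro_peak_time_min, tmax_h = invivo_tmax_h,
                             end_min = invitro_end_min, end_h = invivo_end_h)),
            class = "time_scaling")
}

#' @rdname fit_time_scaling
#' @param scaling a `time_scaling`.
#' @param t_h in vivo times (h), >= 0.
#' @return `scale_time()`: in vitro times (min); `unscale_time()`: in vivo
#'   times (h).
#' @export
scale_time <- function(scaling, t_h) {
  stopifnot(inherits(scaling, "time_scaling"))
  if (any(t_h < 0)) stop("time scaling is defined for t >= 0 only", call. = FALSE)
  scaling$alpha * log1p(scaling$beta * t_h)
}

#' @rdname fit_time_scaling
#' @param t_min in vitro times (min), >= 0.
#' @export
unscale_time <- function(scaling, t_min) {
  stopifnot(inherits(scaling, "time_scaling"))
  if (any(t_min < 0)) stop("time scaling is defined for t >= 0 only", call. = FALSE)
  expm1(t_min / scaling$alpha) / scaling$beta
}

#' Fit the linear scaling constants of the compartmental IVIVR
#'
#' Given triexponential in vitro models and observed plasma profiles for two
#' formulations plus a fitted time scaling, finds the shared pair
#' (CONST1, CONST2) minimizing the pooled squared error of
#' C_pred(t) = CONST1 f_vitro(scale(t)) + CONST2 against the observations,
#' using the DEPS optimizer.
#'
#' @param triexp_models list of two [triexp_model()]s (training formulations).
#' @param plasma_profiles list of two observed plasma [ts_profile()]s (hours),
#'   same order.
#' @param scaling a [fit_time_scaling()] result.
#' @param deps optional [deps_config()]; bounds are set from the data scale.
#' @param fix_const2 force CONST2 = 0 (default `FALSE`).
#' @param seed optimizer seed when `deps` is `NULL`.
#' @return A list of class `ivivr_constants`: `const1`, `const2`,
#'   `pooled_rmse`, `converged`.
#' @export
fit_scaling_constants <- function(triexp_models, plasma_profiles, scaling,
                                  deps = NULL, fix_const2 = FALSE, seed = 1L) {
  stopifnot(length(triexp_models) == 2, length(plasma_profiles) == 2,
            inherits(scaling, "time_scaling"))
  obs_t <- lapply(plasma_profiles, function(p) p$times)
  obs_c <- lapply(plasma_profiles, function(p) p$values)
  vitro <- lapply(1:2, function(i) triexp_value(triexp_models[[i]],
                                                scale_time(scaling, obs_t[[i]])))
  n_tot <- sum(lengths(obs_c))
  cmax_obs <- max(unlist(obs_c)); vmax <- max(abs(unlist(vitro)))
  c1b <- 10 * cmax_obs / max(vmax, 1e-12)
  # the objective scores the prediction as it will actually be issued,
  # i.e. with negative concentrations clipped to zero
  obj <- function(th) {
    c2 <- if (fix_const2) 0 else th[2]
    sse <- 0
    for (i in 1:2) {
      r <- obs_c[[i]] - pmax(th[1] * vitro[[i]] + c2, 0)
      sse <- sse + sum(r * r)
    }
    sse
  }
  bounds <- if (fix_const2) rbind(c(-c1b, c1b))
  else rbind(c(-c1b, c1b), c(-cmax_obs, cmax_obs))
  if (is.null(deps)) deps <- deps_config(bounds, seed = seed) else deps$bounds <- bounds
  res <- deps_minimize(obj, deps)
  structure(list(const1 = res$best_params[1],
                 const2 = if (fix_const2) 0 else res$best_params[2],
                 pooled_rmse = sqrt(res$best_objective / n_tot),
                 converged = res$converged),
            class = "ivivr_constants")
}

#' Assemble a compartmental IVIVR model
#'
#' @param triexp_models named list of [triexp_model()]s, one per formulation
#'   (including the training ones).
#' @param scaling a [fit_time_scaling()] result.
#' @param constants a [fit_scaling_constants()] result (`const1` must be
#'   nonzero).
#' @param formulations_used labels of the training formulations.
#' @return An object of class `compartmental_ivivr`.
#' @export
compartmental_ivivr <- function(triexp_models, scaling, constants,
                                formulations_used = names(triexp_models)) {
  if (abs(constants$const1) < 1e-12)
    stop("const1 must be nonzero", call. = FALSE)
  structure(list(triexp_models = triexp_models, scaling = scaling,
                 const1 = constants$const1, const2 = constants$const2,
                 formulations_used = formulations_used),
            class = "compartmental_ivivr")
}

#' Predict a plasma profile with the compartmental IVIVR
#'
#' Evaluates the test formulation's triexponential at the scaled times and
#' applies the linear scaling constants:
#' C_pred(t) = CONST1 f_vitro(alpha log(1 + beta t)) + CONST2.
#' Negative predictions are clipped to zero with a warning.
#'
#' @param model a [compartmental_ivivr()].
#' @param triexp_test [triexp_model()] of the test formulation (full or
#'   extended profile).
#' @param times_h prediction times (h), >= 0.
#' @return A concentration-kind [ts_profile()].
#' @export
predict_plasma_compartmental <- function(model, triexp_test, times_h) {
  stopifnot(inherits(model, "compartmental_ivivr"),
            inherits(triexp_test, "triexp_model"))
  pred <- model$const1 * triexp_value(triexp_test, scale_time(model$scaling, times_h)) +
    model$const2
  if (any(pred < -1e-9)) warning("negative plasma predictions clipped to 0")
  ts_profile(times_h, pmax(pred, 0), "h", "ng/mL", "concentration")
}
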