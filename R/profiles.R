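#' Sampled time-course profile
#'
#' The elementary container of the package: a strictly increasing time grid
#' with one value per time point. Dissolution curves are carried in minutes,
#' plasma curves in hours; the unit is recorded and conversion between the
#' two scales is always explicit (see [pair_profiles()]).
#'
#' @param times numeric, strictly increasing, first element >= 0. Measured
#'   profiles carry at least 2 points; single-point profiles arise only as
#'   resampling output.
#' @param values numeric, same length as `times`.
#' @param time_unit `"min"` (dissolution) or `"h"` (plasma).
#' @param value_unit free-text label, e.g. `"mg"`, `"mg/mL"`, `"ng/mL"`,
#'   `"fraction"`.
#' @param kind one of `"concentration"`, `"amount"`, `"fraction"`. Fraction
#'   profiles must lie in \[0, 1.0001\].
#'
#' @return An object of class `ts_profile`.
#' @export
#' @examples
#' p <- ts_profile(c(0, 10, 20), c(0, 5, 8), "min", "mg", "amount")
#' auc_trapezoid(p, 0, 20)
ts_profile <- function(times, values, time_unit = c("min", "h"),
                       value_unit = "mg", kind = c("amount", "concentration", "fraction")) {
  time_unit <- match.arg(time_unit)
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length", call. = FALSE)
  if (length(times) < 1)
    stop("a profile needs at least 1 point", call. = FALSE)
  if (anyNA(times) || anyNA(values))
    stop("NA values are not allowed in a profile", call. = FALSE)
  if (times[1] < 0)
    stop("times must be nonnegative", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (kind == "fraction" && (any(values < 0) || any(values > 1.0001)))
    stop("fraction profiles must lie in [0, 1.0001]", call. = FALSE)
  structure(
    list(times = times, values = values, time_unit = time_unit,
         value_unit = value_unit, kind = kind),
    class = "ts_profile"
  )
}

#' @export
print.ts_profile <- function(x, ...) {
  cat(sprintf("<ts_profile> %d points on [%g, %g] %s; %s (%s)\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$time_unit, x$kind, x$value_unit))
  invisible(x)
}

#' Resample a profile by linear interpolation
#'
#' Places a profile on a new time grid. Extrapolation is forbidden: all
#' requested times must fall inside the observed range.
#'
#' @param profile a [ts_profile()].
#' @param new_times numeric vector of requested times (same unit as the
#'   profile).
#' @return A `ts_profile` on `new_times`.
#' @export
resample_linear <- function(profile, new_times) {
  stopifnot(inherits(profile, "ts_profile"))
  rng <- range(profile$times)
  bad <- new_times < rng[1] - 1e-12 | new_times > rng[2] + 1e-12
  if (any(bad))
    stop(sprintf("requested time %g outside observed range [%g, %g]",
                 new_times[which(bad)[1]], rng[1], rng[2]), call. = FALSE)
  new_times <- pmin(pmax(new_times, rng[1]), rng[2])
  ts_profile(new_times, profile_at(profile, new_times),
             profile$time_unit, profile$value_unit, profile$kind)
}

# interpolated value at arbitrary times, without constructing a new profile
# (length-1 grids would violate the >= 2 point invariant)
profile_at <- function(profile, t) {
  rng <- range(profile$times)
  bad <- t < rng[1] - 1e-12 | t > rng[2] + 1e-12
  if (any(bad))
    stop(sprintf("requested time %g outside observed range [%g, %g]",
                 t[which(bad)[1]], rng[1], rng[2]), call. = FALSE)
  t <- pmin(pmax(t, rng[1]), rng[2])
  if (length(profile$times) == 1) return(rep(profile$values, length(t)))
  stats::approx(profile$times, profile$values, xout = t,
                method = "linear", ties = "ordered")$y
}

#' Trapezoidal area under a profile over a window
#'
#' Computes the linear-trapezoidal AUC between `t_start` and `t_end`;
#' boundary values are obtained by linear interpolation. This is the partial
#' AUC (pAUC) used in prediction-error validation.
#'
#' @inheritParams resample_linear
#' @param t_start,t_end window bounds, `t_start < t_end`, both inside the
#'   observed range.
#' @return The trapezoidal area (numeric scalar).
#' @export
auc_trapezoid <- function(profile, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(profile, "ts_profile"))
  if (is.null(t_start)) t_start <- profile$times[1]
  if (is.null(t_end)) t_end <- profile$times[length(profile$times)]
  if (t_start >= t_end)
    stop("t_start must be strictly less than t_end", call. = FALSE)
  rng <- range(profile$times)
  if (t_start < rng[1] - 1e-12 || t_end > rng[2] + 1e-12)
    stop(sprintf("AUC window [%g, %g] outside observed range [%g, %g]",
                 t_start, t_end, rng[1], rng[2]), call. = FALSE)
  inner <- profile$times[profile$times > t_start & profile$times < t_end]
  tt <- c(t_start, inner, t_end)
  vv <- profile_at(profile, tt)
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Maximum of a profile and its time
#'
#' @inheritParams resample_linear
#' @return A named list with elements `cmax` (maximum observed value) and
#'   `tmax` (time of its first occurrence; ties broken to the earliest time).
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "ts_profile"))
  i <- which.max(profile$values)
  list(cmax = profile$values[i], tmax = profile$times[i])
}
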