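#' Polyexponential unit impulse response
#'
#' The disposition kernel: the plasma concentration-time curve that would
#' follow an instantaneous i.v. bolus of `dose_basis_mg`, expressed as a sum
#' of decaying exponentials UIR(t) = sum C_i exp(-lambda_i t). Scaling in
#' dose is linear, so any dose is handled by rescaling per mg.
#'
#' @param terms data frame (or list of lists) with columns/fields `C`
#'   (concentration scale) and `lambda` (1/h, all > 0); at least one term.
#' @param dose_basis_mg dose for which the coefficients are expressed (> 0).
#' @return An object of class `uir_spec`.
#' @export
uir_spec <- function(terms, dose_basis_mg = 80) {
  if (is.list(terms) && !is.data.frame(terms))
    terms <- do.call(rbind, lapply(terms, function(tm) data.frame(C = tm$C, lambda = tm$lambda)))
  terms <- as.data.frame(terms)
  if (!all(c("C", "lambda") %in% names(terms)) || nrow(terms) < 1)
    stop("terms must provide at least one (C, lambda) pair", call. = FALSE)
  if (any(terms$lambda <= 0)) stop("all exponents lambda must be positive", call. = FALSE)
  stopifnot(dose_basis_mg > 0)
  u <- structure(list(terms = terms, dose_basis_mg = dose_basis_mg), class = "uir_spec")
  tt <- seq(0, 5 / min(terms$lambda), length.out = 200)
  if (any(uir_value(u, tt) < -1e-12))
    stop("UIR must be nonnegative over its evaluation window", call. = FALSE)
  u
}

#' Default biexponential disposition kernel
#'
#' A biexponential i.v. disposition curve on an 80 mg dose basis with a fast
#' distribution phase and a slower elimination phase, qualitatively shaped
#' like the simulated i.v. profile of a high-clearance lipophilic weak acid.
#' It is a stand-in kernel for synthetic studies, not a reproduction of any
#' measured or PBPK-simulated profile.
#'
#' @return A [uir_spec()].
#' @export
default_uir <- function() {
  uir_spec(data.frame(C = c(120, 30), lambda = c(2.0, 0.25)), dose_basis_mg = 80)
}

uir_value <- function(uir, t) {
  v <- rep(0, length(t))
  for (k in seq_len(nrow(uir$terms)))
    v <- v + uir$terms$C[k] * exp(-uir$terms$lambda[k] * t)
  v
}

#' Evaluate a unit impulse response on a time grid
#'
#' @param uir a [uir_spec()].
#' @param times_h increasing, nonnegative times (h).
#' @param dose_mg dose to scale to (default the UIR's own dose basis).
#' @return A concentration-kind [ts_profile()].
#' @export
uir_evaluate <- function(uir, times_h, dose_mg = uir$dose_basis_mg) {
  stopifnot(inherits(uir, "uir_spec"))
  if (any(times_h < 0) || any(diff(times_h) <= 0))
    stop("times_h must be nonnegative and strictly increasing", call. = FALSE)
  ts_profile(times_h, uir_value(uir, times_h) * dose_mg / uir$dose_basis_mg,
             "h", "ng/mL", "concentration")
}

# shared discretization of the convolution integral: absorption increments
# delta F on (t_{i-1}, t_i] act as impulses at the interval midpoints (the
# initial value F(t_1) acts at t_1 itself, covering the bolus limit).
conv_matrix <- function(times_h, uir, dose_mg, F_bio) {
  n <- length(times_h)
  mids <- c(times_h[1], (utils::head(times_h, -1) + utils::tail(times_h, -1)) / 2)
  A <- matrix(0, n, n)
  scale <- F_bio * dose_mg / uir$dose_basis_mg
  for (i in seq_len(n)) {
    lag <- times_h - mids[i]
    ok <- lag >= 0
    A[ok, i] <- scale * uir_value(uir, lag[ok])
  }
  A
}

#' Convolve an absorption profile with a unit impulse response
#'
#' Predicts the plasma concentration curve
#' C(t) = F D int_0^t (dFABS/dtau) UIR(t - tau) dtau from a cumulative
#' fraction-absorbed profile, by discretizing dFABS into per-interval
#' increments and summing shifted impulse responses.
#'
#' @param fabs cumulative fraction-absorbed [ts_profile()] (kind
#'   `"fraction"`, nondecreasing within tolerance, time in hours).
#' @param uir a [uir_spec()].
#' @param dose_mg administered dose (mg).
#' @param F_bio fraction bioavailable (default 1).
#' @param times_h output grid (defaults to the FABS grid).
#' @return A concentration-kind [ts_profile()] on `times_h`.
#' @export
convolve_plasma <- function(fabs, uir, dose_mg, F_bio = 1, times_h = fabs$times) {
  stopifnot(inherits(fabs, "ts_profile"), inherits(uir, "uir_spec"))
  if (any(diff(fabs$values) < -1e-6))
    stop("FABS must be nondecreasing", call. = FALSE)
  fv <- profile_at(fabs, pmin(pmax(times_h, fabs$times[1]), fabs$times[length(fabs$times)]))
  if (any(times_h > fabs$times[length(fabs$times)] + 1e-9))
    fv[times_h > fabs$times[length(fabs$times)]] <- fabs$values[length(fabs$values)]
  incr <- diff(c(0, fv))
  A <- conv_matrix(times_h, uir, dose_mg, F_bio)
  ts_profile(times_h, as.numeric(A %*% incr), "h", "ng/mL", "concentration")
}

#' Numerically deconvolve a plasma profile into fraction absorbed
#'
#' Solves the discretized convolution system for nonnegative per-interval
#' absorption increments (a lower-triangular system in the increments) by
#' nonnegative least squares, optionally with a second-difference smoothing
#' penalty, and returns the cumulative fraction-absorbed profile normalized
#' by F x dose. The terminal value is reported as computed, never forced
#' to 1.
#'
#' @param plasma observed plasma [ts_profile()] (hours, concentration).
#' @param uir a [uir_spec()].
#' @param dose_mg administered dose (mg).
#' @param grid_step_h uniform deconvolution grid step (h), default 0.05.
#' @param smoothing_lambda weight of the second-difference penalty on the
#'   increments (default 0 = none).
#' @param nonneg constrain increments to be nonnegative (default `TRUE`,
#'   which makes the returned FABS nondecreasing by construction). With
#'   `nonneg = FALSE` an unconstrained least-squares solution is returned
#'   and negative increments raise a warning.
#' @param F_bio fraction bioavailable used in the normalization (default 1).
#' @return A fraction-kind [ts_profile()] (cumulative FABS). Values above
#'   1.05 trigger a warning (flagged overshoot).
#' @export
deconvolve_fabs <- function(plasma, uir, dose_mg, grid_step_h = 0.05,
                            smoothing_lambda = 0, nonneg = TRUE, F_bio = 1) {
  stopifnot(inherits(plasma, "ts_profile"), inherits(uir, "uir_spec"),
            grid_step_h > 0)
  t_end <- plasma$times[length(plasma$times)]
  grid <- seq(0, t_end, by = grid_step_h)
  if (length(grid) < 3) stop("grid too coarse for the plasma window", call. = FALSE)
  # plasma resampled on the grid (0 before the first observation)
  cobs <- rep(0, length(grid))
  inside <- grid >= plasma$times[1]
  cobs[inside] <- profile_at(plasma, grid[inside])

  A <- conv_matrix(grid, uir, dose_mg, F_bio)
  if (smoothing_lambda > 0) {
    n <- length(grid)
    D2 <- diff(diag(n), differences = 2)
    A_aug <- rbind(A, sqrt(smoothing_lambda) * D2)
    b_aug <- c(cobs, rep(0, nrow(D2)))
  } else {
    A_aug <- A; b_aug <- cobs
  }

  if (nonneg) {
    x <- pracma::lsqnonneg(A_aug, b_aug)$x
  } else {
    x <- tryCatch(qr.solve(A_aug, b_aug),
                  error = function(e) stop(
                    "deconvolution system is ill-conditioned; try smoothing_lambda > 0",
                    call. = FALSE))
    if (any(x < -1e-9)) warning("negative absorption increments in unconstrained solution")
  }
  fabs <- cumsum(x)
  if (any(fabs > 1.05)) warning("deconvolved FABS overshoots 1.05")
  ts_profile(grid, pmin(fabs, 1.0001), "h", "fraction", "fraction")
}
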