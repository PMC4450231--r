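#' Synthetic oral plasma profile (two-compartment, first-order absorption)
#'
#' Closed-form central-compartment concentration of the standard
#' two-compartment disposition model with first-order absorption and an
#' optional lag time. Used as a ground-truth fixture for the deconvolution
#' and correlation stages; with `k12 = k21 = 0` it reduces to the
#' one-compartment Bateman function
#' C(t) = F D ka / (V (ka - k10)) (e^(-k10 t) - e^(-ka t)).
#'
#' @param dose_mg dose (mg).
#' @param ka first-order absorption rate constant (1/h), > 0.
#' @param k10 elimination rate constant from the central compartment (1/h), > 0.
#' @param k12,k21 inter-compartmental rate constants (1/h), >= 0.
#' @param V_central_L central volume of distribution (L), > 0.
#' @param tlag_h absorption lag time (h), >= 0.
#' @param F_bio fraction bioavailable (default 1).
#' @param times_h increasing, nonnegative evaluation times (h).
#' @return A concentration-kind [ts_profile()] in ng/mL (with dose in mg and
#'   volume in L, mg/L numerically equals ug/mL; values are reported x1000 as
#'   ng/mL, the unit plasma assays use for this drug).
#' @export
generate_synthetic_pk <- function(dose_mg, ka, k10, k12 = 0, k21 = 0,
                                  V_central_L, tlag_h = 0, F_bio = 1,
                                  times_h = seq(0, 12, by = 0.25)) {
  stopifnot(ka > 0, k10 > 0, k12 >= 0, k21 >= 0, V_central_L > 0, tlag_h >= 0)
  if (any(diff(times_h) <= 0)) stop("times_h must be strictly increasing", call. = FALSE)

  tt <- pmax(times_h - tlag_h, 0)
  # disposition eigenvalues: s^2 - (k10+k12+k21) s + k10 k21 = 0
  a_sum <- k10 + k12 + k21
  disc <- sqrt(max(a_sum^2 - 4 * k10 * k21, 0))
  alpha <- (a_sum + disc) / 2
  beta <- (a_sum - disc) / 2
  # coincident eigenvalues (or ka colliding with either) are perturbed
  eps <- 1e-9
  if (abs(alpha - beta) < eps && k21 > 0) {
    warning("coincident disposition eigenvalues; perturbing by 1e-9")
    alpha <- alpha + eps
  }
  if (abs(ka - alpha) < eps) { warning("ka coincides with alpha; perturbing by 1e-9"); alpha <- alpha + eps }
  if (abs(ka - beta) < eps) { warning("ka coincides with beta; perturbing by 1e-9"); beta <- beta + eps }

  scale <- F_bio * dose_mg * ka / V_central_L
  if (beta < 1e-12) {
    # one-compartment limit (k12 = k21 = 0): Bateman (alpha = k10, possibly
    # perturbed away from a coincident ka)
    conc <- scale / (ka - alpha) * (exp(-alpha * tt) - exp(-ka * tt))
  } else {
    cA <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
    cB <- (k21 - beta) / ((ka - beta) * (alpha - beta))
    cK <- (k21 - ka) / ((alpha - ka) * (beta - ka))
    conc <- scale * (cA * exp(-alpha * tt) + cB * exp(-beta * tt) + cK * exp(-ka * tt))
  }
  conc[times_h <= tlag_h] <- 0
  conc <- pmax(conc, 0) * 1000  # mg/L -> ng/mL
  ts_profile(times_h, conc, "h", "ng/mL", "concentration")
}
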