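#' Compartment specification for the transit simulator
#'
#' One vessel of the four-compartment gastrointestinal dissolution apparatus.
#' The default chain (see [golem_method()]) is stomach (30 mL gastric juice +
#' 200 mL water, 30 min linear emptying, pH 2.4), duodenum (33 mL, 10 min,
#' pH 6.5), jejunum (33 mL, 60 min, pH 6.6) and ileum (33 mL, 90 min,
#' pH 7.4), draining into a collection canister.
#'
#' @param name compartment label.
#' @param starting_volume_mL initial fluid volume (mL), > 0.
#' @param residence_time_min residence/transit time (min), > 0.
#' @param ph_setpoint pH held in the compartment, or `"free"` for the
#'   stomach, whose pH is determined by the formulation.
#' @param residual_mL volume that never leaves the compartment (defaults to
#'   the starting volume; the stomach keeps only its 30 mL of gastric juice).
#' @param pepsin_mg_per_mL,lipase_U_per_mL,bile_salts_mM descriptive
#'   biorelevance metadata (not used by the mass balance).
#' @return An object of class `compartment_spec`.
#' @export
compartment_spec <- function(name, starting_volume_mL, residence_time_min,
                             ph_setpoint, residual_mL = starting_volume_mL,
                             pepsin_mg_per_mL = 0, lipase_U_per_mL = 0,
                             bile_salts_mM = 0) {
  stopifnot(starting_volume_mL > 0, residence_time_min > 0)
  if (!identical(ph_setpoint, "free")) {
    stopifnot(is.numeric(ph_setpoint), ph_setpoint >= 1, ph_setpoint <= 9)
  }
  structure(list(name = name, starting_volume_mL = starting_volume_mL,
                 residence_time_min = residence_time_min,
                 ph_setpoint = ph_setpoint, residual_mL = residual_mL,
                 pepsin_mg_per_mL = pepsin_mg_per_mL,
                 lipase_U_per_mL = lipase_U_per_mL,
                 bile_salts_mM = bile_salts_mM),
            class = "compartment_spec")
}

fasted_compartments <- function() {
  list(
    compartment_spec("stomach", 230, 30, "free", residual_mL = 30,
                     pepsin_mg_per_mL = 1.3),
    compartment_spec("duodenum", 33, 10, 6.5, lipase_U_per_mL = 70, bile_salts_mM = 3),
    compartment_spec("jejunum", 33, 60, 6.6, lipase_U_per_mL = 70, bile_salts_mM = 3),
    compartment_spec("ileum", 33, 90, 7.4, lipase_U_per_mL = 70, bile_salts_mM = 3)
  )
}

default_sampling_times <- function(duration_min) {
  early <- seq(3, 43, by = 5)
  if (duration_min <= 43) return(early[early <= duration_min])
  late <- seq(53, duration_min, by = 15)
  unique(c(early, late, duration_min))
}

#' Fasted-state dissolution method specification
#'
#' The full method lasts 215 min (the residence times sum to 190 min, so the
#' whole 200 mL mobile volume reaches the canister); the truncated variant
#' stops directly after the 43 min sampling point, covering the window in
#' which immediate-release tablets are informative.
#'
#' @param duration_min total simulated time (min); 215 (full) or 43
#'   (truncated) in the standard protocols.
#' @param sampling_times_min increasing sampling schedule (min); defaults to
#'   every 5 min from 3 to 43 min, then every 15 min.
#' @param withdrawal_mL filtered sample volume removed from each compartment
#'   at every sampling time (default 1 mL; set 0 to disable withdrawal).
#' @param integration_step_min fixed Euler step (min). Must not exceed one
#'   tenth of the smallest residence time.
#' @param compartments ordered list of [compartment_spec()]s,
#'   stomach first; defaults to the fasted-state chain.
#' @return An object of class `method_spec`.
#' @export
golem_method <- function(duration_min = 215,
                         sampling_times_min = default_sampling_times(duration_min),
                         withdrawal_mL = 1,
                         integration_step_min = 0.1,
                         compartments = fasted_compartments()) {
  stopifnot(duration_min > 0, withdrawal_mL >= 0)
  sampling_times_min <- sort(unique(sampling_times_min))
  if (any(sampling_times_min <= 0) || any(sampling_times_min > duration_min))
    stop("sampling times must lie in (0, duration_min]", call. = FALSE)
  min_res <- min(vapply(compartments, function(cp) cp$residence_time_min, 0))
  if (integration_step_min <= 0)
    stop("integration step must be positive", call. = FALSE)
  if (integration_step_min > min_res / 10)
    stop(sprintf("integration step %g min exceeds stability guard %g min (smallest residence time / 10)",
                 integration_step_min, min_res / 10), call. = FALSE)
  names(compartments) <- vapply(compartments, function(cp) cp$name, "")
  structure(list(duration_min = duration_min,
                 sampling_times_min = sampling_times_min,
                 withdrawal_mL = withdrawal_mL,
                 integration_step_min = integration_step_min,
                 compartments = compartments),
            class = "method_spec")
}

#' Formulation specification
#'
#' Describes an immediate-release tablet for the transit simulator. Two
#' designs are shipped as presets ([buffered_crystal()] and
#' [nonbuffered_amorphous()]): buffered tablets carry CaCO3, which raises the
#' gastric pH to 7-8 and lets the weak-acid drug dissolve in the stomach at
#' the price of a Ca2+ salting-out solubility ceiling; nonbuffered tablets
#' leave the stomach at pH 2.4, where a weak acid with pKa 4.33 is
#' essentially insoluble, so gastric dissolution is nil.
#'
#' @param formulation_id character label.
#' @param dose_mg dose (mg), default 80.
#' @param api_form `"amorphous"` or `"crystal"` (descriptive).
#' @param buffered logical; does the tablet buffer the gastric pH?
#' @param pKa acid dissociation constant (default 4.33).
#' @param intrinsic_solubility_mg_per_mL solubility of the unionized form
#'   (mg/mL).
#' @param dissolution_rate_coeff_z dissolution rate coefficient z in
#'   mL mg^(-2/3) min^(-1) of the cube-root rate law
#'   dm/dt = z m_u^(2/3) (S(pH) - C).
#' @param disintegration_time_min lag before any dissolution (default 3 min).
#' @param solubility_ceiling_mg_per_mL optional cap on S(pH) modeling
#'   salting-out by the buffer counter-ion; `NULL` for no cap.
#' @param gastric_ph_after_buffer stomach pH after disintegration of a
#'   buffered tablet (must lie in \[7, 8\]; default 7.5).
#' @return An object of class `formulation_spec`.
#' @export
formulation_spec <- function(formulation_id, dose_mg = 80,
                             api_form = c("amorphous", "crystal"),
                             buffered = FALSE, pKa = 4.33,
                             intrinsic_solubility_mg_per_mL = 0.002,
                             dissolution_rate_coeff_z = 0.2,
                             disintegration_time_min = 3,
                             solubility_ceiling_mg_per_mL = NULL,
                             gastric_ph_after_buffer = 7.5) {
  api_form <- match.arg(api_form)
  stopifnot(dose_mg >= 0, intrinsic_solubility_mg_per_mL > 0,
            dissolution_rate_coeff_z > 0, disintegration_time_min >= 0)
  if (buffered && (gastric_ph_after_buffer < 7 || gastric_ph_after_buffer > 8))
    stop("gastric_ph_after_buffer must lie in [7, 8] for a buffered formulation",
         call. = FALSE)
  structure(list(formulation_id = formulation_id, dose_mg = dose_mg,
                 api_form = api_form, buffered = buffered, pKa = pKa,
                 intrinsic_solubility_mg_per_mL = intrinsic_solubility_mg_per_mL,
                 dissolution_rate_coeff_z = dissolution_rate_coeff_z,
                 disintegration_time_min = disintegration_time_min,
                 solubility_ceiling_mg_per_mL = solubility_ceiling_mg_per_mL,
                 gastric_ph_after_buffer = gastric_ph_after_buffer),
            class = "formulation_spec")
}

#' @rdname formulation_spec
#' @export
buffered_crystal <- function(formulation_id = "buffered_crystal", dose_mg = 80,
                             dissolution_rate_coeff_z = 0.05) {
  formulation_spec(formulation_id, dose_mg = dose_mg, api_form = "crystal",
                   buffered = TRUE,
                   intrinsic_solubility_mg_per_mL = 0.001,
                   dissolution_rate_coeff_z = dissolution_rate_coeff_z,
                   solubility_ceiling_mg_per_mL = 0.3)
}

#' @rdname formulation_spec
#' @export
nonbuffered_amorphous <- function(formulation_id = "nonbuffered_amorphous",
                                  dose_mg = 80, dissolution_rate_coeff_z = 0.2) {
  formulation_spec(formulation_id, dose_mg = dose_mg, api_form = "amorphous",
                   buffered = FALSE,
                   intrinsic_solubility_mg_per_mL = 0.002,
                   dissolution_rate_coeff_z = dissolution_rate_coeff_z)
}

#' pH-dependent solubility of a weak acid
#'
#' Henderson-Hasselbalch total solubility of a monoprotic weak acid,
#' S(pH) = S0 (1 + 10^(pH - pKa)), optionally capped by a salting-out
#' ceiling. At pH = pKa half the drug is ionized, so S = 2 S0.
#'
#' @param intrinsic_solubility mg/mL of the unionized species, > 0.
#' @param pKa acid dissociation constant.
#' @param ph pH of the medium.
#' @param ceiling optional cap (mg/mL) or `NULL`.
#' @return Solubility in mg/mL.
#' @export
solubility_at_ph <- function(intrinsic_solubility, pKa, ph, ceiling = NULL) {
  stopifnot(intrinsic_solubility > 0, is.finite(pKa), all(is.finite(ph)))
  s <- intrinsic_solubility * (1 + 10^(ph - pKa))
  if (!is.null(ceiling)) s <- pmin(s, ceiling)
  s
}

#' Simulate the four-compartment transit dissolution experiment
#'
#' Fixed-step mass-balance integration of tablet disintegration, pH-dependent
#' dissolution, chyme transit and sample withdrawal. Per step: (1) after the
#' disintegration lag, undissolved drug dissolves at rate
#' z m_u^(2/3) (S(pH) - C), clipped at saturation; (2) the stomach empties
#' its mobile volume (starting volume minus residual) at a constant rate over
#' its residence time, carrying dissolved drug at bulk concentration and
#' undissolved drug as a homogeneous suspension; (3) each intestinal
#' compartment passes volume through with a plug-flow delay equal to its
#' residence time (outflow rate now = inflow rate one residence time ago),
#' so each compartment fills, plateaus and returns exactly to its starting
#' volume once upstream flow ceases; the ileum drains into the collection
#' canister; (4) intestinal pH is clamped at the method setpoints while the
#' stomach sits at pH 2.4 unless a buffered tablet raises it at
#' disintegration; (5) at every sampling time `withdrawal_mL` of filtered
#' medium (volume plus its dissolved share; suspended particles are
#' returned) is removed from each compartment and logged.
#'
#' The simulator is deterministic; duplicate experimental runs can be
#' emulated by multiplicative lognormal noise on the recorded dissolved
#' amounts (`noise_sd > 0`, seeded).
#'
#' @param method a [golem_method()].
#' @param formulation a [formulation_spec()].
#' @param noise_sd standard deviation of lognormal observation noise applied
#'   to recorded dissolved amounts only (default 0 = none).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A [dissolution_dataset()] with a canister provenance ledger and a
#'   `mass_balance` attribute (maximum relative drug-mass error over the
#'   sampling times).
#' @export
simulate_transit <- function(method, formulation, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(method, "method_spec"), inherits(formulation, "formulation_spec"))
  dt <- method$integration_step_min
  cps <- method$compartments
  ncomp <- length(cps)
  cnames <- names(cps)
  n_steps <- ceiling(method$duration_min / dt - 1e-9)
  sample_steps <- round(method$sampling_times_min / dt)

  start_v <- vapply(cps, function(cp) cp$starting_volume_mL, 0)
  residual <- vapply(cps, function(cp) cp$residual_mL, 0)
  res_time <- vapply(cps, function(cp) cp$residence_time_min, 0)
  delay_steps <- round(res_time / dt)

  # state: compartments 1..ncomp then canister
  V <- c(start_v, 0)
  undiss <- c(formulation$dose_mg, rep(0, ncomp))
  diss <- matrix(0, nrow = ncomp + 1, ncol = ncomp,
                 dimnames = list(c(cnames, "canister"), cnames))
  withdrawn_v <- rep(0, ncomp)      # per-compartment withdrawn volume
  withdrawn_diss <- 0               # total withdrawn dissolved mass
  gastric_rate <- (start_v[1] - residual[1]) / res_time[1]

  # inflow volume history per step for compartments 2..ncomp (plug-flow delay)
  inflow_hist <- matrix(0, nrow = n_steps, ncol = ncomp)

  events <- vector("list", length(sample_steps) * ncomp)
  n_ev <- 0
  nt <- length(sample_steps)
  rec_diss <- matrix(0, nt, ncomp + 1)
  rec_vol <- matrix(0, nt, ncomp + 1)
  rec_ph <- matrix(NA_real_, nt, ncomp + 1)
  rec_origin <- matrix(0, nt, ncomp, dimnames = list(NULL, cnames))
  rec_mass_err <- numeric(nt)
  rec_i <- 0

  ph_of <- function(i, t) {
    cp <- cps[[i]]
    if (!identical(cp$ph_setpoint, "free")) return(cp$ph_setpoint)
    if (formulation$buffered && t >= formulation$disintegration_time_min)
      formulation$gastric_ph_after_buffer else 2.4
  }

  for (s in seq_len(n_steps)) {
    t_prev <- (s - 1) * dt
    t_now <- s * dt

    # (1) dissolution within each compartment
    if (t_prev >= formulation$disintegration_time_min - 1e-12) {
      for (i in seq_len(ncomp)) {
        if (undiss[i] <= 0 || V[i] <= 0) next
        ph <- ph_of(i, t_prev)
        S <- solubility_at_ph(formulation$intrinsic_solubility_mg_per_mL,
                              formulation$pKa, ph,
                              formulation$solubility_ceiling_mg_per_mL)
        C <- sum(diss[i, ]) / V[i]
        drive <- S - C
        if (drive <= 0) next
        dm <- formulation$dissolution_rate_coeff_z * undiss[i]^(2 / 3) * drive * dt
        dm <- min(dm, undiss[i], drive * V[i])
        undiss[i] <- undiss[i] - dm
        diss[i, i] <- diss[i, i] + dm
      }
    }

    # (2)+(3) transfers, synchronous from post-dissolution state
    outvol <- numeric(ncomp)
    outvol[1] <- min(gastric_rate * dt,
                     max(0, V[1] - (residual[1] - withdrawn_v[1])))
    for (i in 2:ncomp) {
      sched <- if (s > delay_steps[i]) inflow_hist[s - delay_steps[i], i] else 0
      outvol[i] <- min(sched, max(0, V[i] - max(0, residual[i] - withdrawn_v[i])))
    }
    frac <- ifelse(V[seq_len(ncomp)] > 0, outvol / V[seq_len(ncomp)], 0)
    move_diss <- diss[seq_len(ncomp), , drop = FALSE] * frac
    move_undiss <- undiss[seq_len(ncomp)] * frac
    for (i in seq_len(ncomp)) {
      dest <- i + 1  # next compartment, or canister after the last
      V[i] <- V[i] - outvol[i]
      V[dest] <- V[dest] + outvol[i]
      diss[i, ] <- diss[i, ] - move_diss[i, ]
      diss[dest, ] <- diss[dest, ] + move_diss[i, ]
      undiss[i] <- undiss[i] - move_undiss[i]
      undiss[dest] <- undiss[dest] + move_undiss[i]
      if (dest <= ncomp) inflow_hist[s, dest] <- outvol[i]
    }

    # (4) sampling withdrawal + recording
    k <- match(s, sample_steps)
    if (!is.na(k)) {
      for (i in seq_len(ncomp)) {
        w <- min(method$withdrawal_mL, V[i])
        if (w > 0) {
          share <- w / V[i]
          removed <- sum(diss[i, ]) * share
          diss[i, ] <- diss[i, ] * (1 - share)
          V[i] <- V[i] - w
          withdrawn_v[i] <- withdrawn_v[i] + w
          withdrawn_diss <- withdrawn_diss + removed
          n_ev <- n_ev + 1
          events[[n_ev]] <- data.frame(time_min = t_now, compartment = cnames[i],
                                       withdrawn_mL = w,
                                       dissolved_mg_removed = removed)
        }
      }
      rec_i <- rec_i + 1
      rec_diss[rec_i, ] <- rowSums(diss)
      rec_vol[rec_i, ] <- V
      rec_ph[rec_i, seq_len(ncomp)] <- vapply(seq_len(ncomp), ph_of, 0, t = t_now)
      rec_origin[rec_i, ] <- diss[ncomp + 1, ]
      total_mass <- sum(diss) + sum(undiss) + withdrawn_diss
      rec_mass_err[rec_i] <- if (formulation$dose_mg > 0)
        abs(total_mass - formulation$dose_mg) / formulation$dose_mg else 0
    }
  }

  st <- method$sampling_times_min
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    rec_diss <- rec_diss * matrix(exp(stats::rnorm(length(rec_diss), 0, noise_sd)),
                                  nrow = nrow(rec_diss))
  }

  comps <- list()
  all_names <- c(cnames, "canister")
  for (j in seq_along(all_names)) {
    comps[[all_names[j]]] <- list(
      dissolved = ts_profile(st, pmax(rec_diss[, j], 0), "min", "mg", "amount"),
      volume = ts_profile(st, rec_vol[, j], "min", "mL", "amount"),
      ph = ts_profile(st, ifelse(is.na(rec_ph[, j]), 0, rec_ph[, j]),
                      "min", "pH", "amount")
    )
  }
  ev <- if (n_ev > 0) do.call(rbind, events[seq_len(n_ev)]) else empty_sampling_events()
  ds <- dissolution_dataset(formulation$formulation_id, max(formulation$dose_mg, 1e-12),
                            comps, sampling_events = ev,
                            canister_by_origin = rec_origin)
  ds$dose_mg <- formulation$dose_mg  # keep a true zero dose visible
  attr(ds, "mass_balance") <- max(rec_mass_err)
  attr(ds, "withdrawn_volume_mL") <- sum(withdrawn_v)
  ds
}
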