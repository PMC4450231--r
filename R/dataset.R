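GI_COMPARTMENTS <- c("stomach", "duodenum", "jejunum", "ileum")

#' Multicompartment dissolution dataset
#'
#' Holds one formulation run of the four-compartment transit dissolution
#' experiment: per-compartment traces of dissolved drug, fluid volume and pH
#' on a shared sampling grid, the collection canister, and the ledger of
#' sample withdrawals.
#'
#' @param formulation_id character label.
#' @param dose_mg administered dose (mg), > 0.
#' @param compartments named list over `stomach`, `duodenum`, `jejunum`,
#'   `ileum` and `canister`; each element a list with `dissolved` (mg),
#'   `volume` (mL) and `ph` [ts_profile()]s sharing one time grid (minutes).
#' @param sampling_events data frame with columns `time_min`, `compartment`,
#'   `withdrawn_mL` and (optionally) `dissolved_mg_removed`; one row per
#'   sample withdrawal. May have zero rows.
#' @param canister_by_origin optional matrix (sampling times x the four GI
#'   compartments) giving the dissolved mass in the canister attributed to
#'   the compartment in which it dissolved. Produced by [simulate_transit()];
#'   absent for imported datasets.
#' @return An object of class `dissolution_dataset`.
#' @export
dissolution_dataset <- function(formulation_id, dose_mg, compartments,
                                sampling_events = empty_sampling_events(),
                                canister_by_origin = NULL) {
  if (!is.numeric(dose_mg) || length(dose_mg) != 1 || dose_mg <= 0)
    stop("dose_mg must be a positive scalar", call. = FALSE)
  known <- c(GI_COMPARTMENTS, "canister")
  if (!all(names(compartments) %in% known))
    stop("unknown compartment name(s): ",
         paste(setdiff(names(compartments), known), collapse = ", "),
         call. = FALSE)
  grid <- NULL
  for (nm in names(compartments)) {
    cp <- compartments[[nm]]
    for (fld in c("dissolved", "volume")) {
      if (!inherits(cp[[fld]], "ts_profile"))
        stop(sprintf("compartment '%s' lacks a '%s' profile", nm, fld), call. = FALSE)
      if (any(cp[[fld]]$values < -1e-9))
        stop(sprintf("negative %s in compartment '%s'", fld, nm), call. = FALSE)
      if (is.null(grid)) grid <- cp[[fld]]$times
      if (!isTRUE(all.equal(cp[[fld]]$times, grid)))
        stop("all compartment profiles must share one sampling grid", call. = FALSE)
    }
  }
  structure(
    list(formulation_id = formulation_id, dose_mg = dose_mg,
         compartments = compartments, sampling_events = sampling_events,
         canister_by_origin = canister_by_origin, times_min = grid),
    class = "dissolution_dataset"
  )
}

#' Single-compartment dissolution curve
#'
#' Extracts one compartment's dissolved-drug trace, either as the resident
#' amount (mg) or as the bulk concentration (mg/mL). The amount trace shows
#' the rise-and-fall shape used by the compartmental IVIVR: it climbs while
#' drug dissolves and arrives from upstream, and falls while medium is
#' transferred downstream.
#'
#' @param dataset a [dissolution_dataset()].
#' @param compartment compartment name.
#' @param as `"amount"` (mg, default) or `"concentration"` (mg/mL).
#' @return A [ts_profile()] (minutes).
#' @export
compartment_profile <- function(dataset, compartment = "jejunum",
                                as = c("amount", "concentration")) {
  as <- match.arg(as)
  stopifnot(inherits(dataset, "dissolution_dataset"))
  if (!compartment %in% names(dataset$compartments))
    stop("unknown compartment name: ", compartment, call. = FALSE)
  cp <- dataset$compartments[[compartment]]
  if (as == "amount") return(cp$dissolved)
  v <- pmax(cp$volume$values, 1e-12)
  ts_profile(cp$dissolved$times, cp$dissolved$values / v, "min", "mg/mL",
             "concentration")
}

empty_sampling_events <- function() {
  data.frame(time_min = numeric(0), compartment = character(0),
             withdrawn_mL = numeric(0), dissolved_mg_removed = numeric(0))
}

#' @export
print.dissolution_dataset <- function(x, ...) {
  cat(sprintf("<dissolution_dataset> '%s', dose %g mg, %d compartments, %d sampling times\n",
              x$formulation_id, x$dose_mg, length(x$compartments), length(x$times_min)))
  invisible(x)
}

#' Cumulative fraction of dose dissolved
#'
#' Sums the dissolved drug resident in the included compartments at each
#' sampling time, adds the dissolved mass accumulated in the collection
#' canister that is attributable to the included compartments, and (with the
#' withdrawal correction on) adds back the dissolved mass removed by past
#' sample withdrawals from included compartments. The result is divided by
#' the dose.
#'
#' Canister attribution: for simulator-produced datasets the canister mass is
#' tracked by the compartment in which the drug dissolved (provenance
#' ledger); for imported datasets, where no such ledger exists, the whole
#' canister is included if and only if `"ileum"` is included (the canister is
#' fed exclusively by the ileum), a documented limitation.
#'
#' @param dataset a [dissolution_dataset()].
#' @param include_compartments character vector of GI compartment names to
#'   include (default all four). The fraction dissolved in the stomach is
#'   conventionally excluded from correlation work by dropping `"stomach"`.
#' @param apply_withdrawal_correction logical; add back dissolved mass
#'   removed by sampling (default `TRUE`).
#' @return A fraction-kind [ts_profile()] on the dataset grid (minutes).
#' @export
cumulative_fraction <- function(dataset, include_compartments = GI_COMPARTMENTS,
                                apply_withdrawal_correction = TRUE) {
  stopifnot(inherits(dataset, "dissolution_dataset"))
  have <- intersect(names(dataset$compartments), GI_COMPARTMENTS)
  unknown <- setdiff(include_compartments, have)
  if (length(unknown))
    stop("unknown compartment name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  grid <- dataset$times_min
  total <- rep(0, length(grid))
  for (nm in include_compartments)
    total <- total + dataset$compartments[[nm]]$dissolved$values

  if ("canister" %in% names(dataset$compartments)) {
    if (!is.null(dataset$canister_by_origin)) {
      cols <- intersect(include_compartments, colnames(dataset$canister_by_origin))
      if (length(cols))
        total <- total + rowSums(dataset$canister_by_origin[, cols, drop = FALSE])
    } else if ("ileum" %in% include_compartments) {
      total <- total + dataset$compartments$canister$dissolved$values
    }
  }

  if (apply_withdrawal_correction && nrow(dataset$sampling_events) > 0) {
    ev <- dataset$sampling_events
    ev <- ev[ev$compartment %in% include_compartments, , drop = FALSE]
    if (nrow(ev) > 0) {
      if (is.null(ev$dissolved_mg_removed))
        stop("sampling events lack 'dissolved_mg_removed'; cannot correct",
             call. = FALSE)
      for (k in seq_along(grid))
        total[k] <- total[k] + sum(ev$dissolved_mg_removed[ev$time_min <= grid[k] + 1e-9])
    }
  }

  frac <- pmin(total / dataset$dose_mg, 1.0001)
  ts_profile(grid, frac, "min", "fraction", "fraction")
}
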