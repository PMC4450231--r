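#' Read and write dissolution datasets as CSV
#'
#' Dialect: header `time_min,compartment,dissolved_mg,volume_mL,pH`, one row
#' per compartment per sampling time, UTF-8, comma separator, `.` decimal.
#' Rows may arrive in any order; they are sorted canonically by compartment
#' and time. An optional sidecar CSV (`time_min,compartment,withdrawn_mL`,
#' plus `dissolved_mg_removed` when known) carries the sampling events.
#'
#' @param path CSV file path.
#' @param formulation_id,dose_mg metadata for the constructed dataset.
#' @param events_path optional sampling-events sidecar CSV.
#' @return `read_dissolution_csv()`: a [dissolution_dataset()];
#'   `write_dissolution_csv()`: the path, invisibly.
#' @export
read_dissolution_csv <- function(path, formulation_id = basename(path),
                                 dose_mg = 80, events_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "compartment", "dissolved_mg", "volume_mL", "pH")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$volume_mL < 0))
    stop("negative volume at row ", which(df$volume_mL < 0)[1], call. = FALSE)
  if (any(df$dissolved_mg < 0))
    stop("negative dissolved amount at row ", which(df$dissolved_mg < 0)[1], call. = FALSE)
  comps <- list()
  for (nm in unique(df$compartment)) {
    sub <- df[df$compartment == nm, , drop = FALSE]
    sub <- sub[order(sub$time_min), , drop = FALSE]
    if (any(diff(sub$time_min) <= 0))
      stop(sprintf("non-monotone (duplicated) times for compartment '%s' near row %d",
                   nm, which(df$compartment == nm)[1]), call. = FALSE)
    comps[[nm]] <- list(
      dissolved = ts_profile(sub$time_min, sub$dissolved_mg, "min", "mg", "amount"),
      volume = ts_profile(sub$time_min, sub$volume_mL, "min", "mL", "amount"),
      ph = ts_profile(sub$time_min, sub$pH, "min", "pH", "amount"))
  }
  events <- empty_sampling_events()
  if (!is.null(events_path)) {
    ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
    need_ev <- c("time_min", "compartment", "withdrawn_mL")
    miss <- setdiff(need_ev, names(ev))
    if (length(miss))
      stop("sampling events file missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    if (is.null(ev$dissolved_mg_removed)) ev$dissolved_mg_removed <- NA_real_
    events <- ev
  }
  dissolution_dataset(formulation_id, dose_mg, comps, sampling_events = events)
}

#' @rdname read_dissolution_csv
#' @param dataset a [dissolution_dataset()].
#' @export
write_dissolution_csv <- function(dataset, path, events_path = NULL) {
  stopifnot(inherits(dataset, "dissolution_dataset"))
  rows <- lapply(names(dataset$compartments), function(nm) {
    cp <- dataset$compartments[[nm]]
    data.frame(time_min = cp$dissolved$times, compartment = nm,
               dissolved_mg = cp$dissolved$values, volume_mL = cp$volume$values,
               pH = cp$ph$values)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  if (!is.null(events_path))
    utils::write.csv(dataset$sampling_events, events_path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write plasma profiles as CSV
#'
#' Dialect: header `time_h,conc_ng_per_mL`.
#'
#' @param path CSV file path.
#' @return `read_plasma_csv()`: a concentration [ts_profile()] in hours.
#' @export
read_plasma_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "conc_ng_per_mL")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- df[order(df$time_h), , drop = FALSE]
  if (any(diff(df$time_h) <= 0))
    stop("non-monotone (duplicated) times in plasma file", call. = FALSE)
  ts_profile(df$time_h, df$conc_ng_per_mL, "h", "ng/mL", "concentration")
}

#' @rdname read_plasma_csv
#' @param profile a plasma [ts_profile()].
#' @export
write_plasma_csv <- function(profile, path) {
  stopifnot(inherits(profile, "ts_profile"))
  utils::write.csv(data.frame(time_h = profile$times,
                              conc_ng_per_mL = profile$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write a unit impulse response as JSON
#'
#' Format: `{"dose_basis_mg": 80, "terms": [{"C": ..., "lambda": ...}, ...]}`.
#'
#' @param path JSON file path.
#' @return `read_uir_json()`: a [uir_spec()].
#' @export
read_uir_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$terms) || is.null(x$dose_basis_mg))
    stop("UIR JSON must contain 'terms' and 'dose_basis_mg'", call. = FALSE)
  uir_spec(as.data.frame(x$terms), dose_basis_mg = x$dose_basis_mg)
}

#' @rdname read_uir_json
#' @param uir a [uir_spec()].
#' @export
write_uir_json <- function(uir, path) {
  stopifnot(inherits(uir, "uir_spec"))
  jsonlite::write_json(list(dose_basis_mg = uir$dose_basis_mg, terms = uir$terms),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read method and formulation specifications from YAML
#'
#' Method YAML keys: `compartments` (list of `name`, `start_volume_mL`,
#' `residence_min`, `ph`, optional `residual_mL`), `duration_min`,
#' `sampling_min`, `withdrawal_mL`, `step_min`. Formulation YAML keys match
#' the [formulation_spec()] fields.
#'
#' @param path YAML file path.
#' @return A [golem_method()] or [formulation_spec()].
#' @export
read_method_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  comps <- if (is.null(y$compartments)) fasted_compartments() else
    lapply(y$compartments, function(cp)
      compartment_spec(cp$name, cp$start_volume_mL, cp$residence_min,
                       if (identical(cp$ph, "free")) "free" else as.numeric(cp$ph),
                       residual_mL = if (is.null(cp$residual_mL)) cp$start_volume_mL
                       else cp$residual_mL))
  golem_method(
    duration_min = if (is.null(y$duration_min)) 215 else y$duration_min,
    sampling_times_min = if (is.null(y$sampling_min))
      default_sampling_times(if (is.null(y$duration_min)) 215 else y$duration_min)
    else unlist(y$sampling_min),
    withdrawal_mL = if (is.null(y$withdrawal_mL)) 1 else y$withdrawal_mL,
    integration_step_min = if (is.null(y$step_min)) 0.1 else y$step_min,
    compartments = comps)
}

#' @rdname read_method_yaml
#' @export
read_formulation_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$formulation_id)) stop("formulation YAML needs 'formulation_id'", call. = FALSE)
  args <- y[intersect(names(y), names(formals(formulation_spec)))]
  do.call(formulation_spec, args)
}
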