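#' Read a dissolution profile CSV
#'
#' Expected columns: `time_h`, `released_pct` (and optionally replicate
#' columns `released_pct_1 .. released_pct_k`).  Header required.
#'
#' @param path CSV path.
#' @return A single [dissolution_profile()] or, when replicate columns are
#'   present, a list of them (one per replicate column).
#' @export
read_dissolution_csv <- function(path) {
  d <- utils::read.csv(path, check.names = TRUE)
  if (!all(c("time_h", "released_pct") %in% names(d)) &&
      !("time_h" %in% names(d) && any(grepl("^released_pct_\\d+$", names(d)))))
    stop("expected columns `time_h` and `released_pct` (or `released_pct_1..k`)")
  reps <- grep("^released_pct_\\d+$", names(d), value = TRUE)
  if (length(reps) > 0) {
    lapply(reps, function(cn)
      dissolution_profile(d$time_h, d[[cn]], label = cn))
  } else {
    dissolution_profile(d$time_h, d$released_pct,
                        label = tools::file_path_sans_ext(basename(path)))
  }
}

#' Write a dissolution profile CSV
#'
#' @param profile A [dissolution_profile()] or a list of them sharing a grid
#'   (written as replicate columns).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_dissolution_csv <- function(profile, path) {
  if (inherits(profile, "dissolution_profile")) {
    d <- data.frame(time_h = profile$times, released_pct = profile$released)
  } else {
    stopifnot(is.list(profile), length(profile) >= 1)
    d <- data.frame(time_h = profile[[1]]$times)
    for (i in seq_along(profile))
      d[[paste0("released_pct_", i)]] <- profile[[i]]$released
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a formulation library JSON
#'
#' @param library Named list of [virtual_formulation()] objects.
#' @param path JSON path.
#' @return The path (write) or the reconstructed named list (read).
#' @export
write_formulation_json <- function(library, path) {
  rows <- lapply(library, function(f) {
    list(label = f$label, f_max = f$weibull$f_max, alpha = f$weibull$alpha,
         beta = f$weibull$beta, t_lag = f$weibull$t_lag,
         trigger_ph = f$trigger_ph, provenance = f$provenance,
         f2_vs_reference = f$f2_vs_reference)
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_formulation_json
#' @export
read_formulation_json <- function(path) {
  rows <- jsonlite::read_json(path)
  out <- lapply(rows, function(r) {
    virtual_formulation(
      weibull_params(r$f_max, r$alpha, r$beta, r$t_lag),
      trigger_ph = r$trigger_ph, label = r$label,
      provenance = r$provenance,
      f2_vs_reference = if (is.null(r$f2_vs_reference)) NA_real_
                        else r$f2_vs_reference)
  })
  names(out) <- vapply(out, function(f) f$label, character(1))
  out
}

#' Export simulation concentrations and ledgers as CSV
#'
#' Writes the tidy concentration table (`time_h,site,layer,conc_nM`) and a
#' companion ledger CSV (`<stem>_ledger.csv`).
#'
#' @param result A [simulate_dose()] result.
#' @param path Path of the concentration CSV.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(result, path) {
  stopifnot(inherits(result, "gut_sim_result"))
  utils::write.csv(sim_concentrations(result), path, row.names = FALSE)
  stem <- tools::file_path_sans_ext(path)
  utils::write.csv(result$ledgers, paste0(stem, "_ledger.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a drug / physiology configuration YAML
#'
#' Keys carry explicit units in their names (`_h`, `_nM`, `_L_per_h`);
#' unrecognized keys raise an error through the constructors.
#'
#' @param path YAML file.
#' @param what `"drug"` or `"physiology"`.
#' @return A `drug_params` or `subject_physiology` object.
#' @export
read_config_yaml <- function(path, what = c("drug", "physiology")) {
  what <- match.arg(what)
  vals <- yaml::read_yaml(path)
  if (what == "drug") {
    do.call(budesonide_params, vals)
  } else {
    do.call(subject_physiology, vals)
  }
}
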