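#' Healthy-volunteer population specification
#'
#' Mean physiology of the healthy population (gastric fluid MRT 0.27 h, SI
#' fluid MRT 3.4 h, liver CYP3A4 137 pmol/mg, SI CYP3A4 65.4 nmol, colon
#' CYP3A4 1.99 nmol, albumin 50.34 g/L males / 49.38 g/L females), default
#' between-subject variability, truncation bounds, and demographics (age
#' 20-50, 50% female).  Between-subject CVs are not published for the source
#' simulator; the defaults here (30% on enzyme abundances, 20% on residence
#' times, flows and masses, 15% on albumin and weight) are stated
#' assumptions, all configurable.
#'
#' @return An object of class `population_spec`.
#' @export
default_healthy_population <- function() {
  means <- list(
    gastric_pellet_mrt_h = 0.8,
    si_pellet_mrt_h = 3,
    gastric_fluid_mrt_h = 0.27,
    si_fluid_mrt_h = 3.4,
    colon_fluid_mrt_h = c(M = 37.5, F = 55.75),
    liver_cyp3a4_pmol_per_mg = c(M = 137, F = 137),
    si_cyp3a4_nmol = 65.4,
    colon_cyp3a4_nmol = 1.99,
    hsa_g_per_L = c(M = 50.34, F = 49.38),
    liver_blood_flow_L_per_h = 90,
    liver_mass_g = 1650,
    mppgl_mg_per_g = 40,
    pgp_abundance_ref = 0.4,
    body_weight_kg = c(M = 70, F = 60))
  bsv <- c(
    gastric_pellet_mrt_h = 20, si_pellet_mrt_h = 20,
    gastric_fluid_mrt_h = 20, si_fluid_mrt_h = 20, colon_fluid_mrt_h = 20,
    liver_cyp3a4_pmol_per_mg = 30, si_cyp3a4_nmol = 30, colon_cyp3a4_nmol = 30,
    hsa_g_per_L = 15, liver_blood_flow_L_per_h = 20, liver_mass_g = 20,
    mppgl_mg_per_g = 20, pgp_abundance_ref = 30, body_weight_kg = 15)
  bounds <- list(
    gastric_fluid_mrt_h = c(0.01, 12),
    si_fluid_mrt_h = c(0.5, 12),
    colon_fluid_mrt_h = c(0.1, 240))
  structure(list(label = "HV", means = means, bsv = bsv, bounds = bounds,
                 prop_female = 0.5, age_range = c(20, 50)),
            class = "population_spec")
}

#' Crohn's-disease population specification
#'
#' The healthy specification with four parameters overridden: liver CYP3A4
#' 55.4 (M) / 80.5 (F) pmol/mg, small-intestinal CYP3A4 8.6 nmol, colonic
#' CYP3A4 0.2 nmol, and albumin 30.13 (M) / 25.2 (F) g/L.  All other
#' parameters equal the healthy specification.
#'
#' @return An object of class `population_spec`.
#' @export
crohns_population <- function() {
  spec <- default_healthy_population()
  spec$label <- "CD"
  spec$means$liver_cyp3a4_pmol_per_mg <- c(M = 55.4, F = 80.5)
  spec$means$si_cyp3a4_nmol <- 8.6
  spec$means$colon_cyp3a4_nmol <- 0.2
  spec$means$hsa_g_per_L <- c(M = 30.13, F = 25.2)
  spec
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s: age %d-%d, %.0f%% female\n",
              x$label, x$age_range[1], x$age_range[2], 100 * x$prop_female))
  invisible(x)
}

#' Mean (representative) subject of a population
#'
#' @param spec A `population_spec`.
#' @param sex `"M"` or `"F"`.
#' @return A [subject_physiology()] at the specification means.
#' @export
representative_subject <- function(spec, sex = "M") {
  vals <- lapply(spec$means, function(v)
    if (length(v) > 1) unname(v[sex]) else unname(v))
  do.call(subject_physiology, c(list(sex = sex), vals))
}

pick_mean <- function(v, sex) if (length(v) > 1) unname(v[sex]) else unname(v)

#' Sample virtual subjects from a population
#'
#' Lognormal between-subject sampling at the specification CVs (median
#' preserved at the specification mean), clamped to configured physiological
#' bounds; sex is assigned to match the proportion female.  Fully
#' reproducible under the seed.
#'
#' @param spec A `population_spec`.
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed.
#' @return A list of [subject_physiology()] objects; each carries its
#'   subject id and age.
#' @export
sample_subjects <- function(spec, n, seed = 1) {
  stopifnot(inherits(spec, "population_spec"), n >= 1)
  set.seed(seed)
  n_f <- round(n * spec$prop_female)
  sexes <- sample(c(rep("F", n_f), rep("M", n - n_f)))
  ages <- runif(n, spec$age_range[1], spec$age_range[2])
  lapply(seq_len(n), function(i) {
    sex <- sexes[i]
    vals <- lapply(names(spec$means), function(pn) {
      mu <- pick_mean(spec$means[[pn]], sex)
      cv <- spec$bsv[[pn]]
      if (is.null(cv) || is.na(cv) || cv == 0) return(mu)
      sdlog <- sqrt(log(1 + (cv / 100)^2))
      x <- mu * exp(rnorm(1, 0, sdlog))
      b <- spec$bounds[[pn]]
      if (is.null(b)) b <- c(mu / 4, mu * 4)
      min(max(x, b[1]), b[2])
    })
    names(vals) <- names(spec$means)
    do.call(subject_physiology,
            c(list(sex = sex, age = ages[i], gfr_mL_per_min = NA_real_), vals))
  })
}

#' Within-subject variability specification
#'
#' Occasion-to-occasion variability of fluid residence times: the CV, the
#' physiological clamp limits, and the reference value of each parameter.
#' Whole-colon values are used for the single colon compartment.
#'
#' @return A tibble with columns `parameter`, `cv_pct`, `min_limit`,
#'   `base_value`, `max_limit`.
#' @export
wsv_defaults <- function() {
  tibble::tibble(
    parameter = c("gastric_fluid_mrt_h", "si_fluid_mrt_h", "colon_fluid_mrt_h"),
    cv_pct = c(38.217, 21.132, 44.962),
    min_limit = c(0.01, 0.5, 0.1),
    base_value = c(0.27, 3.4, 37.5),
    max_limit = c(12, 12, 240))
}

#' Apply within-subject (occasion) variability
#'
#' Multiplies each listed parameter by an independent lognormal deviate at
#' its CV (median 1), then clamps to the `[min_limit, max_limit]` range.
#' Non-listed parameters are untouched.  Occasions draw independently.
#'
#' @param subject A [subject_physiology()].
#' @param occasion Occasion index (1 or 2).
#' @param wsv A [wsv_defaults()]-shaped tibble.
#' @param seed Integer seed; combine with the occasion index upstream to make
#'   occasions independent.
#' @return A perturbed [subject_physiology()].
#' @export
apply_wsv <- function(subject, occasion, wsv = wsv_defaults(), seed = 1) {
  stopifnot(inherits(subject, "subject_physiology"), occasion %in% c(1, 2))
  set.seed(seed + 7919L * (occasion - 1L))
  out <- unclass(subject)
  for (i in seq_len(nrow(wsv))) {
    pn <- wsv$parameter[i]
    cv <- wsv$cv_pct[i]
    if (cv <= 0) next
    sdlog <- sqrt(log(1 + (cv / 100)^2))
    x <- out[[pn]] * exp(rnorm(1, 0, sdlog))
    out[[pn]] <- min(max(x, wsv$min_limit[i]), wsv$max_limit[i])
  }
  structure(out, class = "subject_physiology")
}

#' Parameter ranges for the local sensitivity analysis
#'
#' One-at-a-time ranges spanning healthy and Crohn's-disease values:
#' gastric MRT 0.27-2.5 h, SI MRT 3.4-6 h, liver CYP3A4 34.35-137 pmol/mg,
#' SI CYP3A4 8.6-65.4 nmol, albumin 30-50 g/L, colon CYP3A4 0.2-1.99 nmol,
#' and reference P-gp abundance 0.075-0.4 pmol/mg.
#'
#' @return Named list of `c(min, max)` ranges keyed by physiology field.
#' @export
lsa_ranges <- function() {
  list(
    gastric_fluid_mrt_h = c(0.27, 2.5),
    si_fluid_mrt_h = c(3.4, 6),
    liver_cyp3a4_pmol_per_mg = c(34.35, 137),
    si_cyp3a4_nmol = c(8.6, 65.4),
    hsa_g_per_L = c(30, 50),
    colon_cyp3a4_nmol = c(0.2, 1.99),
    pgp_abundance_ref = c(0.075, 0.4))
}

#' Local sensitivity analysis
#'
#' One-at-a-time sweep of physiological parameters for a deterministic
#' representative subject: each parameter moves across its range (log-spaced
#' when the range spans more than 3-fold) while all others stay at base;
#' plasma Cmax and AUC_last are recomputed by simulation.  The unbound
#' fraction is re-derived from albumin when albumin is swept.
#'
#' @param base A [subject_physiology()] (the representative).
#' @param ranges Named list of `c(min, max)`; see [lsa_ranges()].
#' @param drug,formulation,dose_mg Simulation inputs.
#' @param n_points Sweep points per parameter (default 5).
#' @param options,t_end Passed to the simulator.
#' @return A tibble: `parameter, value, endpoint, result, ratio_to_base`.
#' @export
local_sensitivity_analysis <- function(base, ranges = lsa_ranges(),
                                       drug = budesonide_params(),
                                       formulation = reference_formulation(),
                                       dose_mg = 3, n_points = 5,
                                       options = model_options(),
                                       t_end = 24) {
  stopifnot(inherits(base, "subject_physiology"))
  bad <- setdiff(names(ranges), names(unclass(base)))
  if (length(bad))
    stop("unknown physiology parameter(s) in `ranges`: ",
         paste(bad, collapse = ", "))
  endpoints_of <- function(ph) {
    sim <- simulate_dose(build_subject_model(drug, ph, formulation, dose_mg,
                                             options), t_end = t_end)
    pk <- nca(sim$times, sim$plasma_conc)
    c(c_max = pk$c_max, auc_last = pk$auc_last)
  }
  base_ep <- endpoints_of(base)
  rows <- lapply(names(ranges), function(pn) {
    r <- ranges[[pn]]
    grid <- if (r[2] / r[1] > 3) exp(seq(log(r[1]), log(r[2]), length.out = n_points))
            else seq(r[1], r[2], length.out = n_points)
    dplyr::bind_rows(lapply(grid, function(v) {
      ph <- unclass(base)
      ph[[pn]] <- v
      ep <- endpoints_of(structure(ph, class = "subject_physiology"))
      tibble::tibble(parameter = pn, value = v,
                     endpoint = names(ep), result = unname(ep),
                     ratio_to_base = unname(ep / base_ep))
    }))
  })
  dplyr::bind_rows(rows)
}
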