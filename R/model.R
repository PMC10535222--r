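#' Structural model options
#'
#' Calibration constants and reduction switches of the gut absorption model.
#' The accessibility fractions scale anatomical cylinder surface areas down
#' to effective exchange areas (fasted gut fluid wets only part of the
#' mucosa); the basolateral fraction is larger so that the simulated
#' enterocyte:lumen concentration ratio sits near the observed ~1%.  These
#' are calibrations chosen once, not measurements.
#'
#' @param apical_area_frac Effective fraction of anatomical area for
#'   apical (lumen to enterocyte) exchange.
#' @param baso_area_frac Same for basolateral (enterocyte to portal) exchange.
#' @param enterocyte_volume_frac Enterocyte volume as a fraction of the
#'   segment's lumen fluid volume.
#' @param v1_frac Central volume as a fraction of steady-state volume.
#' @param q_cld_L_per_h Intercompartment distribution clearance, L/h.
#' @param one_compartment Collapse disposition to one compartment.
#' @param pgp,gut_metabolism,dissolved_transit,enterocyte Process switches;
#'   `enterocyte = FALSE` routes absorbed drug straight to portal blood
#'   (used for closed-form reductions).
#' @param release `"weibull"` (pellets, pH-triggered) or `"instant"`
#'   (dose appears dissolved in `instant_release_segment` at t = 0).
#' @param instant_release_segment Segment name for instant release.
#' @param absorb_segments `NULL` for all absorbing segments, or a character
#'   vector restricting absorption to the named ones.
#' @param hepatic_extraction_override `NULL` to compute the well-stirred
#'   value, or a number in `[0, 1)`.
#' @param hazard_cap Upper bound on the Weibull release hazard, 1/h.
#' @param rtol,atol Solver tolerances.
#' @return A list of options.
#' @export
model_options <- function(apical_area_frac = 0.05,
                          baso_area_frac = 0.25,
                          enterocyte_volume_frac = 0.01,
                          v1_frac = 0.25,
                          q_cld_L_per_h = 40,
                          one_compartment = FALSE,
                          pgp = TRUE,
                          gut_metabolism = TRUE,
                          dissolved_transit = TRUE,
                          enterocyte = TRUE,
                          release = c("weibull", "instant"),
                          instant_release_segment = "duodenum",
                          absorb_segments = NULL,
                          hepatic_extraction_override = NULL,
                          hazard_cap = 50,
                          rtol = 1e-8, atol = 1e-10) {
  release <- match.arg(release)
  as.list(environment())
}

seg_names <- function() c("stomach", "duodenum", "jejunum1", "jejunum2",
                          "ileum1", "ileum2", "ileum3", "ileum4", "colon")
abs_seg_names <- function() seg_names()[-1]

#' Assemble a single-subject gut absorption model
#'
#' Builds the full state/rate structure for one subject, drug and
#' formulation: first-order pellet transit chains honoring the gastric and
#' small-intestinal pellet mean residence times (SI MRT split over the seven
#' SI segments in proportion to length), pH-triggered Weibull release (a
#' shared release clock advances with the solid fraction past its trigger
#' pH), apical absorption with regional scalars, Michaelis-Menten P-gp
#' efflux, abundance-scaled gut CYP3A4, basolateral transfer to portal blood,
#' well-stirred hepatic first pass, renal elimination, and two-compartment
#' systemic disposition with `V_ss = kp_scalar * vss_per_kg * body weight`.
#'
#' @param drug A [budesonide_params()]-style `drug_params` object.
#' @param physio A [subject_physiology()] object.
#' @param formulation A [virtual_formulation()] object.
#' @param dose_mg Dose in mg (> 0).
#' @param options A [model_options()] list.
#' @return An object of class `gut_model`: parameter vector, initial state,
#'   volumes, and metadata, ready for [simulate_dose()].
#' @export
build_subject_model <- function(drug, physio, formulation, dose_mg = 3,
                                options = model_options()) {
  stopifnot(inherits(drug, "drug_params"),
            inherits(physio, "subject_physiology"),
            inherits(formulation, "virtual_formulation"),
            dose_mg > 0)
  seg <- physio$segments
  stopifnot(identical(seg$name, seg_names()))
  o <- options
  dose_nmol <- dose_mg / drug$mol_weight * 1e6

  # --- binding and systemic clearances -------------------------------------
  fu <- fu_from_hsa(drug$fu_plasma, physio$hsa_g_per_L, drug$hsa_ref_g_per_L)
  cl_r <- renal_clearance(fu, physio$gfr_mL_per_min)
  clint_liver <- scale_hepatic_clint(drug$clint_cyp3a4,
                                     physio$liver_cyp3a4_pmol_per_mg,
                                     physio$mppgl_mg_per_g,
                                     physio$liver_mass_g)
  eh <- if (is.null(o$hepatic_extraction_override)) {
    hepatic_extraction(clint_liver, fu / drug$blood_plasma_ratio,
                       physio$liver_blood_flow_L_per_h)
  } else o$hepatic_extraction_override
  cl_h <- physio$liver_blood_flow_L_per_h * eh

  vss <- drug$kp_scalar * drug$vss_per_kg * physio$body_weight_kg
  if (o$one_compartment) {
    v1 <- vss; k12 <- 0; k21 <- 0
  } else {
    v1 <- o$v1_frac * vss
    v2 <- vss - v1
    k12 <- o$q_cld_L_per_h / v1
    k21 <- o$q_cld_L_per_h / v2
  }
  kh <- cl_h / v1
  kr <- cl_r / v1

  # --- transit rates --------------------------------------------------------
  si <- 2:8
  len_si <- seg$length_cm[si]
  ks <- numeric(9)
  ks[1] <- 1 / physio$gastric_pellet_mrt_h
  ks[si] <- 1 / (physio$si_pellet_mrt_h * len_si / sum(len_si))
  ks[9] <- 1 / physio$colon_fluid_mrt_h  # pellets move with colonic contents
  kf <- numeric(9)
  kf[1] <- 1 / physio$gastric_fluid_mrt_h
  kf[si] <- 1 / (physio$si_fluid_mrt_h * len_si / sum(len_si))
  kf[9] <- 1 / physio$colon_fluid_mrt_h
  if (!o$dissolved_transit) kf[] <- 0

  # --- exchange clearances per absorbing segment ---------------------------
  a <- seg[-1, ]
  area <- 2 * pi * a$radius_cm * a$length_cm          # cm^2
  v_lumen <- a$fluid_volume_mL / 1000                 # L
  v_ent <- o$enterocyte_volume_frac * v_lumen
  # P (1e-6 cm/s) * area (cm^2) -> L/h: 1e-6 * 3.6
  cl_ap <- (drug$apical_ptrans0 + drug$p_para) * 1e-6 * area * 3.6 *
    a$absorption_scalar * o$apical_area_frac
  if (!is.null(o$absorb_segments)) {
    stopifnot(all(o$absorb_segments %in% abs_seg_names()))
    cl_ap[!a$name %in% o$absorb_segments] <- 0
  }
  cl_baso <- drug$basolateral_ptrans0 * 1e-6 * area * 3.6 * o$baso_area_frac
  kabs <- cl_ap / v_lumen
  kbaso <- cl_baso * drug$fu_gut / v_ent

  # gut CYP3A4: uL/min/pmol * pmol -> L/h is * 6e-5
  abund_nmol <- c(physio$si_cyp3a4_nmol * a$cyp3a4_share[1:7],
                  physio$colon_cyp3a4_nmol)
  clint_gut <- drug$clint_cyp3a4 * 6e-5 * abund_nmol * 1000
  kmet <- if (o$gut_metabolism) clint_gut * drug$fu_gut / v_ent else rep(0, 8)

  pgp_scale <- physio$pgp_abundance_ref / 0.4
  pgp_v <- if (o$pgp) {
    drug$pgp_jmax * area * 60 / 1000 * pgp_scale * a$transporter_rel_abundance
  } else rep(0, 8)
  pgp_ka <- drug$pgp_km_uM * 1000 * v_ent / drug$fu_gut  # nmol

  if (!o$enterocyte) { kmet[] <- 0; pgp_v[] <- 0 }

  # --- release --------------------------------------------------------------
  wb <- formulation$weibull
  gopen <- as.numeric(seg$ph > formulation$trigger_ph)
  if (o$release == "weibull" && all(gopen == 0))
    warning("trigger pH ", formulation$trigger_ph,
            " is above all segment pH values: no release will occur")

  y0 <- setNames(numeric(42), state_names())
  if (o$release == "instant") {
    gopen[] <- 0
    idx <- match(o$instant_release_segment, seg_names())
    y0[paste0("L_", seg_names()[idx])] <- dose_nmol
  } else {
    y0["S_stomach"] <- dose_nmol
  }

  parms <- c(
    ks = ks, kf = kf, gopen = gopen,
    fmax = wb$f_max, alpha = wb$alpha, beta = wb$beta, tlag = wb$t_lag,
    hcap = o$hazard_cap,
    kabs = kabs, kbaso = kbaso, kmet = kmet,
    pgpV = pgp_v, pgpKA = pgp_ka,
    EH = eh, kH = kh, kR = kr, k12 = k12, k21 = k21,
    bypass = as.numeric(!o$enterocyte))
  stopifnot(length(parms) == 78)

  structure(list(
    parms = parms, y0 = y0, dose_nmol = dose_nmol, dose_mg = dose_mg,
    v1_L = v1, v_lumen_L = setNames(v_lumen, a$name),
    v_ent_L = setNames(v_ent, a$name),
    fu = fu, eh = eh, cl_r_L_per_h = cl_r, cl_h_L_per_h = cl_h,
    clint_liver_L_per_h = clint_liver,
    drug = drug, physio = physio, formulation = formulation,
    options = o), class = "gut_model")
}

state_names <- function() {
  c(paste0("S_", seg_names()), paste0("L_", seg_names()),
    paste0("E_", abs_seg_names()), "A_central", "A_peripheral",
    "gut_met", "liver_met", "renal", "fecal_solid", "fecal_dissolved",
    "tau", paste0("abs_", abs_seg_names()))
}

#' @export
print.gut_model <- function(x, ...) {
  cat(sprintf(paste0("<gut_model> %s, %s %.3g mg (%.0f nmol)\n",
                     "  fu %.3f, E_H %.3f, CL_R %.2f L/h, CL_H %.1f L/h, V1 %.1f L\n"),
              x$drug$name, x$formulation$label, x$dose_mg, x$dose_nmol,
              x$fu, x$eh, x$cl_r_L_per_h, x$cl_h_L_per_h, x$v1_L))
  invisible(x)
}

#' Simulate a dose through the gut model
#'
#' Stiff BDF (vode) integration of the assembled model.  Concentrations are
#' derived from compartment amounts and volumes: lumen and enterocyte
#' concentrations per segment and the systemic plasma concentration (all nM).
#'
#' @param model A [build_subject_model()] result.
#' @param t_end End of simulation, hours.
#' @param output_grid Output times; defaults to 0 to `t_end` in 0.25 h steps.
#' @return An object of class `gut_sim_result` with elements `times`,
#'   `plasma_conc`, `lumen_conc` and `enterocyte_conc` (time x segment
#'   matrices), `ledgers` (a tibble of mass-balance components, nmol),
#'   `absorbed_by_segment`, `dose_nmol` and `model`.
#' @export
simulate_dose <- function(model, t_end = 24,
                          output_grid = seq(0, t_end, by = 0.25)) {
  stopifnot(inherits(model, "gut_model"), t_end >= max(output_grid))
  out <- tryCatch(
    deSolve::vode(y = unname(model$y0), times = output_grid,
                  func = "gut_derivs", parms = unname(model$parms),
                  dllname = "lumenvbe", initfunc = "gut_init",
                  rtol = model$options$rtol, atol = model$options$atol,
                  maxsteps = 100000),
    error = function(e)
      stop("ODE solver failed (", conditionMessage(e), ") for formulation '",
           model$formulation$label, "', dose ", model$dose_mg, " mg"))
  m <- as.matrix(out)[, -1, drop = FALSE]
  colnames(m) <- state_names()
  # tolerate solver-level noise: clamp tiny negatives
  neg <- m < 0
  if (any(m[neg] < -1e-6 * model$dose_nmol))
    warning("state values below -1e-6 * dose encountered")
  m[neg] <- 0

  sn <- seg_names(); an <- abs_seg_names()
  lumen_amt <- m[, paste0("L_", an), drop = FALSE]
  ent_amt <- m[, paste0("E_", an), drop = FALSE]
  lumen_conc <- sweep(lumen_amt, 2, model$v_lumen_L, "/")
  ent_conc <- sweep(ent_amt, 2, model$v_ent_L, "/")
  colnames(lumen_conc) <- colnames(ent_conc) <- an

  ledgers <- tibble::tibble(
    time_h = output_grid,
    undissolved = rowSums(m[, paste0("S_", sn), drop = FALSE]),
    dissolved_lumen = rowSums(m[, paste0("L_", sn), drop = FALSE]),
    enterocyte = rowSums(ent_amt),
    central = m[, "A_central"],
    peripheral = m[, "A_peripheral"],
    gut_metabolized = m[, "gut_met"],
    liver_metabolized = m[, "liver_met"],
    renally_excreted = m[, "renal"],
    fecal = m[, "fecal_solid"] + m[, "fecal_dissolved"],
    absorbed_to_portal = rowSums(m[, paste0("abs_", an), drop = FALSE]))

  structure(list(
    times = output_grid,
    plasma_conc = m[, "A_central"] / model$v1_L,
    lumen_conc = lumen_conc,
    enterocyte_conc = ent_conc,
    ledgers = ledgers,
    absorbed_by_segment = setNames(m[nrow(m), paste0("abs_", an)], an),
    release_clock = m[, "tau"],
    dose_nmol = model$dose_nmol,
    model = model), class = "gut_sim_result")
}

#' @export
print.gut_sim_result <- function(x, ...) {
  cmax <- max(x$plasma_conc)
  cat(sprintf(paste0("<gut_sim_result> %s, %.3g mg, %.0f-%.0f h (%d points)\n",
                     "  plasma Cmax %.3g nM at %.2g h; absorbed %.1f%% of dose\n",
                     "  mass-balance max rel. error %.2g\n"),
              x$model$formulation$label, x$model$dose_mg, min(x$times),
              max(x$times), length(x$times), cmax,
              x$times[which.max(x$plasma_conc)],
              100 * sum(x$absorbed_by_segment) / x$dose_nmol,
              max(mass_balance(x)$rel_error)))
  invisible(x)
}

#' Mass-balance ledger check
#'
#' Sums all ledger components at each output time and reports the relative
#' deviation from the administered dose.
#'
#' @param result A [simulate_dose()] result.
#' @return A tibble with `time_h`, `total_nmol` and `rel_error`.
#' @export
mass_balance <- function(result) {
  stopifnot(inherits(result, "gut_sim_result"))
  l <- result$ledgers
  total <- l$undissolved + l$dissolved_lumen + l$enterocyte + l$central +
    l$peripheral + l$gut_metabolized + l$liver_metabolized +
    l$renally_excreted + l$fecal
  tibble::tibble(time_h = l$time_h, total_nmol = total,
                 rel_error = abs(total - result$dose_nmol) / result$dose_nmol)
}

#' Regional fraction of dose absorbed
#'
#' @param result A [simulate_dose()] result.
#' @return A tibble per segment: amount absorbed to portal blood, fraction
#'   of dose, and fraction of total absorbed (zero total gives zero shares).
#' @export
regional_fraction_absorbed <- function(result) {
  stopifnot(inherits(result, "gut_sim_result"))
  amt <- result$absorbed_by_segment
  tot <- sum(amt)
  tibble::tibble(
    segment = names(amt),
    absorbed_nmol = unname(amt),
    fraction_of_dose = unname(amt) / result$dose_nmol,
    fraction_of_absorbed = if (tot > 0) unname(amt) / tot else rep(0, length(amt)))
}

#' Tidy concentration export of a simulation
#'
#' @param result A [simulate_dose()] result.
#' @return A tibble `time_h, site, layer, conc_nM` covering plasma and the
#'   lumen/enterocyte layers of all eight segments.
#' @export
sim_concentrations <- function(result) {
  stopifnot(inherits(result, "gut_sim_result"))
  an <- abs_seg_names()
  long <- function(mat, layer) {
    tibble::tibble(
      time_h = rep(result$times, length(an)),
      site = rep(an, each = length(result$times)),
      layer = layer,
      conc_nM = as.vector(mat))
  }
  dplyr::bind_rows(
    tibble::tibble(time_h = result$times, site = "plasma", layer = "plasma",
                   conc_nM = result$plasma_conc),
    long(result$lumen_conc, "lumen"),
    long(result$enterocyte_conc, "enterocyte"))
}
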