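#' Renal clearance from unbound filtration
#'
#' `CL_R = fu * GFR`, converted from mL/min to L/h.
#'
#' @param fu Unbound fraction in plasma, in `[0, 1]`.
#' @param gfr Glomerular filtration rate, mL/min.
#' @return Renal clearance in L/h.
#' @export
renal_clearance <- function(fu, gfr) {
  stopifnot(is.numeric(fu), is.numeric(gfr))
  if (any(fu < 0 | fu > 1)) stop("`fu` must be in [0, 1]")
  if (any(gfr < 0)) stop("`gfr` must be non-negative")
  fu * gfr * 60 / 1000
}

#' Apical transcellular permeability from lipophilicity
#'
#' `P_trans,0 = a * P_o:w^b` with `P_o:w = 10^log_p`; reported in units of
#' 1e-6 cm/s.
#'
#' @param log_p Octanol-water log partition coefficient.
#' @param a,b Regression coefficients (defaults 2.36e-6 and 1.1).
#' @return Permeability in 1e-6 cm/s.
#' @export
apical_permeability <- function(log_p, a = 2.36e-6, b = 1.1) {
  stopifnot(is.numeric(log_p), is.numeric(a), is.numeric(b))
  a * (10 ^ log_p) ^ b * 1e6
}

#' Scale in vitro intrinsic clearance to the whole liver
#'
#' Standard IVIVE chain: per-pmol intrinsic clearance x enzyme abundance x
#' microsomal protein per gram of liver x liver mass, converted to L/h.
#'
#' @param clint_per_pmol Intrinsic clearance, uL/min/pmol of isoform.
#' @param abundance Hepatic enzyme abundance, pmol/mg microsomal protein.
#' @param mppgl Microsomal protein per gram of liver, mg/g.
#' @param liver_mass Liver mass, g.
#' @return Whole-liver intrinsic clearance in L/h.
#' @export
scale_hepatic_clint <- function(clint_per_pmol, abundance, mppgl, liver_mass) {
  stopifnot(clint_per_pmol >= 0, abundance >= 0, mppgl >= 0, liver_mass >= 0)
  clint_per_pmol * 1e-6 * abundance * mppgl * liver_mass * 60
}

#' Well-stirred hepatic extraction ratio
#'
#' `E_H = fu_b * CL_int / (Q_H + fu_b * CL_int)`.
#'
#' @param clint_liver Whole-liver intrinsic clearance, L/h.
#' @param fu_blood Unbound fraction in blood.
#' @param q_h Hepatic blood flow, L/h.
#' @return Extraction ratio in `[0, 1)`.
#' @export
hepatic_extraction <- function(clint_liver, fu_blood, q_h) {
  stopifnot(clint_liver >= 0, fu_blood >= 0, q_h > 0)
  fu_blood * clint_liver / (q_h + fu_blood * clint_liver)
}

#' Unbound fraction rescaled for albumin concentration
#'
#' Proportional binding-site scaling: with binding assigned to serum albumin,
#' `fu' = 1 / (1 + (1 - fu)/fu * HSA'/HSA_ref)`.
#'
#' @param fu_ref Unbound fraction at the reference albumin concentration.
#' @param hsa Subject albumin concentration, g/L.
#' @param hsa_ref Reference albumin concentration, g/L.
#' @return Adjusted unbound fraction.
#' @export
fu_from_hsa <- function(fu_ref, hsa, hsa_ref) {
  stopifnot(fu_ref > 0, fu_ref <= 1, hsa > 0, hsa_ref > 0)
  1 / (1 + (1 - fu_ref) / fu_ref * hsa / hsa_ref)
}

#' Drug parameter set for the modelled corticosteroid
#'
#' Physicochemical, binding, permeability, transporter and clearance
#' parameters of budesonide, the neutral lipophilic corticosteroid dosed as
#' enteric-coated controlled-release pellets.
#'
#' @param ... Named overrides of any default.
#' @return An object of class `drug_params`.
#' @export
budesonide_params <- function(...) {
  p <- list(
    name = "budesonide",
    mol_weight = 430.53,          # g/mol
    log_p = 2.62,
    fu_plasma = 0.15,             # at hsa_ref
    hsa_ref_g_per_L = 50.34,
    blood_plasma_ratio = 0.8,
    clint_cyp3a4 = 4.1,           # uL/min/pmol isoform
    pgp_jmax = 93,                # pmol/min/cm^2 equivalent (cited bare)
    pgp_km_uM = 9.4,
    perm_coeff_a = 2.36e-6,
    perm_coeff_b = 1.1,
    apical_ptrans0 = NA_real_,    # 1e-6 cm/s; computed from log_p if NA
    basolateral_ptrans0 = 6000,   # 1e-6 cm/s
    p_para = 0.05506,             # 1e-6 cm/s
    fu_gut = 1,                   # unbound fraction in enterocyte
    kp_scalar = 0.8,
    vss_per_kg = 2.69             # L/kg
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown drug parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (is.na(p$apical_ptrans0))
    p$apical_ptrans0 <- apical_permeability(p$log_p, p$perm_coeff_a,
                                            p$perm_coeff_b)
  stopifnot(p$mol_weight > 0, p$fu_plasma > 0, p$fu_plasma <= 1,
            p$apical_ptrans0 >= 0, p$basolateral_ptrans0 > 0)
  structure(p, class = "drug_params")
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> %s  MW %.1f  logP %.2f  fu %.3g  P_app %.1f e-6 cm/s\n",
              x$name, x$mol_weight, x$log_p, x$fu_plasma, x$apical_ptrans0))
  invisible(x)
}
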