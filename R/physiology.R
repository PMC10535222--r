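#' Default gastrointestinal segment table
#'
#' Nine compartments: stomach plus eight absorbing segments (duodenum, two
#' jejunum, four ileum, colon).  Fasted-state pH values, dimensions, fluid
#' volumes, regional absorption scalars (0.06 duodenum, 0.12 jejunum, 0.54
#' ileum, 1.44 colon), and the share of small-intestinal CYP3A4 abundance per
#' segment.  All values are explicit configuration; pH and geometry are
#' literature-typical fasted defaults.
#'
#' @return A tibble with one row per segment.
#' @export
default_segments <- function() {
  if (!is.null(.seg_cache$tab)) return(.seg_cache$tab)
  .seg_cache$tab <- tibble::tibble(
    name = c("stomach", "duodenum", "jejunum1", "jejunum2",
             "ileum1", "ileum2", "ileum3", "ileum4", "colon"),
    ph = c(1.5, 6.0, 6.2, 6.4, 6.8, 7.0, 7.2, 7.4, 6.4),
    length_cm = c(NA, 30, 90, 90, 75, 75, 75, 75, 110),
    radius_cm = c(NA, 1.6, 1.4, 1.4, 1.25, 1.25, 1.25, 1.25, 2.5),
    fluid_volume_mL = c(35, 12, 30, 25, 20, 15, 12, 10, 13),
    absorption_scalar = c(0, 0.06, 0.12, 0.12, 0.54, 0.54, 0.54, 0.54, 1.44),
    cyp3a4_share = c(0, 0.09, 0.235, 0.235, 0.15, 0.115, 0.095, 0.08, NA),
    transporter_rel_abundance = c(0, 1, 1, 1, 1, 1, 1, 1, 1)
  )
  .seg_cache$tab
}

.seg_cache <- new.env(parent = emptyenv())

#' Virtual subject physiology
#'
#' One virtual subject's gastrointestinal, enzymatic and binding parameter
#' set.  Defaults are the healthy-volunteer representative (a young adult;
#' GFR 172.42 mL/min, liver CYP3A4 137 pmol/mg, small-intestinal CYP3A4
#' 65.4 nmol, colonic CYP3A4 1.99 nmol, albumin 50.34 g/L for males).
#'
#' @param sex `"M"` or `"F"`.
#' @param ... Named overrides of any field.
#' @return An object of class `subject_physiology`.
#' @export
subject_physiology <- function(sex = "M", ...) {
  stopifnot(sex %in% c("M", "F"))
  p <- list(
    sex = sex,
    age = 24,
    body_weight_kg = if (sex == "M") 70 else 60,
    gastric_pellet_mrt_h = 0.8,
    si_pellet_mrt_h = 3,
    gastric_fluid_mrt_h = 0.27,
    si_fluid_mrt_h = 3.4,
    colon_fluid_mrt_h = if (sex == "M") 37.5 else 55.75,  # whole colon
    liver_cyp3a4_pmol_per_mg = 137,
    si_cyp3a4_nmol = 65.4,
    colon_cyp3a4_nmol = 1.99,
    hsa_g_per_L = if (sex == "M") 50.34 else 49.38,
    gfr_mL_per_min = NA_real_,
    liver_blood_flow_L_per_h = 90,
    liver_mass_g = 1650,
    mppgl_mg_per_g = 40,
    pgp_abundance_ref = 0.4,      # pmol/mg, anchored at jejunum I
    segments = default_segments()
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown physiology field(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  # GFR: allometric weight scaling from the 70-kg anchor, unless supplied
  if (is.na(p$gfr_mL_per_min))
    p$gfr_mL_per_min <- 172.42 * (p$body_weight_kg / 70)^0.75
  validate_physiology(p)
  structure(p, class = "subject_physiology")
}

validate_physiology <- function(p) {
  num <- c("body_weight_kg", "gastric_pellet_mrt_h", "si_pellet_mrt_h",
           "gastric_fluid_mrt_h", "si_fluid_mrt_h", "colon_fluid_mrt_h",
           "liver_cyp3a4_pmol_per_mg", "si_cyp3a4_nmol", "colon_cyp3a4_nmol",
           "hsa_g_per_L", "gfr_mL_per_min", "liver_blood_flow_L_per_h",
           "liver_mass_g", "mppgl_mg_per_g", "pgp_abundance_ref")
  for (f in num)
    if (!is.numeric(p[[f]]) || p[[f]] <= 0)
      stop("physiology field `", f, "` must be positive")
  seg <- p$segments
  if (any(seg$ph < 1 | seg$ph > 9)) stop("segment pH must lie in [1, 9]")
  if (any(seg$fluid_volume_mL <= 0)) stop("segment fluid volumes must be positive")
  if (any(seg$absorption_scalar < 0)) stop("absorption scalars must be >= 0")
  invisible(p)
}

#' @export
print.subject_physiology <- function(x, ...) {
  cat(sprintf(paste0("<subject_physiology> sex %s, %.0f kg, GFR %.1f mL/min\n",
                     "  liver CYP3A4 %.3g pmol/mg, SI %.3g nmol, colon %.3g nmol, HSA %.3g g/L\n",
                     "  MRT: pellets %.2g h (gastric) / %.2g h (SI); fluid %.2g / %.2g / %.3g h (colon)\n"),
              x$sex, x$body_weight_kg, x$gfr_mL_per_min,
              x$liver_cyp3a4_pmol_per_mg, x$si_cyp3a4_nmol, x$colon_cyp3a4_nmol,
              x$hsa_g_per_L, x$gastric_pellet_mrt_h, x$si_pellet_mrt_h,
              x$gastric_fluid_mrt_h, x$si_fluid_mrt_h, x$colon_fluid_mrt_h))
  invisible(x)
}
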