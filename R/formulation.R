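#' Virtual formulation
#'
#' A formulation characterized by its Weibull release parameters, the pH at
#' which the enteric coating opens, and (for virtual variants) the
#' modification that produced it from a reference.
#'
#' @param weibull A [weibull_params()] object.
#' @param trigger_ph Coating trigger pH in `[1, 9]`; release can begin only
#'   in segments whose pH exceeds it.
#' @param label Formulation label (e.g. `"+10%"`).
#' @param provenance `NULL` for a reference, or a list
#'   `list(type = "delta", delta = )` / `list(type = "trigger_ph", from = )`.
#' @param f2_vs_reference f2 similarity versus the reference profile, or `NA`.
#' @return An object of class `virtual_formulation`.
#' @export
virtual_formulation <- function(weibull, trigger_ph = 5.5, label = "",
                                provenance = NULL, f2_vs_reference = NA_real_) {
  stopifnot(inherits(weibull, "weibull_params"))
  if (trigger_ph < 1 || trigger_ph > 9)
    stop("`trigger_ph` must be in [1, 9]")
  structure(list(weibull = weibull, trigger_ph = trigger_ph, label = label,
                 provenance = provenance,
                 f2_vs_reference = f2_vs_reference),
            class = "virtual_formulation")
}

#' @export
print.virtual_formulation <- function(x, ...) {
  cat(sprintf("<virtual_formulation> %s  trigger pH %.2g  f2 %s\n",
              if (nzchar(x$label)) x$label else "(unnamed)", x$trigger_ph,
              ifelse(is.na(x$f2_vs_reference), "-",
                     sprintf("%.1f", x$f2_vs_reference))))
  print(x$weibull)
  invisible(x)
}

#' Reference controlled-release formulation
#'
#' The enteric-coated multi-pellet reference product: Weibull release with
#' `f_max` 100%, scale 3.12, shape 0.94, no lag, coating trigger pH 5.5.
#' @return A [virtual_formulation()].
#' @export
reference_formulation <- function() {
  virtual_formulation(weibull_params(100, 3.12, 0.94, 0),
                      trigger_ph = 5.5, label = "reference")
}

#' Library of virtual formulations
#'
#' The reference plus eight virtual variants: six with the release percentage
#' shifted by a constant at every sampling point (+20, +10, +5, +3, -5, -10
#' percentage points, refitted to the Weibull function) and two with only the
#' coating trigger pH changed (5.0 and 6.0).  Stored f2 values are inputs
#' that accompany the fitted parameters, not recomputed quantities.
#'
#' @return Named list of [virtual_formulation()] objects; first element is
#'   the reference.
#' @export
formulation_library <- function() {
  row <- function(label, f2, a, b, ph, prov) {
    virtual_formulation(weibull_params(100, a, b, 0), trigger_ph = ph,
                        label = label, provenance = prov,
                        f2_vs_reference = f2)
  }
  list(
    reference = reference_formulation(),
    `+20%` = row("+20%", 36.1, 1.53, 0.87, 5.5, list(type = "delta", delta = 20)),
    `+10%` = row("+10%", 50.8, 2.14, 0.89, 5.5, list(type = "delta", delta = 10)),
    `+5%`  = row("+5%",  65.5, 2.56, 0.91, 5.5, list(type = "delta", delta = 5)),
    `+3%`  = row("+3%",  75.8, 2.77, 0.92, 5.5, list(type = "delta", delta = 3)),
    `-5%`  = row("-5%",  65.5, 3.90, 1.01, 5.5, list(type = "delta", delta = -5)),
    `-10%` = row("-10%", 50.8, 5.01, 1.09, 5.5, list(type = "delta", delta = -10)),
    `pH5`  = row("pH5",  NA,   3.12, 0.94, 5.0, list(type = "trigger_ph", from = 5.5)),
    `pH6`  = row("pH6",  NA,   3.12, 0.94, 6.0, list(type = "trigger_ph", from = 5.5))
  )
}

#' Apply a constant release-percentage shift to a profile
#'
#' Adds `delta` percentage points at every sampling time, caps at 100%, and
#' applies the completion-time convention: 100% release is forced at 12 h
#' (at 7 h, and beyond, for shifts of +20 or more, where the cap is reached
#' early).
#'
#' @param reference A [dissolution_profile()].
#' @param delta Shift in percentage points (may be negative).
#' @return The modified [dissolution_profile()].
#' @export
apply_delta_modification <- function(reference, delta) {
  stopifnot(inherits(reference, "dissolution_profile"))
  y <- reference$released + delta
  if (any(y < -1e-9))
    stop("delta of ", delta, " produces negative release at ",
         sum(y < -1e-9), " point(s)")
  y <- pmin(y, 100)
  completion_h <- if (delta >= 20) 7 else 12
  y[reference$times >= completion_h - 1e-9] <- 100
  y <- cummax(y)
  dissolution_profile(reference$times, y,
                      label = sprintf("%+g%%", delta))
}

#' Construct a virtual formulation from a reference profile
#'
#' Exactly one of `delta` or `trigger_ph` must be supplied.  In delta mode the
#' sampled reference curve is shifted, capped and completion-standardized (see
#' [apply_delta_modification()]), then refitted to the Weibull function with
#' `f_max` fixed at 100%; the f2 of the modified versus reference profile is
#' stored.  In trigger-pH mode the release curve is untouched and only the
#' coating trigger changes.
#'
#' @param reference A [dissolution_profile()] of the reference product.
#' @param delta Shift in percentage points, or `NULL`.
#' @param trigger_ph New trigger pH, or `NULL`.
#' @param reference_trigger_ph Trigger pH of the reference (default 5.5).
#' @return A [virtual_formulation()].
#' @export
make_virtual_formulation <- function(reference, delta = NULL,
                                     trigger_ph = NULL,
                                     reference_trigger_ph = 5.5) {
  stopifnot(inherits(reference, "dissolution_profile"))
  if (is.null(delta) == is.null(trigger_ph))
    stop("supply exactly one of `delta` or `trigger_ph`")
  if (!is.null(trigger_ph)) {
    wb <- fit_weibull(reference, fix_fmax = 100)
    return(virtual_formulation(
      wb, trigger_ph = trigger_ph,
      label = sprintf("pH threshold = %g", trigger_ph),
      provenance = list(type = "trigger_ph", from = reference_trigger_ph),
      f2_vs_reference = NA_real_))
  }
  mod <- apply_delta_modification(reference, delta)
  wb <- fit_weibull(mod, fix_fmax = 100)
  virtual_formulation(
    wb, trigger_ph = reference_trigger_ph,
    label = sprintf("%+g%%", delta),
    provenance = list(type = "delta", delta = delta),
    f2_vs_reference = similarity_f2(reference, mod))
}

#' Standardized reference dissolution profile
#'
#' The reference Weibull curve sampled on the default grid with the
#' completion convention applied: 100% dissolution is forced at 12 h (the
#' assay does not reach 100% by itself, so completion is standardized before
#' f2 comparisons).
#'
#' @param grid Sampling times, hours.
#' @param standardize Force 100% at and beyond 12 h (default `TRUE`).
#' @return A [dissolution_profile()].
#' @export
reference_dissolution_profile <- function(grid = default_dissolution_grid(),
                                          standardize = TRUE) {
  y <- weibull_release(reference_formulation()$weibull, grid)
  if (standardize) y[grid >= 12 - 1e-9] <- 100
  dissolution_profile(grid, cummax(y), label = "reference")
}

#' Sample a formulation's release curve
#'
#' @param formulation A [virtual_formulation()].
#' @param grid Sampling times in hours.
#' @return A [dissolution_profile()].
#' @export
sample_formulation <- function(formulation,
                               grid = default_dissolution_grid()) {
  stopifnot(inherits(formulation, "virtual_formulation"))
  dissolution_profile(grid, weibull_release(formulation$weibull, grid),
                      label = formulation$label)
}
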