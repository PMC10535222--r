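#' Noncompartmental analysis of a concentration-time profile
#'
#' `c_max` is the maximum concentration, `t_max` the earliest time attaining
#' it, and `auc_last` the linear-trapezoid area up to the last positive
#' concentration (lin-up/log-down available via `method`).
#'
#' @param times Ascending sampling times, hours (>= 3 points).
#' @param conc Concentrations, nM.
#' @param method `"linear"` (default) or `"linuplogdown"`.
#' @return A list: `auc_last`, `c_max`, `t_max`, `all_zero` flag.
#' @export
nca <- function(times, conc, method = c("linear", "linuplogdown")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(conc), length(times) >= 3,
            all(diff(times) > 0))
  if (all(conc <= 0))
    return(list(auc_last = 0, c_max = 0, t_max = times[1], all_zero = TRUE))
  c_max <- max(conc)
  t_max <- times[which.max(conc)]
  last <- max(which(conc > 0))
  tt <- times[seq_len(last)]
  cc <- conc[seq_len(last)]
  dt <- diff(tt)
  c1 <- cc[-length(cc)]
  c2 <- cc[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linuplogdown") {
    down <- c2 < c1 & c2 > 0 & c1 > 0
    seg[down] <- (c1[down] - c2[down]) / log(c1[down] / c2[down]) * dt[down]
  }
  list(auc_last = sum(seg), c_max = c_max, t_max = t_max, all_zero = FALSE)
}

#' Crossover trial design
#'
#' Two-sequence (TR/RT), two-treatment, two-period design with balanced
#' sequence assignment, complete washout (no carryover simulated).
#'
#' @param n_trials Number of replicated trials (default 10).
#' @param n_subjects Subjects per trial; must be even for balance
#'   (default 12).
#' @param seed Master seed governing cohorts and occasion variability.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_trials = 10, n_subjects = 12, seed = 1) {
  stopifnot(n_trials >= 1, n_subjects >= 2)
  if (n_subjects %% 2 != 0)
    stop("`n_subjects` must be even for balanced sequence assignment")
  structure(list(n_trials = n_trials, n_subjects = n_subjects,
                 seed = as.integer(seed)), class = "trial_design")
}

#' Default plasma sampling schedule
#' @return Times in hours.
#' @export
plasma_sampling_grid <- function() c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 24)

#' Run a replicated virtual bioequivalence study
#'
#' For each trial: a fresh cohort is sampled from the population, sequences
#' TR/RT are assigned 50/50, within-subject variability is drawn per period
#' (shared by whichever treatment that period carries), and each
#' subject-period is simulated under its occasion physiology.  NCA metrics
#' (AUC_last, Cmax) are computed for plasma (at the clinical sampling
#' schedule) and for the lumen and enterocyte layers of all eight segments
#' (dense solver grid).  Fully deterministic under the design seed.
#'
#' @param reference,test [virtual_formulation()] objects.
#' @param population A `population_spec`.
#' @param design A [trial_design()].
#' @param drug A `drug_params` object.
#' @param dose_mg Dose per administration, mg.
#' @param wsv Within-subject variability table ([wsv_defaults()]); pass a
#'   table with `cv_pct = 0` to disable.
#' @param options Model options.
#' @param t_end Simulation horizon, hours.
#' @return A tibble of PK metrics:
#'   `trial, subject, sequence, period, treatment, site, layer, metric, value`.
#' @export
run_vbe <- function(reference, test, population, design = trial_design(),
                    drug = budesonide_params(), dose_mg = 3,
                    wsv = wsv_defaults(), options = model_options(),
                    t_end = 24) {
  stopifnot(inherits(reference, "virtual_formulation"),
            inherits(test, "virtual_formulation"),
            inherits(population, "population_spec"),
            inherits(design, "trial_design"))
  set.seed(design$seed)
  trial_seeds <- sample.int(2^30, design$n_trials)
  occ_seeds <- matrix(sample.int(2^30, design$n_trials * design$n_subjects),
                      nrow = design$n_trials)
  grid <- sort(union(seq(0, t_end, by = 0.25), plasma_sampling_grid()))
  plasma_idx <- grid %in% plasma_sampling_grid()
  an <- abs_seg_names()

  all_rows <- vector("list", design$n_trials)
  for (tr in seq_len(design$n_trials)) {
    cohort <- sample_subjects(population, design$n_subjects,
                              seed = trial_seeds[tr])
    seqs <- rep(c("TR", "RT"), length.out = design$n_subjects)
    rows <- vector("list", design$n_subjects * 2L)
    k <- 0L
    for (s in seq_len(design$n_subjects)) {
      for (per in 1:2) {
        trt <- substr(seqs[s], per, per)
        form <- if (trt == "T") test else reference
        occ <- apply_wsv(cohort[[s]], occasion = per, wsv = wsv,
                         seed = occ_seeds[tr, s])
        sim <- simulate_dose(
          build_subject_model(drug, occ, form, dose_mg, options),
          t_end = t_end, output_grid = grid)
        pk_plasma <- nca(grid[plasma_idx], sim$plasma_conc[plasma_idx])
        site_rows <- vector("list", 1 + 2 * length(an))
        site_rows[[1]] <- tibble::tibble(
          site = "plasma", layer = "plasma",
          metric = c("auc_last", "c_max"),
          value = c(pk_plasma$auc_last, pk_plasma$c_max))
        j <- 1L
        for (seg in an) {
          for (lay in c("lumen", "enterocyte")) {
            cm <- if (lay == "lumen") sim$lumen_conc[, seg]
                  else sim$enterocyte_conc[, seg]
            pk <- nca(grid, cm)
            j <- j + 1L
            site_rows[[j]] <- tibble::tibble(
              site = seg, layer = lay, metric = c("auc_last", "c_max"),
              value = c(pk$auc_last, pk$c_max))
          }
        }
        k <- k + 1L
        rows[[k]] <- dplyr::bind_rows(site_rows) %>%
          dplyr::mutate(trial = tr, subject = s, sequence = seqs[s],
                        period = per, treatment = trt, .before = 1)
      }
    }
    all_rows[[tr]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(all_rows)
}

#' Closed-form 2x2 crossover bioequivalence analysis
#'
#' Log-scale analysis equivalent to the linear mixed-effect model with
#' sequence, period and treatment fixed and subject-within-sequence random:
#' for balanced complete data the treatment contrast is the mean of the
#' per-subject log(T) - log(R) differences averaged over sequence groups,
#' with pooled within-sequence variance, `n - 2` degrees of freedom and a
#' 90% t confidence interval.  Bioequivalent iff the CI lies inside
#' `[0.80, 1.25]`.
#'
#' @param table A data frame with columns `subject, sequence, period,
#'   treatment, value` for one trial, one site and one metric.  Must be
#'   balanced and complete; zero or negative values are rejected.
#' @param limits Bioequivalence limits on the ratio scale.
#' @return A one-row tibble: `gmr, ci_low, ci_high, se_log, df, be_flag, n`.
#' @export
crossover_be <- function(table, limits = c(0.80, 1.25)) {
  req <- c("subject", "sequence", "period", "treatment", "value")
  stopifnot(all(req %in% names(table)))
  if (any(table$value <= 0))
    stop("non-positive metric values cannot be log-transformed")
  w <- tidyr::pivot_wider(
    table[, c("subject", "sequence", "treatment", "value")],
    names_from = "treatment", values_from = "value")
  if (!all(c("T", "R") %in% names(w)) || anyNA(w$T) || anyNA(w$R) ||
      nrow(w) != length(unique(table$subject)))
    stop("unbalanced or incomplete 2x2 data (dropouts are not modelled)")
  g1 <- w$sequence == "TR"
  g2 <- w$sequence == "RT"
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 subjects per sequence")
  x <- log(w$T) - log(w$R)
  m1 <- mean(x[g1]); m2 <- mean(x[g2])
  est <- (m1 + m2) / 2
  s2 <- (sum((x[g1] - m1)^2) + sum((x[g2] - m2)^2)) / (n1 + n2 - 2)
  se <- sqrt(s2 / 4 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  ci <- est + qt(c(0.05, 0.95), df) * se
  tibble::tibble(
    gmr = exp(est), ci_low = exp(ci[1]), ci_high = exp(ci[2]),
    se_log = se, df = df,
    be_flag = ci[1] >= log(limits[1]) & ci[2] <= log(limits[2]),
    n = n1 + n2)
}

#' Bioequivalence analysis of a full VBE metric table
#'
#' Applies [crossover_be()] to every trial x site x layer x metric cell.
#' A cell where one formulation produces no exposure at all (a zero metric,
#' e.g. the duodenum when the test coating only opens further downstream)
#' cannot be log-analysed; it is recorded as non-bioequivalent with `NA`
#' statistics rather than dropped.
#'
#' @param pk_table Output of [run_vbe()].
#' @param limits Bioequivalence limits.
#' @return A tibble with one row per trial/site/layer/metric.
#' @export
be_results <- function(pk_table, limits = c(0.80, 1.25)) {
  pk_table %>%
    dplyr::group_by(trial, site, layer, metric) %>%
    dplyr::group_modify(function(d, key) {
      if (any(d$value <= 0)) {
        return(tibble::tibble(
          gmr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          se_log = NA_real_, df = NA_real_, be_flag = FALSE,
          n = length(unique(d$subject))))
      }
      crossover_be(d, limits = limits)
    }) %>%
    dplyr::ungroup()
}

#' Multi-trial bioequivalence decision
#'
#' A formulation is declared bioequivalent at a site/metric when at least
#' `ceiling(0.8 * n_trials)` of the replicated trials individually conclude
#' BE (>= 8 of 10 at the default design).
#'
#' @param outcomes Logical vector of per-trial BE flags (one per trial), or
#'   a data frame with a `be_flag` column.
#' @param n_trials Expected number of trials; defaults to the length of
#'   `outcomes`.
#' @return A list: `be` (decision), `n_be`, `n_trials`, `incidence`.
#' @export
multi_trial_decision <- function(outcomes, n_trials = NULL) {
  flags <- if (is.data.frame(outcomes)) outcomes$be_flag else outcomes
  stopifnot(is.logical(flags))
  if (is.null(n_trials)) n_trials <- length(flags)
  if (length(flags) != n_trials)
    stop("expected exactly ", n_trials, " trial outcomes, got ", length(flags))
  thr <- ceiling(0.8 * n_trials)
  n_be <- sum(flags)
  list(be = n_be >= thr, n_be = n_be, n_trials = n_trials,
       incidence = n_be / n_trials)
}
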