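#' Classify plasma-versus-local bioequivalence discordance
#'
#' With plasma BE as the "test" and local gut BE as the "truth":
#' (BE, BE) is a true positive, (NBE, NBE) a true negative, (BE, NBE) a
#' false positive (a substandard product passing on plasma), and (NBE, BE) a
#' false negative (a locally adequate product failing on plasma).
#'
#' @param plasma_be,local_be Logical vectors (recycled to common length).
#' @return Character vector: `"true_positive"`, `"true_negative"`,
#'   `"false_positive"` or `"false_negative"`.
#' @export
classify_discordance <- function(plasma_be, local_be) {
  stopifnot(is.logical(plasma_be), is.logical(local_be))
  n <- max(length(plasma_be), length(local_be))
  plasma_be <- rep_len(plasma_be, n)
  local_be <- rep_len(local_be, n)
  ifelse(plasma_be,
         ifelse(local_be, "true_positive", "false_positive"),
         ifelse(local_be, "false_negative", "true_negative"))
}

#' Combine AUC and Cmax bioequivalence flags
#'
#' The combined decision is bioequivalent only when both metrics are.
#'
#' @param auc_be,cmax_be Logical vectors.
#' @return Logical vector.
#' @export
combine_metrics <- function(auc_be, cmax_be) {
  stopifnot(is.logical(auc_be), is.logical(cmax_be))
  auc_be & cmax_be
}

#' Build a formulation-level discordance decision table
#'
#' Converts per-trial BE outcomes ([be_results()]) for one formulation into
#' multi-trial decisions per site/layer/metric, adds the combined
#' (AUC-and-Cmax) metric — combined per trial, then thresholded — and
#' classifies each local cell against the plasma decision of the same
#' metric.
#'
#' @param be_tbl Output of [be_results()] for one test formulation.
#' @param formulation Formulation label.
#' @param f2 Optional f2 of the formulation versus reference.
#' @return A tibble: `formulation, f2, site, layer, metric, plasma_be,
#'   local_be, category, incidence`.
#' @export
discordance_table <- function(be_tbl, formulation = "test", f2 = NA_real_) {
  stopifnot(all(c("trial", "site", "layer", "metric", "be_flag") %in%
                  names(be_tbl)))
  combined <- be_tbl %>%
    dplyr::select(trial, site, layer, metric, be_flag) %>%
    tidyr::pivot_wider(names_from = metric, values_from = be_flag) %>%
    dplyr::mutate(metric = "combined",
                  be_flag = combine_metrics(auc_last, c_max)) %>%
    dplyr::select(trial, site, layer, metric, be_flag)
  per_trial <- dplyr::bind_rows(
    dplyr::select(be_tbl, trial, site, layer, metric, be_flag), combined)
  dec <- per_trial %>%
    dplyr::group_by(site, layer, metric) %>%
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_be = sum(be_flag),
      local_be = n_be >= ceiling(0.8 * n_trials),
      incidence = n_be / n_trials, .groups = "drop")
  plasma <- dec %>%
    dplyr::filter(site == "plasma") %>%
    dplyr::select(metric, plasma_be = local_be)
  dec %>%
    dplyr::left_join(plasma, by = "metric") %>%
    dplyr::mutate(
      formulation = formulation, f2 = f2,
      category = classify_discordance(plasma_be, local_be)) %>%
    dplyr::select(formulation, f2, site, layer, metric,
                  plasma_be, local_be, category, incidence)
}

#' Build the bioequivalence discordance heatmap
#'
#' Rows are formulations (ordered by descending f2, then pH variants),
#' columns plasma plus the eight gut segments; each cell carries the
#' discordance category and the incidence of BE across trials.  The "3D
#' bevel" visual code of local non-BE is rendered as the cell border; all
#' semantics also live in the returned table, so nothing is styling-only.
#'
#' @param results A decision table (rows from [discordance_table()], several
#'   formulations allowed).
#' @param layer `"enterocyte"` or `"lumen"` (plasma rows are kept
#'   automatically).
#' @param metric `"auc_last"`, `"c_max"` or `"combined"`.
#' @return A list with `table` (the tibble drawn) and `plot` (ggplot).
#' @export
build_heatmap <- function(results, layer = "enterocyte", metric = "combined") {
  stopifnot(all(c("formulation", "site", "layer", "metric", "plasma_be",
                  "local_be", "category", "incidence") %in% names(results)))
  met <- metric
  lay <- layer
  tab <- results %>%
    dplyr::filter(metric == met, layer %in% c(lay, "plasma"))
  sites <- c("plasma", abs_seg_names())
  missing_cells <- tab %>%
    dplyr::group_by(formulation) %>%
    dplyr::summarise(miss = paste(setdiff(sites, site), collapse = ","),
                     .groups = "drop") %>%
    dplyr::filter(nzchar(miss))
  if (nrow(missing_cells) > 0)
    stop("missing site decisions for: ",
         paste(sprintf("%s (%s)", missing_cells$formulation,
                       missing_cells$miss), collapse = "; "))
  forms <- results %>%
    dplyr::distinct(formulation, f2) %>%
    dplyr::arrange(is.na(f2), dplyr::desc(f2))
  tab <- tab %>%
    dplyr::mutate(
      site = factor(site, levels = sites),
      formulation = factor(formulation, levels = rev(forms$formulation)))
  pal <- c(true_positive = "#2e7d32", true_negative = "#a5d6a7",
           false_positive = "#c62828", false_negative = "#f48fb1")
  plt <- ggplot2::ggplot(tab, ggplot2::aes(x = site, y = formulation)) +
    ggplot2::geom_tile(ggplot2::aes(fill = category,
                                    colour = ifelse(local_be, "grey30", "black"),
                                    linewidth = ifelse(local_be, 0.3, 1.1))) +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::scale_colour_identity() +
    ggplot2::scale_linewidth_identity() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", 100 * incidence)),
                       size = 3) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("BE discordance heatmap (%s, %s)", lay, met),
                  fill = "category") +
    ggplot2::theme_minimal()
  list(table = tab, plot = plt)
}

#' Write / read a heatmap decision table as CSV
#'
#' The CSV round-trips losslessly with respect to the decision columns.
#'
#' @param results Decision table from [discordance_table()].
#' @param path File path.
#' @return `write_heatmap_csv` returns `path` invisibly; `read_heatmap_csv`
#'   returns the tibble.
#' @export
write_heatmap_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @export
read_heatmap_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out$plasma_be <- as.logical(out$plasma_be)
  out$local_be <- as.logical(out$local_be)
  out
}
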