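#' Read model/strain configuration from a YAML file
#'
#' Keys mirror the [uptick_params()] and [uptick_strain()] field names exactly;
#' a top-level `params` block overrides individual model parameters and a
#' `strain` block either names a `preset` or gives flags/multipliers.
#'
#' @param path YAML file.
#' @return List with elements `params` (`uptick_params`) and `strain`
#'   (`uptick_strain`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pargs <- cfg$params %||% list()
  if (!is.null(pargs$g_shape)) pargs$g_shape <- unlist(pargs$g_shape)
  if (!is.null(pargs$h_shape)) pargs$h_shape <- unlist(pargs$h_shape)
  params <- do.call(uptick_params, pargs)
  sargs <- cfg$strain %||% list(preset = "wt")
  if (!is.null(sargs$site_mult)) sargs$site_mult <- unlist(sargs$site_mult)
  strain <- do.call(uptick_strain, sargs)
  list(params = params, strain = strain)
}

write_manifest <- function(dir, command, config, seeds) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("uptick")),
    seeds = seeds,
    config = config,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, paste0(command, "_manifest.json"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

strip_manifest_timestamp <- function(path) {
  # the timestamp is the only line that differs between identical runs
  lines <- readLines(path)
  lines[!grepl("\"timestamp\"", lines)]
}

#' Simulate a strain and write ensemble outputs
#'
#' Runs an ensemble for one strain and writes the mean transcription-rate
#' curve (CSV), the ensemble-mean species counts on the snapshot grid (CSV)
#' and a JSON manifest echoing the configuration, seeds and package version.
#'
#' @param strain preset name or [uptick_strain()].
#' @param out_dir output directory (created if needed).
#' @param n_runs,t_end,seed,bin_width simulation settings.
#' @param params an [uptick_params()].
#' @return Invisibly, a list with the ensemble, curve and file paths.
#' @export
run_simulate <- function(strain = "wt", out_dir, n_runs = 100, t_end = 6,
                         seed = 1L, bin_width = 0.1,
                         params = default_params()) {
  if (is.character(strain)) strain <- uptick_strain(strain)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- build_network(strain, params)
  ens <- run_ensemble(net, n_runs = n_runs, t_end = t_end, base_seed = seed)
  curve <- mean_rate_curve(ens, bin_width = bin_width)
  f_curve <- file.path(out_dir, sprintf("rate_curve_%s.csv", strain$label))
  write_rate_curve(curve, f_curve)
  f_counts <- file.path(out_dir, sprintf("mean_counts_%s.csv", strain$label))
  utils::write.csv(
    data.frame(time_h = ens$times, ens$mean_counts, check.names = FALSE),
    f_counts, row.names = FALSE)
  mf <- write_manifest(out_dir, paste0("simulate_", strain$label),
                       config = list(strain_label = strain$label,
                                     rok_present = strain$rok_present,
                                     spo0a_present = strain$spo0a_present,
                                     site_mult = as.list(strain$site_mult),
                                     n_promoters = strain$n_promoters,
                                     n_runs = n_runs, t_end = t_end,
                                     bin_width = bin_width),
                       seeds = list(base_seed = seed))
  invisible(list(ensemble = ens, curve = curve,
                 files = c(curve = f_curve, counts = f_counts, manifest = mf)))
}

#' Compare strain amplitudes and write a report
#'
#' Simulates each strain, computes smoothed peak amplitudes, half-times and
#' all pairwise-vs-first amplitude ratios, and writes `compare_report.csv`.
#'
#' @param strains character vector of preset names (first is the reference
#'   denominator) or list of [uptick_strain()] objects.
#' @param out_dir output directory.
#' @param n_runs,t_end,seed,bin_width simulation settings.
#' @param params an [uptick_params()].
#' @return Invisibly, list with `curves`, `report` (data frame) and paths.
#' @export
run_compare <- function(strains, out_dir, n_runs = 1000, t_end = 6, seed = 1L,
                        bin_width = 0.1, params = default_params()) {
  stopifnot(length(strains) >= 2)
  strains <- lapply(strains, function(s)
    if (is.character(s)) uptick_strain(s) else s)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  curves <- list()
  for (i in seq_along(strains)) {
    net <- build_network(strains[[i]], params)
    ens <- run_ensemble(net, n_runs = n_runs, t_end = t_end,
                        base_seed = seed + (i - 1L) * as.integer(n_runs))
    curves[[strains[[i]]$label]] <- mean_rate_curve(ens, bin_width)
  }
  ref <- curves[[1]]
  report <- do.call(rbind, lapply(names(curves), function(lbl) {
    cv <- curves[[lbl]]
    pk <- peak_amplitude(cv)
    data.frame(strain_a = lbl, strain_b = names(curves)[1],
               ratio = amplitude_ratio(cv, ref),
               peak_a = unname(pk["value"]),
               peak_b = unname(peak_amplitude(ref)["value"]),
               peak_time_a = unname(pk["time"]),
               halftime_a = as.numeric(decay_halftime(cv)),
               halftime_b = as.numeric(decay_halftime(ref)),
               stringsAsFactors = FALSE)
  }))
  f_report <- file.path(out_dir, "compare_report.csv")
  utils::write.csv(report, f_report, row.names = FALSE)
  for (lbl in names(curves))
    write_rate_curve(curves[[lbl]],
                     file.path(out_dir, sprintf("rate_curve_%s.csv", lbl)))
  mf <- write_manifest(out_dir, "compare",
                       config = list(strains = vapply(strains, `[[`, "", "label"),
                                     n_runs = n_runs, t_end = t_end,
                                     bin_width = bin_width),
                       seeds = list(base_seed = seed))
  invisible(list(curves = curves, report = report,
                 files = c(report = f_report, manifest = mf)))
}

#' Dual-promoter correlation run
#'
#' Simulates the dual-promoter configuration of a strain and writes the
#' per-timepoint Pearson correlations (`correlations.csv`).
#'
#' @param strain preset name (promoter count is forced to 2).
#' @param out_dir output directory.
#' @param n_runs,t_end,seed settings.
#' @param timepoints times (h); default `t0 + c(-0.5, 0, 0.5, 1)`.
#' @param params an [uptick_params()].
#' @return Invisibly, list with the correlation data frame and paths.
#' @export
run_correlate <- function(strain = "wt", out_dir, n_runs = 2000,
                          t_end = NULL, seed = 1L, timepoints = NULL,
                          params = default_params()) {
  if (is.character(strain)) strain <- uptick_strain(strain, n_promoters = 2)
  strain$n_promoters <- 2L
  if (is.null(timepoints)) timepoints <- params$t0 + c(-0.5, 0, 0.5, 1)
  if (is.null(t_end)) t_end <- max(timepoints) + 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  net <- build_network(strain, params)
  ens <- run_ensemble(net, n_runs = n_runs, t_end = t_end, base_seed = seed)
  cors <- promoter_correlation(ens, timepoints)
  f <- file.path(out_dir, "correlations.csv")
  utils::write.csv(cors, f, row.names = FALSE)
  mf <- write_manifest(out_dir, "correlate",
                       config = list(strain_label = strain$label,
                                     n_runs = n_runs, t_end = t_end,
                                     timepoints = timepoints),
                       seeds = list(base_seed = seed))
  invisible(list(correlations = cors, files = c(correlations = f, manifest = mf)))
}

#' Single-cell cytometry pipeline run
#'
#' Reads (or accepts) a per-cell intensity table, classifies cells against a
#' CFP threshold, writes the binned competent-fraction histogram and, when a
#' YFP boundary is supplied, the boundary proportion test.
#'
#' @param cells path to a cell-table CSV, or a `cell_table`.
#' @param out_dir output directory.
#' @param threshold CFP competence threshold (a.u.).
#' @param boundary optional YFP boundary for the proportion test; when `NULL`
#'   the test is skipped with a notice and the other outputs are still
#'   produced.
#' @param yfp_bin_edges bin edges for the histogram; default 12 equal bins
#'   over the YFP range.
#' @return Invisibly, list with `classification`, `histogram`, `test` (NULL if
#'   skipped) and file paths.
#' @export
run_cytometry <- function(cells, out_dir, threshold = 36, boundary = NULL,
                          yfp_bin_edges = NULL) {
  if (is.character(cells)) cells <- read_cell_table(cells)
  cells <- as_cell_table(cells)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cls <- classify_competent(cells, threshold)
  if (is.null(yfp_bin_edges))
    yfp_bin_edges <- seq(min(cells$yfp), max(cells$yfp), length.out = 13)
  hist_df <- binned_competence_fraction(cells, cls$labels, yfp_bin_edges)
  f_cls <- file.path(out_dir, "classification.csv")
  utils::write.csv(data.frame(cell_id = cells$cell_id, cfp = cells$cfp,
                              yfp = cells$yfp, competent = cls$labels),
                   f_cls, row.names = FALSE)
  f_hist <- file.path(out_dir, "competence_histogram.csv")
  utils::write.csv(hist_df, f_hist, row.names = FALSE)
  test <- NULL
  f_test <- NA_character_
  if (is.null(boundary)) {
    message("no YFP boundary supplied; boundary proportion test skipped")
  } else {
    tab <- competence_contingency(cells, cls$labels, boundary)
    test <- boundary_proportion_test(tab)
    f_test <- file.path(out_dir, "boundary_test.csv")
    utils::write.csv(
      data.frame(boundary = boundary, threshold = threshold,
                 n_comp_above = tab$n_comp_above,
                 n_total_above = tab$n_total_above,
                 n_comp_below = tab$n_comp_below,
                 n_total_below = tab$n_total_below,
                 p_above_pct = test$p_above, p_below_pct = test$p_below,
                 z = test$z, p_value = test$p_value,
                 p_fisher = test$p_fisher),
      f_test, row.names = FALSE)
  }
  mf <- write_manifest(out_dir, "cytometry",
                       config = list(threshold = threshold,
                                     boundary = boundary,
                                     n_cells = nrow(cells),
                                     yfp_bin_edges = yfp_bin_edges),
                       seeds = list())
  invisible(list(classification = cls, histogram = hist_df, test = test,
                 files = c(classification = f_cls, histogram = f_hist,
                           test = f_test, manifest = mf)))
}

#' Generate and write a synthetic cell table
#'
#' @param out_dir output directory.
#' @param params a [synth_cell_params()].
#' @param seed integer seed.
#' @param null_model generate with competence independent of YFP.
#' @return Invisibly, the [generate_cells()] result plus file paths.
#' @export
run_synth <- function(out_dir, params = synth_cell_params(), seed = 1L,
                      null_model = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- if (null_model) generate_null_cells(params, seed)
  else generate_cells(params, seed)
  paths <- write_synth_cells(gen, file.path(out_dir, "synth_cells"))
  mf <- write_manifest(out_dir, "synth",
                       config = list(null_model = null_model,
                                     n_cells = params$n_cells),
                       seeds = list(seed = seed))
  invisible(c(gen, list(files = c(paths, manifest = mf))))
}
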