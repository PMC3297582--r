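#' Parameters of the synthetic per-cell intensity generator
#'
#' Defines the statistical structure of simulated two-channel (CFP/YFP)
#' single-cell intensity tables: uniform autofluorescence background, a
#' log-normal extrinsic YFP signal reporting OA~P, a window-shaped dependence
#' of competence probability on YFP (competence occurs within an intermediate
#' OA~P range), and a truncated log-normal CFP distribution for competent
#' (ON) cells that lies strictly above the planted threshold while OFF cells
#' stay strictly below it.
#'
#' @param n_cells number of cells.
#' @param autofluor_range background intensity range (a.u.), both channels.
#' @param competent_fraction_target expected ON fraction (0 < f < 1).
#' @param cfp_threshold_planted CFP value separating ON from OFF cells (a.u.).
#' @param yfp_meanlog,yfp_sdlog log-normal parameters of the YFP signal above
#'   background.
#' @param window `c(low_edge, high_edge, peak_prob)`: competence probability
#'   is a raised-cosine bump on `[low_edge, high_edge]` of height `peak_prob`
#'   (before rescaling to hit the target fraction), zero outside.
#' @param comp_cfp_meanlog,comp_cfp_sdlog log-normal parameters of ON-cell
#'   CFP (truncated above the planted threshold).
#' @param basal_cfp_mean mean of the exponential sub-threshold basal CFP
#'   noise added to OFF-cell background.
#' @return A validated list of class `synth_cell_params`.
#' @export
synth_cell_params <- function(n_cells = 10000,
                              autofluor_range = c(12, 16),
                              competent_fraction_target = 0.133,
                              cfp_threshold_planted = 36,
                              yfp_meanlog = log(40), yfp_sdlog = 0.55,
                              window = c(low_edge = 25, high_edge = 120,
                                         peak_prob = 0.35),
                              comp_cfp_meanlog = log(70), comp_cfp_sdlog = 0.5,
                              basal_cfp_mean = 4) {
  p <- list(n_cells = as.integer(n_cells), autofluor_range = autofluor_range,
            competent_fraction_target = competent_fraction_target,
            cfp_threshold_planted = cfp_threshold_planted,
            yfp_meanlog = yfp_meanlog, yfp_sdlog = yfp_sdlog,
            window = window, comp_cfp_meanlog = comp_cfp_meanlog,
            comp_cfp_sdlog = comp_cfp_sdlog, basal_cfp_mean = basal_cfp_mean)
  if (p$n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  f <- p$competent_fraction_target
  if (!(f > 0 && f < 1))
    stop("competent_fraction_target must lie strictly between 0 and 1",
         call. = FALSE)
  if (length(p$window) != 3 || p$window[[1]] >= p$window[[2]])
    stop("window must be c(low_edge, high_edge, peak_prob) with low < high",
         call. = FALSE)
  if (p$window[[3]] < 0 || p$window[[3]] > 1)
    stop("window peak probability must lie in [0, 1]", call. = FALSE)
  if (diff(p$autofluor_range) < 0 || any(p$autofluor_range < 0))
    stop("autofluor_range must be a nonnegative increasing range", call. = FALSE)
  class(p) <- "synth_cell_params"
  p
}

window_prob <- function(yfp, window) {
  lo <- window[[1]]; hi <- window[[2]]; pk <- window[[3]]
  inside <- yfp >= lo & yfp <= hi
  p <- numeric(length(yfp))
  p[inside] <- pk * sin(pi * (yfp[inside] - lo) / (hi - lo))^2
  p
}

# exponential variate truncated so that bg + value stays below cap
rtrunc_exp <- function(n, mean, cap) {
  u <- stats::runif(n)
  -mean * log(1 - u * (1 - exp(-cap / mean)))
}

#' Generate a synthetic per-cell intensity table
#'
#' Per cell: YFP = background + log-normal extrinsic signal; the competence
#' (ON) state is drawn with probability proportional to the window function of
#' YFP, rescaled so the expected ON fraction matches the target; ON cells draw
#' CFP from a log-normal truncated above the planted threshold, OFF cells
#' from background plus sub-threshold basal noise. Identical `params` and
#' `seed` give identical tables.
#'
#' @param params a [synth_cell_params()] object.
#' @param seed integer seed.
#' @return List with `cells` (a `cell_table`), `truth` (logical ON labels) and
#'   `params`.
#' @export
generate_cells <- function(params = synth_cell_params(), seed = 1L) {
  stopifnot(inherits(params, "synth_cell_params"))
  set.seed(as.integer(seed))
  n <- params$n_cells
  bg_y <- stats::runif(n, params$autofluor_range[1], params$autofluor_range[2])
  yfp <- bg_y + stats::rlnorm(n, params$yfp_meanlog, params$yfp_sdlog)
  w <- window_prob(yfp, params$window)
  mw <- mean(w)
  if (mw <= 0) {
    # degenerate window: no cell can turn on
    warning("window assigns zero competence probability everywhere; ",
            "generating zero ON cells", call. = FALSE)
    p_on <- numeric(n)
  } else {
    p_on <- w * (params$competent_fraction_target / mw)
  }
  if (any(p_on > 1)) {
    achievable <- mw / max(w)  # probabilities cap at 1
    stop(sprintf(paste0("generation error: target fraction %.3f is not ",
                        "achievable with this window (max achievable ~ %.3f)"),
                 params$competent_fraction_target, achievable), call. = FALSE)
  }
  on <- stats::runif(n) < p_on
  cfp <- numeric(n)
  n_on <- sum(on)
  if (n_on) {
    # inverse-CDF truncated log-normal, strictly above the planted threshold
    thr <- params$cfp_threshold_planted
    p_lo <- stats::plnorm(thr, params$comp_cfp_meanlog, params$comp_cfp_sdlog)
    u <- stats::runif(n_on, p_lo, 1)
    cfp[on] <- stats::qlnorm(u, params$comp_cfp_meanlog, params$comp_cfp_sdlog)
  }
  n_off <- n - n_on
  if (n_off) {
    bg_c <- stats::runif(n_off, params$autofluor_range[1],
                         params$autofluor_range[2])
    cap <- params$cfp_threshold_planted - params$autofluor_range[2] - 0.5
    cfp[!on] <- bg_c + rtrunc_exp(n_off, params$basal_cfp_mean, cap)
  }
  cells <- as_cell_table(data.frame(cell_id = seq_len(n), cfp = cfp,
                                    yfp = yfp, stringsAsFactors = FALSE))
  list(cells = cells, truth = on, params = params, seed = as.integer(seed))
}

#' Generate a null table (competence independent of YFP)
#'
#' Identical marginal distributions, but the competence probability is
#' constant in YFP, for calibrating the type-I error of
#' [boundary_proportion_test()].
#'
#' @inheritParams generate_cells
#' @return As [generate_cells()].
#' @export
generate_null_cells <- function(params = synth_cell_params(), seed = 1L) {
  stopifnot(inherits(params, "synth_cell_params"))
  set.seed(as.integer(seed))
  n <- params$n_cells
  bg_y <- stats::runif(n, params$autofluor_range[1], params$autofluor_range[2])
  yfp <- bg_y + stats::rlnorm(n, params$yfp_meanlog, params$yfp_sdlog)
  on <- stats::runif(n) < params$competent_fraction_target
  cfp <- numeric(n)
  n_on <- sum(on)
  if (n_on) {
    thr <- params$cfp_threshold_planted
    p_lo <- stats::plnorm(thr, params$comp_cfp_meanlog, params$comp_cfp_sdlog)
    u <- stats::runif(n_on, p_lo, 1)
    cfp[on] <- stats::qlnorm(u, params$comp_cfp_meanlog, params$comp_cfp_sdlog)
  }
  n_off <- n - n_on
  if (n_off) {
    bg_c <- stats::runif(n_off, params$autofluor_range[1],
                         params$autofluor_range[2])
    cap <- params$cfp_threshold_planted - params$autofluor_range[2] - 0.5
    cfp[!on] <- bg_c + rtrunc_exp(n_off, params$basal_cfp_mean, cap)
  }
  cells <- as_cell_table(data.frame(cell_id = seq_len(n), cfp = cfp,
                                    yfp = yfp, stringsAsFactors = FALSE))
  list(cells = cells, truth = on, params = params, seed = as.integer(seed))
}

#' Write a synthetic cell table with ground truth and metadata
#'
#' Emits `<stem>.csv` (cell_id, cfp, yfp), `<stem>_truth.csv` (cell_id,
#' true_label) and `<stem>_meta.json` (all generator parameters and the seed).
#'
#' @param gen result of [generate_cells()] / [generate_null_cells()].
#' @param stem output path stem.
#' @return Invisibly, the three file paths.
#' @export
write_synth_cells <- function(gen, stem) {
  paths <- paste0(stem, c(".csv", "_truth.csv", "_meta.json"))
  utils::write.csv(gen$cells, paths[1], row.names = FALSE)
  utils::write.csv(data.frame(cell_id = gen$cells$cell_id,
                              true_label = gen$truth), paths[2],
                   row.names = FALSE)
  meta <- gen$params
  class(meta) <- NULL
  meta$seed <- gen$seed
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), paths[3])
  invisible(paths)
}
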