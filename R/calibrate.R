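#' Default calibration targets
#'
#' The amplitude constraints the default parameter set is calibrated against:
#' the ~9-fold drop of the uptick on deleting spo0A, the ~5-fold rise on
#' deleting rok, recovery of the rok spo0A double mutant to ~60 percent of the
#' rok single mutant, the ~30 percent drop on deleting spo0A in the A123
#' triple site mutant, and a peak of about one transcript per cell in the wild
#' type. Ratio constraints must hold within a factor `tol`; ordering
#' constraints (relative strain amplitudes and the faster wild-type decay)
#' must hold strictly.
#'
#' @param tol acceptance factor for ratio constraints (default 1.5).
#' @return A list with elements `ratios` (data frame: `a`, `b`, `target`),
#'   `orderings` (data frame: `hi`, `lo`), `tol`, `peak_mrna`.
#' @export
calibration_targets <- function(tol = 1.5) {
  list(
    ratios = data.frame(
      a = c("wt", "d_rok", "d_rok_d_spo0A", "A123_d_spo0A"),
      b = c("d_spo0A", "wt", "d_rok", "A123"),
      target = c(9, 5, 0.6, 0.7),
      stringsAsFactors = FALSE),
    orderings = data.frame(
      hi = c("d_rok", "A2", "wt", "A123"),
      lo = c("A2", "wt", "A123", "d_spo0A"),
      stringsAsFactors = FALSE),
    tol = tol,
    peak_mrna = 1)
}

#' Default calibration search grid
#'
#' A compact grid of candidate values for the free coefficients (those not
#' pinned by gel-shift measurements), spanning the region where the
#' mean-field amplitude constraints are satisfiable.
#'
#' @return A data frame of candidate parameter combinations.
#' @export
calibration_grid <- function() {
  expand.grid(alpha = c(2.4, 2.8, 3.2),
              rho_rok = c(0.05, 0.066, 0.085),
              rho_R = c(0.2, 0.25, 0.31),
              rok_copies = c(100, 120, 145),
              oap_rate0 = c(1300, 1550, 1850),
              oap_decay = 0.12,
              mutant_residual = 0.135)
}

calibration_strains <- function(mutant_residual) {
  list(
    wt = uptick_strain("wt", mutant_residual = mutant_residual),
    d_spo0A = uptick_strain("d_spo0A", mutant_residual = mutant_residual),
    d_rok = uptick_strain("d_rok", mutant_residual = mutant_residual),
    d_rok_d_spo0A = uptick_strain("d_rok_d_spo0A",
                                  mutant_residual = mutant_residual),
    A123 = uptick_strain("A123", mutant_residual = mutant_residual),
    A123_d_spo0A = uptick_strain("A123", spo0a_present = FALSE,
                                 label = "A123_d_spo0A",
                                 mutant_residual = mutant_residual),
    A2 = uptick_strain("A2", mutant_residual = mutant_residual))
}

score_candidate <- function(params, targets, times = seq(0, 6, by = 0.01)) {
  strains <- calibration_strains(attr(params, "mutant_residual") %||% 0.135)
  curves <- lapply(strains, function(s) mean_rate_meanfield(s, params, times))
  pk <- vapply(curves, function(cv) max(cv$rate_per_h), 0)
  pt <- vapply(curves, function(cv) cv$time_h[which.max(cv$rate_per_h)], 0)
  halftime <- function(cv) {
    i <- which.max(cv$rate_per_h)
    j <- which(cv$rate_per_h[i:nrow(cv)] <= cv$rate_per_h[i] / 2)
    if (!length(j)) Inf else cv$time_h[i + j[1] - 1] - cv$time_h[i]
  }
  ht <- vapply(curves, halftime, 0)
  log_tol <- log(targets$tol)
  r <- targets$ratios
  ratio_vals <- pk[r$a] / pk[r$b]
  ratio_margin <- log_tol - abs(log(ratio_vals / r$target))
  o <- targets$orderings
  order_margin <- log(pk[o$hi] / pk[o$lo] / 1.05)
  shape_margin <- c(
    sharp_decay = log(ht[["d_rok"]] / ht[["wt"]] / 1.05),
    peak_time = 0.25 - abs(pt[["wt"]] - params$t0))
  margins <- c(stats::setNames(ratio_margin,
                               paste(r$a, r$b, sep = "/")),
               stats::setNames(order_margin,
                               paste(o$hi, o$lo, sep = ">")),
               shape_margin)
  list(margins = margins, score = min(margins), ratios = ratio_vals, peaks = pk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Calibrate the free model coefficients against the printed amplitude ratios
#'
#' The measured dissociation constants pin the equilibrium side of the model;
#' the remaining coefficients (transcription boost `alpha`, repression factors,
#' Rok pool size, OA~P production schedule, residual affinity of mutated
#' boxes) are fixed by requiring that the simulated strain ensemble reproduce
#' the relative uptick amplitudes within a factor of `targets$tol`. Scoring
#' uses the deterministic mean-field rate (fast and noise-free); the winning
#' candidate maximizes the worst constraint margin, and `k_tx_base` is then
#' set so the wild-type peak mean mRNA equals `targets$peak_mrna` per cell.
#' Optionally the winner is confirmed by a stochastic ensemble.
#'
#' The search is fully deterministic given `grid`; `seed` only drives the
#' optional stochastic confirmation, so identical `grid` and `seed` always
#' return identical parameters.
#'
#' @param targets a [calibration_targets()] list.
#' @param grid data frame of candidate free-coefficient combinations.
#' @param seed integer seed for the SSA confirmation ensembles.
#' @param confirm_ssa logical: confirm the winning candidate with stochastic
#'   ensembles of `n_confirm` runs per strain and warn if any ratio falls
#'   outside the tolerance band.
#' @param n_confirm runs per strain for the confirmation.
#' @param base_params template [uptick_params()] supplying everything the grid
#'   does not vary.
#' @return The calibrated `uptick_params`, with attributes
#'   `calibration_margins` (per-constraint margins of the winner) and
#'   `mutant_residual`.
#' @export
calibrate_defaults <- function(targets = calibration_targets(),
                               grid = calibration_grid(), seed = 1L,
                               confirm_ssa = FALSE, n_confirm = 200,
                               base_params = default_params()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  make_params <- function(row) {
    p <- uptick_params(
      k_tx_base = base_params$k_tx_base,
      k_deg_mrna = base_params$k_deg_mrna,
      k_on = base_params$k_on,
      alpha = row$alpha, rho_rok = row$rho_rok, rho_R = row$rho_R,
      rok_copies = row$rok_copies, oap_rate0 = row$oap_rate0,
      oap_decay = row$oap_decay, t0 = base_params$t0,
      g_shape = base_params$g_shape, h_shape = base_params$h_shape,
      cell_volume_fl = base_params$cell_volume_fl,
      activation_mode = base_params$activation_mode)
    attr(p, "mutant_residual") <- row$mutant_residual
    p
  }
  best <- NULL
  best_score <- -Inf
  best_margins <- NULL
  for (i in seq_len(nrow(grid))) {
    cand <- make_params(grid[i, ])
    sc <- score_candidate(cand, targets)
    if (sc$score > best_score) {
      best_score <- sc$score
      best <- cand
      best_margins <- sc$margins
    }
  }
  if (best_score <= 0) {
    stop("calibration failure: no grid point satisfies all amplitude ",
         "constraints within a factor of ", targets$tol,
         "; best candidate margins (log scale, negative = violated): ",
         paste(sprintf("%s = %.3f", names(best_margins), best_margins),
               collapse = ", "), call. = FALSE)
  }
  # transcript-scale calibration: one transcript per cell at the wt peak
  unit <- best
  unit$k_tx_base <- 1
  best$k_tx_base <- targets$peak_mrna / meanfield_peak_mrna(unit)
  if (confirm_ssa) {
    res <- attr(best, "mutant_residual")
    strains <- calibration_strains(res)
    curves <- lapply(seq_along(strains), function(k) {
      net <- build_network(strains[[k]], best)
      mean_rate_curve(run_ensemble(net, n_runs = n_confirm,
                                   base_seed = as.integer(seed) + 1000L * k))
    })
    names(curves) <- names(strains)
    r <- targets$ratios
    for (j in seq_len(nrow(r))) {
      val <- amplitude_ratio(curves[[r$a[j]]], curves[[r$b[j]]])
      if (abs(log(val / r$target[j])) > log(targets$tol))
        warning(sprintf(
          "stochastic confirmation: ratio %s/%s = %.2f outside %g-fold band of %g",
          r$a[j], r$b[j], val, targets$tol, r$target[j]), call. = FALSE)
    }
  }
  attr(best, "calibration_margins") <- best_margins
  best
}
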