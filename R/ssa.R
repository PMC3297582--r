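#' Simulate one exact sample path of a reaction network
#'
#' Gillespie's stochastic simulation algorithm with time-dependent drives.
#' The exponential waiting time of each step is capped at `dt_max`; when the
#' cap is hit, no reaction fires and propensities are refreshed at the new
#' time. Because the drives g(t) and h(t) vary on ~1 h scales, a cap of
#' 0.01 h makes the time-discretization bias negligible (see the convergence
#' test in the package suite). Identical `(network, t_end, seed)` give a
#' bit-identical trajectory.
#'
#' @param network an [build_network()] object.
#' @param t_end simulation horizon (h), > 0.
#' @param seed integer random seed for this run.
#' @param dt_max propensity refresh interval (h).
#' @param grid_dt snapshot grid spacing (h).
#' @param record_events keep the full event list (times and reaction indices)
#'   in addition to grid snapshots and transcription event times.
#' @return An object of class `uptick_trajectory` with elements `times`
#'   (snapshot grid), `counts` (matrix of species counts on the grid),
#'   `tx_times` (list per promoter copy of transcription firing times),
#'   `n_events`, `seed`, and optionally `event_times` / `event_ids`.
#' @examples
#' net <- build_network(uptick_strain("d_spo0A"), default_params())
#' tr <- ssa_simulate(net, t_end = 3, seed = 1)
#' tr
#' @export
ssa_simulate <- function(network, t_end = 6, seed = 1L, dt_max = 0.01,
                         grid_dt = 0.05, record_events = TRUE) {
  stopifnot(inherits(network, "uptick_network"))
  if (!is.numeric(t_end) || t_end <= 0)
    stop("t_end must be positive", call. = FALSE)
  if (dt_max <= 0 || grid_dt <= 0)
    stop("dt_max and grid_dt must be positive", call. = FALSE)
  p <- network$params
  drive <- list(
    t0 = p$t0,
    g = as.numeric(p$g_shape[c("floor0", "rise_width", "floor_late",
                               "tau_fast", "tau_slow", "shoulder")]),
    h = as.numeric(p$h_shape[c("floor0", "rise_width")]),
    alpha = p$alpha, rho_rok = p$rho_rok, rho_R = p$rho_R,
    all_or_none = identical(p$activation_mode, "all_or_none"),
    n_a_sites = 3L)
  rr <- network$reactions
  set.seed(as.integer(seed))
  raw <- .ssa_run_cpp(unname(network$species), network$stoich, rr$type,
                      rr$const, ifelse(is.na(rr$s1), -1L, rr$s1 - 1L),
                      ifelse(is.na(rr$s2), -1L, rr$s2 - 1L),
                      lapply(network$tx_meta, function(m) {
                        if (is.null(m)) list() else
                          list(iA = m$iA - 1L, iRok = m$iRok - 1L, iR = m$iR - 1L)
                      }),
                      drive, t_end, dt_max, grid_dt, record_events)
  counts <- raw$snapshots
  colnames(counts) <- names(network$species)
  tx_rx <- which(rr$type == 3L)
  out <- list(times = raw$grid_times, counts = counts,
              tx_times = stats::setNames(raw$tx_times[tx_rx],
                                         sprintf("p%d", seq_along(tx_rx))),
              n_events = raw$n_events, seed = as.integer(seed),
              strain_label = network$strain$label, t_end = t_end)
  if (record_events) {
    out$event_times <- raw$event_times
    out$event_ids <- raw$event_ids
  }
  class(out) <- "uptick_trajectory"
  out
}

#' @export
print.uptick_trajectory <- function(x, ...) {
  cat(sprintf("uptick trajectory ('%s', seed %d): %g events over %g h, %d transcription event(s)\n",
              x$strain_label, x$seed, x$n_events, x$t_end,
              sum(lengths(x$tx_times))))
  invisible(x)
}

#' @export
as.data.frame.uptick_trajectory <- function(x, ...) {
  data.frame(time_h = x$times, x$counts, strain = x$strain_label,
             seed = x$seed, check.names = FALSE)
}

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` independent trajectories with seeds `base_seed + 0:(n_runs-1)`
#' and keeps a streamed reduction: the running mean of all species counts on
#' the snapshot grid, per-run mRNA snapshot counts (needed for dual-promoter
#' correlations), and all transcription event times per promoter copy.
#'
#' @param network an [build_network()] object.
#' @param n_runs number of independent runs (>= 1).
#' @param t_end horizon (h).
#' @param base_seed seed of the first run.
#' @param dt_max,grid_dt passed to [ssa_simulate()].
#' @return An object of class `uptick_ensemble` with elements `times`,
#'   `mean_counts` (grid x species), `mrna_runs` (list per promoter copy of an
#'   `n_runs` x grid integer matrix), `tx_times` (list per promoter copy of
#'   pooled transcription times), `n_runs`, `base_seed`, `strain_label`.
#' @export
run_ensemble <- function(network, n_runs = 1000, t_end = 6, base_seed = 1L,
                         dt_max = 0.01, grid_dt = 0.05) {
  stopifnot(inherits(network, "uptick_network"))
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  n_prom <- network$strain$n_promoters
  first <- ssa_simulate(network, t_end, base_seed, dt_max, grid_dt,
                        record_events = FALSE)
  n_grid <- length(first$times)
  mean_counts <- matrix(0, n_grid, ncol(first$counts),
                        dimnames = list(NULL, colnames(first$counts)))
  mrna_runs <- lapply(seq_len(n_prom),
                      function(i) matrix(0L, n_runs, n_grid))
  tx_times <- vector("list", n_prom)
  for (i in seq_len(n_prom)) tx_times[[i]] <- vector("list", n_runs)

  accumulate <- function(tr, run) {
    mean_counts <<- mean_counts + tr$counts
    for (i in seq_len(n_prom)) {
      mrna_runs[[i]][run, ] <<- tr$counts[, network$mrna_idx[i]]
      tx_times[[i]][[run]] <<- tr$tx_times[[i]]
    }
  }
  accumulate(first, 1L)
  for (run in seq_len(n_runs)[-1]) {
    tr <- tryCatch(
      ssa_simulate(network, t_end, base_seed + run - 1L, dt_max, grid_dt,
                   record_events = FALSE),
      error = function(e) stop("run ", run, " (seed ", base_seed + run - 1L,
                               "): ", conditionMessage(e), call. = FALSE))
    accumulate(tr, run)
  }
  structure(list(times = first$times, mean_counts = mean_counts / n_runs,
                 mrna_runs = mrna_runs,
                 tx_times = lapply(tx_times, function(l) unlist(l, use.names = FALSE)),
                 tx_times_runs = tx_times,
                 n_runs = as.integer(n_runs), base_seed = as.integer(base_seed),
                 strain_label = network$strain$label, t_end = t_end,
                 mrna_species = colnames(first$counts)[network$mrna_idx]),
            class = "uptick_ensemble")
}

#' @export
print.uptick_ensemble <- function(x, ...) {
  cat(sprintf("uptick ensemble ('%s'): %d runs to %g h (base seed %d), mean total transcripts/run %.2f\n",
              x$strain_label, x$n_runs, x$t_end, x$base_seed,
              sum(lengths(x$tx_times)) / x$n_runs))
  invisible(x)
}

#' Restrict an ensemble to a subset of its runs
#'
#' Rebuilds the streamed reductions from a subset of runs, e.g. to check that
#' amplitude ratios are robust to ensemble size. The subset retains only the
#' mRNA species in `mean_counts` (the other species means are not kept
#' per run).
#'
#' @param ensemble an [run_ensemble()] result.
#' @param runs integer vector of run indices.
#' @return An `uptick_ensemble` over the selected runs.
#' @export
subset_runs <- function(ensemble, runs) {
  stopifnot(inherits(ensemble, "uptick_ensemble"))
  runs <- as.integer(runs)
  if (any(runs < 1 | runs > ensemble$n_runs))
    stop("run indices out of range", call. = FALSE)
  n_prom <- length(ensemble$mrna_runs)
  mrna_runs <- lapply(ensemble$mrna_runs, function(m) m[runs, , drop = FALSE])
  mean_counts <- vapply(seq_len(n_prom),
                        function(i) colMeans(mrna_runs[[i]]),
                        numeric(length(ensemble$times)))
  colnames(mean_counts) <- ensemble$mrna_species
  structure(list(times = ensemble$times, mean_counts = mean_counts,
                 mrna_runs = mrna_runs,
                 tx_times = lapply(ensemble$tx_times_runs, function(l)
                   unlist(l[runs], use.names = FALSE)),
                 tx_times_runs = lapply(ensemble$tx_times_runs, `[`, runs),
                 n_runs = length(runs), base_seed = ensemble$base_seed,
                 strain_label = ensemble$strain_label, t_end = ensemble$t_end,
                 mrna_species = ensemble$mrna_species),
            class = "uptick_ensemble")
}

#' Simulate method for uptick networks
#'
#' `simulate(net, nsim, seed)` wraps [ssa_simulate()] (`nsim = 1`) or
#' [run_ensemble()] (`nsim > 1`).
#'
#' @param object an `uptick_network`.
#' @param nsim number of trajectories.
#' @param seed integer seed (first run's seed for ensembles).
#' @param t_end horizon (h).
#' @param ... passed to [ssa_simulate()] / [run_ensemble()].
#' @return An `uptick_trajectory` (`nsim = 1`) or `uptick_ensemble`.
#' @export
simulate.uptick_network <- function(object, nsim = 1, seed = 1L, t_end = 6,
                                    ...) {
  if (nsim == 1) ssa_simulate(object, t_end = t_end, seed = seed, ...)
  else run_ensemble(object, n_runs = nsim, t_end = t_end, base_seed = seed, ...)
}
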