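#' Deterministic OA~P accumulation
#'
#' Integrates `dX/dt = oap_rate0 * h(t) - oap_decay * X` (forward Euler on the
#' supplied grid), the mean-field trajectory of the OA~P pool in molecules.
#'
#' @param times increasing time grid (h) starting at 0.
#' @param params an [uptick_params()] object.
#' @return Numeric vector of expected OA~P molecule counts.
#' @export
oap_mean_trajectory <- function(times, params = default_params()) {
  stopifnot(inherits(params, "uptick_params"))
  h <- spo0a_drive(times, params) / params$oap_rate0
  x <- numeric(length(times))
  for (i in seq_along(times)[-1]) {
    dt <- times[i] - times[i - 1]
    x[i] <- x[i - 1] + dt * (params$oap_rate0 * h[i - 1] -
                               params$oap_decay * x[i - 1])
  }
  x
}

# quasi-equilibrium site occupancies given OA~P count X and the Rok pool;
# returns the factorized expected transcription-rate multiplier
meanfield_factor <- function(X, params, strain) {
  m <- strain$site_mult
  vol <- params$cell_volume_fl
  kd <- function(nm) nm_to_molecules(nm, vol)
  if (!strain$spo0a_present) X <- 0 * X
  R <- if (strain$rok_present) params$rok_copies else 0

  occ1 <- function(load) load / (1 + load)
  pA1 <- occ1(X * m[["A1"]] / kd(params$kd_A1))
  pA3 <- occ1(X * m[["A3"]] / kd(params$kd_A3))
  pR1 <- occ1(X * m[["R1"]] / kd(params$kd_R1))
  pR2 <- occ1(X * m[["R2"]] / kd(params$kd_R2))
  a2o <- X * m[["A2"]] / kd(params$kd_A2)
  a2r <- R * m[["RokA2"]] / kd(params$kd_rok_A2)
  pA2o <- a2o / (1 + a2o + a2r)
  pA2r <- a2r / (1 + a2o + a2r)
  pAux <- occ1(R * m[["RokAux"]] / kd(params$kd_rok_aux))

  al <- params$alpha
  if (identical(params$activation_mode, "all_or_none")) {
    pAll <- pA1 * pA3 * pA2o
    act <- 1 - pAll + pAll * al^3
  } else {
    act <- (1 - pA1 + pA1 * al) * (1 - pA3 + pA3 * al) *
      (1 - pA2o - pA2r + pA2o * al + pA2r * params$rho_rok)
  }
  rep_rok <- (1 - pAux + pAux * params$rho_rok)
  if (identical(params$activation_mode, "all_or_none"))
    rep_rok <- rep_rok * (1 - pA2r + pA2r * params$rho_rok)
  rep_r <- (1 - pR1 + pR1 * params$rho_R) * (1 - pR2 + pR2 * params$rho_R)
  act * rep_rok * rep_r
}

#' Mean-field transcription-rate curve
#'
#' Fast deterministic approximation of the ensemble-mean transcription rate:
#' promoter sites are taken in quasi-equilibrium with the deterministic OA~P
#' trajectory and the fixed Rok pool, and the expected propensity is computed
#' exactly under independent site occupancies (the expectation of the product
#' of per-site factors). Used by [calibrate_defaults()] and as an independent
#' oracle for the stochastic engine.
#'
#' @param strain an [uptick_strain()] object or preset name.
#' @param params an [uptick_params()] object.
#' @param times time grid (h).
#' @return Data frame `time_h`, `rate_per_h`, `oap` with the strain label as
#'   attribute.
#' @export
mean_rate_meanfield <- function(strain = "wt", params = default_params(),
                                times = seq(0, 6, by = 0.01)) {
  if (is.character(strain)) strain <- uptick_strain(strain)
  X <- oap_mean_trajectory(times, params)
  rate <- params$k_tx_base * global_activity(times, params) *
    meanfield_factor(X, params, strain)
  out <- data.frame(time_h = times, rate_per_h = rate, oap = X)
  attr(out, "strain_label") <- strain$label
  out
}

#' Mean-field peak amplitudes for a set of strains
#'
#' @param strains character vector of preset names (or list of
#'   [uptick_strain()] objects).
#' @param params an [uptick_params()] object.
#' @param times time grid (h).
#' @return Named numeric vector of peak mean-field rates (events/h).
#' @export
meanfield_peaks <- function(strains, params = default_params(),
                            times = seq(0, 6, by = 0.01)) {
  vapply(strains, function(s) {
    max(mean_rate_meanfield(s, params, times)$rate_per_h)
  }, 0)
}

# mean-field peak mRNA per cell for the wild type (one promoter copy):
# integrate dM/dt = rate(t) - k_deg * M
meanfield_peak_mrna <- function(params, times = seq(0, 6, by = 0.01)) {
  rate <- mean_rate_meanfield("wt", params, times)$rate_per_h
  m <- numeric(length(times))
  for (i in seq_along(times)[-1]) {
    dt <- times[i] - times[i - 1]
    m[i] <- m[i - 1] + dt * (rate[i - 1] - params$k_deg_mrna * m[i - 1])
  }
  max(m)
}
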