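#' Model parameters for the comK uptick network
#'
#' Constructs and validates the full parameter set of the promoter-occupancy
#' model: equilibrium dissociation constants of Spo0A~P (OA~P) at the
#' activation sites A1-A3 and operator sites R1-R2, Rok dissociation constants
#' at the A2-overlapping site and the auxiliary site, the universal binding
#' on-rate, the transcriptional boost and repression factors, the OA~P
#' production schedule and the shape of the global core-promoter activity
#' profile.
#'
#' Concentrations are in nM and converted to molecule counts with
#' `cell_volume_fl` (default 1.66 fL, at which 1 nM corresponds to one
#' molecule per cell). Time is in hours since inoculation; `t0` is the time of
#' departure from exponential growth, where the global activity peaks.
#'
#' @param k_tx_base transcription propensity scale (events/h per promoter at
#'   peak global activity, unrepressed, no activation).
#' @param k_deg_mrna first-order mRNA decay rate (1/h).
#' @param kd_A1,kd_A2,kd_A3 OA~P dissociation constants at activation sites (nM).
#' @param kd_R1,kd_R2 OA~P dissociation constants at repression sites (nM).
#' @param kd_rok_A2 Rok dissociation constant at the A2-overlapping site (nM).
#' @param kd_rok_aux Rok dissociation constant at the auxiliary site (nM).
#' @param k_on universal binding on-rate (1/(molecule h)); fast, so occupancy
#'   stays near equilibrium with the measured K_Ds.
#' @param alpha per-A-site transcription boost when OA~P is bound (>= 1).
#' @param rho_rok repression factor per Rok-occupied site (0 < rho < 1).
#' @param rho_R repression factor per OA~P-occupied R site (0 < rho < 1).
#' @param rok_copies constant Rok molecule count (the Rok pool does not vary).
#' @param oap_rate0 OA~P production scale (molecules/h) multiplying the
#'   spo0A transcription drive.
#' @param oap_decay first-order OA~P loss rate (1/h, small).
#' @param t0 time of the exponential-to-stationary transition (h).
#' @param g_shape named numeric vector with elements `floor0` (pre-growth
#'   activity floor), `rise_width` (h), `floor_late`, `tau_fast` (h),
#'   `tau_slow` (h) and `shoulder` (weight of the slow decay component);
#'   see [global_activity()].
#' @param h_shape named numeric vector with elements `floor0` and
#'   `rise_width` (h) for the spo0A drive; see [spo0a_drive()].
#' @param cell_volume_fl cell volume (fL) for nM to molecule conversion.
#' @param activation_mode `"per_site"` (boost alpha per occupied A site,
#'   default) or `"all_or_none"` (boost alpha^3 only when all A sites are
#'   occupied).
#'
#' @return An object of class `uptick_params` (a validated named list).
#' @seealso [default_params()] for the calibrated default set,
#'   [uptick_strain()], [build_network()].
#' @export
uptick_params <- function(k_tx_base = 19.185,
                          k_deg_mrna = 10,
                          kd_A1 = 50, kd_A2 = 50, kd_A3 = 50,
                          kd_R1 = 125, kd_R2 = 125,
                          kd_rok_A2 = 15, kd_rok_aux = 50,
                          k_on = 100,
                          alpha = 2.8,
                          rho_rok = 0.05,
                          rho_R = 0.25,
                          rok_copies = 120,
                          oap_rate0 = 1550,
                          oap_decay = 0.12,
                          t0 = 2.25,
                          g_shape = c(floor0 = 0.1, rise_width = 0.8,
                                      floor_late = 0.05, tau_fast = 0.4,
                                      tau_slow = 3.0, shoulder = 0.25),
                          h_shape = c(floor0 = 0.05, rise_width = 0.8),
                          cell_volume_fl = 1.66,
                          activation_mode = c("per_site", "all_or_none")) {
  activation_mode <- match.arg(activation_mode)
  p <- list(k_tx_base = k_tx_base, k_deg_mrna = k_deg_mrna,
            kd_A1 = kd_A1, kd_A2 = kd_A2, kd_A3 = kd_A3,
            kd_R1 = kd_R1, kd_R2 = kd_R2,
            kd_rok_A2 = kd_rok_A2, kd_rok_aux = kd_rok_aux,
            k_on = k_on, alpha = alpha, rho_rok = rho_rok, rho_R = rho_R,
            rok_copies = rok_copies, oap_rate0 = oap_rate0,
            oap_decay = oap_decay, t0 = t0,
            g_shape = g_shape, h_shape = h_shape,
            cell_volume_fl = cell_volume_fl,
            activation_mode = activation_mode)
  validate_params(p)
  class(p) <- "uptick_params"
  p
}

#' Calibrated default model parameters
#'
#' The frozen default parameter set of the package. Dissociation constants are
#' the measured gel-shift values (about 50 nM for the A sites, 125 nM for the
#' R sites, 15 nM for Rok at A2 and 50 nM for the residual Rok site); the
#' remaining free coefficients were fixed by [calibrate_defaults()] against
#' the relative uptick amplitudes of the rok/spo0A deletion strains and the
#' ~1 transcript/cell peak, and are a documented stand-in, not measured rates.
#'
#' @param ... overrides passed on to [uptick_params()].
#' @return An `uptick_params` object.
#' @export
default_params <- function(...) {
  uptick_params(...)
}

validate_params <- function(p) {
  rates <- c("k_tx_base", "k_deg_mrna", "k_on", "oap_rate0", "oap_decay",
             "rok_copies")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] < 0)
      stop("parameter '", nm, "' must be a single nonnegative number",
           call. = FALSE)
  }
  kds <- c("kd_A1", "kd_A2", "kd_A3", "kd_R1", "kd_R2", "kd_rok_A2",
           "kd_rok_aux")
  for (nm in kds) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] <= 0)
      stop("dissociation constant '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  if (p$alpha < 1)
    stop("alpha must be >= 1 (OA~P bound at an A site never reduces transcription)",
         call. = FALSE)
  for (nm in c("rho_rok", "rho_R")) {
    if (p[[nm]] <= 0 || p[[nm]] >= 1)
      stop(nm, " must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!(p$kd_A1 < min(p$kd_R1, p$kd_R2) && p$kd_A3 < min(p$kd_R1, p$kd_R2)))
    stop("activation-site K_Ds (A1, A3) must be below the repression-site K_Ds ",
         "(R1, R2); this ordering is what makes OA~P activate before it represses",
         call. = FALSE)
  if (!(p$kd_rok_A2 < p$kd_A2))
    stop("kd_rok_A2 must be below kd_A2: Rok out-competes OA~P at A2 at low ",
         "concentrations", call. = FALSE)
  gnames <- c("floor0", "rise_width", "floor_late", "tau_fast", "tau_slow",
              "shoulder")
  if (!all(gnames %in% names(p$g_shape)))
    stop("g_shape must contain: ", paste(gnames, collapse = ", "), call. = FALSE)
  if (!all(c("floor0", "rise_width") %in% names(p$h_shape)))
    stop("h_shape must contain floor0 and rise_width", call. = FALSE)
  if (p$t0 <= 0 || p$cell_volume_fl <= 0)
    stop("t0 and cell_volume_fl must be positive", call. = FALSE)
  invisible(p)
}

#' @export
print.uptick_params <- function(x, ...) {
  cat("comK uptick model parameters\n")
  cat(sprintf("  transcription: k_tx_base = %.3g events/h, alpha = %.3g, ",
              x$k_tx_base, x$alpha))
  cat(sprintf("rho_rok = %.3g, rho_R = %.3g (%s)\n", x$rho_rok, x$rho_R,
              x$activation_mode))
  cat(sprintf("  mRNA decay: %.3g /h\n", x$k_deg_mrna))
  cat(sprintf("  K_D (nM): A1/A2/A3 = %g/%g/%g, R1/R2 = %g/%g, RokA2 = %g, RokAux = %g\n",
              x$kd_A1, x$kd_A2, x$kd_A3, x$kd_R1, x$kd_R2, x$kd_rok_A2,
              x$kd_rok_aux))
  cat(sprintf("  OA~P: production %.3g molecules/h x drive, decay %.3g /h; Rok pool: %g\n",
              x$oap_rate0, x$oap_decay, x$rok_copies))
  cat(sprintf("  t0 = %.3g h, cell volume = %.3g fL (1 nM ~ %.3g molecules)\n",
              x$t0, x$cell_volume_fl, nm_to_molecules(1, x$cell_volume_fl)))
  invisible(x)
}

#' Convert a concentration in nM to a molecule count
#'
#' @param nm concentration (nM).
#' @param volume_fl cell volume (fL). At the default 1.66 fL one nM is one
#'   molecule per cell to within 0.04 percent.
#' @return Molecule count (not rounded).
#' @export
nm_to_molecules <- function(nm, volume_fl = 1.66) {
  nm * 1e-9 * volume_fl * 1e-15 * 6.02214076e23
}

#' Single-site equilibrium binding isotherm
#'
#' Fraction of a site (or probe) bound at a free protein concentration `conc`
#' and dissociation constant `kd`: `conc / (conc + kd)`. Used to translate
#' gel-shift K_Ds into equilibrium occupancies; at `conc == kd` exactly half
#' the probe is bound.
#'
#' @param conc free protein concentration (nM), >= 0.
#' @param kd dissociation constant (nM), > 0.
#' @return Fraction bound in `[0, 1)`.
#' @examples
#' fraction_bound(50, 50)   # 0.5
#' fraction_bound(150, 50)  # 0.75
#' @export
fraction_bound <- function(conc, kd) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be a positive dissociation constant", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("conc must be a nonnegative concentration", call. = FALSE)
  conc / (conc + kd)
}

#' Global core-promoter activity profile g(t)
#'
#' Dimensionless activity of a bare (core) promoter over the growth cycle:
#' rises from a low floor during exponential growth as a Gaussian approach,
#' attains its maximum of exactly 1 at `t = t0` (entry into stationary phase),
#' and then declines as a mixture of a fast and a slow exponential whose slow
#' component produces the late shoulder seen in core-promoter activity.
#'
#' @param t time (h), scalar or vector, >= 0.
#' @param params an [uptick_params()] object (uses `t0` and `g_shape`).
#' @return Activity value(s) in (0, 1].
#' @export
global_activity <- function(t, params = default_params()) {
  stopifnot(inherits(params, "uptick_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  gs <- params$g_shape[c("floor0", "rise_width", "floor_late", "tau_fast",
                         "tau_slow", "shoulder")]
  .drive_eval_cpp(as.numeric(t), params$t0, as.numeric(gs),
                  as.numeric(params$h_shape[c("floor0", "rise_width")]))[, 1]
}

#' spo0A production drive
#'
#' Propensity (molecules/h) of OA~P production: `oap_rate0 * h(t)`, where the
#' drive h(t) rises like the global activity and is then maintained at its
#' maximum after `t0` (spo0A transcription does not collapse after the
#' transition). With a small first-order loss this yields a monotonically
#' accumulating OA~P pool: the developmental clock. For strains without
#' spo0A the drive is zero at all times.
#'
#' @param t time (h), scalar or vector.
#' @param params an [uptick_params()] object.
#' @param strain an [uptick_strain()] object, or `NULL` for wild type.
#' @return Production propensity (molecules/h).
#' @export
spo0a_drive <- function(t, params = default_params(), strain = NULL) {
  stopifnot(inherits(params, "uptick_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  if (!is.null(strain) && !strain$spo0a_present) return(rep(0, length(t)))
  gs <- params$g_shape[c("floor0", "rise_width", "floor_late", "tau_fast",
                         "tau_slow", "shoulder")]
  h <- .drive_eval_cpp(as.numeric(t), params$t0, as.numeric(gs),
                       as.numeric(params$h_shape[c("floor0", "rise_width")]))[, 2]
  params$oap_rate0 * h
}
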