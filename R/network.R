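#' Build the executable reaction network for a strain
#'
#' Assembles species, reactions and time-dependent drives for the
#' promoter-occupancy model. Per promoter copy the network contains OA~P
#' binding/unbinding at A1, A2, A3, R1 and R2 (on-rate
#' `k_on * [OAP] * site_mult`, off-rate `k_on * kd` in molecule units), Rok
#' binding/unbinding at the A2-overlapping site (competitive with OA~P at A2)
#' and at the auxiliary site, transcription with the occupancy-dependent
#' propensity of [transcription_propensity()], and first-order mRNA decay.
#' Globally it contains OA~P production driven by [spo0a_drive()] and OA~P
#' loss. Rok is a fixed pool (its amount does not vary). Knockouts remove the
#' corresponding species and reactions; a site multiplier of 0 removes that
#' site's binding reactions.
#'
#' @param strain an [uptick_strain()] object (or preset name).
#' @param params an [uptick_params()] object.
#' @param oap_fixed optional integer: freeze the OA~P pool at this constant
#'   copy number (removes production/decay; used to dissect the extrinsic
#'   contribution of the shared OA~P pool to dual-promoter correlations).
#' @return An object of class `uptick_network`.
#' @examples
#' net <- build_network(uptick_strain("d_rok"), default_params())
#' net
#' @export
build_network <- function(strain = uptick_strain("wt"),
                          params = default_params(), oap_fixed = NULL) {
  if (is.character(strain)) strain <- uptick_strain(strain)
  stopifnot(inherits(strain, "uptick_strain"), inherits(params, "uptick_params"))
  validate_params(params)
  if (!strain$n_promoters %in% c(1L, 2L))
    stop("unsupported configuration: n_promoters must be 1 or 2", call. = FALSE)

  vol <- params$cell_volume_fl
  mult <- strain$site_mult
  has_oap <- strain$spo0a_present || !is.null(oap_fixed)
  has_rok <- strain$rok_present

  species <- character()
  init <- integer()
  add_species <- function(name, count = 0L) {
    species[[length(species) + 1L]] <<- name
    init[[length(init) + 1L]] <<- as.integer(count)
    length(species)
  }

  i_oap <- if (has_oap) add_species("OAP", if (is.null(oap_fixed)) 0L else oap_fixed) else NA_integer_
  i_rok <- if (has_rok) add_species("Rok", params$rok_copies) else NA_integer_

  # reaction accumulator
  rx <- list()
  add_rx <- function(label, type, const, s1 = NA, s2 = NA, stoich,
                     tx = NULL) {
    rx[[length(rx) + 1L]] <<- list(label = label, type = type, const = const,
                                   s1 = s1, s2 = s2, stoich = stoich, tx = tx)
  }

  oap_binding_site <- function(site, kd, prom) {
    # returns bound-species index, or NA if the site cannot be bound
    m <- mult[[site]]
    if (!has_oap || m <= 0) return(NA_integer_)
    i_free <- add_species(sprintf("%s_free_p%d", site, prom), 1L)
    i_bound <- add_species(sprintf("%s_OAP_p%d", site, prom), 0L)
    add_rx(sprintf("bind_OAP_%s_p%d", site, prom), 2L, params$k_on * m,
           s1 = i_oap, s2 = i_free,
           stoich = c(stats::setNames(c(-1L, -1L, 1L),
                                      c(i_oap, i_free, i_bound))))
    add_rx(sprintf("unbind_OAP_%s_p%d", site, prom), 1L,
           params$k_on * nm_to_molecules(kd, vol), s1 = i_bound,
           stoich = c(stats::setNames(c(1L, 1L, -1L),
                                      c(i_oap, i_free, i_bound))))
    i_bound
  }

  tx_meta <- vector("list", 0L)
  mrna_idx <- integer(strain$n_promoters)

  for (prom in seq_len(strain$n_promoters)) {
    iA <- integer(); iRok <- integer(); iR <- integer()

    b <- oap_binding_site("A1", params$kd_A1, prom); if (!is.na(b)) iA <- c(iA, b)
    b <- oap_binding_site("A3", params$kd_A3, prom); if (!is.na(b)) iA <- c(iA, b)
    b <- oap_binding_site("R1", params$kd_R1, prom); if (!is.na(b)) iR <- c(iR, b)
    b <- oap_binding_site("R2", params$kd_R2, prom); if (!is.na(b)) iR <- c(iR, b)

    # A2: one site, competed for by OA~P and Rok
    oap_at_a2 <- has_oap && mult[["A2"]] > 0
    rok_at_a2 <- has_rok && mult[["RokA2"]] > 0
    if (oap_at_a2 || rok_at_a2) {
      i_free <- add_species(sprintf("A2_free_p%d", prom), 1L)
      if (oap_at_a2) {
        i_b <- add_species(sprintf("A2_OAP_p%d", prom), 0L)
        add_rx(sprintf("bind_OAP_A2_p%d", prom), 2L,
               params$k_on * mult[["A2"]], s1 = i_oap, s2 = i_free,
               stoich = stats::setNames(c(-1L, -1L, 1L),
                                        c(i_oap, i_free, i_b)))
        add_rx(sprintf("unbind_OAP_A2_p%d", prom), 1L,
               params$k_on * nm_to_molecules(params$kd_A2, vol), s1 = i_b,
               stoich = stats::setNames(c(1L, 1L, -1L),
                                        c(i_oap, i_free, i_b)))
        iA <- c(iA, i_b)
      }
      if (rok_at_a2) {
        i_b <- add_species(sprintf("A2_Rok_p%d", prom), 0L)
        add_rx(sprintf("bind_Rok_A2_p%d", prom), 2L,
               params$k_on * mult[["RokA2"]], s1 = i_rok, s2 = i_free,
               stoich = stats::setNames(c(-1L, -1L, 1L),
                                        c(i_rok, i_free, i_b)))
        add_rx(sprintf("unbind_Rok_A2_p%d", prom), 1L,
               params$k_on * nm_to_molecules(params$kd_rok_A2, vol), s1 = i_b,
               stoich = stats::setNames(c(1L, 1L, -1L),
                                        c(i_rok, i_free, i_b)))
        iRok <- c(iRok, i_b)
      }
    }

    if (has_rok && mult[["RokAux"]] > 0) {
      i_free <- add_species(sprintf("RokAux_free_p%d", prom), 1L)
      i_b <- add_species(sprintf("RokAux_Rok_p%d", prom), 0L)
      add_rx(sprintf("bind_Rok_RokAux_p%d", prom), 2L,
             params$k_on * mult[["RokAux"]], s1 = i_rok, s2 = i_free,
             stoich = stats::setNames(c(-1L, -1L, 1L), c(i_rok, i_free, i_b)))
      add_rx(sprintf("unbind_Rok_RokAux_p%d", prom), 1L,
             params$k_on * nm_to_molecules(params$kd_rok_aux, vol), s1 = i_b,
             stoich = stats::setNames(c(1L, 1L, -1L), c(i_rok, i_free, i_b)))
      iRok <- c(iRok, i_b)
    }

    i_m <- add_species(sprintf("mRNA_p%d", prom), 0L)
    mrna_idx[prom] <- i_m
    add_rx(sprintf("transcription_p%d", prom), 3L, params$k_tx_base,
           stoich = stats::setNames(1L, i_m),
           tx = list(iA = iA, iRok = iRok, iR = iR))
    add_rx(sprintf("mrna_decay_p%d", prom), 1L, params$k_deg_mrna, s1 = i_m,
           stoich = stats::setNames(-1L, i_m))
  }

  if (strain$spo0a_present && is.null(oap_fixed)) {
    add_rx("oap_production", 0L, params$oap_rate0,
           stoich = stats::setNames(1L, i_oap))
    if (params$oap_decay > 0)
      add_rx("oap_decay", 1L, params$oap_decay, s1 = i_oap,
             stoich = stats::setNames(-1L, i_oap))
  }

  n_sp <- length(species)
  n_rx <- length(rx)
  stoich <- matrix(0L, n_rx, n_sp)
  for (r in seq_len(n_rx)) {
    s <- rx[[r]]$stoich
    stoich[r, as.integer(names(s))] <- as.integer(s)
  }
  structure(list(
    species = stats::setNames(init, species),
    reactions = data.frame(
      label = vapply(rx, `[[`, "", "label"),
      type = vapply(rx, `[[`, 0L, "type"),
      const = vapply(rx, `[[`, 0, "const"),
      s1 = vapply(rx, function(x) as.integer(x$s1), 0L),
      s2 = vapply(rx, function(x) as.integer(x$s2), 0L),
      stringsAsFactors = FALSE),
    stoich = stoich,
    tx_meta = lapply(rx, `[[`, "tx"),
    mrna_idx = mrna_idx,
    oap_idx = i_oap,
    strain = strain,
    params = params,
    oap_fixed = oap_fixed,
    t0 = params$t0), class = "uptick_network")
}

#' @export
print.uptick_network <- function(x, ...) {
  cat(sprintf("uptick reaction network ('%s'): %d species, %d reactions, %d promoter cop%s\n",
              x$strain$label, length(x$species), nrow(x$reactions),
              x$strain$n_promoters,
              if (x$strain$n_promoters == 1) "y" else "ies"))
  cat("  species:", paste(names(x$species), collapse = ", "), "\n")
  if (!is.null(x$oap_fixed))
    cat(sprintf("  OA~P pool frozen at %d molecules\n", x$oap_fixed))
  invisible(x)
}

#' Transcription propensity of a promoter state
#'
#' Returns `k_tx_base * g(t) * alpha^nA * rho_rok^nRok * rho_R^nR`, where `nA`
#' counts A sites occupied by OA~P, `nRok` counts Rok-occupied sites and `nR`
#' counts OA~P-occupied R sites. The multiplicative factors make joint
#' repression by Rok and OA~P stronger than either alone, and OA~P bound at A
#' sites raises transcription even while Rok remains bound elsewhere
#' (non-displacing anti-repression).
#'
#' @param state named list or vector giving the occupant of each site:
#'   `A1`, `A2`, `A3`, `R1`, `R2` take `"empty"` or `"OAP"` (`A2` may also be
#'   `"Rok"`); `RokAux` takes `"empty"` or `"Rok"`.
#' @param t time (h).
#' @param params an [uptick_params()] object.
#' @param strain an [uptick_strain()] object (site multipliers do not change
#'   the propensity of a given occupancy state, but knockouts constrain which
#'   states are reachable).
#' @return Transcription propensity (events/h).
#' @examples
#' p <- default_params()
#' transcription_propensity(list(A2 = "Rok", RokAux = "Rok"), t = p$t0, p)
#' @export
transcription_propensity <- function(state, t, params = default_params(),
                                     strain = uptick_strain("wt")) {
  stopifnot(inherits(params, "uptick_params"))
  full <- list(A1 = "empty", A2 = "empty", A3 = "empty", R1 = "empty",
               R2 = "empty", RokAux = "empty")
  bad <- setdiff(names(state), names(full))
  if (length(bad))
    stop("unknown promoter site(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  full[names(state)] <- state
  allowed <- list(A1 = c("empty", "OAP"), A2 = c("empty", "OAP", "Rok"),
                  A3 = c("empty", "OAP"), R1 = c("empty", "OAP"),
                  R2 = c("empty", "OAP"), RokAux = c("empty", "Rok"))
  for (s in names(full)) {
    if (!full[[s]] %in% allowed[[s]])
      stop("invalid occupant '", full[[s]], "' at site ", s, call. = FALSE)
  }
  nA <- sum(unlist(full[c("A1", "A2", "A3")]) == "OAP")
  nRok <- sum(unlist(full[c("A2", "RokAux")]) == "Rok")
  nR <- sum(unlist(full[c("R1", "R2")]) == "OAP")
  act <- if (params$activation_mode == "all_or_none") {
    if (nA == 3L) params$alpha^3 else 1
  } else params$alpha^nA
  params$k_tx_base * global_activity(t, params) * act *
    params$rho_rok^nRok * params$rho_R^nR
}
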