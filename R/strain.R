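#' Strain configuration
#'
#' Describes which regulators are present and how promoter-site affinities are
#' modified relative to wild type. Site multipliers scale the binding on-rate
#' (so the effective K_D of a site is `kd / mult`); a multiplier of 0 removes
#' the site's binding reactions entirely, 1 is wild type, and intermediate
#' values model mutated boxes with residual affinity.
#'
#' @param preset one of the named presets: `"wt"` (wild-type promoter in the
#'   comK-null background used for all basal-rate measurements), `"d_comK"`
#'   (alias of `"wt"`: the model contains no ComK feedback), `"d_rok"`,
#'   `"d_spo0A"`, `"d_rok_d_spo0A"`, and the site mutants `"A1"`, `"A2"`,
#'   `"A3"`, `"A123"`, `"R1"`, `"R2"`. Ignored when other arguments are given
#'   explicitly with `preset = NULL`.
#' @param rok_present,spo0a_present logical flags; deletions remove the
#'   corresponding species and reactions.
#' @param site_mult named numeric vector of affinity multipliers for the sites
#'   `A1`, `A2`, `A3`, `R1`, `R2`, `RokA2`, `RokAux`. Unnamed sites default
#'   to 1.
#' @param n_promoters number of independent identical comK promoter copies
#'   sharing the cell's OA~P and Rok pools (1, or 2 for the dual-reporter
#'   noise analysis).
#' @param label free-text label; defaults to the preset name.
#' @param mutant_residual residual affinity multiplier retained by a mutated
#'   Spo0A box (the published site mutations leave 2/7 consensus bases and do
#'   not abolish binding completely). Used by the site-mutant presets.
#'
#' @details The `"A2"` and `"A123"` presets also remove the high-affinity Rok
#' interaction at A2 (`RokA2` multiplier 0): in gel shifts the A2 mutation
#' eliminates the 15 nM Rok complex, leaving only the ~50 nM residual
#' interaction that the model carries as the separate auxiliary site.
#'
#' @return An object of class `uptick_strain`.
#' @examples
#' uptick_strain("d_rok")
#' uptick_strain("wt", n_promoters = 2)
#' @export
uptick_strain <- function(preset = "wt", rok_present = NULL,
                          spo0a_present = NULL, site_mult = NULL,
                          n_promoters = 1, label = NULL,
                          mutant_residual = 0.135) {
  sites <- c("A1", "A2", "A3", "R1", "R2", "RokA2", "RokAux")
  mult <- stats::setNames(rep(1, length(sites)), sites)
  rok <- TRUE
  spo0a <- TRUE
  if (!is.null(preset)) {
    presets <- strain_presets(mutant_residual)
    if (!preset %in% names(presets))
      stop("unknown strain preset '", preset, "'; valid presets: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    pr <- presets[[preset]]
    rok <- pr$rok_present
    spo0a <- pr$spo0a_present
    mult[names(pr$site_mult)] <- pr$site_mult
    if (is.null(label)) label <- preset
  }
  if (!is.null(rok_present)) rok <- rok_present
  if (!is.null(spo0a_present)) spo0a <- spo0a_present
  if (!is.null(site_mult)) {
    bad <- setdiff(names(site_mult), sites)
    if (length(bad))
      stop("unknown site(s) in site_mult: ", paste(bad, collapse = ", "),
           call. = FALSE)
    mult[names(site_mult)] <- site_mult
  }
  if (any(mult < 0)) stop("site multipliers must be >= 0", call. = FALSE)
  if (!n_promoters %in% c(1L, 2L))
    stop("n_promoters must be 1 or 2", call. = FALSE)
  if (is.null(label)) label <- "custom"
  structure(list(rok_present = isTRUE(rok), spo0a_present = isTRUE(spo0a),
                 site_mult = mult, n_promoters = as.integer(n_promoters),
                 label = label),
            class = "uptick_strain")
}

#' Named strain presets
#'
#' @param mutant_residual residual affinity multiplier for mutated Spo0A boxes.
#' @return A named list of preset definitions.
#' @export
strain_presets <- function(mutant_residual = 0.135) {
  res <- mutant_residual
  base <- list(rok_present = TRUE, spo0a_present = TRUE, site_mult = numeric())
  list(
    wt = base,
    d_comK = base,
    d_rok = utils::modifyList(base, list(rok_present = FALSE)),
    d_spo0A = utils::modifyList(base, list(spo0a_present = FALSE)),
    d_rok_d_spo0A = utils::modifyList(base, list(rok_present = FALSE,
                                                 spo0a_present = FALSE)),
    A1 = utils::modifyList(base, list(site_mult = c(A1 = res))),
    A2 = utils::modifyList(base, list(site_mult = c(A2 = res, RokA2 = 0))),
    A3 = utils::modifyList(base, list(site_mult = c(A3 = res))),
    A123 = utils::modifyList(base, list(site_mult = c(A1 = res, A2 = res,
                                                      A3 = res, RokA2 = 0))),
    R1 = utils::modifyList(base, list(site_mult = c(R1 = 0))),
    R2 = utils::modifyList(base, list(site_mult = c(R2 = 0)))
  )
}

#' @export
print.uptick_strain <- function(x, ...) {
  cat(sprintf("uptick strain '%s': rok %s, spo0A %s, %d promoter cop%s\n",
              x$label, if (x$rok_present) "present" else "absent",
              if (x$spo0a_present) "present" else "absent",
              x$n_promoters, if (x$n_promoters == 1) "y" else "ies"))
  off <- x$site_mult[x$site_mult != 1]
  if (length(off))
    cat("  site multipliers: ",
        paste(sprintf("%s = %g", names(off), off), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}
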