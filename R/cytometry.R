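#' Read a per-cell two-channel intensity table
#'
#' Reads a delimited text file with (at least) columns `cell_id`, `cfp`,
#' `yfp`: mean pixel intensities per segmented cell in arbitrary units.
#'
#' @param path CSV/TSV file path.
#' @param sep field separator; `","` by default, use `"\t"` for TSV.
#' @return A validated `data.frame` (class `cell_table`).
#' @export
read_cell_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_cell_table(df)
}

#' Validate a per-cell intensity table
#'
#' @param df data frame with columns `cell_id`, `cfp`, `yfp`.
#' @return `df` with class `cell_table` prepended.
#' @export
as_cell_table <- function(df) {
  need <- c("cell_id", "cfp", "yfp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (ch in c("cfp", "yfp")) {
    if (anyNA(df[[ch]]))
      stop("cell table has missing values in '", ch, "'", call. = FALSE)
    if (any(df[[ch]] < 0))
      stop("negative intensities in '", ch, "'", call. = FALSE)
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Calibrate the competence threshold from a late-time reference population
#'
#' Determines (i) the competent fraction as the proportion of calibration
#' cells whose ComK-dependent reporter (in the `yfp` channel of `calib_late`)
#' exceeds `comg_cutoff`, and (ii) the CFP classification threshold as the
#' lower edge of the box enclosing the upper `fraction` of the early-time CFP
#' distribution (nearest-rank quantile: the `floor(n * (1 - fraction))`-th
#' order statistic, so that strictly greater values form the upper
#' `fraction`).
#'
#' @param calib_late `cell_table` of the late calibration timepoint (YFP
#'   channel carries the ComK-dependent reporter).
#' @param comg_cutoff intensity (a.u.) separating the high-reporter cluster;
#'   default 50.
#' @param early `cell_table` of the early timepoint whose CFP distribution
#'   sets the threshold.
#' @return List with `fraction` (dimensionless) and `threshold` (a.u.).
#' @examples
#' early <- as_cell_table(data.frame(cell_id = 1:100, cfp = 1:100, yfp = 0))
#' late <- as_cell_table(data.frame(cell_id = 1:100, cfp = 0,
#'                                  yfp = c(rep(10, 75), rep(80, 25))))
#' calibrate_threshold(late, 50, early)  # fraction 0.25, threshold 75
#' @export
calibrate_threshold <- function(calib_late, comg_cutoff = 50, early) {
  calib_late <- as_cell_table(calib_late)
  early <- as_cell_table(early)
  fraction <- mean(calib_late$yfp > comg_cutoff)
  if (fraction <= 0 || fraction >= 1)
    stop("degenerate calibration: the high-reporter fraction is ",
         fraction, " (no separable cluster above comg_cutoff = ",
         comg_cutoff, ")", call. = FALSE)
  n <- nrow(early)
  k <- max(1L, floor(n * (1 - fraction)))
  threshold <- sort(early$cfp, partial = k)[k]
  list(fraction = fraction, threshold = threshold)
}

#' Classify cells as competent by CFP threshold
#'
#' A cell is competent when its CFP intensity strictly exceeds the threshold.
#'
#' @param cells a `cell_table`.
#' @param threshold CFP threshold (a.u.), > 0.
#' @return List with `labels` (logical vector) and `fraction`.
#' @export
classify_competent <- function(cells, threshold) {
  cells <- as_cell_table(cells)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  labels <- cells$cfp > threshold
  list(labels = labels, fraction = mean(labels))
}

#' Competent fraction per YFP bin
#'
#' Deposits cells into bins of the YFP axis and reports, per bin, the percent
#' of cells classified competent (normalized to the total number of cells in
#' that bin). Empty bins are flagged, not reported as zero.
#'
#' @param cells a `cell_table`.
#' @param labels logical competence labels (from [classify_competent()]).
#' @param yfp_bin_edges strictly increasing bin edges covering the data range.
#' @return Data frame with `bin_lo`, `bin_hi`, `bin_mid`, `n_cells`,
#'   `n_competent`, `percent_competent` (NA for empty bins), `empty`.
#' @export
binned_competence_fraction <- function(cells, labels, yfp_bin_edges) {
  cells <- as_cell_table(cells)
  if (length(labels) != nrow(cells))
    stop("labels must match the number of cells", call. = FALSE)
  e <- yfp_bin_edges
  if (length(e) < 2 || any(diff(e) <= 0))
    stop("yfp_bin_edges must be strictly increasing", call. = FALSE)
  if (min(cells$yfp) < e[1] || max(cells$yfp) > e[length(e)])
    stop("yfp_bin_edges must cover the data range [",
         min(cells$yfp), ", ", max(cells$yfp), "]", call. = FALSE)
  bin <- cut(cells$yfp, breaks = e, include.lowest = TRUE, right = FALSE)
  n_tot <- as.integer(table(bin))
  n_comp <- as.integer(tapply(labels, bin, sum, default = 0L))
  empty <- n_tot == 0L
  data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
             bin_mid = (e[-length(e)] + e[-1]) / 2,
             n_cells = n_tot, n_competent = n_comp,
             percent_competent = ifelse(empty, NA_real_,
                                        100 * n_comp / pmax(n_tot, 1L)),
             empty = empty)
}

#' Contingency table of competent cells across a YFP boundary
#'
#' @param cells a `cell_table`.
#' @param labels logical competence labels.
#' @param boundary YFP value; cells with `yfp > boundary` are "above".
#' @return List of counts `n_comp_above`, `n_total_above`, `n_comp_below`,
#'   `n_total_below` (class `contingency_table`).
#' @export
competence_contingency <- function(cells, labels, boundary) {
  cells <- as_cell_table(cells)
  above <- cells$yfp > boundary
  structure(list(n_comp_above = sum(labels & above),
                 n_total_above = sum(above),
                 n_comp_below = sum(labels & !above),
                 n_total_below = sum(!above)),
            class = "contingency_table")
}

#' Two-proportion test across the YFP boundary
#'
#' Tests whether the proportion of competent cells above a YFP boundary
#' differs from the proportion below it: a two-sided two-proportion z-test
#' with pooled variance. When any cell of the 2x2 table is below 5, Fisher's
#' exact p-value is also computed as a cross-check and returned alongside.
#'
#' @param table a `contingency_table` (or a list with fields `n_comp_above`,
#'   `n_total_above`, `n_comp_below`, `n_total_below`).
#' @return List with `p_above` and `p_below` (percent), `z`, `p_value`
#'   (z-test), and `p_fisher` (NA unless the small-count cross-check ran).
#' @examples
#' tab <- list(n_comp_above = 48, n_total_above = 1655,
#'             n_comp_below = 1371, n_total_below = 9583)
#' boundary_proportion_test(tab)
#' @export
boundary_proportion_test <- function(table) {
  n1 <- table$n_total_above; x1 <- table$n_comp_above
  n2 <- table$n_total_below; x2 <- table$n_comp_below
  if (is.null(n1) || is.null(n2) || n1 <= 0 || n2 <= 0)
    stop("both group totals must be positive", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop("competent counts must lie within group totals", call. = FALSE)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p_value <- 2 * stats::pnorm(-abs(z))
  p_fisher <- NA_real_
  cells <- c(x1, n1 - x1, x2, n2 - x2)
  if (any(cells < 5)) {
    m <- matrix(cells, nrow = 2, byrow = TRUE)
    p_fisher <- stats::fisher.test(m)$p.value
  }
  list(p_above = 100 * p1, p_below = 100 * p2, z = z, p_value = p_value,
       p_fisher = p_fisher)
}
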