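#' Ensemble-mean transcription-rate curve
#'
#' Histograms the pooled transcription event times of an ensemble into bins of
#' width `bin_width` and divides by `bin_width * n_runs`, giving the
#' ensemble-mean transcription rate (events/h per cell) at the bin centers:
#' the model analogue of a luciferase signal, which reports the transcription
#' rate rather than the accumulated product. The mean mRNA count per cell
#' (summed over promoter copies) is interpolated onto the same bin centers.
#'
#' @param ensemble an [run_ensemble()] result.
#' @param bin_width bin width (h), > 0.
#' @return An object of class `uptick_rate_curve` with fields `times` (bin
#'   centers, h), `rate` (events/h per cell), `mrna_mean`, `strain_label`,
#'   `bin_width`, `n_runs`.
#' @export
mean_rate_curve <- function(ensemble, bin_width = 0.1) {
  stopifnot(inherits(ensemble, "uptick_ensemble"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive", call. = FALSE)
  if (ensemble$n_runs < 1) stop("empty ensemble", call. = FALSE)
  edges <- seq(0, ensemble$t_end + bin_width * (1 - 1e-9), by = bin_width)
  if (edges[length(edges)] < ensemble$t_end)
    edges <- c(edges, edges[length(edges)] + bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  all_tx <- unlist(ensemble$tx_times, use.names = FALSE)
  counts <- if (length(all_tx))
    graphics::hist(all_tx, breaks = edges, plot = FALSE, right = FALSE,
                   include.lowest = TRUE)$counts
  else rep(0L, length(centers))
  rate <- counts / (bin_width * ensemble$n_runs)
  mrna_total <- rowSums(ensemble$mean_counts[, ensemble$mrna_species,
                                             drop = FALSE])
  mrna <- stats::approx(ensemble$times, mrna_total, xout = centers,
                        rule = 2)$y
  structure(list(times = centers, rate = rate, mrna_mean = mrna,
                 strain_label = ensemble$strain_label,
                 bin_width = bin_width, n_runs = ensemble$n_runs),
            class = "uptick_rate_curve")
}

#' @export
print.uptick_rate_curve <- function(x, ...) {
  pk <- peak_amplitude(x)
  cat(sprintf("transcription-rate curve ('%s'): %d bins of %g h, peak %.3g events/h at %.2f h\n",
              x$strain_label, length(x$times), x$bin_width, pk["value"],
              pk["time"]))
  invisible(x)
}

#' @export
as.data.frame.uptick_rate_curve <- function(x, ...) {
  data.frame(time_h = x$times, rate_per_h = x$rate, mrna_mean = x$mrna_mean,
             strain = x$strain_label, stringsAsFactors = FALSE)
}

#' @export
plot.uptick_rate_curve <- function(x, ..., col = "darkblue") {
  graphics::plot(x$times, x$rate, type = "l", col = col,
                 xlab = "time (h)", ylab = "transcription rate (events/h)",
                 main = x$strain_label, ...)
  invisible(x)
}

# centered moving average, window must be odd; edge bins average the
# available neighbours
smooth_rate <- function(rate, window = 3L) {
  n <- length(rate)
  if (window <= 1L || n < 3L) return(rate)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(rate[lo:hi])
  }, 0)
}

#' Peak amplitude of a rate curve
#'
#' The "amplitude" of the uptick: maximum of the lightly smoothed rate curve
#' (centered moving average, default window 3 bins, suppressing binning
#' noise) and the bin-center time at which it occurs. Ties are broken by the
#' earliest time.
#'
#' @param curve an [mean_rate_curve()] result.
#' @param window smoothing window in bins (odd).
#' @return Named numeric vector `c(value, time)`; if the curve is identically
#'   zero the value is 0 at the first bin time, with a warning.
#' @export
peak_amplitude <- function(curve, window = 3L) {
  stopifnot(inherits(curve, "uptick_rate_curve"))
  if (!length(curve$times)) stop("empty rate curve", call. = FALSE)
  sm <- smooth_rate(curve$rate, window)
  if (all(sm == 0)) {
    warning("all-zero rate curve; amplitude undefined", call. = FALSE)
    return(c(value = 0, time = curve$times[1]))
  }
  i <- which.max(sm)  # which.max already takes the earliest tie
  c(value = sm[i], time = curve$times[i])
}

#' Amplitude ratio between two strains
#'
#' Ratio of smoothed peak amplitudes, the quantity used to compare mutant
#' uptick amplitudes (e.g. the ~9-fold decrease on deleting spo0A).
#'
#' @param curve_a,curve_b rate curves computed with the same bin width and
#'   horizon.
#' @param window smoothing window passed to [peak_amplitude()].
#' @return Fold ratio `peak(curve_a) / peak(curve_b)`.
#' @export
amplitude_ratio <- function(curve_a, curve_b, window = 3L) {
  stopifnot(inherits(curve_a, "uptick_rate_curve"),
            inherits(curve_b, "uptick_rate_curve"))
  if (abs(curve_a$bin_width - curve_b$bin_width) > 1e-12)
    stop("curves must use the same bin width", call. = FALSE)
  pb <- peak_amplitude(curve_b, window)
  if (pb["value"] <= 0)
    stop("undefined ratio: denominator curve has zero peak", call. = FALSE)
  unname(peak_amplitude(curve_a, window)["value"] / pb["value"])
}

#' Normalize a rate curve to peak 1
#'
#' Divides the rate by its maximum so curves of different strains can be
#' overlaid to compare their shapes (e.g. the sharp wild-type downturn versus
#' the Rok-less shoulder).
#'
#' @param curve a rate curve with a positive peak.
#' @return A rate curve whose maximum rate is exactly 1.
#' @export
normalize_peak <- function(curve) {
  stopifnot(inherits(curve, "uptick_rate_curve"))
  m <- max(curve$rate)
  if (m <= 0) stop("undefined normalization: zero peak", call. = FALSE)
  curve$rate <- curve$rate / m
  curve$mrna_mean <- curve$mrna_mean / m
  curve
}

#' Post-peak decay half-time
#'
#' Time after the peak at which the rate first falls to half the peak value,
#' linearly interpolated between bins. Quantifies how abruptly transcription
#' shuts down: the wild type decays faster than Rok-less strains, whose
#' decline shows a pronounced shoulder. Computed on the raw binned curve
#' (set `window > 1` to smooth first).
#'
#' @param curve a rate curve with positive peak.
#' @param window smoothing window in bins (1 = none).
#' @return Half-decay time (h) with attribute `censored = TRUE` if the rate
#'   never falls below half peak before the horizon (then the value is
#'   horizon minus peak time).
#' @export
decay_halftime <- function(curve, window = 1L) {
  stopifnot(inherits(curve, "uptick_rate_curve"))
  sm <- smooth_rate(curve$rate, window)
  i <- which.max(sm)
  peak <- sm[i]
  if (peak <= 0) stop("undefined half-time: zero peak", call. = FALSE)
  half <- peak / 2
  after <- sm[i:length(sm)]
  j <- which(after <= half)
  if (!length(j)) {
    out <- curve$times[length(curve$times)] - curve$times[i]
    attr(out, "censored") <- TRUE
    return(out)
  }
  j <- j[1]
  if (j == 1L) return(0)
  t1 <- curve$times[i + j - 2L]; t2 <- curve$times[i + j - 1L]
  r1 <- after[j - 1L]; r2 <- after[j]
  t_half <- t1 + (r1 - half) / (r1 - r2) * (t2 - t1)
  out <- t_half - curve$times[i]
  attr(out, "censored") <- FALSE
  out
}

#' Write a rate curve to CSV
#'
#' Columns `time_h, rate_per_h, mrna_mean, strain`.
#'
#' @param curve a rate curve.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_rate_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
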