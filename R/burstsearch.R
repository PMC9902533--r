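#' Parameters for the combined IPT / photon-count burst search
#'
#' A single-molecule burst is a maximal run of consecutive photons whose
#' Lee-filtered inter-photon times (IPTs) all stay at or below
#' `ipt_threshold`; runs containing at least `min_photons` photons are
#' emitted as bursts. The defaults are deliberately absent: the two
#' regimes in routine use are 100 us / 7 photons (small, bright
#' single-fluorophore complexes) and 5 us / 30 photons (large particles
#' such as fibrils, oligomers and exosomes).
#'
#' @param ipt_threshold IPT threshold in seconds (e.g. `100e-6` or `5e-6`).
#' @param min_photons minimum photons per burst (integer >= 2).
#' @param lee_window_n Lee filter half-window `n` (window `2n + 1`),
#'   default 4.
#' @param lee_sigma0 noise scale of the Lee filter, seconds. Defaults to
#'   `ipt_threshold / 2`, a scale that smooths within-burst IPT jitter
#'   while leaving the burst edges (an order-of-magnitude IPT change)
#'   essentially untouched.
#' @return object of class `ipt_burst_params`.
#' @export
ipt_burst_params <- function(ipt_threshold, min_photons,
                             lee_window_n = 4,
                             lee_sigma0 = ipt_threshold / 2) {
  if (!is.numeric(ipt_threshold) || ipt_threshold <= 0)
    stop("`ipt_threshold` must be > 0 seconds")
  if (!is.numeric(min_photons) || min_photons < 2)
    stop("`min_photons` must be an integer >= 2")
  if (!is.numeric(lee_window_n) || lee_window_n < 1)
    stop("`lee_window_n` must be an integer >= 1")
  if (!is.numeric(lee_sigma0) || lee_sigma0 < 0)
    stop("`lee_sigma0` must be >= 0")
  structure(list(ipt_threshold = ipt_threshold,
                 min_photons = as.integer(min_photons),
                 lee_window_n = as.integer(lee_window_n),
                 lee_sigma0 = lee_sigma0),
            class = "ipt_burst_params")
}

#' Parameters for the binned intensity-threshold burst search
#'
#' Used for bright, extended particles (condensates) riding on a bulk
#' background: photon counts are binned, and a burst is a maximal run of
#' bins whose count strictly exceeds a per-trace threshold of
#' `mean + sd_multiplier * sd` of all bin counts.
#'
#' @param bin_width bin width in seconds (default 1 ms).
#' @param sd_multiplier threshold in standard deviations above the mean
#'   (default 5).
#' @return object of class `intensity_burst_params`.
#' @export
intensity_burst_params <- function(bin_width = 1e-3, sd_multiplier = 5) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be > 0 seconds")
  if (!is.numeric(sd_multiplier) || sd_multiplier <= 0)
    stop("`sd_multiplier` must be > 0")
  structure(list(bin_width = bin_width, sd_multiplier = sd_multiplier),
            class = "intensity_burst_params")
}

#' Lee filter for piecewise-constant signals
#'
#' Local adaptive smoother: with running mean `m` and running population
#' variance `v` over a truncated window of half-width `window_n`, each
#' sample is replaced by `m + (x - m) * v / (v + sigma0^2)`. Regions of
#' constant signal (low local variance) are pulled to the local mean;
#' edges and bursts (high local variance) pass through nearly unchanged.
#'
#' @param series numeric vector.
#' @param window_n half-window size `n`; the window is `2n + 1` samples,
#'   truncated at the ends of the series.
#' @param sigma0 noise scale in the units of `series`; `sigma0 = 0`
#'   returns the input unchanged.
#' @return smoothed numeric vector, same length as `series`.
#' @export
lee_filter <- function(series, window_n = 4, sigma0) {
  if (!is.numeric(window_n) || window_n < 1)
    stop("`window_n` must be an integer >= 1")
  if (!is.numeric(sigma0) || length(sigma0) != 1L || sigma0 < 0)
    stop("`sigma0` must be a single non-negative number")
  x <- as.numeric(series)
  n <- length(x)
  if (n == 0L) return(x)
  w <- as.integer(window_n)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x * x))
  i <- seq_len(n)
  lo <- pmax(1L, i - w)
  hi <- pmin(n, i + w)
  cnt <- hi - lo + 1
  m <- (cs[hi + 1] - cs[lo]) / cnt
  v <- pmax((cs2[hi + 1] - cs2[lo]) / cnt - m * m, 0)
  denom <- v + sigma0 * sigma0
  gain <- ifelse(denom > 0, v / denom, 1)
  m + (x - m) * gain
}

burst_set <- function(bursts, source_duration, params) {
  structure(list(bursts = bursts, source_duration = source_duration,
                 params = params),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts over %g s\n",
              nrow(x$bursts), x$source_duration))
  invisible(x)
}

#' Number of bursts in a burst set
#' @param bs a `burst_set`.
#' @return integer count.
#' @export
n_bursts <- function(bs) {
  stopifnot(inherits(bs, "burst_set"))
  nrow(bs$bursts)
}

empty_bursts <- function(intensity = FALSE) {
  df <- data.frame(start_s = numeric(0), end_s = numeric(0),
                   n_photons = integer(0))
  df$peak_bin_count <- integer(0)
  df
}

#' Combined inter-photon-time / photon-count burst search
#'
#' Identifies single-molecule events as maximal runs of consecutive
#' photons in which every inter-photon gap, after Lee filtering of the
#' IPT sequence, is at or below the threshold. A run of `k` qualifying
#' gaps spans `k + 1` photons; runs with at least `min_photons` photons
#' become bursts. Burst boundaries are the arrival times of the first
#' and last photon of the run. All gap comparisons are carried out on
#' the integer tick grid (the threshold is truncated toward zero into
#' ticks), so results are bit-stable under file round trips.
#'
#' @param trace a [photon_trace()].
#' @param params an [ipt_burst_params()].
#' @return a `burst_set`; its `bursts` data frame has columns
#'   `start_s`, `end_s`, `n_photons`, `peak_bin_count` (NA for this
#'   search).
#' @export
find_bursts_ipt <- function(trace, params) {
  stopifnot(inherits(trace, "photon_trace"),
            inherits(params, "ipt_burst_params"))
  res <- tick_resolution(trace)
  ticks <- trace$ticks
  if (length(ticks) < params$min_photons)
    return(burst_set(empty_bursts(), trace$duration, params))
  ipt_ticks <- diff(ticks)
  thr_ticks <- trunc(params$ipt_threshold / res)
  sigma0_ticks <- params$lee_sigma0 / res
  filtered <- lee_filter(ipt_ticks, params$lee_window_n, sigma0_ticks)
  qualify <- filtered <= thr_ticks
  r <- rle(qualify)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= params$min_photons)
  if (!any(keep))
    return(burst_set(empty_bursts(), trace$duration, params))
  gs <- starts[keep]           # first qualifying gap index
  ge <- ends[keep]             # last qualifying gap index
  first_photon <- gs           # photon i precedes gap i
  last_photon <- ge + 1L
  bursts <- data.frame(
    start_s = ticks[first_photon] * res,
    end_s = ticks[last_photon] * res,
    n_photons = as.integer(last_photon - first_photon + 1L))
  bursts$peak_bin_count <- NA_integer_
  burst_set(bursts, trace$duration, params)
}

#' Binned intensity-threshold burst search
#'
#' For traces with a bulk fluorescence background, bursts are maximal
#' runs of consecutive bins whose photon count strictly exceeds
#' `mean + sd_multiplier * sd`, both statistics taken from the
#' distribution of all bin counts of that trace, i.e. the threshold is
#' unique to each trace. Burst extent is the first through last bin of
#' the run; `n_photons` sums the counts in those bins.
#'
#' @param binned a `binned_trace` from [bin_trace()].
#' @param params an [intensity_burst_params()].
#' @return a `burst_set` whose `bursts` data frame has `start_s`,
#'   `end_s`, `n_photons`, `peak_bin_count`.
#' @export
find_bursts_intensity <- function(binned, params = intensity_burst_params()) {
  stopifnot(inherits(binned, "binned_trace"),
            inherits(params, "intensity_burst_params"))
  counts <- binned$counts
  if (length(counts) < 2)
    stop("at least 2 bins are required (SD undefined otherwise)")
  thr <- mean(counts) + params$sd_multiplier * stats::sd(counts)
  above <- counts > thr
  dur <- length(counts) * binned$bin_width
  if (!any(above))
    return(burst_set(empty_bursts(TRUE), dur, params))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  bs <- starts[keep]
  be <- ends[keep]
  w <- binned$bin_width
  bursts <- data.frame(
    start_s = binned$origin + (bs - 1L) * w,
    end_s = binned$origin + be * w,
    n_photons = as.integer(mapply(function(a, b) sum(counts[a:b]), bs, be)))
  bursts$peak_bin_count <- as.integer(
    mapply(function(a, b) max(counts[a:b]), bs, be))
  burst_set(bursts, dur, params)
}

#' Summary statistics of burst intensities
#'
#' Mean and median photons per burst. The median is the statistic used
#' for valency/stoichiometry ratios downstream, because it is resilient
#' to the skew of burst-intensity distributions.
#'
#' @param bs a `burst_set`.
#' @return list with `count`, `mean`, `median` (the latter two `NA` for
#'   an empty set).
#' @export
burst_intensity_summary <- function(bs) {
  stopifnot(inherits(bs, "burst_set"))
  x <- bs$bursts$n_photons
  if (length(x) == 0)
    return(list(count = 0L, mean = NA_real_, median = NA_real_))
  list(count = length(x), mean = mean(x), median = stats::median(x))
}

#' Write a burst set to CSV
#' @param bs a `burst_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bursts <- function(bs, path) {
  stopifnot(inherits(bs, "burst_set"))
  utils::write.csv(bs$bursts, path, row.names = FALSE)
  invisible(path)
}
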