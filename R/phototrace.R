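#' Photon arrival-time trace
#'
#' The atomic measurement of the platform: the ordered arrival times of
#' detected photons at one scan position, recorded as integer ticks on a
#' fixed clock grid (16 ps per tick for the TCSPC hardware emulated here).
#' Timestamps are kept in ticks internally so that round trips through
#' text files are bit-exact; conversions to seconds happen on demand.
#'
#' @param ticks numeric vector of non-decreasing integer tick values
#'   (doubles holding integers are fine; ticks routinely exceed 2^31).
#' @param tick_ps clock resolution in picoseconds per tick (default 16).
#' @param duration trace length in seconds. All ticks must fall in
#'   `[0, duration / tick_resolution]`.
#' @param position channel coordinate in micrometres (optional).
#' @param laser_power laser power in microwatts (optional metadata).
#' @param repeat_id integer repeat index (optional).
#'
#' @return An object of class `photon_trace` with fields `ticks`,
#'   `tick_ps`, `duration`, `position`, `laser_power`, `repeat_id`.
#' @examples
#' tr <- photon_trace(c(0, 625000, 1250000), tick_ps = 16, duration = 1)
#' timestamps(tr) # 0, 10 us, 20 us
#' @export
photon_trace <- function(ticks, tick_ps = 16, duration,
                         position = NULL, laser_power = NULL,
                         repeat_id = NULL) {
  if (!is.numeric(ticks)) stop("`ticks` must be numeric")
  ticks <- as.numeric(ticks)
  if (length(ticks) && any(diff(ticks) < 0)) {
    bad <- which(diff(ticks) < 0)[1] + 1L
    stop(sprintf("timestamps not non-decreasing: first offending index %d", bad))
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number of seconds")
  if (!is.numeric(tick_ps) || tick_ps <= 0)
    stop("`tick_ps` must be a positive tick resolution in picoseconds")
  max_tick <- duration / (tick_ps * 1e-12)
  if (length(ticks) && (ticks[1] < 0 || ticks[length(ticks)] > max_tick))
    stop("timestamps outside [0, duration]")
  structure(
    list(ticks = ticks, tick_ps = tick_ps, duration = duration,
         position = position, laser_power = laser_power,
         repeat_id = repeat_id),
    class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("<photon_trace> %d photons over %g s (%g ps/tick)\n",
              length(x$ticks), x$duration, x$tick_ps))
  if (!is.null(x$position)) cat(sprintf("  position: %g um\n", x$position))
  invisible(x)
}

#' Number of photons in a trace
#' @param trace a [photon_trace()].
#' @return integer photon count.
#' @export
n_photons <- function(trace) {
  stopifnot(inherits(trace, "photon_trace"))
  length(trace$ticks)
}

#' Photon arrival times in seconds
#' @param trace a [photon_trace()].
#' @return numeric vector of arrival times, seconds.
#' @export
timestamps <- function(trace) {
  stopifnot(inherits(trace, "photon_trace"))
  trace$ticks * (trace$tick_ps * 1e-12)
}

#' Seconds-per-tick resolution of a trace
#' @param trace a [photon_trace()].
#' @return seconds per tick.
#' @export
tick_resolution <- function(trace) trace$tick_ps * 1e-12

#' Read a photon timestamp file
#'
#' Two on-disk layouts are supported. The native CSV dialect stores one
#' integer tick per line with `#`-prefixed header lines carrying
#' `tick_ps`, `duration_s` and optionally `position_um`. The
#' photon-HDF5 layout (`/photon_data/timestamps` plus
#' `/photon_data/timestamps_specs/timestamps_unit`) is read through the
#' system `python` interpreter and its `h5py` module; it is read-only.
#'
#' Unsorted input is an error, never silently sorted: a non-monotone
#' file indicates corrupted acquisition, not a formatting quirk.
#'
#' @param path file path.
#' @param format `"csv-ticks"` (default) or `"photon-hdf5"`.
#' @return a [photon_trace()].
#' @export
read_timestamps <- function(path, format = c("csv-ticks", "photon-hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "photon-hdf5") return(read_photon_hdf5(path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  if (is.null(meta$tick_ps))
    stop("configuration error: header missing tick_ps")
  if (is.null(meta$duration_s))
    stop("configuration error: header missing duration_s")
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  ticks <- if (length(body)) as.numeric(body) else numeric(0)
  if (anyNA(ticks)) stop("data error: non-numeric tick entries")
  if (length(ticks) > 1 && any(diff(ticks) < 0)) {
    bad <- which(diff(ticks) < 0)[1] + 1L
    stop(sprintf("data error: non-monotone timestamps at index %d", bad))
  }
  photon_trace(ticks, tick_ps = meta$tick_ps, duration = meta$duration_s,
               position = meta$position_um)
}

read_photon_hdf5 <- function(path) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("configuration error: no python interpreter for photon-HDF5 input")
  script <- paste(
    "import sys, h5py",
    "f = h5py.File(sys.argv[1], 'r')",
    "ts = f['/photon_data/timestamps'][:]",
    "unit = float(f['/photon_data/timestamps_specs/timestamps_unit'][()])",
    "dur = float(f['/acquisition_duration'][()]) if 'acquisition_duration' in f else (ts[-1] * unit if len(ts) else 0.0)",
    "print(unit); print(dur)",
    "sys.stdout.writelines('%d\\n' % t for t in ts)",
    sep = "\n")
  out <- suppressWarnings(system2(py, c("-c", shQuote(script), shQuote(path)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("data error: failed to read photon-HDF5 file: %s",
                 paste(out, collapse = " ")))
  unit <- as.numeric(out[1])          # seconds per tick
  dur <- as.numeric(out[2])
  ticks <- if (length(out) > 2) as.numeric(out[-(1:2)]) else numeric(0)
  if (is.na(unit) || unit <= 0)
    stop("configuration error: photon-HDF5 file missing timestamps_unit")
  if (length(ticks) > 1 && any(diff(ticks) < 0)) {
    bad <- which(diff(ticks) < 0)[1] + 1L
    stop(sprintf("data error: non-monotone timestamps at index %d", bad))
  }
  photon_trace(ticks, tick_ps = unit * 1e12, duration = max(dur, unit * max(ticks, 0)))
}

#' Write a photon trace to the native CSV dialect
#'
#' @param trace a [photon_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timestamps <- function(trace, path) {
  stopifnot(inherits(trace, "photon_trace"))
  hdr <- c(sprintf("# tick_ps = %.10g", trace$tick_ps),
           sprintf("# duration_s = %.10g", trace$duration))
  if (!is.null(trace$position))
    hdr <- c(hdr, sprintf("# position_um = %.10g", trace$position))
  writeLines(c(hdr, sprintf("%.0f", trace$ticks)), path)
  invisible(path)
}

#' Bin a photon trace into fixed-width intervals
#'
#' Bins are half-open `[k*w, (k+1)*w)` with 0-based bin index `k`, so a
#' photon exactly on a boundary lands in the later bin and no photon is
#' double-counted. The number of bins is `ceiling(duration / bin_width)`
#' and total counts are conserved.
#'
#' @param trace a [photon_trace()].
#' @param bin_width bin width in seconds (default 1 ms, the bin time
#'   used for all displayed traces).
#' @return object of class `binned_trace` with fields `bin_width`,
#'   `counts`, `origin`.
#' @export
bin_trace <- function(trace, bin_width = 1e-3) {
  stopifnot(inherits(trace, "photon_trace"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("`bin_width` must be a positive number of seconds")
  n_bins <- as.integer(ceiling(trace$duration / bin_width))
  t <- timestamps(trace)
  idx <- floor(t / bin_width) + 1           # 1-based internally
  idx <- idx[idx >= 1 & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_width = bin_width, counts = counts, origin = 0),
            class = "binned_trace")
}

#' @export
print.binned_trace <- function(x, ...) {
  cat(sprintf("<binned_trace> %d bins of %g s, %d photons\n",
              length(x$counts), x$bin_width, sum(x$counts)))
  invisible(x)
}

#' Inter-photon times
#'
#' Successive differences of the arrival times. A trace with fewer than
#' two photons yields an empty vector (not an error): there is no gap
#' to measure.
#'
#' @param trace a [photon_trace()].
#' @return numeric vector of `n - 1` inter-photon times, seconds.
#' @export
interphoton_times <- function(trace) {
  stopifnot(inherits(trace, "photon_trace"))
  if (length(trace$ticks) < 2) return(numeric(0))
  diff(trace$ticks) * tick_resolution(trace)
}
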