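#' One step-scan across the separation chamber
#'
#' Runs the burst search on the trace recorded at each channel position
#' of a single scan repeat and packages per-position results. The mean
#' photon intensity per position (photons/s) is the total photon count
#' of the trace divided by its duration.
#'
#' @param positions channel coordinates, micrometres, strictly monotone.
#' @param traces list of [photon_trace()] objects, one per position.
#' @param params an [ipt_burst_params()] or [intensity_burst_params()];
#'   the latter bins each trace at `params$bin_width` first.
#' @param repeat_id integer repeat index.
#' @param flip if `TRUE`, positions are mirrored about their midpoint.
#'   Scan direction alternates between experimental campaigns; flipping
#'   re-expresses all scans with electrophoretic deflection increasing
#'   toward smaller coordinates.
#' @return object of class `scan_series` with per-position burst counts
#'   and intensities.
#' @export
scan_series <- function(positions, traces, params, repeat_id = 1L,
                        flip = FALSE) {
  if (length(positions) != length(traces))
    stop("one trace per position is required")
  if (length(positions) > 1 && !(all(diff(positions) > 0) || all(diff(positions) < 0)))
    stop("positions must be strictly monotone within one scan")
  if (flip) positions <- max(positions) + min(positions) - positions
  ord <- order(positions)
  positions <- positions[ord]
  traces <- traces[ord]
  counts <- integer(length(traces))
  intensity <- numeric(length(traces))
  burst_sets <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "photon_trace"))
    bs <- if (inherits(params, "intensity_burst_params")) {
      find_bursts_intensity(bin_trace(tr, params$bin_width), params)
    } else {
      find_bursts_ipt(tr, params)
    }
    burst_sets[[i]] <- bs
    counts[i] <- n_bursts(bs)
    intensity[i] <- n_photons(tr) / tr$duration
  }
  structure(list(positions = positions, counts = counts,
                 intensity = intensity, burst_sets = burst_sets,
                 repeat_id = repeat_id, params = params),
            class = "scan_series")
}

#' Construct an electropherogram from per-position summaries
#'
#' Low-level constructor for count/intensity profiles that did not come
#' through [scan_series()] (e.g. externally tabulated data). The
#' per-repeat matrices may be supplied for region integration; when
#' absent, the means are treated as a single repeat.
#'
#' @param positions channel coordinates, micrometres.
#' @param counts_mean,counts_sd per-position molecule counts (mean, SD).
#' @param intensity_mean,intensity_sd per-position photon intensity,
#'   photons/s (mean, SD).
#' @param counts_matrix,intensity_matrix optional positions x repeats
#'   matrices of per-repeat values.
#' @param n_repeats number of repeats the summaries came from.
#' @return object of class `electropherogram`.
#' @export
electropherogram <- function(positions, counts_mean,
                             counts_sd = rep(0, length(positions)),
                             intensity_mean = counts_mean,
                             intensity_sd = rep(0, length(positions)),
                             counts_matrix = matrix(counts_mean, ncol = 1),
                             intensity_matrix = matrix(intensity_mean, ncol = 1),
                             n_repeats = ncol(counts_matrix)) {
  n <- length(positions)
  lens <- c(length(counts_mean), length(counts_sd),
            length(intensity_mean), length(intensity_sd),
            nrow(counts_matrix), nrow(intensity_matrix))
  if (any(lens != n)) stop("arrays must be congruent in length")
  if (any(counts_sd < 0) || any(intensity_sd < 0))
    stop("standard deviations must be >= 0")
  structure(list(positions = positions, counts_mean = counts_mean,
                 counts_sd = counts_sd, intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd, n_repeats = n_repeats,
                 counts_matrix = counts_matrix,
                 intensity_matrix = intensity_matrix),
            class = "electropherogram")
}

#' Assemble repeats of a step scan into an electropherogram
#'
#' Computes per-position mean and standard deviation (sample, n - 1
#' denominator, matching "mean +/- SD of N repeats"; a single repeat
#' reports SD 0) of the digital molecule counts and of the mean photon
#' intensity across repeat scans sharing the same position grid.
#'
#' @param scans a list of [scan_series()] objects (or a single one).
#' @return object of class `electropherogram` with fields `positions`,
#'   `counts_mean`, `counts_sd`, `intensity_mean`, `intensity_sd`,
#'   `n_repeats`, and the per-repeat `counts_matrix` /
#'   `intensity_matrix` (positions x repeats) that region integration
#'   uses.
#' @export
assemble <- function(scans) {
  if (inherits(scans, "scan_series")) scans <- list(scans)
  stopifnot(length(scans) >= 1, all(vapply(scans, inherits, TRUE, "scan_series")))
  pos <- scans[[1]]$positions
  for (s in scans[-1]) {
    if (length(s$positions) != length(pos) ||
        any(abs(s$positions - pos) > 1e-9)) {
      bad <- if (length(s$positions) == length(pos))
        pos[abs(s$positions - pos) > 1e-9] else s$positions
      stop(sprintf("alignment error: scan position grids differ (offending positions: %s)",
                   paste(utils::head(signif(bad, 6), 5), collapse = ", ")))
    }
  }
  cm <- vapply(scans, function(s) as.numeric(s$counts), numeric(length(pos)))
  im <- vapply(scans, function(s) s$intensity, numeric(length(pos)))
  cm <- matrix(cm, nrow = length(pos))
  im <- matrix(im, nrow = length(pos))
  row_sd <- function(m) {
    if (ncol(m) < 2) return(rep(0, nrow(m)))
    apply(m, 1, stats::sd)
  }
  electropherogram(pos, rowMeans(cm), row_sd(cm), rowMeans(im), row_sd(im),
                   counts_matrix = cm, intensity_matrix = im,
                   n_repeats = length(scans))
}

#' @export
print.electropherogram <- function(x, ...) {
  cat(sprintf("<electropherogram> %d positions (%g..%g um), %d repeat(s)\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$n_repeats))
  invisible(x)
}

#' Integrate molecule counts over an elution region
#'
#' Sums per-position counts inside the half-open region
#' `[x_min, x_max)` separately for each repeat, then reports the mean
#' and sample SD across repeats — the digital molecule count
#' `n_bar +/- s` that the concentration conversion consumes.
#'
#' @param e an [assemble()]d electropherogram.
#' @param x_min,x_max region bounds in micrometres, `x_max > x_min`.
#' @return list with `n_mean`, `n_sd`, and the `per_repeat` sums.
#' @export
integrate_region <- function(e, x_min, x_max) {
  stopifnot(inherits(e, "electropherogram"))
  if (!(x_max > x_min)) stop("`x_max` must exceed `x_min`")
  sel <- e$positions >= x_min & e$positions < x_max
  if (!any(sel))
    stop("region error: no scan position falls inside the region")
  per_repeat <- colSums(e$counts_matrix[sel, , drop = FALSE])
  n_sd <- if (length(per_repeat) > 1) stats::sd(per_repeat) else 0
  list(n_mean = mean(per_repeat), n_sd = n_sd, per_repeat = per_repeat)
}

gauss2_model <- function(x, b, a1, c1, s1, a2, c2, s2) {
  b + a1 * exp(-(x - c1)^2 / (2 * s1^2)) + a2 * exp(-(x - c2)^2 / (2 * s2^2))
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
}

#' Decompose an electropherogram into two Gaussian peaks
#'
#' Nonlinear least-squares fit of a sum of two Gaussians plus a
#' constant baseline to either the count or the intensity channel.
#' Initialisation is deterministic and data-driven: peak centres start
#' at the two highest local maxima (leftmost wins ties; if only one
#' local maximum exists the second centre starts at the highest point
#' outside its neighbourhood), widths start at three grid spacings.
#' Peak areas (`amplitude * sigma * sqrt(2*pi)`) are normalised into
#' area fractions summing to 1, the quantity used to split a total
#' probe concentration into bound and free pools.
#'
#' @param e an [assemble()]d electropherogram.
#' @param channel `"counts"` or `"intensity"`.
#' @return list with `peaks` (data frame: center_um, width_um, area),
#'   `fractions` (length 2, sums to 1), `baseline`, `residual_norm`,
#'   `converged`.
#' @export
fit_two_gaussians <- function(e, channel = c("counts", "intensity")) {
  stopifnot(inherits(e, "electropherogram"))
  channel <- match.arg(channel)
  x <- e$positions
  y <- if (channel == "counts") e$counts_mean else e$intensity_mean
  if (sum(y > 0) < 6)
    stop("fit error: need at least 6 positions with signal")
  spacing <- stats::median(diff(x))
  lm_idx <- local_maxima(y)
  if (length(lm_idx) == 0) lm_idx <- which.max(y)
  lm_idx <- lm_idx[order(-y[lm_idx], x[lm_idx])]
  c1 <- x[lm_idx[1]]
  if (length(lm_idx) >= 2) {
    c2 <- x[lm_idx[2]]
  } else {
    far <- abs(x - c1) > 3 * spacing
    c2 <- if (any(far)) x[far][which.max(y[far])] else c1 + 3 * spacing
  }
  a1 <- max(y[which.min(abs(x - c1))] - min(y), 1e-12)
  a2 <- max(y[which.min(abs(x - c2))] - min(y), 1e-12)
  start <- list(b = min(y), a1 = a1, c1 = c1, s1 = 3 * spacing,
                a2 = a2, c2 = c2, s2 = 3 * spacing)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ gauss2_model(x, b, a1, c1, s1, a2, c2, s2),
      data = dat, start = start,
      lower = c(b = -Inf, a1 = 0, c1 = min(x), s1 = spacing / 10,
                a2 = 0, c2 = min(x), s2 = spacing / 10),
      upper = c(b = Inf, a1 = Inf, c1 = max(x), s1 = diff(range(x)),
                a2 = Inf, c2 = max(x), s2 = diff(range(x))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(err)
      stop(sprintf("fit error: two-Gaussian fit failed to converge (%s)",
                   conditionMessage(err))))
  cf <- stats::coef(fit)
  areas <- c(cf["a1"] * abs(cf["s1"]), cf["a2"] * abs(cf["s2"])) * sqrt(2 * pi)
  peaks <- data.frame(center_um = c(cf["c1"], cf["c2"]),
                      width_um = abs(c(cf["s1"], cf["s2"])),
                      area = as.numeric(areas))
  ord <- order(peaks$center_um)
  peaks <- peaks[ord, ]
  rownames(peaks) <- NULL
  fr <- peaks$area / sum(peaks$area)
  list(peaks = peaks, fractions = fr, baseline = as.numeric(cf["b"]),
       residual_norm = sqrt(sum(stats::resid(fit)^2)),
       converged = TRUE)
}

#' Write an electropherogram to CSV
#' @param e an electropherogram.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_electropherogram <- function(e, path) {
  stopifnot(inherits(e, "electropherogram"))
  utils::write.csv(
    data.frame(position_um = e$positions,
               counts_mean = e$counts_mean, counts_sd = e$counts_sd,
               intensity_mean_cps = e$intensity_mean,
               intensity_sd_cps = e$intensity_sd),
    path, row.names = FALSE)
  invisible(path)
}
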