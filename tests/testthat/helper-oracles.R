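# Independent oracles and fixture builders shared across tests.

# Unoptimised maximal-run scan for the IPT/photon-count burst search:
# walks the qualifying-gap sequence one element at a time.
brute_force_bursts <- function(trace, params) {
  res <- tick_resolution(trace)
  ticks <- trace$ticks
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_photons = integer(0))
  if (length(ticks) < 2) return(empty)
  ipt <- diff(ticks)
  f <- lee_filter(ipt, params$lee_window_n, params$lee_sigma0 / res)
  thr <- trunc(params$ipt_threshold / res)
  q <- f <= thr
  out <- list()
  i <- 1
  while (i <= length(q)) {
    if (q[i]) {
      j <- i
      while (j < length(q) && q[j + 1]) j <- j + 1
      if (j - i + 2 >= params$min_photons)
        out[[length(out) + 1]] <- c(i, j + 1, j - i + 2)
      i <- j + 1
    }
    i <- i + 1
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  data.frame(start_s = ticks[m[, 1]] * res, end_s = ticks[m[, 2]] * res,
             n_photons = as.integer(m[, 3]))
}

# Direct per-index evaluation of the Lee filter definition.
lee_filter_direct <- function(x, n, sigma0) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    w <- x[max(1, i - n):min(length(x), i + n)]
    m <- mean(w)
    v <- mean((w - m)^2)
    out[i] <- if (v + sigma0^2 > 0) m + (x[i] - m) * v / (v + sigma0^2) else x[i]
  }
  out
}

# Trace with deterministic photon times (seconds) on the 16-ps grid.
trace_at <- function(times_s, duration = max(times_s) + 1e-3) {
  photon_trace(round(times_s / 16e-12), tick_ps = 16, duration = duration)
}

# Events on a regular grid (guaranteed well-separated), Poisson photon
# counts, uniform emission over the transit window, optional Poisson
# background.
separated_events_trace <- function(n_events, brightness, transit,
                                   duration, background_rate = 0) {
  starts <- seq(0.1, duration - 0.1, length.out = n_events)
  nph <- stats::rpois(n_events, brightness)
  t <- unlist(mapply(function(a, k) sort(stats::runif(k, a, a + transit)),
                     starts, nph, SIMPLIFY = FALSE))
  if (background_rate > 0) {
    nb <- stats::rpois(1, background_rate * duration)
    t <- c(t, stats::runif(nb, 0, duration))
  }
  t <- sort(t)
  list(trace = photon_trace(floor(t / 16e-12), 16, duration),
       starts = starts, n_photons = nph)
}

# Intensity trace of an immigration-death occupancy process: arrivals
# at rate N / tau_res, exponential residence tau_res, photon rate eps
# per occupant. Occupancy is Poisson(N), so G(0+) = 1/N.
occupancy_trace <- function(N, tau_res, eps, duration) {
  arr <- stats::runif(stats::rpois(1, N / tau_res * duration), 0, duration)
  stay <- stats::rexp(length(arr), 1 / tau_res)
  nph <- stats::rpois(length(arr), eps * stay)
  ph <- sort(unlist(mapply(function(a, s, k) stats::runif(k, a, a + s),
                           arr, stay, nph, SIMPLIFY = FALSE)))
  ph <- ph[ph <= duration]
  photon_trace(floor(ph / 16e-12), 16, duration)
}

# Two-Gaussian profile on a scan grid as an electropherogram object.
gauss2_epherogram <- function(x, b, a1, c1, s1, a2, c2, s2) {
  y <- b + a1 * exp(-(x - c1)^2 / (2 * s1^2)) +
    a2 * exp(-(x - c2)^2 / (2 * s2^2))
  electropherogram(x, y)
}
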