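test_that("Lee filter matches its definition and limiting cases", {
  # constant signal: local variance 0, output pulled exactly to the mean
  expect_equal(lee_filter(rep(5, 5), 2, sigma0 = 1), rep(5, 5))
  # sigma0 -> 0: gain -> 1, filter is the identity
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(lee_filter(x, 2, sigma0 = 0), x)

  # hand-checkable spike, n = 1, sigma0 = 1, against direct evaluation
  spike <- c(0, 0, 10, 0, 0)
  expect_equal(lee_filter(spike, 1, 1), lee_filter_direct(spike, 1, 1))
  # frozen values from the definition: m = 10/3, v = 200/9 at the spike
  expect_equal(lee_filter(spike, 1, 1)[3],
               10 / 3 + (10 - 10 / 3) * (200 / 9) / (200 / 9 + 1))

  # random series, several window sizes, against the direct oracle
  set.seed(1)
  for (n in c(1, 4, 7)) {
    y <- rexp(300, 1 / 50)
    expect_equal(lee_filter(y, n, 25), lee_filter_direct(y, n, 25))
  }
  expect_error(lee_filter(x, 0, 1), "window_n")
})

test_that("IPT burst search counts photons, not gaps", {
  p <- ipt_burst_params(100e-6, 7)
  # 10 photons spaced 10 us: every gap qualifies, one burst of 10
  tr <- trace_at(seq(0, 90e-6, by = 10e-6))
  bs <- find_bursts_ipt(tr, p)
  expect_equal(n_bursts(bs), 1L)
  expect_equal(bs$bursts$n_photons, 10L)
  expect_equal(bs$bursts$start_s, 0)
  expect_equal(bs$bursts$end_s, 90e-6)

  # 6 photons: below the 7-photon minimum, no burst
  tr6 <- trace_at(seq(0, 50e-6, by = 10e-6))
  expect_equal(n_bursts(find_bursts_ipt(tr6, p)), 0L)

  # exactly 7 photons = 6 qualifying gaps: emitted
  tr7 <- trace_at(seq(0, 60e-6, by = 10e-6))
  expect_equal(find_bursts_ipt(tr7, p)$bursts$n_photons, 7L)

  # empty trace is fine
  empty <- photon_trace(numeric(0), duration = 1)
  expect_equal(n_bursts(find_bursts_ipt(empty, p)), 0L)
})

test_that("optimised IPT search equals the brute-force run scan", {
  p5 <- ipt_burst_params(5e-6, 30)
  p100 <- ipt_burst_params(100e-6, 7)
  for (s in 1:25) {
    sim <- simulate_trace(1000, 5, 40, 1e-3, 8, seed = s)
    for (p in list(p5, p100)) {
      bs <- find_bursts_ipt(sim$trace, p)
      bf <- brute_force_bursts(sim$trace, p)
      expect_equal(nrow(bf), n_bursts(bs))
      expect_equal(bf$start_s, bs$bursts$start_s)
      expect_equal(bf$end_s, bs$bursts$end_s)
      expect_equal(bf$n_photons, bs$bursts$n_photons)
    }
  }
})

test_that("burst count is monotone in min_photons and in the IPT threshold", {
  # min_photons sweep: runs are fixed, emission is a pure >= M filter
  sim <- simulate_trace(2000, 8, 30, 0.5e-3, 6, seed = 42)
  counts_m <- sapply(c(5, 10, 20, 30, 50), function(m)
    n_bursts(find_bursts_ipt(sim$trace, ipt_burst_params(50e-6, m))))
  expect_true(all(diff(counts_m) <= 0))
  # threshold sweep with the filter noise scale held fixed and events
  # too far apart to merge: qualification only grows with the threshold
  set.seed(43)
  sep <- separated_events_trace(25, 40, 2e-4, 6, background_rate = 1000)
  # with min_photons above half the per-event yield an event yields at
  # most one qualifying fragment, so bursts can only be added
  counts_t <- sapply(c(2e-6, 5e-6, 10e-6, 25e-6), function(thr)
    n_bursts(find_bursts_ipt(sep$trace,
                             ipt_burst_params(thr, 30, lee_sigma0 = 5e-6))))
  expect_true(all(diff(counts_t) >= 0))
})

test_that("splitting a trace at a long gap preserves the burst set", {
  set.seed(3)
  ev <- separated_events_trace(10, 40, 0.5e-3, 5, background_rate = 200)
  p <- ipt_burst_params(100e-6, 7)
  whole <- find_bursts_ipt(ev$trace, p)

  ts <- timestamps(ev$trace)
  ipt <- interphoton_times(ev$trace)
  cut_idx <- which.max(ipt)          # longest gap, >> threshold here
  expect_gt(ipt[cut_idx], 100e-6)
  cut_t <- ts[cut_idx] + ipt[cut_idx] / 2
  left <- trace_at(ts[ts < cut_t], duration = ev$trace$duration)
  right_t <- ts[ts >= cut_t]
  right <- photon_trace(round((right_t - right_t[1]) / 16e-12), 16,
                        duration = ev$trace$duration)
  halves <- rbind(find_bursts_ipt(left, p)$bursts,
                  transform(find_bursts_ipt(right, p)$bursts,
                            start_s = start_s + right_t[1],
                            end_s = end_s + right_t[1]))
  expect_equal(nrow(halves), n_bursts(whole))
  expect_equal(halves$n_photons, whole$bursts$n_photons)
  expect_equal(halves$start_s, whole$bursts$start_s, tolerance = 1e-9)
})

test_that("well-separated injected bursts are each recovered exactly once", {
  set.seed(8)
  ev <- separated_events_trace(20, 50, 5e-5, 10)
  bs <- find_bursts_ipt(ev$trace, ipt_burst_params(5e-6, 30))
  expect_equal(n_bursts(bs), 20L)
  # each detected burst window sits inside one injected event window
  hits <- findInterval(bs$bursts$start_s, ev$starts)
  expect_equal(sort(unique(hits)), 1:20)

  with_bg <- separated_events_trace(20, 60, 0.5e-3, 10, background_rate = 500)
  bs2 <- find_bursts_ipt(with_bg$trace, ipt_burst_params(100e-6, 7))
  expect_equal(n_bursts(bs2), 20L)
})

test_that("intensity threshold search applies the per-trace 5-SD rule", {
  # all bins equal: SD 0, threshold = mean, nothing strictly above it
  flat <- structure(list(bin_width = 1e-3, counts = rep(7L, 100), origin = 0),
                    class = "binned_trace")
  expect_equal(n_bursts(find_bursts_intensity(flat)), 0L)

  set.seed(21)
  counts <- rpois(1000, 10)
  spikes <- c(100, 300, 500, 700, 900)
  counts[spikes] <- 200L
  bt <- structure(list(bin_width = 1e-3, counts = counts, origin = 0),
                  class = "binned_trace")
  bs <- find_bursts_intensity(bt, intensity_burst_params(sd_multiplier = 5))
  # direct threshold-scan oracle
  thr <- mean(counts) + 5 * sd(counts)
  runs <- rle(counts > thr)
  expect_equal(n_bursts(bs), sum(runs$values))
  expect_equal(n_bursts(bs), 5L)
  expect_equal(bs$bursts$start_s, (spikes - 1) * 1e-3)
  expect_equal(bs$bursts$end_s, spikes * 1e-3)
  expect_equal(bs$bursts$n_photons, rep(200L, 5))
  expect_equal(bs$bursts$peak_bin_count, rep(200L, 5))

  # default parameters encode the 5-SD-above-mean rule on 1-ms bins
  d <- intensity_burst_params()
  expect_equal(d$sd_multiplier, 5)
  expect_equal(d$bin_width, 1e-3)

  one_bin <- structure(list(bin_width = 1e-3, counts = 3L, origin = 0),
                       class = "binned_trace")
  expect_error(find_bursts_intensity(one_bin), "2 bins")
})

test_that("burst intensity summaries use a sort-robust median", {
  mk <- function(nph) {
    structure(list(bursts = data.frame(start_s = seq_along(nph),
                                       end_s = seq_along(nph) + 0.1,
                                       n_photons = as.integer(nph)),
                   source_duration = 10, params = NULL),
              class = "burst_set")
  }
  s <- burst_intensity_summary(mk(c(1, 2, 3)))
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)
  expect_equal(burst_intensity_summary(mk(7))$median, 7)

  set.seed(4)
  big <- rpois(1e4, 50)
  expect_equal(burst_intensity_summary(mk(big))$median,
               sort(big)[c(5000, 5001)] |> mean())

  e <- burst_intensity_summary(mk(integer(0)))
  expect_equal(e$count, 0L)
  expect_true(is.na(e$median))
})
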