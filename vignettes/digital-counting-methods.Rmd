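---
title: "Digital single-molecule counting for free-flow electrophoresis step scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital single-molecule counting for free-flow electrophoresis step scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digicount)
```

## The measurement this package models

A surface-free digital immunosensor couples microchip free-flow
electrophoresis (FFE) with confocal single-molecule detection. A sample
containing a fluorescently labelled affinity probe (typically an
aptamer) and its protein target flows through a shallow separation
chamber; an electric field perpendicular to the flow deflects species
according to their electrophoretic mobility, so probe–target complexes
separate laterally from unbound probe within seconds. A confocal volume
is stepped across the chamber and, at each position, the photon
arrival-time trace is searched for bursts — clusters of photons emitted
by one molecule (or particle) transiting the detection volume. Counting
bursts position-by-position yields an *electropherogram* of digital
molecule counts versus deflection coordinate, and the counts convert to
an absolute number concentration with no calibration curve.

`digicount` implements that full analysis chain plus the binding
arithmetic built on top of it, the FCS calibration of the confocal
volume, and a seeded synthetic-data generator so that every stage is
testable without instrument data.

## Burst detection

### Combined inter-photon-time / photon-count search

Within a burst, photons arrive much faster than background, so the
inter-photon times (IPTs) drop by an order of magnitude. The search
declares a burst wherever a maximal run of consecutive photons has
every (filtered) IPT at or below a threshold, and keeps runs with at
least *M* photons. Two operating points are in routine use: 100 µs /
7 photons for small, bright complexes against low background, and
5 µs / 30 photons for large, intense particles (fibrils, oligomers,
exosomes) against elevated background.

Three decisions here are worth making explicit:

* **Photons, not gaps.** "At least *M* photons with short IPTs" is
  interpreted as a run of ≥ *M* photons, i.e. ≥ *M* − 1 consecutive
  qualifying gaps. Photon-count thresholds in the burst-search
  literature count photons, and the `n_photons` of an emitted burst is
  then directly the burst intensity used downstream.
* **Tick-exact comparisons.** Timestamps are stored as integer ticks of
  the 16-ps acquisition clock, the IPT threshold is truncated toward
  zero into ticks, and all comparisons happen on that grid. Results are
  therefore bit-stable under file round trips.
* **Qualification is `<=`, intensity bins are `>`.** The IPT test is
  inclusive; the binned intensity test below is strict, so a degenerate
  all-equal trace yields zero intensity bursts rather than one
  trace-long burst.

### Lee filter

Before thresholding, the IPT sequence is smoothed with a Lee filter of
half-window *n* = 4: with running mean $\bar m_i$ and running
population variance $\sigma_i^2$ over the truncated window of
$2n + 1$ samples,

$$\hat x_i = \bar m_i + (x_i - \bar m_i)\,
  \frac{\sigma_i^2}{\sigma_i^2 + \sigma_0^2}.$$

Regions of constant signal (low local variance) are pulled to their
local mean — suppressing the occasional long gap inside an otherwise
dense burst — while edges, where the local variance is large, pass
through almost unchanged. The noise scale $\sigma_0$ is not fixed by
any published analysis we are aware of; the default is
`ipt_threshold / 2`, which smooths within-burst IPT jitter (a few µs at
these photon rates) without dragging multi-millisecond background gaps
below threshold. It is an explicit parameter of
`ipt_burst_params()` and every property we test is robust to moderate
changes in it.

### Binned intensity-threshold search

Condensate-type samples ride on a bulk fluorescence background (e.g.
monomer-bound probe), which defeats the IPT criterion. There the trace
is binned at 1 ms and a burst is a maximal run of bins whose count
strictly exceeds a threshold *unique to that trace*: the mean plus 5
standard deviations of all its bin counts. The burst spans exactly the
above-threshold bins (no shoulder extension); extension would add a
parameter without changing counts, which is the quantity used
downstream. The filter is not applied to binned counts — the 5-SD rule
operates on raw bins.

## Electropherograms

`scan_series()` runs the burst search at every position of one scan
repeat; `assemble()` aligns repeats on a shared position grid and
reports per-position means and standard deviations (sample SD,
$n - 1$, matching "mean ± SD of *N* = 3 repeats"; a single repeat
reports SD 0). Scan direction can alternate between campaigns, so
`scan_series(flip = TRUE)` mirrors coordinates to keep deflection
increasing toward smaller positions consistently.

`integrate_region()` sums counts over a half-open region
$[x_{\min}, x_{\max})$ *per repeat* and only then averages, so the
reported SD reflects repeat-to-repeat scatter of the physically
meaningful total. Half-open bounds make region partitions exactly
additive.

`fit_two_gaussians()` decomposes a profile into two Gaussian peaks plus
a constant baseline by Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`). Initialisation is deterministic and data-driven:
centres at the two highest local maxima (leftmost wins ties; with a
single maximum the second centre starts at the highest point outside
its 3-step neighbourhood), widths at three grid spacings. Peak areas
($a\,\sigma\sqrt{2\pi}$) are normalised to area fractions, the
quantity that splits a known total probe concentration into bound and
free pools. Non-convergence raises an error carrying diagnostics;
defaults are never silently returned.

## From counts to concentrations

A count of $\bar n$ molecules in traces of duration $t$ samples only
the confocal cross-section $\tfrac{\pi}{4} z w$ of one scan step
$h \cdot d_\mathrm{step}$ of the chamber cross-section, so the total
molecular flux through the device is

$$F_\mathrm{total} = \frac{\bar n}{t}\cdot
  \frac{h\, d_\mathrm{step}}{\tfrac{\pi}{4} z w},$$

and with a volumetric sample flow rate $Q$ the number concentration is
$c = F_\mathrm{total} / (N_A Q)$. Defaults for the device geometry are
$h = 28$ µm, $d_\mathrm{step} = 31.7$ µm, and effective confocal
cross-section values $z = 3$ µm, $w = 0.4$ µm.

Numerical choices:

* $N_A$ is the exact SI value 6.02214076 × 10²³; worked examples
  historically printed with 6.02 × 10²³ differ by 0.04%, far below the
  repeat scatter.
* Uncertainty is propagated first-order from the count SD only; the
  geometry is treated as exact, because reported uncertainties derive
  from repeat counts.
* Background subtraction (`net_count()`) combines sample and control
  SDs in quadrature; a negative net count — the control can exceed the
  sample by counting noise — clamps to zero with a warning flag rather
  than erroring.
* `count_to_concentration()` exposes a `recovery_factor` (default 1)
  for device variants in which only a known fraction of large analytes
  stays in the counted sample stream (an on-chip desalting module
  retains about 70% of particles above ~10 nm radius). Published
  concentrations for assays run on such variants are not reproducible
  from the raw flux equations alone, and no correction value is
  guessed here; the factor is configuration.

The binding arithmetic layered on top is deliberately plain
mass-action algebra: `target_from_equilibrium()` back-calculates the
free target as $K_d\, c_\mathrm{complex} / c_\mathrm{free}$;
`binding_site_concentration()` evaluates
$(c_\mathrm{complex}/c_\mathrm{free})(K_d + c_\mathrm{free})$;
`valency_from_intensities()` takes the ratio of *median* burst
intensities (the median resists the heavy right tail of
burst-intensity distributions); condensate metrics follow from sphere
volumes ($\phi = c N_A \tfrac{4}{3}\pi r^3$), phase scaling
($c_\mathrm{dense} = c_\mathrm{in} / \phi$) and molar mass
($\rho = c_\mathrm{dense} M_w$, molar × g/mol ≡ mg/mL exactly).

One arithmetic caveat is documented rather than reproduced: a
published protein/RNA ratio of "40" for condensates is inconsistent
with its own inputs (1414.6 nM / 3.5 nM ≈ 404); the package returns
the computed ratio.

## The 1:1 binding model

`solve_equilibrium()` solves $K_d\,[PA] = [P][A]$ under mass
conservation. The complex is the physical root of
$[PA]^2 - (P + A + K_d)[PA] + PA = 0$, computed in the product form
$2PA / (b + \sqrt{b^2 - 4PA})$ that avoids cancellation in the
quantitative-capture limit. The free species are *not* obtained by
subtraction (which cancels catastrophically when nearly everything is
bound) but from their own quadratics with the root branch chosen by the
sign of the linear coefficient. Conservation and mass action then both
close to better than 10⁻¹⁰ relative across fifteen orders of magnitude
of inputs, which the test suite verifies on 10⁵ random triples.

`dissociation_survival()` models washout as irreversible first-order
decay, $\exp(-k_\mathrm{off} t)$ with
$k_\mathrm{off} = K_d k_\mathrm{on}$. The association rate constant has
**no default**: published figures built on such simulations have
quoted $k_\mathrm{on} = 10^{-4}\,\mathrm{M^{-1}s^{-1}}$, which is
physically implausible (diffusion-limited association is ~10⁹, typical
aptamer–protein rates 10⁴–10⁶) and inconsistent with the dissociation
percentages quoted alongside it; the likely intended value is 10⁴.
Forcing the caller to state $k_\mathrm{on}$ keeps that ambiguity out of
the package.

## FCS calibration of the confocal volume

`autocorrelate()` computes the normalised intensity autocorrelation
$G(\tau) = \langle\delta I(t)\,\delta I(t+\tau)\rangle / \langle
I\rangle^2$ by uniform fine binning (a quarter of the smallest
requested lag by default) with symmetric normalisation over the
overlapping segments. `fit_diffusion_model()` fits the single-species
3D diffusion model

$$G(\tau) = \frac{1}{N}\left(1 + \frac{\tau}{\tau_D}\right)^{-1}
  \left(1 + \frac{\tau}{\kappa^2 \tau_D}\right)^{-1/2}$$

with weights $1/G^2$ (relative least squares, matching the
multiplicative noise of measured correlation curves), then converts via
the calibrant's known diffusion coefficient:
$w_0 = \sqrt{4 D \tau_D}$ (lateral $1/e^2$ radius convention),
$z_0 = \kappa w_0$, $V_\mathrm{eff} = \pi^{3/2} w_0^2 z_0$. No
triplet-state term is included; at the microsecond-and-longer lags
used for volume calibration its omission is benign, and adding it
would trade bias for variance on noiseless synthetic curves.

The fitted shape parameters and the effective cross-section values
$(z, w)$ used in the flux equation are kept as *independent*
device-level quantities. A calibration reporting
$V_\mathrm{eff} = 4.2$ fL and $\kappa = 6.0$ is not numerically
consistent with $z = 3$ µm and $w = 0.4$ µm under any single
convention ($z/w = 7.5 \ne 6.0$); both representations are retained
without forcing a reconciliation, and the flux equation always takes
its cross-section from `experiment_geometry`.

## The synthetic-data generator

`simulate_trace()` merges homogeneous Poisson background photons with
transit events: event starts form a Poisson process, each event emits
Poisson-distributed photons uniformly over its transit window
(rectangular profile — burst detection at the operating settings is
insensitive to profile shape, and a Gaussian profile is a pluggable
refinement that would change nothing the tests measure). The
ground-truth event list is returned, and output is bit-reproducible
per seed.

`simulate_scan()` builds a full step-scan experiment: each species'
elution profile is a Gaussian over the position grid (centre given
directly or as mobility × field × residence time), and the
per-position event rate inverts the flux relation above so that the
analysis pipeline applied to the simulated traces recovers the input
concentration within Poisson error. The default study conditions used
throughout the tests mirror the validation assay: 25 pM of a single
bright species, 70 µL/h sample flow, 5-s traces on a 31.7-µm grid,
500 s⁻¹ background, ~40 photons per transit, and a 0.1-ms transit
time (a 0.4-µm detection width traversed at the mm/s chamber flow
speeds of this device class).

What the generator emulates — Poisson counting statistics,
burst/background IPT contrast, mobility-dependent elution positions,
repeat-to-repeat scatter — is what the pipeline's correctness depends
on. What it does not emulate: diffusion-shaped intensity profiles,
detector dead time and afterpulsing, polydisperse brightness,
electro-osmotic drift, Joule heating, or field-efficiency calibration
(the simulator takes the *effective* field directly). Closed-loop
recovery on synthetic scans therefore validates the analysis
arithmetic and detection logic, not instrument physics: passing tests
say the pipeline is unbiased for data matching its model, which real
traces approximate but do not equal. One residual model effect is
visible in the tests themselves: two transits overlapping in time
merge into one burst, so recovered counts run a few tenths of a
percent low at the default rates — well inside the Poisson scatter the
acceptance check allows.

## Problem sizes and runtime choices

The test suite runs entirely on synthetic data generated at test time:
burst-search equivalence against a brute-force oracle on 100 traces of
≤ 10⁴ photons; closed-loop concentration recovery over 50 seeded
scan experiments (3 repeats × 31 positions × 5 s each); FCS recovery
on 100 noisy replicates; and 10⁵ random triples for the equilibrium
solver. These sizes keep the whole suite under a minute on one core
while leaving every statistical bound comfortably resolvable.

## Known limitations

* The IPT search assumes the background is sparse at the threshold
  scale; at background rates approaching `1 / ipt_threshold` the
  false-positive rate rises steeply and the intensity search is the
  better tool.
* Burst-count monotonicity in the IPT threshold holds per event only
  while `min_photons` exceeds half the per-event photon yield;
  below that, a single transit can fragment into several qualifying
  runs at small thresholds.
* `fit_two_gaussians()` is exactly what it says: profiles with three
  or more species need a different model, and none is provided.
* Photon-HDF5 input is read through the system Python interpreter's
  `h5py`; environments without one must use the native CSV dialect.
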