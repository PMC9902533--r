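#' Avogadro constant (exact SI), molecules per mole
#' @export
N_AVOGADRO <- 6.02214076e23

#' Device and acquisition geometry for digital quantification
#'
#' Everything the flux and concentration conversions need: the
#' fabricated chamber height `h`, the step size `d_step` of the
#' confocal scan, the effective height `z` and width `w` of the
#' confocal detection cross-section, the sample flow rate and the trace
#' duration recorded at each position.
#'
#' @param h_um chamber height, micrometres (device default 28).
#' @param d_step_um scan step size, micrometres (default 31.7).
#' @param z_um confocal detection height, micrometres (default 3).
#' @param w_um confocal detection width, micrometres (default 0.4).
#' @param Q_sample_uL_h sample flow rate, microlitres per hour.
#' @param t_s trace duration per scan position, seconds.
#' @return object of class `experiment_geometry`.
#' @export
experiment_geometry <- function(h_um = 28, d_step_um = 31.7, z_um = 3,
                                w_um = 0.4, Q_sample_uL_h, t_s) {
  vals <- c(h = h_um, d_step = d_step_um, z = z_um, w = w_um,
            Q = Q_sample_uL_h, t = t_s)
  if (anyNA(vals) || any(vals <= 0))
    stop("configuration error: all geometry fields must be strictly positive")
  structure(as.list(vals), class = "experiment_geometry")
}

#' Background-corrected molecule count
#'
#' Difference between the digital counts of a sample and its
#' probe-only control over the same region and duration, with the
#' repeat SDs combined in quadrature. A negative difference (control
#' exceeding sample by counting noise) is clamped to zero and flagged.
#'
#' @param n_sample,n_control mean molecule counts.
#' @param sd_sample,sd_control their SDs across repeats (default 0).
#' @return list with `n`, `sd`, `clamped`.
#' @examples
#' net_count(2391, 37, 789, 30) # ~1602 +/- 48 complexes
#' @export
net_count <- function(n_sample, sd_sample = 0, n_control, sd_control = 0) {
  d <- n_sample - n_control
  clamped <- d < 0
  if (clamped) warning("control count exceeds sample count; clamping to 0")
  list(n = max(d, 0), sd = sqrt(sd_sample^2 + sd_control^2),
       clamped = clamped)
}

#' Total molecular flux through the device
#'
#' Scales the molecules counted in the scanned confocal cross-sections
#' up to the full chamber cross-section:
#' `F = (n / t) * (h * d_step) / ((pi/4) * z * w)`.
#' The elliptical factor `(pi/4) z w` is the effective confocal
#' detection cross-section; `h * d_step` is the chamber cross-section
#' sampled by one scan step.
#'
#' @param n_complex background-corrected molecule count over the
#'   integration region (molecules per trace duration).
#' @param geom an [experiment_geometry()].
#' @return flux in molecules per second.
#' @export
total_flux <- function(n_complex, geom) {
  stopifnot(inherits(geom, "experiment_geometry"))
  (n_complex / geom$t) * (geom$h * geom$d_step) / ((pi / 4) * geom$z * geom$w)
}

#' Number concentration from molecular flux
#'
#' `c = F / (N_A * Q)` with the flow rate converted from uL/h to L/s.
#'
#' @param F_total flux, molecules per second.
#' @param Q_sample_uL_h sample flow rate, microlitres per hour.
#' @return concentration in molar.
#' @export
number_concentration <- function(F_total, Q_sample_uL_h) {
  if (!is.numeric(Q_sample_uL_h) || Q_sample_uL_h <= 0)
    stop("`Q_sample_uL_h` must be > 0")
  Q_L_s <- Q_sample_uL_h * 1e-6 / 3600
  F_total / (N_AVOGADRO * Q_L_s)
}

#' Digital count to absolute concentration
#'
#' Convenience chain [total_flux()] then [number_concentration()],
#' with first-order propagation of the count SD (geometry treated as
#' exact, matching how the repeat scatter dominates the reported
#' uncertainty). An optional `recovery_factor` divides the result for
#' device variants where only a known fraction of large analytes
#' remains in the counted sample stream (e.g. on-chip desalting);
#' default 1 (no correction).
#'
#' @param n_complex molecule count (mean over repeats).
#' @param geom an [experiment_geometry()].
#' @param n_sd SD of the count across repeats (default 0).
#' @param recovery_factor fraction of analyte retained in the sample
#'   stream, in (0, 1]; default 1.
#' @return list with `n_complex`, `F_total`, `concentration` (molar)
#'   and `sd` (molar).
#' @export
count_to_concentration <- function(n_complex, geom, n_sd = 0,
                                   recovery_factor = 1) {
  if (recovery_factor <= 0 || recovery_factor > 1)
    stop("`recovery_factor` must be in (0, 1]")
  F_total <- total_flux(n_complex, geom)
  conc <- number_concentration(F_total, geom$Q) / recovery_factor
  sd <- if (n_complex > 0) conc * n_sd / n_complex else
    number_concentration(total_flux(n_sd, geom), geom$Q) / recovery_factor
  list(n_complex = n_complex, F_total = F_total,
       concentration = conc, sd = sd)
}

#' Back-calculate target concentration from the binding equilibrium
#'
#' For a 1:1 probe-target equilibrium measured far below saturation,
#' the free-target concentration follows from the measured complex and
#' the known affinity: `c_free_probe = c_probe_total - valency *
#' c_complex`, `c_target_free = K_d * c_complex / c_free_probe`, and
#' the total target adds back the bound pool.
#'
#' @param c_complex measured probe-target complex concentration, molar.
#' @param c_probe_total total probe concentration, molar.
#' @param K_d dissociation constant, molar.
#' @param valency probes bound per target (default 1; multivalent
#'   targets pass their measured valency).
#' @return list with `c_free_probe`, `c_target_free`, `c_target_total`
#'   (molar).
#' @export
target_from_equilibrium <- function(c_complex, c_probe_total, K_d,
                                    valency = 1) {
  c_free <- c_probe_total - valency * c_complex
  if (c_free <= 0)
    stop("infeasibility error: bound probe exceeds total probe")
  c_target_free <- K_d * c_complex / c_free
  list(c_free_probe = c_free, c_target_free = c_target_free,
       c_target_total = c_target_free + c_complex)
}

#' Binding-site concentration from bound and free probe
#'
#' `c_sites = (c_complex / c_free) * (K_d + c_free)`: the total
#' concentration of probe binding sites on the analyte implied by the
#' occupancy at equilibrium.
#'
#' @param c_complex bound-probe concentration, molar.
#' @param c_free_probe free-probe concentration, molar (> 0).
#' @param K_d dissociation constant, molar.
#' @return binding-site concentration, molar.
#' @export
binding_site_concentration <- function(c_complex, c_free_probe, K_d) {
  if (!is.numeric(c_free_probe) || any(c_free_probe <= 0))
    stop("`c_free_probe` must be > 0")
  (c_complex / c_free_probe) * (K_d + c_free_probe)
}

#' Binding sites per particle
#' @param c_sites binding-site concentration, molar.
#' @param c_particles particle concentration, molar.
#' @return average sites per particle.
#' @export
sites_per_particle <- function(c_sites, c_particles) {
  if (any(c_particles <= 0)) stop("`c_particles` must be > 0")
  c_sites / c_particles
}

#' Valency / stoichiometry from burst-intensity ratio
#'
#' Ratio of the median burst intensity of the probe-analyte complex to
#' that of the free probe: the average number of probes per detected
#' particle (aptamers per oligomer, per exosome, per condensate, ...).
#'
#' @param I_complex_median median photons per burst of the complex.
#' @param I_free_median median photons per burst of the free probe
#'   (> 0).
#' @return intensity ratio (probes per particle).
#' @export
valency_from_intensities <- function(I_complex_median, I_free_median) {
  if (!is.numeric(I_free_median) || any(I_free_median <= 0))
    stop("`I_free_median` must be > 0")
  I_complex_median / I_free_median
}

#' Condensate volume fraction
#'
#' `phi = c * N_A * (4/3) * pi * r^3` assuming spherical particles of
#' mean radius `r`.
#'
#' @param c_particles particle number concentration, molar.
#' @param radius_m mean particle radius, metres.
#' @return list with `phi` (dimensionless) and `clipped` (`TRUE` if the
#'   nominal value exceeded 1 and was reported clipped).
#' @export
condensate_volume_fraction <- function(c_particles, radius_m) {
  if (!is.numeric(radius_m) || any(radius_m <= 0))
    stop("`radius_m` must be > 0")
  v_m3 <- (4 / 3) * pi * radius_m^3
  per_L <- c_particles * N_AVOGADRO            # particles per litre
  phi <- per_L * v_m3 * 1e3                    # 1 L = 1e-3 m^3
  clipped <- phi > 1
  list(phi = min(phi, 1), clipped = clipped)
}

#' Dense-phase concentration and mass density
#'
#' Scales a per-total-volume species concentration inside particles up
#' to the dense phase: `c_dense = c_in_particles / phi`; the mass
#' density is `c_dense * M_w` (molar times g/mol gives g/L, i.e.
#' mg/mL).
#'
#' @param c_species_in_particles species concentration attributed to
#'   the particles, molar (per total sample volume).
#' @param phi particle volume fraction, in (0, 1].
#' @param M_w molecular weight, g/mol.
#' @return list with `c_dense` (molar) and `mass_density_mg_mL`.
#' @export
dense_phase_concentration <- function(c_species_in_particles, phi, M_w) {
  if (!is.numeric(phi) || any(phi <= 0) || any(phi > 1))
    stop("`phi` must be in (0, 1]")
  c_dense <- c_species_in_particles / phi
  list(c_dense = c_dense, mass_density_mg_mL = c_dense * M_w)
}

#' Partition fractions of a probe into particles
#'
#' Share of the probe inside particles relative to the free pool and
#' to the total pool, in percent.
#'
#' @param c_probe_in_particles probe inside particles, molar.
#' @param c_free_probe free probe, molar (> 0).
#' @param c_probe_total total probe, molar (> 0).
#' @return list with `fraction_of_free_pct`, `fraction_of_total_pct`.
#' @export
partition_fractions <- function(c_probe_in_particles, c_free_probe,
                                c_probe_total) {
  if (any(c_free_probe <= 0) || any(c_probe_total <= 0))
    stop("denominators must be > 0")
  list(fraction_of_free_pct = 100 * c_probe_in_particles / c_free_probe,
       fraction_of_total_pct = 100 * c_probe_in_particles / c_probe_total)
}
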