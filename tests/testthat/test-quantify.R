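pM <- 1e-12
nM <- 1e-9

test_that("background subtraction combines repeat SDs in quadrature", {
  # streptavidin worked chain: 2391 +/- 37 minus 789 +/- 30
  r <- net_count(2391, 37, 789, 30)
  expect_equal(r$n, 1602)
  expect_equal(r$sd, sqrt(37^2 + 30^2), tolerance = 1e-12)
  expect_equal(r$sd, 47.63402, tolerance = 1e-6)
  expect_false(r$clamped)

  expect_equal(net_count(100, 5, 100, 5)$n, 0)

  r2 <- net_count(2847, 62, 856, 29)
  expect_equal(r2$n, 1991)
  expect_equal(r2$sd, sqrt(62^2 + 29^2))

  expect_warning(r3 <- net_count(50, 5, 80, 5), "clamping")
  expect_equal(r3$n, 0)
  expect_true(r3$clamped)
})

test_that("flux and concentration conversion reproduce the printed chain", {
  g <- experiment_geometry(h_um = 28, d_step_um = 31.7, z_um = 3, w_um = 0.4,
                           Q_sample_uL_h = 70, t_s = 5)
  F <- total_flux(1601, g)
  expect_equal(F, 298000, tolerance = 0.02)
  expect_equal(total_flux(0, g), 0)

  # geometry whose cross-section factor is 1: F = n / t
  g1 <- experiment_geometry(h_um = 1, d_step_um = pi / 4, z_um = 1, w_um = 1,
                            Q_sample_uL_h = 70, t_s = 5)
  expect_equal(total_flux(10, g1), 2)

  c1 <- number_concentration(F, 70)
  expect_equal(c1 / pM, 25.5, tolerance = 0.02)
  expect_equal(number_concentration(0, 70), 0)
  # inverse identity: F = N_A * (1 pM) * Q returns exactly 1 pM
  Q_L_s <- 70e-6 / 3600
  expect_equal(number_concentration(N_AVOGADRO * pM * Q_L_s, 70), pM)
  expect_error(number_concentration(1, 0), "Q_sample")

  # linearity
  expect_equal(total_flux(3202, g), 2 * F)
  expect_equal(number_concentration(2 * F, 70), 2 * c1)
  expect_equal(number_concentration(F, 140), c1 / 2)

  q <- count_to_concentration(1601, g, n_sd = 48)
  expect_equal(q$concentration, c1)
  expect_equal(q$sd / q$concentration, 48 / 1601)
})

test_that("equilibrium back-calculation recovers the target concentration", {
  # IgE: 21.7 pM complex, 50 pM probe, K_d = 50 nM -> 38.4 nM
  eq <- target_from_equilibrium(21.7 * pM, 50 * pM, 50 * nM)
  expect_equal(eq$c_free_probe, 28.3 * pM)
  expect_equal(eq$c_target_free / nM, 38.4, tolerance = 0.01)
  expect_equal(eq$c_target_total, eq$c_target_free + 21.7 * pM)

  expect_equal(target_from_equilibrium(0, 50 * pM, 50 * nM)$c_target_free, 0)
  # half-saturation identity: c_complex = c_free -> c_target_free = K_d
  eq2 <- target_from_equilibrium(25 * pM, 50 * pM, 50 * nM)
  expect_equal(eq2$c_target_free, 50 * nM)
  expect_error(target_from_equilibrium(60 * pM, 50 * pM, 50 * nM),
               "infeasibility")

  # round trip with the equilibrium solver
  for (i in 1:20) {
    set.seed(i)
    P <- runif(1, 1e-12, 1e-6); A <- runif(1, 1e-12, 1e-6)
    Kd <- 10^runif(1, -12, -6)
    sp <- solve_equilibrium(P, A, Kd)
    back <- target_from_equilibrium(sp$PA, P, Kd)
    expect_equal(back$c_target_free, sp$A_free, tolerance = 1e-9)
    expect_equal(back$c_target_total, A, tolerance = 1e-9)
  }
})

test_that("binding-site arithmetic reproduces the fibril and oligomer cases", {
  # fibrils: 18.7 pM bound, 10 nM aptamer, K_d = 1000 nM -> ~1.9 nM sites
  cs_f <- binding_site_concentration(18.7 * pM, 10 * nM - 18.7 * pM, 1000 * nM)
  expect_equal(cs_f / nM, 1.9, tolerance = 0.005)
  # K_d = 500 nM end of the range -> ~1.0 nM
  expect_equal(binding_site_concentration(18.7 * pM, 10 * nM - 18.7 * pM,
                                          500 * nM) / nM, 0.95,
               tolerance = 0.01)

  # oligomers: valency-corrected free probe, K_d = 200 nM -> ~98 pM, 3.0 sites
  v <- valency_from_intensities(59.5, 43.0)
  expect_equal(v, 1.38, tolerance = 0.005)
  cf <- 100 * nM - v * 32.7 * pM
  cs_o <- binding_site_concentration(32.7 * pM, cf, 200 * nM)
  expect_equal(cs_o / pM, 98, tolerance = 0.005)
  expect_equal(sites_per_particle(cs_o, 32.7 * pM), 3.0, tolerance = 0.005)
  # K_d = 150 nM end -> 2.5 sites
  cs_o2 <- binding_site_concentration(32.7 * pM, cf, 150 * nM)
  expect_equal(sites_per_particle(cs_o2, 32.7 * pM), 2.5, tolerance = 0.01)

  expect_equal(binding_site_concentration(0, 1 * nM, 100 * nM), 0)
  expect_error(binding_site_concentration(1 * pM, 0, 100 * nM), "c_free")

  # exosome stoichiometry from median burst intensities
  expect_equal(valency_from_intensities(114, 16.0), 7.125)
  expect_equal(valency_from_intensities(93.8, 16.0), 5.8625)
  expect_equal(valency_from_intensities(43, 43), 1)
  expect_error(valency_from_intensities(10, 0), "I_free")
})

test_that("condensate metrics chain reproduces the printed block", {
  # volume fraction at 11.0 pM and r = 825 nm -> 1.55%
  vf <- condensate_volume_fraction(11.0 * pM, 825e-9)
  expect_equal(vf$phi, 0.0156, tolerance = 0.005)
  expect_false(vf$clipped)
  expect_equal(condensate_volume_fraction(0, 825e-9)$phi, 0)
  # algebraic inversion: radius chosen so the particle volume gives 1e-3
  r_inv <- (1e-3 / (1 * pM * N_AVOGADRO * 1e3 * (4 / 3) * pi))^(1 / 3)
  expect_equal(condensate_volume_fraction(1 * pM, r_inv)$phi, 1e-3)

  # dense-phase concentration and mass density
  dp <- dense_phase_concentration(1414.6 * nM, vf$phi, 94.4e3)
  expect_equal(dp$c_dense * 1e6, 90.9, tolerance = 0.005)
  expect_equal(dp$mass_density_mg_mL, 8.6, tolerance = 0.01)
  # unit identity: mass_density / c_dense = M_w exactly
  expect_equal(dp$mass_density_mg_mL / dp$c_dense, 94.4e3)
  expect_equal(dense_phase_concentration(5 * nM, 1, 1e4)$c_dense, 5 * nM)
  expect_equal(dense_phase_concentration(0, 0.5, 1e4)$mass_density_mg_mL, 0)
  expect_error(dense_phase_concentration(1, 0, 1), "phi")

  # aptamers per condensate and partitioning
  st <- valency_from_intensities(7307, 22.7)
  expect_equal(st, 322, tolerance = 0.005)
  c_in <- st * 11.0 * pM
  expect_equal(c_in / nM, 3.5, tolerance = 0.02)
  pf <- partition_fractions(c_in, 110.0 * nM, 700 * nM)
  expect_equal(pf$fraction_of_free_pct, 3.2, tolerance = 0.01)
  expect_equal(pf$fraction_of_total_pct, 0.5, tolerance = 0.02)
  pf0 <- partition_fractions(0, 110 * nM, 700 * nM)
  expect_equal(pf0$fraction_of_free_pct, 0)
  expect_error(partition_fractions(1, 0, 1), "denominators")
})
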