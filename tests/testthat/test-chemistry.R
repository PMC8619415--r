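# Site-binding interface model: point of zero charge, buffer factors,
# surface potential, surface proton activity, surface charge density.

test_that("point of zero charge is the mean of the dissociation exponents", {
  expect_equal(point_of_zero_charge(ref_oxide), 2)           # SiO2 defaults
  expect_equal(point_of_zero_charge(oxide_surface(pKa = 3.7, pKb = 3.7)), 3.7)
  expect_equal(point_of_zero_charge(oxide_surface(pKa = 7, pKb = 3)), 5)
})

test_that("sensitivity factors follow the site-binding closed forms", {
  sf <- sensitivity_factor(ref_oxide)
  expect_equal(sf$eta, 2 * 10^(-(6 - (-2)) / 2))   # direct evaluation, 2e-4
  beta_oracle <- Q_E^2 * (5e12 * 1e4) * 2e-4 / (0.2 * K_B * 298.15)
  expect_equal(sf$beta, beta_oracle, tolerance = 1e-12)
  expect_equal(sf$delta_w, beta_oracle / (beta_oracle + 1), tolerance = 1e-12)

  # beta -> infinity saturates delta_w at 1 (tiny double-layer capacitance)
  sat <- sensitivity_factor(oxide_surface(Ceq = 1e-12))
  expect_gt(sat$delta_w, 0.999)
  # solve Ceq for beta = 1: delta_w = 1/2
  Ceq1 <- Q_E^2 * (5e12 * 1e4) * 2e-4 / (K_B * 298.15)
  expect_equal(sensitivity_factor(oxide_surface(Ceq = Ceq1))$delta_w, 0.5,
               tolerance = 1e-12)
  expect_error(oxide_surface(Ceq = 0), "Ceq")
})

test_that("surface potential is the attenuated Nernst line", {
  expect_equal(surface_potential(2, ref_oxide), 0)   # zero at the pzc
  # delta_w = 1 limit: one pH unit gives -ln(10) kB T / q
  nernst_ox <- oxide_surface(Ceq = 1e-15)
  slope <- surface_potential(3, nernst_ox) - surface_potential(2, nernst_ox)
  expect_equal(slope, -log(10) * K_B * 298.15 / Q_E, tolerance = 1e-6)
  # linear scaling in delta_w: half the factor gives half the potential
  expect_equal(surface_potential(5, ref_oxide) / surface_potential(8, ref_oxide),
               (5 - 2) / (8 - 2), tolerance = 1e-12)
})

test_that("surface proton activity applies the Boltzmann factor", {
  expect_equal(surface_proton_activity(7, 0), 1e-7)
  expect_equal(surface_proton_activity(2, 0), 1e-2)
  # one Nernst unit of negative surface potential concentrates protons 10x
  Vt <- K_B * 298.15 / Q_E
  expect_equal(surface_proton_activity(7, -log(10) * Vt), 1e-6,
               tolerance = 1e-12)
  expect_true(all(surface_proton_activity(seq(0, 14, 2), -0.2) > 0))
})

test_that("surface charge density is bounded, signed and increasing in Hs", {
  ox <- ref_oxide
  qNs <- Q_E * 5e16
  # zero at Hs = sqrt(Ka Kb) = 1e-2 (the pzc proton activity)
  expect_equal(surface_charge_density(1e-2, ox), 0)
  # protonated asymptote +q Ns
  expect_equal(surface_charge_density(1e8, ox), qNs, tolerance = 1e-5)
  # brute-force scalar oracle at Hs = 1e-7
  a <- 1e-7 / 1e-6; b <- 1e2 / 1e-7
  expect_equal(surface_charge_density(1e-7, ox),
               qNs * (a - b) / (a + b + 1), tolerance = 1e-14)
  # strictly increasing in Hs, bounded by +/- q Ns
  hs <- 10^seq(-13, 3, by = 0.5)
  s <- surface_charge_density(hs, ox)
  expect_true(all(diff(s) > 0))
  expect_true(all(abs(s) < qNs))
  expect_error(surface_charge_density(-1, ox), "positive")
})

test_that("pH charge table chains the scalar operations with no hidden state", {
  grid <- c(9, 4, 6, 7, 5, 8)
  tab <- ph_charge_table(grid, ref_oxide)
  expect_equal(tab$pH, sort(grid))
  expect_equal(nrow(tab), length(grid))
  for (i in seq_len(nrow(tab))) {
    psi <- surface_potential(tab$pH[i], ref_oxide)
    hs <- surface_proton_activity(tab$pH[i], psi, ref_oxide$T_K)
    expect_identical(tab$psi0_V[i], psi)
    expect_identical(tab$Hs_mol_per_L[i], hs)
    expect_identical(tab$sigma0_C_per_m2[i],
                     surface_charge_density(hs, ref_oxide))
  }
  expect_true(all(diff(tab$sigma0_C_per_m2) < 0))
  one <- ph_charge_table(2, ref_oxide)
  expect_equal(one$psi0_V, 0)
  expect_equal(one$sigma0_C_per_m2, 0)
  expect_error(ph_charge_table(numeric(0), ref_oxide), "non-empty")
  expect_error(ph_charge_table(15, ref_oxide), "0, 14")
})

test_that("sign of the surface charge follows the pzc and delta_w stays in (0,1)", {
  tab <- ph_charge_table(seq(0, 14, by = 0.5), ref_oxide)
  expect_true(all(sign(tab$sigma0_C_per_m2) ==
                    sign(2 - tab$pH)))
  # delta_w in (0, 1) for any finite Ceq; increases with Ns
  Ns_grid <- 10^seq(10, 15, by = 1)
  dw <- vapply(Ns_grid, function(ns)
    sensitivity_factor(oxide_surface(Ns_per_cm2 = ns))$delta_w, numeric(1))
  expect_true(all(dw > 0 & dw < 1))
  expect_true(all(diff(dw) > 0))
})
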