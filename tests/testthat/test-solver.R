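# Drift-diffusion-Poisson core: equilibrium oracles, channel electrostatics
# against the depletion approximation, Gummel bias solves, discretization
# identities.

test_that("equilibrium solve reproduces the built-in potential and mass action", {
  eq <- solve_equilibrium(ref_device, mesh_default)
  expect_true(eq$meta$converged)
  Vt <- K_B * 300 / Q_E
  vbi_oracle <- Vt * log(5e21 * 1e24 / 1e32)        # ~0.815 V
  drop <- max(eq$psi) - min(eq$psi)
  expect_equal(drop, vbi_oracle, tolerance = 1e-2)
  # n p = ni^2 holds everywhere at equilibrium
  expect_equal(eq$n * eq$p / ref_device$material$ni^2,
               rep(1, length(eq$n)), tolerance = 1e-3)
  # global neutrality: integrated space charge ~ 0 relative to layer charge
  h <- diff(eq$x)
  rho <- Q_E * (eq$p - eq$n + net_doping(eq$x, ref_device))
  q_tot <- sum(h * (rho[-1] + rho[-length(rho)]) / 2)
  q_scale <- Q_E * ref_device$NA_ * ref_device$tp
  expect_lt(abs(q_tot) / q_scale, 1e-3)
})

test_that("gate sheet charge enters through the displacement jump", {
  # positive charge depletes the p surface; negative accumulates holes
  f_pos <- solve_channel(ref_device, mesh_default, sigma0 = 4e-3, Vr = 0)
  f_neg <- solve_channel(ref_device, mesh_default, sigma0 = -4e-3, Vr = 0)
  f_zero <- solve_channel(ref_device, mesh_default, sigma0 = 0, Vr = 0)
  expect_lt(f_pos$meta$sheet_holes, f_zero$meta$sheet_holes)
  expect_gt(f_neg$meta$sheet_holes, f_zero$meta$sheet_holes)
  # accumulated sheet ~ bulk + |sigma0|/q (surface charge fully imaged as
  # mobile holes on an insulated window)
  extra <- f_neg$meta$sheet_holes - f_zero$meta$sheet_holes
  expect_equal(extra, 4e-3 / Q_E, tolerance = 0.05)
})

test_that("channel depletion widens with reverse bias and tracks the closed form", {
  ws <- vapply(c(0, 1, 3), function(vr)
    solve_channel(abrupt_device, mesh_abrupt, sigma0 = 0, Vr = vr)$meta$w_p,
    numeric(1))
  expect_true(all(diff(ws) > 0))
  wa <- vapply(c(0, 1, 3), function(vr)
    depletion_width_analytic(abrupt_device, -vr)$w_p, numeric(1))
  expect_equal(ws[2:3], wa[2:3], tolerance = 0.05)
  # undepleted thickness shrinks strictly with reverse back-gate bias
  sheets <- vapply(c(0, 2, 4, 6, 8), function(vr)
    solve_channel(ref_device, mesh_default, sigma0 = 0, Vr = vr)$meta$sheet_holes,
    numeric(1))
  expect_true(all(diff(sheets) < 0))
})

test_that("continuation warm start and cold start agree", {
  cold <- solve_channel(ref_device, mesh_default, sigma0 = 0, Vr = 3)
  warm_src <- solve_channel(ref_device, mesh_default, sigma0 = 0, Vr = 5)
  warm <- solve_channel(ref_device, mesh_default, sigma0 = 0, Vr = 3,
                        psi_init = warm_src$psi)
  expect_equal(warm$meta$sheet_holes, cold$meta$sheet_holes,
               tolerance = 1e-3)
})

test_that("zero-bias Gummel solve carries no terminal current", {
  f <- solve_bias(ref_device, mesh_contact, bias_point(0, 0))
  expect_true(f$meta$converged)
  expect_lt(abs(f$meta$I_A), 1e-9)
})

test_that("forward-bias currents conserve across the structure", {
  for (vj in c(0.3, 0.45, 0.6)) {
    f <- solve_bias(ref_device, mesh_contact, bias_point(Vds = vj, Vgs = 0))
    expect_lt(f$meta$conservation, 1e-4)
    expect_gt(f$meta$I_A, 0)
  }
  # forward current grows steeply (diode-like) toward the ~0.67 V turn-on
  i1 <- solve_bias(ref_device, mesh_contact, bias_point(0.45, 0))$meta$I_A
  i2 <- solve_bias(ref_device, mesh_contact, bias_point(0.60, 0))$meta$I_A
  expect_gt(i2 / i1, 50)
  expect_error(solve_bias(ref_device, mesh_contact, bias_point(1.2, 0)),
               "overflow guard")
})

test_that("reverse bias gives small negative leakage of generation scale", {
  f <- solve_bias(ref_device, mesh_contact, bias_point(Vds = 0, Vgs = 1))
  expect_lt(f$meta$I_A, 0)
  expect_lt(abs(f$meta$I_A), 1e-8)
  # generation-limited leakage: order q ni W A / (2 tau)
  w <- depletion_width_analytic(ref_device, -1)$w_total
  gen <- Q_E * 1e16 * w * ref_device$L_OG * ref_device$depth / (2 * 1e-6)
  expect_lt(abs(f$meta$I_A), 20 * gen)
})

test_that("Scharfetter-Gummel factors hit the central-difference limit", {
  B <- ogjfet:::.bernoulli
  expect_equal(B(0), 1)
  # for |x| -> 0 the SG edge flux reduces to pure diffusion:
  # B(x) n2 - B(-x) n1 -> (n2 - n1) - x (n1 + n2)/2
  x <- 1e-9; n1 <- 3; n2 <- 5
  expect_equal(B(x) * n2 - B(-x) * n1, (n2 - n1) - x * (n1 + n2) / 2,
               tolerance = 1e-12)
  # equilibrium identity: B(d) e^{psi2} = B(-d) e^{psi1} for d = psi2 - psi1
  d <- 0.8
  expect_equal(B(d) * exp(d), B(-d), tolerance = 1e-12)
})

test_that("Fermi-Dirac statistics shift degenerate contacts below Boltzmann", {
  mat_fd <- material(statistics = "fermi_dirac")
  dev_fd <- device(mat = mat_fd)
  eq_b <- solve_equilibrium(ref_device, mesh_default)
  eq_f <- solve_equilibrium(dev_fd, mesh_default)
  expect_true(eq_f$meta$converged)
  # in the heavily doped substrate the FD potential differs from Boltzmann
  # by a small positive degeneracy correction, well under kT/q
  d_sub <- eq_f$psi[length(eq_f$psi)] - eq_b$psi[length(eq_b$psi)]
  expect_gt(d_sub, 0)
  expect_lt(d_sub, 0.026)
  # lightly doped p layer: the two statistics agree closely
  expect_equal(eq_f$psi[1], eq_b$psi[1], tolerance = 1e-3)
})
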