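# Chemistry-to-device coupling: bias-mode classification, gradual-channel
# current, transfer and output families.

test_that("bias mode classifies against the junction turn-on voltage", {
  expect_identical(bias_mode(0.67, 0), "forward")       # at the threshold
  expect_identical(bias_mode(0, 0), "reverse")
  expect_identical(bias_mode(0.67 - 1e-9, 0), "reverse")
  expect_identical(bias_mode(10, 9.5, Von = 0.5), "forward")
})

test_that("ohmic-limit channel conductance matches the resistivity oracle", {
  sf <- ogjfet:::.sheet_table(ref_device, mesh_default, 0, Vr_max = 0.05)
  g <- channel_current(ref_device, Vds = 0.01, Vgs = 0, sigma0 = 0,
                       sheet_fun = sf) / 0.01
  # oracle: p-layer resistivity and geometry, thinned by the zero-bias
  # junction depletion width
  w <- depletion_width_analytic(ref_device, 0)$w_p
  R <- layer_resistivity(ref_device) * ref_device$L_OG /
    (ref_device$depth * (ref_device$tp - w))
  expect_equal(g, 1 / R, tolerance = 0.15)
  # ungated resistance scale ~1.7 kOhm for the design parameters
  R0 <- layer_resistivity(ref_device) * ref_device$L_OG /
    (ref_device$depth * ref_device$tp)
  expect_equal(R0, 1700, tolerance = 0.05)
})

test_that("channel current saturates beyond pinch-off and is monotone", {
  sf <- ogjfet:::.sheet_table(ref_device, mesh_default, 0, Vr_max = 14)
  vds <- c(0.5, 2, 4, 8, 10, 12)
  ids <- vapply(vds, function(v)
    channel_current(ref_device, v, Vgs = 0, sigma0 = 0, sheet_fun = sf),
    numeric(1))
  expect_true(all(diff(ids) >= 0))                     # dIds/dVds >= 0
  # saturation: the 10 -> 12 V increment is a tiny fraction of 0.5 -> 2 V
  expect_lt((ids[6] - ids[5]) / (ids[2] - ids[1]), 0.05)
  # increasing reverse back-gate bias strictly decreases the current
  ids_vg <- vapply(c(0, 1, 2, 3), function(vg)
    channel_current(ref_device, 2, Vgs = vg, sigma0 = 0, sheet_fun = sf),
    numeric(1))
  expect_true(all(diff(ids_vg) < 0))
  # a fully pinched channel returns the leakage floor
  sf_hi <- ogjfet:::.sheet_table(ref_device, mesh_default, 0, Vr_max = 16)
  expect_equal(channel_current(ref_device, Vds = 0.5, Vgs = 15, sigma0 = 0,
                               sheet_fun = sf_hi, leakage = 1e-12), 1e-12)
})

test_that("transfer families are ordered in pH and decay with back-gate bias", {
  fam <- simulate_transfer_family(ref_device, ref_oxide, pH = c(4, 6, 9),
                                  Vds_fixed = 4, Vgs_grid = c(0, 0.25, 0.5),
                                  mesh = mesh_default)
  expect_s3_class(fam, "iv_family")
  cur <- family_curves(fam)
  at0 <- vapply(cur, function(d) d$Ids_A[d$sweep_V == 0], numeric(1))
  expect_true(all(diff(at0) > 0))                      # pH up -> current up
  expect_true(all(vapply(cur, function(d) all(diff(d$Ids_A) < 0),
                         logical(1))))                 # Vgs up -> current down
})

test_that("output families separate more in saturation than in the ohmic region", {
  fam <- simulate_output_family(ref_device, ref_oxide, pH = c(4, 9),
                                Vgs_fixed = 0, Vds_grid = c(0.5, 5, 10),
                                mesh = mesh_default)
  cur <- family_curves(fam)
  expect_true(all(vapply(cur, function(d) all(diff(d$Ids_A) >= 0),
                         logical(1))))
  gap <- cur[["9"]]$Ids_A - cur[["4"]]$Ids_A
  expect_gt(gap[3], gap[1])                            # saturation > ohmic
})

test_that("pH at the pzc is equivalent to an uncharged gate window", {
  sig <- ph_charge_table(2, ref_oxide)$sigma0_C_per_m2
  expect_identical(sig, 0)
  fam <- simulate_transfer_family(ref_device, ref_oxide, pH = 2,
                                  Vds_fixed = 2, Vgs_grid = c(0, 0.3),
                                  mesh = mesh_default)
  sf <- ogjfet:::.sheet_table(ref_device, mesh_default, 0, Vr_max = 2.3)
  i0 <- channel_current(ref_device, 2, 0, 0, sheet_fun = sf)
  expect_equal(family_curves(fam)[[1]]$Ids_A[1], i0, tolerance = 1e-10)
})

test_that("family generation is deterministic and order-invariant in pH", {
  a <- simulate_transfer_family(ref_device, ref_oxide, pH = c(7, 4),
                                Vds_fixed = 2, Vgs_grid = c(0, 0.3),
                                mesh = mesh_default)
  b <- simulate_transfer_family(ref_device, ref_oxide, pH = c(4, 7),
                                Vds_fixed = 2, Vgs_grid = c(0, 0.3),
                                mesh = mesh_default)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
})

test_that("IV containers validate their shape contracts", {
  expect_error(iv_curve(c(0, 0.1, 0.05), c(1, 2, 3) * 1e-3), "monotone")
  expect_error(iv_curve(0.1, 1e-3), "at least 2")
  c1 <- iv_curve(c(0, 0.1), c(2, 1) * 1e-3, analyte_value = 4)
  c2 <- iv_curve(c(0, 0.1), c(3, 2) * 1e-3, analyte_value = 7)
  fam <- iv_family(list(c1, c2))
  expect_length(family_curves(fam), 2)
  c3 <- iv_curve(c(0, 0.1), c(3, 2) * 1e-3, sweep_name = "Vds",
                 analyte_value = 9)
  expect_error(iv_family(list(c1, c3)), "share sweep")
})
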