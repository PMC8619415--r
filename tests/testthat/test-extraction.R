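# Characterization analyses: constant-current reference voltage, voltage
# and current sensitivity fits, step response, Debye length.

make_transfer <- function(shift_mV, levels, analyte = "pH",
                          grid = seq(0, 1.5, by = 0.01), noise = 0,
                          seed = NULL, Vds = 10) {
  spec <- generator_spec(levels = levels, analyte_name = analyte,
                         planted_shift_mV = shift_mV, noise_sd = noise,
                         seed = seed)
  parametric_iv_family(spec, "Vgs", grid = grid, fixed_V = Vds)
}

test_that("reference voltage inverts the transfer curve exactly at knots", {
  fam <- make_transfer(0, levels = 7)
  cv <- family_curves(fam)[[1]]
  k <- 31
  expect_identical(reference_voltage(cv, cv$Ids_A[k]), cv$sweep_V[k])
  # two-point linear curve: midpoint current maps to midpoint voltage
  lin <- iv_curve(c(0, 1), c(2e-3, 1e-3), analyte_value = 1)
  expect_equal(reference_voltage(lin, 1.5e-3), 0.5)
  # closed-form inverse oracle: V(I) = Vp (1 - sqrt(I/Idss)), error below
  # the grid-resolution bound
  v_oracle <- 2 * (1 - sqrt(0.5e-3 / 1e-3))
  expect_lt(abs(reference_voltage(cv, 0.5e-3) - v_oracle), 0.01)
  # shuffling the points does not change the answer
  shuf <- cv[sample.int(nrow(cv)), ]
  expect_identical(reference_voltage(shuf, 0.5e-3),
                   reference_voltage(cv, 0.5e-3))
  expect_error(reference_voltage(cv, 1), "span")
})

test_that("voltage sensitivity recovers planted shifts exactly without noise", {
  fam <- make_transfer(51.26, levels = 4:9)
  r <- voltage_sensitivity(fam, 0.5e-3)
  expect_equal(r$slope, 51.26, tolerance = 1e-9)
  expect_equal(r$r_squared, 1)
  expect_equal(r$n_points, 6L)
  # current-keyed shift table: slope tracks the reference current
  spec <- generator_spec(levels = 1:5, analyte_name = "DNAc",
                         planted_shift_mV = dna_shift_table)
  fam2 <- parametric_iv_family(spec, "Vgs", grid = seq(0, 1.8, 0.002),
                               fixed_V = 10)
  expect_equal(voltage_sensitivity(fam2, 0.65e-3)$slope, 41.40,
               tolerance = 2e-3)
  expect_equal(voltage_sensitivity(fam2, 0.45e-3)$slope, 29.38,
               tolerance = 2e-3)
  expect_error(voltage_sensitivity(make_transfer(5, levels = 3), 0.5e-3),
               "two distinct")
})

test_that("current sensitivity recovers planted offsets per bias point", {
  # fixed-bias data.frame form: exact linear recovery
  lev <- c(25, 50, 75, 100)
  d <- data.frame(analyte_value = lev, Ids_A = 2e-3 + 0.15e-3 * lev)
  r <- current_sensitivity(d, reference = 4)
  expect_equal(r$slope, 0.15e-3, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  # family form: planted current offset recovered at every Vds
  spec <- generator_spec(levels = c(1, 2, 3), analyte_name = "cells",
                         current_offset_A = 2e-4)
  fam <- parametric_iv_family(spec, "Vds", grid = seq(0.5, 10, by = 0.5),
                              fixed_V = 0.2)
  rs <- current_sensitivity(fam, Vds_at = c(1, 5, 10))
  for (r in rs) expect_equal(r$slope, 2e-4, tolerance = 1e-12)
})

test_that("simulated pH families are more current-sensitive in saturation", {
  fam <- simulate_output_family(ref_device, ref_oxide, pH = c(4, 7, 9),
                                Vgs_fixed = 0, Vds_grid = c(0.5, 10),
                                mesh = mesh_default)
  rs <- current_sensitivity(fam, Vds_at = c(0.5, 10))
  expect_gt(rs[["10"]]$slope, rs[["0.5"]]$slope)
})

test_that("step response measures fold change and transition time", {
  tr <- step_trace(0.5e-3, 2.5e-3, t_step = 10, rise = 0)
  s <- step_response(tr)
  expect_true(s$event)
  expect_identical(s$fold_change, 5)
  # noisy ramp: fold within 2% of the planted ratio; 10-90% time ~ 0.8 rise
  tr2 <- step_trace(0.5e-3, 2.5e-3, t_step = 10, rise = 3,
                    noise_sd = 0.5e-5, seed = 11, duration = 40)
  s2 <- step_response(tr2)
  expect_equal(s2$fold_change, 5, tolerance = 0.02)
  expect_equal(s2$transition_time_s, 0.8 * 3, tolerance = 0.15)
  # constant trace: explicit no-event result
  flat <- step_response(step_trace(1e-3, 1e-3 * (1 + 1e-9), t_step = 10))
  expect_false(flat$event)
  expect_true(is.na(flat$fold_change))
  expect_error(step_response(data.frame(time_s = 1:5, Ids_A = 1:5)),
               "10 samples")
})

test_that("step fold change is invariant to uniform time rescaling", {
  tr <- step_trace(0.5e-3, 2.5e-3, t_step = 10, rise = 2,
                   noise_sd = 1e-5, seed = 3, duration = 40)
  s1 <- step_response(tr)
  tr$time_s <- tr$time_s * 7.5
  s2 <- step_response(tr)
  expect_identical(s1$fold_change, s2$fold_change)
  expect_equal(s2$transition_time_s, 7.5 * s1$transition_time_s)
})

test_that("Debye length follows the electrolyte closed form", {
  lam <- debye_length(0.15)
  oracle <- sqrt(78.5 * EPS0 * K_B * 298.15 /
                   (2 * N_AV * Q_E^2 * 0.15 * 1000))
  expect_equal(lam, oracle, tolerance = 1e-12)
  expect_equal(lam * 1e9, 0.785, tolerance = 1e-3)
  # inverse square-root scaling: quadrupling I halves lambda
  expect_equal(debye_length(0.6), lam / 2, tolerance = 1e-12)
  expect_error(debye_length(0), "positive")
})

test_that("noisy-slope recovery stays within its standard-error band", {
  # 1% current noise (of the saturation scale); coverage of the t-based 95%
  # confidence band over replicate seeds, within binomial Monte-Carlo slack.
  # The sweep window keeps the curve steep enough that noise cannot reorder
  # adjacent samples (reference_voltage requires monotone currents).
  n_rep <- 100
  hits <- 0L
  for (k in seq_len(n_rep)) {
    fam <- make_transfer(51.26, levels = 4:9, grid = seq(0, 0.9, by = 0.15),
                         noise = 1e-5, seed = 1000 + k)
    r <- voltage_sensitivity(fam, 0.5e-3)
    ci <- r$slope + c(-1, 1) * stats::qt(0.975, r$n_points - 2) * r$slope_se
    if (ci[1] <= 51.26 && 51.26 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95 - 2 * sqrt(0.95 * 0.05 / n_rep))
})
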