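# Synthetic measurement generator: square-law JFET surrogate IV families
# with planted analyte sensitivities, baseline-to-plateau step traces, and
# the device/oxide configuration fixtures.  Kept deliberately independent
# of the drift-diffusion solver so extraction analyses can be validated by
# exact parameter recovery.

#' Generator specification for synthetic IV families
#'
#' Square-law JFET surrogate: in saturation
#' `Ids = Idss (1 - Vgs_eff / Vp)^2` with
#' `Vgs_eff = Vgs - planted_shift * level`, the textbook linear region below
#' it, optional per-level current offset and additive Gaussian noise.
#'
#' @param Idss saturation current scale, A.
#' @param Vp pinch-off voltage, V (non-zero).
#' @param levels distinct analyte levels.
#' @param analyte_name analyte label (e.g. `"pH"`, `"DNA_ng_per_uL"`).
#' @param planted_shift_mV gate-voltage shift per analyte unit: a single
#'   number (parallel curves), or a data.frame with columns `I_A` and
#'   `shift_mV` for a current-dependent (non-parallel) shift, interpolated
#'   monotonically in current.
#' @param current_offset_A additive current per analyte unit, A.
#' @param noise_sd additive Gaussian noise SD on current, A (>= 0).
#' @param seed integer RNG seed (NULL = leave RNG state alone).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(Idss = 1e-3, Vp = 2, levels,
                           analyte_name = "analyte",
                           planted_shift_mV = 0, current_offset_A = 0,
                           noise_sd = 0, seed = NULL) {
  stopifnot(is.finite(Idss), Idss > 0, is.finite(Vp), Vp != 0,
            is.numeric(levels), length(levels) >= 1,
            is.finite(noise_sd), noise_sd >= 0)
  if (anyDuplicated(levels))
    stop("'levels' must be distinct", call. = FALSE)
  if (is.data.frame(planted_shift_mV)) {
    if (!all(c("I_A", "shift_mV") %in% names(planted_shift_mV)))
      stop("shift table needs 'I_A' and 'shift_mV' columns", call. = FALSE)
    if (any(diff(order(planted_shift_mV$I_A)) < 0))
      planted_shift_mV <- planted_shift_mV[order(planted_shift_mV$I_A), ]
  } else stopifnot(is.finite(planted_shift_mV))
  structure(list(Idss = Idss, Vp = Vp, levels = levels,
                 analyte_name = analyte_name,
                 planted_shift_mV = planted_shift_mV,
                 current_offset_A = current_offset_A,
                 noise_sd = noise_sd, seed = seed),
            class = "generator_spec")
}

# base square-law current at effective gate drive vg_eff and drain vds
.square_law <- function(Idss, Vp, vg_eff, vds) {
  u <- pmin(pmax(1 - vg_eff / Vp, 0), 1)   # normalized gate drive
  vsat <- u * abs(Vp)
  ifelse(vds >= vsat,
         Idss * u^2,
         Idss * (2 * u * vds / abs(Vp) - (vds / abs(Vp))^2))
}

#' Generate a synthetic IV family with planted sensitivities
#'
#' Deterministic for a fixed seed; `noise_sd = 0` yields exact model
#' values, so extraction analyses recover the planted parameters exactly.
#'
#' @param spec a [generator_spec()].
#' @param sweep `"Vgs"` (transfer curves) or `"Vds"` (output curves).
#' @param grid strictly monotone sweep voltages, V.
#' @param fixed_V the held terminal voltage, V.
#' @return An [iv_family()].
#' @export
parametric_iv_family <- function(spec, sweep = c("Vgs", "Vds"), grid,
                                 fixed_V) {
  stopifnot(inherits(spec, "generator_spec"))
  sweep <- match.arg(sweep)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  shift_V_at <- function(I_base) {
    if (is.data.frame(spec$planted_shift_mV))
      stats::approx(spec$planted_shift_mV$I_A,
                    spec$planted_shift_mV$shift_mV,
                    xout = I_base, rule = 2, ties = "ordered")$y * 1e-3
    else rep(spec$planted_shift_mV * 1e-3, length(I_base))
  }
  curves <- lapply(spec$levels, function(lev) {
    if (sweep == "Vgs") {
      # construct in current space so a current-keyed shift is exact at
      # the sampled currents
      I0 <- .square_law(spec$Idss, spec$Vp, grid, fixed_V)
      v <- grid + shift_V_at(I0) * lev
      if (any(diff(v) <= 0))
        stop(paste("shift table too steep for level", lev,
                   "- the shifted sweep folds; reduce the shift-vs-current",
                   "slope or the analyte levels"), call. = FALSE)
      ids <- I0 + spec$current_offset_A * lev
    } else {
      v <- grid
      vg_eff <- fixed_V - shift_V_at(spec$Idss / 2) * lev
      ids <- .square_law(spec$Idss, spec$Vp, vg_eff, grid) +
        spec$current_offset_A * lev
    }
    if (spec$noise_sd > 0)
      ids <- ids + stats::rnorm(length(ids), 0, spec$noise_sd)
    iv_curve(v, ids, sweep_name = sweep,
             fixed_name = if (sweep == "Vgs") "Vds" else "Vgs",
             fixed_V = fixed_V, analyte_name = spec$analyte_name,
             analyte_value = lev)
  })
  iv_family(curves)
}

#' Synthetic baseline-to-plateau current step trace
#'
#' Constant baseline, a linear ramp of duration `rise` starting at
#' `t_step`, then a constant plateau; optional additive Gaussian noise.
#' Deterministic per seed.
#'
#' @param baseline_A,plateau_A pre- and post-step currents, A (> 0).
#' @param t_step ramp start time, s.
#' @param rise ramp duration, s (0 = ideal step).
#' @param noise_sd additive Gaussian noise SD, A.
#' @param seed integer RNG seed.
#' @param duration total trace length, s.
#' @param dt sampling interval, s.
#' @return A data.frame of class `trace_series` with `time_s`, `Ids_A`.
#' @export
step_trace <- function(baseline_A, plateau_A, t_step = 10, rise = 0,
                       noise_sd = 0, seed = NULL, duration = 30, dt = 0.05) {
  stopifnot(baseline_A > 0, plateau_A > 0, rise >= 0, noise_sd >= 0,
            duration > t_step, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = dt)
  frac <- if (rise == 0) as.numeric(t >= t_step)
  else pmin(pmax((t - t_step) / rise, 0), 1)
  y <- baseline_A + frac * (plateau_A - baseline_A)
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  out <- data.frame(time_s = t, Ids_A = y)
  class(out) <- c("trace_series", "data.frame")
  out
}

#' Reference device and oxide configuration fixtures
#'
#' The design-parameter set of the simulated/fabricated sensor: 100 um
#' open-gate window, 1.6 um p channel at NA = 5e15/cm^3 on a 450 um
#' substrate at ND = 1e18/cm^3, 1000 um depth, 20 um x 1000 um
#' source/drain at 2e16/cm^3, 10 um minimum surround; native-SiO2 oxide
#' with Ns = 5e12/cm^2, pKa = 6, pKb = -2 (pH_pzc = 2).
#'
#' @return A list with `device` and `oxide` configuration blocks that
#'   round-trip through [load_config()].
#' @export
fixture_configs <- function() {
  list(
    device = list(tp_um = 1.6, tn_um = 450, L_OG_um = 100, depth_um = 1000,
                  NA_per_cm3 = 5e15, ND_per_cm3 = 1e18,
                  sd_doping_per_cm3 = 2e16, Ls_um = 20, W_um = 1000,
                  L_MS_um = 10, gauss_sigma_um = 0.05),
    oxide = list(Ns_per_cm2 = 5e12, pKa = 6, pKb = -2,
                 Ceq_F_per_m2 = 0.2, T_K = 298.15))
}
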