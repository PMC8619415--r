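# Couples the interface chemistry to the device core.  The vertical
# electrostatics are solved per lateral station (gradual-channel
# approximation); lateral hole conduction is integrated along the gate
# window to give the drain-source current.

#' Bias-mode classification
#'
#' The channel/substrate p-n junction conducts directly (forward mode) once
#' the drain-to-back-gate voltage reaches the turn-on voltage; below it the
#' device operates in the sensing (reverse) mode where all current flows in
#' the p channel.
#'
#' @param Vd drain voltage, V.
#' @param Vg back-gate voltage, V.
#' @param Von junction turn-on voltage, V (default 0.67).
#' @return `"forward"` if `Vd - Vg >= Von`, else `"reverse"`.
#' @export
bias_mode <- function(Vd, Vg, Von = 0.67) {
  stopifnot(is.finite(Vd), is.finite(Vg), is.finite(Von))
  if (Vd - Vg >= Von) "forward" else "reverse"
}

#' Ideal-diode estimate of the forward junction current
#'
#' Order-of-magnitude Shockley estimate I = I0 (exp(Vf/Vt) - 1) with the
#' long-base saturation current of the abrupt junction and the gate-window
#' area.  Forward conduction traverses the full substrate and is not
#' quantitatively modelled; the sensing analyses all run in reverse mode.
#'
#' @param dev a [device()].
#' @param Vf forward junction voltage, V.
#' @param T_K temperature, kelvin.
#' @return Estimated diode current in amperes.
#' @export
forward_diode_current <- function(dev, Vf, T_K = 300) {
  stopifnot(inherits(dev, "device"))
  mat <- dev$material
  Vt <- thermal_voltage(T_K)
  Dn <- Vt * mat$mu_n; Dp <- Vt * mat$mu_p
  Ln <- sqrt(Dn * mat$tau_n); Lp <- sqrt(Dp * mat$tau_p)
  J0 <- .k_q * mat$ni^2 * (Dp / (Lp * dev$ND) + Dn / (Ln * dev$NA_))
  J0 * dev$L_OG * dev$depth * expm1(pmin(Vf, 0.9) / Vt)
}

# --- IV containers -----------------------------------------------------------

.iv_cols <- c("analyte_name", "analyte_value", "sweep_name", "sweep_V",
              "fixed_name", "fixed_V", "Ids_A")

#' Single current-voltage curve
#'
#' @param sweep_V swept terminal voltage values (strictly monotone), V.
#' @param Ids_A drain-source currents, A.
#' @param sweep_name `"Vgs"` or `"Vds"`.
#' @param fixed_name,fixed_V the held terminal and its value, V.
#' @param analyte_name,analyte_value analyte label (e.g. `"pH"`) and level.
#' @return A data.frame of class `iv_curve` with the family column schema.
#' @export
iv_curve <- function(sweep_V, Ids_A, sweep_name = c("Vgs", "Vds"),
                     fixed_name = NULL, fixed_V = NA_real_,
                     analyte_name = "analyte", analyte_value = NA_real_) {
  sweep_name <- match.arg(sweep_name)
  if (is.null(fixed_name))
    fixed_name <- if (sweep_name == "Vgs") "Vds" else "Vgs"
  if (length(sweep_V) < 2L)
    stop("an IV curve needs at least 2 points", call. = FALSE)
  d <- diff(sweep_V)
  if (!(all(d > 0) || all(d < 0)))
    stop("'sweep_V' must be strictly monotone", call. = FALSE)
  if (length(Ids_A) != length(sweep_V))
    stop("'Ids_A' and 'sweep_V' lengths differ", call. = FALSE)
  out <- data.frame(analyte_name = analyte_name,
                    analyte_value = analyte_value,
                    sweep_name = sweep_name, sweep_V = sweep_V,
                    fixed_name = fixed_name, fixed_V = fixed_V,
                    Ids_A = Ids_A)
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Family of IV curves keyed by analyte level
#'
#' @param curves a list of [iv_curve()]s sharing sweep axis and fixed bias,
#'   with distinct analyte values, or a single long data.frame with the
#'   family column schema.
#' @return A data.frame of class `iv_family`.
#' @export
iv_family <- function(curves) {
  if (is.data.frame(curves)) fam <- as.data.frame(curves)
  else fam <- do.call(rbind, lapply(curves, as.data.frame))
  miss <- setdiff(.iv_cols, names(fam))
  if (length(miss))
    stop("missing IV family column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fam <- fam[, .iv_cols]
  if (length(unique(fam$sweep_name)) != 1L ||
      length(unique(fam$fixed_name)) != 1L)
    stop("all curves in a family must share sweep and fixed axes",
         call. = FALSE)
  key <- interaction(fam$analyte_value, fam$fixed_V, drop = TRUE)
  if (any(duplicated(fam[c("analyte_value", "fixed_V", "sweep_V")])))
    stop("duplicate (analyte, fixed bias, sweep) points in family",
         call. = FALSE)
  for (lev in split(fam, key)) {
    v <- lev$sweep_V[order(lev$sweep_V)]
    if (any(diff(v) <= 0))
      stop("non-monotone sweep within a curve", call. = FALSE)
  }
  class(fam) <- c("iv_family", "data.frame")
  fam
}

#' Split a family into its member curves
#'
#' @param fam an [iv_family()].
#' @return Named list of `iv_curve` data.frames, keyed by analyte value.
#' @export
family_curves <- function(fam) {
  stopifnot(inherits(fam, "iv_family"))
  fam <- as.data.frame(fam)
  out <- lapply(split(fam, fam$analyte_value), function(d) {
    d <- d[order(d$sweep_V), ]
    rownames(d) <- NULL
    class(d) <- c("iv_curve", "data.frame")
    d
  })
  out[order(as.numeric(names(out)))]
}

#' @export
print.iv_family <- function(x, ...) {
  cat(sprintf("iv_family: %s sweep at fixed %s, %d curves (%s = %s)\n",
              x$sweep_name[1], x$fixed_name[1],
              length(unique(x$analyte_value)), x$analyte_name[1],
              paste(sort(unique(x$analyte_value)), collapse = ", ")))
  NextMethod()
}

# --- gradual-channel current -------------------------------------------------

# Hole sheet-density lookup: solves the vertical channel Poisson problem on
# a reverse-bias grid and returns a monotone interpolant of the integrated
# hole sheet density (1/m^2) versus Vr.
.sheet_table <- function(dev, mesh, sigma0, Vr_max, T_K = 300, dVr = 0.5) {
  Vr_grid <- unique(c(seq(0, Vr_max, by = dVr), Vr_max))
  sheet <- numeric(length(Vr_grid))
  init <- NULL
  for (i in seq_along(Vr_grid)) {
    f <- solve_channel(dev, mesh, sigma0 = sigma0, Vr = Vr_grid[i],
                       T_K = T_K, psi_init = init)
    init <- f$psi
    sheet[i] <- f$meta$sheet_holes
  }
  if (length(Vr_grid) >= 4 && all(diff(sheet) < 0))
    stats::splinefun(Vr_grid, sheet, method = "hyman")
  else stats::approxfun(Vr_grid, sheet, rule = 2)
}

#' Drain-source current by gradual-channel integration
#'
#' At each lateral station of the gate window the local channel potential
#' V in `[0, Vds]` sets the junction reverse bias `Vgs + V`; the vertical
#' Poisson solution there yields the conducting hole sheet density
#' (equivalently the undepleted p-layer thickness times NA, plus any
#' surface accumulation induced by negative gate charge).  The current is
#' the lateral integral
#' `Ids = (depth / L_OG) * integral_0^Vds q mu_p P_sheet(Vgs + V) dV`,
#' which saturates once the bulk channel pinches (the integrand vanishes);
#' a fully pinched channel returns the leakage floor.
#'
#' @param dev a [device()].
#' @param Vds drain-source voltage (>= 0), V.
#' @param Vgs back-gate voltage (reverse bias > 0), V.
#' @param sigma0 gate-window surface charge density, C/m^2.
#' @param mesh optional [build_mesh()] (default 300 nodes).
#' @param T_K temperature, kelvin.
#' @param n_stations lateral integration stations.
#' @param leakage leakage floor returned for a fully pinched channel, A.
#' @param sheet_fun optional precomputed sheet-density interpolant (from a
#'   family driver); must cover `[Vgs, Vgs + Vds]`.
#' @return Drain-source current in amperes.
#' @export
channel_current <- function(dev, Vds, Vgs = 0, sigma0 = 0, mesh = NULL,
                            T_K = 300, n_stations = 41, leakage = 0,
                            sheet_fun = NULL) {
  stopifnot(inherits(dev, "device"), Vds >= 0)
  if (is.null(sheet_fun)) {
    if (is.null(mesh)) mesh <- build_mesh(dev)
    sheet_fun <- .sheet_table(dev, mesh, sigma0, Vr_max = Vgs + Vds,
                              T_K = T_K)
  }
  if (Vds == 0) return(leakage)
  V <- seq(0, Vds, length.out = n_stations)
  g <- .k_q * dev$material$mu_p * pmax(sheet_fun(Vgs + V), 0)
  ids <- dev$depth / dev$L_OG *
    sum(diff(V) * (g[-1] + g[-length(g)]) / 2)
  max(ids, leakage)
}

# sigma0 for a set of pH values through the site-binding chain.
.sigma0_of_ph <- function(pH, surface) {
  ph_charge_table(pH, surface)$sigma0_C_per_m2[match(pH, sort(pH))]
}

#' Simulated transfer family (Ids-Vgs) across analyte levels
#'
#' For each pH the site-binding model supplies the gate-window surface
#' charge; [channel_current()] is then evaluated over the back-gate grid at
#' fixed Vds.  At fixed reverse bias the current increases with pH (more
#' negative surface charge accumulates holes in the p channel).
#'
#' @param dev a [device()].
#' @param surface an [oxide_surface()].
#' @param pH numeric vector of pH levels.
#' @param Vds_fixed fixed drain-source voltage, V.
#' @param Vgs_grid back-gate sweep grid (strictly monotone), V.
#' @param mesh optional [build_mesh()].
#' @param T_K temperature, kelvin.
#' @param ... passed to [channel_current()] (`n_stations`, `leakage`).
#' @return An [iv_family()] with `analyte_name = "pH"`.
#' @export
simulate_transfer_family <- function(dev, surface, pH, Vds_fixed, Vgs_grid,
                                     mesh = NULL, T_K = 300, ...) {
  stopifnot(inherits(dev, "device"), inherits(surface, "oxide_surface"))
  if (is.null(mesh)) mesh <- build_mesh(dev)
  pH <- sort(pH)
  sig <- .sigma0_of_ph(pH, surface)
  Vr_max <- max(Vgs_grid) + Vds_fixed
  curves <- lapply(seq_along(pH), function(i) {
    sf <- .sheet_table(dev, mesh, sig[i], Vr_max = Vr_max, T_K = T_K)
    ids <- vapply(sort(Vgs_grid), function(vg)
      channel_current(dev, Vds_fixed, vg, sig[i], mesh = mesh, T_K = T_K,
                      sheet_fun = sf, ...), numeric(1))
    iv_curve(sort(Vgs_grid), ids, sweep_name = "Vgs",
             fixed_name = "Vds", fixed_V = Vds_fixed,
             analyte_name = "pH", analyte_value = pH[i])
  })
  iv_family(curves)
}

#' Simulated output family (Ids-Vds) across analyte levels
#'
#' As [simulate_transfer_family()] but sweeping Vds at fixed back-gate
#' voltage.  The per-pH curves separate more in the saturation region than
#' in the ohmic region.
#'
#' @inheritParams simulate_transfer_family
#' @param Vgs_fixed fixed back-gate voltage, V.
#' @param Vds_grid drain sweep grid (strictly monotone, >= 0), V.
#' @return An [iv_family()] with `analyte_name = "pH"`.
#' @export
simulate_output_family <- function(dev, surface, pH, Vgs_fixed, Vds_grid,
                                   mesh = NULL, T_K = 300, ...) {
  stopifnot(inherits(dev, "device"), inherits(surface, "oxide_surface"))
  if (is.null(mesh)) mesh <- build_mesh(dev)
  pH <- sort(pH)
  sig <- .sigma0_of_ph(pH, surface)
  Vds_grid <- sort(Vds_grid)
  Vr_max <- Vgs_fixed + max(Vds_grid)
  curves <- lapply(seq_along(pH), function(i) {
    sf <- .sheet_table(dev, mesh, sig[i], Vr_max = Vr_max, T_K = T_K)
    ids <- vapply(Vds_grid, function(vd)
      channel_current(dev, vd, Vgs_fixed, sig[i], mesh = mesh, T_K = T_K,
                      sheet_fun = sf, ...), numeric(1))
    iv_curve(Vds_grid, ids, sweep_name = "Vds",
             fixed_name = "Vgs", fixed_V = Vgs_fixed,
             analyte_name = "pH", analyte_value = pH[i])
  })
  iv_family(curves)
}
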