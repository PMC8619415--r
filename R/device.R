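# Device geometry, doping and material description of the open-gate JFET:
# a thin p-type epitaxial channel (thickness tp) on a thick n-type substrate
# (thickness tn), gated from the top by the exposed native-oxide window of
# length L_OG and from the bottom by the back-gate p-n junction.
# Coordinate convention: x = 0 at the open-gate (top) surface, increasing
# toward the back gate.

#' Semiconductor material description
#'
#' Silicon-like defaults.  Carrier statistics are Boltzmann by default; the
#' `"fermi_dirac"` option applies a Fermi-Dirac degeneracy correction to the
#' equilibrium/contact carrier relations (transport coefficients keep the
#' drift-diffusion form either way).
#'
#' @param ni_per_cm3 intrinsic carrier density in 1/cm^3 (default 1e10 at
#'   300 K).
#' @param mu_n_cm2,mu_p_cm2 electron/hole mobilities in cm^2/(V s)
#'   (defaults 1417 and 470).
#' @param eps_r relative permittivity (silicon 11.7).
#' @param Eg0_eV bandgap in eV; `chi0_eV` electron affinity in eV.
#' @param Nc_per_cm3,Nv_per_cm3 effective densities of states, 1/cm^3.
#' @param alpha band-edge split fraction of the bandgap narrowing `dEg_eV`
#'   (conduction edge takes `alpha * dEg`).
#' @param dEg_eV bandgap narrowing in eV (default 0).
#' @param tau_n_s,tau_p_s SRH lifetimes in seconds.
#' @param statistics `"boltzmann"` or `"fermi_dirac"`.
#' @return An object of class `material` with all quantities converted to SI.
#' @export
material <- function(ni_per_cm3 = 1e10, mu_n_cm2 = 1417, mu_p_cm2 = 470,
                     eps_r = 11.7, Eg0_eV = 1.12, chi0_eV = 4.05,
                     Nc_per_cm3 = 2.8e19, Nv_per_cm3 = 1.04e19,
                     alpha = 0.5, dEg_eV = 0,
                     tau_n_s = 1e-6, tau_p_s = 1e-6,
                     statistics = c("boltzmann", "fermi_dirac")) {
  statistics <- match.arg(statistics)
  vals <- c(ni_per_cm3, mu_n_cm2, mu_p_cm2, eps_r, Nc_per_cm3, Nv_per_cm3,
            tau_n_s, tau_p_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("densities, mobilities, permittivity and lifetimes must be positive",
         call. = FALSE)
  if (alpha < 0 || alpha > 1)
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  structure(
    list(ni = ni_per_cm3 * 1e6, mu_n = mu_n_cm2 * 1e-4, mu_p = mu_p_cm2 * 1e-4,
         eps = eps_r * .k_eps0, eps_r = eps_r,
         Eg0 = Eg0_eV, chi0 = chi0_eV,
         Nc = Nc_per_cm3 * 1e6, Nv = Nv_per_cm3 * 1e6,
         alpha = alpha, dEg = dEg_eV,
         tau_n = tau_n_s, tau_p = tau_p_s,
         statistics = statistics),
    class = "material")
}

#' Open-gate JFET device description
#'
#' Defaults are the design parameters of the simulated/fabricated sensor:
#' 1.6 um p-channel (NA = 5e15/cm^3) on a 450 um n substrate
#' (ND = 1e18/cm^3), 100 um gate window, 1000 um depth, with an analytic
#' Gaussian-decay doping transition at the metallurgical junction.
#'
#' @param tp_um p-layer (channel) thickness, um.
#' @param tn_um n-substrate thickness, um.
#' @param L_OG_um open-gate window length, um.
#' @param depth_um third-dimension channel depth, um.
#' @param NA_per_cm3 acceptor density of the p channel, 1/cm^3.
#' @param ND_per_cm3 donor density of the n substrate, 1/cm^3.
#' @param sd_doping_per_cm3 source/drain implant density, 1/cm^3 (carried for
#'   configuration fidelity; the implants are not distinct solver regions).
#' @param Ls_um,W_um source/drain contact length and width, um.
#' @param L_MS_um source/drain minimum surround, um.
#' @param gauss_sigma_um Gaussian decay length of the doping transition, um.
#' @param mat a [material()].
#' @return An object of class `device` with SI fields (`tp`, `tn`, `L_OG`,
#'   `depth`, `NA_`, `ND`, `gauss_sigma`, ... in m and 1/m^3).
#' @export
device <- function(tp_um = 1.6, tn_um = 450, L_OG_um = 100, depth_um = 1000,
                   NA_per_cm3 = 5e15, ND_per_cm3 = 1e18,
                   sd_doping_per_cm3 = 2e16, Ls_um = 20, W_um = 1000,
                   L_MS_um = 10, gauss_sigma_um = 0.05, mat = material()) {
  stopifnot(inherits(mat, "material"))
  geom <- c(tp_um, tn_um, L_OG_um, depth_um, gauss_sigma_um)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("geometry lengths must be positive", call. = FALSE)
  if (!is.finite(NA_per_cm3) || NA_per_cm3 <= 0 ||
      !is.finite(ND_per_cm3) || ND_per_cm3 <= 0)
    stop("doping densities must be positive", call. = FALSE)
  structure(
    list(tp = tp_um * 1e-6, tn = tn_um * 1e-6,
         L_OG = L_OG_um * 1e-6, depth = depth_um * 1e-6,
         NA_ = NA_per_cm3 * 1e6, ND = ND_per_cm3 * 1e6,
         sd_doping = sd_doping_per_cm3 * 1e6,
         Ls = Ls_um * 1e-6, W = W_um * 1e-6, L_MS = L_MS_um * 1e-6,
         gauss_sigma = gauss_sigma_um * 1e-6,
         material = mat),
    class = "device")
}

#' @export
print.device <- function(x, ...) {
  cat("device (open-gate JFET, vertical p-on-n)\n")
  cat(sprintf("  p channel: tp = %.3g um, NA = %.3g /cm^3\n",
              x$tp * 1e6, x$NA_ * 1e-6))
  cat(sprintf("  n substrate: tn = %.3g um, ND = %.3g /cm^3\n",
              x$tn * 1e6, x$ND * 1e-6))
  cat(sprintf("  gate window L_OG = %.3g um, depth = %.3g um\n",
              x$L_OG * 1e6, x$depth * 1e6))
  invisible(x)
}

#' Net doping profile along the vertical axis
#'
#' Signed net doping ND(x) - NA(x) in 1/m^3.  Each species is constant in
#' its home region and decays as a Gaussian of length `gauss_sigma` past the
#' metallurgical junction at x = tp, giving a smooth transition with exactly
#' one sign change just above the junction.
#'
#' @param x position(s) in metres, 0 <= x <= tp + tn.
#' @param dev a [device()].
#' @return Net signed doping density in 1/m^3 (negative = p-type).
#' @export
net_doping <- function(x, dev) {
  stopifnot(inherits(dev, "device"), is.numeric(x))
  if (any(x < 0 | x > dev$tp + dev$tn))
    stop("'x' outside the device [0, tp + tn]", call. = FALSE)
  u <- (x - dev$tp) / dev$gauss_sigma
  na <- dev$NA_ * ifelse(u <= 0, 1, exp(-u^2))
  nd <- dev$ND  * ifelse(u >= 0, 1, exp(-u^2))
  nd - na
}

#' Graded vertical mesh
#'
#' Deterministic 1-D mesh over `[0, tp + tn]`, geometrically refined near the
#' top (gate) surface, the metallurgical junction and the back contact.  The
#' top-surface spacing must resolve sub-nanometre accumulation layers, so it
#' defaults to 0.2 nm; adjacent cell sizes never differ by more than a
#' factor `ratio`.
#'
#' @param dev a [device()].
#' @param n_nodes requested minimum node count (>= 50); the generated mesh
#'   may exceed it slightly to satisfy the grading constraints.
#' @param dx_surface top-surface spacing, m.
#' @param dx_junction junction-region spacing, m (default `gauss_sigma / 4`).
#' @param ratio maximum adjacent-cell size ratio (<= 3).
#' @return An object of class `mesh1d`: list with node positions `x` (m).
#' @export
build_mesh <- function(dev, n_nodes = 300, dx_surface = 2e-10,
                       dx_junction = NULL, ratio = 1.5) {
  stopifnot(inherits(dev, "device"))
  if (n_nodes < 50) stop("'n_nodes' must be at least 50", call. = FALSE)
  if (ratio <= 1 || ratio > 3) stop("'ratio' must be in (1, 3]", call. = FALSE)
  if (is.null(dx_junction)) dx_junction <- dev$gauss_sigma / 4
  L <- dev$tp + dev$tn

  # Cell sizes grow geometrically away from each refinement anchor and are
  # capped so the total count stays near n_nodes.
  anchors <- c(0, dev$tp, L)
  dx_anchor <- c(dx_surface, dx_junction, L / n_nodes)
  dx_max <- L / max(30, round(n_nodes / 6))

  local_dx <- function(x) {
    d <- pmax(abs(outer(x, anchors, "-")), 0)
    # allowed size near each anchor: dx_anchor * ratio^(distance/dx profile)
    # approximated by dx_anchor + (ratio - 1) * distance
    dx <- sweep(d * (ratio - 1), 2, dx_anchor, "+")
    pmin(apply(dx, 1, min), dx_max)
  }

  x <- 0
  repeat {
    xc <- x[length(x)]
    if (xc >= L) break
    step <- local_dx(xc)
    xn <- min(xc + step, L)
    # avoid a terminal sliver smaller than half the local step
    if (L - xn < step / 2) xn <- L
    x <- c(x, xn)
  }
  # enforce nodes count by subdividing the largest cells if short
  while (length(x) < n_nodes) {
    h <- diff(x)
    i <- which.max(h)
    x <- sort(c(x, x[i] + h[i] / 2))
  }
  structure(list(x = x, n = length(x)), class = "mesh1d")
}

#' @export
print.mesh1d <- function(x, ...) {
  h <- diff(x$x)
  cat(sprintf("mesh1d: %d nodes over [0, %.4g] m, dx in [%.3g, %.3g] m\n",
              x$n, max(x$x), min(h), max(h)))
  invisible(x)
}

#' Shockley-Read-Hall net recombination rate
#'
#' Trap-assisted net recombination with a midgap trap level:
#' U = (n p - ni^2) / (tau_p (n + ni) + tau_n (p + ni)), in 1/(m^3 s).
#' Positive for excess carriers (n p > ni^2), zero in equilibrium.
#'
#' @param n,p carrier densities in 1/m^3 (vectorized, > 0).
#' @param mat a [material()].
#' @return Net recombination rate in 1/(m^3 s).
#' @export
srh_rate <- function(n, p, mat) {
  stopifnot(inherits(mat, "material"), all(n > 0), all(p > 0))
  ni <- mat$ni
  (n * p - ni^2) / (mat$tau_p * (n + ni) + mat$tau_n * (p + ni))
}

#' Band edges from the electrostatic potential
#'
#' Ec = -(V + chi0) - alpha dEg and Ev = -(V + chi0 + Eg0) + (1 - alpha) dEg
#' in eV, with V the electrostatic potential in volts.  With dEg = 0 the
#' separation Ec - Ev equals Eg0 everywhere.
#'
#' @param V electrostatic potential, volts (vectorized).
#' @param mat a [material()].
#' @return A list with numeric vectors `Ec` and `Ev` (eV).
#' @export
band_edges <- function(V, mat) {
  stopifnot(inherits(mat, "material"), is.numeric(V))
  list(Ec = -(V + mat$chi0) - mat$alpha * mat$dEg,
       Ev = -(V + mat$chi0 + mat$Eg0) + (1 - mat$alpha) * mat$dEg)
}

#' Abrupt-junction depletion widths (closed form)
#'
#' Standard depletion approximation for the p-n junction:
#' w_total = sqrt(2 eps (Vbi - V) / q * (NA + ND) / (NA ND)), split so that
#' w_p NA = w_n ND.  Serves as the analytic oracle for the numerical solver
#' in the abrupt-junction limit.
#'
#' @param dev a [device()].
#' @param V_applied junction bias in volts (positive = forward, p above n);
#'   must be below the built-in potential.
#' @return A list with `w_p`, `w_n`, `w_total` (m) and `Vbi` (V, at the
#'   material's 300 K-referenced thermal voltage using T_K).
#' @param T_K temperature in kelvin.
#' @export
depletion_width_analytic <- function(dev, V_applied = 0, T_K = 300) {
  stopifnot(inherits(dev, "device"))
  mat <- dev$material
  Vt <- thermal_voltage(T_K)
  Vbi <- Vt * log(dev$NA_ * dev$ND / mat$ni^2)
  if (V_applied >= Vbi)
    stop("'V_applied' must be below the built-in potential", call. = FALSE)
  w <- sqrt(2 * mat$eps * (Vbi - V_applied) / .k_q *
              (dev$NA_ + dev$ND) / (dev$NA_ * dev$ND))
  w_p <- w * dev$ND / (dev$NA_ + dev$ND)
  w_n <- w * dev$NA_ / (dev$NA_ + dev$ND)
  list(w_p = w_p, w_n = w_n, w_total = w, Vbi = Vbi)
}

#' p-layer resistivity
#'
#' rho = 1 / (q NA mu_p) for the epitaxial channel with the default hole
#' mobility; about 2.66 ohm cm for NA = 5e15/cm^3 and mu_p = 470 cm^2/(V s),
#' consistent with the 3.0 ohm cm +/- 10% epitaxial specification.
#'
#' @param dev a [device()].
#' @return Resistivity in ohm metres (multiply by 100 for ohm cm).
#' @export
layer_resistivity <- function(dev) {
  stopifnot(inherits(dev, "device"))
  1 / (.k_q * dev$NA_ * dev$material$mu_p)
}

# --- Fermi-Dirac helpers -----------------------------------------------------

#' Fermi-Dirac integral of order 1/2 (normalized)
#'
#' Approximation of F_{1/2}(eta) / (sqrt(pi)/2), i.e. the degeneracy-corrected
#' ratio n / (Nc exp(eta)) multiplier such that n = Nc * fermi_half(eta).
#' Uses the Bednarczyk-Bednarczyk closed form (max error ~0.4%); reduces to
#' exp(eta) for eta << 0.
#'
#' @param eta reduced Fermi level (Ef - Ec)/kT, vectorized.
#' @return n/Nc.
#' @export
fermi_half <- function(eta) {
  a <- eta^4 + 50 + 33.6 * eta * (1 - 0.68 * exp(-0.17 * (eta + 1)^2))
  nu <- a^(-3 / 8)
  1 / (exp(-eta) + 3 * sqrt(pi) / 4 * nu)
}

#' Inverse of the normalized Fermi-Dirac integral of order 1/2
#'
#' Joyce-Dixon series inverse: eta(u) = log(u) + sum a_k u^k for u = n/Nc,
#' accurate for u up to ~8; reduces to log(u) in the non-degenerate limit.
#'
#' @param u ratio n/Nc (positive).
#' @return Reduced Fermi level eta.
#' @export
inv_fermi_half <- function(u) {
  stopifnot(all(u > 0))
  a1 <- 3.53553e-1; a2 <- -4.95009e-3; a3 <- 1.48386e-4; a4 <- -4.42563e-6
  log(u) + a1 * u + a2 * u^2 + a3 * u^3 + a4 * u^4
}
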