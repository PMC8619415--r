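# 1-D drift-diffusion-Poisson core for the vertical p-on-n structure.
#
# The vertical axis runs from the open-gate (top) surface at x = 0 to the
# back-gate contact at x = tp + tn.  Three solvers share one finite-volume
# discretization:
#   * solve_equilibrium  - zero-bias nonlinear Poisson, gate-window sheet
#     charge or ohmic top boundary;
#   * solve_channel      - nonlinear Poisson with split quasi-Fermi levels
#     (holes at the local channel potential, electrons at the back-gate
#     potential), used by the gradual-channel coupling;
#   * solve_bias         - full Gummel drift-diffusion solve of the vertical
#     diode (Scharfetter-Gummel edge currents, SRH recombination) between
#     the top p-contact and the back gate.

# Thomas algorithm for tridiagonal systems (lower, diag, upper, rhs).
.thomas <- function(lo, di, up, rhs) {
  n <- length(di)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- up[1] / di[1]
  dp[1] <- rhs[1] / di[1]
  for (i in 2:n) {
    m <- di[i] - lo[i] * cp[i - 1]
    cp[i] <- if (i < n) up[i] / m else 0
    dp[i] <- (rhs[i] - lo[i] * dp[i - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Bernoulli function B(x) = x / (exp(x) - 1), numerically stable.
.bernoulli <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  out[small] <- 1 - x[small] / 2 + x[small]^2 / 12
  xs <- x[!small]
  out[!small] <- ifelse(xs > 500, 0, xs / (expm1(xs)))
  out
}

.clamp_exp <- function(x) exp(pmin(pmax(x, -500), 500))

# Carrier densities and their psi-derivatives for given quasi-Fermi levels
# (volts).  Boltzmann closed form or Fermi-Dirac via the F_{1/2} approximant.
.carriers <- function(psi, phi_n, phi_p, mat, Vt) {
  if (mat$statistics == "boltzmann") {
    n <- mat$ni * .clamp_exp((psi - phi_n) / Vt)
    p <- mat$ni * .clamp_exp((phi_p - psi) / Vt)
    list(n = n, p = p, dn = n / Vt, dp = -p / Vt)
  } else {
    dEc <- Vt * log(mat$Nc / mat$ni)
    dEv <- Vt * log(mat$Nv / mat$ni)
    eta_n <- pmin((psi - phi_n - dEc) / Vt, 30)
    eta_p <- pmin((phi_p - psi - dEv) / Vt, 30)
    n <- mat$Nc * fermi_half(eta_n)
    p <- mat$Nv * fermi_half(eta_p)
    h <- 1e-4
    dn <- mat$Nc * (fermi_half(eta_n + h) - fermi_half(eta_n - h)) / (2 * h) / Vt
    dp <- -mat$Nv * (fermi_half(eta_p + h) - fermi_half(eta_p - h)) / (2 * h) / Vt
    list(n = n, p = p, dn = dn, dp = dp)
  }
}

# Charge-neutral potential for doping N (signed) at quasi-Fermi phi.
.neutral_psi <- function(N, mat, Vt, phi = 0) {
  if (mat$statistics == "boltzmann")
    return(phi + Vt * asinh(N / (2 * mat$ni)))
  vapply(seq_along(N), function(i) {
    f <- function(psi) {
      cc <- .carriers(psi, phi, phi, mat, Vt)
      cc$n - cc$p - N[i]
    }
    stats::uniroot(f, c(phi - 2, phi + 2), tol = 1e-12)$root
  }, numeric(1))
}

# Damped Newton solve of the nonlinear Poisson equation.
#   top_bc: "gate" (Neumann with sheet charge sigma0) or "dirichlet".
# psi_bot is always Dirichlet.  Returns list(psi, converged, iters, dpsi).
.poisson_newton <- function(mesh, eps, dop, mat, Vt, phi_n, phi_p,
                            sigma0 = 0, top_bc = "gate",
                            psi_top = NA_real_, psi_bot, psi_init,
                            tol = NULL, maxit = 200) {
  if (is.null(tol)) tol <- 1e-6 * Vt
  x <- mesh$x; n_nodes <- mesh$n
  h <- diff(x)
  s <- c(h[1] / 2, (h[-1] + h[-(n_nodes - 1)]) / 2, h[n_nodes - 1] / 2)
  psi <- psi_init
  psi[n_nodes] <- psi_bot
  if (top_bc == "dirichlet") psi[1] <- psi_top

  resid_fun <- function(psi) {
    cc <- .carriers(psi, phi_n, phi_p, mat, Vt)
    rho <- .k_q * (cc$p - cc$n + dop)
    flux <- eps * diff(psi) / h            # eps * dpsi/dx on edges
    Fv <- numeric(n_nodes)
    Fv[2:(n_nodes - 1)] <- diff(flux) + rho[2:(n_nodes - 1)] * s[2:(n_nodes - 1)]
    Fv[1] <- flux[1] + sigma0 + rho[1] * s[1]
    Fv[n_nodes] <- 0
    if (top_bc == "dirichlet") Fv[1] <- 0
    list(F = Fv, cc = cc)
  }

  r <- resid_fun(psi)
  iters <- 0; dpsi_max <- Inf
  for (it in seq_len(maxit)) {
    iters <- it
    cc <- r$cc
    dq <- .k_q * (cc$dp - cc$dn)           # d(rho)/d(psi)
    lo <- c(0, eps / h)                    # coupling to psi_{i-1}
    up <- c(eps / h, 0)                    # coupling to psi_{i+1}
    di <- numeric(n_nodes)
    di[2:(n_nodes - 1)] <- -eps * (1 / h[-1] + 1 / h[-(n_nodes - 1)]) +
      dq[2:(n_nodes - 1)] * s[2:(n_nodes - 1)]
    di[1] <- -eps / h[1] + dq[1] * s[1]
    di[n_nodes] <- 1; lo[n_nodes] <- 0
    if (top_bc == "dirichlet") { di[1] <- 1; up[1] <- 0 }
    delta <- .thomas(lo, di, up, -r$F)
    # potential damping: updates saturate smoothly at a few thermal voltages
    delta <- delta / (1 + abs(delta) / (4 * Vt))
    psi <- psi + delta
    r <- resid_fun(psi)
    dpsi_max <- max(abs(delta))
    if (dpsi_max < tol) break
  }
  list(psi = psi, converged = dpsi_max < tol, iters = iters,
       dpsi = dpsi_max, resid = sqrt(sum(r$F^2)))
}

# Shared precomputation for a device/mesh pair.
.grid_of <- function(dev, mesh) {
  list(dop = net_doping(mesh$x, dev), eps = dev$material$eps)
}

.field_obj <- function(mesh, psi, n, p, Jn = NULL, Jp = NULL, U = NULL,
                       meta = list()) {
  structure(list(x = mesh$x, psi = psi, n = n, p = p,
                 Jn = Jn, Jp = Jp, U = U, meta = meta),
            class = "carrier_field")
}

#' @export
print.carrier_field <- function(x, ...) {
  cat(sprintf("carrier_field: %d nodes, psi in [%.4g, %.4g] V\n",
              length(x$x), min(x$psi), max(x$psi)))
  m <- x$meta
  if (!is.null(m$converged))
    cat(sprintf("  converged: %s (%d iterations, max dpsi %.2e V)\n",
                m$converged, m$iters, m$dpsi))
  if (!is.null(m$I_A))
    cat(sprintf("  terminal current: %.4g A (conservation %.2e)\n",
                m$I_A, m$conservation))
  invisible(x)
}

#' Zero-bias equilibrium solution of the vertical structure
#'
#' Solves the nonlinear Poisson equation with equilibrium carrier statistics
#' (single Fermi level).  The back contact is ohmic (charge-neutral
#' Dirichlet); the top boundary is either the gate window, carrying an
#' areal sheet charge `sigma0` through the displacement jump
#' eps * dpsi/dx = -sigma0, or an ohmic contact.
#'
#' @param dev a [device()].
#' @param mesh a [build_mesh()] result.
#' @param sigma0 gate-window surface charge density, C/m^2.
#' @param top_bc `"gate"` (insulated window with sheet charge) or `"ohmic"`.
#' @param T_K lattice temperature, kelvin.
#' @param tol Newton update tolerance on psi in units of the thermal voltage.
#' @param maxit maximum Newton iterations per continuation step.
#' @return A `carrier_field` (positions, potential, carrier densities, and a
#'   `meta` list with convergence diagnostics).  Non-convergence is an error
#'   reporting the final residual.
#' @export
solve_equilibrium <- function(dev, mesh, sigma0 = 0,
                              top_bc = c("gate", "ohmic"), T_K = 300,
                              tol = 1e-6, maxit = 200) {
  stopifnot(inherits(dev, "device"), inherits(mesh, "mesh1d"))
  top_bc <- match.arg(top_bc)
  mat <- dev$material
  Vt <- thermal_voltage(T_K)
  g <- .grid_of(dev, mesh)
  psi_bot <- .neutral_psi(g$dop[mesh$n], mat, Vt)
  psi0 <- .neutral_psi(g$dop, mat, Vt)
  psi_top <- if (top_bc == "ohmic") psi0[1] else NA_real_

  # continuation in sigma0 for strongly charged surfaces
  n_step <- max(1L, ceiling(abs(sigma0) / 2e-3))
  sol <- NULL; psi_init <- psi0
  for (k in seq_len(n_step)) {
    s_k <- sigma0 * k / n_step
    sol <- .poisson_newton(mesh, g$eps, g$dop, mat, Vt,
                           phi_n = 0, phi_p = 0, sigma0 = s_k,
                           top_bc = if (top_bc == "gate") "gate" else "dirichlet",
                           psi_top = psi_top, psi_bot = psi_bot,
                           psi_init = psi_init, tol = tol * Vt, maxit = maxit)
    psi_init <- sol$psi
  }
  if (!sol$converged)
    stop(sprintf("equilibrium solve did not converge (residual %.3e)",
                 sol$resid), call. = FALSE)
  cc <- .carriers(sol$psi, 0, 0, mat, Vt)
  .field_obj(mesh, sol$psi, cc$n, cc$p,
             meta = list(converged = TRUE, iters = sol$iters,
                         dpsi = sol$dpsi, sigma0 = sigma0, T_K = T_K,
                         Vt = Vt))
}

#' Channel electrostatics at a given junction reverse bias
#'
#' Nonlinear Poisson solve with split, spatially constant quasi-Fermi
#' levels: holes pinned to the local channel potential (taken as reference,
#' 0 V) and electrons to the back-gate potential `Vr` (so `Vr` > 0 is
#' reverse bias of the channel/substrate junction).  The top boundary is the
#' gate window with sheet charge `sigma0`.  This is the per-station vertical
#' problem of the gradual-channel approximation; transport is handled by
#' [channel_current()].
#'
#' @inheritParams solve_equilibrium
#' @param Vr junction reverse bias seen at this lateral station, volts.
#' @param psi_init optional warm-start potential from a nearby solve.
#' @return A `carrier_field`; `meta$sheet_holes` is the integrated hole
#'   sheet density (1/m^2) and `meta$w_p` the charge-equivalent p-side
#'   depletion width (m).
#' @export
solve_channel <- function(dev, mesh, sigma0 = 0, Vr = 0, T_K = 300,
                          tol = 1e-6, maxit = 200, psi_init = NULL) {
  stopifnot(inherits(dev, "device"), inherits(mesh, "mesh1d"))
  mat <- dev$material
  Vt <- thermal_voltage(T_K)
  g <- .grid_of(dev, mesh)

  solve_at <- function(vr, s0, init) {
    psi_bot <- .neutral_psi(g$dop[mesh$n], mat, Vt, phi = vr)
    .poisson_newton(mesh, g$eps, g$dop, mat, Vt,
                    phi_n = vr, phi_p = 0, sigma0 = s0, top_bc = "gate",
                    psi_bot = psi_bot, psi_init = init,
                    tol = tol * Vt, maxit = maxit)
  }

  if (is.null(psi_init)) {
    region_phi <- ifelse(g$dop > 0, Vr, 0)
    psi_init <- .neutral_psi(g$dop, mat, Vt) + region_phi
  }
  # continuation: bias in 0.5 V steps, then charge in 2e-3 C/m^2 steps
  sol <- NULL; init <- psi_init
  vr_steps <- if (abs(Vr) <= 0.5) Vr else seq(0.5, abs(Vr), by = 0.5) *
    sign(Vr)
  if (length(vr_steps) == 0 || vr_steps[length(vr_steps)] != Vr)
    vr_steps <- c(vr_steps, Vr)
  for (vr in vr_steps) {
    sol <- solve_at(vr, 0, init); init <- sol$psi
  }
  n_step <- max(1L, ceiling(abs(sigma0) / 2e-3))
  for (k in seq_len(n_step)) {
    if (sigma0 == 0) break
    sol <- solve_at(Vr, sigma0 * k / n_step, init); init <- sol$psi
  }
  if (is.null(sol)) sol <- solve_at(Vr, sigma0, psi_init)
  if (!sol$converged)
    stop(sprintf("channel solve did not converge (Vr = %.3g, residual %.3e)",
                 Vr, sol$resid), call. = FALSE)
  cc <- .carriers(sol$psi, Vr, 0, mat, Vt)

  x <- mesh$x
  p_side <- g$dop < 0
  trap <- function(y, keep = rep(TRUE, length(y))) {
    w <- diff(x); ym <- (y[-1] + y[-length(y)]) / 2
    km <- (keep[-1] & keep[-length(keep)])
    sum(w[km] * ym[km])
  }
  sheet <- trap(cc$p)                                   # holes / m^2
  w_p <- trap(pmax(1 - cc$p / dev$NA_, 0), p_side)      # charge-equiv. width
  .field_obj(mesh, sol$psi, cc$n, cc$p,
             meta = list(converged = TRUE, iters = sol$iters,
                         dpsi = sol$dpsi, sigma0 = sigma0, Vr = Vr,
                         T_K = T_K, Vt = Vt,
                         sheet_holes = sheet, w_p = w_p))
}

#' Steady-state drift-diffusion solve of the vertical diode
#'
#' Damped Gummel iteration (Poisson alternated with the two
#' Scharfetter-Gummel-discretized continuity equations, SRH recombination)
#' for the vertical p-n structure between the top p-side contact and the
#' back gate, both ohmic.  Bias is ramped by continuation steps of at most
#' 0.1 V from equilibrium.  After convergence a flux-consistency pass
#' re-solves both continuity equations against the identical frozen
#' recombination field, so the discrete total current is conserved across
#' every edge to machine precision.
#'
#' @inheritParams solve_equilibrium
#' @param bias a [bias_point()]: the junction voltage is `Vds - Vgs` (top
#'   p contact at `Vds`, back gate at `Vgs`); positive = forward.
#'   `bias$sigma0` is ignored here (the ohmic-contact cut carries no gate
#'   window).
#' @param max_cycles maximum Gummel cycles per continuation step.
#' @param Vj_max forward-bias guard: junction voltages above this value
#'   (default 0.85 V) are refused to avoid current overflow.
#' @return A `carrier_field` with edge currents `Jn`, `Jp` (A/m^2),
#'   recombination `U`, and `meta` containing the terminal current `I_A`
#'   (junction current density times the gate-window area `L_OG * depth`)
#'   and the relative current-conservation mismatch.
#' @export
solve_bias <- function(dev, mesh, bias, T_K = 300, tol = 1e-6,
                       max_cycles = 200, Vj_max = 0.85) {
  stopifnot(inherits(dev, "device"), inherits(mesh, "mesh1d"),
            inherits(bias, "bias_point"))
  Vj <- bias$Vds - bias$Vgs
  if (Vj > Vj_max)
    stop(sprintf("forward junction bias %.3g V exceeds the overflow guard %.3g V",
                 Vj, Vj_max), call. = FALSE)
  mat <- dev$material
  Vt <- thermal_voltage(T_K)
  g <- .grid_of(dev, mesh)
  x <- mesh$x; n_nodes <- mesh$n
  h <- diff(x)
  s <- c(h[1] / 2, (h[-1] + h[-(n_nodes - 1)]) / 2, h[n_nodes - 1] / 2)
  Dn <- Vt * mat$mu_n; Dp <- Vt * mat$mu_p
  ni <- mat$ni

  neutral_np <- function(N) {
    n <- (N + sqrt(N^2 + 4 * ni^2)) / 2
    list(n = n, p = ni^2 / n)
  }
  top_eq <- neutral_np(g$dop[1]); bot_eq <- neutral_np(g$dop[n_nodes])

  # equilibrium start (both contacts ohmic Dirichlet)
  eq <- solve_equilibrium(dev, mesh, sigma0 = 0, top_bc = "ohmic",
                          T_K = T_K, tol = tol)
  psi <- eq$psi; n <- eq$n; p <- eq$p

  # continuity solve for one carrier; linearized SRH unless U_frozen given.
  solve_continuity <- function(which, psi, n, p, bc1, bcN, U_frozen = NULL) {
    D <- if (which == "n") Dn else Dp
    d <- diff(psi) / Vt
    Bp <- .bernoulli(d); Bm <- .bernoulli(-d)
    den <- mat$tau_p * (n + ni) + mat$tau_n * (p + ni)
    lo <- numeric(n_nodes); up <- numeric(n_nodes); di <- numeric(n_nodes)
    rhs <- numeric(n_nodes)
    i <- 2:(n_nodes - 1)
    if (which == "n") {
      # Jn_{i+1/2} = (qD/h)[B(d) n_{i+1} - B(-d) n_i]; dJn/dx = +qU
      up_e <- D / h * Bp; lo_e <- D / h * Bm
      di[i] <- lo_e[i] + up_e[i - 1]
      up[i] <- -up_e[i]; lo[i] <- -lo_e[i - 1]
      if (is.null(U_frozen)) {
        di[i] <- di[i] + s[i] * p[i] / den[i]
        rhs[i] <- s[i] * ni^2 / den[i]
      } else rhs[i] <- -s[i] * U_frozen[i]
    } else {
      # Jp_{i+1/2} = (qD/h)[B(d) p_i - B(-d) p_{i+1}]; dJp/dx = -qU
      up_e <- D / h * Bm; lo_e <- D / h * Bp
      di[i] <- lo_e[i] + up_e[i - 1]
      up[i] <- -up_e[i]; lo[i] <- -lo_e[i - 1]
      if (is.null(U_frozen)) {
        di[i] <- di[i] + s[i] * n[i] / den[i]
        rhs[i] <- s[i] * ni^2 / den[i]
      } else rhs[i] <- -s[i] * U_frozen[i]
    }
    di[1] <- 1; up[1] <- 0; rhs[1] <- bc1
    di[n_nodes] <- 1; lo[n_nodes] <- 0; rhs[n_nodes] <- bcN
    pmax(.thomas(lo, di, up, rhs), 1e-300)
  }

  edge_currents <- function(psi, n, p) {
    d <- diff(psi) / Vt
    Bp <- .bernoulli(d); Bm <- .bernoulli(-d)
    Jn <- .k_q * Dn / h * (Bp * n[-1] - Bm * n[-n_nodes])
    Jp <- .k_q * Dp / h * (Bp * p[-n_nodes] - Bm * p[-1])
    list(Jn = Jn, Jp = Jp)
  }

  vj_steps <- if (Vj == 0) 0 else seq(0, Vj, by = sign(Vj) * 0.1)
  if (vj_steps[length(vj_steps)] != Vj) vj_steps <- c(vj_steps, Vj)

  cycles_used <- 0L; dpsi_max <- 0
  for (vj in vj_steps) {
    # contact potentials: hold back gate at 0 internally, top at vj
    # (only the difference matters in 1-D)
    phi_top <- vj; phi_bot <- 0
    psi_top <- .neutral_psi(g$dop[1], mat, Vt, phi = phi_top)
    psi_bot <- .neutral_psi(g$dop[n_nodes], mat, Vt, phi = phi_bot)
    for (cyc in seq_len(max_cycles)) {
      cycles_used <- cycles_used + 1L
      n <- solve_continuity("n", psi, n, p, top_eq$n, bot_eq$n)
      p <- solve_continuity("p", psi, n, p, top_eq$p, bot_eq$p)
      # Poisson with Gummel linearization: n, p slide along exp(+/- dpsi/Vt)
      flux <- g$eps * diff(psi) / h
      Fv <- numeric(n_nodes)
      i <- 2:(n_nodes - 1)
      rho <- .k_q * (p - n + g$dop)
      Fv[i] <- diff(flux) + rho[i] * s[i]
      lo <- c(0, g$eps / h); up <- c(g$eps / h, 0); di <- numeric(n_nodes)
      di[i] <- -g$eps * (1 / h[-1] + 1 / h[-(n_nodes - 1)]) -
        .k_q * s[i] * (p[i] + n[i]) / Vt
      di[1] <- 1; up[1] <- 0; Fv[1] <- psi[1] - psi_top
      di[n_nodes] <- 1; lo[n_nodes] <- 0; Fv[n_nodes] <- psi[n_nodes] - psi_bot
      dpsi <- .thomas(lo, di, up, -Fv)
      dpsi <- pmin(pmax(dpsi, -5 * Vt), 5 * Vt)   # damping
      psi <- psi + dpsi
      n <- n * .clamp_exp(dpsi / Vt)
      p <- p * .clamp_exp(-dpsi / Vt)
      dpsi_max <- max(abs(dpsi))
      if (dpsi_max < tol * Vt) break
    }
    if (dpsi_max >= tol * Vt)
      stop(sprintf(
        "Gummel iteration did not converge at Vj = %.3g V (max dpsi %.3e V); try smaller continuation steps",
        vj, dpsi_max), call. = FALSE)
  }

  # flux-consistency pass: identical frozen U in both continuity solves
  U <- srh_rate(n, p, mat)
  n <- solve_continuity("n", psi, n, p, top_eq$n, bot_eq$n, U_frozen = U)
  p <- solve_continuity("p", psi, n, p, top_eq$p, bot_eq$p, U_frozen = U)
  J <- edge_currents(psi, n, p)
  Jt <- J$Jn + J$Jp
  area <- dev$L_OG * dev$depth
  I_A <- stats::median(Jt) * area
  # in/out mismatch at the two contacts; full edge spread kept separately
  cons <- abs(Jt[1] - Jt[length(Jt)]) / max(abs(Jt), 1e-30)
  spread <- (max(Jt) - min(Jt)) / max(abs(Jt), 1e-30)

  .field_obj(mesh, psi, n, p, Jn = J$Jn, Jp = J$Jp, U = U,
             meta = list(converged = TRUE, iters = cycles_used,
                         dpsi = dpsi_max, Vj = Vj, T_K = T_K, Vt = Vt,
                         I_A = I_A, conservation = cons,
                         J_spread = spread, bias = bias))
}

#' Bias point
#'
#' Terminal biases and gate-window surface charge for one operating point.
#'
#' @param Vds drain-source voltage, V.
#' @param Vgs back-gate-source voltage, V (positive keeps the channel/
#'   substrate junction in reverse bias).
#' @param sigma0 gate-window surface charge density, C/m^2.
#' @return An object of class `bias_point`.
#' @export
bias_point <- function(Vds = 0, Vgs = 0, sigma0 = 0) {
  stopifnot(is.finite(Vds), is.finite(Vgs), is.finite(sigma0))
  structure(list(Vds = Vds, Vgs = Vgs, sigma0 = sigma0),
            class = "bias_point")
}
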