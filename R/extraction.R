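# Characterization analyses: constant-current reference-voltage
# sensitivity, current sensitivity versus bias, step-response analysis of
# time traces, and electrolyte Debye screening length.

#' Sensitivity fit result
#'
#' @param slope fitted slope in the units given by `units`.
#' @param intercept fitted intercept.
#' @param r_squared coefficient of determination.
#' @param reference reference current (A) or fixed Vds (V) the fit refers to.
#' @param n_points number of analyte levels fitted.
#' @param units slope units string.
#' @param slope_se standard error of the slope (same units as `slope`).
#' @return Object of class `sensitivity_result`.
#' @export
sensitivity_result <- function(slope, intercept, r_squared, reference,
                               n_points, units, slope_se = NA_real_) {
  stopifnot(n_points >= 2, is.na(r_squared) ||
              (r_squared >= -1e-12 && r_squared <= 1 + 1e-12))
  structure(list(slope = slope, intercept = intercept,
                 r_squared = min(max(r_squared, 0), 1),
                 reference = reference, n_points = n_points,
                 units = units, slope_se = slope_se),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("sensitivity: %.6g %s (intercept %.6g, r^2 %.6f, n = %d)\n",
              x$slope, x$units, x$intercept, x$r_squared, x$n_points))
  cat(sprintf("  reference: %.4g\n", x$reference))
  invisible(x)
}

# closed-form simple OLS (avoids lm()'s perfect-fit warnings on exact
# synthetic recoveries)
.ols <- function(xv, yv) {
  n <- length(xv)
  xm <- mean(xv); ym <- mean(yv)
  sxx <- sum((xv - xm)^2)
  if (sxx == 0) stop("degenerate fit: all analyte values equal",
                     call. = FALSE)
  slope <- sum((xv - xm) * (yv - ym)) / sxx
  intercept <- ym - slope * xm
  res <- yv - intercept - slope * xv
  sst <- sum((yv - ym)^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  se <- if (n > 2) sqrt(sum(res^2) / (n - 2) / sxx) else NA_real_
  list(slope = slope, intercept = intercept,
       r_squared = max(min(r2, 1), 0), slope_se = se)
}

#' Constant-current reference voltage
#'
#' The back-gate voltage required to hold a drain current `I_ref` on a
#' transfer curve, by piecewise-linear inverse interpolation of the
#' (current, voltage) samples.  Input point order is irrelevant (the curve
#' is sorted internally); currents must be strictly monotone along the
#' sweep and `I_ref` must lie within their span (no extrapolation).
#'
#' @param curve an [iv_curve()] over Vgs (or any data.frame with `sweep_V`
#'   and `Ids_A` columns).
#' @param I_ref reference current, A.
#' @return Interpolated reference voltage, V.
#' @export
reference_voltage <- function(curve, I_ref) {
  if (!all(c("sweep_V", "Ids_A") %in% names(curve)))
    stop("'curve' needs 'sweep_V' and 'Ids_A' columns", call. = FALSE)
  stopifnot(is.finite(I_ref))
  d <- curve[order(curve$sweep_V), c("sweep_V", "Ids_A")]
  dI <- diff(d$Ids_A)
  if (!(all(dI > 0) || all(dI < 0)))
    stop("curve current is not strictly monotone in the sweep voltage",
         call. = FALSE)
  lo <- min(d$Ids_A); hi <- max(d$Ids_A)
  if (I_ref < lo || I_ref > hi)
    stop(sprintf(
      "I_ref = %.4g A outside the curve current span [%.4g, %.4g] A",
      I_ref, lo, hi), call. = FALSE)
  d <- d[order(d$Ids_A), ]
  stats::approx(d$Ids_A, d$sweep_V, xout = I_ref, ties = "ordered")$y
}

#' Constant-current voltage sensitivity
#'
#' Extracts the reference voltage at `I_ref` from every curve of a transfer
#' family and fits reference voltage against analyte level by ordinary
#' least squares.  The slope, in mV per analyte unit, is the voltage
#' sensitivity of the sensor at that reference current.
#'
#' @param fam an [iv_family()] sweeping Vgs, with at least two distinct
#'   analyte levels.
#' @param I_ref reference current, A.
#' @return A [sensitivity_result()] with slope in mV per analyte unit.
#' @export
voltage_sensitivity <- function(fam, I_ref) {
  stopifnot(inherits(fam, "iv_family"))
  if (fam$sweep_name[1] != "Vgs")
    stop("voltage sensitivity needs a Vgs-sweep (transfer) family",
         call. = FALSE)
  curves <- family_curves(fam)
  lev <- as.numeric(names(curves))
  if (length(unique(lev)) < 2)
    stop("need at least two distinct analyte levels", call. = FALSE)
  vref <- vapply(curves, reference_voltage, numeric(1), I_ref = I_ref)
  f <- .ols(lev, vref * 1e3)
  sensitivity_result(f$slope, f$intercept, f$r_squared, reference = I_ref,
                     n_points = length(lev),
                     units = sprintf("mV/%s", fam$analyte_name[1]),
                     slope_se = f$slope_se)
}

#' Current sensitivity versus analyte level
#'
#' Least-squares slope of drain current against analyte level at fixed
#' bias.  Accepts either a long Ids-Vds [iv_family()] (one fit per
#' requested Vds value) or a plain data.frame of fixed-bias currents with
#' columns `analyte_value` and `Ids_A` (single fit).
#'
#' @param x an [iv_family()] over Vds, or a data.frame with columns
#'   `analyte_value`, `Ids_A`.
#' @param Vds_at for the family form: Vds values at which to fit (default:
#'   every shared sweep point).
#' @param reference recorded reference for the data.frame form (e.g. the
#'   fixed Vds), V.
#' @return A single [sensitivity_result()] (data.frame form) or a list of
#'   them named by Vds (family form), slopes in A per analyte unit.
#' @export
current_sensitivity <- function(x, Vds_at = NULL, reference = NA_real_) {
  if (inherits(x, "iv_family")) {
    if (x$sweep_name[1] != "Vds")
      stop("family form needs a Vds-sweep (output) family", call. = FALSE)
    curves <- family_curves(x)
    lev <- as.numeric(names(curves))
    if (length(unique(lev)) < 2)
      stop("need at least two distinct analyte levels", call. = FALSE)
    if (is.null(Vds_at))
      Vds_at <- Reduce(intersect, lapply(curves, function(d) d$sweep_V))
    if (length(Vds_at) == 0)
      stop("no shared Vds sweep points across curves", call. = FALSE)
    out <- lapply(Vds_at, function(vd) {
      ids <- vapply(curves, function(d) {
        i <- which(abs(d$sweep_V - vd) < 1e-12)
        if (length(i) != 1)
          stats::approx(d$sweep_V, d$Ids_A, xout = vd, ties = "ordered")$y
        else d$Ids_A[i]
      }, numeric(1))
      f <- .ols(lev, ids)
      sensitivity_result(f$slope, f$intercept, f$r_squared, reference = vd,
                         n_points = length(lev),
                         units = sprintf("A/%s", x$analyte_name[1]),
                         slope_se = f$slope_se)
    })
    names(out) <- as.character(Vds_at)
    if (length(out) == 1) out[[1]] else out
  } else {
    if (!all(c("analyte_value", "Ids_A") %in% names(x)))
      stop("data.frame form needs 'analyte_value' and 'Ids_A' columns",
           call. = FALSE)
    if (length(unique(x$analyte_value)) < 2)
      stop("need at least two distinct analyte levels", call. = FALSE)
    f <- .ols(x$analyte_value, x$Ids_A)
    sensitivity_result(f$slope, f$intercept, f$r_squared,
                       reference = reference, n_points = nrow(x),
                       units = "A/analyte", slope_se = f$slope_se)
  }
}

#' Step response of a current time trace
#'
#' Locates the largest sustained level shift of the trace (maximum
#' normalized two-sample mean contrast over all split points), takes robust
#' medians of the pre- and post-transition windows as baseline and plateau,
#' and measures the 10%-to-90% transition time on a rolling-median-smoothed
#' copy of the trace.  If the level shift does not exceed the noise floor
#' the result reports no event.
#'
#' @param trace a data.frame with strictly increasing `time_s` and `Ids_A`
#'   columns (>= 10 samples), e.g. from [step_trace()] or [read_trace()].
#' @param noise_mult event threshold in units of the estimated noise SD
#'   (from the median absolute first difference), default 6.
#' @param rel_floor minimum relative shift treated as an event, default
#'   1e-6 of the baseline magnitude.
#' @param smooth_k rolling-median half-width (samples) for the crossing
#'   detection.
#' @return A list with `event` (logical), `baseline_A`, `plateau_A`,
#'   `fold_change`, `transition_time_s` (all `NA` when no event).
#' @export
step_response <- function(trace, noise_mult = 6, rel_floor = 1e-6,
                          smooth_k = 2) {
  if (!all(c("time_s", "Ids_A") %in% names(trace)))
    stop("'trace' needs 'time_s' and 'Ids_A' columns", call. = FALSE)
  if (nrow(trace) < 10)
    stop("step analysis needs at least 10 samples", call. = FALSE)
  if (any(diff(trace$time_s) <= 0))
    stop("'time_s' must be strictly increasing", call. = FALSE)
  t <- trace$time_s; y <- trace$Ids_A; n <- length(y)

  cs <- cumsum(y)
  k <- 1:(n - 1)
  contrast <- abs(cs[k] / k - (cs[n] - cs[k]) / (n - k)) *
    sqrt(k * (n - k) / n)
  kk <- which.max(contrast)
  baseline <- stats::median(y[1:kk])
  plateau <- stats::median(y[(kk + 1):n])
  shift <- plateau - baseline

  noise_sd <- stats::median(abs(diff(y))) / (sqrt(2) * 0.6745)
  if (abs(shift) <= max(noise_mult * noise_sd, rel_floor * abs(baseline),
                        .Machine$double.xmin))
    return(list(event = FALSE, baseline_A = NA_real_, plateau_A = NA_real_,
                fold_change = NA_real_, transition_time_s = NA_real_))

  ys <- stats::runmed(y, 2 * smooth_k + 1)
  l10 <- baseline + 0.1 * shift
  l90 <- baseline + 0.9 * shift
  past90 <- if (shift > 0) ys >= l90 else ys <= l90
  below10 <- if (shift > 0) ys <= l10 else ys >= l10
  i90 <- which(past90)[1]
  i10 <- max(which(below10[seq_len(max(i90 - 1, 1))]), 1)
  tt <- t[i90] - t[i10]

  list(event = TRUE, baseline_A = baseline, plateau_A = plateau,
       fold_change = plateau / baseline, transition_time_s = tt)
}

#' Electrolyte Debye screening length
#'
#' lambda_D = sqrt(eps_r eps0 kB T / (2 N_Avogadro q^2 I * 1000)) for a
#' 1:1-equivalent ionic strength I in mol/L.  About 0.78 nm at
#' physiological ionic strength (0.15 M, 298.15 K, eps_r 78.5); charge
#' farther than a few lambda_D from the oxide is screened from the gate.
#'
#' @param ionic_strength ionic strength, mol/L (> 0).
#' @param T_K temperature, kelvin.
#' @param eps_r relative permittivity of the solvent (water 78.5).
#' @return Debye length in metres.
#' @export
debye_length <- function(ionic_strength, T_K = 298.15, eps_r = 78.5) {
  if (any(!is.finite(ionic_strength)) || any(ionic_strength <= 0))
    stop("'ionic_strength' must be positive (mol/L)", call. = FALSE)
  if (T_K <= 0 || eps_r <= 0)
    stop("'T_K' and 'eps_r' must be positive", call. = FALSE)
  sqrt(eps_r * .k_eps0 * .k_kB * T_K /
         (2 * .k_NAv * .k_q^2 * ionic_strength * 1000))
}
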