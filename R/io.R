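# Configuration loading/validation, CSV interchange for IV families and
# time traces, logging, and the command-line entry point.
#
# Configuration files are JSON with blocks `device`, `material`, `oxide`,
# `solver`, `extraction` (all optional; defaults applied and logged).  CSV
# is the sole tabular interchange, written with 12 significant digits.

.log_levels <- c(debug = 1L, info = 2L, warning = 3L)

#' Set the package log level
#'
#' @param level `"debug"`, `"info"` or `"warning"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warning")) {
  level <- match.arg(level)
  old <- getOption("ogjfet.log_level", "info")
  options(ogjfet.log_level = level)
  invisible(old)
}

.og_log <- function(level, fmt, ...) {
  thr <- .log_levels[[getOption("ogjfet.log_level", "info")]]
  if (.log_levels[[level]] >= thr)
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

# --- configuration -----------------------------------------------------------

.config_schema <- function() list(
  device = list(tp_um = 1.6, tn_um = 450, L_OG_um = 100, depth_um = 1000,
                NA_per_cm3 = 5e15, ND_per_cm3 = 1e18,
                sd_doping_per_cm3 = 2e16, Ls_um = 20, W_um = 1000,
                L_MS_um = 10, gauss_sigma_um = 0.05),
  material = list(ni_per_cm3 = 1e10, mu_n_cm2 = 1417, mu_p_cm2 = 470,
                  eps_r = 11.7, Eg0_eV = 1.12, chi0_eV = 4.05,
                  Nc_per_cm3 = 2.8e19, Nv_per_cm3 = 1.04e19, alpha = 0.5,
                  dEg_eV = 0, tau_n_s = 1e-6, tau_p_s = 1e-6,
                  statistics = "boltzmann"),
  oxide = list(Ns_per_cm2 = 5e12, pKa = 6, pKb = -2, Ceq_F_per_m2 = 0.2,
               T_K = 298.15),
  solver = list(n_nodes = 300, tol = 1e-6, max_cycles = 200,
                continuation_step_V = 0.1, T_K = 300, Von_V = 0.67),
  extraction = list(noise_mult = 6, rel_floor = 1e-6, smooth_k = 2))

.positive_keys <- list(
  device = c("tp_um", "tn_um", "L_OG_um", "depth_um", "NA_per_cm3",
             "ND_per_cm3", "sd_doping_per_cm3", "gauss_sigma_um"),
  material = c("ni_per_cm3", "mu_n_cm2", "mu_p_cm2", "eps_r", "Nc_per_cm3",
               "Nv_per_cm3", "tau_n_s", "tau_p_s"),
  oxide = c("Ns_per_cm2", "Ceq_F_per_m2", "T_K"),
  solver = c("n_nodes", "tol", "T_K"),
  extraction = c("noise_mult"))

#' Default run configuration
#'
#' @return A `run_config`: list of blocks `device`, `material`, `oxide`,
#'   `solver`, `extraction` with all defaults, plus `schema_version`.
#' @export
default_config <- function() {
  cfg <- .config_schema()
  cfg$schema_version <- 1L
  class(cfg) <- "run_config"
  cfg
}

#' Load and validate a configuration file
#'
#' Reads a JSON configuration, overlays it on the defaults, rejects unknown
#' blocks or keys (naming the offender), validates positivity constraints,
#' and logs which values fell back to defaults.  An empty file yields the
#' all-defaults configuration.
#'
#' @param path path to a JSON configuration file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (!nzchar(trimws(txt))) list()
  else tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                error = function(e)
                  stop("config parse error in '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  cfg <- default_config()
  known <- names(.config_schema())
  extra <- setdiff(names(user), c(known, "schema_version"))
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (blk in intersect(names(user), known)) {
    bad <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
    if (length(bad))
      stop("unknown config key(s): ",
           paste(paste0(blk, ".", bad), collapse = ", "), call. = FALSE)
    for (key in names(user[[blk]])) cfg[[blk]][[key]] <- user[[blk]][[key]]
    defaulted <- setdiff(names(cfg[[blk]]), names(user[[blk]]))
    if (length(defaulted))
      .og_log("debug", "config %s: defaulted %s", blk,
              paste(defaulted, collapse = ", "))
  }
  if (length(intersect(names(user), known)) == 0)
    .og_log("info", "config '%s': all values defaulted", path)
  for (blk in names(.positive_keys)) for (key in .positive_keys[[blk]]) {
    v <- cfg[[blk]][[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("config value %s.%s must be a positive number", blk, key),
           call. = FALSE)
  }
  if (!cfg$material$statistics %in% c("boltzmann", "fermi_dirac"))
    stop("config value material.statistics must be 'boltzmann' or 'fermi_dirac'",
         call. = FALSE)
  cfg
}

#' Write a configuration to JSON
#'
#' @param cfg a `run_config` (or plain list of blocks).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a device from a configuration
#'
#' @param cfg a `run_config` from [load_config()] or [default_config()].
#' @return A [device()] (with its [material()]).
#' @export
config_device <- function(cfg) {
  d <- cfg$device; m <- cfg$material
  mat <- material(ni_per_cm3 = m$ni_per_cm3, mu_n_cm2 = m$mu_n_cm2,
                  mu_p_cm2 = m$mu_p_cm2, eps_r = m$eps_r,
                  Eg0_eV = m$Eg0_eV, chi0_eV = m$chi0_eV,
                  Nc_per_cm3 = m$Nc_per_cm3, Nv_per_cm3 = m$Nv_per_cm3,
                  alpha = m$alpha, dEg_eV = m$dEg_eV, tau_n_s = m$tau_n_s,
                  tau_p_s = m$tau_p_s, statistics = m$statistics)
  device(tp_um = d$tp_um, tn_um = d$tn_um, L_OG_um = d$L_OG_um,
         depth_um = d$depth_um, NA_per_cm3 = d$NA_per_cm3,
         ND_per_cm3 = d$ND_per_cm3, sd_doping_per_cm3 = d$sd_doping_per_cm3,
         Ls_um = d$Ls_um, W_um = d$W_um, L_MS_um = d$L_MS_um,
         gauss_sigma_um = d$gauss_sigma_um, mat = mat)
}

#' Build an oxide surface from a configuration
#'
#' @param cfg a `run_config`.
#' @return An [oxide_surface()].
#' @export
config_oxide <- function(cfg) {
  o <- cfg$oxide
  oxide_surface(Ns_per_cm2 = o$Ns_per_cm2, pKa = o$pKa, pKb = o$pKb,
                Ceq = o$Ceq_F_per_m2, T_K = o$T_K)
}

# --- CSV interchange ---------------------------------------------------------

.fmt12 <- function(x) formatC(x, digits = 12, format = "g")

#' Write an IV family to CSV
#'
#' Schema: `analyte_name,analyte_value,sweep_name,sweep_V,fixed_name,
#' fixed_V,Ids_A`, floats at 12 significant digits for lossless round trip.
#'
#' @param fam an [iv_family()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_iv_family <- function(fam, path) {
  stopifnot(inherits(fam, "iv_family"))
  out <- as.data.frame(fam)
  for (cl in c("analyte_value", "sweep_V", "fixed_V", "Ids_A"))
    out[[cl]] <- .fmt12(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IV family from CSV
#'
#' @param path CSV path with the [write_iv_family()] schema.
#' @return An [iv_family()]; missing columns or non-monotone sweeps are
#'   errors.
#' @export
read_iv_family <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.iv_cols, names(d))
  if (length(miss))
    stop("missing IV family column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cl in c("analyte_value", "sweep_V", "fixed_V", "Ids_A"))
    d[[cl]] <- as.numeric(d[[cl]])
  iv_family(d)
}

#' Write a current time trace to CSV
#'
#' Schema: `time_s,Ids_A`.
#'
#' @param trace a `trace_series` (or data.frame with those columns).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("time_s", "Ids_A") %in% names(trace)))
  out <- data.frame(time_s = .fmt12(trace$time_s),
                    Ids_A = .fmt12(trace$Ids_A))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a current time trace from CSV
#'
#' @param path CSV path with `time_s,Ids_A` columns.
#' @return A `trace_series` data.frame.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "Ids_A") %in% names(d)))
    stop("missing trace column(s): time_s, Ids_A", call. = FALSE)
  d$time_s <- as.numeric(d$time_s); d$Ids_A <- as.numeric(d$Ids_A)
  if (any(diff(d$time_s) <= 0))
    stop("'time_s' must be strictly increasing", call. = FALSE)
  class(d) <- c("trace_series", "data.frame")
  d
}

# --- command-line interface --------------------------------------------------

.cli_usage <- function() {
  paste(
    "usage: ogjfet <subcommand> [--key value ...]",
    "subcommands:",
    "  ph-sweep  --from 4 --to 9 --by 1 [--config file] --out table.csv",
    "  simulate  --mode transfer|output --ph 4,5,...,9 --fixed V",
    "            --grid start:stop:step [--config file] --out family.csv",
    "  extract   --family family.csv --iref A [--out results.csv]",
    "            or --trace trace.csv [--out results.csv]",
    "  synth     --kind family|trace|fixtures [--seed N] --out path",
    "  debye     --ionic-strength M [--temp K] [--eps-r 78.5]",
    "options: --log-level debug|info|warning",
    sep = "\n")
}

.cli_opts <- function(args) {
  opts <- list(); i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("missing value for --", key, call. = FALSE)
    opts[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

.cli_num <- function(opts, key, default = NULL) {
  if (is.null(opts[[key]])) {
    if (is.null(default)) stop("missing required --", gsub("_", "-", key),
                               call. = FALSE)
    return(default)
  }
  as.numeric(opts[[key]])
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; see
#' `system.file("scripts", "ogjfet-cli.R", package = "ogjfet")` for the
#' Rscript wrapper.  Subcommands: `ph-sweep`, `simulate`, `extract`,
#' `synth`, `debye`.
#'
#' @param argv character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status (0 on success), invisibly.
#' @export
cli_run <- function(argv = character()) {
  status <- tryCatch({
    if (length(argv) == 0) { cat(.cli_usage(), "\n"); return(invisible(2L)) }
    cmd <- argv[1]
    opts <- .cli_opts(argv[-1])
    if (!is.null(opts$log_level)) set_log_level(opts$log_level)
    cfg <- if (!is.null(opts$config)) load_config(opts$config)
    else default_config()
    switch(cmd,
      "ph-sweep" = {
        grid <- seq(.cli_num(opts, "from", 4), .cli_num(opts, "to", 9),
                    by = .cli_num(opts, "by", 1))
        tab <- ph_charge_table(grid, config_oxide(cfg))
        out <- data.frame(pH = .fmt12(tab$pH), psi0_V = .fmt12(tab$psi0_V),
                          Hs_mol_per_L = .fmt12(tab$Hs_mol_per_L),
                          sigma0_C_per_m2 = .fmt12(tab$sigma0_C_per_m2))
        if (is.null(opts$out)) stop("missing required --out", call. = FALSE)
        utils::write.csv(out, opts$out, row.names = FALSE, quote = FALSE)
        .og_log("info", "wrote %s (%d rows)", opts$out, nrow(out))
        0L
      },
      "simulate" = {
        mode <- match.arg(opts$mode, c("transfer", "output"))
        pH <- as.numeric(strsplit(opts$ph %||% "4,5,6,7,8,9", ",")[[1]])
        gr <- as.numeric(strsplit(opts$grid %||% stop("missing --grid",
                                                      call. = FALSE),
                                  ":")[[1]])
        grid <- seq(gr[1], gr[2], by = gr[3])
        dev <- config_device(cfg)
        ox <- config_oxide(cfg)
        mesh <- build_mesh(dev, n_nodes = cfg$solver$n_nodes)
        fam <- if (mode == "transfer")
          simulate_transfer_family(dev, ox, pH,
                                   Vds_fixed = .cli_num(opts, "fixed", 10),
                                   Vgs_grid = grid, mesh = mesh,
                                   T_K = cfg$solver$T_K)
        else
          simulate_output_family(dev, ox, pH,
                                 Vgs_fixed = .cli_num(opts, "fixed", 0),
                                 Vds_grid = grid, mesh = mesh,
                                 T_K = cfg$solver$T_K)
        if (is.null(opts$out)) stop("missing required --out", call. = FALSE)
        write_iv_family(fam, opts$out)
        .og_log("info", "wrote %s", opts$out)
        0L
      },
      "extract" = {
        res <- if (!is.null(opts$family)) {
          fam <- read_iv_family(opts$family)
          if (fam$sweep_name[1] == "Vgs") {
            r <- voltage_sensitivity(fam, .cli_num(opts, "iref"))
            data.frame(analysis = "voltage_sensitivity",
                       reference = r$reference, slope = r$slope,
                       units = r$units, intercept = r$intercept,
                       r_squared = r$r_squared, n = r$n_points)
          } else {
            rs <- current_sensitivity(fam)
            if (inherits(rs, "sensitivity_result")) rs <- list(rs)
            do.call(rbind, lapply(rs, function(r)
              data.frame(analysis = "current_sensitivity",
                         reference = r$reference, slope = r$slope,
                         units = r$units, intercept = r$intercept,
                         r_squared = r$r_squared, n = r$n_points)))
          }
        } else if (!is.null(opts$trace)) {
          s <- step_response(read_trace(opts$trace),
                             noise_mult = cfg$extraction$noise_mult,
                             rel_floor = cfg$extraction$rel_floor,
                             smooth_k = cfg$extraction$smooth_k)
          if (!s$event) .og_log("info", "no step event detected")
          data.frame(analysis = "step_response",
                     reference = NA_real_,
                     slope = if (s$event) s$fold_change else NA_real_,
                     units = "fold_change",
                     intercept = if (s$event) s$baseline_A else NA_real_,
                     r_squared = NA_real_,
                     n = if (s$event) s$transition_time_s else NA_real_)
        } else stop("extract needs --family or --trace", call. = FALSE)
        if (!is.null(opts$out))
          utils::write.csv(res, opts$out, row.names = FALSE, quote = FALSE)
        else print(res)
        0L
      },
      "synth" = {
        kind <- match.arg(opts$kind, c("family", "trace", "fixtures"))
        seed <- as.integer(.cli_num(opts, "seed", 1))
        if (is.null(opts$out)) stop("missing required --out", call. = FALSE)
        if (kind == "family") {
          spec <- generator_spec(levels = 4:9, analyte_name = "pH",
                                 planted_shift_mV = 51.26, noise_sd = 0,
                                 seed = seed)
          write_iv_family(
            parametric_iv_family(spec, "Vgs",
                                 grid = seq(0, 1.5, by = 0.01),
                                 fixed_V = 10), opts$out)
        } else if (kind == "trace") {
          write_trace(step_trace(0.5e-3, 2.5e-3, t_step = 10, rise = 1,
                                 noise_sd = 0.5e-5, seed = seed), opts$out)
        } else write_config(fixture_configs(), opts$out)
        .og_log("info", "wrote %s", opts$out)
        0L
      },
      "debye" = {
        lam <- debye_length(.cli_num(opts, "ionic_strength"),
                            T_K = .cli_num(opts, "temp", 298.15),
                            eps_r = .cli_num(opts, "eps_r", 78.5))
        cat(sprintf("debye_length_nm,%.*g\n", 6, lam * 1e9))
        0L
      },
      { cat("unknown subcommand: ", cmd, "\n", .cli_usage(), "\n", sep = "")
        2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
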