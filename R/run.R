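# Configuration-driven orchestration: one YAML (or list) config in, text
# artifacts out. Units are always explicit in the config; nothing is
# inferred.

#' Read a run configuration
#'
#' Flat YAML with explicit units on every physical quantity. See the package
#' vignette for the schema; the main blocks are `units`, `task`, `bath`
#' (exactly one of `case`, `params`, `modes`), `broadening` (`ohmic` add-on
#' coupled through g only, and/or `bo_gamma`), `thermo`, `gap`,
#' `integration` and `output`.
#'
#' @param path YAML file path.
#' @return the configuration list (class `ndc_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) ndc_stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("ndc_config", class(cfg)))
}

cfg_get <- function(cfg, name, default = NULL, required = FALSE) {
  v <- cfg[[name]]
  if (is.null(v)) {
    if (required) ndc_stop("config field '", name, "' is required")
    return(default)
  }
  v
}

# grid sizes: accept YAML-safe aliases, since a bare `n:` key is parsed as a
# boolean by YAML 1.1 readers
cfg_n <- function(cfg, default) {
  v <- cfg[["n_steps"]]
  if (is.null(v)) v <- cfg[["points"]]
  if (is.null(v)) v <- cfg[["n"]]
  if (is.null(v)) default else v
}

params_from_list <- function(p, u) {
  ohmic_delta_params(
    eta = p$eta, omega_c = p$omega_c,
    s_h = if (is.null(p$s_h)) 0 else p$s_h, omega_h = p$omega_h,
    eta_D = if (is.null(p$eta_D)) 0 else p$eta_D,
    s_D = if (is.null(p$s_D)) 0 else p$s_D,
    eta_F = if (is.null(p$eta_F)) 0 else p$eta_F, s_F = p$s_F,
    units = u)
}

build_thermo <- function(cfg, units) {
  th <- cfg_get(cfg, "thermo", required = TRUE)
  if (!is.null(th$theta)) thermo_state(theta = th$theta, units = "reduced")
  else thermo_state(th$temperature,
                    units = if (units == "reduced") "reduced" else "kelvin")
}

build_corr_from_config <- function(cfg) {
  units <- match.arg(cfg_get(cfg, "units", "physical"), c("physical", "reduced"))
  u <- if (units == "reduced") "reduced" else "cm1"
  bath <- cfg_get(cfg, "bath", required = TRUE)
  sources <- intersect(c("case", "params", "modes"), names(bath))
  if (length(sources) != 1L)
    ndc_stop("config must name exactly one bath source (case, params or modes); found: ",
             paste(sources, collapse = ", "))
  br <- cfg_get(cfg, "broadening", list())
  thermo <- NULL
  integ <- cfg_get(cfg, "integration", list())
  if (sources == "case") {
    case <- table2_case(bath$case)
    thermo <- if (is.null(cfg$thermo)) case$thermo else build_thermo(cfg, "reduced")
    grid <- time_grid(cfg_get(integ, "t_max", 60), n = cfg_n(integ, 6000))
    corr <- corr_closed_form(case$params, thermo, grid)
  } else {
    thermo <- build_thermo(cfg, units)
    if (sources == "params") {
      params <- params_from_list(bath$params, u)
      grid <- time_grid(cfg_get(integ, "t_max", 60), n = cfg_n(integ, 6000))
      corr <- corr_closed_form(params, thermo, grid)
    } else {
      modes <- read_modes(bath$modes)
      grid <- time_grid(cfg_get(integ, "t_max", 3), n = cfg_n(integ, 20000))
      corr <- if (!is.null(br$bo_gamma)) {
        corr_from_spectrum(triple_from_modes(modes, gamma = br$bo_gamma),
                           thermo, grid)
      } else {
        corr_from_discrete(modes, thermo, grid)
      }
    }
  }
  if (!is.null(br$ohmic)) {
    env_params <- ohmic_delta_params(eta = br$ohmic$eta,
                                     omega_c = br$ohmic$omega_c, units = u)
    corr <- corr_add(corr, corr_closed_form(env_params, thermo, corr$grid))
  }
  corr
}

config_gaps <- function(cfg) {
  gp <- cfg_get(cfg, "gap", required = TRUE)
  units <- cfg_get(gp, "units", required = TRUE)
  if (!is.null(gp$value)) list(gaps = gp$value, units = units)
  else list(gaps = seq(gp$from, gp$to, length.out = cfg_n(gp, 9L)),
            units = units)
}

#' Run a configured computation
#'
#' Executes the task named in the configuration (`spectra`, `corr`, `rate`,
#' `scan` or `fixtures`) and writes the corresponding delimited-text
#' artifacts plus a human-readable log and a YAML diagnostics sidecar.
#' Deterministic configurations give byte-identical numeric outputs.
#'
#' @param config an `ndc_config` list or a YAML file path.
#' @param dir output directory (overrides `output$dir`).
#' @return named character vector of the files written, invisibly.
#' @export
run <- function(config, dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  task <- match.arg(cfg_get(cfg, "task", "rate"),
                    c("spectra", "corr", "rate", "scan", "fixtures"))
  out <- cfg_get(cfg, "output", list())
  dir <- if (!is.null(dir)) dir else cfg_get(out, "dir", ".")
  prefix <- cfg_get(out, "prefix", "ndcrate")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, "_", suffix))
  written <- character(0)
  log <- c(sprintf("ndcrate run: task=%s", task))

  if (task == "fixtures") {
    sur <- azulene_surrogate()
    write_modes(sur$modes, p("azulene_modes.txt"))
    written["modes"] <- p("azulene_modes.txt")
    for (id in names(.table2)) {
      cfg_case <- list(units = "reduced", task = "scan",
                       bath = list(case = id),
                       thermo = list(theta = 1),
                       gap = list(from = 2, to = 30, points = 57, units = "reduced"))
      yaml::write_yaml(cfg_case, p(paste0("case_", id, ".yaml")))
      written[paste0("case_", id)] <- p(paste0("case_", id, ".yaml"))
    }
    writeLines(c(log, "wrote surrogate mode table and named-case configs"),
               p("log.txt"))
    written["log"] <- p("log.txt")
    return(invisible(written))
  }

  corr <- build_corr_from_config(cfg)
  log <- c(log,
           sprintf("units=%s method=%s n_t=%d dt=%g t_max=%g",
                   corr$units, corr$method, length(corr$grid$t),
                   corr$grid$dt, corr$grid$t_max),
           sprintf("lambda/hbar=%g D0=%g undamped=%s",
                   corr$lambda, Re(corr$D[1]), corr$undamped))
  diag <- list(task = task, units = corr$units, method = corr$method,
               lambda_over_hbar = corr$lambda, D0 = Re(corr$D[1]),
               undamped = corr$undamped)

  if (task == "spectra") {
    # spectra need the triple, rebuilt from the bath source
    bath <- cfg$bath
    units <- if (cfg_get(cfg, "units", "physical") == "reduced") "reduced" else "cm1"
    triple <- if (!is.null(bath$case)) {
      parametric_triple(table2_case(bath$case)$params)
    } else if (!is.null(bath$modes)) {
      triple_from_modes(read_modes(bath$modes),
                        gamma = cfg_get(cfg_get(cfg, "broadening", list()),
                                        "bo_gamma"))
    } else {
      parametric_triple(params_from_list(bath$params, units))
    }
    sp <- cfg_get(cfg, "spectra", list())
    omega <- seq(cfg_get(sp, "omega_min", 0), cfg_get(sp, "omega_max",
                 if (units == "reduced") 30 else 4000),
                 length.out = cfg_n(sp, 601))
    write_spectra(triple, omega, p("spectra.csv"))
    written["spectra"] <- p("spectra.csv")
  } else if (task == "corr") {
    write_corr(corr, p("corr.csv"))
    written["corr"] <- p("corr.csv")
  } else {
    gp <- config_gaps(cfg)
    integ <- cfg_get(cfg, "integration", list())
    scan <- gap_scan(corr, gp$gaps, gap_units = gp$units,
                     gaussian_damping = cfg_get(integ, "gaussian_damping"),
                     tail_tol = cfg_get(integ, "tail_tol", 1e-6),
                     per_period = cfg_get(integ, "per_period", 20))
    if (task == "rate" && length(gp$gaps) != 1L)
      ndc_stop("task 'rate' expects a single gap value; use task 'scan' for grids")
    if (any(!scan$converged))
      log <- c(log, sprintf("WARNING: %d of %d points not converged",
                            sum(!scan$converged), nrow(scan)))
    write_scan(scan, p("rates.csv"),
               description = sprintf("task %s, gap units %s", task, gp$units))
    written["rates"] <- p("rates.csv")
    diag$n_gaps <- nrow(scan)
    diag$converged <- all(scan$converged)
    log <- c(log, sprintf("gap=%g k=%g k_condon=%g converged=%s",
                          scan$gap, scan$k, scan$k_condon, scan$converged))
  }
  writeLines(log, p("log.txt"))
  yaml::write_yaml(diag, p("diag.yaml"))
  written["log"] <- p("log.txt")
  written["diag"] <- p("diag.yaml")
  invisible(written)
}
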