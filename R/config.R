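#' Run configuration
#'
#' Collects every tunable parameter block of the pipeline with defaults,
#' serializable losslessly to YAML. Reports embed the MD5 hash of the
#' serialized configuration so runs can be matched to their settings.
#'
#' @param potentials,thermostat Parameter lists (see [potential_params()],
#'   [thermostat_params()]).
#' @param schedule Folding-schedule fields; `t_fold = NULL` means derive it
#'   from [folding_time()] with the given `variant`/`cap`.
#' @param docking,scan Docking-sweep and pair-scan settings.
#' @param n_replicas Replica count per fitness measurement.
#' @param base_seed Global seed.
#' @param out_dir Output directory for CLI runs.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(potentials = list(l = 3.8, kappa = 11, alpha = 2.1,
                                         eps_core = 2, T0 = 302.15),
                       thermostat = list(mass = 1.66e-22, gamma = 10,
                                         dt = 0.01),
                       schedule = list(t_fold = NULL, dt_f = 10,
                                       T_fold = 302.15, T1 = 218.2,
                                       T2 = 134.3,
                                       T_f_estimate = 1.25 * 302.15,
                                       variant = "sqrt_exponent",
                                       cap = NULL),
                       docking = list(sweep = 0.25, n_points = 1e4,
                                      tolerance = 1.0),
                       scan = list(n_pairs = 100, lambda = -0.2,
                                   dP = 0.037, error_mode = "quadrature",
                                   sig_mult = 3),
                       n_replicas = 127, base_seed = 1, out_dir = ".") {
  structure(list(potentials = potentials, thermostat = thermostat,
                 schedule = schedule, docking = docking, scan = scan,
                 n_replicas = n_replicas, base_seed = base_seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- unclass(run_config())
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  structure(cfg[names(defaults)], class = "run_config")
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

# Materialize parameter objects from a run_config.
config_objects <- function(config) {
  p <- do.call(potential_params, config$potentials)
  th <- do.call(thermostat_params,
                c(config$thermostat, list(T = config$schedule$T_fold)))
  sch <- config$schedule
  if (is.null(sch$t_fold)) {
    abort("schedule t_fold must be set (or derived) before use",
          class = "epifold_invalid_input")
  }
  schedule <- folding_schedule(t_fold = sch$t_fold, dt_f = sch$dt_f,
                               T_fold = sch$T_fold, T1 = sch$T1,
                               T2 = sch$T2,
                               T_f_estimate = sch$T_f_estimate)
  list(params = p, thermostat = th, schedule = schedule)
}
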