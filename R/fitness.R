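#' Fitness-measurement protocols
#'
#' `fitness_protocol()` bundles everything [fitness()] needs to run the
#' full fold-and-dock pipeline. `mock_protocol()` replaces the pipeline
#' with a stochastic or deterministic stand-in: either per-replica
#' Bernoulli activity with probability `p_active`, or an exact fitness
#' function of the sequence (useful for constructed fitness landscapes).
#'
#' @param n_replicas Number of replicas per measurement (default 127).
#' @param schedule A [folding_schedule()].
#' @param table A [build_contact_table()] result.
#' @param params A [potential_params()] object.
#' @param thermostat A [thermostat_params()] object.
#' @param sweep,n_points Docking sweep step and shell point count.
#' @return A protocol object for [fitness()].
#' @export
fitness_protocol <- function(n_replicas = 127, schedule, table,
                             params = potential_params(),
                             thermostat = thermostat_params(),
                             sweep = 0.25, n_points = 1e4) {
  structure(list(n_replicas = as.integer(n_replicas), schedule = schedule,
                 table = table, params = params, thermostat = thermostat,
                 sweep = sweep, n_points = n_points,
                 points = sphere_points(n_points)),
            class = "fitness_protocol")
}

#' @rdname fitness_protocol
#' @param p_active Bernoulli activity probability per replica.
#' @param fitness_fn Function of the sequence returning P directly.
#' @export
mock_protocol <- function(n_replicas = 127, p_active = NULL,
                          fitness_fn = NULL) {
  if (is.null(p_active) == is.null(fitness_fn)) {
    abort("supply exactly one of p_active or fitness_fn",
          class = "epifold_invalid_input")
  }
  structure(list(n_replicas = as.integer(n_replicas), p_active = p_active,
                 fitness_fn = fitness_fn),
            class = "mock_protocol")
}

#' Measure the fitness of a sequence
#'
#' Fitness is the fraction of active replicas, `P = n_active /
#' n_replicas`: the ensemble is folded ([fold_ensemble()]), the ligand is
#' docked onto each replica ([dock()]), and a replica counts as active
#' when its binding complex matches the target geometry ([is_active()]).
#' Replicas whose folding fails are counted inactive. The measurement is
#' deterministic given `base_seed`.
#'
#' @param seq Amino-acid sequence.
#' @param site A [binding_site()] (ignored by mock protocols).
#' @param target A [target_state()] (ignored by mock protocols).
#' @param protocol A [fitness_protocol()] or [mock_protocol()].
#' @param base_seed Integer seed.
#' @return An object of class `fitness_measurement` with `n_active`,
#'   `n_replicas`, `P`, `seed`.
#' @export
fitness <- function(seq, site = NULL, target = NULL, protocol,
                    base_seed = 1) {
  if (inherits(protocol, "mock_protocol")) {
    n <- protocol$n_replicas
    if (!is.null(protocol$fitness_fn)) {
      P <- protocol$fitness_fn(seq)
      n_active <- as.integer(round(P * n))
    } else {
      set.seed(derive_seed(base_seed, 17L))
      n_active <- sum(runif(n) < protocol$p_active)
    }
    return(new_fitness_measurement(n_active, n, base_seed))
  }
  stopifnot(inherits(protocol, "fitness_protocol"),
            inherits(site, "binding_site"),
            inherits(target, "target_state"))
  ens <- fold_ensemble(seq, protocol$n_replicas, protocol$schedule,
                       protocol$table, protocol$params, protocol$thermostat,
                       base_seed)
  n_active <- 0L
  for (r in seq_along(ens$members)) {
    if (ens$failed[r]) next
    pose <- tryCatch(
      dock(ens$members[[r]], site, protocol$params, protocol$sweep,
           points = protocol$points),
      error = function(e) NULL)
    if (!is.null(pose) &&
        is_active(ens$members[[r]], site, pose, target)) {
      n_active <- n_active + 1L
    }
  }
  new_fitness_measurement(n_active, protocol$n_replicas, base_seed)
}

new_fitness_measurement <- function(n_active, n_replicas, seed) {
  structure(list(n_active = as.integer(n_active),
                 n_replicas = as.integer(n_replicas),
                 P = n_active / n_replicas, seed = seed),
            class = "fitness_measurement")
}

#' @export
print.fitness_measurement <- function(x, ...) {
  cat(sprintf("<fitness_measurement> P = %d/%d = %.4f\n",
              x$n_active, x$n_replicas, x$P))
  invisible(x)
}

#' Width of the fitness distribution
#'
#' Summarizes repeated fitness measurements of one sequence: the mean, the
#' sample standard deviation, and the maximum-likelihood Gaussian width of
#' the fitness histogram (both width estimates are reported).
#'
#' @param measurements Numeric vector of P values, or a list of
#'   `fitness_measurement` objects; at least 10 values.
#' @return A one-row tibble with `mean`, `sigma` (sample SD), `sigma_mle`
#'   (Gaussian fit), and `n`.
#' @export
fitness_error <- function(measurements) {
  P <- if (is.numeric(measurements)) measurements
       else vapply(measurements, `[[`, numeric(1), "P")
  if (length(P) < 10) {
    abort("need at least 10 measurements", class = "epifold_invalid_input")
  }
  mu <- mean(P)
  tibble(mean = mu, sigma = sd(P),
         sigma_mle = sqrt(mean((P - mu)^2)), n = length(P))
}
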