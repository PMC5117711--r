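#' Analytic forces on a chain
#'
#' Negative gradient of [total_energy()] with respect to the monomer
#' coordinates. Pairwise terms obey Newton's third law, so the forces sum
#' to zero. Coincident non-bonded monomers trigger a singularity guard
#' (capped force) and a warning.
#'
#' @inheritParams total_energy
#' @return An n x 3 matrix of forces in `k_B*T0` per Angstrom.
#' @export
forces <- function(conf, seq, table = default_contact_table(params),
                   params = potential_params()) {
  conf <- as_conformation(conf)
  res <- seq_residues(seq)
  if (nrow(conf) != length(res)) {
    abort("conformation and sequence lengths must match",
          class = "epifold_invalid_input")
  }
  EP <- seq_pair_strengths(res, table)
  out <- cpp_forces(conf, EP, params$kappa, params$l, params$eps_core,
                    params$alpha)
  if (out$n_guard > 0) {
    warning(sprintf("singularity guard hit %d time(s): coincident monomers",
                    out$n_guard))
  }
  out$F
}

#' Chain state for Langevin propagation
#'
#' @param positions n x 3 coordinate matrix (Angstroms).
#' @param velocities n x 3 velocity matrix (Angstroms/ps); defaults to rest.
#' @return An object of class `chain_state`.
#' @export
chain_state <- function(positions, velocities = NULL) {
  positions <- as_conformation(positions)
  if (is.null(velocities)) {
    velocities <- matrix(0, nrow(positions), 3)
  } else {
    velocities <- as_conformation(velocities)
    if (nrow(velocities) != nrow(positions)) {
      abort("positions and velocities must have the same length",
            class = "epifold_invalid_input")
    }
  }
  structure(list(positions = positions, velocities = velocities),
            class = "chain_state")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each Cartesian velocity component is Gaussian with variance
#' `k_B*T / m`, expressed in reduced units as `(T/T0) / m_red`.
#'
#' @param n_res Number of monomers.
#' @param thermostat A [thermostat_params()] object (bath temperature `T`).
#' @param params A [potential_params()] object (supplies `T0`).
#' @return An n x 3 velocity matrix in Angstroms/ps.
#' @export
maxwell_velocities <- function(n_res, thermostat, params = potential_params()) {
  m_red <- reduced_mass(thermostat$mass, params$T0)
  sd_v <- sqrt((thermostat$T / params$T0) / m_red)
  matrix(rnorm(3 * n_res, sd = sd_v), n_res, 3)
}

#' Propagate a chain by Langevin dynamics
#'
#' Integrates the Langevin equation with a BAOAB splitting: deterministic
#' half-kicks and drifts around an exact Ornstein-Uhlenbeck velocity update
#' at the bath temperature. With `gamma = 0` the scheme reduces to velocity
#' Verlet. All noise is drawn from R's RNG, so `set.seed()` (or the `seed`
#' argument) makes trajectories bit-reproducible.
#'
#' @param state A [chain_state()].
#' @inheritParams total_energy
#' @param thermostat A [thermostat_params()] object.
#' @param n_steps Number of integration steps (>= 0).
#' @param seed Optional integer seed applied before propagation.
#' @param sample_every If positive, record a snapshot every that many steps.
#' @return The propagated `chain_state`; if `sample_every > 0` it carries a
#'   `samples` attribute, a list with arrays `positions` and `velocities`
#'   of dimension `n_samples x n_res x 3`.
#' @export
integrate_chain <- function(state, seq, table = default_contact_table(params),
                            thermostat = thermostat_params(),
                            params = potential_params(), n_steps,
                            seed = NULL, sample_every = 0) {
  stopifnot(inherits(state, "chain_state"))
  if (n_steps < 0) {
    abort("n_steps must be >= 0", class = "epifold_invalid_input")
  }
  if (n_steps == 0) return(state)
  if (!is.null(seed)) set.seed(seed)
  res <- seq_residues(seq)
  EP <- seq_pair_strengths(res, table)
  m_red <- reduced_mass(thermostat$mass, params$T0)
  kT <- thermostat$T / params$T0
  out <- cpp_integrate(state$positions, state$velocities, EP,
                       params$kappa, params$l, params$eps_core, params$alpha,
                       m_red, thermostat$gamma, thermostat$dt, kT,
                       as.integer(n_steps), as.integer(sample_every))
  if (out$bad_step > 0) {
    abort(sprintf("integration failure: non-finite coordinates at step %d",
                  out$bad_step),
          class = "epifold_integration_failure")
  }
  new_state <- chain_state(out$X, out$V)
  if (sample_every > 0 && out$n_samples > 0) {
    n_res <- nrow(state$positions)
    ns <- out$n_samples
    attr(new_state, "samples") <- list(
      positions = aperm(array(out$sample_X[seq_len(ns * n_res), , drop = FALSE],
                              dim = c(n_res, ns, 3)), c(2, 1, 3)),
      velocities = aperm(array(out$sample_V[seq_len(ns * n_res), , drop = FALSE],
                               dim = c(n_res, ns, 3)), c(2, 1, 3)))
  }
  new_state
}

#' Instantaneous kinetic temperature
#'
#' `T_kin = 2 KE / (3 n_res k_B)`, reported in Kelvin.
#'
#' @inheritParams integrate_chain
#' @return Temperature in Kelvin.
#' @export
kinetic_temperature <- function(state, thermostat = thermostat_params(),
                                params = potential_params()) {
  stopifnot(inherits(state, "chain_state"))
  n <- nrow(state$positions)
  if (n < 1) abort("need at least one monomer", class = "epifold_invalid_input")
  m_red <- reduced_mass(thermostat$mass, params$T0)
  ke <- 0.5 * m_red * sum(state$velocities^2) # in k_B*T0
  (2 * ke / (3 * n)) * params$T0
}
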