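#' Potential parameters
#'
#' Bundles the constants that define the chain potentials: the equilibrium
#' bond length `l`, the bond stiffness `kappa`, the Morse range `alpha`, the
#' excluded-volume core strength `eps_core`, and the reference temperature
#' `T0`. Energies throughout the package are expressed in units of
#' `k_B * T0`; `kappa` is therefore `k_B*T0` per square Angstrom.
#'
#' @param l Equilibrium bond length in Angstroms.
#' @param kappa Bond stiffness in `k_B*T0` per square Angstrom.
#' @param alpha Morse range parameter in inverse Angstroms.
#' @param eps_core Excluded-volume core strength in `k_B*T0`.
#' @param T0 Reference temperature in Kelvin.
#' @return An object of class `potential_params`.
#' @examples
#' p <- potential_params()
#' bond_energy(p$l + 1, p)
#' @export
potential_params <- function(l = 3.8, kappa = 11, alpha = 2.1,
                             eps_core = 2, T0 = 302.15) {
  vals <- c(l = l, kappa = kappa, alpha = alpha,
            eps_core = eps_core, T0 = T0)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all potential parameters must be strictly positive and finite",
          class = "epifold_invalid_input")
  }
  structure(list(l = l, kappa = kappa, alpha = alpha,
                 eps_core = eps_core, T0 = T0),
            class = "potential_params")
}

#' Thermostat parameters for Langevin propagation
#'
#' @param mass Monomer mass in grams.
#' @param gamma Friction coefficient in 1/ps. `gamma = 0` is accepted and
#'   gives the deterministic velocity-Verlet limit (no bath coupling),
#'   useful for energy-conservation checks.
#' @param dt Integration time step in ps.
#' @param T Bath temperature in Kelvin.
#' @return An object of class `thermostat_params`.
#' @export
thermostat_params <- function(mass = 1.66e-22, gamma = 10, dt = 0.01,
                              T = 302.15) {
  if (!is.finite(mass) || mass <= 0 || !is.finite(dt) || dt <= 0 ||
      !is.finite(T) || T <= 0 || !is.finite(gamma) || gamma < 0) {
    abort("mass, dt, T must be > 0 and gamma >= 0",
          class = "epifold_invalid_input")
  }
  structure(list(mass = mass, gamma = gamma, dt = dt, T = T),
            class = "thermostat_params")
}

#' Folding-and-quench schedule
#'
#' Defines the temperatures and durations of the three propagation stages
#' applied to every replica: folding at `T_fold` for `t_fold` ps, then one
#' equilibration of `t_q` ps at each quench temperature `T1` and `T2`.
#' By default `t_q = t_fold / 3`.
#'
#' @param t_fold Folding duration in ps (see [folding_time()]).
#' @param dt_f Surface-exchange timescale in ps entering [folding_time()].
#' @param T_fold Folding temperature in Kelvin.
#' @param T1,T2 First and second quench temperatures in Kelvin.
#' @param t_q Equilibration time per quench stage in ps.
#' @param T_f_estimate Folding-transition temperature estimate in Kelvin;
#'   the schedule requires `T_fold < T_f_estimate`.
#' @return An object of class `folding_schedule`.
#' @export
folding_schedule <- function(t_fold, dt_f = 10, T_fold = 302.15,
                             T1 = 218.2, T2 = 134.3, t_q = t_fold / 3,
                             T_f_estimate = 1.25 * 302.15) {
  if (!is.finite(t_fold) || t_fold <= 0 || !is.finite(t_q) || t_q <= 0) {
    abort("t_fold and t_q must be positive", class = "epifold_invalid_input")
  }
  if (!(T2 < T1 && T1 < T_fold)) {
    abort("quench temperatures must satisfy T2 < T1 < T_fold",
          class = "epifold_invalid_input")
  }
  if (!(T_fold < T_f_estimate)) {
    abort("T_fold must lie below the folding-transition estimate",
          class = "epifold_invalid_input")
  }
  structure(list(t_fold = t_fold, dt_f = dt_f, T_fold = T_fold,
                 T1 = T1, T2 = T2, t_q = t_q,
                 T_f_estimate = T_f_estimate),
            class = "folding_schedule")
}

# Derive a 32-bit-safe child seed from a base seed and integer keys.
derive_seed <- function(base, ...) {
  keys <- c(...)
  x <- as.double(base)
  for (k in keys) x <- (x * 69069 + as.double(k) * 104729 + 1) %% 2147483647
  as.integer(x)
}
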