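#' Folding time as a function of chain length
#'
#' Chain-length scaling of the time alloted for folding, built on the
#' surface-exchange timescale `dt_f`. The `"literal"` variant is
#' `n^3 * exp(n) * dt_f`; it grows so fast that it is unusable beyond very
#' short chains, so the default `"sqrt_exponent"` variant
#' `n^3 * exp(sqrt(n)) * dt_f` is provided, along with a `"fixed"` variant
#' that returns a user-supplied cap.
#'
#' @param n_res Chain length (>= 2).
#' @param dt_f Exchange timescale in ps.
#' @param variant One of `"sqrt_exponent"`, `"literal"`, `"fixed"`.
#' @param cap Duration in ps returned by the `"fixed"` variant.
#' @return Folding duration in ps.
#' @export
folding_time <- function(n_res, dt_f = 10,
                         variant = c("sqrt_exponent", "literal", "fixed"),
                         cap = NULL) {
  variant <- match.arg(variant)
  if (n_res < 2) abort("n_res must be >= 2", class = "epifold_invalid_input")
  switch(variant,
         literal = n_res^3 * exp(n_res) * dt_f,
         sqrt_exponent = n_res^3 * exp(sqrt(n_res)) * dt_f,
         fixed = {
           if (is.null(cap) || cap <= 0) {
             abort("fixed variant requires a positive cap",
                   class = "epifold_invalid_input")
           }
           cap
         })
}

#' Generate a self-avoiding random coil
#'
#' Grows a chain with every consecutive distance exactly equal to the bond
#' length `l` and every non-consecutive pair distance at least `0.8 * l`,
#' restarting segments on clashes with bounded retries.
#'
#' @param n_res Chain length (>= 2).
#' @param params A [potential_params()] object.
#' @param seed Optional integer seed.
#' @param min_sep_frac Minimum non-consecutive separation as a fraction of `l`.
#' @param max_tries Retries per placement before restarting the coil.
#' @param max_restarts Whole-coil restarts before giving up.
#' @return An n x 3 coordinate matrix.
#' @export
random_coil <- function(n_res, params = potential_params(), seed = NULL,
                        min_sep_frac = 0.8, max_tries = 200,
                        max_restarts = 50) {
  if (n_res < 2) abort("n_res must be >= 2", class = "epifold_invalid_input")
  if (!is.null(seed)) set.seed(seed)
  l <- params$l
  min_sep <- min_sep_frac * l
  for (restart in seq_len(max_restarts)) {
    X <- matrix(0, n_res, 3)
    ok <- TRUE
    for (i in 2:n_res) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        # uniform direction on the sphere
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- X[i - 1, ] + l * u
        if (i == 2) { X[i, ] <- cand; placed <- TRUE; break }
        d2 <- rowSums(sweep(X[seq_len(i - 2), , drop = FALSE], 2, cand)^2)
        if (min(d2) >= min_sep^2) { X[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(X)
  }
  abort("random-coil generation failed after bounded retries",
        class = "epifold_generation_error")
}

#' Fold a replica ensemble
#'
#' Runs the three-stage protocol for each of `n_replicas` independent
#' replicas: a fresh random coil with Maxwell-Boltzmann velocities at the
#' folding temperature, propagation for `t_fold` ps at `T_fold`, then `t_q`
#' ps at each of the quench temperatures `T1` and `T2`. Each replica and
#' stage has its own seed derived from `base_seed`, so results are
#' independent of execution order. A replica whose integration blows up is
#' flagged and its last valid coordinates kept.
#'
#' @param seq Amino-acid sequence.
#' @param n_replicas Number of replicas (default 127).
#' @param schedule A [folding_schedule()].
#' @param table A [build_contact_table()] result.
#' @param params A [potential_params()] object.
#' @param thermostat A [thermostat_params()] object; its `T` field is
#'   overridden stage by stage.
#' @param base_seed Integer base seed.
#' @return An object of class `replica_ensemble`: list with `members` (list
#'   of n x 3 matrices), `failed` (logical), `seeds`, `schedule`, `sequence`.
#' @export
fold_ensemble <- function(seq, n_replicas = 127, schedule, table,
                          params = potential_params(),
                          thermostat = thermostat_params(),
                          base_seed = 1) {
  res <- seq_residues(seq)
  stopifnot(inherits(schedule, "folding_schedule"))
  stage_T <- c(schedule$T_fold, schedule$T1, schedule$T2)
  stage_t <- c(schedule$t_fold, schedule$t_q, schedule$t_q)
  members <- vector("list", n_replicas)
  failed <- logical(n_replicas)
  seeds <- vapply(seq_len(n_replicas), function(r) derive_seed(base_seed, r),
                  integer(1))
  for (r in seq_len(n_replicas)) {
    X <- random_coil(length(res), params, seed = derive_seed(seeds[r], 0L))
    set.seed(derive_seed(seeds[r], 1L))
    st <- chain_state(X, maxwell_velocities(
      length(res), thermostat_at(thermostat, schedule$T_fold), params))
    for (stage in seq_along(stage_T)) {
      th <- thermostat_at(thermostat, stage_T[stage])
      n_steps <- max(1L, as.integer(round(stage_t[stage] / th$dt)))
      st <- tryCatch(
        integrate_chain(st, res, table, th, params, n_steps,
                        seed = derive_seed(seeds[r], 1L + stage)),
        epifold_integration_failure = function(e) {
          failed[r] <<- TRUE
          st
        })
      if (failed[r]) break
    }
    members[[r]] <- st$positions
  }
  structure(list(members = members, failed = failed, seeds = seeds,
                 schedule = schedule, sequence = paste(res, collapse = "")),
            class = "replica_ensemble")
}

thermostat_at <- function(thermostat, T) {
  thermostat$T <- T
  thermostat
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat(sprintf("<replica_ensemble> %d replicas of %d-mer %s (%d failed)\n",
              length(x$members), nchar(x$sequence), x$sequence,
              sum(x$failed)))
  invisible(x)
}
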