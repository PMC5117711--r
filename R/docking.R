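#' Binding-site definition
#'
#' @param site_indices Monomer indices (1-based, unique) forming the site.
#' @param ligand_count Number of ligand monomers; only 1 is supported.
#' @return An object of class `binding_site`.
#' @export
binding_site <- function(site_indices, ligand_count = 1) {
  site_indices <- as.integer(site_indices)
  if (length(site_indices) == 0 || anyDuplicated(site_indices) ||
      any(site_indices < 1)) {
    abort("site indices must be unique positive integers",
          class = "epifold_invalid_input")
  }
  if (ligand_count != 1) {
    abort("only a single-monomer ligand is supported",
          class = "epifold_invalid_input")
  }
  structure(list(site_indices = site_indices, ligand_count = 1L),
            class = "binding_site")
}

#' Target geometry of the binding complex
#'
#' Stores every pairwise distance within the binding complex (site monomers
#' plus the docked ligand) and the activity tolerance.
#'
#' @param pair_distances Symmetric `(k+1) x (k+1)` distance matrix for the
#'   `k` site monomers followed by the ligand.
#' @param tolerance Activity tolerance in Angstroms (inclusive).
#' @return An object of class `target_state`.
#' @export
target_state <- function(pair_distances, tolerance = 1.0) {
  m <- as.matrix(pair_distances)
  if (nrow(m) != ncol(m) || nrow(m) < 2 ||
      max(abs(m - t(m))) > 1e-9 || any(m[upper.tri(m)] <= 0)) {
    abort("pair_distances must be a symmetric matrix of positive distances",
          class = "epifold_invalid_target")
  }
  structure(list(pair_distances = m, tolerance = tolerance),
            class = "target_state")
}

# Distance matrix of the binding complex: site monomers + ligand position.
complex_distances <- function(conf, site, ligand_position) {
  pts <- rbind(conf[site$site_indices, , drop = FALSE], ligand_position)
  as.matrix(dist(pts))
}

#' Near-uniform points on the unit sphere
#'
#' Generalized-spiral construction: latitudes with equal-area spacing and a
#' golden-angle longitude increment, giving near-constant nearest-neighbor
#' spacing.
#'
#' @param n Number of points (>= 4).
#' @return An n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n = 1e4) {
  n <- as.integer(n)
  if (n < 4) abort("need at least 4 points", class = "epifold_invalid_input")
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- (i - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Dock the single-monomer ligand by a spherical shell sweep
#'
#' Encloses the conformation in a spherical shell of near-uniformly
#' distributed points centered on the monomer centroid and evaluates the
#' ligand energy at every point: site monomers attract through the unit
#' Morse potential, all other monomers contribute the excluded-volume
#' core (the left Morse branch shifted to vanish at the bond length), a
#' purely repulsive term. The shell radius is reduced in steps of `sweep`
#' from just outside the structure until the shell lies inside it, and
#' the minimum-energy point over all shells is returned.
#'
#' @param conf n x 3 conformation matrix.
#' @param site A [binding_site()].
#' @param params A [potential_params()] object.
#' @param sweep Radius step in Angstroms.
#' @param n_points Number of shell points.
#' @param points Optional precomputed unit vectors (overrides `n_points`).
#' @return An object of class `pose`: `ligand_position`, `energy`
#'   (`k_B*T0`), `shell_radius`.
#' @export
dock <- function(conf, site, params = potential_params(), sweep = 0.25,
                 n_points = 1e4, points = NULL) {
  conf <- as_conformation(conf)
  stopifnot(inherits(site, "binding_site"))
  if (max(site$site_indices) > nrow(conf)) {
    abort("site indices outside the chain", class = "epifold_invalid_input")
  }
  center <- colMeans(conf)
  dists <- sqrt(rowSums((conf - matrix(center, nrow(conf), 3,
                                       byrow = TRUE))^2))
  r_max <- max(dists) + 2 * params$l
  r_min <- max(min(dists), sweep)
  radii <- seq(r_max, r_min, by = -sweep)
  if (length(radii) == 0) {
    abort("empty docking sweep range", class = "epifold_docking_error")
  }
  if (is.null(points)) points <- sphere_points(n_points)
  out <- cpp_dock(conf, site$site_indices - 1L, points, radii, center,
                  params$alpha, params$l)
  structure(list(ligand_position = out$position, energy = out$energy,
                 shell_radius = out$shell_radius),
            class = "pose")
}

#' Activity test of a docked replica
#'
#' A replica is active when every pairwise distance within its binding
#' complex (site monomers plus docked ligand) lies within the target
#' tolerance (inclusive) of the corresponding target distance.
#'
#' @param conf n x 3 conformation matrix.
#' @param site A [binding_site()].
#' @param pose A [dock()] result.
#' @param target A [target_state()].
#' @return Logical flag.
#' @export
is_active <- function(conf, site, pose, target) {
  stopifnot(inherits(pose, "pose"), inherits(target, "target_state"))
  d <- complex_distances(as_conformation(conf), site, pose$ligand_position)
  if (!all(dim(d) == dim(target$pair_distances))) {
    abort("target state does not cover every complex pair",
          class = "epifold_invalid_target")
  }
  dev <- abs(d - target$pair_distances)
  all(dev[upper.tri(dev)] <= target$tolerance)
}

#' Build the target state by averaging properly formed replicas
#'
#' Docks the ligand onto every (non-failed) ensemble member, keeps the
#' replicas active with respect to a provisional target, and averages
#' their complex pair distances into the final target geometry.
#'
#' @param ens A [fold_ensemble()] result.
#' @param site A [binding_site()].
#' @param seed_target Provisional [target_state()] identifying properly
#'   formed replicas.
#' @inheritParams dock
#' @return A [target_state()] with the averaged distances and the
#'   provisional target's tolerance.
#' @export
make_target <- function(ens, site, seed_target, params = potential_params(),
                        sweep = 0.25, n_points = 1e4, points = NULL) {
  stopifnot(inherits(ens, "replica_ensemble"),
            inherits(seed_target, "target_state"))
  if (is.null(points)) points <- sphere_points(n_points)
  mats <- list()
  for (m in ens$members[!ens$failed]) {
    pose <- dock(m, site, params, sweep, points = points)
    if (is_active(m, site, pose, seed_target)) {
      mats[[length(mats) + 1]] <- complex_distances(m, site,
                                                    pose$ligand_position)
    }
  }
  if (length(mats) == 0) {
    abort("no replica is active under the provisional target",
          class = "epifold_cannot_build_target")
  }
  target_state(Reduce(`+`, mats) / length(mats), seed_target$tolerance)
}
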