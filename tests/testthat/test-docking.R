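p <- potential_params()

test_that("spiral sphere points are unit and near-uniform", {
  n <- 1e4
  pts <- sphere_points(n)
  expect_equal(nrow(pts), n)
  expect_equal(rowSums(pts^2), rep(1, n), tolerance = 1e-12)
  expect_lt(sqrt(sum(colMeans(pts)^2)), 0.01)
  # nearest-neighbor spacing within a factor 2 of the uniform ideal
  ideal <- sqrt(4 * pi / n)
  nn <- oracle_nn_dist(pts)
  expect_true(all(nn > ideal / 2 & nn < ideal * 2))
  expect_error(sphere_points(3), class = "epifold_invalid_input")
})

test_that("an isolated site monomer binds the ligand at the Morse minimum", {
  conf <- rbind(matrix(rnorm(21, sd = 1), 7, 3),
                c(25, 0, 0))
  pose <- dock(conf, binding_site(8), p, sweep = 0.1, n_points = 4000)
  d <- sqrt(sum((pose$ligand_position - conf[8, ])^2))
  expect_equal(d, p$l, tolerance = 0.15)
  expect_lt(pose$energy, -0.95)
})

test_that("the returned pose is the minimum over sampled shell energies", {
  fx <- make_fixture("docking-toy", seed = 3)
  pose <- dock(fx$conf, fx$site, p, sweep = 0.25, n_points = 1000)
  # re-evaluate a random subsample of shell points in R
  center <- colMeans(fx$conf)
  dists <- sqrt(rowSums((fx$conf - matrix(center, 8, 3, byrow = TRUE))^2))
  pts <- sphere_points(1000)
  set.seed(4)
  for (R in sample(seq(min(dists), max(dists) + 2 * p$l, by = 0.25), 5)) {
    for (ip in sample(1000, 40)) {
      pt <- center + R * pts[ip, ]
      r <- sqrt(rowSums((fx$conf - matrix(pt, 8, 3, byrow = TRUE))^2))
      mu <- exp(-2 * p$alpha * (r - p$l)) - 2 * exp(-p$alpha * (r - p$l))
      e <- sum(mu[fx$site$site_indices]) +
        sum(ifelse(r <= p$l, mu + 1, 0)[-fx$site$site_indices])
      expect_gte(e, pose$energy - 1e-9)
    }
  }
})

test_that("shell-sweep docking matches an exhaustive grid search", {
  fx <- make_fixture("docking-toy", seed = 3)
  pose <- dock(fx$conf, fx$site, p, sweep = 0.1, n_points = 8000)
  grid <- oracle_grid_dock(fx$conf, fx$site$site_indices, p$alpha, p$l,
                           spacing = 0.25)
  expect_equal(pose$energy, grid$energy, tolerance = 0.35)
})

test_that("dock energy is invariant under rigid transformation", {
  fx <- make_fixture("docking-toy", seed = 5)
  e1 <- dock(fx$conf, fx$site, p, sweep = 0.1, n_points = 6000)$energy
  e2 <- dock(random_rigid(fx$conf, seed = 6), fx$site, p, sweep = 0.1,
             n_points = 6000)$energy
  expect_equal(e1, e2, tolerance = 0.2)
})

test_that("refining the sweep never raises the minimum appreciably", {
  fx <- make_fixture("docking-toy", seed = 7)
  e_coarse <- dock(fx$conf, fx$site, p, sweep = 0.4, n_points = 3000)$energy
  e_fine <- dock(fx$conf, fx$site, p, sweep = 0.1, n_points = 3000)$energy
  expect_lte(e_fine, e_coarse + 0.05)
})

test_that("activity compares every complex pair inclusively", {
  conf <- rbind(c(0, 0, 0), c(p$l, 0, 0), c(0, p$l, 0), c(8, 8, 8))
  site <- binding_site(c(1, 2))
  pose <- structure(list(ligand_position = c(0, 0, p$l), energy = -1,
                         shell_radius = 3), class = "pose")
  d <- epifold:::complex_distances(conf, site, pose$ligand_position)
  tgt <- target_state(d, tolerance = 1)
  expect_true(is_active(conf, site, pose, tgt))
  # exactly at the tolerance boundary: still active (inclusive)
  d2 <- d
  d2[1, 2] <- d2[1, 2] + 1
  d2[2, 1] <- d2[2, 1] + 1
  expect_true(is_active(conf, site, pose, target_state(d2, 1)))
  # beyond tolerance on one pair: inactive
  d3 <- d
  d3[1, 3] <- d3[1, 3] + 1.5
  d3[3, 1] <- d3[3, 1] + 1.5
  expect_false(is_active(conf, site, pose, target_state(d3, 1)))
  # wrong-sized target
  expect_error(is_active(conf, binding_site(c(1, 2, 3)), pose, tgt),
               class = "epifold_invalid_target")
})

test_that("target construction averages the properly formed replicas", {
  X <- random_coil(8, p, seed = 8, min_sep_frac = 0.9)
  site <- binding_site(c(2, 5))
  pose <- dock(X, site, p, sweep = 0.15, n_points = 3000)
  dX <- epifold:::complex_distances(X, site, pose$ligand_position)
  # all replicas identical: target equals that geometry
  ens <- as_ensemble(rep(list(X), 4), "WLIVGSKE")
  tgt <- make_target(ens, site, target_state(dX, 1), p, sweep = 0.15,
                     n_points = 3000)
  expect_equal(tgt$pair_distances, dX, tolerance = 1e-9)
  # two groups; only the X-like group is active under the seed target
  Y <- X
  Y[5, ] <- Y[5, ] + 10 # breaks the site-site pair distance
  ens2 <- as_ensemble(c(rep(list(X), 3), rep(list(Y), 3)), "WLIVGSKE")
  tgt2 <- make_target(ens2, site, target_state(dX, 1), p, sweep = 0.15,
                      n_points = 3000)
  expect_equal(tgt2$pair_distances, dX, tolerance = 1e-9)
  # idempotence: re-averaging with the produced target reproduces it
  jitter <- lapply(1:4, function(i) X + matrix(rnorm(24, sd = 0.02), 8, 3))
  ens3 <- as_ensemble(jitter, "WLIVGSKE")
  t1 <- make_target(ens3, site, target_state(dX, 1), p, sweep = 0.15,
                    n_points = 3000)
  t2 <- make_target(ens3, site, t1, p, sweep = 0.15, n_points = 3000)
  expect_lt(max(abs(t1$pair_distances - t2$pair_distances)), 0.01)
  # no active replica: explicit error
  far <- target_state(dX + 30, 0.1)
  expect_error(make_target(ens, site, far, p, sweep = 0.3, n_points = 500),
               class = "epifold_cannot_build_target")
})
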