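p <- potential_params()
tab <- default_contact_table(p)
m_red <- epifold:::reduced_mass(1.66e-22, p$T0)

test_that("analytic forces match the finite-difference gradient", {
  # isolated bonded pair at equilibrium: zero force
  X2 <- rbind(c(0, 0, 0), c(p$l, 0, 0))
  expect_equal(forces(X2, "GG", tab, p), matrix(0, 2, 3))
  for (i in 1:3) {
    X <- random_coil(8, p, seed = 200 + i)
    s <- "WLKEDFGH"
    F <- forces(X, s, tab, p)
    # translation invariance: net force vanishes
    expect_equal(colSums(F), c(0, 0, 0), tolerance = 1e-10)
    fd <- oracle_fd_forces(X, strsplit(s, "")[[1]], tab, p)
    expect_lt(max(abs(F - fd)) / max(abs(F)), 1e-5)
  }
})

test_that("coincident non-bonded monomers trigger the singularity guard", {
  X <- rbind(c(0, 0, 0), c(p$l, 0, 0), c(0, 0, 0))
  expect_warning(F <- forces(X, "GGG", tab, p), "singularity")
  expect_true(all(is.finite(F)))
})

test_that("propagation is deterministic and n_steps = 0 is the identity", {
  st <- chain_state(random_coil(6, p, seed = 5))
  th <- thermostat_params(T = 302.15)
  expect_identical(integrate_chain(st, "GGGGGG", tab, th, p, 0), st)
  a <- integrate_chain(st, "GGGGGG", tab, th, p, 500, seed = 9)
  b <- integrate_chain(st, "GGGGGG", tab, th, p, 500, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  c_ <- integrate_chain(st, "GGGGGG", tab, th, p, 500, seed = 10)
  expect_false(identical(a$positions, c_$positions))
})

test_that("a free monomer equilibrates to the bath temperature", {
  th <- thermostat_params(T = 250)
  st <- chain_state(matrix(0, 1, 3))
  out <- integrate_chain(st, "G", tab, th, p, n_steps = 6e4, seed = 11,
                         sample_every = 20)
  sm <- attr(out, "samples")
  v2 <- apply(sm$velocities, 1, function(m) sum(m^2))
  T_inst <- m_red * v2 / 3 * p$T0 # 2*KE/(3 kB) per snapshot, one monomer
  se <- sd(T_inst) / sqrt(length(T_inst) / 10) # generous decorrelation
  expect_lt(abs(mean(T_inst) - 250), 3 * se + 1)
})

test_that("bonded pair reproduces the harmonic stationary variance", {
  th <- thermostat_params(T = 302.15)
  st <- chain_state(rbind(c(0, 0, 0), c(p$l, 0, 0)))
  out <- integrate_chain(st, "GG", tab, th, p, n_steps = 15e4, seed = 12,
                         sample_every = 100)
  sm <- attr(out, "samples")
  r <- sqrt(rowSums((sm$positions[, 2, ] - sm$positions[, 1, ])^2))
  v <- var(r - p$l)
  expected <- (th$T / p$T0) / p$kappa
  se <- expected * sqrt(2 / length(r))
  # small positive bias from the radial Jacobian is within the band
  expect_lt(abs(v - expected), 4 * se + 0.03 * expected)
})

test_that("kinetic temperature follows its definition", {
  st <- chain_state(matrix(0, 4, 3), matrix(0, 4, 3))
  th <- thermostat_params()
  expect_equal(kinetic_temperature(st, th, p), 0)
  st2 <- chain_state(matrix(0, 4, 3), matrix(1, 4, 3))
  st4 <- chain_state(matrix(0, 4, 3), matrix(2, 4, 3))
  expect_equal(kinetic_temperature(st4, th, p),
               4 * kinetic_temperature(st2, th, p))
})

test_that("zero-friction limit conserves energy like velocity Verlet", {
  th <- thermostat_params(gamma = 0, T = 302.15)
  X <- random_coil(6, p, seed = 21)
  set.seed(22)
  V <- maxwell_velocities(6, thermostat_params(T = 150), p)
  st <- chain_state(X, V)
  e0 <- total_energy(X, "GGGGGG", tab, p) +
    0.5 * m_red * sum(V^2)
  out <- integrate_chain(st, "GGGGGG", tab, th, p, n_steps = 1e4)
  e1 <- total_energy(out$positions, "GGGGGG", tab, p) +
    0.5 * m_red * sum(out$velocities^2)
  expect_lt(abs(e1 - e0), 0.01 * abs(e0))
})

test_that("free-monomer diffusion matches the Einstein relation", {
  th <- thermostat_params(T = 302.15)
  st <- chain_state(matrix(0, 1, 3))
  out <- integrate_chain(st, "G", tab, th, p, n_steps = 2e5, seed = 31,
                         sample_every = 100)
  sm <- attr(out, "samples")
  pos <- sm$positions[, 1, ]
  # MSD over lag of 1 sample (1 ps) from increments
  inc <- diff(pos)
  msd1 <- mean(rowSums(inc^2))
  D <- (th$T / p$T0) / (m_red * th$gamma)
  se <- msd1 * sqrt(2 / nrow(inc))
  expect_lt(abs(msd1 - 6 * D * 1.0), 4 * se)
})

test_that("numerical blow-up raises an integration failure with the step", {
  th <- thermostat_params(dt = 50, T = 302.15) # absurd step: unstable
  st <- chain_state(rbind(c(0, 0, 0), c(p$l + 1, 0, 0)))
  expect_error(integrate_chain(st, "GG", tab, th, p, n_steps = 1000,
                               seed = 3),
               "step", class = "epifold_integration_failure")
})
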