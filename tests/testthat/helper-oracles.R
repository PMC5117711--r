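# Independent pure-R oracles used across the suite. These deliberately
# re-derive every quantity from the defining formulas, separate from the
# package's compiled code paths.

oracle_morse <- function(r, alpha, l) {
  exp(-2 * alpha * (r - l)) - 2 * exp(-alpha * (r - l))
}

oracle_nonbonded <- function(r, ep, eps, alpha, l) {
  mu <- oracle_morse(r, alpha, l)
  if (ep <= 0) {
    if (r <= l) eps * mu + (eps + ep) else -ep * mu
  } else {
    if (r <= l) eps * mu + eps + ep * exp(-alpha * (r - l))
    else ep * exp(-alpha * (r - l))
  }
}

# Brute-force per-term total energy of a conformation.
oracle_total_energy <- function(X, res, table, params) {
  n <- nrow(X)
  u <- 0
  for (i in seq_len(n - 1)) {
    r <- sqrt(sum((X[i + 1, ] - X[i, ])^2))
    u <- u + params$kappa / 2 * (r - params$l)^2
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i >= 2) {
      r <- sqrt(sum((X[j, ] - X[i, ])^2))
      u <- u + oracle_nonbonded(r, table$eps_prime[res[i], res[j]],
                                params$eps_core, params$alpha, params$l)
    }
  }
  u
}

# Central finite-difference gradient of the oracle energy.
oracle_fd_forces <- function(X, res, table, params, h = 1e-6) {
  F <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) for (k in 1:3) {
    Xp <- X; Xp[i, k] <- Xp[i, k] + h
    Xm <- X; Xm[i, k] <- Xm[i, k] - h
    F[i, k] <- -(oracle_total_energy(Xp, res, table, params) -
                 oracle_total_energy(Xm, res, table, params)) / (2 * h)
  }
  F
}

# Closed-form single-shot superposition allowing reflection: evaluates the
# proper- and improper-rotation optima explicitly and keeps the better.
oracle_superpose_rms <- function(mobile, target) {
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  M <- sweep(mobile, 2, cm)
  T_ <- sweep(target, 2, ct)
  H <- t(M) %*% T_
  s <- svd(H)
  best <- Inf
  for (sign3 in c(1, -1)) {
    D <- diag(c(1, 1, sign3 * sign(det(s$v %*% t(s$u)))))
    R <- s$v %*% D %*% t(s$u)
    moved <- M %*% t(R)
    best <- min(best, sqrt(mean(rowSums((moved - T_)^2))))
  }
  best
}

# Exhaustive dense-grid docking oracle: minimum ligand energy over a 3-D
# grid covering the structure plus margin.
oracle_grid_dock <- function(X, site_idx, alpha, l, spacing = 0.3,
                             margin = 2 * l) {
  gx <- seq(min(X[, 1]) - margin, max(X[, 1]) + margin, by = spacing)
  gy <- seq(min(X[, 2]) - margin, max(X[, 2]) + margin, by = spacing)
  gz <- seq(min(X[, 3]) - margin, max(X[, 3]) + margin, by = spacing)
  pts <- as.matrix(expand.grid(gx, gy, gz))
  E <- numeric(nrow(pts))
  for (i in seq_len(nrow(X))) {
    r <- sqrt((pts[, 1] - X[i, 1])^2 + (pts[, 2] - X[i, 2])^2 +
              (pts[, 3] - X[i, 3])^2)
    mu <- exp(-2 * alpha * (r - l)) - 2 * exp(-alpha * (r - l))
    if (i %in% site_idx) E <- E + mu
    else E <- E + ifelse(r <= l, mu + 1, 0) # shifted repulsive core
  }
  k <- which.min(E)
  list(energy = E[k], position = pts[k, ])
}

# Brute-force nearest-neighbor distances among points.
oracle_nn_dist <- function(pts) {
  n <- nrow(pts)
  nn <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2 +
      (pts[, 3] - pts[i, 3])^2
    d2[i] <- Inf
    nn[i] <- sqrt(min(d2))
  }
  nn
}

# A tiny contact table with uniform pair strength, for geometric tests.
flat_contact_table <- function(ep = -1) {
  m <- matrix(ep, 20, 20,
              dimnames = list(epifold:::AA20, epifold:::AA20))
  structure(list(E = m, E_o = 1, eps_prime = m), class = "contact_table")
}

# Build a replica_ensemble object directly from a list of conformations.
as_ensemble <- function(members, sequence) {
  structure(list(members = members, failed = logical(length(members)),
                 seeds = seq_along(members), schedule = NULL,
                 sequence = sequence),
            class = "replica_ensemble")
}

# Rigid (optionally improper) random transform.
random_rigid <- function(X, seed, reflect = FALSE) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(A))
  if (xor(det(q) < 0, reflect)) q[, 1] <- -q[, 1]
  X %*% t(q) + matrix(rnorm(3, sd = 5), nrow(X), 3, byrow = TRUE)
}
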