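p <- potential_params()

test_that("alignment recovers rigid and mirror copies exactly", {
  X <- random_coil(10, p, seed = 31)
  expect_equal(align_structures(X, X)$rms_all, 0, tolerance = 1e-10)
  # proper rigid copy
  Y <- random_rigid(X, seed = 32)
  expect_equal(align_structures(Y, X)$rms_all, 0, tolerance = 1e-8)
  # mirror image: reflection is permitted
  Z <- X
  Z[, 1] <- -Z[, 1]
  a <- align_structures(Z, X)
  expect_equal(a$rms_all, 0, tolerance = 1e-8)
  expect_equal(abs(det(a$rotation)), 1, tolerance = 1e-9)
})

test_that("full-match alignment equals the closed-form superposition", {
  for (i in 1:5) {
    A <- random_coil(10, p, seed = 40 + i)
    B <- random_coil(10, p, seed = 50 + i)
    a <- align_structures(A, B, match_fraction = 1)
    expect_equal(a$rms_all, oracle_superpose_rms(A, B), tolerance = 1e-8)
  }
})

test_that("trimmed-core alignment matches a perturbed subset structure", {
  X <- random_coil(12, p, seed = 60)
  Y <- X
  Y[11:12, ] <- Y[11:12, ] + 10 # displace a third of the chain
  a <- align_structures(random_rigid(Y, seed = 61, reflect = TRUE), X,
                        match_fraction = 2 / 3)
  expect_equal(length(a$matched), 8) # floor(2*12/3)
  expect_lt(a$rms_matched, 1e-6)
  expect_true(all(a$matched %in% 1:10))
})

test_that("degenerate collinear geometry is rejected", {
  L <- cbind(seq_len(5) * p$l, 0, 0)
  expect_error(align_structures(L, L),
               class = "epifold_alignment_degenerate")
})

test_that("reference selection recovers a planted dominant cluster", {
  A <- random_coil(10, p, seed = 70)
  B <- random_coil(10, p, seed = 71)
  members <- c(
    lapply(1:24, function(i) random_rigid(A + matrix(rnorm(30, sd = 0.05),
                                                     10, 3),
                                          seed = 80 + i,
                                          reflect = i %% 2 == 0)),
    lapply(1:8, function(i) random_rigid(B + matrix(rnorm(30, sd = 0.05),
                                                    10, 3),
                                         seed = 120 + i)))
  ens <- as_ensemble(members, "GGGGGGGGGG")
  ref <- select_reference(ens, params = p)
  expect_equal(length(ref$member_ids), 24) # floor(3/4 * 32)
  expect_true(all(ref$member_ids <= 24)) # subset drawn from the A cluster
  expect_lt(ref$score, 0.2)
})

test_that("identical ensembles give zero score and the leading subset", {
  X <- random_coil(9, p, seed = 90)
  ens <- as_ensemble(rep(list(X), 8), "GGGGGGGGG")
  ref <- select_reference(ens, params = p)
  expect_equal(ref$score, 0, tolerance = 1e-10)
  expect_identical(ref$member_ids, 1:6) # floor(3/4 * 8), ties by index
  expect_equal(ref$rmsf, rep(0, 9), tolerance = 1e-10)
  expect_equal(ref$n_ordered, 9)
})

test_that("selection score is invariant under rigid motion of a member", {
  X <- random_coil(9, p, seed = 91)
  members <- lapply(1:8, function(i) X + matrix(rnorm(27, sd = 0.1), 9, 3))
  ens <- as_ensemble(members, "GGGGGGGGG")
  ref1 <- select_reference(ens, params = p)
  members2 <- members
  members2[[3]] <- random_rigid(members2[[3]], seed = 92, reflect = TRUE)
  ref2 <- select_reference(as_ensemble(members2, "GGGGGGGGG"), params = p)
  expect_equal(ref1$score, ref2$score, tolerance = 1e-6)
})

test_that("order profile flags fluctuating monomers by the Lindemann rule", {
  X <- random_coil(10, p, seed = 95)
  # displace monomer 4 by +/- 2 A in alternating members
  members <- lapply(1:8, function(i) {
    Y <- X
    Y[4, 1] <- Y[4, 1] + ifelse(i %% 2 == 0, 2, -2)
    Y
  })
  ref <- structure(list(x_star = X, member_ids = 1:8, aligned = members,
                        score = 0, lindemann_c = 0.25, l = p$l,
                        rmsf = NULL, ordered_mask = NULL, n_ordered = NULL),
                   class = "reference_fold")
  ref <- order_profile(ref)
  expect_equal(ref$rmsf[4], 2, tolerance = 1e-12)
  expect_false(ref$ordered_mask[4])
  expect_true(all(ref$ordered_mask[-4]))
  # brute-force RMSF cross-check
  rmsf_bf <- sapply(1:10, function(j)
    sqrt(mean(sapply(members, function(m) sum((m[j, ] - X[j, ])^2)))))
  expect_equal(ref$rmsf, rmsf_bf, tolerance = 1e-12)
  # viability needs at least 15 ordered monomers; 9 here
  expect_false(is_viable(ref))
  expect_true(is_viable(ref, min_ordered = 9))
})
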