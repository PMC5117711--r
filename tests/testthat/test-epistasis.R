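p <- potential_params()

test_that("the epistasis statistic is exact arithmetic and symmetric", {
  expect_equal(epsilon(-0.13, -0.61, -0.29), 0.77)
  expect_equal(epsilon(-0.47, -0.17, 0.02), -0.32)
  expect_equal(epsilon(0.3, 0.1, 0.2), 0)
  expect_equal(epsilon(-0.4, -0.1, -0.2), epsilon(-0.4, -0.2, -0.1))
})

test_that("pair scans recover constructed fitness landscapes", {
  # additive landscape (effects exact multiples of 1/n): zero epistasis
  wt <- "WLKEDFGHIVAC"
  wt_res <- strsplit(wt, "")[[1]]
  additive <- function(s) {
    r <- strsplit(s, "")[[1]]
    0.9 - 0.05 * sum(r != wt_res)
  }
  proto <- mock_protocol(n_replicas = 20, fitness_fn = additive)
  recs <- pair_scan(wt, 25, proto, base_seed = 5)
  expect_equal(nrow(recs), 25)
  expect_equal(recs$eps, rep(0, 25), tolerance = 1e-12)
  expect_equal(attr(recs, "P0"), 0.9)
  # empty scan
  expect_equal(nrow(pair_scan(wt, 0, proto, base_seed = 5)), 0)
  # planted interaction: fitness recovers only in the double mutant
  fx <- make_fixture("planted-epistasis", seed = 1)
  sampler <- function(n, seed) fx$pair
  recs2 <- pair_scan(fx$sequence, 5, fx$protocol, base_seed = 6,
                     site_sampler = sampler)
  expect_true(all(recs2$site_i == fx$pair[1] & recs2$site_j == fx$pair[2]))
  expect_true(all(recs2$eps > 0.2))
})

test_that("inter-site distances use the reference fold, contact is strict", {
  X <- random_coil(10, p, seed = 7)
  ref <- structure(list(x_star = X, l = p$l), class = "reference_fold")
  sd12 <- site_distance(ref, 1, 2)
  expect_equal(sd12$R, p$l, tolerance = 1e-9)
  expect_true(sd12$in_contact)
  for (i in c(1, 3)) for (j in c(6, 9)) {
    expect_equal(site_distance(ref, i, j)$R,
                 sqrt(sum((X[i, ] - X[j, ])^2)), tolerance = 1e-12)
  }
  # boundary: R exactly 1.5 l is not a contact
  Y <- rbind(c(0, 0, 0), c(1.5 * p$l, 0, 0), c(0, 5, 0))
  refY <- structure(list(x_star = Y, l = p$l), class = "reference_fold")
  expect_false(site_distance(refY, 1, 2)$in_contact)
  expect_error(site_distance(ref, 3, 3), class = "epifold_invalid_input")
})

test_that("the lambda filter keeps viable mutants and is monotone", {
  recs <- tibble::tibble(
    dP1 = c(-0.61, -0.5, -0.1, 0.0), dP2 = c(-0.29, -0.5, -0.1, -0.3),
    dP12 = c(-0.13, -0.5, -0.5, -0.1),
    eps = 0, site_i = 1:4, site_j = 5:8)
  kept <- lambda_filter(recs, -0.2)
  expect_identical(kept$site_i, c(1L, 3L, 4L)) # row 2 excluded
  expect_equal(nrow(lambda_filter(recs, -1)), 4)
  lams <- seq(-1, 0.2, by = 0.05)
  sizes <- vapply(lams, function(l) nrow(lambda_filter(recs, l)),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("quadrature error propagation matches Monte-Carlo binomial noise", {
  em <- error_model(dP = 0.037)
  expect_identical(em$dEps / em$dP, sqrt(3))
  expect_identical(em$dSum / em$dP, sqrt(2))
  lin <- error_model(dP = 0.037, mode = "linear")
  expect_identical(lin$dEps, 3 * 0.037)
  # independent binomial fitness errors pushed through the statistic
  N <- 127
  prob <- 0.8
  dP <- sqrt(prob * (1 - prob) / N)
  set.seed(13)
  draws <- 6e4
  eps_noise <- (rbinom(draws, N, prob) - rbinom(draws, N, prob) -
                rbinom(draws, N, prob)) / N + prob
  expect_lt(abs(sd(eps_noise) - sqrt(3) * dP) / (sqrt(3) * dP), 0.02)
})

test_that("distribution summaries recover a known Gaussian width", {
  set.seed(14)
  recs <- tibble::tibble(dP1 = 0, dP2 = 0, dP12 = 0,
                         eps = rnorm(1500, 0, 0.14))
  s <- summarize_epistasis(recs, lam = -1)
  se <- 0.14 * sqrt(1 / (2 * 1499))
  expect_lt(abs(s$sigma - 0.14), 4 * se)
  expect_equal(s$n, 1500)
  g <- glance(s)
  expect_identical(g$sigma, s$sigma)
  td <- tidy(s)
  expect_true(all(c("eps", "count", "density", "gaussian") %in% names(td)))
  # degenerate all-zero records
  z <- tibble::tibble(dP1 = 0, dP2 = 0, dP12 = 0, eps = rep(0, 50))
  sz <- summarize_epistasis(z, lam = -1)
  expect_equal(sz$sigma, 0)
  expect_equal(sz$frac_significant, 0)
  expect_error(summarize_epistasis(z[0, ], lam = -1),
               class = "epifold_summary_error")
  # width-vs-lambda table is finite everywhere it is defined
  recs$dP1 <- recs$eps / 2
  recs$dP12 <- recs$eps
  svl <- sigma_vs_lambda(recs, seq(-0.5, 0, by = 0.1))
  expect_true(all(is.finite(svl$sigma)))
  expect_true(all(svl$n >= 2))
})
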