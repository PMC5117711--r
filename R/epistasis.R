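#' Epistasis statistic
#'
#' Deviation of the double-mutant fitness change from additivity,
#' `epsilon = dP12 - dP1 - dP2`, where each `dP` is the fitness change of
#' a mutant relative to the unmutated sequence. Positive values mean the
#' double mutant is less deleterious than the sum of the single mutants;
#' negative values mean more deleterious. Symmetric under swapping the two
#' mutations.
#'
#' @param dP12 Fitness change of the double mutant.
#' @param dP1,dP2 Fitness changes of the single mutants.
#' @return The epistasis value (vectorized).
#' @examples
#' epsilon(-0.13, -0.61, -0.29) # strong positive epistasis
#' @export
epsilon <- function(dP12, dP1, dP2) {
  stopifnot(all(abs(c(dP12, dP1, dP2)) <= 1 + 1e-12))
  dP12 - dP1 - dP2
}

#' Distance between two sites in the reference fold
#'
#' Euclidean distance between monomers `i` and `j` in the reference
#' structure; the pair is in direct contact when `R < 1.5 * l` (strict).
#'
#' @param ref A [select_reference()] result.
#' @param i,j Distinct monomer indices.
#' @return A list with `R` (Angstroms) and `in_contact`.
#' @export
site_distance <- function(ref, i, j) {
  stopifnot(inherits(ref, "reference_fold"))
  n <- nrow(ref$x_star)
  if (i == j || i < 1 || j < 1 || i > n || j > n) {
    abort("i and j must be distinct valid monomer indices",
          class = "epifold_invalid_input")
  }
  R <- sqrt(sum((ref$x_star[i, ] - ref$x_star[j, ])^2))
  list(R = R, in_contact = R < 1.5 * ref$l)
}

#' Scan random pair mutations for epistasis
#'
#' Samples `n_pairs` unordered site pairs, proposes a mutation at each
#' site under the exchange matrix, measures the fitness of both single
#' mutants and the double mutant, and records the fitness changes, the
#' epistasis statistic, and (when a reference fold is supplied) the
#' distance between the sites in the initial reference structure. Every
#' measurement is seeded from `base_seed`, so a scan is fully
#' reproducible. Per-pair failures are skipped and counted.
#'
#' @param seq Unmutated sequence with fitness `P0`.
#' @param n_pairs Number of site pairs to sample.
#' @param protocol A [fitness_protocol()] or [mock_protocol()].
#' @param base_seed Integer seed.
#' @param xmat An [exchange_matrix()].
#' @param site,target Passed to [fitness()] for real protocols.
#' @param ref Optional [select_reference()] result of the unmutated
#'   sequence, used for inter-site distances.
#' @param site_sampler Optional function `(n_res, seed) -> c(i, j)`
#'   replacing uniform pair sampling.
#' @param P0 Optional precomputed base fitness (skips one measurement).
#' @return A tibble of class `epistasis_records`, one row per pair:
#'   `site_i`, `site_j`, `from1`, `to1`, `from2`, `to2`, `dP1`, `dP2`,
#'   `dP12`, `eps`, `R`, `in_contact`. Attributes: `P0`, `n_failed`.
#' @export
pair_scan <- function(seq, n_pairs, protocol, base_seed = 1,
                      xmat = exchange_matrix(), site = NULL, target = NULL,
                      ref = NULL, site_sampler = NULL, P0 = NULL) {
  res <- seq_residues(seq)
  n <- length(res)
  if (is.null(P0)) {
    P0 <- fitness(seq, site, target, protocol, derive_seed(base_seed, 0L))$P
  }
  rows <- vector("list", n_pairs)
  n_failed <- 0L
  for (k in seq_len(n_pairs)) {
    rec <- tryCatch({
      if (is.null(site_sampler)) {
        set.seed(derive_seed(base_seed, k, 1L))
        ij <- sort(sample.int(n, 2))
      } else {
        ij <- sort(site_sampler(n, derive_seed(base_seed, k, 1L)))
      }
      m1 <- propose_mutation(seq, ij[1], xmat, derive_seed(base_seed, k, 2L))
      m2 <- propose_mutation(seq, ij[2], xmat, derive_seed(base_seed, k, 3L))
      P1 <- fitness(apply_mutations(seq, m1), site, target, protocol,
                    derive_seed(base_seed, k, 4L))$P
      P2 <- fitness(apply_mutations(seq, m2), site, target, protocol,
                    derive_seed(base_seed, k, 5L))$P
      P12 <- fitness(apply_mutations(seq, m1, m2), site, target, protocol,
                     derive_seed(base_seed, k, 6L))$P
      dP1 <- P1 - P0
      dP2 <- P2 - P0
      dP12 <- P12 - P0
      sd_ij <- if (is.null(ref)) list(R = NA_real_, in_contact = NA)
               else site_distance(ref, ij[1], ij[2])
      tibble(site_i = ij[1], site_j = ij[2],
             from1 = m1$from_aa, to1 = m1$to_aa,
             from2 = m2$from_aa, to2 = m2$to_aa,
             dP1 = dP1, dP2 = dP2, dP12 = dP12,
             eps = epsilon(dP12, dP1, dP2),
             R = sd_ij$R, in_contact = sd_ij$in_contact)
    }, error = function(e) NULL)
    if (is.null(rec)) n_failed <- n_failed + 1L else rows[[k]] <- rec
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(site_i = integer(), site_j = integer(),
                  from1 = character(), to1 = character(),
                  from2 = character(), to2 = character(),
                  dP1 = double(), dP2 = double(), dP12 = double(),
                  eps = double(), R = double(), in_contact = logical())
  }
  attr(out, "P0") <- P0
  attr(out, "n_failed") <- n_failed
  class(out) <- c("epistasis_records", class(out))
  out
}

#' Filter pair-mutation records by viability
#'
#' Keeps records whose double mutant is no more deleterious than `lambda`,
#' or whose two single mutants both are: `dP12 >= lambda` OR
#' (`dP1 >= lambda` AND `dP2 >= lambda`). The filter is monotone in
#' `lambda`: raising it can only shrink the kept set.
#'
#' @param records An `epistasis_records` tibble (or any data frame with
#'   `dP1`, `dP2`, `dP12`).
#' @param lam Viability threshold on fitness changes.
#' @return The filtered records.
#' @export
lambda_filter <- function(records, lam = -0.2) {
  dplyr::filter(records,
                .data$dP12 >= lam | (.data$dP1 >= lam & .data$dP2 >= lam))
}

#' Measurement error model for fitness changes and epistasis
#'
#' Propagates the single-measurement fitness error `dP` to the error of
#' `dP1 + dP2` and of the epistasis statistic. With independent errors the
#' propagation is in quadrature: `sqrt(2) * dP` and `sqrt(3) * dP`. A
#' literal linear mode (`2 * dP`, `3 * dP`) is also available.
#'
#' @param dP Single fitness-measurement error.
#' @param mode `"quadrature"` or `"linear"`.
#' @param sig_mult Significance multiplier on `dEps`.
#' @return A list with `dP`, `dSum`, `dEps`, `sig_mult`, `mode`.
#' @export
error_model <- function(dP = 0.037, mode = c("quadrature", "linear"),
                        sig_mult = 3) {
  mode <- match.arg(mode)
  f <- if (mode == "quadrature") c(sqrt(2), sqrt(3)) else c(2, 3)
  list(dP = dP, dSum = f[1] * dP, dEps = f[2] * dP, sig_mult = sig_mult,
       mode = mode)
}

#' Summarize an epistasis distribution
#'
#' Applies the lambda filter, fits a Gaussian to the epistasis histogram
#' (maximum likelihood; the sample SD is reported alongside), and
#' computes the fraction of records with significant epistasis,
#' `|eps| > sig_mult * dEps`.
#'
#' @param records An `epistasis_records` tibble.
#' @param lam Threshold for [lambda_filter()]; use `-Inf` to keep all.
#' @param err An [error_model()].
#' @return An object of class `epistasis_summary`.
#' @export
summarize_epistasis <- function(records, lam = -0.2, err = error_model()) {
  kept <- lambda_filter(records, lam)
  if (nrow(kept) < 2) {
    abort("need at least 2 filtered records to summarize",
          class = "epifold_summary_error")
  }
  e <- kept$eps
  mu <- mean(e)
  structure(list(eps = e, n = length(e), lambda = lam, mean = mu,
                 sigma = sd(e), sigma_mle = sqrt(mean((e - mu)^2)),
                 err = err,
                 frac_significant = mean(abs(e) > err$sig_mult * err$dEps)),
            class = "epistasis_summary")
}

#' @export
print.epistasis_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<epistasis_summary> n = %d (lambda = %g)\n",
    "  sigma(eps) = %.4f (MLE %.4f), mean = %.4f\n",
    "  significant |eps| > %g * %.4f: %.1f%%\n"),
    x$n, x$lambda, x$sigma, x$sigma_mle, x$mean,
    x$err$sig_mult, x$err$dEps, 100 * x$frac_significant))
  invisible(x)
}

#' @rdname summarize_epistasis
#' @param x An `epistasis_summary`.
#' @param ... Unused.
#' @export
glance.epistasis_summary <- function(x, ...) {
  tibble(n = x$n, lambda = x$lambda, mean = x$mean, sigma = x$sigma,
         sigma_mle = x$sigma_mle, dEps = x$err$dEps,
         sig_mult = x$err$sig_mult, frac_significant = x$frac_significant)
}

#' @rdname summarize_epistasis
#' @param bins Number of histogram bins for `tidy()`.
#' @export
tidy.epistasis_summary <- function(x, bins = 20, ...) {
  h <- graphics::hist(x$eps, breaks = bins, plot = FALSE)
  tibble(eps = h$mids, count = h$counts, density = h$density,
         gaussian = dnorm(h$mids, x$mean, max(x$sigma_mle, 1e-12)))
}

#' Width of the epistasis distribution as a function of lambda
#'
#' @param records An `epistasis_records` tibble.
#' @param lambdas Vector of thresholds.
#' @param err An [error_model()].
#' @return A tibble with `lambda`, `n`, `sigma`, `frac_significant`.
#' @export
sigma_vs_lambda <- function(records, lambdas = seq(-1, 0, by = 0.1),
                            err = error_model()) {
  purrr::map_dfr(lambdas, function(lam) {
    s <- tryCatch(summarize_epistasis(records, lam, err),
                  epifold_summary_error = function(e) NULL)
    if (is.null(s)) return(tibble())
    tibble(lambda = lam, n = s$n, sigma = s$sigma,
           frac_significant = s$frac_significant)
  })
}
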