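#' Align one conformation onto another through its closest pairs
#'
#' Least-squares superposition allowing improper rotations (reflection),
#' iterated over a trimmed core: after each superposition the
#' `floor(match_fraction * n)` index pairs with the smallest residual
#' distances are re-selected and the fit repeated until the matched set
#' repeats (oscillations are broken by keeping the lowest-RMS iterate).
#' With `match_fraction = 1` this is a single closed-form superposition.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3, equal lengths.
#' @param match_fraction Fraction of pairs forming the matched core.
#' @param max_iter Maximum trim-refit iterations.
#' @return An object of class `alignment` with `rotation` (3 x 3,
#'   `|det| = 1`, reflection allowed), `translation`, `matched` (sorted
#'   index set), `rms_matched`, `rms_all`, and `aligned` (transformed
#'   mobile coordinates).
#' @export
align_structures <- function(mobile, target, match_fraction = 2 / 3,
                             max_iter = 50) {
  mobile <- as_conformation(mobile)
  target <- as_conformation(target)
  n <- nrow(mobile)
  if (nrow(target) != n || n < 3) {
    abort("conformations must have equal lengths >= 3",
          class = "epifold_invalid_input")
  }
  if (is_degenerate(mobile) || is_degenerate(target)) {
    abort("degenerate (collinear) geometry cannot be aligned",
          class = "epifold_alignment_degenerate")
  }
  m <- max(2L, as.integer(floor(match_fraction * n)))
  matched <- seq_len(n)
  seen <- list()
  best <- NULL
  for (iter in seq_len(max_iter)) {
    tr <- superpose_transform(mobile, target, matched)
    moved <- mobile %*% t(tr$rotation) +
      matrix(tr$translation, n, 3, byrow = TRUE)
    d <- sqrt(rowSums((moved - target)^2))
    cand <- list(rotation = tr$rotation, translation = tr$translation,
                 matched = matched,
                 rms_matched = sqrt(mean(d[matched]^2)),
                 rms_all = sqrt(mean(d^2)), aligned = moved)
    if (is.null(best) || cand$rms_matched < best$rms_matched) best <- cand
    new_matched <- sort(order(d)[seq_len(m)])
    if (identical(new_matched, matched)) break
    if (any(vapply(seen, identical, logical(1), y = new_matched))) break
    seen[[length(seen) + 1]] <- matched
    matched <- new_matched
  }
  structure(best, class = "alignment")
}

is_degenerate <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  sv[2] < 1e-9 * max(sv[1], 1)
}

# Closed-form least-squares transform (reflection allowed) on an index set.
superpose_transform <- function(mobile, target, idx) {
  M <- mobile[idx, , drop = FALSE]
  T_ <- target[idx, , drop = FALSE]
  cm <- colMeans(M)
  ct <- colMeans(T_)
  H <- crossprod(sweep(M, 2, cm), sweep(T_, 2, ct))
  s <- svd(H)
  R <- s$v %*% t(s$u) # improper rotations permitted
  list(rotation = R, translation = as.numeric(ct - R %*% cm))
}

#' Select the reference fold of a replica ensemble
#'
#' Searches over ensemble members for the structure whose
#' `floor(subset_fraction * N)` closest members (by trimmed-core RMS,
#' [align_structures()]) have the smallest mean aligned distance. The
#' winning member becomes the reference structure and the closest members
#' form the dominant-basin subset. Ties are broken by the lowest member
#' index. The per-monomer fluctuation profile is computed immediately via
#' [order_profile()].
#'
#' @param ens A [fold_ensemble()] result (failed replicas are excluded).
#' @param subset_fraction Fraction of replicas forming the basin subset.
#' @param match_fraction Passed to [align_structures()].
#' @param lindemann_c Order threshold as a fraction of the bond length.
#' @param params A [potential_params()] object (bond length for the
#'   Lindemann threshold).
#' @return An object of class `reference_fold` with `x_star`, `member_ids`,
#'   `aligned` (list of aligned subset members), `score`, `rmsf`,
#'   `ordered_mask`, `n_ordered`.
#' @export
select_reference <- function(ens, subset_fraction = 3 / 4,
                             match_fraction = 2 / 3, lindemann_c = 0.25,
                             params = potential_params()) {
  stopifnot(inherits(ens, "replica_ensemble"))
  ids <- which(!ens$failed)
  members <- ens$members[ids]
  N <- length(members)
  k <- as.integer(floor(subset_fraction * N))
  if (N < 1 || k < 1) {
    abort("ensemble has too few members for the requested subset",
          class = "epifold_invalid_input")
  }
  best <- NULL
  for (c_i in seq_len(N)) {
    alns <- lapply(members, align_structures, target = members[[c_i]],
                   match_fraction = match_fraction)
    rms <- vapply(alns, `[[`, numeric(1), "rms_matched")
    sel <- order(rms)[seq_len(k)] # stable: ties keep lowest index
    score <- mean(rms[sel])
    if (is.null(best) || score < best$score - 1e-12) {
      best <- list(candidate = c_i, score = score, sel = sort(sel),
                   alns = alns)
    }
  }
  ref <- structure(
    list(x_star = members[[best$candidate]],
         member_ids = ids[best$sel],
         aligned = lapply(best$alns[best$sel], `[[`, "aligned"),
         score = best$score, lindemann_c = lindemann_c, l = params$l,
         rmsf = NULL, ordered_mask = NULL, n_ordered = NULL),
    class = "reference_fold")
  order_profile(ref, lindemann_c)
}

#' Per-monomer order profile of a reference fold
#'
#' Root-mean-square fluctuation of each monomer position over the aligned
#' basin subset about its reference position; a monomer is ordered when its
#' fluctuation is below `lindemann_c` times the bond length (a Lindemann
#' melting criterion).
#'
#' @param ref A [select_reference()] result.
#' @param lindemann_c Order threshold as a fraction of the bond length.
#' @return The `reference_fold` with `rmsf`, `ordered_mask` and `n_ordered`
#'   filled in.
#' @export
order_profile <- function(ref, lindemann_c = ref$lindemann_c) {
  stopifnot(inherits(ref, "reference_fold"))
  n <- nrow(ref$x_star)
  dev2 <- matrix(0, length(ref$aligned), n)
  for (mi in seq_along(ref$aligned)) {
    dev2[mi, ] <- rowSums((ref$aligned[[mi]] - ref$x_star)^2)
  }
  ref$rmsf <- sqrt(colMeans(dev2))
  ref$lindemann_c <- lindemann_c
  ref$ordered_mask <- ref$rmsf < lindemann_c * ref$l
  ref$n_ordered <- sum(ref$ordered_mask)
  ref
}

#' Viability of a sequence's folded ensemble
#'
#' A sequence is considered viable when its reference fold recovers at
#' least `min_ordered` ordered monomers.
#'
#' @param ref A `reference_fold`.
#' @param min_ordered Minimum count of ordered monomers.
#' @return Logical flag.
#' @export
is_viable <- function(ref, min_ordered = 15) {
  stopifnot(inherits(ref, "reference_fold"))
  ref$n_ordered >= min_ordered
}

#' @export
print.reference_fold <- function(x, ...) {
  cat(sprintf(
    "<reference_fold> %d-mer, basin of %d members, score %.3f A, %d ordered\n",
    nrow(x$x_star), length(x$member_ids), x$score, x$n_ordered))
  invisible(x)
}
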