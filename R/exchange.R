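# Standard genetic code, codon order TTT, TTC, TTA, TTG, TCT, ... (bases
# in T, C, A, G order at each position); '*' marks stop codons.
GENETIC_CODE_TCAG <-
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

#' Amino-acid exchange counts from the genetic code
#'
#' Counts, for every ordered pair of residues, the number of
#' single-nucleotide codon substitutions converting a codon of the first
#' into a codon of the second under the standard genetic code (stop codons
#' excluded). The diagonal holds synonymous changes. This provides a
#' default transition structure "roughly consistent with the genetic code"
#' for mutation proposals; an empirical count table (e.g. Dayhoff-style
#' accepted-mutation counts) can be read with [read_exchange_counts()]
#' instead.
#'
#' @return A 20 x 20 integer matrix of counts with amino-acid dimnames.
#' @export
codon_exchange_counts <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    codons[k] <- paste0(b1, b2, b3)
  }
  aa <- strsplit(GENETIC_CODE_TCAG, "")[[1]]
  names(aa) <- codons
  A <- matrix(0L, 20, 20, dimnames = list(AA20, AA20))
  for (c1 in codons) {
    if (aa[c1] == "*") next
    s1 <- strsplit(c1, "")[[1]]
    for (pos in 1:3) for (b in setdiff(bases, s1[pos])) {
      s2 <- s1
      s2[pos] <- b
      c2 <- paste(s2, collapse = "")
      if (aa[c2] == "*") next
      A[aa[c1], aa[c2]] <- A[aa[c1], aa[c2]] + 1L
    }
  }
  A
}

#' Amino-acid exchange matrix
#'
#' Row-normalizes a 20 x 20 transition-count matrix into exchange
#' probabilities `p(u, v) = A_uv / sum_v A_uv`. A mutation `u -> v` is
#' proposable exactly when `p(u, v) > 0`.
#'
#' @param counts 20 x 20 non-negative count matrix with amino-acid
#'   dimnames; defaults to [codon_exchange_counts()].
#' @return An object of class `exchange_matrix` with `counts` and `probs`.
#' @export
exchange_matrix <- function(counts = codon_exchange_counts()) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(20, 20)) || any(m < 0) ||
      is.null(rownames(m)) || !setequal(rownames(m), AA20)) {
    abort("counts must be a non-negative 20x20 amino-acid matrix",
          class = "epifold_format_error")
  }
  rs <- rowSums(m)
  probs <- m
  probs[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(list(counts = m, probs = probs), class = "exchange_matrix")
}

#' @rdname exchange_matrix
#' @param path Whitespace-delimited 20 x 20 count table with amino-acid
#'   header row and column (`#` comments allowed).
#' @export
read_exchange_counts <- function(path) {
  df <- read.table(path, header = TRUE, comment.char = "#",
                   check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- rownames(df)
  m
}

#' Propose a point mutation at a site
#'
#' Samples the replacement residue among those reachable from the current
#' residue under the exchange matrix (`p > 0`, excluding the residue
#' itself), uniformly by default or proportionally to the exchange
#' probabilities.
#'
#' @param seq Amino-acid sequence.
#' @param site Position to mutate (1-based).
#' @param xmat An [exchange_matrix()].
#' @param seed Optional integer seed.
#' @param weighting `"uniform"` over the allowed set, or `"probability"`
#'   proportional to `p(u, v)`.
#' @return An object of class `mutation_spec` with `site`, `from_aa`,
#'   `to_aa`.
#' @export
propose_mutation <- function(seq, site, xmat = exchange_matrix(),
                             seed = NULL,
                             weighting = c("uniform", "probability")) {
  weighting <- match.arg(weighting)
  res <- seq_residues(seq)
  if (site < 1 || site > length(res)) {
    abort("site outside the sequence", class = "epifold_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  from <- res[site]
  p <- xmat$probs[from, ]
  allowed <- setdiff(names(p)[p > 0], from)
  if (length(allowed) == 0) {
    abort(sprintf("no allowed exchange from %s", from),
          class = "epifold_no_move")
  }
  to <- if (weighting == "uniform") {
    allowed[sample.int(length(allowed), 1)]
  } else {
    w <- p[allowed]
    allowed[sample.int(length(allowed), 1, prob = w / sum(w))]
  }
  structure(list(site = as.integer(site), from_aa = from, to_aa = to),
            class = "mutation_spec")
}

# Apply one or more mutation specs to a sequence string.
apply_mutations <- function(seq, ...) {
  res <- seq_residues(seq)
  for (mut in list(...)) {
    stopifnot(inherits(mut, "mutation_spec"))
    if (res[mut$site] != mut$from_aa) {
      abort("mutation from_aa does not match the sequence",
            class = "epifold_invalid_input")
    }
    res[mut$site] <- mut$to_aa
  }
  paste(res, collapse = "")
}

#' Single-lineage selection walk
#'
#' Iterates propose-measure-accept from a starting sequence: at each step
#' a random site is mutated via [propose_mutation()], the mutant fitness is
#' measured, and the mutation is accepted according to `rule`. The default
#' rule accepts whenever the new fitness is at least `P_min`. This is a
#' convenience scaffold for generating evolved sequences, not a
#' population-genetics model.
#'
#' @param seq Starting sequence.
#' @param steps Number of proposal steps.
#' @param rule `"threshold"` (accept if `P_new >= P_min`), `"accept_all"`,
#'   `"reject_all"`, `"greedy"` (accept if `P_new >= P_old`), or a
#'   function `(P_new, P_old) -> logical`.
#' @param site,target,protocol Passed to [fitness()].
#' @param xmat An [exchange_matrix()].
#' @param base_seed Integer seed.
#' @param P_min Acceptance threshold for the default rule.
#' @return A tibble with one row per state (steps + 1 rows): `step`,
#'   `sequence`, `P`, `accepted`.
#' @export
evolve <- function(seq, steps, rule = "threshold", site = NULL,
                   target = NULL, protocol, xmat = exchange_matrix(),
                   base_seed = 1, P_min = 0.5) {
  accept <- if (is.function(rule)) rule else switch(
    rule,
    threshold = function(P_new, P_old) P_new >= P_min,
    accept_all = function(P_new, P_old) TRUE,
    reject_all = function(P_new, P_old) FALSE,
    greedy = function(P_new, P_old) P_new >= P_old,
    abort("unknown acceptance rule", class = "epifold_invalid_input"))
  cur <- paste(seq_residues(seq), collapse = "")
  P_cur <- fitness(cur, site, target, protocol,
                   derive_seed(base_seed, 0L))$P
  out <- tibble(step = 0L, sequence = cur, P = P_cur, accepted = TRUE)
  for (s in seq_len(steps)) {
    set.seed(derive_seed(base_seed, s, 1L))
    pos <- sample.int(nchar(cur), 1)
    mut <- tryCatch(propose_mutation(cur, pos, xmat,
                                     derive_seed(base_seed, s, 2L)),
                    epifold_no_move = function(e) NULL)
    if (is.null(mut)) {
      out <- dplyr::bind_rows(out, tibble(step = s, sequence = cur,
                                          P = P_cur, accepted = FALSE))
      next
    }
    cand <- apply_mutations(cur, mut)
    P_new <- fitness(cand, site, target, protocol,
                     derive_seed(base_seed, s, 3L))$P
    ok <- isTRUE(accept(P_new, P_cur))
    if (ok) {
      cur <- cand
      P_cur <- P_new
    }
    out <- dplyr::bind_rows(out, tibble(step = s, sequence = cur,
                                        P = P_cur, accepted = ok))
  }
  out
}
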