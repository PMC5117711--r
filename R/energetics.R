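#' @title Chain potentials
#' @description Bond, Morse and non-bonded pair energies in reduced units
#'   (`k_B*T0`). The non-bonded potential combines an excluded-volume core of
#'   strength `eps_core` with a sequence-dependent tail of signed strength
#'   `eps_prime`; its value at the bond length `l` equals `eps_prime`, it
#'   vanishes at large separation, and for attractive pairs
#'   (`eps_prime < 0`) it has a minimum of depth `|eps_prime|` at `r = l`.
#' @param r Monomer-monomer distance in Angstroms (scalar or vector).
#' @param params A [potential_params()] object.
#' @return Energy in `k_B*T0` units, vectorized over `r`.
#' @name potentials
NULL

check_distance <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) {
    abort("distances must be finite and non-negative",
          class = "epifold_invalid_input")
  }
}

#' @rdname potentials
#' @export
bond_energy <- function(r, params = potential_params()) {
  check_distance(r)
  params$kappa / 2 * (r - params$l)^2
}

#' @rdname potentials
#' @export
morse_unit <- function(r, params = potential_params()) {
  check_distance(r)
  e <- exp(-params$alpha * (r - params$l))
  e^2 - 2 * e
}

#' @rdname potentials
#' @param eps_prime Signed interaction strength for the pair (`k_B*T0`);
#'   negative values are attractive, positive repulsive.
#' @export
nonbonded_energy <- function(r, eps_prime, params = potential_params()) {
  check_distance(r)
  vapply(r, cpp_nonbonded_energy, numeric(1), ep = eps_prime,
         eps = params$eps_core, alpha = params$alpha, l = params$l)
}

#' Read a residue contact-energy table
#'
#' Parses a whitespace-delimited 20x20 matrix with one-letter amino-acid
#' codes as header row and first column. Lines starting with `#` are
#' comments. The bundled default table is
#' `system.file("extdata", "contact_energies.txt", package = "epifold")`.
#'
#' @param path Path to the table file.
#' @return A symmetric 20x20 numeric matrix with amino-acid dimnames.
#' @export
read_contact_energies <- function(path) {
  df <- read.table(path, header = TRUE, comment.char = "#",
                   check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- rownames(df)
  validate_raw_energies(m)
  m
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

validate_raw_energies <- function(m) {
  if (!is.matrix(m) || nrow(m) != 20 || ncol(m) != 20) {
    abort("contact-energy table must be 20x20", class = "epifold_format_error")
  }
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !setequal(rownames(m), AA20) || !identical(rownames(m), colnames(m))) {
    abort("table must be labeled by the 20 canonical amino acids",
          class = "epifold_format_error")
  }
  if (max(abs(m - t(m))) > 1e-8) {
    abort("contact-energy table must be symmetric",
          class = "epifold_format_error")
  }
  invisible(m)
}

#' Build the interaction table from raw contact energies
#'
#' Applies the threonine-reference-solvent rescaling
#' `E'_ij = E_ij - E_iT - E_jT + E_TT` to a raw quasi-chemical contact
#' table, computes the mean interaction strength `E_o` (mean of `|E'_ij|`
#' over the upper triangle including the diagonal), and the signed pair
#' strengths `eps_prime = eps_core * E' / E_o` that scale the non-bonded
#' potential for each residue pair.
#'
#' @param raw_energies Symmetric 20x20 matrix of raw contact energies with
#'   one-letter amino-acid dimnames.
#' @param params A [potential_params()] object.
#' @return An object of class `contact_table` with elements `E` (rescaled
#'   matrix), `E_o`, and `eps_prime`.
#' @export
build_contact_table <- function(raw_energies, params = potential_params()) {
  validate_raw_energies(raw_energies)
  ET <- raw_energies[, "T"]
  E <- raw_energies - outer(ET, rep(1, 20)) - outer(rep(1, 20), ET) +
    raw_energies["T", "T"]
  dimnames(E) <- dimnames(raw_energies)
  E_o <- mean(abs(E[upper.tri(E, diag = TRUE)]))
  if (E_o <= 0) {
    abort("degenerate contact table: rescaled energies are identically zero",
          class = "epifold_degenerate_table")
  }
  structure(list(E = E, E_o = E_o, eps_prime = params$eps_core * E / E_o),
            class = "contact_table")
}

#' @rdname build_contact_table
#' @details `default_contact_table()` builds the table from the bundled
#'   contact-energy file.
#' @export
default_contact_table <- function(params = potential_params()) {
  path <- system.file("extdata", "contact_energies.txt", package = "epifold")
  build_contact_table(read_contact_energies(path), params)
}

# Split a 1-letter sequence string into a validated character vector.
seq_residues <- function(seq) {
  res <- if (length(seq) == 1 && nchar(seq) > 1)
    strsplit(seq, "")[[1]] else as.character(seq)
  bad <- setdiff(res, AA20)
  if (length(bad) > 0) {
    abort(paste0("unknown residue code(s): ", paste(unique(bad), collapse = ", ")),
          class = "epifold_invalid_input")
  }
  res
}

# Per-pair eps_prime matrix for a sequence (entries for |i-j| < 2 unused).
seq_pair_strengths <- function(seq, table) {
  res <- seq_residues(seq)
  table$eps_prime[res, res, drop = FALSE]
}

#' Total potential energy of a conformation
#'
#' Sums the harmonic bond term over consecutive monomers and the
#' sequence-scaled non-bonded potential over all pairs separated by at
#' least two positions along the chain.
#'
#' @param conf Numeric n x 3 coordinate matrix (Angstroms).
#' @param seq Amino-acid sequence (1-letter string or character vector) of
#'   length n.
#' @param table A [build_contact_table()] result.
#' @param params A [potential_params()] object.
#' @return Total energy in `k_B*T0`.
#' @export
total_energy <- function(conf, seq, table = default_contact_table(params),
                         params = potential_params()) {
  conf <- as_conformation(conf)
  res <- seq_residues(seq)
  if (nrow(conf) != length(res) || length(res) < 2) {
    abort("conformation and sequence lengths must match and be >= 2",
          class = "epifold_invalid_input")
  }
  EP <- seq_pair_strengths(res, table)
  cpp_total_energy(conf, EP, params$kappa, params$l, params$eps_core,
                   params$alpha)
}

as_conformation <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3 || any(!is.finite(x))) {
    abort("a conformation is a finite n x 3 coordinate matrix",
          class = "epifold_invalid_input")
  }
  storage.mode(x) <- "double"
  unname(x)
}
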