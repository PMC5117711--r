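AA1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
            M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
AA3TO1 <- setNames(names(AA1TO3), AA1TO3)

#' Write a replica ensemble as multi-model PDB
#'
#' Emits a CA-only multi-model PDB, one MODEL per structure, residues
#' named by the sequence, single chain A. When a reference fold is given,
#' the reference structure is written as MODEL 1 and all ensemble members
#' follow aligned to it, in order of decreasing alignment quality
#' (increasing trimmed-core RMS). Docked ligand positions, if supplied,
#' are appended to each model as a HETATM record in chain B.
#'
#' @param ens A [fold_ensemble()] result.
#' @param path Output file.
#' @param ref Optional [select_reference()] result.
#' @param poses Optional list of [dock()] poses, one per written model.
#' @param match_fraction Trimmed-core fraction used when aligning members
#'   to the reference for ordering.
#' @return `path`, invisibly. A YAML sidecar `<path>.yml` records the
#'   sequence, seeds and schedule.
#' @export
write_ensemble <- function(ens, path, ref = NULL, poses = NULL,
                           match_fraction = 2 / 3) {
  stopifnot(inherits(ens, "replica_ensemble"))
  res <- seq_residues(ens$sequence)
  models <- ens$members
  if (!is.null(ref)) {
    alns <- lapply(models, align_structures, target = ref$x_star,
                   match_fraction = match_fraction)
    ord <- order(vapply(alns, `[[`, numeric(1), "rms_matched"))
    models <- c(list(ref$x_star), lapply(alns[ord], `[[`, "aligned"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (mi in seq_along(models)) {
    X <- models[[mi]]
    writeLines(sprintf("MODEL     %4d", mi), con)
    for (i in seq_len(nrow(X))) {
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, AA1TO3[[res[i]]], i, X[i, 1], X[i, 2], X[i, 3]), con)
    }
    if (!is.null(poses) && mi <= length(poses) && !is.null(poses[[mi]])) {
      p <- poses[[mi]]$ligand_position
      writeLines(sprintf(
        "HETATM%5d  CA  LIG B%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        nrow(X) + 1L, 1L, p[1], p[2], p[3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  yaml::write_yaml(list(sequence = ens$sequence, seeds = ens$seeds,
                        schedule = unclass(ens$schedule)),
                   paste0(path, ".yml"))
  invisible(path)
}

#' Read a multi-model CA-trace PDB ensemble
#'
#' Parses MODEL/ATOM/ENDMDL records of a CA-only multi-model PDB (as
#' written by [write_ensemble()]). Malformed ATOM records or models with
#' inconsistent atom counts raise format errors naming the offending line.
#'
#' @param path PDB file path.
#' @return A `replica_ensemble` with `members` and `sequence`; ligand
#'   HETATM records are returned in the `ligands` element.
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path)
  members <- list()
  ligands <- list()
  cur <- NULL
  cur_seq <- character()
  seqs <- list()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    tag <- substr(line, 1, 6)
    if (tag == "MODEL ") {
      cur <- list()
      cur_seq <- character()
    } else if (tag == "ATOM  ") {
      if (is.null(cur)) {
        abort(sprintf("line %d: ATOM record outside MODEL block", ln),
              class = "epifold_format_error")
      }
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                           substr(line, 39, 46),
                                           substr(line, 47, 54))))
      res3 <- trimws(substr(line, 18, 20))
      if (anyNA(xyz) || !res3 %in% names(AA3TO1)) {
        abort(sprintf("line %d: malformed ATOM record", ln),
              class = "epifold_format_error")
      }
      cur[[length(cur) + 1]] <- xyz
      cur_seq <- c(cur_seq, AA3TO1[[res3]])
    } else if (tag == "HETATM") {
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                           substr(line, 39, 46),
                                           substr(line, 47, 54))))
      ligands[[length(members) + 1L]] <- xyz
    } else if (tag == "ENDMDL") {
      if (is.null(cur) || length(cur) == 0) {
        abort(sprintf("line %d: empty MODEL block", ln),
              class = "epifold_format_error")
      }
      members[[length(members) + 1]] <- do.call(rbind, cur)
      seqs[[length(seqs) + 1]] <- paste(cur_seq, collapse = "")
      cur <- NULL
    }
  }
  if (length(members) == 0) {
    abort("no MODEL blocks found", class = "epifold_format_error")
  }
  n_atoms <- vapply(members, nrow, integer(1))
  if (length(unique(n_atoms)) != 1 || length(unique(unlist(seqs))) != 1) {
    abort("models have inconsistent atom counts or sequences",
          class = "epifold_format_error")
  }
  structure(list(members = members, failed = logical(length(members)),
                 seeds = NULL, schedule = NULL, sequence = seqs[[1]],
                 ligands = ligands),
            class = "replica_ensemble")
}
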