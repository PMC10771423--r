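#' Protein model container
#'
#' A light S3 wrapper around a per-atom tibble plus bookkeeping: indices of the
#' backbone nodes used by the elastic-network moves (`ca_indices`) and the
#' optional catalytic anchor atom, named as (residue index, atom name). Units
#' are Angstrom for coordinates, elementary charges for partial charges and
#' kcal/mol for Lennard-Jones well depths; residue indices are 1-based as in
#' PDB files.
#'
#' @param atoms Tibble with columns `serial`, `name`, `element`, `res_index`,
#'   `res_name`, `x`, `y`, `z` and optionally `charge`, `lj_epsilon`,
#'   `lj_rmin`.
#' @param anchor Optional list/vector `(res_index, atom_name)` naming the
#'   catalytic anchor atom (for alditol oxidases, the side-chain terminal
#'   nitrogen NZ of the catalytic lysine).
#' @param ca_indices Integer row indices of `atoms` to use as elastic-network
#'   nodes; defaults to atoms named "CA", or every atom when none exist (as in
#'   pseudo-atom pocket models).
#' @return An object of class `protein_model`.
#' @export
protein_model <- function(atoms, anchor = NULL, ca_indices = NULL) {
  atoms <- as_tibble(atoms)
  required <- c("serial", "name", "element", "res_index", "res_name", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(atoms) == 0) abort("protein model must contain at least one atom")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  for (col in c("charge", "lj_epsilon", "lj_rmin")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  }
  if (any(!is.na(atoms$lj_epsilon) & atoms$lj_epsilon < 0)) {
    abort("lj_epsilon must be >= 0")
  }
  if (any(!is.na(atoms$lj_rmin) & atoms$lj_rmin <= 0)) {
    abort("lj_rmin must be > 0")
  }
  if (is.null(ca_indices)) {
    ca_indices <- which(atoms$name == "CA")
    if (length(ca_indices) == 0) ca_indices <- seq_len(nrow(atoms))
  }
  model <- structure(
    list(atoms = atoms, ca_indices = as.integer(ca_indices), anchor = NULL),
    class = "protein_model"
  )
  if (!is.null(anchor)) model <- set_anchor(model, anchor[[1]], anchor[[2]])
  model
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf(
    "<protein_model> %d atoms, %d residues, %d network nodes\n",
    nrow(x$atoms), length(unique(x$atoms$res_index)), length(x$ca_indices)
  ))
  if (!is.null(x$anchor)) {
    cat(sprintf("  anchor: residue %d atom %s\n", x$anchor$res_index, x$anchor$atom_name))
  }
  invisible(x)
}

#' Set the catalytic anchor atom of a protein model
#'
#' @param model A [protein_model()].
#' @param res_index Residue index of the anchor.
#' @param atom_name Atom name of the anchor (e.g. "NZ").
#' @return The model with the anchor recorded.
#' @export
set_anchor <- function(model, res_index, atom_name) {
  hit <- which(model$atoms$res_index == res_index & model$atoms$name == atom_name)
  if (length(hit) != 1) {
    abort(sprintf(
      "anchor (%s, %s) resolves to %d atoms; need exactly one",
      res_index, atom_name, length(hit)
    ))
  }
  model$anchor <- list(res_index = as.integer(res_index), atom_name = atom_name,
                       atom_index = hit)
  model
}

anchor_coords <- function(model) {
  if (is.null(model$anchor)) abort("protein model has no anchor atom set")
  unlist(model$atoms[model$anchor$atom_index, c("x", "y", "z")], use.names = FALSE)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a [protein_model()]. Waters are
#' skipped by default. When alternate locations are present, the
#' highest-occupancy altloc is kept (the first one in file order on ties).
#'
#' @param path Path to a PDB file.
#' @param keep_waters Keep water residues (HOH/WAT/H2O)? Default `FALSE`.
#' @return A [protein_model()] (unparameterized; see [assign_parameters()]).
#' @export
read_pdb <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) abort(paste0("PDB file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(
          substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
        ))))) {
      abort(sprintf("malformed ATOM/HETATM record at line %d of %s", i, path))
    }
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB file: ", conditionMessage(e)))
  )
  at <- pdb$atom
  if (!keep_waters) at <- at[!at$resid %in% c("HOH", "WAT", "H2O"), , drop = FALSE]
  if (nrow(at) == 0) abort("PDB file contains no (non-water) atoms")
  at$occ <- ifelse(is.na(at$o), 1, at$o)
  at$file_order <- seq_len(nrow(at))
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    idx[order(-at$occ[idx], at$file_order[idx])][1]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  element <- ifelse(is.na(at$elesy) | at$elesy == "",
                    toupper(substr(gsub("[^A-Za-z].*$", "", at$elety), 1, 1)),
                    toupper(trimws(at$elesy)))
  atoms <- tibble(
    serial = at$eleno,
    name = at$elety,
    element = element,
    res_index = at$resno,
    res_name = at$resid,
    x = at$x, y = at$y, z = at$z
  )
  protein_model(atoms)
}

#' Write a protein model to a PDB file
#'
#' @param model A [protein_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$res_index,
    resid = a$res_name,
    eleno = a$serial,
    elety = a$name,
    elesy = a$element
  )
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence` (uppercase, any trailing
#'   '*' stop characters stripped), in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) abort(paste0("failed to parse FASTA file: ", conditionMessage(e)))
  )
  if (length(set) == 0) abort("FASTA file contains no records")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(gsub("\\*", "", as.character(set)))
  tibble(id = ids, sequence = unname(seqs))
}
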