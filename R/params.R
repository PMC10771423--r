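# Embedded minimal nonbonded parameter table. This is deliberately a small,
# self-contained set: element-class Lennard-Jones parameters plus coarse
# formal/partial charges for the 20 amino acids (heavy atoms + amide H) and
# FAD as a rigid neutral cofactor. It is NOT a general force field; all
# planted-landscape properties in this package are defined relative to it.

SIDECHAIN_ATOMS <- list(
  ALA = c("CB"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

# homonuclear LJ minimum-energy distances (A) and well depths (kcal/mol)
element_lj <- function(element) {
  lj <- list(
    C = c(0.08, 3.8), N = c(0.16, 3.6), O = c(0.18, 3.4),
    S = c(0.30, 4.0), H = c(0.02, 2.0), P = c(0.25, 4.2)
  )
  out <- lj[[element]]
  if (is.null(out)) c(0.05, 3.5) else out
}

atom_charge_rule <- function(res_name, atom_name, element) {
  backbone <- c(N = -0.35, CA = 0.10, C = 0.55, O = -0.55, OXT = -0.55, H = 0.25)
  if (atom_name %in% names(backbone)) return(backbone[[atom_name]])
  special <- list(
    ASP = c(OD1 = -0.5, OD2 = -0.5, CG = 0.5),
    GLU = c(OE1 = -0.5, OE2 = -0.5, CD = 0.5),
    LYS = c(NZ = 0.6, CE = 0.2),
    ARG = c(NH1 = 0.4, NH2 = 0.4, NE = -0.3, CZ = 0.5),
    HIS = c(ND1 = -0.3, NE2 = -0.3, CE1 = 0.3),
    SER = c(OG = -0.4, CB = 0.2),
    THR = c(OG1 = -0.4, CB = 0.2),
    TYR = c(OH = -0.4, CZ = 0.2),
    ASN = c(OD1 = -0.5, ND2 = -0.4, CG = 0.55),
    GLN = c(OE1 = -0.5, NE2 = -0.4, CD = 0.55),
    CYS = c(SG = -0.2),
    TRP = c(NE1 = -0.3)
  )
  s <- special[[res_name]]
  if (!is.null(s) && atom_name %in% names(s)) return(s[[atom_name]])
  0
}

# standard PDB chemical-component atom names for FAD (heavy atoms)
FAD_ATOMS <- c(
  "PA", "O1A", "O2A", "O5B", "C5B", "C4B", "O4B", "C3B", "O3B", "C2B", "O2B",
  "C1B", "N9A", "C8A", "N7A", "C5A", "C6A", "N6A", "N1A", "C2A", "N3A", "C4A",
  "N1", "C2", "O2", "N3", "C4", "O4", "C4X", "N5", "C5X", "C6", "C7", "C7M",
  "C8", "C8M", "C9", "C9A", "N10", "C10", "C1'", "C2'", "O2'", "C3'", "O3'",
  "C4'", "O4'", "C5'", "O5'", "P", "O1P", "O2P", "O3P"
)

#' Default nonbonded parameter table
#'
#' One row per (residue name, atom name): partial charge (elementary charges),
#' Lennard-Jones well depth (kcal/mol) and minimum-energy distance (Angstrom).
#' Covers the heavy atoms (plus the amide H) of the 20 standard amino acids
#' and FAD treated as a rigid, neutral HETATM cofactor.
#'
#' @return A tibble with columns `res_name`, `atom_name`, `charge`,
#'   `lj_epsilon`, `lj_rmin`.
#' @export
default_paramset <- function() {
  rows <- list()
  for (res in names(SIDECHAIN_ATOMS)) {
    atoms <- c("N", "CA", "C", "O", "OXT", "H", SIDECHAIN_ATOMS[[res]])
    if (res == "PRO") atoms <- setdiff(atoms, "H")
    for (a in atoms) {
      el <- substr(gsub("[0-9]", "", a), 1, 1)
      lj <- element_lj(el)
      rows[[length(rows) + 1]] <- tibble(
        res_name = res, atom_name = a,
        charge = atom_charge_rule(res, a, el),
        lj_epsilon = lj[1], lj_rmin = lj[2]
      )
    }
  }
  for (a in FAD_ATOMS) {
    el <- substr(gsub("[0-9'X]", "", a), 1, 1)
    lj <- element_lj(el)
    rows[[length(rows) + 1]] <- tibble(
      res_name = "FAD", atom_name = a, charge = 0,
      lj_epsilon = lj[1], lj_rmin = lj[2]
    )
  }
  bind_rows(rows)
}

#' Assign nonbonded parameters to a protein model
#'
#' Looks up each atom by (residue name, atom name) in `paramset`. Atoms not
#' found get neutral defaults (charge 0, generic LJ) and a single warning
#' reporting the count; if more than half the atoms are unknown the paramset
#' is presumed wrong and an error is raised.
#'
#' @param model A [protein_model()].
#' @param paramset Parameter tibble as from [default_paramset()].
#' @return The model with `charge`, `lj_epsilon`, `lj_rmin` filled in.
#' @export
assign_parameters <- function(model, paramset = default_paramset()) {
  a <- model$atoms
  m <- left_join(
    a[, c("res_name", "name")],
    paramset,
    by = c("res_name" = "res_name", "name" = "atom_name")
  )
  unknown <- is.na(m$lj_epsilon)
  n_unknown <- sum(unknown)
  if (n_unknown > 0.5 * nrow(a)) {
    abort(sprintf(
      "%d of %d atoms not found in paramset; this looks like the wrong parameter table",
      n_unknown, nrow(a)
    ))
  }
  if (n_unknown > 0) {
    warn(sprintf(
      "%d of %d atoms not in paramset; neutral defaults applied (charge 0, generic LJ)",
      n_unknown, nrow(a)
    ))
    m$charge[unknown] <- 0
    m$lj_epsilon[unknown] <- 0.05
    m$lj_rmin[unknown] <- 3.5
  }
  model$atoms$charge <- m$charge
  model$atoms$lj_epsilon <- m$lj_epsilon
  model$atoms$lj_rmin <- m$lj_rmin
  model
}
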