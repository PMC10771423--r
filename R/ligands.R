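#' Construct a ligand template
#'
#' A rigid ligand conformer with explicit polar hydrogens, a bond list and
#' labeled terminal hydroxyl protons (the atoms to which the catalytic
#' distance is measured). Validates that the labeled protons are hydrogens
#' bonded to an oxygen and that the bond graph is connected.
#'
#' @param name Identifier.
#' @param atoms Atom tibble (columns as in [protein_model()] atoms; charges
#'   and LJ parameters must be present).
#' @param bonds Two-column matrix/data frame of atom indices (1-based).
#' @param terminal_protons Character vector of atom names of the terminal
#'   hydroxyl protons.
#' @return An object of class `ligand_template`.
#' @export
ligand_template <- function(name, atoms, bonds, terminal_protons) {
  atoms <- as_tibble(atoms)
  bonds <- as.matrix(bonds)
  if (length(terminal_protons) == 0) {
    abort("ligand template needs at least one labeled terminal hydroxyl proton")
  }
  idx <- match(terminal_protons, atoms$name)
  if (anyNA(idx)) {
    abort(paste0("terminal proton atom(s) not found: ",
                 paste(terminal_protons[is.na(idx)], collapse = ", ")))
  }
  for (i in idx) {
    if (atoms$element[i] != "H") abort("terminal protons must be hydrogen atoms")
    nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    if (!any(atoms$element[nb] == "O")) {
      abort(sprintf("terminal proton %s is not bonded to an oxygen", atoms$name[i]))
    }
  }
  # connectivity of the bond graph
  n <- nrow(atoms)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1) abort("ligand bond graph is not connected")
  ctr <- colMeans(atoms[, c("x", "y", "z")])
  structure(
    list(
      name = name, atoms = atoms, bonds = bonds,
      terminal_protons = atoms$name[idx], terminal_indices = idx,
      centroid = as.numeric(ctr)
    ),
    class = "ligand_template"
  )
}

#' @export
print.ligand_template <- function(x, ...) {
  cat(sprintf("<ligand_template> %s: %d atoms, %d bonds, terminal protons: %s\n",
              x$name, nrow(x$atoms), nrow(x$bonds),
              paste(x$terminal_protons, collapse = ", ")))
  invisible(x)
}

ligand_atom_params <- function(atoms, bonds) {
  # hydroxyl O: oxygen bonded to an H; carbonyl O: oxygen with no H neighbour.
  # Terminal (primary) hydroxyls are assigned a larger partial polarization
  # than internal (secondary) ones: the terminal O-H is the exposed
  # hydrogen-bond donor the catalytic geometry is measured to.
  n <- nrow(atoms)
  has_h <- logical(n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds[k, 1]; b <- bonds[k, 2]
    if (atoms$element[a] == "O" && atoms$element[b] == "H") has_h[a] <- TRUE
    if (atoms$element[b] == "O" && atoms$element[a] == "H") has_h[b] <- TRUE
  }
  neighbours <- function(i) c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
  # a hydroxyl is "terminal" when its carbon has at most one carbon neighbour
  terminal_o <- vapply(seq_len(n), function(i) {
    if (atoms$element[i] != "O" || !has_h[i]) return(FALSE)
    cs <- neighbours(i)
    cs <- cs[atoms$element[cs] == "C"]
    if (length(cs) == 0) return(TRUE)
    sum(atoms$element[neighbours(cs[1])] == "C") <= 1
  }, TRUE)
  charge <- numeric(n)
  eps <- numeric(n)
  rmin <- numeric(n)
  for (i in seq_len(n)) {
    el <- atoms$element[i]
    if (el == "O") {
      charge[i] <- if (!has_h[i]) -0.50 else if (terminal_o[i]) -0.60 else -0.45
      eps[i] <- 0.18; rmin[i] <- 3.3
    } else if (el == "C") {
      nb <- neighbours(i)
      carbonyl <- any(atoms$element[nb] == "O" & !has_h[nb])
      charge[i] <- if (carbonyl) 0.50 else 0.15
      eps[i] <- 0.08; rmin[i] <- 3.8
    } else if (el == "H") {
      nb <- neighbours(i)
      o_nb <- nb[atoms$element[nb] == "O"]
      polar <- length(o_nb) > 0
      charge[i] <- if (!polar) 0.05 else if (any(terminal_o[o_nb])) 0.40 else 0.28
      eps[i] <- if (polar) 0.15 else 0.02
      rmin[i] <- if (polar) 1.2 else 2.4
    } else {
      charge[i] <- 0; eps[i] <- 0.05; rmin[i] <- 3.5
    }
  }
  atoms$charge <- charge
  atoms$lj_epsilon <- eps
  atoms$lj_rmin <- rmin
  atoms
}

#' Load a built-in ligand template
#'
#' Built-in polyol templates are shipped as PDB files with a sidecar table of
#' terminal-hydroxyl-proton labels and bonds. Glycerol and xylitol are
#' end-symmetric and carry two labeled terminal O-H protons; open-chain
#' D-xylulose has a C2 ketone, is not end-symmetric, and only its C1 hydroxyl
#' proton is labeled as the reactive terminus.
#'
#' @param name One of "glycerol", "xylitol", "d-xylulose".
#' @return A [ligand_template()] with nonbonded parameters assigned.
#' @export
load_ligand_template <- function(name) {
  dir <- system.file("extdata", "ligands", package = "aldoscape")
  manifest <- read.delim(file.path(dir, "ligands.tsv"), stringsAsFactors = FALSE)
  row <- manifest[manifest$name == tolower(name), , drop = FALSE]
  if (nrow(row) != 1) {
    abort(sprintf("unknown ligand template '%s'; available: %s",
                  name, paste(manifest$name, collapse = ", ")))
  }
  model <- read_pdb(file.path(dir, row$file))
  atoms <- model$atoms
  bonds_tab <- read.delim(file.path(dir, sub("\\.pdb$", "_bonds.tsv", row$file)),
                          stringsAsFactors = FALSE)
  bonds <- cbind(match(bonds_tab$atom1, atoms$name), match(bonds_tab$atom2, atoms$name))
  atoms <- ligand_atom_params(atoms, bonds)
  terminal <- strsplit(row$terminal_protons, ",")[[1]]
  ligand_template(row$name, atoms, bonds, terminal)
}

#' Construct a rigid ligand pose
#'
#' A pose is the template plus a rigid-body frame: coordinates are realized
#' as `R(q) %*% (x - centroid) + centroid + translation`, so the identity
#' rotation with zero translation reproduces the template exactly.
#'
#' @param template A [ligand_template()].
#' @param translation Length-3 numeric, Angstrom.
#' @param rotation Unit quaternion (w, x, y, z).
#' @return An object of class `ligand_pose`.
#' @export
ligand_pose <- function(template, translation = c(0, 0, 0),
                        rotation = c(1, 0, 0, 0)) {
  stopifnot(inherits(template, "ligand_template"))
  nq <- sqrt(sum(rotation^2))
  if (abs(nq - 1) > 1e-9) abort("pose rotation must be a unit quaternion")
  structure(
    list(template = template, translation = as.numeric(translation),
         rotation = as.numeric(rotation)),
    class = "ligand_pose"
  )
}

#' Realize the coordinates of a ligand pose
#'
#' @param pose A [ligand_pose()].
#' @return Numeric matrix (atoms x 3), rows in template atom order (labels are
#'   therefore preserved under any pose transformation).
#' @export
pose_coords <- function(pose) {
  tpl <- pose$template
  X <- as.matrix(tpl$atoms[, c("x", "y", "z")])
  R <- quat_to_matrix(pose$rotation)
  ctr <- tpl$centroid
  sweep(sweep(X, 2, ctr) %*% t(R), 2, ctr + pose$translation, `+`)
}

pose_centroid <- function(pose) {
  pose$template$centroid + pose$translation
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose> %s at (%.2f, %.2f, %.2f)\n", x$template$name,
              pose_centroid(x)[1], pose_centroid(x)[2], pose_centroid(x)[3]))
  invisible(x)
}
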