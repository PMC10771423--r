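# Shared fixtures, built in code at test time.

# --- toy tripeptide PDB (Gly-Lys-Gly, 21 atoms incl. amide H, full Lys side
# chain; idealized-ish coordinates, adequate for parsing/parameter/rotamer
# tests) ---------------------------------------------------------------------
toy_pdb_lines <- function() {
  atoms <- list(
    #      name  res  resno x      y      z
    list("N",  "GLY", 1, 0.00, 1.40, 0.00),
    list("CA", "GLY", 1, 1.20, 0.60, 0.00),
    list("C",  "GLY", 1, 2.50, 1.30, 0.00),
    list("O",  "GLY", 1, 2.60, 2.50, 0.00),
    list("H",  "GLY", 1, -0.80, 1.90, 0.00),
    list("N",  "LYS", 2, 3.50, 0.60, 0.00),
    list("CA", "LYS", 2, 4.80, 1.10, 0.00),
    list("C",  "LYS", 2, 6.00, 0.20, 0.00),
    list("O",  "LYS", 2, 6.00, -1.00, 0.00),
    list("CB", "LYS", 2, 5.00, 2.00, 1.20),
    list("CG", "LYS", 2, 5.20, 3.45, 1.20),
    list("CD", "LYS", 2, 5.40, 4.15, 2.50),
    list("CE", "LYS", 2, 5.60, 5.60, 2.50),
    list("NZ", "LYS", 2, 5.80, 6.30, 3.70),
    list("H",  "LYS", 2, 3.45, -0.35, 0.00),
    list("N",  "GLY", 3, 7.10, 0.70, 0.00),
    list("CA", "GLY", 3, 8.40, 0.10, 0.00),
    list("C",  "GLY", 3, 9.60, 1.00, 0.00),
    list("O",  "GLY", 3, 9.70, 2.20, 0.00),
    list("OXT","GLY", 3, 10.50, 0.40, 0.00),
    list("H",  "GLY", 3, 7.00, 1.70, 0.00)
  )
  lines <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    el <- substr(a[[1]], 1, 1)
    nm <- if (nchar(a[[1]]) == 4) a[[1]] else sprintf(" %-3s", a[[1]])
    sprintf("ATOM  %5d %s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm, a[[2]], a[[3]], a[[4]], a[[5]], a[[6]], el)
  }, "")
  c(lines, "END")
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_lines(), path)
  path
}

# --- independent R-side reference for the nonbonded model --------------------
# (deliberately written from the model definition, not from the C++ code path)
reference_energy <- function(model, pose, cutoff = 10) {
  P <- model$atoms
  L <- pose$template$atoms
  X <- pose_coords(pose)
  lj <- 0; coul <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(nrow(L))) {
      r2 <- (P$x[i] - X[j, 1])^2 + (P$y[i] - X[j, 2])^2 + (P$z[i] - X[j, 3])^2
      if (r2 >= cutoff^2) next
      eps <- sqrt(P$lj_epsilon[i] * L$lj_epsilon[j])
      rmin <- (P$lj_rmin[i] + L$lj_rmin[j]) / 2
      ulj <- function(rr2) eps * ((rmin^2 / rr2)^6 - 2 * (rmin^2 / rr2)^3)
      uc <- function(rr2) 332.0636 / 4 * P$charge[i] * L$charge[j] / rr2
      lj <- lj + ulj(r2) - ulj(cutoff^2)
      coul <- coul + uc(r2) - uc(cutoff^2)
    }
  }
  list(lj = lj, coulomb = coul, total = lj + coul)
}

# --- small single-site pseudo-receptors, shared across test files ------------
# (built once per test run; generation is itself under test in
# test-synthetic.R, which uses its own instances)
fixture_env <- new.env()

cached_receptor <- function(key, maker) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- maker()
  fixture_env[[key]]
}

glycerol_template <- function() {
  cached_receptor("glycerol", function() load_ligand_template("glycerol"))
}

catalytic_receptor <- function() {
  cached_receptor("rec_cat", function() {
    make_pocket_receptor(pocket_spec(3.0, 8, seed = 101), glycerol_template())
  })
}

noncatalytic_receptor <- function() {
  cached_receptor("rec_noncat", function() {
    make_pocket_receptor(pocket_spec(6.0, 8, seed = 102), glycerol_template())
  })
}

# a rotation-insensitive "point probe" ligand: all interaction on the oxygen,
# the labeled proton rides 0.05 A away, so the energy is (to ~0.02 kcal/mol)
# a function of the probe position only; used for equilibrium checks
point_probe <- function() {
  atoms <- tibble::tibble(
    serial = 1:2, name = c("O1", "HO1"), element = c("O", "H"),
    res_index = 1L, res_name = "PRB",
    x = c(0, 0.05), y = 0, z = 0,
    charge = 0, lj_epsilon = c(0.18, 0), lj_rmin = c(3.3, 0.5)
  )
  ligand_template("probe", atoms, rbind(c(1L, 2L)), "HO1")
}

# frozen two-well toy: invisible anchor at the origin, two attractor atoms on
# the x axis; wells are kept shallow (~2 kT) so the chain mixes between them
two_well_toy <- function(eps1 = 25, eps2 = 10) {
  atoms <- tibble::tibble(
    serial = 1:3,
    name = c("NZ", "W1", "W2"),
    element = "X",
    res_index = 1:3,
    res_name = c("LYS", "PSD", "PSD"),
    x = c(0, 3.5, 12.5), y = 0, z = 0,
    charge = 0,
    lj_epsilon = c(0, eps1, eps2),
    lj_rmin = c(1, 3.4, 3.4)
  )
  protein_model(atoms, anchor = list(1L, "NZ"))
}

two_well_config <- function(n_steps = 5000, n_walkers = 20, seed = 7) {
  sampler_config(
    box_center = c(8, 0, 0), box_radius = 6.5, trans_max = 2.5, rot_max = 60,
    kT = 1.2, anm_every = 0, minimize = FALSE,
    n_steps = n_steps, n_walkers = n_walkers, seed = seed
  )
}

# exact Boltzmann quadrature over the two-well toy (translation grid; the
# energy is rotation-invariant by construction of the point probe)
two_well_quadrature <- function(toy, probe, t_step = 0.125, kT = 1.2) {
  sc <- grid_scan_oracle(toy, probe, box_center = c(8, 0, 0), box_radius = 6.5,
                         t_step = t_step, r_step = 360, return_table = TRUE)
  tab <- sc$table
  tab <- tab[abs(tab$qw - 1) < 1e-9, ]  # identity rotation only
  w <- exp(-tab$energy / kT)
  # probe position = box_center + translation (+ tiny centroid offset)
  d <- sqrt((8 + tab$tx)^2 + tab$ty^2 + tab$tz^2)
  list(d = d, w = w,
       p_well1 = sum(w[d < 8]) / sum(w),
       p_well2 = sum(w[d >= 8]) / sum(w))
}
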