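# Simplified nonbonded protein-ligand interaction model. The functional form
# (12-6 Lennard-Jones with Lorentz-Berthelot combining, Coulomb with
# distance-dependent dielectric eps(r) = 4r, 10 A cutoff with potential shift,
# no solvation) is a deliberate, documented minimal model: all landscape
# properties in this package are defined relative to it, and its energies are
# never compared numerically to energies from other force fields.

DEFAULT_CUTOFF <- 10

check_parameterized <- function(atoms, what = "protein") {
  if (anyNA(atoms$charge) || anyNA(atoms$lj_epsilon) || anyNA(atoms$lj_rmin)) {
    abort(sprintf("%s atoms are not parameterized; run assign_parameters()", what))
  }
}

protein_param_matrices <- function(model) {
  check_parameterized(model$atoms)
  list(
    x = as.matrix(model$atoms[, c("x", "y", "z")]),
    q = model$atoms$charge,
    eps = model$atoms$lj_epsilon,
    rmin = model$atoms$lj_rmin
  )
}

ligand_param_vectors <- function(template) {
  check_parameterized(template$atoms, "ligand")
  list(
    q = template$atoms$charge,
    eps = template$atoms$lj_epsilon,
    rmin = template$atoms$lj_rmin
  )
}

#' Protein-ligand interaction energy
#'
#' Pairwise sum over all protein-ligand atom pairs within the cutoff of a
#' shifted 12-6 Lennard-Jones term plus a Coulomb term with distance-dependent
#' dielectric; both terms vanish exactly at the cutoff. Deterministic.
#'
#' @param model A parameterized [protein_model()].
#' @param pose A [ligand_pose()].
#' @param cutoff Pair cutoff in Angstrom (default 10).
#' @return A one-row tibble with columns `lj`, `coulomb`, `total` (kcal/mol);
#'   `total` is exactly `lj + coulomb`.
#' @export
interaction_energy <- function(model, pose, cutoff = DEFAULT_CUTOFF) {
  p <- protein_param_matrices(model)
  l <- ligand_param_vectors(pose$template)
  e <- cpp_interaction_energy(p$x, p$q, p$eps, p$rmin, pose_coords(pose),
                              l$q, l$eps, l$rmin, cutoff)
  tibble(lj = e[["lj"]], coulomb = e[["coulomb"]], total = e[["total"]])
}

#' Rigid-body gradient of the interaction energy
#'
#' Gradient with respect to the six rigid-body degrees of freedom of the
#' ligand: translation (first three components) and an infinitesimal rotation
#' about the ligand centroid (last three), both in kcal/mol per Angstrom or
#' per radian.
#'
#' @inheritParams interaction_energy
#' @return Numeric length-6 vector.
#' @export
rigid_gradient <- function(model, pose, cutoff = DEFAULT_CUTOFF) {
  p <- protein_param_matrices(model)
  l <- ligand_param_vectors(pose$template)
  X <- pose_coords(pose)
  cpp_rigid_gradient(p$x, p$q, p$eps, p$rmin, X, l$q, l$eps, l$rmin, cutoff,
                     colMeans(X))
}

#' Brute-force rigid-body grid scan (docking oracle)
#'
#' Exhaustively enumerates ligand poses: centroid translations on a cubic
#' grid clipped to a sphere, crossed with a ZYZ Euler rotation grid. Returns
#' the global minimum-energy pose; because halving either step produces a
#' superset of poses, refining the grid can never raise the minimum. This is
#' the deterministic placement/verification oracle used to validate the
#' synthetic pocket generators and to bound sampler results.
#'
#' @param model A parameterized [protein_model()].
#' @param template A [ligand_template()].
#' @param box_center Length-3 centre of the translation sphere (Angstrom).
#' @param box_radius Sphere radius (Angstrom).
#' @param t_step Translation grid step (Angstrom).
#' @param r_step Rotation grid step (degrees).
#' @param cutoff Pair cutoff (Angstrom).
#' @param return_table Also return the full pose/energy table (only sensible
#'   for small grids).
#' @param ref_rotation Optional reference rotation matrix: when given together
#'   with `max_rot_angle < 180`, only grid rotations within that angle of the
#'   reference are scanned (local refinement mode).
#' @param max_rot_angle Rotation neighbourhood half-width, degrees.
#' @return A list with `best_pose` (a [ligand_pose()]), `best_energy`
#'   (kcal/mol), `n_poses`, and optionally `table` (a tibble with columns
#'   `tx`, `ty`, `tz`, `qw`, `qx`, `qy`, `qz`, `energy`; translations are the
#'   centroid offset from `box_center`).
#' @export
grid_scan_oracle <- function(model, template, box_center, box_radius,
                             t_step = 0.5, r_step = 60,
                             cutoff = DEFAULT_CUTOFF, return_table = FALSE,
                             ref_rotation = NULL, max_rot_angle = 180) {
  p <- protein_param_matrices(model)
  l <- ligand_param_vectors(template)
  res <- cpp_grid_scan(p$x, p$q, p$eps, p$rmin,
                       as.matrix(template$atoms[, c("x", "y", "z")]),
                       l$q, l$eps, l$rmin, as.numeric(box_center), box_radius,
                       t_step, r_step, cutoff, return_table,
                       ref_rotation, max_rot_angle)
  # reconstruct the pose: rotation about template centroid, centroid moved to
  # box_center + best_translation
  q <- quat_normalize(res$best_quaternion)
  translation <- as.numeric(box_center) + res$best_translation - template$centroid
  out <- list(
    best_pose = ligand_pose(template, translation = translation, rotation = q),
    best_energy = res$best_energy,
    n_poses = res$n_poses
  )
  if (return_table) out$table <- as_tibble(as.data.frame(res$table))
  out
}
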