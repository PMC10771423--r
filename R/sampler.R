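# Monte Carlo induced-fit sampling engine. Each step applies the five-phase
# scheme: random rigid-body ligand perturbation inside a spherical box ->
# (periodically) an elastic-network backbone move -> rotamer-grid side-chain
# relief near the ligand -> rigid-body ligand minimization -> Metropolis
# acceptance on the total energy, restoring the previous state on rejection.

#' Sampler configuration
#'
#' @param box_center Centre of the spherical sampling box (Angstrom). When
#'   `NULL`, taken from the receptor's pocket metadata if present.
#' @param box_radius Box radius, Angstrom; `NULL` (the default) resolves to
#'   the receptor's pocket metadata when present, else 6 (the radius used to
#'   confine the ligand perturbation around the active site; two-site pocket
#'   receptors record a radius wide enough to cover both planted minima).
#' @param trans_max Maximum random translation per step, Angstrom.
#' @param rot_max Maximum random rotation per step, degrees.
#' @param sidechain_radius Residues with any atom within this distance of the
#'   ligand enter the rotamer optimization phase, Angstrom.
#' @param kT Metropolis temperature, kcal/mol (default 1.2; an effective
#'   sampling temperature chosen for mixing, not a physical one).
#' @param anm_every Apply an elastic-network backbone move every this many
#'   steps (0 disables the phase).
#' @param anm_amplitude Node RMSD of each backbone move, Angstrom.
#' @param n_steps Monte Carlo steps per walker (default 200; the original
#'   HPC-scale protocol used 1000).
#' @param n_walkers Independent walkers; walker w uses seed `seed + w`
#'   (default 8; the original HPC-scale protocol used 70).
#' @param minimize Run the rigid-body minimization phase (disabling it, along
#'   with the protein phases, yields a plain Metropolis chain with a
#'   symmetric kernel, used for equilibrium checks).
#' @param seed Base random seed.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(box_center = NULL, box_radius = NULL, trans_max = 1.0,
                           rot_max = 20, sidechain_radius = 6, kT = 1.2,
                           anm_every = 4, anm_amplitude = 0.5,
                           n_steps = 200, n_walkers = 8, minimize = TRUE,
                           seed = 1) {
  if ((!is.null(box_radius) && box_radius <= 0) || trans_max < 0 ||
      rot_max < 0 || sidechain_radius <= 0) {
    abort("radii and step sizes must be positive")
  }
  if (n_steps < 1 || n_walkers < 1) abort("n_steps and n_walkers must be >= 1")
  if (kT < 0) abort("kT must be >= 0")
  structure(
    list(box_center = box_center, box_radius = box_radius,
         trans_max = trans_max, rot_max = rot_max,
         sidechain_radius = sidechain_radius, kT = kT,
         anm_every = as.integer(anm_every), anm_amplitude = anm_amplitude,
         n_steps = as.integer(n_steps), n_walkers = as.integer(n_walkers),
         minimize = isTRUE(minimize), seed = as.integer(seed)),
    class = "sampler_config"
  )
}

#' Random rigid-body perturbation of a ligand pose
#'
#' Applies a uniform random translation of magnitude at most `trans_max`
#' along a uniform random direction and a rotation about a uniform random
#' axis by an angle at most `rot_max`. Proposals whose ligand centroid leaves
#' the spherical box are rejected and resampled (up to 50 tries, after which
#' the identity proposal is returned); the kernel is symmetric.
#'
#' @param pose A [ligand_pose()].
#' @param config A [sampler_config()] (with `box_center` resolved).
#' @return The proposed [ligand_pose()].
#' @export
perturb_ligand <- function(pose, config) {
  centre <- config$box_center
  if (is.null(centre)) abort("config$box_center must be set")
  if (is.null(config$box_radius)) config$box_radius <- 6
  for (try in seq_len(50)) {
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    dt <- runif(1, 0, config$trans_max) * dir
    dq <- random_rotation_quat(config$rot_max * pi / 180)
    cand <- ligand_pose(pose$template,
                        translation = pose$translation + dt,
                        rotation = quat_normalize(quat_multiply(dq, pose$rotation)))
    if (sqrt(sum((pose_centroid(cand) - centre)^2)) <= config$box_radius) {
      return(cand)
    }
  }
  pose
}

#' Metropolis acceptance decision
#'
#' @param delta_e Energy change, kcal/mol.
#' @param kT Temperature, kcal/mol.
#' @return `TRUE` (accept) or `FALSE`; moves downhill in energy are always
#'   accepted, uphill moves with probability `exp(-delta_e/kT)`.
#' @export
metropolis_accept <- function(delta_e, kT) {
  if (delta_e <= 0) return(TRUE)
  if (kT <= 0) return(FALSE)
  runif(1) < exp(-delta_e / kT)
}

# side-chain atoms beyond CB (chi1 set) and beyond CG (chi2 set), by name
chi_movers <- function(res_atoms) {
  nm <- res_atoms$name
  beyond_cb <- nm[grepl("^[CNOS][GDEZH][0-9]?$", nm) | nm %in% c("OH", "NZ", "SD", "SG")]
  beyond_cg <- setdiff(beyond_cb, c("CG", "CG1", "CG2", "OG", "OG1", "SG"))
  list(chi1 = beyond_cb, chi2 = beyond_cg)
}

rotate_about_axis <- function(X, p1, p2, angle) {
  ax <- p2 - p1
  R <- quat_to_matrix(quat_from_axis_angle(ax, angle))
  sweep(sweep(X, 2, p2) %*% t(R), 2, p2, `+`)
}

#' Greedy rotamer-grid side-chain optimization
#'
#' For every residue with an atom within `sidechain_radius` of the ligand,
#' scans chi1 (and chi2 where defined) on a 30-degree grid, keeping the
#' conformation with the lowest energy of the side chain against the ligand
#' plus the rest of the protein. The current conformation is always a
#' candidate, so the energy never increases and a second call is a no-op.
#'
#' @param model A parameterized [protein_model()].
#' @param pose A [ligand_pose()].
#' @param config A [sampler_config()].
#' @return The optimized model, with attribute `self_energy` (the summed
#'   side-chain/protein terms of the optimized residues, kcal/mol).
#' @export
optimize_sidechains <- function(model, pose, config = sampler_config()) {
  lig <- pose_coords(pose)
  l <- ligand_param_vectors(pose$template)
  atoms <- model$atoms
  # residues close to the ligand
  d2min <- rep(Inf, nrow(atoms))
  for (k in seq_len(nrow(lig))) {
    d2 <- (atoms$x - lig[k, 1])^2 + (atoms$y - lig[k, 2])^2 + (atoms$z - lig[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  near_res <- unique(atoms$res_index[d2min <= config$sidechain_radius^2])
  self_total <- 0
  for (res in near_res) {
    ridx <- which(atoms$res_index == res)
    res_atoms <- atoms[ridx, ]
    movers <- chi_movers(res_atoms)
    if (length(movers$chi1) == 0) next
    ca <- which(res_atoms$name == "CA")
    cb <- which(res_atoms$name == "CB")
    if (length(ca) != 1 || length(cb) != 1) next
    others <- atoms[-ridx, ]
    ox <- as.matrix(others[, c("x", "y", "z")])
    score <- function(ratoms) {
      idx1 <- match(movers$chi1, ratoms$name)
      sc <- ratoms[idx1, ]
      sx <- as.matrix(sc[, c("x", "y", "z")])
      # side chain vs ligand
      e1 <- cpp_interaction_energy(sx, sc$charge, sc$lj_epsilon, sc$lj_rmin,
                                   lig, l$q, l$eps, l$rmin, DEFAULT_CUTOFF)[["total"]]
      # side chain vs rest of protein
      e2 <- cpp_interaction_energy(sx, sc$charge, sc$lj_epsilon, sc$lj_rmin,
                                   ox, others$charge, others$lj_epsilon,
                                   others$lj_rmin, DEFAULT_CUTOFF)[["total"]]
      e1 + e2
    }
    best <- res_atoms
    best_e <- score(res_atoms)
    p_ca <- unlist(res_atoms[ca, c("x", "y", "z")], use.names = FALSE)
    p_cb <- unlist(res_atoms[cb, c("x", "y", "z")], use.names = FALSE)
    chi2_ok <- length(movers$chi2) > 0 && "CG" %in% res_atoms$name
    for (a1 in seq(0, 330, by = 30)) {
      cand <- res_atoms
      i1 <- match(movers$chi1, cand$name)
      X1 <- rotate_about_axis(as.matrix(res_atoms[i1, c("x", "y", "z")]),
                              p_ca, p_cb, a1 * pi / 180)
      cand$x[i1] <- X1[, 1]; cand$y[i1] <- X1[, 2]; cand$z[i1] <- X1[, 3]
      angles2 <- if (chi2_ok) seq(0, 330, by = 30) else 0
      for (a2 in angles2) {
        cand2 <- cand
        if (chi2_ok && a2 > 0) {
          cg <- match("CG", cand$name)
          i2 <- match(movers$chi2, cand$name)
          p_cg <- c(cand$x[cg], cand$y[cg], cand$z[cg])
          X2 <- rotate_about_axis(as.matrix(cand[i2, c("x", "y", "z")]),
                                  p_cb, p_cg, a2 * pi / 180)
          cand2$x[i2] <- X2[, 1]; cand2$y[i2] <- X2[, 2]; cand2$z[i2] <- X2[, 3]
        }
        e <- score(cand2)
        if (e < best_e - 1e-9) {
          best_e <- e
          best <- cand2
        }
      }
    }
    atoms[ridx, ] <- best
    self_total <- self_total + best_e
  }
  model$atoms <- atoms
  attr(model, "self_energy") <- self_total
  model
}

#' Rigid-body minimization of the ligand pose
#'
#' Gradient descent with backtracking line search on the six rigid-body
#' degrees of freedom (at most `max_iter` iterations, stopping when the
#' gradient norm falls below `gtol` or when the energy stops improving
#' meaningfully). The energy is monotonically non-increasing; the protein is
#' not moved (backbone and side chains relax only through their own sampler
#' phases).
#'
#' @param model A parameterized [protein_model()].
#' @param pose A [ligand_pose()].
#' @param max_iter Iteration cap (default 200).
#' @param gtol Gradient-norm stopping threshold (default 1e-3).
#' @param cutoff Pair cutoff, Angstrom.
#' @return List with `pose` (minimized), `energy` (kcal/mol), `iterations`,
#'   `converged`.
#' @export
minimize_pose <- function(model, pose, max_iter = 200, gtol = 1e-3,
                          cutoff = DEFAULT_CUTOFF) {
  p <- protein_param_matrices(model)
  l <- ligand_param_vectors(pose$template)
  X <- pose_coords(pose)
  res <- cpp_minimize(p$x, p$q, p$eps, p$rmin, X, l$q, l$eps, l$rmin, cutoff,
                      max_iter, gtol)
  new_centroid <- colMeans(res$coords)
  new_q <- quat_normalize(quat_multiply(quat_from_matrix(res$rotation),
                                        pose$rotation))
  new_pose <- ligand_pose(pose$template,
                          translation = new_centroid - pose$template$centroid,
                          rotation = new_q)
  list(pose = new_pose, energy = res$energy, iterations = res$iterations,
       converged = res$converged)
}

resolve_box <- function(model, config) {
  info <- attr(model, "pocket_info")
  if (is.null(config$box_center)) {
    if (is.null(info)) {
      abort("config$box_center is NULL and the receptor carries no pocket metadata")
    }
    config$box_center <- as.numeric(info$box_center)
  }
  if (is.null(config$box_radius)) {
    config$box_radius <- (info$box_radius %||% 6)
  }
  config
}

#' Run the Monte Carlo induced-fit simulation
#'
#' Runs `n_walkers` independent trajectories (walker `w` seeded with
#' `seed + w`) of `n_steps` five-phase Monte Carlo steps each. Every step
#' emits one record with the post-decision state.
#'
#' @param model A parameterized [protein_model()] with an anchor atom.
#' @param template A [ligand_template()].
#' @param config A [sampler_config()].
#' @param start_pose Starting [ligand_pose()]; by default each walker starts
#'   at a uniform random point inside the box with a random orientation
#'   (spread starting poses explore multi-well landscapes). Must be inside
#'   the box when given.
#' @return A tibble (`trajectory`) with columns `walker`, `step`,
#'   `total_energy`, `interaction_energy`, `catalytic_distance`, `accepted`.
#' @export
run_simulation <- function(model, template, config = sampler_config(),
                           start_pose = NULL) {
  config <- resolve_box(model, config)
  check_parameterized(model$atoms)
  if (!is.null(start_pose)) {
    if (sqrt(sum((pose_centroid(start_pose) - config$box_center)^2)) >
        config$box_radius) {
      abort("start pose centroid is outside the sampling box")
    }
  }
  modes <- if (config$anm_every > 0) {
    build_modes(model)
  } else {
    NULL
  }
  l <- ligand_param_vectors(template)
  interaction_of <- function(p, pose) {
    cpp_interaction_energy(p$x, p$q, p$eps, p$rmin, pose_coords(pose),
                           l$q, l$eps, l$rmin, DEFAULT_CUTOFF)[["total"]]
  }
  minimize_raw <- function(p, pose) {
    res <- cpp_minimize(p$x, p$q, p$eps, p$rmin, pose_coords(pose),
                        l$q, l$eps, l$rmin, DEFAULT_CUTOFF, 200, 1e-3)
    pose <- ligand_pose(template,
                        translation = colMeans(res$coords) - template$centroid,
                        rotation = quat_normalize(quat_multiply(
                          quat_from_matrix(res$rotation), pose$rotation)))
    list(pose = pose, energy = res$energy)
  }
  # the side-chain phase can only act on residues with a CA-CB axis
  res_names <- split(model$atoms$name, model$atoms$res_index)
  has_rotatable <- any(vapply(res_names, function(nm) {
    all(c("CA", "CB") %in% nm)
  }, TRUE))
  anchor_idx <- model$anchor$atom_index
  h_idx <- template$terminal_indices
  out <- vector("list", config$n_walkers)
  for (w in seq_len(config$n_walkers)) {
    set.seed(config$seed + w)
    pose <- start_pose
    if (is.null(pose)) {
      # uniform random start in the box, locally relaxed (the initial-pose
      # analogue of docking): each walker settles into the basin of
      # attraction its random start falls in, so multi-well landscapes get
      # walkers in every basin; starts that cannot relax out of an atomic
      # core are resampled
      p0 <- protein_param_matrices(model)
      for (try in 1:20) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        r <- config$box_radius * runif(1)^(1 / 3)
        pose <- ligand_pose(template,
                            translation = config$box_center + r * u -
                              template$centroid,
                            rotation = random_rotation_quat(pi))
        if (config$minimize) {
          res <- minimize_raw(p0, pose)
          if (res$energy < 0 || (try == 20 && res$energy < 50)) {
            pose <- res$pose
            break
          }
        } else if (interaction_of(p0, pose) < 100) {
          break
        }
      }
    }
    mod <- model
    self_e <- 0
    if (has_rotatable) {
      mod <- optimize_sidechains(mod, pose, config)
      self_e <- attr(mod, "self_energy") %||% 0
    }
    p_cur <- protein_param_matrices(mod)
    e_inter <- interaction_of(p_cur, pose)
    e_total <- e_inter + self_e
    n <- config$n_steps
    rec_total <- numeric(n)
    rec_inter <- numeric(n)
    rec_dist <- numeric(n)
    rec_acc <- logical(n)
    for (s in seq_len(n)) {
      pose_p <- perturb_ligand(pose, config)
      mod_p <- mod
      p_prop <- p_cur
      self_p <- self_e
      protein_moved <- FALSE
      if (!is.null(modes) && s %% config$anm_every == 0) {
        # harmonic fluctuation about the reference structure: each backbone
        # proposal is a fresh mode displacement of the *input* model, so the
        # protein ensemble stays within `anm_amplitude` of the native fold
        # instead of random-walking away from it
        mod_p <- displace_backbone(model, modes, config$anm_amplitude)
        protein_moved <- TRUE
      }
      if (has_rotatable) {
        mod_p <- optimize_sidechains(mod_p, pose_p, config)
        self_p <- attr(mod_p, "self_energy") %||% 0
        protein_moved <- TRUE
      }
      if (protein_moved) p_prop <- protein_param_matrices(mod_p)
      if (config$minimize) {
        minres <- minimize_raw(p_prop, pose_p)
        pose_p <- minres$pose
        e_inter_p <- minres$energy
      } else {
        e_inter_p <- interaction_of(p_prop, pose_p)
      }
      e_total_p <- e_inter_p + self_p
      if (metropolis_accept(e_total_p - e_total, config$kT)) {
        pose <- pose_p
        mod <- mod_p
        p_cur <- p_prop
        e_total <- e_total_p
        e_inter <- e_inter_p
        self_e <- self_p
        rec_acc[s] <- TRUE
      }
      rec_total[s] <- e_total
      rec_inter[s] <- e_inter
      a <- p_cur$x[anchor_idx, ]
      H <- pose_coords(pose)[h_idx, , drop = FALSE]
      rec_dist[s] <- min(sqrt(rowSums(sweep(H, 2, a)^2)))
    }
    out[[w]] <- tibble(walker = w, step = seq_len(n), total_energy = rec_total,
                       interaction_energy = rec_inter,
                       catalytic_distance = rec_dist, accepted = rec_acc)
  }
  traj <- bind_rows(out)
  class(traj) <- c("trajectory", class(traj))
  traj
}

#' Write / read a trajectory report as TSV
#'
#' @param trajectory A trajectory tibble from [run_simulation()].
#' @param path File path.
#' @return `path` (write) or the trajectory tibble (read).
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  need <- c("walker", "step", "total_energy", "interaction_energy",
            "catalytic_distance", "accepted")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(need %in% names(tab))) {
    abort(paste0("trajectory report is missing columns: ",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  traj <- as_tibble(tab)
  class(traj) <- c("trajectory", class(traj))
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
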