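# Seeded generators for every input the pipeline needs: pocket receptors with
# planted interaction-energy landscapes, mutant variants, Michaelis-Menten
# datasets, melt curves and isotope-effect datasets. Every generator is a pure
# function of its spec (including the seed).

#' Specification of a synthetic pocket receptor
#'
#' Describes a pseudo-protein pocket whose protein-ligand interaction-energy
#' landscape has a planted global minimum at catalytic distance `d_star`
#' (distance from the anchor NZ atom to the nearest terminal hydroxyl proton
#' of the docked ligand) with depth `well_depth`, and optionally a second
#' ("decoy") minimum at distance `d2` with depth `depth2`.
#'
#' @param d_star Planted catalytic distance, Angstrom (> 0).
#' @param well_depth Depth of the planted minimum, kcal/mol (> 0).
#' @param decoy Optional `list(d2 = , depth2 = )` for a second minimum.
#' @param n_shell_atoms Number of passive scaffold atoms on the outer shell
#'   (elastic-network nodes; they sit beyond the interaction cutoff).
#' @param anchor_position Position of the anchor NZ atom.
#' @param seed Integer seed.
#' @return An object of class `pocket_spec`.
#' @export
pocket_spec <- function(d_star, well_depth = 8, decoy = NULL,
                        n_shell_atoms = 36, anchor_position = c(0, 0, 0),
                        seed = 1) {
  if (d_star <= 0) abort("d_star must be > 0")
  if (well_depth <= 0) abort("well_depth must be > 0")
  if (!is.null(decoy)) {
    if (is.null(decoy$d2) || is.null(decoy$depth2)) {
      abort("decoy must be list(d2 = , depth2 = )")
    }
    if (abs(decoy$d2 - d_star) < 1e-9) abort("decoy d2 must differ from d_star")
  }
  structure(
    list(d_star = d_star, well_depth = well_depth, decoy = decoy,
         n_shell_atoms = as.integer(n_shell_atoms),
         anchor_position = as.numeric(anchor_position),
         seed = as.integer(seed)),
    class = "pocket_spec"
  )
}

# rotation matrix taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # pick any perpendicular axis for the half-turn
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * a) * a
    ax <- ax / sqrt(sum(ax^2))
    return(quat_to_matrix(quat_from_axis_angle(ax, pi)))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}

# the "docked" target pose: rotate/translate the template so its first labeled
# terminal proton sits at distance d from the anchor along direction u, with
# the rest of the molecule pointing away from the anchor
target_pose <- function(template, anchor, d, u) {
  u <- u / sqrt(sum(u^2))
  h <- unlist(template$atoms[template$terminal_indices[1], c("x", "y", "z")],
              use.names = FALSE)
  m <- template$centroid
  w <- h - m
  lw <- sqrt(sum(w^2))
  R <- rotation_between(w / lw, -u)
  h_target <- anchor + d * u
  m_target <- h_target + lw * u
  ligand_pose(template, translation = m_target - m, rotation = quat_from_matrix(R))
}

# evenly spread unit vectors (Fibonacci sphere)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

pseudo_atom_row <- function(serial, name, res_index, pos, charge, eps, rmin,
                            res_name = "PSD") {
  tibble(serial = serial, name = name, element = "X", res_index = res_index,
         res_name = res_name, x = pos[1], y = pos[2], z = pos[3],
         charge = charge, lj_epsilon = eps, lj_rmin = rmin)
}

CRADLE_RMIN <- 3.4   # pseudo-atom homonuclear LJ rmin for cradle attractors
CRADLE_EPS0 <- 1.0   # unit well depth before depth calibration
PIN_RMIN <- 3.0      # proton-pin atom LJ rmin (contact with polar H ~2.1 A)
PIN_EPS <- 0.5
# the pin is negatively charged: it attracts the (partially positive)
# hydroxyl proton and repels the hydroxyl oxygens, so the site energy is
# genuinely selective for the planted proton-to-anchor geometry - a neutral
# LJ pin cannot discriminate a proton from the larger, more polarizable
# heavy atoms (this mirrors how the catalytic base reads out the O-H dipole)
PIN_CHARGE <- -0.9

# equilibrium distance of the pin / terminal-proton pair (LJ + Coulomb with
# the distance-dependent dielectric): the pin is placed this far behind the
# planted proton position so the proton settles at exactly d_star
pin_equilibrium_distance <- function(h_eps, h_rmin, h_charge) {
  eps <- sqrt(PIN_EPS * h_eps)
  rmin <- (PIN_RMIN + h_rmin) / 2
  kqq <- 332.0636 / 4 * PIN_CHARGE * h_charge
  f <- function(r) eps * ((rmin / r)^12 - 2 * (rmin / r)^6) + kqq / r^2
  stats::optimize(f, c(0.6 * rmin, 2 * rmin))$minimum
}
WALL_RMIN <- 4.6     # excluded-volume wall atoms: wide core, negligible well
WALL_EPS <- 0.005

# place attractor pseudo-atoms around a docked pose: for each heavy "partner"
# atom an attractor at the exact combined LJ minimum distance, in a direction
# perpendicular to the pocket axis chosen from a fan so that the attractor
# does not clash with any ligand atom of any docked pose. Attractors may sit
# close to one another (no protein self-energy is computed; overlapping
# attractors simply act as one stronger site).
place_cradle <- function(pose, u, avoid_coords, avoid_rmin, lig_rmin) {
  X <- pose_coords(pose)
  atoms <- pose$template$atoms
  heavy <- which(atoms$element %in% c("C", "O"))
  u <- u / sqrt(sum(u^2))
  p1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- p1 - sum(p1 * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  min_sep <- 0.97 * (CRADLE_RMIN + avoid_rmin) / 2
  out <- list()
  for (jj in seq_along(heavy)) {
    j <- heavy[jj]
    contact <- (CRADLE_RMIN + lig_rmin[j]) / 2
    angles <- (0:11) * pi / 6 + jj * 0.7
    kept <- numeric(0)
    for (a in angles) {
      cand <- X[j, ] + contact * (cos(a) * e1 + sin(a) * e2)
      dists <- sqrt(rowSums(sweep(avoid_coords, 2, cand)^2))
      # the partner pair sits exactly at its LJ minimum; everything else must
      # be at least (almost) at LJ contact so no pair is repulsive
      if (all(dists >= pmin(min_sep, contact - 1e-6))) {
        # two attractors per partner atom, at well-separated angles, grip the
        # pose snugly enough to discriminate slid/flipped alternatives
        if (length(kept) == 0 || min(abs(a - kept)) > pi / 2) {
          out[[length(out) + 1]] <- cand
          kept <- c(kept, a)
          if (length(kept) == 2) break
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Generate a pocket receptor with a planted energy landscape
#'
#' Builds a pseudo-protein: an anchor atom named "NZ" on a pseudo-lysine
#' residue, a "cradle" of attractive pseudo-atoms placed at exact
#' Lennard-Jones contact around the docked target pose of the ligand (so the
#' docked pose is simultaneously the minimum of every cradle pair term and
#' hence the global minimum of the landscape), an optional second cradle for
#' a decoy minimum, and an outer shell of passive scaffold atoms used only as
#' elastic-network nodes. Cradle well depths are calibrated by exact linear
#' scaling of the pair well depths, then the construction is verified with the
#' brute-force grid-scan oracle (a fine local scan around the planted site
#' plus a coarse global scan of the whole sampling box).
#'
#' @param spec A [pocket_spec()].
#' @param template Ligand the landscape is planted for (default glycerol).
#' @param verify Run the grid-scan oracle check (default `TRUE`).
#' @return A parameterized, anchored [protein_model()] with attribute
#'   `pocket_info` (spec, docked pose(s), cradle atom indices, box centre).
#' @export
make_pocket_receptor <- function(spec, template = load_ligand_template("glycerol"),
                                 verify = TRUE) {
  stopifnot(inherits(spec, "pocket_spec"))
  set.seed(spec$seed)
  anchor <- spec$anchor_position
  u1 <- c(1, 0, 0)
  pose1 <- target_pose(template, anchor, spec$d_star, u1)
  lig_rmin <- template$atoms$lj_rmin
  avoid1 <- pose_coords(pose1)
  has_decoy <- !is.null(spec$decoy)
  if (has_decoy) {
    # decoy direction well separated from the primary site so the two
    # attractor clusters cannot be bridged by a single ligand pose
    th <- 2 * pi / 3
    u2 <- c(cos(th), sin(th), 0)
    pose2 <- target_pose(template, anchor, spec$decoy$d2, u2)
    avoid <- rbind(avoid1, pose_coords(pose2))
    avoid_rmin <- c(lig_rmin, lig_rmin)
  } else {
    avoid <- avoid1
    avoid_rmin <- lig_rmin
  }
  cr1 <- place_cradle(pose1, u1, avoid, avoid_rmin, lig_rmin)
  cr2 <- if (has_decoy) place_cradle(pose2, u2, avoid, avoid_rmin, lig_rmin) else NULL
  # backing walls: one wide-core atom directly behind every cradle attractor
  # (away from its ligand partner), so the attractors can only be engaged
  # from the pocket side - alternative poses hugging the outside of the
  # attractor cluster would otherwise compete with the planted minimum
  make_backings <- function(cr) {
    if (is.null(cr) || nrow(cr) == 0) return(NULL)
    out <- list()
    for (i in seq_len(nrow(cr))) {
      d <- sqrt(rowSums(sweep(avoid, 2, cr[i, ])^2))
      nearest <- which.min(d)
      dir <- (cr[i, ] - avoid[nearest, ]) / d[nearest]
      cand <- cr[i, ] + 3.2 * dir
      dd <- sqrt(rowSums(sweep(avoid, 2, cand)^2))
      if (all(dd >= 0.95 * (WALL_RMIN + avoid_rmin) / 2)) {
        out[[length(out) + 1]] <- cand
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  backings <- rbind(make_backings(cr1), make_backings(cr2))
  # proton pin: a charged attractor at pair equilibrium distance "behind" the
  # terminal proton on the anchor axis, so the proton (and hence the
  # catalytic distance) is held at the planted value
  h_row <- template$atoms[template$terminal_indices[1], ]
  pin_contact <- pin_equilibrium_distance(h_row$lj_epsilon, h_row$lj_rmin,
                                          h_row$charge)
  hpos1 <- anchor + spec$d_star * u1
  pin1 <- hpos1 - pin_contact * u1
  pin2 <- if (has_decoy) anchor + (spec$decoy$d2 - pin_contact) * u2 else NULL
  # pin guards: a wide-core wall atom on the anchor side of each pin blocks
  # poses that swing the proton around the (isotropic) pin towards the
  # anchor, which would break the planted distance geometry
  guard1 <- pin1 - 2.6 * u1
  guard2 <- if (has_decoy) pin2 - 2.6 * u2 else NULL
  # excluded-volume wall: weak wide-core atoms on a sphere around each site
  # remove alternative binding poses on the outside of the attractor cluster
  sites <- list(list(pose = pose1, cr = cr1))
  if (has_decoy) sites <- c(sites, list(list(pose = pose2, cr = cr2)))
  centers <- lapply(sites, function(s) pose_centroid(s$pose))
  radii <- vapply(seq_along(sites), function(k) {
    pts <- rbind(pose_coords(sites[[k]]$pose), sites[[k]]$cr)
    max(sqrt(rowSums(sweep(pts, 2, centers[[k]])^2))) + 4.0
  }, 0)
  n_wall_per_site <- max(24L, spec$n_shell_atoms %/% length(sites))
  walls <- list()
  for (k in seq_along(sites)) {
    pts <- fibonacci_sphere(n_wall_per_site * 2)
    pts <- sweep(pts * (radii[k] + matrix(runif(length(pts), -0.3, 0.3), nrow(pts))),
                 2, centers[[k]], `+`)
    ok <- rep(TRUE, nrow(pts))
    for (i in seq_len(nrow(pts))) {
      d_avoid <- sqrt(rowSums(sweep(avoid, 2, pts[i, ])^2))
      if (any(d_avoid < 0.97 * (WALL_RMIN + avoid_rmin) / 2)) ok[i] <- FALSE
      # keep the cavity of the other site open (connects the two wells)
      for (k2 in seq_along(sites)) {
        if (k2 != k && sqrt(sum((pts[i, ] - centers[[k2]])^2)) < radii[k2] - 0.5) {
          ok[i] <- FALSE
        }
      }
    }
    pts <- pts[ok, , drop = FALSE]
    walls[[k]] <- pts[seq_len(min(nrow(pts), n_wall_per_site)), , drop = FALSE]
  }
  walls <- do.call(rbind, walls)
  rows <- list(pseudo_atom_row(1L, "NZ", 1L, anchor, 0, 0.1, 3.2, res_name = "LYS"))
  serial <- 1L
  add_atoms <- function(coords, eps, rmin, prefix, charge = 0) {
    lapply(seq_len(nrow(coords)), function(i) {
      serial <<- serial + 1L
      pseudo_atom_row(serial, paste0(prefix, i), serial, coords[i, ], charge,
                      eps, rmin)
    })
  }
  rows <- c(rows, add_atoms(cr1, CRADLE_EPS0, CRADLE_RMIN, "PC"))
  idx_cr1 <- seq(2L, serial)
  rows <- c(rows, add_atoms(matrix(pin1, 1), PIN_EPS, PIN_RMIN, "PN",
                            charge = PIN_CHARGE))
  idx_pin1 <- serial
  if (has_decoy) {
    first <- serial + 1L
    rows <- c(rows, add_atoms(cr2, CRADLE_EPS0, CRADLE_RMIN, "PD"))
    idx_cr2 <- seq(first, serial)
    rows <- c(rows, add_atoms(matrix(pin2, 1), PIN_EPS, PIN_RMIN, "PM",
                              charge = PIN_CHARGE))
    idx_pin2 <- serial
  } else {
    idx_cr2 <- integer(0)
    idx_pin2 <- integer(0)
  }
  if (!is.null(backings)) {
    rows <- c(rows, add_atoms(backings, WALL_EPS, WALL_RMIN, "PB"))
  }
  guards <- rbind(guard1, guard2)
  keep_guard <- vapply(seq_len(nrow(guards)), function(i) {
    all(sqrt(rowSums(sweep(avoid, 2, guards[i, ])^2)) >=
          0.95 * (WALL_RMIN + avoid_rmin) / 2)
  }, TRUE)
  if (any(keep_guard)) {
    rows <- c(rows, add_atoms(guards[keep_guard, , drop = FALSE],
                              WALL_EPS, WALL_RMIN, "PG"))
  }
  rows <- c(rows, add_atoms(walls, WALL_EPS, WALL_RMIN, "PW"))
  atoms <- bind_rows(rows)
  model <- protein_model(atoms, anchor = list(1L, "NZ"))
  # depth calibration: pair LJ terms scale linearly with the pair well depth,
  # i.e. with sqrt(eps_atom); solve for the cradle scale(s) exactly
  model <- calibrate_depths(model, template, pose1,
                            if (has_decoy) pose2 else NULL,
                            idx_cr1, idx_cr2, spec)
  min_poses <- attr(model, "min_poses")
  attr(model, "min_poses") <- NULL
  if (has_decoy) {
    box_center <- (pose_centroid(pose1) + pose_centroid(pose2)) / 2
    box_radius <- max(6, sqrt(sum((pose_centroid(pose1) -
                                     pose_centroid(pose2))^2)) / 2 + 1.5)
  } else {
    box_center <- pose_centroid(pose1)
    box_radius <- 6
  }
  info <- list(spec = spec, ligand = template$name, docked_pose = pose1,
               decoy_pose = if (has_decoy) pose2 else NULL,
               min_pose = min_poses$primary, decoy_min_pose = min_poses$decoy,
               cradle_indices = idx_cr1, decoy_indices = idx_cr2,
               pin_index = idx_pin1, decoy_pin_index = idx_pin2,
               box_center = box_center, box_radius = box_radius)
  attr(model, "pocket_info") <- info
  if (verify) verify_pocket(model, template)
  model
}

energy_subset <- function(model, pose, idx, cutoff = DEFAULT_CUTOFF) {
  sub <- model
  sub$atoms <- model$atoms[idx, , drop = FALSE]
  interaction_energy(sub, pose, cutoff)$total
}

calibrate_at_poses <- function(model, pose1, pose2, idx1, idx2, spec) {
  n <- nrow(model$atoms)
  fixed <- setdiff(seq_len(n), c(idx1, idx2))
  f1 <- energy_subset(model, pose1, fixed)
  a11 <- energy_subset(model, pose1, idx1)
  if (length(idx2) > 0) {
    a12 <- energy_subset(model, pose1, idx2)
    f2 <- energy_subset(model, pose2, fixed)
    a21 <- energy_subset(model, pose2, idx1)
    a22 <- energy_subset(model, pose2, idx2)
    A <- matrix(c(a11, a12, a21, a22), 2, byrow = TRUE)
    s <- solve(A, c(-spec$well_depth - f1, -spec$decoy$depth2 - f2))
    if (any(s <= 0)) abort("pocket depth calibration failed (non-positive scale)")
    model$atoms$lj_epsilon[idx1] <- model$atoms$lj_epsilon[idx1] * s[1]^2
    model$atoms$lj_epsilon[idx2] <- model$atoms$lj_epsilon[idx2] * s[2]^2
  } else {
    s <- (-spec$well_depth - f1) / a11
    if (s <= 0) abort("pocket depth calibration failed (non-positive scale)")
    model$atoms$lj_epsilon[idx1] <- model$atoms$lj_epsilon[idx1] * s^2
  }
  model
}

# local refinement scan: fine grid around a known pose, rotations restricted
# to a neighbourhood of that pose's orientation
local_argmin <- function(model, template, around_pose, radius = 1.5,
                         r_step = 30, max_rot_angle = 80) {
  grid_scan_oracle(model, template, box_center = pose_centroid(around_pose),
                   box_radius = radius, t_step = 0.25, r_step = r_step,
                   ref_rotation = quat_to_matrix(around_pose$rotation),
                   max_rot_angle = max_rot_angle)
}

# iterative depth calibration: pair terms scale linearly with the pair well
# depth at a fixed pose, but the landscape argmin shifts slightly as the
# cradle is rescaled, so solve-at-argmin is iterated to a fixed point on the
# fine local grid
calibrate_depths <- function(model, template, pose1, pose2, idx1, idx2, spec) {
  model <- calibrate_at_poses(model, pose1, pose2, idx1, idx2, spec)
  m1 <- pose1
  m2 <- pose2
  for (it in 1:4) {
    sc1 <- local_argmin(model, template, pose1)
    m1 <- sc1$best_pose
    err <- abs(sc1$best_energy + spec$well_depth)
    if (!is.null(pose2)) {
      sc2 <- local_argmin(model, template, pose2)
      m2 <- sc2$best_pose
      err <- max(err, abs(sc2$best_energy + spec$decoy$depth2))
    }
    if (err < 0.1) break
    model <- calibrate_at_poses(model, m1, m2, idx1, idx2, spec)
  }
  attr(model, "min_poses") <- list(primary = m1, decoy = m2)
  model
}

#' Catalytic distance of a pose (internal shortcut used by generators)
#' @noRd
pose_catalytic_distance <- function(model, pose) {
  a <- anchor_coords(model)
  H <- pose_coords(pose)[pose$template$terminal_indices, , drop = FALSE]
  min(sqrt(rowSums(sweep(H, 2, a)^2)))
}

verify_pocket <- function(model, template, d_tol = 0.3, e_tol = 0.5) {
  info <- attr(model, "pocket_info")
  spec <- info$spec
  check_site <- function(pose, d_planted, depth_planted, what) {
    loc <- local_argmin(model, template, pose, radius = 2, max_rot_angle = 100)
    d <- pose_catalytic_distance(model, loc$best_pose)
    if (abs(d - d_planted) > d_tol ||
        abs(loc$best_energy + depth_planted) > e_tol) {
      abort(sprintf(
        paste0("pocket verification failed at the %s site: oracle minimum at ",
               "%.2f A / %.2f kcal/mol, planted %.2f A / %.2f kcal/mol ",
               "(generator/forcefield inconsistency)"),
        what, d, loc$best_energy, d_planted, -depth_planted
      ))
    }
    loc$best_energy
  }
  e1 <- check_site(info$docked_pose, spec$d_star, spec$well_depth, "primary")
  e2 <- if (!is.null(spec$decoy)) {
    check_site(info$decoy_pose, spec$decoy$d2, spec$decoy$depth2, "decoy")
  } else {
    Inf
  }
  # stray-minimum checks: a coarse exhaustive scan of the whole sampling box
  # plus a multi-start continuous minimization (which reaches pose families
  # between grid points)
  glob <- grid_scan_oracle(model, template, box_center = info$box_center,
                           box_radius = info$box_radius %||% 6,
                           t_step = 0.75, r_step = 60)
  if (glob$best_energy < min(e1, e2) - e_tol) {
    abort(sprintf(
      paste0("pocket verification failed: stray minimum of %.2f kcal/mol at ",
             "%.2f A (generator/forcefield inconsistency)"),
      glob$best_energy, pose_catalytic_distance(model, glob$best_pose)
    ))
  }
  # the continuous bottom of a planted well is naturally somewhat deeper
  # than its grid-calibrated value; only deep minima at off-site catalytic
  # distances count as strays
  cb <- continuous_best(model, template, info, n_starts = 40,
                        seed = spec$seed + 4242L)
  d_cb <- pose_catalytic_distance(model, cb$pose)
  on_site <- abs(d_cb - spec$d_star) <= 0.5 ||
    (!is.null(spec$decoy) && abs(d_cb - spec$decoy$d2) <= 0.5)
  if (!on_site && cb$energy < min(e1, e2) - 0.25) {
    abort(sprintf(
      paste0("pocket verification failed: continuous stray minimum of %.2f ",
             "kcal/mol at %.2f A (generator/forcefield inconsistency)"),
      cb$energy, d_cb
    ))
  }
  invisible(model)
}

# multi-start rigid-body minimization: the continuous analogue of the grid
# oracle, used to locate the reachable global minimum of a pocket landscape
continuous_best <- function(model, template, info, n_starts = 24, seed = 1) {
  set.seed(seed)
  best <- minimize_pose(model, info$min_pose)
  starts <- list(info$min_pose)
  for (k in seq_len(n_starts)) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    r <- 0.9 * (info$box_radius %||% 6) * runif(1)^(1 / 3)
    pose <- ligand_pose(template,
                        translation = info$box_center + r * u - template$centroid,
                        rotation = random_rotation_quat(pi))
    res <- minimize_pose(model, pose)
    if (res$energy < best$energy) best <- res
  }
  best
}

#' Derive a mutant variant of a pocket receptor
#'
#' Emulates an activity-enhancing tunnel-mouth mutation: the well depths of
#' every attractive site atom (cradle, proton pin and anchor) are rescaled
#' uniformly so the landscape minimum deepens by `delta_e` while its
#' position (and hence the catalytic distance) is unchanged. Because the
#' site energy is a pure attractive sum with this construction, uniform
#' scaling deepens every binding pose in proportion to its own energy, so
#' the measured deepening is robust to exactly which pose a sampler or
#' oracle identifies as the minimum. The calibration reference is the
#' continuous (multi-start minimized) global minimum; the result is checked
#' against the same multi-start search on the mutant.
#'
#' @param receptor A receptor from [make_pocket_receptor()].
#' @param delta_e Change in minimum interaction energy, kcal/mol (negative
#'   deepens; magnitude must not exceed the planted well depth).
#' @param template Ligand template (defaults to the one the pocket was built for).
#' @param verify Re-check the deepening and minimum position (default `TRUE`).
#' @return The mutated [protein_model()].
#' @export
make_mutant_variant <- function(receptor, delta_e,
                                template = load_ligand_template(
                                  attr(receptor, "pocket_info")$ligand),
                                verify = TRUE) {
  info <- attr(receptor, "pocket_info")
  if (is.null(info)) abort("receptor does not carry pocket_info; not a generated pocket")
  if (abs(delta_e) > info$spec$well_depth) {
    abort("abs(delta_e) exceeds the planted well depth")
  }
  idx <- unique(c(info$cradle_indices, info$pin_index,
                  receptor$anchor$atom_index))
  wt_best <- continuous_best(receptor, template, info,
                             seed = info$spec$seed + 7777L)
  e_site <- energy_subset(receptor, wt_best$pose, idx)
  s <- (e_site + delta_e) / e_site
  if (s <= 0) abort("delta_e would invert the site well")
  mut <- receptor
  # pair LJ terms scale with sqrt(eps_atom), the pin Coulomb term linearly
  # with the pin charge: both site contributions scale by exactly s
  mut$atoms$lj_epsilon[idx] <- receptor$atoms$lj_epsilon[idx] * s^2
  mut$atoms$charge[idx] <- receptor$atoms$charge[idx] * s
  info$spec$well_depth <- info$spec$well_depth - delta_e
  attr(mut, "pocket_info") <- info
  if (verify && abs(delta_e) > 1e-9) {
    mut_best <- continuous_best(mut, template, info,
                                seed = info$spec$seed + 7777L)
    achieved <- mut_best$energy - wt_best$energy
    d_shift <- abs(pose_catalytic_distance(mut, mut_best$pose) -
                     pose_catalytic_distance(receptor, wt_best$pose))
    if (abs(achieved - delta_e) > 0.5 || d_shift > 0.3) {
      abort(sprintf(
        paste0("mutant verification failed: deepening %.2f (planted %.2f) ",
               "kcal/mol, minimum moved %.2f A"),
        achieved, delta_e, d_shift
      ))
    }
  }
  mut
}

#' Specification of a synthetic initial-rate assay
#'
#' @param kcat Turnover number, 1/s.
#' @param km Michaelis constant, mM.
#' @param concentrations Substrate concentrations, mM (>= 5 values spanning
#'   below and above `km` for an identifiable fit).
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   rate noise (default 0.05; rates are positive so CV-style noise matches
#'   enzymology practice).
#' @param replicates Replicates per concentration.
#' @param seed Integer seed.
#' @return An object of class `assay_spec`.
#' @export
assay_spec <- function(kcat, km, concentrations = NULL, noise_cv = 0.05,
                       replicates = 3, seed = 1) {
  if (kcat <= 0 || km <= 0) abort("kcat and km must be > 0")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (is.null(concentrations)) {
    concentrations <- km * c(0.1, 0.2, 0.5, 1, 2, 4, 8, 16, 32, 64) / 4
  }
  structure(
    list(kcat = kcat, km = km, concentrations = as.numeric(concentrations),
         noise_cv = noise_cv, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "assay_spec"
  )
}

#' Generate a synthetic Michaelis-Menten initial-rate dataset
#'
#' Rates follow `v = kcat * S / (km + S)` with multiplicative lognormal noise
#' of coefficient of variation `noise_cv` per replicate; bit-reproducible
#' from the seed.
#'
#' @param spec An [assay_spec()].
#' @param label Enzyme/substrate label attached to the dataset.
#' @param assay Assay type label (`"oxygen_electrode"` or `"hrp_aap_dchbs"`).
#' @return A tibble (`rate_dataset`) with columns `substrate_mM`,
#'   `rate_per_s`, `replicate`, `label`, `assay`.
#' @export
make_mm_dataset <- function(spec, label = "synthetic", assay = "oxygen_electrode") {
  stopifnot(inherits(spec, "assay_spec"))
  if (length(spec$concentrations) < 5) {
    abort("need at least 5 substrate concentrations")
  }
  if (all(spec$concentrations < spec$km / 10)) {
    warn("all concentrations are far below km; kcat is unidentifiable")
  }
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  grid <- tidyr::expand_grid(substrate_mM = spec$concentrations,
                             replicate = seq_len(spec$replicates))
  v0 <- spec$kcat * grid$substrate_mM / (spec$km + grid$substrate_mM)
  noise <- if (spec$noise_cv > 0) {
    exp(rnorm(nrow(grid), mean = -sdlog^2 / 2, sd = sdlog))
  } else {
    rep(1, nrow(grid))
  }
  out <- tibble(
    substrate_mM = grid$substrate_mM,
    rate_per_s = v0 * noise,
    replicate = grid$replicate,
    label = label,
    assay = assay
  )
  class(out) <- c("rate_dataset", class(out))
  out
}

#' Generate a synthetic thermal-shift melt curve
#'
#' Sigmoidal flavin-fluorescence unfolding signal with inflection at `tm`,
#' on a 20-95 degC grid with 1 degC steps (the standard ThermoFAD ramp), plus
#' optional Gaussian noise relative to the transition amplitude.
#'
#' @param tm Melting temperature, degC.
#' @param slope Transition width parameter, degC (default 1.5; the 10-90%
#'   rise then spans ~6.6 degC, typical of a cooperative two-state unfolding
#'   transition).
#' @param grid Temperature grid, degC.
#' @param noise Multiplicative noise level: each reading is scaled by
#'   `1 + N(0, noise)`, i.e. a coefficient of variation, matching the
#'   CV-style noise model used for the rate generator (fluorescence readings
#'   are positive and their error scales with the signal).
#' @param seed Integer seed.
#' @return A tibble (`melt_curve`) with columns `temperature_c`,
#'   `fluorescence`.
#' @export
make_melt_curve <- function(tm, slope = 1.5, grid = seq(20, 95, by = 1),
                            noise = 0, seed = 1) {
  if (tm < min(grid) || tm > max(grid)) abort("tm must lie within the grid")
  set.seed(seed)
  f <- 1 / (1 + exp(-(grid - tm) / slope))
  if (noise > 0) f <- f * (1 + rnorm(length(grid), sd = noise))
  out <- tibble(temperature_c = grid, fluorescence = f)
  class(out) <- c("melt_curve", class(out))
  out
}

#' Generate a paired H/D kinetic isotope effect dataset
#'
#' Two Michaelis-Menten datasets sharing `km` (substrate binding is isotope
#' insensitive in this toy) with separate turnover numbers for protiated and
#' deuterated substrate.
#'
#' @param kcat_h,kcat_d Turnover numbers with protiated / deuterated
#'   substrate, 1/s.
#' @param km Shared Michaelis constant, mM.
#' @param concentrations,noise_cv,replicates,seed As in [assay_spec()].
#' @return A list with tibbles `protiated` and `deuterated`.
#' @export
make_kie_dataset <- function(kcat_h, kcat_d, km, concentrations = NULL,
                             noise_cv = 0.05, replicates = 3, seed = 1) {
  sp_h <- assay_spec(kcat_h, km, concentrations, noise_cv, replicates, seed)
  sp_d <- assay_spec(kcat_d, km, concentrations, noise_cv, replicates, seed + 1000L)
  list(
    protiated = make_mm_dataset(sp_h, label = "protiated"),
    deuterated = make_mm_dataset(sp_d, label = "deuterated")
  )
}
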