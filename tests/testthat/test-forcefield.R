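make_random_protein <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    serial = seq_len(n), name = paste0("PS", seq_len(n)), element = "X",
    res_index = seq_len(n), res_name = "PSD",
    x = runif(n, -8, 8), y = runif(n, -8, 8), z = runif(n, -8, 8),
    charge = runif(n, -0.5, 0.5),
    lj_epsilon = runif(n, 0.02, 0.4),
    lj_rmin = runif(n, 3, 4.2)
  ) |> protein_model()
}

test_that("interaction energy matches an independent R implementation", {
  tpl <- glycerol_template()
  for (seed in 1:10) {
    prot <- make_random_protein(6, seed)
    set.seed(seed + 100)
    pose <- ligand_pose(tpl, translation = runif(3, -5, 5),
                        rotation = aldoscape:::random_rotation_quat(pi))
    got <- interaction_energy(prot, pose)
    ref <- reference_energy(prot, pose)
    expect_equal(got$lj, ref$lj, tolerance = 1e-9)
    expect_equal(got$coulomb, ref$coulomb, tolerance = 1e-9)
    expect_equal(got$total, got$lj + got$coulomb) # breakdown sums exactly
  }
})

test_that("energy is zero beyond the cutoff and at the pair LJ minimum", {
  tpl <- glycerol_template()
  prot <- make_random_protein(5, 3)
  far <- ligand_pose(tpl, translation = c(50, 0, 0))
  e <- interaction_energy(prot, far)
  expect_equal(e$total, 0)

  # two neutral atoms at the combined rmin: lj equals -sqrt(eps1*eps2) up to
  # the cutoff shift
  one <- protein_model(tibble::tibble(
    serial = 1L, name = "PS1", element = "X", res_index = 1L, res_name = "PSD",
    x = 0, y = 0, z = 0, charge = 0, lj_epsilon = 0.2, lj_rmin = 3.6
  ))
  probe <- point_probe()
  rmin_pair <- (3.6 + 3.3) / 2
  pose <- ligand_pose(probe, translation = c(rmin_pair, 0, 0))
  eps_pair <- sqrt(0.2 * 0.18)
  shift <- eps_pair * ((rmin_pair^2 / 100)^6 - 2 * (rmin_pair^2 / 100)^3)
  expect_equal(interaction_energy(one, pose)$lj, -eps_pair - shift,
               tolerance = 1e-9)
})

test_that("joint rigid motion of the whole complex leaves the energy unchanged", {
  tpl <- glycerol_template()
  prot <- make_random_protein(6, 11)
  pose <- ligand_pose(tpl, translation = c(2, 1, -1))
  e0 <- interaction_energy(prot, pose)$total
  # translate protein and ligand together
  shift <- c(3.3, -1.7, 2.2)
  prot2 <- prot
  prot2$atoms$x <- prot2$atoms$x + shift[1]
  prot2$atoms$y <- prot2$atoms$y + shift[2]
  prot2$atoms$z <- prot2$atoms$z + shift[3]
  pose2 <- ligand_pose(tpl, translation = pose$translation + shift)
  expect_equal(interaction_energy(prot2, pose2)$total, e0, tolerance = 1e-9)
})

test_that("rigid gradient matches central finite differences", {
  tpl <- glycerol_template()
  h <- 1e-5
  for (seed in 1:20) {
    prot <- make_random_protein(6, seed + 40)
    set.seed(seed + 400)
    base_t <- runif(3, -4, 4)
    q <- aldoscape:::random_rotation_quat(pi)
    pose <- ligand_pose(tpl, translation = base_t, rotation = q)
    if (abs(interaction_energy(prot, pose)$total) > 1e4) next # clashed draw
    g <- rigid_gradient(prot, pose)
    for (k in 1:3) {
      dt <- c(0, 0, 0)
      dt[k] <- h
      ep <- interaction_energy(prot, ligand_pose(tpl, base_t + dt, q))$total
      em <- interaction_energy(prot, ligand_pose(tpl, base_t - dt, q))$total
      fd <- (ep - em) / (2 * h)
      expect_equal(g[k], fd, tolerance = 1e-4 * max(1, abs(fd)))
    }
    for (k in 1:3) {
      ax <- c(0, 0, 0)
      ax[k] <- 1
      qp <- aldoscape:::quat_multiply(aldoscape:::quat_from_axis_angle(ax, h), q)
      qm <- aldoscape:::quat_multiply(aldoscape:::quat_from_axis_angle(ax, -h), q)
      # rotation about the ligand centroid: keep the centroid fixed
      ep <- interaction_energy(prot, ligand_pose(tpl, base_t, aldoscape:::quat_normalize(qp)))$total
      em <- interaction_energy(prot, ligand_pose(tpl, base_t, aldoscape:::quat_normalize(qm)))$total
      fd <- (ep - em) / (2 * h)
      expect_equal(g[3 + k], fd, tolerance = 1e-3 * max(1, abs(fd)))
    }
  }
})

test_that("gradient is translation invariant under joint motion", {
  tpl <- glycerol_template()
  prot <- make_random_protein(6, 77)
  pose <- ligand_pose(tpl, translation = c(1, 2, 0))
  g0 <- rigid_gradient(prot, pose)
  shift <- c(-2, 4, 1)
  prot2 <- prot
  prot2$atoms$x <- prot2$atoms$x + shift[1]
  prot2$atoms$y <- prot2$atoms$y + shift[2]
  prot2$atoms$z <- prot2$atoms$z + shift[3]
  g1 <- rigid_gradient(prot2, ligand_pose(tpl, pose$translation + shift))
  expect_equal(g0, g1, tolerance = 1e-9)
})

test_that("grid oracle: empty receptor, random-pose lower bound, refinement", {
  tpl <- glycerol_template()
  empty <- protein_model(tibble::tibble(
    serial = 1L, name = "PS1", element = "X", res_index = 1L, res_name = "PSD",
    x = 50, y = 50, z = 50, charge = 0, lj_epsilon = 0.1, lj_rmin = 3.5
  ))
  sc <- grid_scan_oracle(empty, tpl, c(0, 0, 0), 2, t_step = 1, r_step = 120,
                         return_table = TRUE)
  expect_true(all(sc$table$energy == 0))

  rec <- catalytic_receptor()
  info <- attr(rec, "pocket_info")
  sc <- grid_scan_oracle(rec, tpl, info$box_center, 2.5, t_step = 0.25, r_step = 30)
  # the oracle minimum bounds 1000 random poses from below (within the grid
  # resolution of the scan)
  set.seed(5)
  worst <- Inf
  for (i in 1:1000) {
    dirn <- rnorm(3)
    tr <- info$box_center + runif(1, 0, 2.5) * dirn / sqrt(sum(dirn^2)) -
      tpl$centroid
    e <- interaction_energy(rec, ligand_pose(tpl, tr,
                                             aldoscape:::random_rotation_quat(pi)))$total
    worst <- min(worst, e)
  }
  expect_lte(sc$best_energy, worst + 0.25)

  # halving the translation step can only lower the minimum (pose superset)
  coarse <- grid_scan_oracle(rec, tpl, info$box_center, 1.5, t_step = 1,
                             r_step = 90)
  fine <- grid_scan_oracle(rec, tpl, info$box_center, 1.5, t_step = 0.5,
                           r_step = 90)
  finer <- grid_scan_oracle(rec, tpl, info$box_center, 1.5, t_step = 0.5,
                            r_step = 45)
  expect_lte(fine$best_energy, coarse$best_energy)
  expect_lte(finer$best_energy, fine$best_energy)
  # the reported best pose reproduces the reported best energy
  expect_equal(interaction_energy(rec, sc$best_pose)$total, sc$best_energy,
               tolerance = 1e-9)
})
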