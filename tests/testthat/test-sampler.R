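test_that("zero-size perturbations are the identity and moves respect bounds", {
  tpl <- glycerol_template()
  cfg <- sampler_config(box_center = c(0, 0, 0), box_radius = 50,
                        trans_max = 0, rot_max = 0)
  pose <- ligand_pose(tpl, translation = c(1, 1, 1) - tpl$centroid)
  set.seed(1)
  prop <- perturb_ligand(pose, cfg)
  expect_equal(prop$translation, pose$translation)
  expect_equal(prop$rotation, pose$rotation)

  cfg2 <- sampler_config(box_center = c(0, 0, 0), box_radius = 50,
                         trans_max = 0.8, rot_max = 15)
  set.seed(2)
  pose0 <- ligand_pose(tpl, translation = -tpl$centroid)
  for (i in 1:2000) {
    p <- perturb_ligand(pose0, cfg2)
    expect_lte(sqrt(sum((p$translation - pose0$translation)^2)), 0.8 + 1e-12)
  }
})

test_that("box-confined proposals stay in the box with identity fallback", {
  tpl <- glycerol_template()
  cfg <- sampler_config(box_center = c(0, 0, 0), box_radius = 2, trans_max = 1)
  pose <- ligand_pose(tpl, translation = c(1.9, 0, 0) - tpl$centroid)
  set.seed(3)
  for (i in 1:500) {
    p <- perturb_ligand(pose, cfg)
    expect_lte(sqrt(sum(aldoscape:::pose_centroid(p)^2)), 2 + 1e-9)
  }
  # a box so tight that nothing fits: the identity proposal comes back
  cfg0 <- sampler_config(box_center = c(10, 0, 0), box_radius = 0.001,
                         trans_max = 1)
  pose_out <- ligand_pose(tpl, translation = -tpl$centroid)
  set.seed(4)
  p <- perturb_ligand(pose_out, cfg0)
  expect_equal(p$translation, pose_out$translation)
})

test_that("the proposal kernel is symmetric (forward/reverse histogram test)", {
  tpl <- point_probe()
  cfg <- sampler_config(box_center = c(0, 0, 0), box_radius = 100,
                        trans_max = 1.5, rot_max = 30)
  x <- ligand_pose(tpl, translation = c(0, 0, 0) - tpl$centroid)
  y <- ligand_pose(tpl, translation = c(0.9, 0, 0) - tpl$centroid)
  ball <- 0.45
  n <- 20000
  count_hits <- function(from, target) {
    hits <- 0
    for (i in seq_len(n)) {
      p <- perturb_ligand(from, cfg)
      d <- sqrt(sum((aldoscape:::pose_centroid(p) -
                       aldoscape:::pose_centroid(target))^2))
      if (d <= ball) hits <- hits + 1
    }
    hits
  }
  set.seed(10)
  fwd <- count_hits(x, y)
  rev <- count_hits(y, x)
  expect_gt(stats::prop.test(c(fwd, rev), c(n, n))$p.value, 0.01)
})

test_that("Metropolis decisions follow the acceptance law", {
  set.seed(1)
  expect_true(metropolis_accept(-1, kT = 1.2))
  expect_true(metropolis_accept(0, kT = 1.2))
  expect_false(metropolis_accept(0.5, kT = 0))
  # acceptance rate at delta = kT is exp(-1) to within 0.01 over 1e5 draws
  set.seed(42)
  acc <- mean(vapply(1:1e5, function(i) metropolis_accept(1.2, 1.2), TRUE))
  expect_lt(abs(acc - exp(-1)), 0.01)
})

test_that("side-chain optimization relieves a planted clash and is idempotent", {
  model <- assign_parameters(read_pdb(write_toy_pdb()))
  model <- set_anchor(model, 2, "NZ")
  tpl <- glycerol_template()
  # drop the ligand right onto the lysine side chain to create a clash
  nz <- as.numeric(model$atoms[model$atoms$name == "NZ", c("x", "y", "z")])
  pose <- ligand_pose(tpl, translation = nz + c(0.3, 0.8, 0.4) - tpl$centroid)
  cfg <- sampler_config(box_center = nz)
  e_before <- interaction_energy(model, pose)$total +
    attr(optimize_sidechains(model, pose, cfg), "self_energy") * 0 # clash in place
  opt <- optimize_sidechains(model, pose, cfg)
  e_after <- interaction_energy(opt, pose)$total
  expect_lt(e_after, interaction_energy(model, pose)$total)
  # greedy fixed point: a second pass changes nothing
  opt2 <- optimize_sidechains(opt, pose, cfg)
  expect_equal(opt2$atoms, opt$atoms, tolerance = 1e-12)
  # no residues in range: untouched model
  far_pose <- ligand_pose(tpl, translation = c(500, 0, 0))
  same <- optimize_sidechains(model, far_pose, cfg)
  expect_equal(same$atoms, model$atoms)
})

test_that("minimization is monotone and converges on an analytic well", {
  # single attractor: the continuous minimum of the probe sits at the pair
  # rmin distance; start nearby and expect convergence to it
  one <- protein_model(tibble::tibble(
    serial = 1L, name = "PS1", element = "X", res_index = 1L, res_name = "PSD",
    x = 0, y = 0, z = 0, charge = 0, lj_epsilon = 1.0, lj_rmin = 3.4
  ))
  probe <- point_probe()
  rmin_pair <- (3.4 + 3.3) / 2
  pose0 <- ligand_pose(probe, translation = c(rmin_pair + 0.6, 0.2, -0.1))
  res <- minimize_pose(one, pose0)
  expect_true(res$converged)
  d <- sqrt(sum(aldoscape:::pose_centroid(res$pose)^2))
  # analytic optimum: the oxygen at rmin_pair from the attractor (the probe
  # centroid rides 0.025 A from the oxygen)
  expect_lt(abs(d - rmin_pair), 0.03)
  expect_lte(res$energy, interaction_energy(one, pose0)$total)

  # starting at the grid-scan minimum, minimization barely moves the ligand
  tpl <- glycerol_template()
  rec <- catalytic_receptor()
  info <- attr(rec, "pocket_info")
  sc <- aldoscape:::local_argmin(rec, tpl, info$min_pose, radius = 1)
  res2 <- minimize_pose(rec, sc$best_pose)
  moved <- sqrt(sum((aldoscape:::pose_centroid(res2$pose) -
                       aldoscape:::pose_centroid(sc$best_pose))^2))
  # within the combined resolution of the translation and rotation grids
  expect_lt(moved, 0.5)
  expect_lte(res2$energy, sc$best_energy)
})

test_that("simulation bookkeeping: record counts, determinism, rejection restore", {
  tpl <- glycerol_template()
  rec <- catalytic_receptor()
  cfg1 <- sampler_config(n_steps = 1, n_walkers = 5, seed = 3)
  t1 <- run_simulation(rec, tpl, cfg1)
  expect_equal(nrow(t1), 5)

  cfg <- sampler_config(n_steps = 60, n_walkers = 2, seed = 11)
  a <- run_simulation(rec, tpl, cfg)
  b <- run_simulation(rec, tpl, cfg)
  expect_identical(a, b)
  expect_true(all(a$catalytic_distance > 0))
  expect_true(all(diff(a$step[a$walker == 1]) == 1))

  # a rejected step leaves the recorded state identical to the previous one
  # (a plain Metropolis chain at low temperature rejects plenty of moves)
  toy <- two_well_toy()
  cfg_rej <- sampler_config(box_center = c(8, 0, 0), box_radius = 6.5,
                            trans_max = 2.5, kT = 0.3, anm_every = 0,
                            minimize = FALSE, n_steps = 300, n_walkers = 2,
                            seed = 4)
  b2 <- run_simulation(toy, point_probe(), cfg_rej)
  rej <- which(!b2$accepted & b2$step > 1 & b2$walker == dplyr::lag(b2$walker))
  expect_gt(length(rej), 0)
  expect_equal(b2$total_energy[rej], b2$total_energy[rej - 1])
  expect_equal(b2$catalytic_distance[rej], b2$catalytic_distance[rej - 1])

  # a start pose outside the box is rejected up front
  far <- ligand_pose(tpl, translation = c(100, 0, 0))
  expect_error(run_simulation(rec, tpl, cfg, start_pose = far), "outside")
})

test_that("trajectory reports round-trip through TSV", {
  tpl <- glycerol_template()
  rec <- catalytic_receptor()
  a <- run_simulation(rec, tpl, sampler_config(n_steps = 10, n_walkers = 1,
                                               seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_trajectory(a, path)
  b <- read_trajectory(path)
  expect_equal(as.data.frame(b), as.data.frame(a), tolerance = 1e-12)
  bad <- tempfile(fileext = ".tsv")
  writeLines("walker\tstep", bad)
  expect_error(read_trajectory(bad), "missing columns")
})

test_that("frozen-receptor chain reproduces Boltzmann well occupancies", {
  toy <- two_well_toy()
  probe <- point_probe()
  quad <- two_well_quadrature(toy, probe)
  cfg <- two_well_config(n_steps = 4000, n_walkers = 12, seed = 21)
  traj <- run_simulation(toy, probe, cfg)
  burn <- traj$step > 500
  occ <- traj[burn, ] |>
    dplyr::group_by(walker) |>
    dplyr::summarise(p1 = mean(catalytic_distance < 8), .groups = "drop")
  sem <- stats::sd(occ$p1) / sqrt(nrow(occ))
  expect_lt(abs(mean(occ$p1) - quad$p_well1), 3 * sem)
  # and the sampled distance marginal matches the quadrature distribution
  breaks <- c(0, 3, 4.5, 6, 8, 10, 12, 20)
  p_exp <- vapply(seq_len(length(breaks) - 1), function(i) {
    sum(quad$w[quad$d >= breaks[i] & quad$d < breaks[i + 1]])
  }, 0)
  p_exp <- p_exp / sum(p_exp)
  thin <- traj[burn & (traj$step %% 40 == 0), ]
  obs <- table(cut(thin$catalytic_distance, breaks))
  keep <- p_exp > 1e-4
  expect_gt(stats::chisq.test(as.numeric(obs)[keep],
                              p = p_exp[keep] / sum(p_exp[keep]))$p.value,
            0.01)
})
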