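test_that("catalytic distance takes the closest labeled terminal proton", {
  tpl <- glycerol_template()
  rec <- catalytic_receptor()
  pose <- attr(rec, "pocket_info")$docked_pose
  d <- catalytic_distance(pose, rec)
  a <- as.numeric(rec$atoms[rec$anchor$atom_index, c("x", "y", "z")])
  H <- pose_coords(pose)[tpl$terminal_indices, ]
  manual <- min(sqrt(rowSums(sweep(H, 2, a)^2)))
  expect_equal(d, manual)
  expect_equal(d, 3, tolerance = 1e-9) # the planted docking geometry

  # swapping the two labels cannot change the minimum
  swapped <- tpl
  swapped$terminal_indices <- rev(tpl$terminal_indices)
  pose_sw <- ligand_pose(swapped, pose$translation, pose$rotation)
  expect_equal(catalytic_distance(pose_sw, rec), d)

  # joint rigid motion of complex + anchor leaves the distance unchanged
  shift <- c(5, -3, 2)
  rec2 <- rec
  rec2$atoms$x <- rec2$atoms$x + shift[1]
  rec2$atoms$y <- rec2$atoms$y + shift[2]
  rec2$atoms$z <- rec2$atoms$z + shift[3]
  pose2 <- ligand_pose(tpl, pose$translation + shift, pose$rotation)
  expect_equal(catalytic_distance(pose2, rec2), d, tolerance = 1e-9)

  # missing anchor errors
  rec3 <- rec
  rec3$anchor <- NULL
  expect_error(catalytic_distance(pose, rec3), "anchor")
})

test_that("profiles locate envelope minima with the prominence rule", {
  single <- tibble::tibble(catalytic_distance = 3, interaction_energy = -10)
  prof <- build_profile(single)
  expect_equal(nrow(prof$minima), 1)
  expect_equal(prof$global_min$distance, 3)
  expect_equal(prof$global_min$energy, -10)

  # V-shaped envelope: one minimum at the vertex
  d <- seq(2, 6, by = 0.1)
  v <- tibble::tibble(catalytic_distance = d, interaction_energy = abs(d - 3.5) * 4 - 8)
  prof_v <- build_profile(v)
  expect_equal(nrow(prof_v$minima), 1)
  expect_equal(prof_v$minima$distance, 3.5, tolerance = 0.25)

  # synthetic two-well envelope with a 3 kcal/mol barrier: exactly two minima
  d2 <- seq(2, 8, by = 0.05)
  e2 <- -8 * exp(-(d2 - 3)^2 / 0.5) - 6 * exp(-(d2 - 6)^2 / 0.5)
  two <- tibble::tibble(catalytic_distance = d2, interaction_energy = e2)
  prof2 <- build_profile(two)
  expect_equal(nrow(prof2$minima), 2)
  expect_equal(sort(prof2$minima$distance), c(3, 6), tolerance = 0.25)

  expect_error(build_profile(two[0, ]), "empty")
})

test_that("two-minimum receptors produce two-well landscapes end to end", {
  tpl <- glycerol_template()
  rec <- make_pocket_receptor(
    pocket_spec(3.0, 9, decoy = list(d2 = 6, depth2 = 7), seed = 104), tpl
  )
  cfg <- sampler_config(n_steps = 250, n_walkers = 12, seed = 5, anm_every = 0)
  traj <- run_simulation(rec, tpl, cfg)
  prof <- build_profile(traj)
  expect_gte(nrow(prof$minima), 2)
  # wells on both sides of the cut-off: a catalytic basin near the planted
  # site (the broad well can split into sub-basins) and the decoy
  dmins <- sort(prof$minima$distance)
  expect_true(any(abs(dmins - 3) <= 1))
  expect_true(any(abs(dmins - 6) <= 0.6))
  # the verdict flags the secondary, non-catalytic minimum
  v <- classify_landscape(prof, candidate_id = "two_minimum")
  expect_true(v$catalytic)
  expect_gte(v$n_secondary_minima, 1)
})

test_that("the 4 A rule classifies by global-minimum distance, boundary inclusive", {
  mk <- function(d) {
    build_profile(tibble::tibble(
      catalytic_distance = c(d, d + 2), interaction_energy = c(-10, -5)
    ))
  }
  expect_true(classify_landscape(mk(3.2))$catalytic)
  expect_false(classify_landscape(mk(5.5))$catalytic)
  expect_true(classify_landscape(mk(4.0))$catalytic) # boundary convention

  # lowering the cutoff never converts non-catalytic to catalytic
  for (d in c(2.5, 3.9, 4.4, 6)) {
    p <- mk(d)
    verdicts <- vapply(c(5, 4.5, 4, 3.5, 3, 2.5),
                       function(ct) classify_landscape(p, cutoff = ct)$catalytic,
                       TRUE)
    expect_true(all(diff(as.integer(verdicts)) <= 0))
  }
})

test_that("mutant comparison implements the similar-distance/better-energy rule", {
  set.seed(8)
  wt <- tibble::tibble(
    catalytic_distance = c(runif(200, 2.5, 3.5), runif(100, 4, 7)),
    interaction_energy = c(rnorm(200, -7, 0.5), rnorm(100, -3, 0.5))
  )
  # identical datasets: no improvement, unit ratios
  same <- compare_mutant(wt, wt)
  expect_false(same$improved)
  expect_equal(same$density_ratio, 1)
  expect_equal(same$delta_min_energy, 0)

  # deeper minimum at the same distance: improved
  mut <- wt
  mut$interaction_energy <- mut$interaction_energy - 1.46
  cmp <- compare_mutant(wt, mut)
  expect_true(cmp$improved)
  expect_equal(cmp$delta_min_energy, -1.46, tolerance = 1e-9)

  # minimum shifted beyond the window: not improved no matter how deep
  shifted <- tibble::tibble(
    catalytic_distance = wt$catalytic_distance + 3,
    interaction_energy = wt$interaction_energy - 5
  )
  expect_false(compare_mutant(wt, shifted)$improved)
})

test_that("planted wild-type/mutant pair is recovered by the full comparison", {
  tpl <- glycerol_template()
  rec <- catalytic_receptor()
  mut <- make_mutant_variant(rec, -1.46, tpl)
  cfg <- sampler_config(n_steps = 350, n_walkers = 8, seed = 17, anm_every = 0)
  t_wt <- run_simulation(rec, tpl, cfg)
  t_mut <- run_simulation(mut, tpl, cfg)
  cmp <- compare_mutant(t_wt, t_mut)
  expect_true(cmp$improved)
  expect_lt(abs(cmp$delta_min_energy + 1.46), 0.5)
  expect_lte(abs(cmp$delta_min_distance), 0.5)
})

test_that("candidate ranking is deterministic with documented tie-breaks", {
  v <- dplyr::bind_rows(
    tibble::tibble(candidate_id = "b", global_min_distance = 3.1,
                   global_min_energy = -9, catalytic = TRUE),
    tibble::tibble(candidate_id = "a", global_min_distance = 3.5,
                   global_min_energy = -9, catalytic = TRUE),
    tibble::tibble(candidate_id = "c", global_min_distance = 2.9,
                   global_min_energy = -7, catalytic = TRUE),
    tibble::tibble(candidate_id = "d", global_min_distance = 6,
                   global_min_energy = -12, catalytic = FALSE)
  )
  r <- rank_candidates(v)
  expect_equal(r$candidate_id, c("b", "a", "c", "d")) # non-catalytic last
  # equal energies and distances: lexicographic by id
  v2 <- v
  v2$global_min_energy <- -9
  v2$global_min_distance <- 3
  r2 <- rank_candidates(v2[v2$catalytic, ])
  expect_equal(r2$candidate_id, c("a", "b", "c"))
  # permuting the input leaves the ranking unchanged
  r3 <- rank_candidates(v[c(3, 1, 4, 2), ])
  expect_equal(r3$candidate_id, r$candidate_id)
})

test_that("end-to-end archetype recovery across seeded runs", {
  tpl <- glycerol_template()
  run_one <- function(d_star, seed) {
    rec <- make_pocket_receptor(pocket_spec(d_star, 8, seed = seed), tpl,
                                verify = FALSE)
    cfg <- sampler_config(seed = seed)
    traj <- run_simulation(rec, tpl, cfg)
    classify_landscape(build_profile(traj))$catalytic
  }
  cat_ok <- vapply(1:3, function(s) run_one(c(2.5, 3.0, 3.5)[s], 300 + s), TRUE)
  non_ok <- vapply(1:3, function(s) !run_one(c(5, 6, 7)[s], 400 + s), TRUE)
  expect_gte(mean(c(cat_ok, non_ok)), 0.95)
})
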