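test_that("pocket spec validates its fields", {
  expect_error(pocket_spec(-1, 8), "d_star")
  expect_error(pocket_spec(3, 0), "well_depth")
  expect_error(pocket_spec(3, 8, decoy = list(d2 = 3, depth2 = 5)), "differ")
  expect_error(pocket_spec(3, 8, decoy = list(d2 = 6)), "decoy")
})

test_that("catalytic archetype plants its minimum at d_star (exhaustive oracle)", {
  tpl <- glycerol_template()
  rec <- catalytic_receptor() # d_star = 3.0, depth 8
  info <- attr(rec, "pocket_info")
  sc <- grid_scan_oracle(rec, tpl, info$box_center, 2.5, t_step = 0.25,
                         r_step = 30)
  d <- catalytic_distance(sc$best_pose, rec)
  expect_gte(d, 2.7)
  expect_lte(d, 3.3)
  expect_lt(abs(sc$best_energy + 8), 0.5)
})

test_that("non-catalytic archetype has its minimum beyond the 4 A cut-off", {
  tpl <- glycerol_template()
  rec <- noncatalytic_receptor() # d_star = 6.0
  info <- attr(rec, "pocket_info")
  sc <- grid_scan_oracle(rec, tpl, info$box_center, 2.5, t_step = 0.25,
                         r_step = 30)
  d <- catalytic_distance(sc$best_pose, rec)
  expect_gt(d, 4)
  expect_lt(abs(d - 6), 0.3)
})

test_that("a deeper decoy beats the catalytic site in the two-minimum archetype", {
  tpl <- glycerol_template()
  rec <- make_pocket_receptor(
    pocket_spec(3.0, 8, decoy = list(d2 = 6, depth2 = 10), seed = 103), tpl
  )
  info <- attr(rec, "pocket_info")
  # site-local refinement scans around each planted site
  s1 <- aldoscape:::local_argmin(rec, tpl, info$docked_pose, radius = 2)
  s2 <- aldoscape:::local_argmin(rec, tpl, info$decoy_pose, radius = 2)
  expect_lt(abs(s1$best_energy + 8), 0.5)
  expect_lt(abs(s2$best_energy + 10), 0.5)
  expect_lt(s2$best_energy, s1$best_energy)
  expect_lt(abs(catalytic_distance(s2$best_pose, rec) - 6), 0.3)
})

test_that("mutant rescaling deepens the well in place", {
  tpl <- glycerol_template()
  rec <- catalytic_receptor()
  info <- attr(rec, "pocket_info")
  wt_min <- aldoscape:::local_argmin(rec, tpl, info$min_pose, radius = 1)

  mut <- make_mutant_variant(rec, -1.46, tpl)
  mut_min <- aldoscape:::local_argmin(mut, tpl, info$min_pose, radius = 1)
  expect_lt(abs((mut_min$best_energy - wt_min$best_energy) + 1.46), 0.5)
  expect_lt(abs(catalytic_distance(mut_min$best_pose, mut) -
                  catalytic_distance(wt_min$best_pose, rec)), 0.3)

  # identity mutation leaves the landscape untouched
  same <- make_mutant_variant(rec, 0, tpl)
  expect_equal(same$atoms$lj_epsilon, rec$atoms$lj_epsilon, tolerance = 1e-12)

  # a large deepening is applied to within the oracle tolerance too
  deep <- make_mutant_variant(rec, -3, tpl)
  deep_min <- aldoscape:::local_argmin(deep, tpl, info$min_pose, radius = 1)
  expect_lt(abs((deep_min$best_energy - wt_min$best_energy) + 3), 0.5)

  expect_error(make_mutant_variant(rec, -20, tpl), "well depth")
})

test_that("generators are pure functions of their spec", {
  tpl <- glycerol_template()
  r1 <- make_pocket_receptor(pocket_spec(3.0, 8, seed = 202), tpl, verify = FALSE)
  r2 <- make_pocket_receptor(pocket_spec(3.0, 8, seed = 202), tpl, verify = FALSE)
  expect_identical(r1$atoms, r2$atoms)
  d1 <- make_mm_dataset(assay_spec(4, 41, seed = 5))
  d2 <- make_mm_dataset(assay_spec(4, 41, seed = 5))
  expect_identical(d1, d2)
  m1 <- make_melt_curve(76, noise = 0.02, seed = 9)
  m2 <- make_melt_curve(76, noise = 0.02, seed = 9)
  expect_identical(m1, m2)
})

test_that("noiseless rate data sit exactly on the Michaelis-Menten curve", {
  spec <- assay_spec(1.6, 50, noise_cv = 0, replicates = 1)
  d <- make_mm_dataset(spec)
  expect_equal(d$rate_per_s, 1.6 * d$substrate_mM / (50 + d$substrate_mM))
  # half-saturation identity
  half <- make_mm_dataset(assay_spec(1.6, 50, concentrations = c(1, 5, 20, 50, 200),
                                     noise_cv = 0, replicates = 1))
  expect_equal(half$rate_per_s[half$substrate_mM == 50], 0.8)
})

test_that("rate generator warns when kcat is unidentifiable and validates input", {
  expect_warning(
    make_mm_dataset(assay_spec(2, 100, concentrations = c(1, 2, 3, 4, 5),
                               noise_cv = 0)),
    "unidentifiable"
  )
  expect_error(make_mm_dataset(assay_spec(2, 100, concentrations = c(1, 2))),
               "at least 5")
  expect_error(assay_spec(-1, 50), "kcat")
  expect_error(assay_spec(1, 50, noise_cv = -0.1), "noise_cv")
})

test_that("fitting recovers the planted kinetic parameters from noisy data", {
  d <- make_mm_dataset(assay_spec(4.0, 41, noise_cv = 0.02, replicates = 10,
                                  seed = 7))
  fit <- fit_mm(d)
  expect_true(fit$converged)
  expect_lt(abs(fit$kcat - 4.0) / 4.0, 0.05)
  expect_lt(abs(fit$km - 41) / 41, 0.10)
})

test_that("melt-curve generator and extractor agree", {
  expect_equal(tm_from_melt(make_melt_curve(76))$tm, 76, tolerance = 1)
  expect_equal(tm_from_melt(make_melt_curve(81))$tm, 81, tolerance = 1)
  # noisy recovery across 50 seeds
  hits <- vapply(1:50, function(s) {
    tm <- tm_from_melt(make_melt_curve(85, noise = 0.02, seed = s))$tm
    !is.na(tm) && abs(tm - 85) <= 1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_error(make_melt_curve(150), "grid")
})

test_that("isotope-effect datasets share km and encode the planted ratio", {
  z <- make_kie_dataset(2, 1, 50, noise_cv = 0, replicates = 1)
  f_h <- fit_mm(z$protiated)
  f_d <- fit_mm(z$deuterated)
  expect_equal(kie(f_h, f_d)$kie, 2, tolerance = 1e-6)
  expect_equal(f_h$km, f_d$km, tolerance = 1e-6)
  same <- make_kie_dataset(2, 2, 50, noise_cv = 0, replicates = 1)
  expect_equal(kie(fit_mm(same$protiated), fit_mm(same$deuterated))$kie, 1,
               tolerance = 1e-6)
  noisy <- make_kie_dataset(3.0, 1.5, 40, noise_cv = 0.03, replicates = 5,
                            seed = 11)
  r <- kie(fit_mm(noisy$protiated), fit_mm(noisy$deuterated))
  expect_lt(abs(r$kie - 2) / 2, 0.10)
  expect_match(r$interpretation, "rate-limiting")
})
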