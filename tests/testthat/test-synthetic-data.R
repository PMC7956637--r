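# Synthetic generator: geometry, determinism, ground-truth consistency.

test_that("bundle geometry: atom counts, CA spacing, clash detection", {
  spec <- synthetic_spec(
    helices = lapply(1:5, function(h)
      list(name = paste("TM", h), start = (h - 1) * 20 + 1, length = 20,
           direction = if (h %% 2) 1 else -1, kink_pos = NULL, kink_angle = 0)),
    n_popc = 0, n_pope = 0, n_chl = 0, n_frames = 1)
  sys <- build_bundle(spec)
  expect_equal(nrow(sys$atoms), 20 * 5 * 6)
  ca <- sys$frames[[1]]$xyz[select_atoms(sys, residue_range = c(1, 20),
                                         calpha = TRUE), ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.05))

  crowded <- spec
  crowded$bundle_radius <- 3
  expect_error(build_bundle(crowded), "overlap")
})

test_that("identical spec and seed give bit-identical trajectories", {
  spec <- one_helix_spec(n_res = 12, n_frames = 20, n_chl = 1, sigma = 0.15,
                         schedule = list(list(mol = 1, region = "H1",
                                              frames = 1:7, target_residue = 6)),
                         seed = 33)
  t1 <- synthesize_trajectory(spec)
  t2 <- synthesize_trajectory(spec)
  expect_identical(serialize(t1$system$frames, NULL),
                   serialize(t2$system$frames, NULL))
  expect_identical(t1$truth, t2$truth)
  spec$seed <- 34L
  t3 <- synthesize_trajectory(spec)
  expect_false(identical(t1$system$frames, t3$system$frames))
})

test_that("every ground-truth table is recovered by its pipeline stage at sigma 0", {
  spec <- one_helix_spec(
    n_res = 20, n_frames = 80, n_chl = 2, sigma = 0,
    schedule = list(
      list(mol = 1, region = "H1", frames = c(1:20, 41:60), target_residue = 6),
      list(mol = 2, region = "H1", frames = 10:30, target_residue = 14)),
    ligand_schedule = list(
      contacts = list(`10` = 1:40),
      hbond = list(residue = 10, frames = 1:24)))
  tr <- synthesize_trajectory(spec)
  ser <- region_contact_series(tr$system, spec_regions(spec))
  expect_identical(c(ser$occupancy), c(tr$truth$contact))
  expect_equal(occupancy_percent(ser, "H1"),
               100 * tr$truth$region_fraction[["H1"]])
  expect_equal(mean_bound_per_frame(ser, "H1"),
               tr$truth$mean_per_frame[["H1"]])
  expect_equal(total_bound_events(ser), tr$truth$total_bound_events)
  fr <- residue_contact_fractions(tr$system)
  expect_equal(unname(fr[names(tr$truth$ligand_fraction)]),
               unname(tr$truth$ligand_fraction))
  hb <- hbond_occupancy(tr$system, donor = list(residue = 10, atom = "CB"),
                        acceptor = list(residue = 400, atom = "O1"))
  expect_equal(as.numeric(hb), tr$truth$hbond_fraction)
  expect_equal(as.numeric(hb), 0.3)
})

test_that("norm-clipped noise preserves every contact label", {
  spec <- suppressWarnings(one_helix_spec(
    n_res = 20, n_frames = 120, n_chl = 2, sigma = 0.4,
    schedule = list(
      list(mol = 1, region = "H1", frames = 1:60, target_residue = 6),
      list(mol = 2, region = "H1", frames = 30:90, target_residue = 14)),
    seed = 55))
  tr <- synthesize_trajectory(spec)
  ser <- region_contact_series(tr$system, spec_regions(spec))
  expect_identical(c(ser$occupancy), c(tr$truth$contact))
})

test_that("spec validation rejects inconsistent noise and kink settings", {
  expect_error(one_helix_spec(sigma = 0.1, clip = 0.6), "margin")
  expect_error(synthesize_trajectory(one_helix_spec(kink_pos = 5, kink_angle = 95,
                                                    n_frames = 2)), "90")
  expect_warning(one_helix_spec(sigma = 0.4, clip = 0.45), "truncated")
  expect_error(one_helix_spec(n_frames = 0), "n_frames")
  expect_error(
    synthetic_spec(ligand_schedule = list(contacts = list(`5` = 1:2),
                                          hbond = list(residue = 5, frames = 1)),
                   sigma = 0.1, clip = 0.3, n_frames = 2),
    "H-bond")
})

test_that("bridging placements realize multi-region contact in the truth table", {
  spec <- synthetic_spec(
    helices = list(
      list(name = "H1", start = 1, length = 16, direction = 1,
           kink_pos = NULL, kink_angle = 0)),
    regions = list(low = c(2, 5), high = c(12, 15)),
    n_popc = 0, n_pope = 0, n_chl = 2,
    chol_schedule = list(
      list(mol = 1, region = "low", frames = 1:10, target_residue = 3),
      list(mol = 1, region = "high", frames = 6:10, target_residue = 13),
      list(mol = 2, region = "high", frames = 9:10, target_residue = 14)),
    n_frames = 10, sigma = 0,
    drift = list(rot_deg = 0, trans = c(0, 0, 0)), seed = 3)
  tr <- synthesize_trajectory(spec)
  ser <- region_contact_series(tr$system, spec_regions(spec))
  expect_identical(c(ser$occupancy), c(tr$truth$contact))
  cl <- motif_occupancy_classes(ser, "low", "high")
  expect_identical(cl$classes[1:5], rep("only_A", 5))
  expect_identical(cl$classes[6:8], rep("bridged_only", 3))
  expect_identical(cl$classes[9:10], rep("simultaneous", 2))
})

test_that("demo specs realize the published occupancy statistics exactly", {
  n <- 200  # scaled run; schedules scale with the frame count
  apo <- synthesize_trajectory(demo_apo_spec(n, seed = 7))
  holo <- synthesize_trajectory(demo_holo_spec(n, seed = 8))
  expect_equal(unname(100 * apo$truth$region_fraction[paste("TM", c("I", "II", "III", "IV", "V"))]),
               c(32, 51, 23, 27, 100), tolerance = 1e-9)
  expect_equal(unname(100 * holo$truth$region_fraction[paste("TM", c("I", "II", "III", "IV", "V"))]),
               c(47, 26, 19, 15, 48), tolerance = 1e-9)
  expect_equal(unname(apo$truth$mean_per_frame[["TM V"]]), 1.5)
  expect_equal(apo$truth$total_bound_events / holo$truth$total_bound_events, 1.5)
  expect_equal(holo$truth$hbond_fraction, 0.6)
})
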