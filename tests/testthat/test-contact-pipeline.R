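# Contact engine, occupancy statistics, motif-pair classification, leaflets.

test_that("frame_contacts honours the <= cutoff boundary convention", {
  mk <- function(d) {
    atoms <- tiny_atoms(2, resno = c(1, 50), resname = c("ALA", "CHL"),
                        chain = c("A", "L"))
    tiny_system(atoms, list(list(time_ns = 0,
                                 xyz = rbind(c(0, 0, 0), c(d, 0, 0)),
                                 box = NULL)))
  }
  expect_true(frame_contacts(mk(4.9), 1L, 2L, 5))
  expect_true(frame_contacts(mk(5.0), 1L, 2L, 5))
  expect_false(frame_contacts(mk(5.1), 1L, 2L, 5))
  expect_error(frame_contacts(mk(1), 1L, 2L, -1), "positive")
})

test_that("grid-accelerated contacts match the all-pairs oracle", {
  set.seed(3)
  for (rep in 1:40) {
    na <- sample(c(20, 200, 500), 1)
    nb <- sample(c(20, 200, 500), 1)
    scale <- sample(c(10, 30, 80), 1)
    xa <- matrix(runif(na * 3, 0, scale), na, 3)
    xb <- matrix(runif(nb * 3, 0, scale), nb, 3)
    cutoff <- runif(1, 1, 8)
    expect_identical(choltraj:::groups_within_cutoff(xa, xb, cutoff),
                     bf_within(xa, xb, cutoff))
  }
})

test_that("minimum-image distances are used when a box is present", {
  box <- c(20, 20, 20)
  xa <- matrix(c(1, 1, 1), 1, 3)
  xb <- matrix(c(19, 1, 1), 1, 3)  # 2 A through the boundary
  expect_true(choltraj:::groups_within_cutoff(xa, xb, 3, box))
  expect_false(choltraj:::groups_within_cutoff(xa, xb, 1.5, box))
})

test_that("occupancy percent and mean-per-frame arithmetic", {
  A <- matrix(FALSE, 1000, 2)
  A[1:320, 1] <- TRUE
  s <- make_series(A)
  expect_equal(occupancy_percent(s, "A"), 32)
  expect_equal(mean_bound_per_frame(s, "A"), 0.32)
  expect_equal(occupancy_percent(make_series(matrix(TRUE, 10, 1)), "A"), 100)
  expect_equal(occupancy_percent(make_series(matrix(FALSE, 10, 1)), "A"), 0)
  # 2 bound in half the frames, 1 in the other half -> 1.5 per frame
  M <- matrix(TRUE, 100, 2); M[51:100, 2] <- FALSE
  expect_equal(mean_bound_per_frame(make_series(M), "A"), 1.5)
})

test_that("occupancy is zero exactly when the mean per frame is zero", {
  set.seed(5)
  for (rep in 1:20) {
    A <- matrix(runif(60) < 0.2, 20, 3)
    s <- make_series(A)
    expect_equal(occupancy_percent(s, "A") == 0,
                 mean_bound_per_frame(s, "A") == 0)
  }
})

test_that("simultaneous/bridging classification matches exhaustive enumeration", {
  states <- c("none", "A", "B", "AB")
  grid <- expand.grid(m1 = states, m2 = states, m3 = states,
                      stringsAsFactors = FALSE)
  A <- matrix(FALSE, nrow(grid), 3)
  B <- matrix(FALSE, nrow(grid), 3)
  for (m in 1:3) {
    st <- grid[[m]]
    A[, m] <- st %in% c("A", "AB")
    B[, m] <- st %in% c("B", "AB")
  }
  s <- make_series(A, B)
  got <- motif_occupancy_classes(s, "A", "B")
  want <- vapply(seq_len(nrow(grid)), function(f)
    oracle_pair_class(which(A[f, ]), which(B[f, ])), character(1))
  expect_identical(got$classes, want)
  expect_equal(sum(got$counts), nrow(grid))

  # the three canonical cases: distinct pair / lone bridger / bridger+partner
  A3 <- rbind(c(TRUE, FALSE), c(TRUE, FALSE), c(TRUE, FALSE))
  B3 <- rbind(c(FALSE, TRUE), c(FALSE, FALSE), c(TRUE, TRUE))
  A3[2, 1] <- TRUE; B3[2, 1] <- TRUE            # lone bridger
  cl <- motif_occupancy_classes(make_series(A3, B3), "A", "B")
  expect_identical(cl$classes, c("simultaneous", "bridged_only", "simultaneous"))
  expect_error(motif_occupancy_classes(s, "A", "A"), "differ")
})

test_that("total bound ratio mirrors the apo/holo event counting", {
  M <- matrix(TRUE, 10, 1)
  s <- make_series(M)
  expect_equal(total_bound_ratio(s, s), 1)
  apo <- make_series(matrix(TRUE, 3000, 1))
  holo <- make_series(rbind(matrix(TRUE, 2000, 1), matrix(FALSE, 1000, 1)))
  expect_equal(total_bound_ratio(apo, holo), 1.5)
  none <- make_series(matrix(FALSE, 10, 1))
  expect_error(total_bound_ratio(s, none), "no bound events")
})

test_that("deterministic schedules are recovered exactly, with and without noise", {
  for (sigma in c(0, 0.3)) {
    spec <- suppressWarnings(one_helix_spec(
      n_res = 16, n_frames = 60, n_chl = 2, sigma = sigma,
      schedule = list(
        list(mol = 1, region = "H1", frames = 1:30, target_residue = 8),
        list(mol = 2, region = "H1", frames = 11:40, target_residue = 9))))
    tr <- synthesize_trajectory(spec)
    ser <- region_contact_series(tr$system, spec_regions(spec))
    expect_identical(c(ser$occupancy), c(tr$truth$contact))
    expect_equal(occupancy_percent(ser, "H1"), 100 * 40 / 60)
    expect_equal(mean_bound_per_frame(ser, "H1"), 60 / 60)
  }
})

test_that("Markov schedules recover the stationary occupancy", {
  k_on <- 0.2; k_off <- 0.2
  spec <- one_helix_spec(
    n_res = 12, n_frames = 2000, n_chl = 1, sigma = 0,
    schedule = list(list(mol = 1, region = "H1", k_on = k_on, k_off = k_off,
                         target_residue = 6)),
    seed = 17)
  tr <- synthesize_trajectory(spec)
  ser <- region_contact_series(tr$system, spec_regions(spec))
  expect_identical(c(ser$occupancy), c(tr$truth$contact))
  p <- k_on / (k_on + k_off)
  rho <- 1 - k_on - k_off
  se <- sqrt(p * (1 - p) * (1 + rho) / (1 - rho) / 2000)
  expect_lt(abs(mean_bound_per_frame(ser, "H1") - p), 3 * se)
})

test_that("enlarging the cutoff never decreases any occupancy percentage", {
  spec <- one_helix_spec(
    n_res = 16, n_frames = 40, n_chl = 2, sigma = 0.15,
    schedule = list(list(mol = 1, region = "H1", frames = 1:20,
                         target_residue = 8)))
  tr <- synthesize_trajectory(spec)
  prev <- -1
  for (cut in c(3, 4, 5, 6, 8)) {
    ser <- region_contact_series(tr$system, spec_regions(spec),
                                 analysis_parameters(cholesterol_cutoff = cut))
    cur <- occupancy_percent(ser, "H1")
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("leaflet assignment uses reference-atom z against the midplane", {
  atoms <- rbind(
    tiny_atoms(1, name = "O3", element = "O", resno = 10, resname = "CHL", chain = "L"),
    tiny_atoms(1, name = "O3", element = "O", resno = 11, resname = "CHL", chain = "L"))
  atoms$index <- 1:2
  sys <- tiny_system(atoms, list(list(time_ns = 0,
                                      xyz = rbind(c(0, 0, 10), c(0, 0, -10)),
                                      box = NULL)))
  lf <- assign_leaflets(sys)
  expect_equal(lf$leaflet, c("upper", "lower"))
  lf2 <- assign_leaflets(sys, midplane = -20)
  expect_equal(lf2$leaflet, c("upper", "upper"))

  # generator ground truth: labels recovered 100%
  spec <- synthetic_spec(n_popc = 6, n_pope = 6, n_chl = 4, n_frames = 3,
                         sigma = 0.1, seed = 2)
  tr <- synthesize_trajectory(spec)
  lf3 <- assign_leaflets(tr$system, frame = 2)
  chl <- lf3$leaflet[lf3$class == "cholesterol"]
  expect_identical(unname(chl), unname(tr$truth$leaflet[2, ]))
  expect_error(
    assign_leaflets(build_bundle(one_helix_spec(n_frames = 1, n_chl = 0))),
    "no lipids")
})

test_that("occupancy reports and CSV round-trip preserve values", {
  spec <- one_helix_spec(
    n_res = 16, n_frames = 50, n_chl = 1,
    schedule = list(list(mol = 1, region = "H1", frames = 1:13,
                         target_residue = 8)))
  tr <- synthesize_trajectory(spec)
  ser <- region_contact_series(tr$system, spec_regions(spec))
  rep <- occupancy_report(ser, "toy", helix_regions = "H1")
  f <- tempfile(fileext = ".csv")
  write_occupancy_table(rep, f)
  back <- read_occupancy_table(f)
  expect_equal(back[["H1"]], 26.0)
  expect_equal(back$system, "toy")
})
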