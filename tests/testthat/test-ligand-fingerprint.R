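# Ligand fingerprint: contact fractions, binder classes, H-bond occupancy.

holo_mini <- function(n_frames = 200, sigma = 0.05, seed = 9) {
  one_helix_spec(
    n_res = 20, n_frames = n_frames, n_chl = 0, sigma = sigma, clip = 0.18,
    seed = seed,
    ligand_schedule = list(
      contacts = list(`4` = seq_len(round(0.903 * n_frames)),
                      `10` = seq_len(n_frames),
                      `16` = seq_len(round(0.5 * n_frames))),
      hbond = list(residue = 10, frames = seq_len(round(0.6 * n_frames)))))
}

test_that("residue contact fractions match the schedule and a direct oracle", {
  spec <- holo_mini()
  tr <- synthesize_trajectory(spec)
  n <- spec$n_frames
  fr <- residue_contact_fractions(tr$system)
  expect_equal(unname(fr["4"]), round(0.903 * n) / n, tolerance = 1e-9)
  expect_equal(unname(fr["10"]), 1.0)
  expect_equal(unname(fr["16"]), 0.5)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(unname(fr[names(tr$truth$ligand_fraction)]),
               unname(tr$truth$ligand_fraction))

  # all-pairs oracle on a handful of frames
  atoms <- tr$system$atoms
  lig <- which(atoms$residue_name == "PK1" & atoms$is_heavy)
  for (f in c(1, 50, 150)) {
    xyz <- tr$system$frames[[f]]$xyz
    for (r in c(4, 10, 16, 7)) {
      ra <- which(atoms$chain == "A" & atoms$residue_index == r & atoms$is_heavy)
      expect_equal(
        bf_min_dist(xyz[lig, , drop = FALSE], xyz[ra, , drop = FALSE]) <= 4.5,
        r %in% c(4, 10, 16) &&
          f <= length(spec$ligand_schedule$contacts[[as.character(r)]]))
    }
  }
})

test_that("disjoint window fractions average to the full-trajectory fraction", {
  spec <- holo_mini(n_frames = 100)
  tr <- synthesize_trajectory(spec)
  full <- residue_contact_fractions(tr$system)
  w1 <- residue_contact_fractions(tr$system, window = c(0, 49))
  w2 <- residue_contact_fractions(tr$system, window = c(50, 99))
  n1 <- attr(w1, "frames"); n2 <- attr(w2, "frames")
  expect_equal(as.numeric((w1 * n1 + w2 * n2) / (n1 + n2)), as.numeric(full))
})

test_that("binder classification applies inclusive thresholds", {
  fr <- c(a = 0.95, b = 0.90, c = 0.89, d = 0.75, e = 0.7499, f = 0, g = 1)
  cl <- classify_binders(fr)
  expect_equal(unname(cl), c("constant", "constant", "frequent", "frequent",
                             "transient", "none", "constant"))
  # pure threshold function: permutation-invariant, idempotent
  perm <- sample(seq_along(fr))
  expect_equal(classify_binders(fr[perm]), cl[perm])
  expect_error(classify_binders(c(1.2)), "0, 1")
})

test_that("raising the contact cutoff never lowers any fraction", {
  spec <- holo_mini(n_frames = 60)
  tr <- synthesize_trajectory(spec)
  f1 <- residue_contact_fractions(tr$system, analysis_parameters(ligand_cutoff = 4.0))
  f2 <- residue_contact_fractions(tr$system, analysis_parameters(ligand_cutoff = 4.5))
  f3 <- residue_contact_fractions(tr$system, analysis_parameters(ligand_cutoff = 6.0))
  expect_true(all(f2 >= f1))
  expect_true(all(f3 >= f2))
})

test_that("hbond occupancy is a pure distance criterion", {
  mk <- function(d) {
    atoms <- rbind(tiny_atoms(1, name = "NE1", element = "N"),
                   tiny_atoms(1, name = "O1", element = "O", resno = 50,
                              resname = "PK1", chain = "B"))
    atoms$index <- 1:2
    tiny_system(atoms, lapply(0:4, function(t)
      list(time_ns = t, xyz = rbind(c(0, 0, 0), c(d, 0, 0)), box = NULL)))
  }
  expect_equal(as.numeric(hbond_occupancy(mk(3.4), 1L, 2L)), 1.0)
  expect_equal(as.numeric(hbond_occupancy(mk(3.6), 1L, 2L)), 0.0)

  spec <- holo_mini(n_frames = 100)
  tr <- synthesize_trajectory(spec)
  hb <- hbond_occupancy(tr$system, donor = list(residue = 10, atom = "CB"),
                        acceptor = list(residue = 400, atom = "O1"))
  expect_equal(as.numeric(hb), 0.6)
  expect_equal(as.numeric(hb), tr$truth$hbond_fraction)
  # direct per-frame distance oracle
  atoms <- tr$system$atoms
  di <- which(atoms$residue_index == 10 & atoms$name == "CB")
  ai <- which(atoms$name == "O1")
  d <- vapply(seq_len(n_frames(tr$system)), function(f) {
    x <- tr$system$frames[[f]]$xyz
    sqrt(sum((x[di, ] - x[ai, ])^2))
  }, numeric(1))
  expect_equal(as.numeric(hb), mean(d <= 3.5))
  expect_error(hbond_occupancy(tr$system, donor = list(residue = 99, atom = "CB"),
                               acceptor = ai), "not found")
})

test_that("fingerprint stage requires a ligand and reports consistently", {
  apo <- synthesize_trajectory(one_helix_spec(n_res = 10, n_frames = 3))
  expect_error(residue_contact_fractions(apo$system), "ligand")
  spec <- holo_mini(n_frames = 60)
  tr <- synthesize_trajectory(spec)
  rep <- fingerprint_report(tr$system,
                            windows = list(early = c(0, 29), late = c(30, 59)))
  expect_named(rep$fractions, c("early", "late"))
  expect_true(all(unlist(rep$fractions) >= 0 & unlist(rep$fractions) <= 1))
  f <- tempfile(fileext = ".csv")
  write_fingerprint_csv(rep, f)
  back <- utils::read.csv(f, comment.char = "#")
  expect_setequal(unique(back$window), c("early", "late"))
})
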