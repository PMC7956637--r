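# Kabsch superposition, RMSD/RMSF, PCA, bend profiles.

rand_rotation <- function() {
  ax <- rnorm(3)
  choltraj:::rotation_about(ax, runif(1, 0, 180))
}

test_that("Kabsch recovers rigid transforms exactly", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  s0 <- kabsch_superpose(P, P)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-8)
  R <- choltraj:::rotation_about(c(1, 2, 3), 37)
  Q <- sweep(P %*% R, 2, c(4, -1, 2), "+")
  s <- kabsch_superpose(P, Q)
  expect_lt(s$rmsd, 1e-10)
  expect_equal(s$rotation, R, tolerance = 1e-8)
  expect_equal(det(s$rotation), 1, tolerance = 1e-8)
  # reflection is corrected to a proper rotation
  Qm <- P %*% diag(c(-1, 1, 1))
  sm <- kabsch_superpose(P, Qm)
  expect_equal(det(sm$rotation), 1, tolerance = 1e-8)
  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "3 points")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("Kabsch RMSD equals a direct numerical-minimization oracle", {
  set.seed(2)
  for (rep in 1:6) {
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    got <- kabsch_superpose(P, Q)$rmsd
    obj <- function(par) {
      R <- choltraj:::rotation_about(c(1, 0, 0), par[1]) %*%
        choltraj:::rotation_about(c(0, 1, 0), par[2]) %*%
        choltraj:::rotation_about(c(0, 0, 1), par[3])
      M <- sweep(P, 2, colMeans(P)) %*% R
      sqrt(mean(rowSums((M - sweep(Q, 2, colMeans(Q)))^2)))
    }
    best <- Inf
    for (st in list(c(0, 0, 0), c(90, 0, 0), c(0, 120, 45), c(180, 60, -60),
                    c(-90, 30, 150), c(45, -120, 90))) {
      o <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
      best <- min(best, o$value)
    }
    expect_lt(abs(got - best), 1e-6)
    expect_lte(got, best + 1e-9)
  }
})

test_that("RMSD series is zero for rigid motion and invariant under rigid transforms", {
  spec <- one_helix_spec(n_res = 15, n_frames = 20, sigma = 0.1, seed = 3)
  tr <- synthesize_trajectory(spec)
  sel <- select_atoms(tr$system, backbone = TRUE, heavy_only = TRUE)

  static <- tr$system
  for (k in seq_len(n_frames(static))) static$frames[[k]]$xyz <- tr$system$frames[[1]]$xyz
  for (k in seq_len(n_frames(static))) static$frames[[k]]$time_ns <- k - 1
  expect_equal(rmsd_series(static, sel)$rmsd, rep(0, 20), tolerance = 1e-10)

  rigid <- static
  set.seed(4)
  for (k in 2:n_frames(rigid))
    rigid$frames[[k]]$xyz <- sweep(rigid$frames[[k]]$xyz %*% rand_rotation(),
                                   2, rnorm(3, 0, 10), "+")
  expect_equal(rmsd_series(rigid, sel)$rmsd, rep(0, 20), tolerance = 1e-8)

  base <- rmsd_series(tr$system, sel)$rmsd
  moved <- tr$system
  R <- rand_rotation(); tsl <- c(5, -3, 8)
  for (k in seq_len(n_frames(moved)))
    moved$frames[[k]]$xyz <- sweep(moved$frames[[k]]$xyz %*% R, 2, tsl, "+")
  expect_equal(rmsd_series(moved, sel)$rmsd, base, tolerance = 1e-8)

  # superposed RMSD never exceeds the unfitted RMSD
  for (k in 2:20) {
    raw <- sqrt(mean(rowSums((tr$system$frames[[k]]$xyz[sel, ] -
                                tr$system$frames[[1]]$xyz[sel, ])^2)))
    expect_lte(base[k], raw + 1e-12)
  }
})

test_that("RMSF matches closed forms and generator ground truth", {
  spec <- one_helix_spec(n_res = 12, n_frames = 10, sigma = 0)
  tr <- synthesize_trajectory(spec)
  ca <- select_atoms(tr$system, calpha = TRUE)
  expect_equal(rmsf_profile(tr$system, ca)$rmsf, rep(0, 12), tolerance = 1e-10)

  # one atom oscillating +-a along x, superposition disabled -> rmsf = a
  a <- 0.8
  atoms <- tiny_atoms(4, resno = 1:4)
  frames <- lapply(0:9, function(t) {
    xyz <- cbind(c(0, 3, 6, 9), 0, 0)
    xyz[2, 1] <- 3 + a * ifelse(t %% 2 == 0, 1, -1)
    list(time_ns = t, xyz = xyz, box = NULL)
  })
  sys <- tiny_system(atoms, frames)
  rf <- rmsf_profile(sys, 1:4, superpose = FALSE)
  expect_equal(rf$rmsf, c(0, a, 0, 0), tolerance = 1e-10)

  # Gaussian noise sigma: rmsf ~ sigma * sqrt(3) with the 6-dof fit correction
  sigma <- 0.12
  spec2 <- one_helix_spec(n_res = 40, n_frames = 400, sigma = sigma, seed = 8)
  tr2 <- synthesize_trajectory(spec2)
  ca2 <- select_atoms(tr2$system, calpha = TRUE)
  rf2 <- rmsf_profile(tr2$system, ca2)
  N <- length(ca2)
  expected <- sigma * sqrt(3) * sqrt(1 - 2 / N)
  se <- stats::sd(rf2$rmsf) / sqrt(N)
  expect_lt(abs(mean(rf2$rmsf) - expected), 3 * se)
  expect_error(rmsf_profile(tr2$system, ca2, window = c(0, 0)), "2 frames")
})

test_that("PCA satisfies the trace identity and recovers a rank-1 mode", {
  spec <- one_helix_spec(n_res = 12, n_frames = 30, sigma = 0.15, seed = 5)
  tr <- synthesize_trajectory(spec)
  ca <- select_atoms(tr$system, calpha = TRUE)
  p <- pca_modes(tr$system, ca)
  expect_lt(abs(sum(p$eigenvalues) - p$total_variance) /
              p$total_variance, 1e-6)
  expect_true(all(p$eigenvalues >= -1e-8))
  V <- p$eigenvectors
  expect_equal(t(V) %*% V, diag(ncol(V)), tolerance = 1e-8)

  # static trajectory -> all eigenvalues zero
  static <- tr$system
  for (k in seq_len(30)) {
    static$frames[[k]]$xyz <- tr$system$frames[[1]]$xyz
    static$frames[[k]]$time_ns <- k - 1
  }
  p0 <- pca_modes(static, ca)
  expect_lt(max(p0$eigenvalues), 1e-12)

  # single synthetic mode: one nonzero eigenvalue, eigenvector parallel.
  # The mode is built orthogonal to the rigid-body subspace, which the
  # superposition step projects out by construction.
  X0 <- tr$system$frames[[1]]$xyz[ca, ]
  Xc <- sweep(X0, 2, colMeans(X0))
  rigid <- matrix(0, 36, 6)
  for (k in 1:3) rigid[seq(k, 36, by = 3), k] <- 1
  for (i in 1:12) {
    rigid[(i - 1) * 3 + 1:3, 4] <- c(0, -Xc[i, 3], Xc[i, 2])
    rigid[(i - 1) * 3 + 1:3, 5] <- c(Xc[i, 3], 0, -Xc[i, 1])
    rigid[(i - 1) * 3 + 1:3, 6] <- c(-Xc[i, 2], Xc[i, 1], 0)
  }
  Qr <- qr.Q(qr(rigid))
  set.seed(6)
  mode <- rnorm(3 * 12)
  mode <- mode - Qr %*% (t(Qr) %*% mode)
  mode <- as.numeric(mode / sqrt(sum(mode^2)))
  amp <- sin(seq(0, 4 * pi, length.out = 30))
  onemode <- static
  base <- tr$system$frames[[1]]$xyz
  for (k in seq_len(30)) {
    d <- matrix(amp[k] * mode, ncol = 3, byrow = TRUE)
    onemode$frames[[k]]$xyz[ca, ] <- base[ca, ] + d
  }
  p1 <- pca_modes(onemode, ca)
  expect_gt(p1$eigenvalues[1], 1e-4)
  expect_lt(p1$eigenvalues[2] / p1$eigenvalues[1], 1e-4)
  expect_gt(abs(sum(p1$eigenvectors[, 1] * mode)), 0.99)
})

test_that("bend profiles: ideal helices are blue at every window size", {
  spec <- one_helix_spec(n_res = 24, n_frames = 2, sigma = 0)
  tr <- synthesize_trajectory(spec)
  for (w in 3:6) {
    bp <- bend_profile(tr$system, c(1, 24), axis_window = w)
    expect_true(all(bp$angles < 6))
    expect_true(all(bp$bins == "blue"))
  }
  expect_error(bend_profile(tr$system, c(1, 5)), "short")
})

test_that("synthetic kinks are recovered at the right angle and bin", {
  bins <- c(`5` = "blue", `10` = "cyan", `15` = "green", `20` = "yellow",
            `30` = "red")
  for (ang in as.numeric(names(bins))) {
    spec <- one_helix_spec(n_res = 24, n_frames = 2, sigma = 0,
                           kink_pos = 12, kink_angle = ang)
    tr <- synthesize_trajectory(spec)
    bp <- bend_profile(tr$system, c(1, 24))
    i <- which.max(bp$angles[1, ])
    expect_equal(bp$angles[1, i], ang, tolerance = 0.5)
    expect_equal(bp$bins[1, i], unname(bins[as.character(ang)]))
  }
})

test_that("make_kinked_helix limits and the zero-angle identity", {
  ideal <- make_kinked_helix(20)
  zero <- make_kinked_helix(20, 10, 0)
  expect_equal(ideal, zero, tolerance = 1e-6)
  d <- sqrt(rowSums(diff(ideal)^2))
  expect_true(all(abs(d - 3.8) < 0.05))
  expect_error(make_kinked_helix(20, 10, 95), "90")
  expect_error(make_kinked_helix(20, 25, 30), "inside")
})
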