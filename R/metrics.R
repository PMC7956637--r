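# Structural stability metrics: Kabsch superposition, RMSD/RMSF series,
# coordinate PCA and helix bend-angle profiles.

#' Kabsch least-squares superposition
#'
#' Optimal rigid superposition of point set `P` onto `Q` (row-vector
#' convention: the aligned coordinates are `P %*% rotation`, translated by
#' `translation`). The reflection case is corrected so the rotation is always
#' proper (determinant +1).
#'
#' @param P,Q Numeric n x 3 matrices, n >= 3, equal sizes, non-degenerate.
#' @param weights Optional non-negative per-point weights.
#' @return A `superposition` object: list with `rotation` (3 x 3,
#'   determinant +1), `translation` (length 3), `rmsd` (Angstrom) and
#'   `align`, a function mapping an m x 3 matrix through the fitted transform.
#' @export
kabsch_superpose <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stopf("P and Q must be equal-sized n x 3 matrices")
  n <- nrow(P)
  if (n < 3L) stopf("superposition needs at least 3 points")
  w <- if (is.null(weights)) rep(1, n) else {
    if (length(weights) != n || any(weights < 0)) stopf("invalid weights")
    weights
  }
  W <- sum(w)
  cp <- colSums(P * w) / W
  cq <- colSums(Q * w) / W
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- t(Pc * w) %*% Qc
  s <- svd(H)
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2)
    stopf("degenerate (collinear) point set")
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  resid <- Pc %*% R - Qc
  rmsd <- sqrt(sum(w * rowSums(resid^2)) / W)
  translation <- cq - as.numeric(cp %*% R)
  align <- function(X) sweep(as.matrix(X) %*% R, 2, translation, "+")
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 align = align),
            class = "superposition")
}

#' Per-frame RMSD series
#'
#' Each frame's selection is superposed onto the reference frame's selection
#' (Kabsch), then the RMSD is computed on that selection. The conventional
#' choice for the protein is the heavy backbone atoms of the core residue
#' range, excluding the termini.
#'
#' @param system A `molecular_system`.
#' @param selection Integer atom indices (non-empty).
#' @param reference_frame Frame number used as reference (default 1).
#' @return Data frame with `frame`, `time_ns`, `rmsd`.
#' @export
rmsd_series <- function(system, selection, reference_frame = 1L) {
  if (length(selection) == 0L) stopf("empty selection")
  ref <- system$frames[[reference_frame]]$xyz[selection, , drop = FALSE]
  r <- vapply(seq_len(n_frames(system)), function(f) {
    kabsch_superpose(system$frames[[f]]$xyz[selection, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(system)), time_ns = frame_times(system),
             rmsd = r)
}

# Superpose selected coordinates of all frames onto their iteratively refined
# average (2 passes); returns list(coords = list of n x 3, mean = n x 3).
#' @noRd
superpose_to_mean <- function(system, selection, frames, passes = 2L) {
  coords <- lapply(frames, function(f)
    system$frames[[f]]$xyz[selection, , drop = FALSE])
  ref <- coords[[1]]
  for (p in seq_len(passes)) {
    fitted <- lapply(coords, function(X) {
      s <- kabsch_superpose(X, ref)
      s$align(X)
    })
    ref <- Reduce(`+`, fitted) / length(fitted)
    coords <- fitted
  }
  list(coords = coords, mean = ref)
}

#' Per-residue RMSF profile
#'
#' Root mean squared fluctuation about the window-average structure after
#' iterative superposition (2 passes), typically computed for the C-alpha
#' atoms over the equilibrated part of the trajectory.
#'
#' @param system A `molecular_system`.
#' @param selection Integer atom indices (e.g. C-alpha atoms).
#' @param window `c(start_ns, end_ns)` time window, or `NULL` for all frames.
#' @param superpose Set `FALSE` to skip the superposition (fluctuations in
#'   the raw frame).
#' @return Data frame with `atom`, `residue_index`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(system, selection, window = NULL, superpose = TRUE) {
  frames <- frames_in_window(system, window)
  if (length(frames) < 2L) stopf("RMSF window must contain at least 2 frames")
  if (superpose) {
    sp <- superpose_to_mean(system, selection, frames)
    coords <- sp$coords; m <- sp$mean
  } else {
    coords <- lapply(frames, function(f)
      system$frames[[f]]$xyz[selection, , drop = FALSE])
    m <- Reduce(`+`, coords) / length(coords)
  }
  dev2 <- Reduce(`+`, lapply(coords, function(X) rowSums((X - m)^2))) /
    length(coords)
  data.frame(atom = selection,
             residue_index = system$atoms$residue_index[selection],
             rmsf = sqrt(dev2))
}

#' Principal component analysis of coordinate fluctuations
#'
#' Frames are superposed onto their window-average on the selection, then the
#' 3N-dimensional coordinate covariance is eigendecomposed (via SVD of the
#' centered frame matrix). Eigenvalues are reported in descending order in
#' squared Angstrom; their sum equals the total coordinate variance.
#'
#' @param system A `molecular_system` with at least 2 frames in the window.
#' @param selection Integer atom indices (typically C-alpha of the core
#'   residue range).
#' @param window Optional `c(start_ns, end_ns)` window.
#' @param ncomp Number of components to return (default: all available;
#'   truncated with a warning if more are requested than frames support).
#' @return A `pca_modes` object: list with `eigenvalues` (all, descending,
#'   zero-padded to 3N), `eigenvectors` (3N x ncomp, orthonormal),
#'   `projections` (frames x ncomp), `total_variance`, `frames`.
#' @export
pca_modes <- function(system, selection, window = NULL, ncomp = NULL) {
  frames <- frames_in_window(system, window)
  if (length(frames) < 2L) stopf("PCA needs at least 2 frames")
  sp <- superpose_to_mean(system, selection, frames)
  X <- do.call(rbind, lapply(sp$coords, function(M) as.numeric(t(M))))
  X <- sweep(X, 2, colMeans(X))
  F <- nrow(X); D <- ncol(X)
  s <- svd(X)
  eig <- s$d^2 / (F - 1)
  eigfull <- c(eig, rep(0, max(0, D - length(eig))))
  avail <- sum(s$d > 1e-12)
  k <- ncomp %||% length(s$d)
  if (k > length(s$d)) {
    warnf("only %d components available; truncating", length(s$d))
    k <- length(s$d)
  }
  structure(list(eigenvalues = eigfull,
                 eigenvectors = s$v[, seq_len(k), drop = FALSE],
                 projections = (X %*% s$v)[, seq_len(k), drop = FALSE],
                 total_variance = sum(X^2) / (F - 1),
                 rank = avail, frames = frames),
            class = "pca_modes")
}

# ---------------------------------------------------------------------------
# Helix bend profile

# Local helix axis from a C-alpha quadruple: for an ideal helix the
# differences of successive chords are exactly radial, so their cross product
# is exactly the axis direction.
#' @noRd
quad_axes <- function(ca) {
  n <- nrow(ca)
  m <- n - 3L
  axes <- matrix(NA_real_, m, 3)
  valid <- logical(m)
  chain <- ca[n, ] - ca[1, ]
  for (j in seq_len(m)) {
    v1 <- ca[j + 1, ] - ca[j, ]
    v2 <- ca[j + 2, ] - ca[j + 1, ]
    v3 <- ca[j + 3, ] - ca[j + 2, ]
    n1 <- v2 - v1
    n2 <- v3 - v2
    ax <- cross3(n1, n2)
    na <- vnorm(ax)
    if (na < 1e-9) next
    ax <- ax / na
    if (sum(ax * (ca[j + 3, ] - ca[j, ])) < 0) ax <- -ax
    axes[j, ] <- ax
    lens <- c(vnorm(v1), vnorm(v2), vnorm(v3))
    turn <- vec_angle(n1, n2)
    # helical-geometry validity: chords ~3.8 A, radial turn ~100 deg/residue
    valid[j] <- all(lens > 2.8 & lens < 4.8) && turn > 60 && turn < 140
  }
  list(axes = axes, valid = valid)
}

# Componentwise median of valid axes in an index window, normalized.
#' @noRd
window_axis <- function(qa, idx) {
  idx <- idx[idx >= 1 & idx <= nrow(qa$axes)]
  idx <- idx[!is.na(qa$axes[idx, 1])]
  if (length(idx) == 0L) return(NULL)
  use <- idx[qa$valid[idx]]
  if (length(use) == 0L) use <- idx
  v <- apply(qa$axes[use, , drop = FALSE], 2, stats::median)
  if (vnorm(v) < 1e-9) return(NULL)
  unit(v)
}

# Bend angles along one C-alpha trace. Position p (1-based along the helix)
# gets the angle between the aggregated local axis of the w quadruples ending
# at p and the w quadruples starting after p.
#' @noRd
bend_angles_trace <- function(ca, w) {
  n <- nrow(ca)
  qa <- quad_axes(ca)
  m <- n - 3L
  pos <- seq.int(4L, n - 4L)
  ang <- rep(NA_real_, length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    left <- window_axis(qa, seq.int(p - 3L - w + 1L, p - 3L))
    right <- window_axis(qa, seq.int(p + 1L, min(m, p + w)))
    if (is.null(left) || is.null(right)) next
    ang[i] <- vec_angle(left, right)
  }
  list(positions = pos, angles = ang)
}

#' Bin label for a bend angle
#'
#' The five-colour convention: blue below 6 degrees, cyan 6-12, green 12-18,
#' yellow 18-24, red above 24.
#'
#' @param angle Numeric vector of angles in degrees.
#' @param edges Bin edges (default `c(6, 12, 18, 24)`).
#' @return Character vector of labels.
#' @export
bend_bin_label <- function(angle, edges = c(6, 12, 18, 24)) {
  ifelse(is.na(angle), NA_character_,
  ifelse(angle < edges[1], "blue",
  ifelse(angle < edges[2], "cyan",
  ifelse(angle < edges[3], "green",
  ifelse(angle <= edges[4], "yellow", "red")))))
}

#' Helix bend-angle profile
#'
#' Per-frame, per-position bend angles of a helix from sliding-window local
#' axes of the C-alpha trace (window default 4). The local axis of each
#' C-alpha quadruple is the exact helix-axis construction (cross product of
#' successive chord differences), aggregated over the window by a robust
#' componentwise median; the bend angle at a position is the angle between
#' the local axes before and after it. Both the instantaneous angles and the
#' change relative to the first analyzed frame are returned; each value gets
#' a colour-bin label.
#'
#' @param system A `molecular_system`.
#' @param helix_residues `c(start, end)` residue range of the helix (needs at
#'   least `2 * axis_window` C-alpha atoms).
#' @param axis_window Sliding-window size in quadruples (default 4).
#' @param params [analysis_parameters()] (bin edges).
#' @param frames Frames to analyze (default all).
#' @return A `bend_profile` object: list with `residues` (positions, residue
#'   numbering), `angles` and `delta_angles` (frames x positions matrices,
#'   degrees), `bins` and `delta_bins` (label matrices), `times`.
#' @export
bend_profile <- function(system, helix_residues, axis_window = 4L,
                         params = analysis_parameters(), frames = NULL) {
  ca <- select_atoms(system, residue_range = helix_residues, calpha = TRUE,
                     molecule_class = "protein")
  n <- length(ca)
  if (n < 2L * axis_window) stopf("helix too short: %d C-alpha for window %d",
                                  n, axis_window)
  if (n < 8L) stopf("helix too short for quadruple axes")
  frames <- frames %||% seq_len(n_frames(system))
  res_idx <- system$atoms$residue_index[ca]
  first <- bend_angles_trace(system$frames[[frames[1]]]$xyz[ca, , drop = FALSE],
                             axis_window)
  pos <- first$positions
  A <- matrix(NA_real_, length(frames), length(pos))
  A[1, ] <- first$angles
  if (length(frames) > 1L) {
    for (k in 2:length(frames)) {
      A[k, ] <- bend_angles_trace(
        system$frames[[frames[k]]]$xyz[ca, , drop = FALSE], axis_window)$angles
    }
  }
  D <- sweep(A, 2, A[1, ])
  structure(list(residues = res_idx[pos],
                 angles = A,
                 delta_angles = D,
                 bins = matrix(bend_bin_label(A, params$bend_bins), nrow(A)),
                 delta_bins = matrix(bend_bin_label(abs(D), params$bend_bins),
                                     nrow(D)),
                 times = frame_times(system)[frames],
                 axis_window = axis_window),
            class = "bend_profile")
}
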