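# Synthetic membrane-protein trajectory generator with exact ground truth.
#
# The generator emits a five-helix bundle in an implicit bilayer slab with a
# POPC/POPE/cholesterol-like molecule population, cholesterol molecules
# entering and leaving contact with named residue regions on a deterministic
# or two-state Markov schedule, an optional bound ligand with prescribed
# per-residue contact residence, and rigid-body drift plus bounded thermal
# noise. Every downstream statistic is known exactly by construction: bound
# placements sit at cutoff minus a margin, unbound ones beyond cutoff plus a
# margin, and the per-atom noise displacement is norm-clipped so labels can
# never cross a cutoff.

HELIX_RISE <- 1.5    # A per residue
HELIX_TWIST <- 100   # degrees per residue
HELIX_CA_RADIUS <- 2.3

#' Default five-helix layout mirroring the hTSPO transmembrane ranges
#'
#' @return List of helix definitions (`name`, `start`, `length`, `direction`,
#'   `kink_pos`, `kink_angle`).
#' @export
default_helices <- function() {
  mk <- function(name, start, len, dir)
    list(name = name, start = start, length = len, direction = dir,
         kink_pos = NULL, kink_angle = 0)
  list(mk("TM I", 5, 21, 1), mk("TM II", 47, 21, -1), mk("TM III", 79, 23, 1),
       mk("TM IV", 110, 24, -1), mk("TM V", 134, 24, 1))
}

#' Specification for a synthetic trajectory
#'
#' Defaults emulate the simulated TSPO systems: five transmembrane helices, a
#' 3:3:1 POPC:POPE:cholesterol lipid population, 1000 frames at 1 ns stride
#' (the normalization used for all percentage statistics), and a small
#' thermal jitter.
#'
#' @param helices Helix definitions (see [default_helices()]); each may carry
#'   a `kink_pos` (absolute residue) and `kink_angle` (degrees).
#' @param bundle_radius Radius (A) of the circle on which helices sit.
#' @param n_popc,n_pope,n_chl Lipid counts per class (default 30/30/10, the
#'   3:3:1 mix).
#' @param chol_schedule List of entries
#'   `list(mol =, region =, frames = | k_on =, k_off =, target_residue =)`.
#'   Deterministic entries give explicit frame numbers; Markov entries give
#'   per-frame on/off transition probabilities.
#' @param ligand_schedule `NULL` (apo) or
#'   `list(contacts = list("<residue>" = frames, ...), hbond = list(residue =,
#'   frames =))`; at most 8 residues may be scheduled in the same frame (one
#'   per ligand heavy atom).
#' @param n_frames,stride_ns Frame count and stride.
#' @param sigma Thermal noise, standard deviation per coordinate (A).
#' @param clip Maximum per-atom displacement norm (A); must stay below half
#'   the placement margins so contact labels are preserved exactly.
#' @param rmsf_sigma Optional named vector residue -> sigma overriding `sigma`
#'   for protein residues.
#' @param drift `list(rot_deg =, trans =)`: rigid z-rotation (degrees) and
#'   translation (A) ramped linearly over the trajectory.
#' @param regions Extra named residue ranges (motifs) beyond the helices.
#' @param sequence Optional character vector of one-letter codes indexed by
#'   residue number (default all alanine).
#' @param params [analysis_parameters()] supplying the cutoffs that placement
#'   margins are measured against.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(helices = default_helices(), bundle_radius = 16,
                           n_popc = 30, n_pope = 30, n_chl = 10,
                           chol_schedule = list(), ligand_schedule = NULL,
                           n_frames = 1000, stride_ns = 1,
                           sigma = 0.12, clip = 0.45, rmsf_sigma = NULL,
                           drift = list(rot_deg = 8, trans = c(2, 1, 0.5)),
                           regions = NULL, sequence = NULL,
                           params = analysis_parameters(), seed = 1L) {
  if (n_frames < 1 || n_popc < 0 || n_pope < 0 || n_chl < 0)
    stopf("counts must be non-negative and n_frames >= 1")
  if (sigma < 0 || clip <= 0) stopf("sigma >= 0 and clip > 0 required")
  bound_margin <- 1; unbound_margin <- 2
  if (sigma > 0) {
    if (2 * clip >= bound_margin)
      stopf("noise clip %.2f A too large for the %.1f A placement margin",
            clip, bound_margin)
    if (!is.null(ligand_schedule) && !is.null(ligand_schedule$hbond)) {
      band <- (params$ligand_cutoff - params$hbond_cutoff) / 2
      if (2 * clip >= band)
        stopf("noise clip %.2f A too large for the H-bond/contact band (%.2f A)",
              clip, band)
    }
    if (clip < 2.5 * sigma)
      warnf("clip %.2f < 2.5 sigma: noise is visibly truncated", clip)
  }
  structure(list(helices = helices, bundle_radius = bundle_radius,
                 n_popc = n_popc, n_pope = n_pope, n_chl = n_chl,
                 chol_schedule = chol_schedule,
                 ligand_schedule = ligand_schedule,
                 n_frames = as.integer(n_frames), stride_ns = stride_ns,
                 sigma = sigma, clip = clip, rmsf_sigma = rmsf_sigma,
                 drift = drift, regions = regions, sequence = sequence,
                 params = params, seed = as.integer(seed),
                 bound_margin = bound_margin, unbound_margin = unbound_margin),
            class = "synthetic_spec")
}

#' Helix residue ranges of a spec
#' @param spec A `synthetic_spec`.
#' @return A [region_definition()] with one range per helix.
#' @export
spec_helix_regions <- function(spec) {
  rg <- lapply(spec$helices, function(h) c(h$start, h$start + h$length - 1L))
  names(rg) <- vapply(spec$helices, `[[`, character(1), "name")
  region_definition(rg)
}

#' All named regions of a spec (helices plus extra motif regions)
#' @param spec A `synthetic_spec`.
#' @return A [region_definition()].
#' @export
spec_regions <- function(spec) {
  rg <- as_region_list(spec_helix_regions(spec))
  if (!is.null(spec$regions)) rg <- c(rg, as_region_list(spec$regions))
  region_definition(rg)
}

# ---------------------------------------------------------------------------
# Geometry builders

# All-atom ideal helix in a local frame (axis +z from z = 0), 6 atoms per
# residue (N, CA, C, O, CB, HN), optionally kinked: residues past the kink
# are rigidly rotated about the kink C-alpha around its radial direction.
#' @noRd
helix_atoms_local <- function(n_res, kink_local = NULL, kink_angle = 0) {
  offs <- list(N = c(-0.3, 0.8, -1.0), CA = c(0, 0, 0), C = c(-0.3, -0.8, 1.0),
               O = c(-0.9, -1.0, 2.1), CB = c(1.5, 0, 0), HN = c(-0.3, 1.3, -1.9))
  elems <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C", HN = "H")
  coords <- matrix(0, n_res * 6L, 3)
  name <- character(n_res * 6L)
  resloc <- integer(n_res * 6L)
  k <- 0L
  for (i in seq_len(n_res)) {
    phi <- (i - 1) * HELIX_TWIST * pi / 180
    u <- c(cos(phi), sin(phi), 0)
    a <- c(0, 0, 1)
    t <- cross3(a, u)
    ca <- HELIX_CA_RADIUS * u + c(0, 0, (i - 1) * HELIX_RISE)
    for (nm in names(offs)) {
      k <- k + 1L
      o <- offs[[nm]]
      coords[k, ] <- ca + o[1] * u + o[2] * t + o[3] * a
      name[k] <- nm
      resloc[k] <- i
    }
  }
  if (!is.null(kink_local) && kink_angle != 0) {
    if (kink_angle < 0 || kink_angle >= 90)
      stopf("kink angle must lie in [0, 90) degrees")
    if (kink_local <= 0 || kink_local >= n_res)
      stopf("kink position must be inside the helix")
    phi <- (kink_local - 1) * HELIX_TWIST * pi / 180
    axis <- c(cos(phi), sin(phi), 0)  # radial direction at the kink residue
    pivot <- HELIX_CA_RADIUS * axis + c(0, 0, (kink_local - 1) * HELIX_RISE)
    R <- rotation_about(axis, kink_angle)
    sel <- resloc > kink_local
    coords[sel, ] <- sweep(sweep(coords[sel, , drop = FALSE], 2, pivot) %*% R,
                           2, pivot, "+")
  }
  list(coords = coords, name = name, element = unname(elems[name]),
       resloc = resloc)
}

#' C-alpha coordinates of an ideal or kinked helix
#'
#' Two ideal helical segments (1.5 A rise, 100 degrees twist per residue)
#' joined with the specified inter-axis angle at the kink residue. A kink
#' angle of 0 gives the ideal straight helix.
#'
#' @param n_res Number of residues.
#' @param kink_position Residue (1-based within the helix) at which the helix
#'   bends; the following residues are rotated. `NULL` for no kink.
#' @param kink_angle Inter-axis angle in degrees, `0 <= angle < 90`.
#' @return `n_res` x 3 matrix of C-alpha coordinates (A).
#' @export
make_kinked_helix <- function(n_res, kink_position = NULL, kink_angle = 0) {
  h <- helix_atoms_local(n_res, kink_position, kink_angle)
  h$coords[h$name == "CA", , drop = FALSE]
}

# Template assembly: returns list(atoms = data.frame, xyz = matrix, aux = ...)
#' @noRd
build_template <- function(spec) {
  nh <- length(spec$helices)
  blocks <- list()
  helix_center <- list()
  for (hi in seq_len(nh)) {
    h <- spec$helices[[hi]]
    kl <- if (!is.null(h$kink_pos)) h$kink_pos - h$start + 1L else NULL
    loc <- helix_atoms_local(h$length, kl, h$kink_angle %||% 0)
    xyz <- loc$coords
    xyz[, 3] <- xyz[, 3] - (h$length - 1) * HELIX_RISE / 2  # center z
    if ((h$direction %||% 1) < 0) {  # flip through 180 deg about x
      xyz[, 2] <- -xyz[, 2]; xyz[, 3] <- -xyz[, 3]
    }
    th <- 2 * pi * (hi - 1) / nh
    cx <- spec$bundle_radius * cos(th)
    cy <- spec$bundle_radius * sin(th)
    xyz[, 1] <- xyz[, 1] + cx
    xyz[, 2] <- xyz[, 2] + cy
    resno <- h$start + loc$resloc - 1L
    rn <- if (is.null(spec$sequence)) rep("ALA", length(resno)) else {
      aa1 <- spec$sequence[resno]
      aa1[is.na(aa1)] <- "A"
      names(AA3)[match(aa1, AA3)]
    }
    blocks[[length(blocks) + 1L]] <- list(
      atoms = data.frame(name = loc$name, element = loc$element,
                         residue_index = resno, residue_name = rn,
                         chain = "A", stringsAsFactors = FALSE),
      xyz = xyz)
    for (r in unique(resno)) helix_center[[as.character(r)]] <- c(cx, cy)
  }
  # inter-helix clash check
  for (i in seq_len(nh)) for (j in seq_len(nh)) if (j > i) {
    if (min_dist2_block(blocks[[i]]$xyz, blocks[[j]]$xyz) < 4)
      stopf("helices %d and %d overlap (atom pair closer than 2 A)", i, j)
  }
  z_top <- max(vapply(blocks, function(b) max(b$xyz[, 3]), numeric(1)))

  # cholesterol parked slots (5 heavy atoms along z, O3 is the reference)
  chol_park <- list()
  if (spec$n_chl > 0) for (m in seq_len(spec$n_chl)) {
    phi <- 2 * pi * (m - 0.5) / spec$n_chl
    zb <- if (m %% 2 == 1) 10 else -10
    base <- c(40 * cos(phi), 40 * sin(phi), zb)
    xyz <- t(vapply(1:5, function(i) base + c(0, 0, (i - 3) * 2), numeric(3)))
    chol_park[[m]] <- xyz
    blocks[[length(blocks) + 1L]] <- list(
      atoms = data.frame(name = c("O3", "C1", "C2", "C3", "C4"),
                         element = c("O", "C", "C", "C", "C"),
                         residue_index = 200L + m, residue_name = "CHL",
                         chain = "L", stringsAsFactors = FALSE),
      xyz = xyz)
  }
  # phospholipids, static two-leaflet rings
  npl <- spec$n_popc + spec$n_pope
  if (npl > 0) for (l in seq_len(npl)) {
    r <- 26 + 4 * ((l - 1) %% 3)
    phi <- 2 * pi * l * 0.381966
    zs <- if (l %% 2 == 1) 1 else -1
    xyz <- cbind(rep(r * cos(phi), 4), rep(r * sin(phi), 4),
                 zs * c(12, 9, 6, 3))
    blocks[[length(blocks) + 1L]] <- list(
      atoms = data.frame(name = c("P", "C1", "C2", "C3"),
                         element = c("P", "C", "C", "C"),
                         residue_index = 300L + l,
                         residue_name = if (l <= spec$n_popc) "POPC" else "POPE",
                         chain = "L", stringsAsFactors = FALSE),
      xyz = xyz)
  }
  # ligand parked high above the bundle
  lig_park <- NULL
  if (!is.null(spec$ligand_schedule)) {
    lig_park <- cbind(2 * (1:8) - 9, 0, z_top + 12)
    blocks[[length(blocks) + 1L]] <- list(
      atoms = data.frame(name = c("O1", "N1", paste0("C", 1:6)),
                         element = c("O", "N", rep("C", 6)),
                         residue_index = 400L, residue_name = "PK1",
                         chain = "B", stringsAsFactors = FALSE),
      xyz = lig_park)
  }
  atoms <- do.call(rbind, lapply(blocks, `[[`, "atoms"))
  xyz <- do.call(rbind, lapply(blocks, `[[`, "xyz"))
  atoms$index <- seq_len(nrow(atoms))
  atoms$is_heavy <- toupper(atoms$element) != "H"
  atoms <- atoms[, c("index", "name", "element", "is_heavy", "residue_index",
                     "residue_name", "chain")]
  list(atoms = atoms, xyz = unname(xyz), helix_center = helix_center,
       chol_park = chol_park, lig_park = lig_park, z_top = z_top)
}

#' Build the synthetic bundle (single frame)
#'
#' Constructs the five-helix bundle with its lipid population and (if a
#' ligand schedule is present) the parked ligand, as a single-frame
#' classified system. Deterministic for a given spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A `molecular_system` with one frame.
#' @export
build_bundle <- function(spec) {
  tpl <- build_template(spec)
  atoms <- tpl$atoms
  atoms$molecule_id <- assign_molecule_ids(atoms)
  sys <- new_molecular_system(atoms,
                              list(list(time_ns = 0, xyz = tpl$xyz, box = NULL)))
  classify_molecules(sys, quiet = TRUE)
}

# ---------------------------------------------------------------------------
# Schedules

# Resolve the cholesterol schedule to per-(molecule, region) logical vectors.
#' @noRd
resolve_chol_schedule <- function(spec) {
  rg <- as_region_list(spec_regions(spec))
  out <- list()
  for (e in spec$chol_schedule) {
    m <- e$mol
    if (m < 1 || m > spec$n_chl) stopf("scheduled cholesterol %s does not exist", m)
    if (!e$region %in% names(rg)) stopf("unknown region '%s' in schedule", e$region)
    on <- logical(spec$n_frames)
    if (!is.null(e$frames)) {
      f <- as.integer(e$frames)
      if (any(f < 1 | f > spec$n_frames)) stopf("schedule frames out of range")
      on[f] <- TRUE
    } else if (!is.null(e$k_on)) {
      p_on <- e$k_on / (e$k_on + e$k_off)
      s <- stats::runif(1) < p_on
      for (f in seq_len(spec$n_frames)) {
        on[f] <- s
        s <- if (s) stats::runif(1) >= e$k_off else stats::runif(1) < e$k_on
      }
    } else stopf("schedule entry needs frames or k_on/k_off")
    key <- as.character(m)
    out[[key]] <- out[[key]] %||% list()
    prev <- out[[key]][[e$region]] %||% logical(spec$n_frames)
    out[[key]][[e$region]] <- prev | on
    attr(out[[key]][[e$region]], "target") <-
      e$target_residue %||% floor((rg[[e$region]][1] + rg[[e$region]][2]) / 2)
  }
  out
}

# ---------------------------------------------------------------------------
# Trajectory synthesis

#' Synthesize a trajectory with exact ground truth
#'
#' Realizes the contact schedules exactly: a molecule scheduled as bound is
#' placed with its nearest heavy atom at cutoff minus 1 A from the target
#' residue, unbound molecules are parked far beyond cutoff plus 2 A, the
#' ligand's scheduled residues each receive a dedicated ligand atom at the
#' midpoint of the H-bond/contact band, and the H-bond frames place the
#' carbonyl oxygen well inside the H-bond cutoff. Ground-truth tables are
#' computed from the exact pre-noise, pre-drift coordinates by direct
#' distance evaluation; rigid drift preserves all internal distances and the
#' norm-clipped noise cannot move any pair across a cutoff, so the truth
#' holds for the emitted frames too. When `sigma > 0` the generator verifies
#' that no molecule-region distance falls inside the ambiguous band around a
#' cutoff and errors otherwise.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_trajectory` with elements `system` (a
#'   `molecular_system`), `truth` (ground-truth tables; see Details) and
#'   `spec`.
#' @details `truth` contains `contact` (frames x cholesterol x region logical
#'   array), `region_fraction`, `mean_per_frame`, `total_bound_events`,
#'   `ligand_fraction` (per residue), `hbond_fraction`, `leaflet` (frames x
#'   cholesterol labels plus the static lipid table), `kink_angles` and
#'   `rmsf_sigma`.
#' @export
synthesize_trajectory <- function(spec) {
  set.seed(spec$seed)
  tpl <- build_template(spec)
  atoms <- tpl$atoms
  rg <- as_region_list(spec_regions(spec))
  nf <- spec$n_frames
  p <- spec$params
  cc <- p$cholesterol_cutoff
  lc <- p$ligand_cutoff
  hc <- p$hbond_cutoff

  prot_heavy <- which(atoms$chain == "A" & atoms$is_heavy)
  reg_atoms <- lapply(rg, function(r)
    prot_heavy[atoms$residue_index[prot_heavy] >= r[1] &
               atoms$residue_index[prot_heavy] <= r[2]])
  chol_atoms <- lapply(seq_len(spec$n_chl), function(m)
    which(atoms$residue_index == 200L + m & atoms$chain == "L"))
  lig_atoms <- which(atoms$chain == "B")
  cb_of <- function(res) which(atoms$chain == "A" & atoms$residue_index == res &
                                 atoms$name == "CB")[1]
  # reference atoms for leaflet truth
  chol_ref <- vapply(chol_atoms, function(ai) ai[1], integer(1))
  phos_ref <- which(atoms$name == "P" & atoms$residue_name %in% c("POPC", "POPE"))

  sched <- resolve_chol_schedule(spec)
  lig <- spec$ligand_schedule
  lig_contacts <- if (!is.null(lig)) lig$contacts %||% list() else list()
  hb <- if (!is.null(lig)) lig$hbond else NULL
  d_chol <- cc - spec$bound_margin
  d_lig <- (hc + lc) / 2
  d_hb <- hc - 0.8

  radial_out <- function(res, pos) {
    ctr <- tpl$helix_center[[as.character(res)]]
    if (is.null(ctr)) return(unit(c(pos[1], pos[2], 0)))
    unit(c(pos[1] - ctr[1], pos[2] - ctr[2], 0))
  }

  contact <- array(FALSE, dim = c(nf, spec$n_chl, length(rg)),
                   dimnames = list(NULL, as.character(seq_len(spec$n_chl)),
                                   names(rg)))
  prot_res <- sort(unique(atoms$residue_index[prot_heavy]))
  lig_counts <- setNames(numeric(length(prot_res)), prot_res)
  hb_hits <- 0L
  leaflet_chol <- matrix(NA_character_, nf, spec$n_chl)
  frames <- vector("list", nf)
  band_lo_c <- cc - 2 * spec$clip; band_hi_c <- cc + 2 * spec$clip
  band_lo_l <- lc - 2 * spec$clip; band_hi_l <- lc + 2 * spec$clip

  pair_min <- function(xa, xb, skip_above) {
    gap <- max(max(apply(xa, 2, min) - apply(xb, 2, max)),
               max(apply(xb, 2, min) - apply(xa, 2, max)))
    if (gap > skip_above) return(Inf)
    sqrt(min_dist2_block(xa, xb))
  }

  rot_deg <- spec$drift$rot_deg %||% 0
  trans <- spec$drift$trans %||% c(0, 0, 0)

  for (f in seq_len(nf)) {
    xyz <- tpl$xyz
    # cholesterol placements
    for (m in seq_len(spec$n_chl)) {
      sc <- sched[[as.character(m)]]
      bound <- if (is.null(sc)) character(0) else
        names(sc)[vapply(sc, function(v) v[f], logical(1))]
      if (length(bound) > 5L) stopf("cholesterol %d bound to >5 regions", m)
      ai <- chol_atoms[[m]]
      if (length(bound) == 0L) {
        xyz[ai, ] <- tpl$chol_park[[m]]
      } else if (length(bound) == 1L) {
        tr <- attr(sc[[bound]], "target")
        tb <- xyz[cb_of(tr), ]
        base <- tb + d_chol * radial_out(tr, tb)
        xyz[ai, ] <- t(vapply(1:5, function(i) base + c(0, 0, (i - 3) * 2),
                              numeric(3)))
      } else {
        # bridging: one anchor atom per region, the rest interpolated
        anchors <- lapply(bound, function(rn) {
          tr <- attr(sc[[rn]], "target")
          tb <- xyz[cb_of(tr), ]
          tb + d_chol * radial_out(tr, tb)
        })
        p1 <- anchors[[1]]; p2 <- anchors[[length(anchors)]]
        pts <- t(vapply(seq_len(5), function(i)
          p1 + (i - 1) / 4 * (p2 - p1), numeric(3)))
        for (bi in seq_along(bound))
          pts[min(bi, 5L), ] <- anchors[[bi]]
        xyz[ai, ] <- pts
      }
    }
    # ligand placement
    if (!is.null(lig)) {
      sres <- sort(as.integer(names(lig_contacts)[
        vapply(lig_contacts, function(fr) f %in% fr, logical(1))]))
      hb_now <- !is.null(hb) && f %in% hb$frames
      if (hb_now && !(hb$residue %in% sres)) sres <- sort(c(sres, hb$residue))
      if (length(sres) > 8L)
        stopf("frame %d schedules %d ligand residues (max 8)", f, length(sres))
      xyz[lig_atoms, ] <- tpl$lig_park
      if (length(sres) > 0L) {
        if (!is.null(hb) && hb$residue %in% sres) {
          slots <- integer(length(sres))
          slots[sres == hb$residue] <- 1L
          slots[sres != hb$residue] <- seq_len(length(sres) - 1L) + 1L
        } else slots <- seq_along(sres)
        for (k in seq_along(sres)) {
          r <- sres[k]
          tb <- xyz[cb_of(r), ]
          d <- if (!is.null(hb) && r == hb$residue && hb_now) d_hb else d_lig
          xyz[lig_atoms[slots[k]], ] <- tb + d * radial_out(r, tb)
        }
      }
    }

    # ---- ground truth from exact pre-noise coordinates ----
    for (m in seq_len(spec$n_chl)) {
      xm <- xyz[chol_atoms[[m]], , drop = FALSE]
      for (ri in seq_along(rg)) {
        d <- pair_min(xm, xyz[reg_atoms[[ri]], , drop = FALSE], band_hi_c)
        if (spec$sigma > 0 && d > band_lo_c && d < band_hi_c)
          stopf("frame %d: cholesterol %d sits %.2f A from region %s, inside the ambiguous band",
                f, m, d, names(rg)[ri])
        contact[f, m, ri] <- d <= cc
      }
    }
    if (!is.null(lig)) {
      xl <- xyz[lig_atoms, , drop = FALSE]
      xp <- xyz[prot_heavy, , drop = FALSE]
      dmin2 <- rep(Inf, nrow(xp))
      for (j in seq_len(nrow(xl))) {
        d2 <- (xp[, 1] - xl[j, 1])^2 + (xp[, 2] - xl[j, 2])^2 +
          (xp[, 3] - xl[j, 3])^2
        dmin2 <- pmin(dmin2, d2)
      }
      dres <- tapply(sqrt(dmin2), atoms$residue_index[prot_heavy], min)
      if (spec$sigma > 0) {
        badr <- names(dres)[dres > band_lo_l & dres < band_hi_l]
        if (length(badr) > 0L)
          stopf("frame %d: ligand sits in the ambiguous band of residue %s",
                f, badr[1])
      }
      hit <- names(dres)[dres <= lc]
      lig_counts[hit] <- lig_counts[hit] + 1
      if (!is.null(hb)) {
        dh <- vnorm(xyz[lig_atoms[1], ] - xyz[cb_of(hb$residue), ])
        if (dh <= hc) hb_hits <- hb_hits + 1L
      }
    }
    ref_z <- xyz[c(chol_ref, phos_ref), 3]
    mid <- mean(ref_z)
    if (spec$n_chl > 0)
      leaflet_chol[f, ] <- ifelse(xyz[chol_ref, 3] >= mid, "upper", "lower")

    # ---- rigid drift + clipped thermal noise ----
    s <- if (nf > 1) (f - 1) / (nf - 1) else 0
    if (rot_deg != 0) xyz <- xyz %*% rotation_about(c(0, 0, 1), rot_deg * s)
    xyz <- sweep(xyz, 2, trans * s, "+")
    if (spec$sigma > 0) {
      sig <- rep(spec$sigma, nrow(atoms))
      if (!is.null(spec$rmsf_sigma)) {
        prot <- atoms$chain == "A"
        ov <- spec$rmsf_sigma[as.character(atoms$residue_index)]
        sig[prot & !is.na(ov)] <- ov[prot & !is.na(ov)]
      }
      noise <- matrix(stats::rnorm(3 * nrow(atoms)), ncol = 3) * sig
      nn <- sqrt(rowSums(noise^2))
      fac <- pmin(1, spec$clip / pmax(nn, 1e-12))
      xyz <- xyz + noise * fac
    }
    frames[[f]] <- list(time_ns = (f - 1) * spec$stride_ns, xyz = xyz,
                        box = NULL)
  }

  atoms$molecule_id <- assign_molecule_ids(atoms)
  sys <- classify_molecules(new_molecular_system(atoms, frames), quiet = TRUE)

  if (spec$n_chl > 0) {
    region_fraction <- apply(contact, 3, function(M)
      sum(rowSums(matrix(M, nrow = nf)) > 0) / nf)
    mean_pf <- apply(contact, 3, sum) / nf
  } else {
    region_fraction <- setNames(rep(0, length(rg)), names(rg))
    mean_pf <- region_fraction
  }
  bound_any <- if (spec$n_chl > 0) apply(contact, c(1, 2), any) else
    matrix(FALSE, nf, 0)
  kinks <- vapply(spec$helices, function(h) h$kink_angle %||% 0, numeric(1))
  names(kinks) <- vapply(spec$helices, `[[`, character(1), "name")
  rmsf_sig <- setNames(rep(spec$sigma, length(prot_res)), prot_res)
  if (!is.null(spec$rmsf_sigma)) {
    ov <- spec$rmsf_sigma[as.character(prot_res)]
    rmsf_sig[!is.na(ov)] <- ov[!is.na(ov)]
  }
  truth <- list(contact = contact,
                region_fraction = region_fraction,
                mean_per_frame = mean_pf,
                total_bound_events = sum(bound_any),
                ligand_fraction = if (!is.null(lig)) lig_counts / nf else NULL,
                hbond_fraction = if (!is.null(hb)) hb_hits / nf else NULL,
                leaflet = leaflet_chol,
                kink_angles = kinks,
                rmsf_sigma = rmsf_sig,
                frame_count = nf, stride_ns = spec$stride_ns)
  structure(list(system = sys, truth = truth, spec = spec),
            class = "synthetic_trajectory")
}
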