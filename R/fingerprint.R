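# Per-residue ligand interaction fingerprints: contact fractions,
# constant/frequent binder classes and the distance-criterion H-bond
# occupancy.

#' @noRd
ligand_heavy_atoms <- function(system) {
  lig <- molecules_of_class(system, "ligand")
  if (length(lig) == 0L) stopf("system contains no molecule of class 'ligand'")
  if (length(lig) > 1L) warnf("multiple ligand molecules; using molecule %d", lig[1])
  which(system$atoms$molecule_id == lig[1] & system$atoms$is_heavy)
}

#' @noRd
frames_in_window <- function(system, window) {
  t <- frame_times(system)
  if (is.null(window)) seq_along(t)
  else which(t >= window[1] & t <= window[2])
}

#' Per-residue ligand contact fractions
#'
#' For every protein residue, the fraction of frames (within the analysis
#' window) in which any heavy atom of the residue is within the ligand cutoff
#' of any ligand heavy atom.
#'
#' @param system A classified `molecular_system` containing a ligand.
#' @param params [analysis_parameters()] (uses `ligand_cutoff`).
#' @param window Optional `c(start_ns, end_ns)` time window (inclusive);
#'   default full trajectory. Split windows (e.g. before/after a binding-pose
#'   change) are supported by calling once per window.
#' @return Named numeric vector: contact fraction in `[0, 1]` per protein
#'   residue index, plus attributes `frames` (frames used) and `window`.
#' @export
residue_contact_fractions <- function(system, params = analysis_parameters(),
                                      window = NULL) {
  lat <- ligand_heavy_atoms(system)
  atoms <- system$atoms
  prot <- select_atoms(system, molecule_class = "protein", heavy_only = TRUE)
  resid <- atoms$residue_index[prot]
  resids <- sort(unique(resid))
  fsel <- frames_in_window(system, window)
  if (length(fsel) == 0L) stopf("analysis window contains no frames")
  cutoff2 <- params$ligand_cutoff^2
  counts <- setNames(numeric(length(resids)), resids)
  for (f in fsel) {
    xyz <- system$frames[[f]]$xyz
    xp <- xyz[prot, , drop = FALSE]
    dmin2 <- rep(Inf, nrow(xp))
    for (j in lat) {
      d2 <- (xp[, 1] - xyz[j, 1])^2 + (xp[, 2] - xyz[j, 2])^2 +
        (xp[, 3] - xyz[j, 3])^2
      dmin2 <- pmin(dmin2, d2)
    }
    touched <- unique(resid[dmin2 <= cutoff2])
    counts[as.character(touched)] <- counts[as.character(touched)] + 1
  }
  frac <- counts / length(fsel)
  attr(frac, "frames") <- length(fsel)
  attr(frac, "window") <- window
  frac
}

#' Classify residues by ligand contact fraction
#'
#' Pure threshold classification: fraction >= constant threshold (0.90) is
#' `constant`; frequent threshold (0.75) <= fraction < constant is
#' `frequent`; 0 < fraction < frequent is `transient`; 0 is `none`. Both
#' class boundaries are closed on the left (a fraction of exactly 0.90 is
#' constant, exactly 0.75 is frequent).
#'
#' @param fractions Numeric vector of fractions in `[0, 1]` (names kept).
#' @param params [analysis_parameters()].
#' @return Character vector of classes, same names as `fractions`.
#' @export
classify_binders <- function(fractions, params = analysis_parameters()) {
  if (any(fractions < 0 | fractions > 1)) stopf("fractions must lie in [0, 1]")
  out <- ifelse(fractions >= params$constant_binder_threshold, "constant",
         ifelse(fractions >= params$frequent_binder_threshold, "frequent",
         ifelse(fractions > 0, "transient", "none")))
  setNames(as.character(out), names(fractions))
}

#' Resolve a single atom by residue index and atom name
#' @noRd
resolve_atom <- function(system, residue, atom_name, molecule_class = NULL) {
  idx <- select_atoms(system, residue_range = c(residue, residue),
                      atom_names = atom_name, molecule_class = molecule_class,
                      allow_empty = TRUE)
  if (length(idx) == 0L)
    stopf("atom '%s' of residue %d not found", atom_name, residue)
  idx[1]
}

#' Distance-criterion hydrogen-bond occupancy
#'
#' Fraction of frames in which the donor-acceptor heavy-atom distance is
#' within the H-bond cutoff (3.5 A by default). Deliberately distance-only,
#' with no angular term. Donor and acceptor atoms are configuration, not
#' inferred from bonding; the canonical case is the tryptophan side-chain
#' nitrogen of the binding pocket versus the ligand carbonyl oxygen.
#'
#' @param system A `molecular_system`.
#' @param donor,acceptor Either an integer atom index, or
#'   `list(residue =, atom =)` resolved against the system.
#' @param params [analysis_parameters()] (uses `hbond_cutoff`).
#' @param window Optional `c(start_ns, end_ns)` window.
#' @return Fraction in `[0, 1]` with attribute `frames`.
#' @export
hbond_occupancy <- function(system, donor, acceptor,
                            params = analysis_parameters(), window = NULL) {
  as_idx <- function(a) {
    if (is.numeric(a)) {
      if (a < 1 || a > nrow(system$atoms)) stopf("atom index %d not found", a)
      as.integer(a)
    } else resolve_atom(system, a$residue, a$atom, a$class %||% NULL)
  }
  di <- as_idx(donor); ai <- as_idx(acceptor)
  if (!system$atoms$is_heavy[di] || !system$atoms$is_heavy[ai])
    stopf("H-bond occupancy is defined between heavy atoms")
  fsel <- frames_in_window(system, window)
  d <- vapply(fsel, function(f) {
    xyz <- system$frames[[f]]$xyz
    vnorm(xyz[di, ] - xyz[ai, ])
  }, numeric(1))
  frac <- mean(d <= params$hbond_cutoff)
  attr(frac, "frames") <- length(fsel)
  frac
}

#' Build a fingerprint report
#'
#' Combines contact fractions (optionally per split window), binder classes
#' and H-bond occupancies into one report.
#'
#' @param system A classified `molecular_system` with a ligand.
#' @param params [analysis_parameters()].
#' @param windows Named list of `c(start_ns, end_ns)` windows; `NULL` for the
#'   full trajectory only.
#' @param hbonds Optional named list of `list(donor =, acceptor =)` pairs
#'   (see [hbond_occupancy()]).
#' @return A `fingerprint_report`: list with `fractions` (per window),
#'   `classes` (per window), `hbond` occupancies and the parameters used.
#' @export
fingerprint_report <- function(system, params = analysis_parameters(),
                               windows = NULL, hbonds = NULL) {
  wlist <- if (is.null(windows)) list(full = NULL) else windows
  fr <- lapply(wlist, function(w) residue_contact_fractions(system, params, w))
  cl <- lapply(fr, classify_binders, params = params)
  hb <- if (is.null(hbonds)) list() else
    lapply(hbonds, function(h)
      hbond_occupancy(system, h$donor, h$acceptor, params, h$window %||% NULL))
  structure(list(fractions = fr, classes = cl, hbond = hb, params = params),
            class = "fingerprint_report")
}

#' Write a fingerprint report as CSV
#'
#' One row per (window, residue) with fraction and class; `#` metadata header
#' records cutoffs, thresholds and the boundary convention.
#'
#' @param report A `fingerprint_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fingerprint_csv <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  p <- report$params
  writeLines(sprintf("# ligand contact fingerprint; cutoff_A=%g", p$ligand_cutoff), con)
  writeLines(sprintf("# constant>=%g frequent>=%g (boundaries inclusive)",
                     p$constant_binder_threshold, p$frequent_binder_threshold), con)
  writeLines("window,residue,fraction,class", con)
  for (w in names(report$fractions)) {
    fr <- report$fractions[[w]]
    cl <- report$classes[[w]]
    writeLines(sprintf("%s,%s,%.6f,%s", w, names(fr), as.numeric(fr), cl), con)
  }
  if (length(report$hbond) > 0L) {
    writeLines("# hbond occupancies", con)
    for (nm in names(report$hbond))
      writeLines(sprintf("# hbond,%s,%.6f", nm, as.numeric(report$hbond[[nm]])), con)
  }
  invisible(path)
}
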