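# Cholesterol contact/occupancy analysis: per-region contact series,
# occupancy statistics and the individual/simultaneous/bridging motif
# classification.

# ---------------------------------------------------------------------------
# Contact primitive

# Grid-accelerated minimum-distance test between two coordinate blocks.
# Contractually identical to the all-pairs search. With box dimensions,
# falls back to all-pairs with minimum-image distances.
#' @noRd
groups_within_cutoff <- function(xa, xb, cutoff, box = NULL) {
  if (!is.null(box)) {
    dmin2 <- Inf
    for (i in seq_len(nrow(xa))) {
      dx <- xb[, 1] - xa[i, 1]; dy <- xb[, 2] - xa[i, 2]; dz <- xb[, 3] - xa[i, 3]
      dx <- dx - box[1] * round(dx / box[1])
      dy <- dy - box[2] * round(dy / box[2])
      dz <- dz - box[3] * round(dz / box[3])
      m <- min(dx * dx + dy * dy + dz * dz)
      if (m < dmin2) dmin2 <- m
      if (dmin2 <= cutoff^2) return(TRUE)
    }
    return(dmin2 <= cutoff^2)
  }
  # quick bounding-box rejection
  if (any(apply(xa, 2, min) - apply(xb, 2, max) > cutoff) ||
      any(apply(xb, 2, min) - apply(xa, 2, max) > cutoff)) return(FALSE)
  c2 <- cutoff^2
  if (nrow(xa) * nrow(xb) <= 4096) return(min_dist2_block(xa, xb) <= c2)
  # cell lists with cell edge = cutoff: only 27 neighbour cells can hold a hit
  ka <- floor(xa / cutoff)
  kb <- floor(xb / cutoff)
  keyb <- paste(kb[, 1], kb[, 2], kb[, 3])
  bcells <- split(seq_len(nrow(xb)), keyb)
  acells <- split(seq_len(nrow(xa)), paste(ka[, 1], ka[, 2], ka[, 3]))
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (cell in names(acells)) {
    ia <- acells[[cell]]
    cc <- as.integer(strsplit(cell, " ", fixed = TRUE)[[1]])
    nb <- paste(cc[1] + off[, 1], cc[2] + off[, 2], cc[3] + off[, 3])
    ib <- unlist(bcells[nb], use.names = FALSE)
    if (is.null(ib) || length(ib) == 0L) next
    if (min_dist2_block(xa[ia, , drop = FALSE], xb[ib, , drop = FALSE]) <= c2)
      return(TRUE)
  }
  FALSE
}

#' Are two atom groups within a distance cutoff in a frame?
#'
#' `TRUE` iff the minimum inter-group heavy-atom distance is less than or
#' equal to `cutoff` (the boundary counts as a contact). Accelerated by
#' spatial binning but contractually identical to the all-pairs search.
#' Minimum-image distances are used when the frame carries box dimensions.
#'
#' @param system A `molecular_system`.
#' @param group_a,group_b Non-empty integer atom-index vectors.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param frame Frame number (default 1).
#' @return Logical scalar.
#' @export
frame_contacts <- function(system, group_a, group_b, cutoff, frame = 1L) {
  if (cutoff <= 0) stopf("cutoff must be positive")
  if (length(group_a) == 0L || length(group_b) == 0L)
    stopf("contact groups must be non-empty")
  fr <- system$frames[[frame]]
  groups_within_cutoff(fr$xyz[group_a, , drop = FALSE],
                       fr$xyz[group_b, , drop = FALSE], cutoff, fr$box)
}

# ---------------------------------------------------------------------------
# Contact series

#' Per-frame cholesterol-region contact series
#'
#' For every frame, cholesterol molecule and named region, records whether any
#' heavy-atom pair between the molecule and the region's residues is within
#' the cholesterol cutoff. Regions resolve to the heavy atoms of their protein
#' residue ranges (side chain and backbone).
#'
#' @param system A classified `molecular_system`.
#' @param regions A [region_definition()] (or named list of ranges).
#' @param params [analysis_parameters()].
#' @param molecule_class Class of the contacting molecules (default
#'   `"cholesterol"`).
#' @return An object of class `contact_series`: list with `occupancy` (logical
#'   array frames x molecules x regions), `molecules`, `regions`, `cutoff`,
#'   `frame_count` and `times`.
#' @export
region_contact_series <- function(system, regions, params = analysis_parameters(),
                                  molecule_class = "cholesterol") {
  rg <- as_region_list(regions)
  cutoff <- params$cholesterol_cutoff
  reg_atoms <- lapply(rg, function(r) region_atom_indices(system, r))
  empty <- vapply(reg_atoms, length, integer(1)) == 0L
  if (any(empty))
    stopf("region(s) with no atoms: %s", paste(names(rg)[empty], collapse = ", "))
  mols <- molecules_of_class(system, molecule_class)
  mol_atoms <- lapply(mols, function(m)
    which(system$atoms$molecule_id == m & system$atoms$is_heavy))
  nf <- n_frames(system)
  occ <- array(FALSE, dim = c(nf, length(mols), length(rg)),
               dimnames = list(NULL, as.character(mols), names(rg)))
  for (f in seq_len(nf)) {
    fr <- system$frames[[f]]
    for (mi in seq_along(mols)) {
      xm <- fr$xyz[mol_atoms[[mi]], , drop = FALSE]
      for (ri in seq_along(rg)) {
        occ[f, mi, ri] <- groups_within_cutoff(
          xm, fr$xyz[reg_atoms[[ri]], , drop = FALSE], cutoff, fr$box)
      }
    }
  }
  structure(list(occupancy = occ, molecules = mols, regions = names(rg),
                 cutoff = cutoff, frame_count = nf,
                 times = frame_times(system)),
            class = "contact_series")
}

# Always a frames x molecules logical matrix.
#' @noRd
series_region_slice <- function(series, region) {
  if (!region %in% series$regions) stopf("region '%s' not in series", region)
  matrix(series$occupancy[, , region], nrow = series$frame_count)
}

#' Percent of time a region is occupied
#'
#' `100 * (#frames with >= 1 bound molecule) / frame_count`, the Table-1-style
#' per-helix statistic.
#'
#' @param series A `contact_series`.
#' @param region Region name.
#' @return Percentage in `[0, 100]`.
#' @export
occupancy_percent <- function(series, region) {
  sl <- series_region_slice(series, region)
  if (ncol(sl) == 0L) return(0)
  100 * sum(rowSums(sl) > 0) / series$frame_count
}

#' Mean number of bound molecules per frame
#'
#' Total (frame, molecule) bound pairs for the region divided by the frame
#' count.
#'
#' @inheritParams occupancy_percent
#' @return Non-negative numeric.
#' @export
mean_bound_per_frame <- function(series, region) {
  sl <- series_region_slice(series, region)
  sum(sl) / series$frame_count
}

#' Classify paired motif occupancy per frame
#'
#' For two motif regions A and B, each frame is classified as `none` (neither
#' occupied), `only_A` / `only_B` (exactly one occupied), `simultaneous`
#' (there exist two *distinct* molecules, one bound to A and one bound to B),
#' or `bridged_only` (both occupied, but only because one and the same
#' molecule bridges the two motifs, which is excluded from simultaneous
#' binding). Distinct representatives exist iff both motifs are occupied and
#' the union of their binders has at least two molecules.
#'
#' @param series A `contact_series`.
#' @param motif_a,motif_b Distinct region names present in the series.
#' @return List with `classes` (character vector per frame) and `counts`
#'   (named totals over the five classes; they partition the frames).
#' @export
motif_occupancy_classes <- function(series, motif_a, motif_b) {
  if (identical(motif_a, motif_b)) stopf("motif_a and motif_b must differ")
  A <- series_region_slice(series, motif_a)
  B <- series_region_slice(series, motif_b)
  nf <- series$frame_count
  classes <- character(nf)
  for (f in seq_len(nf)) {
    a <- which(A[f, ]); b <- which(B[f, ])
    classes[f] <-
      if (length(a) == 0L && length(b) == 0L) "none"
      else if (length(b) == 0L) "only_A"
      else if (length(a) == 0L) "only_B"
      else if (length(union(a, b)) >= 2L) "simultaneous"
      else "bridged_only"
  }
  lev <- c("none", "only_A", "only_B", "simultaneous", "bridged_only")
  counts <- vapply(lev, function(l) sum(classes == l), numeric(1))
  list(classes = classes, counts = counts,
       motif_a = motif_a, motif_b = motif_b, frame_count = nf)
}

#' Total bound events of a series
#'
#' A bound event is one (frame, molecule) pair with at least one region
#' contact; a molecule touching several regions in the same frame counts once
#' for the system total.
#'
#' @param series A `contact_series`.
#' @return Integer count.
#' @export
total_bound_events <- function(series) {
  occ <- series$occupancy
  if (length(series$molecules) == 0L) return(0L)
  bound <- apply(occ, c(1, 2), any)
  sum(bound)
}

#' Ratio of total bound events between two systems
#'
#' E.g. apo versus holo: total (frame, molecule) bound events of the first
#' series divided by those of the second.
#'
#' @param series_apo,series_holo `contact_series` objects.
#' @return Numeric ratio.
#' @export
total_bound_ratio <- function(series_apo, series_holo) {
  num <- total_bound_events(series_apo)
  den <- total_bound_events(series_holo)
  if (den == 0) stopf("denominator series has no bound events")
  num / den
}

#' Assign lipids to membrane leaflets
#'
#' Each cholesterol or phospholipid is assigned to the `upper` or `lower`
#' leaflet by the z coordinate of its reference atom (cholesterol: hydroxyl
#' oxygen, i.e. the molecule's first oxygen atom; phospholipid: the
#' phosphorus) relative to the membrane midplane. The midplane defaults to
#' the mean z of all lipid reference atoms (robust to membrane drift).
#'
#' @param system A classified `molecular_system`.
#' @param frame Frame number (default 1).
#' @param midplane Optional explicit midplane z (Angstrom).
#' @return Data frame with `molecule_id`, `class`, `ref_z`, `leaflet`.
#' @export
assign_leaflets <- function(system, frame = 1L, midplane = NULL) {
  chl <- molecules_of_class(system, "cholesterol")
  pl <- molecules_of_class(system, "phospholipid")
  mols <- c(chl, pl)
  if (length(mols) == 0L) stopf("system contains no lipids")
  atoms <- system$atoms
  xyz <- system$frames[[frame]]$xyz
  ref_z <- vapply(mols, function(m) {
    ai <- which(atoms$molecule_id == m)
    cls <- system$molecule_classes[as.character(m)]
    ref <- if (cls == "cholesterol") ai[toupper(atoms$element[ai]) == "O"]
           else ai[toupper(atoms$element[ai]) == "P" | atoms$name[ai] == "P"]
    if (length(ref) == 0L) ref <- ai[1]
    xyz[ref[1], 3]
  }, numeric(1))
  if (is.null(midplane)) midplane <- mean(ref_z)
  data.frame(molecule_id = mols,
             class = unname(system$molecule_classes[as.character(mols)]),
             ref_z = ref_z,
             leaflet = ifelse(ref_z >= midplane, "upper", "lower"),
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Reports

#' Summarize a contact series into an occupancy report
#'
#' @param series A `contact_series`.
#' @param system_label Row label for the report (e.g. `"apo"`).
#' @param helix_regions Region names to tabulate (default: those starting
#'   with `"TM"`).
#' @return An `occupancy_report`: list with per-region `percent` and
#'   `mean_per_frame`, `total_events`, `frame_count` and the label.
#' @export
occupancy_report <- function(series, system_label = "system",
                             helix_regions = grep("^TM", series$regions,
                                                  value = TRUE)) {
  percent <- vapply(helix_regions, function(r) occupancy_percent(series, r),
                    numeric(1))
  meanpf <- vapply(helix_regions, function(r) mean_bound_per_frame(series, r),
                   numeric(1))
  structure(list(label = system_label, regions = helix_regions,
                 percent = percent, mean_per_frame = meanpf,
                 total_events = total_bound_events(series),
                 frame_count = series$frame_count, cutoff = series$cutoff),
            class = "occupancy_report")
}

#' Write Table-1-style occupancy percentages as CSV
#'
#' Systems as rows, helices as columns, percentages to one decimal, with
#' self-describing `#` metadata header lines (frame count and cutoff; the
#' percentages are meaningless without the frame normalization).
#'
#' @param reports A single `occupancy_report` or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_occupancy_table <- function(reports, path) {
  if (inherits(reports, "occupancy_report")) reports <- list(reports)
  con <- file(path, open = "wt")
  on.exit(close(con))
  r1 <- reports[[1]]
  writeLines(sprintf("# occupancy percent of simulation time; cutoff_A=%g", r1$cutoff), con)
  writeLines(sprintf("# frame_count=%s",
                     paste(vapply(reports, function(r)
                       sprintf("%s:%d", r$label, r$frame_count), character(1)),
                       collapse = ",")), con)
  writeLines(paste(c("system", r1$regions), collapse = ","), con)
  for (r in reports)
    writeLines(paste(c(r$label, sprintf("%.1f", r$percent)), collapse = ","), con)
  invisible(path)
}

#' Read back an occupancy CSV written by [write_occupancy_table()]
#'
#' @param path CSV path.
#' @return Data frame with one row per system.
#' @export
read_occupancy_table <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Write motif-occupancy class counts as CSV
#'
#' @param classes Result of [motif_occupancy_classes()], or a named list of
#'   such results (one row each).
#' @param path Output path.
#' @param trace_path Optional TSV path for the per-frame class trace.
#' @return Invisibly, `path`.
#' @export
write_motif_class_table <- function(classes, path, trace_path = NULL) {
  if (!is.null(classes$counts)) classes <- list(system = classes)
  con <- file(path, open = "wt")
  writeLines("# paired motif occupancy frame counts", con)
  lev <- c("none", "only_A", "only_B", "simultaneous", "bridged_only")
  writeLines(paste(c("system", "motif_a", "motif_b", lev), collapse = ","), con)
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    writeLines(paste(c(nm, cl$motif_a, cl$motif_b,
                       format(cl$counts[lev], trim = TRUE)), collapse = ","), con)
  }
  close(con)
  if (!is.null(trace_path)) {
    tr <- do.call(rbind, lapply(names(classes), function(nm)
      data.frame(system = nm, frame = seq_along(classes[[nm]]$classes),
                 class = classes[[nm]]$classes)))
    utils::write.table(tr, trace_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
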