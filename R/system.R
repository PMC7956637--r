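# Topology/trajectory container, structure readers and atom selection.

STANDARD_AA <- names(AA3)

#' Analysis parameters
#'
#' Bundles the distance cutoffs and thresholds used throughout the pipeline,
#' with the defaults used for the TSPO analyses: 5.0 A heavy-atom cutoff for
#' cholesterol contacts, 4.5 A for ligand contacts, 3.5 A for the
#' distance-criterion hydrogen bond, binder-class thresholds 0.90 (constant)
#' and 0.75 (frequent), equilibrated-window start 400 ns, and helix bend-angle
#' bin edges 6/12/18/24 degrees.
#'
#' @param cholesterol_cutoff,ligand_cutoff,hbond_cutoff Distance cutoffs (A).
#' @param constant_binder_threshold,frequent_binder_threshold Contact-fraction
#'   thresholds in (0, 1], with frequent <= constant.
#' @param equilibration_start_ns Start of the equilibrated analysis window (ns).
#' @param bend_bins Strictly increasing bend-angle bin edges (degrees).
#' @param rmsd_selection Residue range (c(lo, hi)) for backbone RMSD; defaults
#'   to 5..158 (W5-N158, excluding the termini).
#' @return An object of class `analysis_parameters`.
#' @export
analysis_parameters <- function(cholesterol_cutoff = 5.0,
                                ligand_cutoff = 4.5,
                                hbond_cutoff = 3.5,
                                constant_binder_threshold = 0.90,
                                frequent_binder_threshold = 0.75,
                                equilibration_start_ns = 400,
                                bend_bins = c(6, 12, 18, 24),
                                rmsd_selection = c(5L, 158L)) {
  if (any(c(cholesterol_cutoff, ligand_cutoff, hbond_cutoff) <= 0))
    stopf("distance cutoffs must be positive")
  if (!(frequent_binder_threshold > 0 &&
        frequent_binder_threshold <= constant_binder_threshold &&
        constant_binder_threshold <= 1))
    stopf("need 0 < frequent <= constant <= 1 binder thresholds")
  if (any(diff(bend_bins) <= 0)) stopf("bend_bins must be strictly increasing")
  structure(list(cholesterol_cutoff = cholesterol_cutoff,
                 ligand_cutoff = ligand_cutoff,
                 hbond_cutoff = hbond_cutoff,
                 constant_binder_threshold = constant_binder_threshold,
                 frequent_binder_threshold = frequent_binder_threshold,
                 equilibration_start_ns = equilibration_start_ns,
                 bend_bins = bend_bins,
                 rmsd_selection = as.integer(rmsd_selection)),
            class = "analysis_parameters")
}

#' Named residue regions
#'
#' A region definition maps region names (TM helices, loops, motifs) to
#' inclusive residue ranges in the numbering of the structure. Ranges may
#' overlap (motifs sit inside helices).
#'
#' @param ... Named `c(start, end)` ranges, or a single named list of them.
#' @return An object of class `region_definition` (named list of integer
#'   ranges).
#' @export
region_definition <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)[1]))
    args <- args[[1]]
  if (is.null(names(args)) || any(names(args) == ""))
    stopf("all regions must be named")
  rg <- lapply(args, function(r) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1] > r[2]) stopf("regions are c(start, end) with start <= end")
    r
  })
  structure(rg, class = "region_definition")
}

#' @noRd
as_region_list <- function(regions) {
  if (inherits(regions, "region_definition")) return(unclass(regions))
  if (is.list(regions)) return(unclass(region_definition(regions)))
  stopf("regions must be a region_definition or a named list of ranges")
}

#' Default hTSPO region definition
#'
#' Transmembrane helix ranges for human TSPO (TM I 5-25, TM II 47-67,
#' TM III 79-101, TM IV 110-133, TM V 134-157), the inter-helix loops, and the
#' cholesterol-motif regions (CRAC 150-156, CARC 135-141, CRAC-like 17-24,
#' LAF 144-146). Helix boundaries are inferred from the published loop
#' definitions and are explicitly overridable.
#'
#' @return A [region_definition()].
#' @export
default_htspo_regions <- function() {
  region_definition(
    "TM I" = c(5, 25), "TM II" = c(47, 67), "TM III" = c(79, 101),
    "TM IV" = c(110, 133), "TM V" = c(134, 157),
    "LP I" = c(26, 46), "LP II" = c(68, 78), "LP III" = c(102, 109),
    CRAC = c(150, 156), CARC = c(135, 141),
    "CRAC-like" = c(17, 24), LAF = c(144, 146))
}

#' Default residue-name classification rules
#'
#' @return Named list mapping molecule classes to residue names. The ligand
#'   residue name defaults to `PK1`.
#' @param ligand_resname Residue name(s) of the ligand.
#' @export
default_naming_rules <- function(ligand_resname = "PK1") {
  list(protein = STANDARD_AA,
       cholesterol = c("CHL", "CHL1", "CLOL"),
       phospholipid = c("POPC", "POPE"),
       water = c("HOH", "SOL", "TIP3"),
       ion = c("NA", "CL"),
       ligand = ligand_resname)
}

# ---------------------------------------------------------------------------
# Molecular system container

#' @noRd
new_molecular_system <- function(atoms, frames, molecule_classes = NULL) {
  stopifnot(is.data.frame(atoms), is.list(frames), length(frames) >= 1L)
  n <- nrow(atoms)
  times <- vapply(frames, function(f) f$time_ns, numeric(1))
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$xyz) != n)
      stopf("frame %d has %d atoms; topology has %d", i, nrow(frames[[i]]$xyz), n)
    if (!all(is.finite(frames[[i]]$xyz)))
      stopf("frame %d contains non-finite coordinates", i)
  }
  if (length(times) > 1L && any(diff(times) <= 0))
    stopf("frame times must be strictly increasing")
  sys <- structure(list(atoms = atoms, frames = frames,
                        molecule_classes = molecule_classes),
                   class = "molecular_system")
  if (is.null(molecule_classes)) sys <- classify_molecules(sys, quiet = TRUE)
  sys
}

#' @export
print.molecular_system <- function(x, ...) {
  cls <- table(x$molecule_classes)
  cat(sprintf("<molecular_system> %d atoms, %d frames (%.6g..%.6g ns)\n",
              nrow(x$atoms), length(x$frames),
              x$frames[[1]]$time_ns, x$frames[[length(x$frames)]]$time_ns))
  cat("  molecules:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a system
#' @param system A `molecular_system`.
#' @return Integer frame count.
#' @export
n_frames <- function(system) length(system$frames)

#' Frame times in nanoseconds
#' @param system A `molecular_system`.
#' @return Numeric vector of frame times.
#' @export
frame_times <- function(system)
  vapply(system$frames, function(f) f$time_ns, numeric(1))

# Element inference from atom names (used when the element field is absent).
#' @noRd
infer_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  ifelse(substr(nm, 1, 1) == "H" | grepl("^[0-9]*H", toupper(name)), "H",
         substr(nm, 1, 1))
}

# Molecule ids: protein residues per chain collapse into one molecule; every
# non-protein residue instance is its own molecule.
#' @noRd
assign_molecule_ids <- function(atoms) {
  is_prot <- atoms$residue_name %in% STANDARD_AA
  key <- ifelse(is_prot,
                paste0("P|", atoms$chain),
                paste0("M|", atoms$chain, "|", atoms$residue_index, "|",
                       atoms$residue_name))
  match(key, unique(key))
}

#' Classify molecules by residue name
#'
#' Assigns each molecule of the system to one of `protein`, `cholesterol`,
#' `ligand`, `phospholipid`, `water`, `ion` or `other` from its residue
#' name(s). Unmatched names go to `other` with a warning.
#'
#' @param system A `molecular_system`.
#' @param naming_rules Rules as from [default_naming_rules()].
#' @param quiet Suppress the unmatched-name warning.
#' @return The system with its `molecule_classes` (named character vector,
#'   one entry per molecule id) replaced.
#' @export
classify_molecules <- function(system, naming_rules = default_naming_rules(),
                               quiet = FALSE) {
  atoms <- system$atoms
  mol_ids <- sort(unique(atoms$molecule_id))
  lut <- character(0)
  for (cls in names(naming_rules))
    lut[toupper(naming_rules[[cls]])] <- cls
  classes <- vapply(mol_ids, function(m) {
    rn <- toupper(unique(atoms$residue_name[atoms$molecule_id == m]))
    hit <- lut[rn]
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) NA_character_ else hit[1]
  }, character(1))
  if (anyNA(classes)) {
    if (!quiet) {
      unk <- unique(atoms$residue_name[atoms$molecule_id %in% mol_ids[is.na(classes)]])
      warnf("unmatched residue name(s) %s classified as 'other'",
            paste(unk, collapse = ", "))
    }
    classes[is.na(classes)] <- "other"
  }
  names(classes) <- mol_ids
  system$molecule_classes <- classes
  system
}

# ---------------------------------------------------------------------------
# Readers / writers

# Parse the ATOM/HETATM records of a character vector of PDB lines into an
# atom table plus a coordinate matrix.
#' @noRd
parse_pdb_atom_lines <- function(lines, lineno) {
  f <- function(a, b) trimws(substr(lines, a, b))
  name <- f(13, 16)
  elem <- f(77, 78)
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0L)
    stopf("unreadable coordinate record at line %d", lineno[bad[1]])
  resno <- suppressWarnings(as.integer(f(23, 26)))
  if (anyNA(resno))
    stopf("unreadable residue number at line %d", lineno[which(is.na(resno))[1]])
  elem <- ifelse(elem == "", infer_element(name), elem)
  atoms <- data.frame(index = seq_along(lines), name = name, element = elem,
                      is_heavy = toupper(elem) != "H",
                      residue_index = resno, residue_name = f(18, 21),
                      chain = substr(lines, 22, 22), stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = cbind(x, y, z))
}

# Multi-MODEL PDB reader. Box from CRYST1; frame times from
# "REMARK TIME_NS <t>" lines when present, else stride_ns * (0..n-1).
#' @noRd
read_pdb_frames <- function(path, stride_ns = 1) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stopf("no ATOM/HETATM records in %s", path)
  model_starts <- which(rec == "MODEL ")
  box <- NULL
  cry <- which(startsWith(lines, "CRYST1"))
  if (length(cry) > 0L) {
    v <- suppressWarnings(as.numeric(c(substr(lines[cry[1]], 7, 15),
                                       substr(lines[cry[1]], 16, 24),
                                       substr(lines[cry[1]], 25, 33))))
    if (!anyNA(v) && all(v > 1)) box <- v
  }
  tm <- grep("^REMARK +TIME_NS ", lines, value = TRUE)
  times <- if (length(tm) > 0L)
    as.numeric(sub("^REMARK +TIME_NS +", "", tm)) else NULL

  if (length(model_starts) == 0L) {
    frame_of <- rep(1L, sum(is_atom))
  } else {
    grp <- findInterval(which(is_atom), model_starts)
    if (any(grp == 0L)) stopf("ATOM record before first MODEL in %s", path)
    frame_of <- grp
  }
  atom_idx <- which(is_atom)
  nfr <- max(frame_of)
  counts <- tabulate(frame_of, nbins = nfr)
  if (length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1])[1]
    stopf("frame %d has %d atoms; frame 1 has %d (atom-count mismatch in %s)",
          bad, counts[bad], counts[1], path)
  }
  first <- atom_idx[frame_of == 1L]
  parsed <- parse_pdb_atom_lines(lines[first], first)
  atoms <- parsed$atoms
  n <- nrow(atoms)
  frames <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    idx <- atom_idx[frame_of == k]
    xyz <- if (k == 1L) parsed$xyz else parse_pdb_atom_lines(lines[idx], idx)$xyz
    t_ns <- if (!is.null(times) && length(times) >= k) times[k] else (k - 1) * stride_ns
    frames[[k]] <- list(time_ns = t_ns, xyz = unname(xyz), box = box)
  }
  list(atoms = atoms, frames = frames)
}

# Minimal GRO reader (fixed columns, nm -> Angstrom).
#' @noRd
read_gro_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stopf("GRO file %s too short", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stopf("unreadable atom count at line 2 of %s", path)
  if (length(lines) < 3L + n) stopf("GRO file %s truncated", path)
  al <- lines[3:(2 + n)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resnm <- trimws(substr(al, 6, 10))
  atnm <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28))) * 10
  y <- suppressWarnings(as.numeric(substr(al, 29, 36))) * 10
  z <- suppressWarnings(as.numeric(substr(al, 37, 44))) * 10
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resno))
  if (length(bad) > 0L) stopf("unreadable GRO record at line %d", bad[1] + 2L)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  box <- if (length(boxv) >= 3 && !anyNA(boxv[1:3])) boxv[1:3] * 10 else NULL
  elem <- infer_element(atnm)
  atoms <- data.frame(index = seq_len(n), name = atnm, element = elem,
                      is_heavy = toupper(elem) != "H",
                      residue_index = resno, residue_name = resnm,
                      chain = " ", stringsAsFactors = FALSE)
  list(atoms = atoms,
       frames = list(list(time_ns = 0, xyz = unname(cbind(x, y, z)),
                          box = box)))
}

#' Load a molecular system from structure (and trajectory) files
#'
#' The structure may be a PDB (read via bio3d for single structures, with the
#' PDB element column taking precedence over name-based element inference) or
#' a GRO file. The optional trajectory is a multi-MODEL PDB, or any source
#' exposed through `adapter`: a function called as `adapter(trajectory_path)`
#' that must return a list of frames, each `list(time_ns=, xyz=, box=)` with
#' coordinates in Angstrom.
#'
#' @param structure_path Path to a PDB or GRO structure.
#' @param trajectory_path Optional path to a multi-MODEL PDB trajectory whose
#'   atom order matches the structure.
#' @param stride_ns Frame stride used when the trajectory carries no times.
#' @param naming_rules Classification rules (see [classify_molecules()]).
#' @param adapter Optional trajectory reader function (see Description).
#' @return A `molecular_system`.
#' @export
load_system <- function(structure_path, trajectory_path = NULL, stride_ns = 1,
                        naming_rules = default_naming_rules(), adapter = NULL) {
  if (!file.exists(structure_path)) stopf("structure file not found: %s", structure_path)
  ext <- tolower(tools::file_ext(structure_path))
  if (ext == "gro") {
    parsed <- read_gro_file(structure_path)
  } else if (sum(startsWith(readLines(structure_path), "MODEL")) > 1L) {
    # multi-MODEL trajectory-style file: needs per-frame validation and times
    parsed <- read_pdb_frames(structure_path, stride_ns)
  } else {
    parsed <- tryCatch({
      pdb <- bio3d::read.pdb(structure_path, verbose = FALSE)
      a <- pdb$atom
      elem <- trimws(a$elesy %||% "")
      if (length(elem) == 0L) elem <- rep("", nrow(a))
      elem <- ifelse(is.na(elem) | elem == "", infer_element(a$elety), elem)
      atoms <- data.frame(index = seq_len(nrow(a)), name = a$elety,
                          element = elem, is_heavy = toupper(elem) != "H",
                          residue_index = a$resno, residue_name = a$resid,
                          chain = ifelse(is.na(a$chain), " ", a$chain),
                          stringsAsFactors = FALSE)
      xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
      list(atoms = atoms, frames = list(list(time_ns = 0, xyz = xyz, box = NULL)))
    }, error = function(e) read_pdb_frames(structure_path, stride_ns))
  }
  atoms <- parsed$atoms
  frames <- parsed$frames
  if (!is.null(trajectory_path)) {
    tf <- if (!is.null(adapter)) adapter(trajectory_path)
          else read_pdb_frames(trajectory_path, stride_ns)$frames
    for (i in seq_along(tf)) {
      if (nrow(tf[[i]]$xyz) != nrow(atoms))
        stopf("trajectory frame %d has %d atoms; topology has %d",
              i, nrow(tf[[i]]$xyz), nrow(atoms))
    }
    frames <- tf
  }
  atoms$molecule_id <- assign_molecule_ids(atoms)
  sys <- new_molecular_system(atoms, frames)
  classify_molecules(sys, naming_rules, quiet = FALSE)
}

#' Write a system as a (multi-MODEL) PDB file
#'
#' Emits one MODEL block per frame with a `REMARK TIME_NS` line per frame and
#' a CRYST1 record when box dimensions are present. Coordinates are written at
#' PDB precision (0.001 A).
#'
#' @param system A `molecular_system`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_system_pdb <- function(system, path) {
  atoms <- system$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  box <- system$frames[[1]]$box
  if (!is.null(box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1], box[2], box[3]), con)
  is_het <- !(atoms$residue_name %in% STANDARD_AA)
  rectype <- ifelse(is_het, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(atoms$name) < 4, sprintf(" %-3s", atoms$name),
                  substr(atoms$name, 1, 4))
  pre <- sprintf("%s%5d %s %-4s%s%4d    ", rectype,
                 seq_len(nrow(atoms)) %% 100000L, name4,
                 substr(atoms$residue_name, 1, 4), atoms$chain,
                 atoms$residue_index %% 10000L)
  post <- sprintf("  1.00  0.00          %2s", substr(atoms$element, 1, 2))
  for (k in seq_along(system$frames)) {
    fr <- system$frames[[k]]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("REMARK TIME_NS %.6f", fr$time_ns), con)
    writeLines(paste0(pre,
                      sprintf("%8.3f%8.3f%8.3f", fr$xyz[, 1], fr$xyz[, 2],
                              fr$xyz[, 3]),
                      post), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Atom selection

#' Select atoms of a system
#'
#' Deterministic, order-preserving selection combining residue range, residue
#' names, atom-name sets, molecule class, backbone (N/CA/C/O) or C-alpha
#' shortcuts and a heavy-only flag.
#'
#' @param system A `molecular_system`.
#' @param residue_range Optional `c(lo, hi)` residue-index range (inclusive).
#' @param residue_names,atom_names Optional name filters.
#' @param molecule_class Optional class filter (e.g. `"protein"`).
#' @param backbone If `TRUE`, restrict to backbone atoms N, CA, C, O.
#' @param calpha If `TRUE`, restrict to CA atoms.
#' @param heavy_only If `TRUE`, drop hydrogens.
#' @param allow_empty Return an empty selection instead of erroring.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(system, residue_range = NULL, residue_names = NULL,
                         atom_names = NULL, molecule_class = NULL,
                         backbone = FALSE, calpha = FALSE, heavy_only = FALSE,
                         allow_empty = FALSE) {
  atoms <- system$atoms
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(residue_range))
    keep <- keep & atoms$residue_index >= residue_range[1] &
      atoms$residue_index <= residue_range[2]
  if (!is.null(residue_names))
    keep <- keep & atoms$residue_name %in% residue_names
  if (!is.null(atom_names)) keep <- keep & atoms$name %in% atom_names
  if (!is.null(molecule_class)) {
    cls <- system$molecule_classes[as.character(atoms$molecule_id)]
    keep <- keep & cls %in% molecule_class
  }
  if (backbone) keep <- keep & atoms$name %in% c("N", "CA", "C", "O")
  if (calpha) keep <- keep & atoms$name == "CA"
  if (heavy_only) keep <- keep & atoms$is_heavy
  idx <- which(keep)
  if (length(idx) == 0L && !allow_empty) stopf("atom selection is empty")
  idx
}

# Heavy atoms of a region (protein residues in the region's range).
#' @noRd
region_atom_indices <- function(system, range) {
  select_atoms(system, residue_range = range, molecule_class = "protein",
               heavy_only = TRUE, allow_empty = TRUE)
}

#' Molecule ids belonging to a class
#' @param system A `molecular_system`.
#' @param class Molecule class name (e.g. `"cholesterol"`).
#' @return Integer vector of molecule ids (possibly empty).
#' @export
molecules_of_class <- function(system, class) {
  ids <- as.integer(names(system$molecule_classes))
  sort(ids[system$molecule_classes == class])
}
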