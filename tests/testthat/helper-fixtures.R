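# Shared fixtures and independent oracles for the test suite. Oracles here
# deliberately re-derive quantities by the most direct route (all-pairs
# loops, exhaustive enumeration, direct formulas) independent of the package
# implementation paths they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_seq <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# regex with lookahead so overlapping matches are all found
pattern_regex <- function(pattern) {
  parts <- vapply(seq_along(pattern$anchors), function(i) {
    a <- pattern$anchors[[i]]
    set <- if (length(a$set) == 1) a$set else paste0("[", paste(a$set, collapse = ""), "]")
    gap <- if (i < length(pattern$anchors)) {
      g <- pattern$anchors[[i]]
      if (g$max_gap == 0) "" else sprintf(".{%d,%d}", g$min_gap, g$max_gap)
    } else ""
    paste0(set, gap)
  }, character(1))
  paste0("(?=", paste(parts, collapse = ""), ")")
}

regex_starts <- function(s, pattern) {
  m <- gregexpr(pattern_regex(pattern), s, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# --- brute-force global alignment oracle -----------------------------------

# Enumerate every global alignment of two short character vectors; return the
# optimal score and the set of identity percentages achieved at that score.
bf_align <- function(a, b, gap_open = 10, gap_ext = 0.5, digits = 2) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- BLOSUM62
  best <- new.env()
  best$score <- -Inf
  best$ids <- numeric(0)
  score_aln <- function(sa, sb) {
    sc <- 0
    for (k in seq_along(sa)) {
      if (sa[k] != "-" && sb[k] != "-") sc <- sc + mat[sa[k], sb[k]]
    }
    for (s in list(sa, sb)) {
      r <- rle(s == "-")
      runs <- r$lengths[r$values]
      if (length(runs) > 0) sc <- sc - sum(gap_open + gap_ext * runs)
    }
    sc
  }
  identity_of <- function(sa, sb) {
    # identical columns / aligned columns excluding terminal-gap columns
    keep <- rep(TRUE, length(sa))
    for (s in list(sa, sb)) {
      isgap <- s == "-"
      keep <- keep & !(cumsum(!isgap) == 0) &
        !rev(cumsum(rev(!isgap)) == 0)
    }
    if (!any(keep)) return(0)
    round(100 * sum(sa[keep] == sb[keep]) / sum(keep), digits)
  }
  rec <- function(i, j, sa, sb) {
    if (i > length(a) && j > length(b)) {
      sc <- score_aln(sa, sb)
      if (sc > best$score + 1e-9) {
        best$score <- sc
        best$ids <- identity_of(sa, sb)
      } else if (abs(sc - best$score) <= 1e-9) {
        best$ids <- union(best$ids, identity_of(sa, sb))
      }
      return()
    }
    if (i <= length(a) && j <= length(b)) rec(i + 1, j + 1, c(sa, a[i]), c(sb, b[j]))
    if (i <= length(a)) rec(i + 1, j, c(sa, a[i]), c(sb, "-"))
    if (j <= length(b)) rec(i, j + 1, c(sa, "-"), c(sb, b[j]))
  }
  rec(1L, 1L, character(0), character(0))
  list(score = best$score, identities = best$ids)
}

# --- distance / contact oracles --------------------------------------------

bf_min_dist <- function(xa, xb) {
  best <- Inf
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    d <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# vectorized all-pairs verdict (still independent of the grid path)
bf_within <- function(xa, xb, cutoff) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  min(d2) <= cutoff^2 + 1e-12
}

# --- exhaustive simultaneous/bridging oracle -------------------------------

oracle_pair_class <- function(Aset, Bset) {
  if (length(Aset) == 0 && length(Bset) == 0) return("none")
  if (length(Bset) == 0) return("only_A")
  if (length(Aset) == 0) return("only_B")
  for (x in Aset) for (y in Bset) if (x != y) return("simultaneous")
  "bridged_only"
}

# build a contact_series object directly from occupancy matrices
make_series <- function(A, B = NULL, regions = c("A", "B"), cutoff = 5) {
  nf <- nrow(A)
  nm <- ncol(A)
  occ <- array(FALSE, dim = c(nf, nm, length(regions)),
               dimnames = list(NULL, as.character(seq_len(nm)), regions))
  occ[, , 1] <- A
  if (!is.null(B)) occ[, , 2] <- B
  structure(list(occupancy = occ, molecules = seq_len(nm), regions = regions,
                 cutoff = cutoff, frame_count = nf, times = seq_len(nf) - 1),
            class = "contact_series")
}

# --- small synthetic specs --------------------------------------------------

one_helix_spec <- function(n_res = 20, n_frames = 50, n_chl = 1, sigma = 0,
                           schedule = list(), seed = 1, kink_pos = NULL,
                           kink_angle = 0, ligand_schedule = NULL, ...) {
  synthetic_spec(
    helices = list(list(name = "H1", start = 1, length = n_res, direction = 1,
                        kink_pos = kink_pos, kink_angle = kink_angle)),
    n_popc = 0, n_pope = 0, n_chl = n_chl,
    chol_schedule = schedule, ligand_schedule = ligand_schedule,
    n_frames = n_frames, sigma = sigma,
    drift = list(rot_deg = 0, trans = c(0, 0, 0)), seed = seed, ...)
}

# hand-built minimal molecular system from an atom table and frame list
tiny_system <- function(atoms, frames) {
  atoms$molecule_id <- choltraj:::assign_molecule_ids(atoms)
  classify_molecules(choltraj:::new_molecular_system(atoms, frames),
                     quiet = TRUE)
}

tiny_atoms <- function(n, name = "CA", element = "C", resno = seq_len(n),
                       resname = "ALA", chain = "A") {
  data.frame(index = seq_len(n), name = name, element = element,
             is_heavy = toupper(element) != "H", residue_index = resno,
             residue_name = resname, chain = chain, stringsAsFactors = FALSE)
}

htspo_fasta <- function() {
  system.file("extdata", "P30536_hTSPO.fasta", package = "choltraj")
}
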