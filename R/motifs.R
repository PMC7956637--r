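# Sequence-level analysis: cholesterol-binding and oligomerization motif
# scanning, and pairwise sequence identity.

#' Construct a protein sequence object
#'
#' A `protein_sequence` holds an identifier, the one-letter residue string and
#' the 1-based index of its first residue, so that motif coordinates can be
#' reported in the numbering of the source record (e.g., UniProt numbering).
#'
#' @param id Sequence identifier (e.g., a UniProt accession).
#' @param residues Character scalar of one-letter amino-acid codes, or a
#'   character vector of single letters. Allowed letters are the 20 standard
#'   amino acids plus `X`.
#' @param offset 1-based index of the first residue (default 1).
#' @return An object of class `protein_sequence` with elements `id`,
#'   `residues` (character vector of single letters) and `offset`.
#' @export
protein_sequence <- function(id, residues, offset = 1L) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- strsplit(residues, "", fixed = TRUE)[[1]]
  }
  residues <- toupper(residues)
  if (length(residues) < 1L) stopf("sequence '%s' is empty", id)
  bad <- which(!residues %in% c(AA1, "X"))
  if (length(bad) > 0L) {
    stopf("sequence '%s': non-amino-acid character '%s' at position %d",
          id, residues[bad[1]], bad[1])
  }
  structure(list(id = as.character(id), residues = residues,
                 offset = as.integer(offset)),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d residues (%s%d..%s%d)\n",
              x$id, length(x$residues),
              x$residues[1], x$offset,
              x$residues[length(x$residues)],
              x$offset + length(x$residues) - 1L))
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) length(x$residues)

#' Read protein sequences from a FASTA file
#'
#' Reads every record of a FASTA file into [protein_sequence()] objects. The
#' header token before the first whitespace becomes the sequence id. Gap
#' characters (`-`, `.`) and stop codons (`*`) are stripped with a warning;
#' any other non-amino-acid character is an error naming its position.
#'
#' @param path Path to a FASTA file.
#' @return A list of `protein_sequence` objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("FASTA file '%s' contains no records", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    s <- toupper(as.character(set[[i]]))
    if (grepl("[-.*]", s)) {
      warnf("record '%s': stripping gap/stop characters", ids[i])
      s <- gsub("[-.*]", "", s)
    }
    if (nchar(s) == 0L) stopf("record '%s' is empty after cleaning", ids[i])
    protein_sequence(ids[i], s)
  })
}

#' Define an anchor/gap motif pattern
#'
#' A motif pattern is an ordered list of anchors; each anchor is a set of
#' allowed residues followed by a (possibly variable) gap of unconstrained
#' residues before the next anchor. The built-in TSPO patterns (see
#' [builtin_motif_patterns()]) are instantiated directly from the published
#' motif instances, e.g. CRAC as L-X-Y-X(3)-R.
#'
#' @param name Pattern name.
#' @param anchors List; each element is `list(set, min_gap, max_gap)` where
#'   `set` is a character vector of allowed one-letter residues and the gaps
#'   give the number of unconstrained residues before the *next* anchor
#'   (ignored for the last anchor; default gap 0).
#' @return An object of class `motif_pattern`.
#' @export
motif_pattern <- function(name, anchors) {
  if (length(anchors) < 2L) stopf("pattern '%s': need at least 2 anchors", name)
  anchors <- lapply(anchors, function(a) {
    if (is.character(a)) a <- list(set = a, min_gap = 0L, max_gap = 0L)
    a$set <- toupper(a$set)
    if (length(a$set) < 1L) stopf("pattern '%s': empty anchor set", name)
    a$min_gap <- as.integer(a$min_gap %||% 0L)
    a$max_gap <- as.integer(a$max_gap %||% a$min_gap)
    if (a$min_gap < 0L || a$max_gap < a$min_gap)
      stopf("pattern '%s': invalid gap range", name)
    a
  })
  structure(list(name = name, anchors = anchors), class = "motif_pattern")
}

# Fixed-gap anchor shorthand: residues with gap after each.
#' @noRd
fixed_pattern <- function(name, letters, gaps) {
  stopifnot(length(gaps) == length(letters) - 1L)
  anchors <- lapply(seq_along(letters), function(i) {
    g <- if (i < length(letters)) gaps[i] else 0L
    list(set = letters[i], min_gap = g, max_gap = g)
  })
  motif_pattern(name, anchors)
}

#' Built-in TSPO motif patterns
#'
#' The six motifs analyzed for TSPO, instantiated from their published
#' instances (anchor residues and exact gap counts) rather than from generic
#' consensus definitions:
#' CRAC `L-X-Y-X(3)-R`, CARC `R-X(2)-Y-X(2)-L`, CRAC-like `L-X(2)-F-X(3)-R`,
#' GXXXG `G-X(3)-G`, WXPXF `W-X-P-X-F`, and the LAF tripeptide `L-A-F`.
#'
#' @return Named list of [motif_pattern()] objects.
#' @export
builtin_motif_patterns <- function() {
  list(
    CRAC        = fixed_pattern("CRAC",      c("L", "Y", "R"), c(1L, 3L)),
    CARC        = fixed_pattern("CARC",      c("R", "Y", "L"), c(2L, 2L)),
    `CRAC-like` = fixed_pattern("CRAC-like", c("L", "F", "R"), c(2L, 3L)),
    GXXXG       = fixed_pattern("GXXXG",     c("G", "G"),      3L),
    WXPXF       = fixed_pattern("WXPXF",     c("W", "P", "F"), c(1L, 1L)),
    LAF         = fixed_pattern("LAF",       c("L", "A", "F"), c(0L, 0L))
  )
}

#' Scan a sequence for all matches of a motif pattern
#'
#' Returns every match, including overlapping ones; for variable gaps, every
#' distinct anchor placement is a distinct hit. Positions are reported in the
#' numbering of the input record (`offset`-based).
#'
#' @param seq A [protein_sequence()].
#' @param pattern A [motif_pattern()].
#' @return A data frame of class `motif_hits` with columns `pattern`, `start`,
#'   `end` (inclusive, record numbering), `anchors` (e.g. `"L150,Y152,R156"`)
#'   and a list column `anchor_idx` of absolute anchor positions; sorted by
#'   `start`, empty if there is no match.
#' @export
scan_pattern <- function(seq, pattern) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(pattern, "motif_pattern"))
  res <- seq$residues
  n <- length(res)
  anchors <- pattern$anchors
  hits <- list()

  place <- function(k, pos, placed) {
    # anchor k must sit at `pos` (0-based internal index + 1)
    if (pos > n) return()
    if (!(res[pos] %in% anchors[[k]]$set)) return()
    placed <- c(placed, pos)
    if (k == length(anchors)) {
      hits[[length(hits) + 1L]] <<- placed
      return()
    }
    g <- anchors[[k]]
    for (gap in seq.int(g$min_gap, g$max_gap)) {
      place(k + 1L, pos + 1L + gap, placed)
    }
  }
  for (start in seq_len(n)) place(1L, start, integer(0))

  if (length(hits) == 0L) {
    out <- data.frame(pattern = character(0), start = integer(0),
                      end = integer(0), anchors = character(0),
                      stringsAsFactors = FALSE)
    out$anchor_idx <- list()
  } else {
    off <- seq$offset - 1L
    starts <- vapply(hits, function(h) h[1] + off, integer(1))
    ends <- vapply(hits, function(h) h[length(h)] + off, integer(1))
    lab <- vapply(hits, function(h)
      paste0(res[h], h + off, collapse = ","), character(1))
    ord <- order(starts, ends)
    out <- data.frame(pattern = pattern$name, start = starts[ord],
                      end = ends[ord], anchors = lab[ord],
                      stringsAsFactors = FALSE)
    out$anchor_idx <- lapply(hits[ord], function(h) h + off)
  }
  class(out) <- c("motif_hits", class(out))
  out
}

#' Locate the built-in motifs and annotate them with regions
#'
#' Runs all six built-in patterns (or a user-supplied list) over a sequence
#' and annotates each hit with the name of the region containing its start
#' position. Multiple raw matches are kept and disambiguated by the region
#' annotation, never dropped.
#'
#' @param seq A [protein_sequence()].
#' @param regions Optional [region_definition()] (or named list of
#'   `c(start, end)` ranges) used to annotate hits; hits outside every region
#'   get region `NA`.
#' @param patterns Named list of [motif_pattern()]s; defaults to
#'   [builtin_motif_patterns()].
#' @return Named list (one element per pattern) of `motif_hits` data frames,
#'   each with an extra `region` column.
#' @export
find_named_motifs <- function(seq, regions = NULL,
                              patterns = builtin_motif_patterns()) {
  rg <- if (is.null(regions)) list() else as_region_list(regions)
  lapply(patterns, function(p) {
    h <- scan_pattern(seq, p)
    h$region <- vapply(seq_len(nrow(h)), function(i) {
      s <- h$start[i]
      for (nm in names(rg)) {
        r <- rg[[nm]]
        if (s >= r[1] && s <= r[2]) return(nm)
      }
      NA_character_
    }, character(1))
    h
  })
}

#' Write motif hits as TSV
#'
#' @param hits A list of `motif_hits` (as from [find_named_motifs()]) or a
#'   single `motif_hits` data frame.
#' @param path Output path.
#' @param sequence_id Sequence identifier written in the first column.
#' @return Invisibly, the combined data frame written.
#' @export
write_motif_tsv <- function(hits, path, sequence_id = "") {
  if (is.data.frame(hits)) hits <- list(hits)
  rows <- do.call(rbind, lapply(hits, function(h) {
    data.frame(sequence_id = sequence_id, pattern = h$pattern,
               start = h$start, end = h$end, anchors = h$anchors,
               region = if ("region" %in% names(h)) h$region else NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(sequence_id = character(0), pattern = character(0),
                       start = integer(0), end = integer(0),
                       anchors = character(0), region = character(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' Percent identity from a global pairwise alignment
#'
#' Aligns two sequences globally (Needleman-Wunsch with affine gaps via
#' Biostrings) and reports identity as identical aligned positions divided by
#' the number of aligned columns, excluding terminal-gap columns.
#'
#' @param a,b [protein_sequence()] objects.
#' @param substitution_matrix Scoring matrix name (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension Affine gap penalties (defaults 10 and 0.5).
#' @param digits Rounding for the returned percentage (default 0, i.e. whole
#'   percent as conventionally reported).
#' @return Percent identity (numeric scalar).
#' @export
pairwise_identity <- function(a, b, substitution_matrix = "BLOSUM62",
                              gap_opening = 10, gap_extension = 0.5,
                              digits = 0) {
  stopifnot(inherits(a, "protein_sequence"), inherits(b, "protein_sequence"))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(a$residues, collapse = "")),
    Biostrings::AAString(paste(b$residues, collapse = "")),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  alignment_identity(sa, sb, digits = digits)
}

# Identity of an explicit aligned pair (character vectors with '-') excluding
# terminal-gap columns. Shared with the tests' brute-force oracle contract.
#' @noRd
alignment_identity <- function(sa, sb, digits = 0) {
  stopifnot(length(sa) == length(sb))
  keep <- rep(TRUE, length(sa))
  for (s in list(sa, sb)) {
    isgap <- s == "-"
    lead <- cumsum(!isgap) == 0
    trail <- rev(cumsum(rev(!isgap)) == 0)
    keep <- keep & !lead & !trail
  }
  cols <- sum(keep)
  if (cols == 0L) return(0)
  round(100 * sum(sa[keep] == sb[keep]) / cols, digits = digits)
}
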