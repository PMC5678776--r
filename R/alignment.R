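#' Read a gapped multiple sequence alignment from FASTA
#'
#' Loads an alignment of two or more equal-length gapped sequences (the
#' standard output format of aligners such as clustalW or MAFFT) and builds,
#' for every row, the coordinate map between consensus (column) space and the
#' ungapped source sequence.
#'
#' Residues are stored uppercase; the permitted alphabet is \code{A C G T N -}.
#'
#' @param path path to a FASTA file of gapped sequences.
#' @param groups optional named character vector mapping row ids to group
#'   labels (e.g. ingroup genus vs outgroup); rows not named get \code{NA}.
#' @return an object of class \code{MultiAlignment}: a list with elements
#'   \code{seqs} (named character vector of gapped rows), \code{L} (number of
#'   columns), \code{groups}, and \code{maps} (per-row integer vectors of
#'   length \code{L}, 0-based ungapped positions, \code{NA} at gap columns).
#' @export
read_alignment <- function(path, groups = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2)
    stop("need >=2 sequences in an alignment, got ", length(ss))
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  new_alignment(seqs, groups = groups)
}

#' Construct a MultiAlignment from in-memory gapped sequences
#'
#' @param seqs named character vector of equal-length gapped sequences.
#' @param groups optional named character vector of group labels per row id.
#' @return a \code{MultiAlignment} (see [read_alignment()]).
#' @export
new_alignment <- function(seqs, groups = NULL) {
  seqs <- toupper(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("alignment rows must carry unique ids")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- names(seqs)[which(lens != lens[1])[1]]
    stop("gapped lengths differ; offending record: ", bad)
  }
  for (i in seq_along(seqs)) {
    illegal <- regexpr("[^ACGTN-]", seqs[[i]])
    if (illegal > 0)
      stop("illegal character in record '", names(seqs)[i],
           "' at column ", illegal)
  }
  L <- lens[1]
  if (L < 1) stop("alignment must have >=1 column")
  m <- seq_char_matrix(seqs)
  if (any(colSums(m == GAP_CHAR) == nrow(m)))
    stop("alignment contains an all-gap column")
  maps <- lapply(seq_along(seqs), function(i) {
    notgap <- m[i, ] != GAP_CHAR
    pos <- cumsum(notgap) - 1L
    pos[!notgap] <- NA_integer_
    as.integer(pos)
  })
  names(maps) <- names(seqs)
  grp <- rep(NA_character_, length(seqs))
  names(grp) <- names(seqs)
  if (!is.null(groups)) grp[names(groups)] <- unname(groups)
  structure(list(seqs = seqs, L = unname(L), groups = grp, maps = maps,
                 matrix = m),
            class = "MultiAlignment")
}

#' @export
print.MultiAlignment <- function(x, ...) {
  cat("MultiAlignment:", length(x$seqs), "rows x", x$L, "columns\n")
  for (id in names(x$seqs)) {
    g <- x$groups[[id]]
    cat(sprintf("  %s%s (%d residues)\n", id,
                if (is.na(g)) "" else paste0(" [", g, "]"),
                sum(!is.na(x$maps[[id]]))))
  }
  invisible(x)
}

#' Write a gapped alignment back to FASTA
#'
#' @param aln a \code{MultiAlignment}.
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path)
  invisible(path)
}

#' Map a consensus column to its ungapped sequence position
#'
#' @param aln a \code{MultiAlignment}.
#' @param row row id.
#' @param column 0-based consensus column (scalar or vector).
#' @return 0-based position(s) in the ungapped row sequence; \code{NA} where
#'   the row has a gap.
#' @export
ungapped_position <- function(aln, row, column) {
  if (!row %in% names(aln$maps)) stop("unknown row id: ", row)
  if (any(column < 0 | column >= aln$L))
    stop("column out of range [0, ", aln$L, ")")
  aln$maps[[row]][column + 1L]
}

#' Map an ungapped position back to its consensus column
#'
#' Inverse of [ungapped_position()] restricted to non-gap columns.
#'
#' @inheritParams ungapped_position
#' @param position 0-based ungapped position(s) in row \code{row}.
#' @return 0-based consensus column(s).
#' @export
consensus_column <- function(aln, row, position) {
  if (!row %in% names(aln$maps)) stop("unknown row id: ", row)
  map <- aln$maps[[row]]
  inv <- which(!is.na(map)) - 1L          # columns carrying residues
  n <- length(inv)
  if (any(position < 0 | position >= n))
    stop("position out of range [0, ", n, ")")
  inv[position + 1L]
}

#' Degap one alignment row
#'
#' @inheritParams ungapped_position
#' @return the row's ungapped residue string.
#' @export
ungapped_sequence <- function(aln, row) {
  if (!row %in% names(aln$seqs)) stop("unknown row id: ", row)
  gsub(GAP_CHAR, "", aln$seqs[[row]], fixed = TRUE)
}
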