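#' Construct a genome sequence
#'
#' @param id sequence id.
#' @param residues residue string over \code{A C G T N} (case-insensitive on
#'   input, stored uppercase).
#' @param topology \code{"circular"} (chloroplast genomes) or \code{"linear"}.
#' @return a \code{GenomeSequence}: list with \code{id}, \code{residues},
#'   \code{topology}, \code{length}.
#' @export
genome_sequence <- function(id, residues, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  residues <- toupper(residues)
  if (nchar(residues) == 0) stop("residues must be non-empty")
  bad <- regexpr("[^ACGTN]", residues)
  if (bad > 0)
    stop("illegal residue at position ", bad, " in '", id, "'")
  structure(list(id = id, residues = residues, topology = topology,
                 length = nchar(residues)),
            class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat(sprintf("GenomeSequence '%s': %d bp, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Read a genome from FASTA
#'
#' @param path FASTA path; the first record is used unless \code{id} is given.
#' @param id optional record id to select.
#' @param topology sequence topology (chloroplast references are circular).
#' @return a \code{GenomeSequence}.
#' @export
read_genome <- function(path, id = NULL, topology = "circular") {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  i <- if (is.null(id)) 1L else match(id, nm)
  if (is.na(i)) stop("record '", id, "' not found in ", path)
  genome_sequence(nm[i], as.character(ss[[i]]), topology = topology)
}

#' Write one or more sequences to FASTA
#'
#' @param seqs named character vector of residue strings (may contain
#'   \code{-} for scaffold gaps).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

## ReadPair table ------------------------------------------------------------

#' Assemble a read-pair table
#'
#' Read pairs are kept in a plain data frame: columns \code{id}, \code{read1},
#' \code{qual1}, \code{read2}, \code{qual2} (sequences uppercase, qualities
#' Phred+33 strings of matching length).
#'
#' @param id,read1,qual1,read2,qual2 parallel character vectors.
#' @return a \code{data.frame} of read pairs.
#' @export
read_pairs <- function(id, read1, qual1, read2, qual2) {
  df <- data.frame(id = id, read1 = toupper(read1), qual1 = qual1,
                   read2 = toupper(read2), qual2 = qual2,
                   stringsAsFactors = FALSE)
  if (any(nchar(df$read1) != nchar(df$qual1)) ||
      any(nchar(df$read2) != nchar(df$qual2)))
    stop("read and quality lengths differ")
  sc <- unlist(phred_decode(c(df$qual1, df$qual2)))
  if (length(sc) && (min(sc) < 0 || max(sc) > 60))
    stop("Phred scores must lie in [0, 60]")
  df
}

parse_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (", path, "): ", length(lines),
         " lines is not a multiple of 4")
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seq <- lines[seq(2, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(substr(hdr, 1, 1) != "@")
  if (length(bad))
    stop("malformed FASTQ (", path, "): record ", bad[1],
         " does not start with '@'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ (", path, "): record ", bad[1],
         " sequence/quality length mismatch")
  list(id = sub("\\s.*$", "", substring(hdr, 2)), seq = toupper(seq),
       qual = qual)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 FASTQ files for read 1 and read 2 (Phred+33).
#' @return a read-pair \code{data.frame} (see [read_pairs()]).
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- parse_fastq(path1)
  r2 <- parse_fastq(path2)
  if (length(r1$id) != length(r2$id))
    stop("mate files differ in record count")
  read_pairs(r1$id, r1$seq, r1$qual, r2$seq, r2$qual)
}

#' Write a read-pair table to two FASTQ files
#'
#' @param pairs read-pair \code{data.frame}.
#' @param path1,path2 output FASTQ paths for the two mates.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  fmt <- function(id, s, q) as.vector(rbind(paste0("@", id), s, "+", q))
  writeLines(fmt(pairs$id, pairs$read1, pairs$qual1), path1)
  writeLines(fmt(pairs$id, pairs$read2, pairs$qual2), path2)
  invisible(c(path1, path2))
}

## Region helpers ------------------------------------------------------------

#' Length of 0-based half-open regions on a possibly circular axis
#'
#' A region with \code{end <= start} encodes a wrap around the origin of a
#' circular axis of length \code{L}.
#'
#' @param start,end 0-based half-open bounds.
#' @param L axis length (needed for wrapped regions).
#' @return integer region lengths.
#' @export
region_length <- function(start, end, L = NA_integer_) {
  len <- ifelse(end > start, end - start,
                ifelse(is.na(L), NA_integer_, end - start + L))
  as.integer(len)
}

#' Write regions as BED (0-based half-open)
#'
#' Wrapped regions on a circular axis are split at the origin into two BED
#' lines sharing one name.
#'
#' @param regions data.frame with columns \code{start}, \code{end} (0-based
#'   half-open) and optionally \code{name}.
#' @param path output path.
#' @param chrom chromosome/sequence label for column 1.
#' @param L axis length, used to split wrapped regions.
#' @export
write_bed <- function(regions, path, chrom = "consensus", L = NA_integer_) {
  name <- if ("name" %in% names(regions)) regions$name
          else sprintf("region_%d", seq_len(nrow(regions)))
  out <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    if (e > s) data.frame(chrom = chrom, start = s, end = e, name = name[i])
    else rbind(data.frame(chrom = chrom, start = s, end = L, name = name[i]),
               data.frame(chrom = chrom, start = 0L, end = e, name = name[i]))
  })
  out <- do.call(rbind, out)
  out <- out[out$end > out$start, , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
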