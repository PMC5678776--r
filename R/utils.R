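#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
NULL

GAP_CHAR <- "-"
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

## reverse complement of a plain character string (IUPAC core + N + gap)
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    rc <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(rc, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## substring of a possibly circular sequence, 0-based half-open [start, end);
## indices outside [0, L) wrap when circular
circ_substr <- function(seq, start, end, circular = TRUE) {
  L <- nchar(seq)
  n <- end - start
  if (n < 0) stop("end must be >= start")
  if (n == 0) return("")
  if (!circular) {
    if (start < 0 || end > L) stop("substring out of range on a linear sequence")
    return(substr(seq, start + 1, end))
  }
  idx <- ((seq.int(start, end - 1L)) %% L) + 1L
  if (idx[1] <= idx[length(idx)] && all(diff(idx) == 1L)) {
    substr(seq, idx[1], idx[length(idx)])
  } else {
    paste(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = "")
  }
}

## Phred+33 helpers ----------------------------------------------------------

phred_decode <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

phred_encode <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(pmin(s, 60L) + 33L)),
         character(1))
}

## split sequences into a character matrix (rows = sequences)
seq_char_matrix <- function(seqs) {
  n <- length(seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1)
    stop("sequences differ in length")
  m <- matrix("", nrow = n, ncol = L)
  for (i in seq_len(n)) m[i, ] <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
  rownames(m) <- names(seqs)
  m
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance needs equal lengths")
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

## longest suffix(a)/prefix(b) overlap with per-base identity >= min_identity;
## returns 0 when no overlap of at least min_overlap qualifies.
## Candidate overlap lengths are located by exact seed words from the prefix
## of b (seed-and-verify, as overlap assemblers do), so a handful of
## substring checks replaces a scan over every possible overlap length.
best_overlap <- function(a, b, min_overlap = 20L, min_identity = 0.95) {
  na <- nchar(a); nb <- nchar(b)
  max_o <- min(na, nb)
  if (max_o < min_overlap) return(0L)
  seed_len <- 12L
  n_seeds <- if (min_identity >= 1) 1L else 3L
  cand <- integer(0)
  for (k in seq_len(n_seeds)) {
    s <- (k - 1L) * seed_len + 1L             # 1-based seed start in b
    if (s + seed_len - 1L > nb) break
    seed <- substr(b, s, s + seed_len - 1L)
    hits <- gregexpr(seed, a, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    cand <- c(cand, na - hits + s)            # implied overlap lengths
  }
  cand <- sort(unique(cand[cand >= min_overlap & cand <= max_o]),
               decreasing = TRUE)
  max_mm <- function(o) floor((1 - min_identity) * o)
  for (o in cand) {
    sa <- substr(a, na - o + 1L, na)
    sb <- substr(b, 1L, o)
    if (sa == sb) return(as.integer(o))
    if (max_mm(o) > 0L && hamming(sa, sb) <= max_mm(o)) return(as.integer(o))
  }
  0L
}

## merge b onto the right end of a given a suffix/prefix overlap of length o.
## In the overlapping window the base of the deeper sequence wins; ties go to
## the lexicographically smaller base (deterministic).
merge_with_overlap <- function(a, b, o, depth_a = 1L, depth_b = 1L) {
  if (o == 0L) stop("cannot merge without overlap")
  na <- nchar(a)
  ov_a <- substr(a, na - o + 1L, na)
  ov_b <- substr(b, 1L, o)
  ov <- if (depth_a > depth_b) ov_a
        else if (depth_b > depth_a) ov_b
        else {
          va <- strsplit(ov_a, "", fixed = TRUE)[[1]]
          vb <- strsplit(ov_b, "", fixed = TRUE)[[1]]
          paste(pmin(va, vb), collapse = "")
        }
  paste0(substr(a, 1L, na - o), ov, substr(b, o + 1L, nchar(b)))
}

## 1-based inclusive reporting of 0-based half-open internal coordinates
report_1based <- function(start0, end0) {
  data.frame(start = start0 + 1L, end = end0)
}
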