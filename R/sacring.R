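#' Default parameters for the RAD-Seq sub-assembly pipeline
#'
#' Clustering thresholds follow common stacks-style defaults and merge
#' thresholds CAP3-style defaults; all are adjustable.
#'
#' @param min_depth minimum read-1 support for a tag cluster.
#' @param max_mismatch maximum mismatches between a read 1 and its cluster
#'   seed.
#' @param min_overlap,min_identity suffix/prefix overlap length and identity
#'   required for any merge (tag-2 assembly, overlap tags, contig chaining).
#' @param max_mismatch_frac maximum mismatch fraction for the cut-anchored
#'   read-1 matcher against the reference.
#' @param motif restriction recognition motif (EcoRI \code{GAATTC}).
#' @param cut_offset bases before the cut on the forward strand
#'   (EcoRI \code{G^AATTC}: 1).
#' @param q20_min minimum fraction of bases at Q>=20 per read.
#' @param n_max maximum fraction of \code{N} bases per read.
#' @return named list of parameters.
#' @export
sacring_params <- function(min_depth = 3L, max_mismatch = 2L,
                           min_overlap = 20L, min_identity = 0.95,
                           max_mismatch_frac = 0.05,
                           motif = "GAATTC", cut_offset = 1L,
                           q20_min = 0.90, n_max = 0.05) {
  list(min_depth = min_depth, max_mismatch = max_mismatch,
       min_overlap = min_overlap, min_identity = min_identity,
       max_mismatch_frac = max_mismatch_frac, motif = toupper(motif),
       cut_offset = cut_offset, q20_min = q20_min, n_max = n_max)
}

#' Quality-filter read pairs
#'
#' A pair is kept only when both mates have a Q20 base fraction of at least
#' \code{q20_min} and an \code{N} fraction below \code{n_max}.
#'
#' @param pairs read-pair data.frame (see [read_pairs()]).
#' @param q20_min,n_max thresholds (defaults 0.90 and 0.05).
#' @return list with \code{pairs} (the kept rows) and \code{report}
#'   (totals plus per-mate Q30 base fractions among kept pairs).
#' @export
qc_filter <- function(pairs, q20_min = 0.90, n_max = 0.05) {
  stat <- function(seqs, quals) {
    sc <- phred_decode(quals)
    q20 <- vapply(sc, function(s) mean(s >= 20L), numeric(1))
    q30 <- vapply(sc, function(s) mean(s >= 30L), numeric(1))
    nf <- vapply(seqs, function(s)
      lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s),
      numeric(1), USE.NAMES = FALSE)
    list(q20 = q20, q30 = q30, nf = nf)
  }
  s1 <- stat(pairs$read1, pairs$qual1)
  s2 <- stat(pairs$read2, pairs$qual2)
  keep <- s1$q20 >= q20_min & s2$q20 >= q20_min &
          s1$nf < n_max & s2$nf < n_max
  report <- data.frame(
    reads_total = nrow(pairs), reads_kept = sum(keep),
    reads_dropped = sum(!keep),
    q30_read1 = if (any(keep)) mean(s1$q30[keep]) else NA_real_,
    q30_read2 = if (any(keep)) mean(s2$q30[keep]) else NA_real_)
  list(pairs = pairs[keep, , drop = FALSE], report = report)
}

#' Find restriction sites on a reference
#'
#' Reports every forward-strand occurrence of the recognition motif,
#' including occurrences spanning the origin of a circular reference.
#' Palindromic motifs (EcoRI) are reported once per position.
#'
#' @param ref a \code{GenomeSequence}.
#' @param motif recognition motif (default EcoRI \code{GAATTC}).
#' @return integer vector of 0-based motif start positions, sorted.
#' @export
find_re_sites <- function(ref, motif = "GAATTC") {
  motif <- toupper(motif)
  if (nchar(motif) == 0) stop("motif must be non-empty")
  s <- ref$residues
  ext <- if (ref$topology == "circular")
    paste0(s, substr(s, 1, nchar(motif) - 1L)) else s
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(ext))
  pos <- BiocGenerics::start(m) - 1L
  sort(unique(pos[pos < ref$length]))
}

## expected read-1 sequences at each cut, in read orientation:
##   right side: forward strand from position site + cut_offset
##   left side:  reverse complement ending at site + motif_len - cut_offset
## Both start with the post-cut motif remnant (EcoRI: AATTC).
cut_read1_candidates <- function(ref, sites, read_len, motif = "GAATTC",
                                 cut_offset = 1L) {
  ml <- nchar(motif)
  circ <- ref$topology == "circular"
  do.call(rbind, lapply(sites, function(p) {
    right <- circ_substr(ref$residues, p + cut_offset,
                         p + cut_offset + read_len, circ)
    left <- revcomp(circ_substr(ref$residues, p + ml - cut_offset - read_len,
                                p + ml - cut_offset, circ))
    data.frame(site = p, side = c("left", "right"),
               expected = c(left, right), stringsAsFactors = FALSE)
  }))
}

#' Extract chloroplast read pairs anchored at restriction cuts
#'
#' A pair is chloroplast-related when its read 1 matches the reference
#' starting at the cut position of some restriction site (either side) with
#' a mismatch fraction of at most \code{max_mismatch_frac}. Kept pairs are
#' annotated with the matched site and side; everything else (nuclear
#' contamination, chimeras) is dropped.
#'
#' @param pairs QC-passed read-pair data.frame.
#' @param ref reference \code{GenomeSequence}.
#' @param sites 0-based motif positions from [find_re_sites()].
#' @param params parameter list from [sacring_params()].
#' @return the kept pairs with columns \code{site} and \code{side} appended,
#'   reads truncated to the common read length.
#' @export
extract_cp_pairs <- function(pairs, ref, sites = find_re_sites(ref),
                             params = sacring_params()) {
  if (!length(sites)) stop("reference contains no restriction sites")
  if (!nrow(pairs)) {
    out <- pairs
    out$site <- integer(0); out$side <- character(0)
    return(out)
  }
  rl <- min(nchar(pairs$read1))
  cand <- cut_read1_candidates(ref, sites, rl, params$motif,
                               params$cut_offset)
  reads <- substr(pairs$read1, 1L, rl)
  readm <- seq_char_matrix(setNames(reads, seq_along(reads)))
  max_mm <- floor(params$max_mismatch_frac * rl)
  best_mm <- rep(Inf, nrow(pairs))
  best_k <- rep(NA_integer_, nrow(pairs))
  for (k in seq_len(nrow(cand))) {
    cv <- strsplit(cand$expected[k], "", fixed = TRUE)[[1]]
    mm <- rowSums(readm != matrix(cv, nrow = nrow(readm), ncol = rl,
                                  byrow = TRUE))
    better <- mm < best_mm
    best_mm[better] <- mm[better]
    best_k[better] <- k
  }
  keep <- best_mm <= max_mm
  out <- pairs[keep, , drop = FALSE]
  out$read1 <- substr(out$read1, 1L, rl)
  out$qual1 <- substr(out$qual1, 1L, rl)
  out$site <- cand$site[best_k[keep]]
  out$side <- cand$side[best_k[keep]]
  rownames(out) <- NULL
  out
}

## majority consensus of equal-length reads with per-read weights;
## ties resolved toward the lexicographically smaller base
majority_consensus <- function(reads, weights = rep(1L, length(reads))) {
  m <- seq_char_matrix(setNames(reads, seq_along(reads)))
  apply_cols <- vapply(seq_len(ncol(m)), function(j) {
    tab <- tapply(weights, m[, j], sum)
    tab <- tab[order(-tab, names(tab))]
    names(tab)[1]
  }, character(1))
  paste(apply_cols, collapse = "")
}

#' Cluster read 1s into tags at each cut site and side
#'
#' Within each (site, side) group, the most frequent read seeds a cluster
#' that absorbs all reads within \code{max_mismatch} of it; the cluster
#' consensus is the per-column majority. Remaining reads seed further
#' clusters. Groups supported by fewer than \code{min_depth} reads are
#' discarded. Because the organelle is effectively haploid, when two or more
#' clusters survive in one group only the deepest is emitted and the tag is
#' flagged as a candidate assembly artefact.
#'
#' @param cp_pairs annotated pairs from [extract_cp_pairs()].
#' @param ref reference \code{GenomeSequence} (for forward-strand anchoring).
#' @param params parameter list from [sacring_params()].
#' @return data.frame of tags: \code{site}, \code{side}, \code{consensus}
#'   (read orientation), \code{depth}, \code{flagged}, \code{fwd}
#'   (reference-forward orientation), \code{fwd_start} (0-based anchor).
#' @export
cluster_tag1 <- function(cp_pairs, ref, params = sacring_params()) {
  ml <- nchar(params$motif)
  co <- params$cut_offset
  groups <- split(seq_len(nrow(cp_pairs)),
                  paste(cp_pairs$site, cp_pairs$side))
  tags <- lapply(groups, function(idx) {
    reads <- cp_pairs$read1[idx]
    rl <- nchar(reads[1])
    clusters <- list()
    pool <- reads
    while (length(pool)) {
      tab <- table(pool)
      tab <- tab[order(-tab, names(tab))]
      seed <- names(tab)[1]
      d <- vapply(pool, hamming, integer(1), b = seed, USE.NAMES = FALSE)
      members <- pool[d <= params$max_mismatch]
      cons <- majority_consensus(members)
      clusters[[length(clusters) + 1L]] <- list(consensus = cons,
                                                depth = length(members))
      pool <- pool[d > params$max_mismatch]
    }
    depths <- vapply(clusters, `[[`, integer(1), "depth")
    keep <- depths >= params$min_depth
    if (!any(keep)) return(NULL)
    surv <- clusters[keep]
    cons_of <- vapply(surv, `[[`, character(1), "consensus")
    pick <- order(-depths[keep], cons_of)[1]
    site <- cp_pairs$site[idx[1]]
    side <- cp_pairs$side[idx[1]]
    cons <- surv[[pick]]$consensus
    if (side == "right") {
      fwd <- cons
      fwd_start <- site + co
    } else {
      fwd <- revcomp(cons)
      fwd_start <- site + ml - co - rl
    }
    data.frame(site = site, side = side, consensus = cons,
               depth = surv[[pick]]$depth, flagged = sum(keep) > 1L,
               fwd = fwd, fwd_start = fwd_start, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tags)
  if (is.null(out))
    out <- data.frame(site = integer(0), side = character(0),
                      consensus = character(0), depth = integer(0),
                      flagged = logical(0), fwd = character(0),
                      fwd_start = integer(0))
  out <- out[order(out$site, out$side), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy overlap-layout assembly of the read 2s of one tag
#'
#' Identical reads are collapsed with depth counts, then the pair of
#' sequences with the longest suffix/prefix overlap (at least
#' \code{min_overlap} long with identity at least \code{min_identity}) is
#' merged repeatedly; in the overlapping window the deeper sequence's base
#' wins, ties going to the lexicographically smaller base. The longest
#' resulting contig is the tag-2; if no contig exceeds the read length the
#' result is \code{NULL}.
#'
#' @param reads read 2 sequences, already oriented to the reference forward
#'   strand.
#' @param params parameter list from [sacring_params()].
#' @return list with \code{contig} and \code{depth}, or \code{NULL}.
#' @export
assemble_tag2 <- function(reads, params = sacring_params()) {
  if (!length(reads)) return(NULL)
  read_len <- min(nchar(reads))
  tab <- table(reads)
  tab <- tab[order(names(tab))]
  seqs <- names(tab)
  depths <- as.integer(tab)
  ## absorb exact containments
  repeat {
    n <- length(seqs)
    contained <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (contained[i]) next
      for (j in seq_len(n)) {
        if (i == j || contained[j] || contained[i]) next
        if (nchar(seqs[i]) <= nchar(seqs[j]) &&
            grepl(seqs[i], seqs[j], fixed = TRUE) &&
            !(nchar(seqs[i]) == nchar(seqs[j]) && i > j)) {
          depths[j] <- depths[j] + depths[i]
          contained[i] <- TRUE
          break
        }
      }
    }
    if (!any(contained)) break
    seqs <- seqs[!contained]; depths <- depths[!contained]
  }
  ## pairwise overlap matrix, updated incrementally after each merge
  n <- length(seqs)
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) ov[i, j] <- best_overlap(seqs[i], seqs[j],
                                         params$min_overlap,
                                         params$min_identity)
  repeat {
    n <- length(seqs)
    if (n < 2 || max(ov) < params$min_overlap) break
    hits <- which(ov == max(ov), arr.ind = TRUE)
    if (nrow(hits) > 1) {                 # ties: lexicographically smallest
      key <- paste(seqs[hits[, 1]], seqs[hits[, 2]])
      hits <- hits[order(key)[1], , drop = FALSE]
    }
    i <- hits[1, 1]; j <- hits[1, 2]
    merged <- merge_with_overlap(seqs[i], seqs[j], ov[i, j],
                                 depths[i], depths[j])
    md <- depths[i] + depths[j]
    keep <- setdiff(seq_len(n), c(i, j))
    seqs <- c(seqs[keep], merged)
    depths <- c(depths[keep], md)
    m <- length(seqs)
    ov2 <- matrix(0L, m, m)
    ov2[seq_len(m - 1L), seq_len(m - 1L)] <- ov[keep, keep]
    ov <- ov2
    for (k in seq_len(m - 1L)) {
      ov[k, m] <- best_overlap(seqs[k], merged, params$min_overlap,
                               params$min_identity)
      ov[m, k] <- best_overlap(merged, seqs[k], params$min_overlap,
                               params$min_identity)
    }
  }
  k <- order(-nchar(seqs), seqs)[1]
  if (nchar(seqs[k]) <= read_len) return(NULL)
  list(contig = seqs[k], depth = depths[k])
}

## orient the read 2s of one (site, side) group to the reference forward
## strand: left-side read 2s already read the forward strand, right-side
## read 2s are reverse complemented
orient_read2 <- function(reads, side) {
  if (side == "right") revcomp(reads) else reads
}

#' Form paired, overlap, and paired-overlap tags at every site
#'
#' Per restriction site: the paired tag (pT) positionally fuses the two
#' forward-oriented tag-1 consensuses across the 4 bp cut remnant; an
#' overlap tag (oT) extends a tag-1 with its tag-2 when they share a
#' qualifying suffix/prefix overlap; the paired-overlap tag (poT) spans
#' tag-2(left) .. both tag-1s .. tag-2(right) and requires the pT plus both
#' oT merges. A product whose overlap fails the thresholds is simply absent.
#'
#' @param tags1 tag table from [cluster_tag1()].
#' @param tag2s named list of [assemble_tag2()] results, keyed
#'   \code{"<site> <side>"}.
#' @param params parameter list from [sacring_params()].
#' @return data.frame of products: \code{site}, \code{type}
#'   (\code{pT}/\code{oT_left}/\code{oT_right}/\code{poT}), \code{seq}
#'   (forward orientation), \code{fwd_start}, \code{length}, \code{depth}.
#' @export
form_site_products <- function(tags1, tag2s, params = sacring_params()) {
  ml <- nchar(params$motif)
  co <- params$cut_offset
  remnant <- ml - 2L * co            # positional pT overlap (EcoRI: 4)
  rows <- list()
  add <- function(site, type, seq, fwd_start, depth)
    rows[[length(rows) + 1L]] <<- data.frame(
      site = site, type = type, seq = seq, fwd_start = fwd_start,
      length = nchar(seq), depth = depth, stringsAsFactors = FALSE)
  for (p in unique(tags1$site)) {
    tl <- tags1[tags1$site == p & tags1$side == "left", ]
    tr <- tags1[tags1$site == p & tags1$side == "right", ]
    t2l <- tag2s[[paste(p, "left")]]
    t2r <- tag2s[[paste(p, "right")]]
    ## overlap tags: tag2(left) + tag1(left); tag1(right) + tag2(right)
    otl <- otr <- NULL
    if (nrow(tl) == 1 && !is.null(t2l)) {
      o <- best_overlap(t2l$contig, tl$fwd, params$min_overlap,
                        params$min_identity)
      if (o > 0L) {
        seq <- merge_with_overlap(t2l$contig, tl$fwd, o, t2l$depth, tl$depth)
        start <- tl$fwd_start - (nchar(t2l$contig) - o)
        otl <- list(seq = seq, start = start, depth = tl$depth + t2l$depth)
        add(p, "oT_left", seq, start, otl$depth)
      }
    }
    if (nrow(tr) == 1 && !is.null(t2r)) {
      o <- best_overlap(tr$fwd, t2r$contig, params$min_overlap,
                        params$min_identity)
      if (o > 0L) {
        seq <- merge_with_overlap(tr$fwd, t2r$contig, o, tr$depth, t2r$depth)
        otr <- list(seq = seq, start = tr$fwd_start,
                    depth = tr$depth + t2r$depth)
        add(p, "oT_right", seq, tr$fwd_start, otr$depth)
      }
    }
    ## paired tag: both tag1s positionally fused across the cut remnant
    if (nrow(tl) == 1 && nrow(tr) == 1) {
      pt <- merge_with_overlap(tl$fwd, tr$fwd, remnant, tl$depth, tr$depth)
      add(p, "pT", pt, tl$fwd_start, tl$depth + tr$depth)
      ## paired-overlap tag: needs both overlap-tag merges
      if (!is.null(otl) && !is.null(otr)) {
        pot <- merge_with_overlap(otl$seq, otr$seq, remnant,
                                  otl$depth, otr$depth)
        add(p, "poT", pot, otl$start, otl$depth + otr$depth)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = integer(0), type = character(0),
                      seq = character(0), fwd_start = integer(0),
                      length = integer(0), depth = integer(0))
  rownames(out) <- NULL
  out
}

#' Chain anchored site contigs into CpContigs
#'
#' Per site the most complete product (poT, else per-side overlap tags /
#' tag-1s bridged by the pT) is taken; products sorted by reference anchor
#' are merged whenever their anchors imply a suffix/prefix overlap of at
#' least \code{min_overlap} that agrees at \code{min_identity}. A tag whose
#' anchor conflicts with the growing contig (expected overlap disagrees) is
#' dropped, and anchor overlaps below the merge threshold are trimmed, so
#' the resulting contigs are strictly disjoint on the reference (including
#' across the origin of a circular reference). CpContigs contain no gaps or
#' unknown bases.
#'
#' @param tags1 tag table from [cluster_tag1()].
#' @param products product table from [form_site_products()].
#' @param ref reference \code{GenomeSequence} (for circular bookkeeping).
#' @param params parameter list from [sacring_params()].
#' @return data.frame of contigs: \code{contig}, \code{ref_start},
#'   \code{ref_end}, \code{length}, \code{depth}, \code{n_dropped}
#'   (conflicting tags discarded while chaining, same value on all rows).
#' @export
assemble_cpcontigs <- function(tags1, products, ref,
                               params = sacring_params()) {
  pieces <- list()
  for (p in unique(c(tags1$site, products$site))) {
    pr <- products[products$site == p, , drop = FALSE]
    if ("poT" %in% pr$type) {
      sel <- pr[pr$type == "poT", ][1, ]
      pieces[[length(pieces) + 1L]] <-
        data.frame(seq = sel$seq, start = sel$fwd_start, depth = sel$depth)
      next
    }
    if ("pT" %in% pr$type) {
      ## widest span through the cut: arm products where available
      armL <- pr[pr$type == "oT_left", , drop = FALSE]
      armR <- pr[pr$type == "oT_right", , drop = FALSE]
      tl <- tags1[tags1$site == p & tags1$side == "left", , drop = FALSE]
      tr <- tags1[tags1$site == p & tags1$side == "right", , drop = FALSE]
      l <- if (nrow(armL)) armL[1, c("seq", "fwd_start", "depth")]
           else data.frame(seq = tl$fwd, fwd_start = tl$fwd_start,
                           depth = tl$depth)
      r <- if (nrow(armR)) armR[1, c("seq", "fwd_start", "depth")]
           else data.frame(seq = tr$fwd, fwd_start = tr$fwd_start,
                           depth = tr$depth)
      o <- (l$fwd_start + nchar(l$seq)) - r$fwd_start
      merged <- merge_with_overlap(l$seq, r$seq, o, l$depth, r$depth)
      pieces[[length(pieces) + 1L]] <-
        data.frame(seq = merged, start = l$fwd_start, depth = l$depth + r$depth)
      next
    }
    ## single-sided leftovers: per-side best piece
    for (side in c("left", "right")) {
      arm <- pr[pr$type == paste0("oT_", side), , drop = FALSE]
      if (nrow(arm)) {
        pieces[[length(pieces) + 1L]] <-
          data.frame(seq = arm$seq[1], start = arm$fwd_start[1],
                     depth = arm$depth[1])
      } else {
        t1 <- tags1[tags1$site == p & tags1$side == side, , drop = FALSE]
        if (nrow(t1))
          pieces[[length(pieces) + 1L]] <-
            data.frame(seq = t1$fwd, start = t1$fwd_start, depth = t1$depth)
      }
    }
  }
  empty <- data.frame(contig = character(0), ref_start = integer(0),
                      ref_end = integer(0), length = integer(0),
                      depth = integer(0), n_dropped = integer(0))
  if (!length(pieces)) return(empty)
  pc <- do.call(rbind, pieces)
  pc <- pc[order(pc$start, -nchar(pc$seq)), , drop = FALSE]
  contigs <- list()
  n_dropped <- 0L
  cur <- pc[1, ]
  for (i in seq_len(nrow(pc))[-1]) {
    nxt <- pc[i, ]
    cur_end <- cur$start + nchar(cur$seq)
    o <- cur_end - nxt$start
    if (o <= 0L) {                      # disjoint: close the contig
      contigs[[length(contigs) + 1L]] <- cur
      cur <- nxt
    } else if (nxt$start + nchar(nxt$seq) <= cur_end) {
      cur$depth <- cur$depth + nxt$depth   # contained: absorb
    } else if (o >= params$min_overlap) {
      ident <- 1 - hamming(substr(cur$seq, nchar(cur$seq) - o + 1L,
                                  nchar(cur$seq)),
                           substr(nxt$seq, 1L, o)) / o
      if (ident >= params$min_identity) {
        cur$seq <- merge_with_overlap(cur$seq, nxt$seq, o, cur$depth,
                                      nxt$depth)
        cur$depth <- cur$depth + nxt$depth
      } else {                          # anchor conflict: drop the tag
        n_dropped <- n_dropped + 1L
      }
    } else {                  # sub-threshold overlap: trim and break
      contigs[[length(contigs) + 1L]] <- cur
      nxt$seq <- substr(nxt$seq, o + 1L, nchar(nxt$seq))
      nxt$start <- cur_end
      cur <- nxt
    }
  }
  contigs[[length(contigs) + 1L]] <- cur
  ## circular references: the last contig may reach across the origin into
  ## the first one; merge when the implied overlap qualifies, trim otherwise
  L <- ref$length
  if (length(contigs) >= 2) {
    first <- contigs[[1]]; last <- contigs[[length(contigs)]]
    o <- (last$start + nchar(last$seq) - L) - first$start
    if (o > 0L) {
      if (o >= params$min_overlap &&
          1 - hamming(substr(last$seq, nchar(last$seq) - o + 1L,
                             nchar(last$seq)),
                      substr(first$seq, 1L, o)) / o >= params$min_identity) {
        merged <- merge_with_overlap(last$seq, first$seq, o,
                                     last$depth, first$depth)
        last$seq <- merged
        last$depth <- last$depth + first$depth
        contigs <- c(contigs[-c(1, length(contigs))], list(last))
      } else {
        first$seq <- substr(first$seq, o + 1L, nchar(first$seq))
        first$start <- first$start + o
        contigs[[1]] <- first
      }
    }
  }
  out <- do.call(rbind, lapply(contigs, function(x)
    data.frame(contig = x$seq, ref_start = x$start,
               ref_end = x$start + nchar(x$seq), length = nchar(x$seq),
               depth = x$depth)))
  out$n_dropped <- n_dropped
  rownames(out) <- NULL
  out
}

#' Build the sub-super-marker scaffold
#'
#' A reference-length string carrying each CpContig's residues at its anchor
#' and \code{'-'} at every unassembled position: a reduced, reference-ordered
#' representation of the chloroplast genome. When contig anchors overlap the
#' deeper contig wins.
#'
#' @param cpcontigs contig table from [assemble_cpcontigs()].
#' @param ref reference \code{GenomeSequence}.
#' @return list with \code{scaffold} (character string),
#'   \code{covered_fraction}, and \code{provenance} (integer vector: index
#'   of the contig at each position, \code{NA} where unknown).
#' @export
build_sub_super_marker <- function(cpcontigs, ref) {
  L <- ref$length
  sc <- rep(GAP_CHAR, L)
  prov <- rep(NA_integer_, L)
  ord <- order(cpcontigs$depth)         # deeper contigs written last
  for (i in ord) {
    chars <- strsplit(cpcontigs$contig[i], "", fixed = TRUE)[[1]]
    idx <- ((cpcontigs$ref_start[i] + seq_along(chars) - 1L) %% L) + 1L
    sc[idx] <- chars
    prov[idx] <- i
  }
  list(scaffold = paste(sc, collapse = ""),
       covered_fraction = mean(sc != GAP_CHAR),
       provenance = prov)
}

#' Run the full sub-assembly pipeline for one individual
#'
#' QC, cut-anchored extraction, tag-1 clustering, tag-2 assembly, product
#' formation (pT/oT/poT), contig chaining and scaffold construction.
#'
#' @param pairs raw read-pair data.frame for one individual.
#' @param ref reference \code{GenomeSequence}.
#' @param params parameter list from [sacring_params()].
#' @param denominator_length reference length used for the coverage ratio
#'   (e.g. excluding one inverted repeat); default the full reference.
#' @return list: \code{qc}, \code{sites}, \code{cp_pairs}, \code{tags1},
#'   \code{tag2s}, \code{products}, \code{cpcontigs}, \code{scaffold},
#'   \code{report} (one-row data.frame of pipeline statistics).
#' @export
sacring_individual <- function(pairs, ref, params = sacring_params(),
                               denominator_length = ref$length) {
  qc <- qc_filter(pairs, params$q20_min, params$n_max)
  sites <- find_re_sites(ref, params$motif)
  cp <- extract_cp_pairs(qc$pairs, ref, sites, params)
  tags1 <- cluster_tag1(cp, ref, params)
  ## tag-2 per (site, side): read 2s of reads in the kept cluster,
  ## oriented to the reference forward strand
  tag2s <- list()
  if (nrow(tags1)) {
    for (k in seq_len(nrow(tags1))) {
      p <- tags1$site[k]; side <- tags1$side[k]
      idx <- which(cp$site == p & cp$side == side)
      keep <- vapply(cp$read1[idx], hamming, integer(1),
                     b = tags1$consensus[k], USE.NAMES = FALSE) <=
        params$max_mismatch
      r2 <- orient_read2(cp$read2[idx[keep]], side)
      tag2s[[paste(p, side)]] <- assemble_tag2(r2, params)
    }
  }
  products <- form_site_products(tags1, tag2s, params)
  cpcontigs <- assemble_cpcontigs(tags1, products, ref, params)
  scaffold <- build_sub_super_marker(cpcontigs, ref)
  n_pt <- sum(products$type == "pT")
  n_ot <- sum(products$type %in% c("oT_left", "oT_right"))
  n_pot <- sum(products$type == "poT")
  n_tag1 <- nrow(tags1)
  report <- cbind(qc$report, data.frame(
    n_sites = length(sites),
    tag1_n = n_tag1,
    sites_touched = length(unique(tags1$site)),
    pt_n = n_pt, pt_ratio = if (n_tag1) 2 * n_pt / n_tag1 else NA_real_,
    ot_n = n_ot, ot_ratio = if (n_tag1) n_ot / n_tag1 else NA_real_,
    pot_n = n_pot, pot_ratio = if (n_tag1) 2 * n_pot / n_tag1 else NA_real_,
    cpcontig_n = nrow(cpcontigs),
    cpcontig_len = sum(cpcontigs$length),
    cpcontig_ratio = sum(cpcontigs$length) / denominator_length))
  list(qc = qc$report, sites = sites, cp_pairs = cp, tags1 = tags1,
       tag2s = tag2s, products = products, cpcontigs = cpcontigs,
       scaffold = scaffold, report = report)
}
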