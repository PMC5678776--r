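## -------------------------------------------------------------------------
## Synthetic data: circular references with planted restriction sites,
## mutated individual genomes with truth sets, in-silico restriction-digest
## paired-end reads, and true (edit-script derived) gapped alignments.
## All generators are seed-deterministic.
## -------------------------------------------------------------------------

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## positions (0-based) of motif occurrences on a circular string
scan_motif <- function(s, motif) {
  L <- nchar(s)
  ext <- paste0(s, substr(s, 1, nchar(motif) - 1L))
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(ext))
  pos <- BiocGenerics::start(m) - 1L
  sort(unique(pos[pos < L]))
}

#' Simulate a circular reference with a fixed number of restriction sites
#'
#' Generates a random circular genome carrying exactly \code{n_sites}
#' occurrences of the recognition motif, planted with pairwise (circular)
#' spacing of at least \code{min_spacing}; spurious occurrences arising by
#' chance are removed by resampling single bases.
#'
#' @param length genome length in bp (default 30 kb: a compact stand-in for
#'   a chloroplast genome that keeps the full pipeline fast).
#' @param n_sites number of motif occurrences to plant (default 12).
#' @param min_spacing minimum circular distance between planted motifs.
#' @param seed RNG seed.
#' @param motif recognition motif (default EcoRI \code{GAATTC}).
#' @return list with \code{genome} (a circular \code{GenomeSequence}) and
#'   \code{sites} (0-based motif positions).
#' @export
simulate_reference <- function(length = 30000L, n_sites = 12L,
                               min_spacing = 1000L, seed = 1L,
                               motif = "GAATTC") {
  ml <- nchar(motif)
  if (n_sites * (min_spacing + ml) > length)
    stop("infeasible: n_sites * (min_spacing + motif length) exceeds length")
  set.seed(seed)
  s <- random_bases(length)
  ## choose planting positions with circular spacing >= min_spacing
  pos <- integer(0)
  if (n_sites > 0) {
    for (try in 1:1000) {
      cand <- sort(sample.int(length, n_sites) - 1L)
      gaps <- diff(c(cand, cand[1] + length))
      if (n_sites == 1 || all(gaps >= min_spacing + ml)) { pos <- cand; break }
    }
    if (n_sites > 1 && !base::length(pos))
      stop("could not place sites with the requested spacing")
  }
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  mv <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (p in pos) sv[((p + seq_len(ml) - 1L) %% length) + 1L] <- mv
  planted_cols <- unlist(lapply(pos, function(p)
    ((p + seq_len(ml) - 1L) %% length) + 1L))
  ## knock out spurious occurrences without touching planted bases
  s <- paste(sv, collapse = "")
  repeat {
    occ <- scan_motif(s, motif)
    spurious <- setdiff(occ, pos)
    if (!base::length(spurious)) break
    for (p in spurious) {
      cols <- ((p + seq_len(ml) - 1L) %% length) + 1L
      free <- setdiff(cols, planted_cols)
      j <- free[sample.int(base::length(free), 1L)]
      sv[j] <- sample(setdiff(c("A", "C", "G", "T"), sv[j]), 1L)
    }
    s <- paste(sv, collapse = "")
  }
  list(genome = genome_sequence("simref", s, "circular"), sites = pos)
}

#' Plant SNPs and indels into a genome, recording the truth
#'
#' SNP and indel positions are drawn per site at the given rates and then
#' thinned: events falling inside protected intervals (by default the
#' restriction motifs plus a buffer) or closer than \code{min_separation}
#' to an already accepted event are discarded, so each planted event is
#' individually identifiable in an alignment. If an event combination
#' happens to create a new motif occurrence the draw is repeated.
#'
#' @param ref reference \code{GenomeSequence}.
#' @param snp_rate,indel_rate per-site event rates in \[0, 0.1\].
#' @param seed RNG seed.
#' @param protect integer positions that events must avoid (default: all
#'   motif occurrences, each padded by \code{min_separation}).
#' @param min_separation minimum distance between planted events.
#' @param indel_max maximum indel length (lengths uniform on 1..indel_max).
#' @param motif recognition motif, used for protection and rescans.
#' @return list with \code{genome} (the mutant), \code{truth} (data.frame:
#'   \code{type} in snp/ins/del, \code{pos} 0-based reference position,
#'   \code{ref}, \code{alt}, \code{len}).
#' @export
mutate_genome <- function(ref, snp_rate = 0.005, indel_rate = 0,
                          seed = 1L, protect = NULL, min_separation = 12L,
                          indel_max = 10L, motif = "GAATTC") {
  if (snp_rate < 0 || snp_rate > 0.1 || indel_rate < 0 || indel_rate > 0.1)
    stop("rates must lie in [0, 0.1]")
  set.seed(seed)
  L <- ref$length
  if (is.null(protect)) {
    occ <- scan_motif(ref$residues, motif)
    protect <- unique(unlist(lapply(occ, function(p)
      ((p - min_separation):(p + nchar(motif) + min_separation - 1L)) %% L)))
  }
  n_occ <- length(scan_motif(ref$residues, motif))
  rv <- strsplit(ref$residues, "", fixed = TRUE)[[1]]
  for (attempt in 1:50) {
    truth <- draw_events(rv, L, snp_rate, indel_rate, protect,
                         min_separation, indel_max)
    mut <- apply_truth(ref$residues, truth)
    if (length(scan_motif(mut, motif)) == n_occ) {
      return(list(genome = genome_sequence(paste0(ref$id, "_mut"), mut,
                                           ref$topology),
                  truth = truth))
    }
  }
  stop("could not plant mutations without disturbing motif occurrences")
}

draw_events <- function(rv, L, snp_rate, indel_rate, protect,
                        min_separation, indel_max) {
  snp_pos <- which(runif(L) < snp_rate) - 1L
  ind_pos <- which(runif(L) < indel_rate) - 1L
  cand <- rbind(
    if (length(snp_pos)) data.frame(type = "snp", pos = snp_pos),
    if (length(ind_pos)) data.frame(type = "indel", pos = ind_pos))
  if (is.null(cand))
    return(data.frame(type = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      len = integer(0)))
  cand <- cand[order(cand$pos, cand$type), , drop = FALSE]
  accepted <- list(); last_end <- -Inf
  for (i in seq_len(nrow(cand))) {
    p <- cand$pos[i]
    len <- if (cand$type[i] == "indel")
      sample.int(indel_max, 1L) else 1L
    span <- p:(p + len)                 # event footprint plus one flank base
    if (any(span %% L %in% protect)) next
    if (p - last_end < min_separation) next
    if (p + len > L) next               # keep events off the origin join
    ev <- if (cand$type[i] == "snp") {
      data.frame(type = "snp", pos = p, ref = rv[p + 1L],
                 alt = sample(setdiff(c("A", "C", "G", "T"), rv[p + 1L]), 1L),
                 len = 1L)
    } else if (runif(1) < 0.5) {
      data.frame(type = "ins", pos = p, ref = "",
                 alt = random_bases(len), len = len)
    } else {
      data.frame(type = "del", pos = p,
                 ref = paste(rv[(p + 1L):(p + len)], collapse = ""),
                 alt = "", len = len)
    }
    accepted[[length(accepted) + 1L]] <- ev
    last_end <- p + len
  }
  out <- do.call(rbind, accepted)
  if (is.null(out))
    out <- data.frame(type = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      len = integer(0))
  out
}

#' Apply a truth set to a reference sequence
#'
#' Reproduces the mutant genome from the reference and the recorded events
#' (insertions are placed before their reference position).
#'
#' @param residues reference residue string.
#' @param truth truth data.frame from [mutate_genome()].
#' @return mutant residue string.
#' @export
apply_truth <- function(residues, truth) {
  rv <- strsplit(residues, "", fixed = TRUE)[[1]]
  out <- as.list(rv)
  for (i in seq_len(nrow(truth))) {
    p <- truth$pos[i] + 1L
    switch(truth$type[i],
           snp = { out[[p]] <- truth$alt[i] },
           ins = { out[[p]] <- paste0(truth$alt[i], out[[p]]) },
           del = { for (k in p:(p + truth$len[i] - 1L)) out[[k]] <- "" })
  }
  paste(unlist(out), collapse = "")
}

#' Simulate a set of genomes diverged from one reference
#'
#' Event positions are drawn from a shared pool so that no two genomes
#' carry events within \code{min_separation} of each other: every planted
#' event is then attributable in the true alignment and pairwise PIC between
#' any two genomes equals the sum of their event counts.
#'
#' @param ref reference \code{GenomeSequence}.
#' @param n number of genomes.
#' @param snp_rate,indel_rate per-site rates per genome.
#' @param seed RNG seed.
#' @inheritParams mutate_genome
#' @return list with \code{genomes} (named list of \code{GenomeSequence})
#'   and \code{truths} (named list of truth data.frames).
#' @export
simulate_divergent_genomes <- function(ref, n, snp_rate = 0.005,
                                       indel_rate = 0.001, seed = 1L,
                                       min_separation = 12L,
                                       indel_max = 10L, motif = "GAATTC") {
  set.seed(seed)
  L <- ref$length
  occ <- scan_motif(ref$residues, motif)
  protect <- unique(unlist(lapply(occ, function(p)
    ((p - min_separation):(p + nchar(motif) + min_separation - 1L)) %% L)))
  rv <- strsplit(ref$residues, "", fixed = TRUE)[[1]]
  taken <- protect
  genomes <- list(); truths <- list()
  n_occ <- length(occ)
  for (g in seq_len(n)) {
    for (attempt in 1:50) {
      truth <- draw_events(rv, L, snp_rate, indel_rate, taken,
                           min_separation, indel_max)
      mut <- apply_truth(ref$residues, truth)
      if (length(scan_motif(mut, motif)) == n_occ) break
      if (attempt == 50) stop("could not place events for genome ", g)
    }
    id <- sprintf("g%d", g)
    genomes[[id]] <- genome_sequence(id, mut, ref$topology)
    truths[[id]] <- truth
    if (nrow(truth))
      taken <- unique(c(taken, unlist(lapply(seq_len(nrow(truth)),
        function(i) {
          p <- truth$pos[i]
          ((p - min_separation):(p + truth$len[i] + min_separation)) %% L
        }))))
  }
  list(genomes = genomes, truths = truths)
}

#' Build the true gapped alignment from edit scripts
#'
#' Constructs the multiple alignment of mutant genomes (optionally with the
#' reference as an extra row) directly from their truth sets -- no aligner
#' is involved, so the alignment is exact by construction. Insertions open
#' gap columns in all other rows; deletions leave gap runs in their own row.
#'
#' @param ref reference \code{GenomeSequence}.
#' @param truths named list of truth data.frames (disjoint event positions,
#'   as produced by [simulate_divergent_genomes()]).
#' @param include_reference add the reference itself as the first row?
#' @param groups optional group labels passed to [new_alignment()].
#' @return a \code{MultiAlignment}.
#' @export
simulate_alignment <- function(ref, truths, include_reference = FALSE,
                               groups = NULL) {
  L <- ref$length
  rv <- strsplit(ref$residues, "", fixed = TRUE)[[1]]
  ids <- names(truths)
  ## per-genome column characters on the reference backbone
  cols <- lapply(ids, function(id) {
    v <- rv
    t <- truths[[id]]
    for (i in seq_len(nrow(t))) {
      p <- t$pos[i] + 1L
      if (t$type[i] == "snp") v[p] <- t$alt[i]
      else if (t$type[i] == "del")
        v[p:(p + t$len[i] - 1L)] <- GAP_CHAR
    }
    v
  })
  names(cols) <- ids
  ## insertions: (genome, position, sequence), disjoint across genomes
  ins <- do.call(rbind, lapply(ids, function(id) {
    t <- truths[[id]]
    t <- t[t$type == "ins", , drop = FALSE]
    if (!nrow(t)) return(NULL)
    data.frame(id = id, pos = t$pos, seq = t$alt, len = t$len)
  }))
  rows <- lapply(ids, function(id) cols[[id]])
  names(rows) <- ids
  if (!is.null(ins) && nrow(ins)) {
    ins <- ins[order(-ins$pos), , drop = FALSE]   # insert right-to-left
    for (i in seq_len(nrow(ins))) {
      at <- ins$pos[i]                            # before ref position `at`
      block_len <- ins$len[i]
      for (id in ids) {
        piece <- if (id == ins$id[i])
          strsplit(ins$seq[i], "", fixed = TRUE)[[1]]
          else rep(GAP_CHAR, block_len)
        rows[[id]] <- append(rows[[id]], piece, after = at)
      }
      if (include_reference) rv <- append(rv, rep(GAP_CHAR, block_len),
                                          after = at)
    }
  }
  seqs <- vapply(rows, paste, character(1), collapse = "")
  if (include_reference)
    seqs <- c(setNames(paste(rv, collapse = ""), ref$id), seqs)
  new_alignment(seqs, groups = groups)
}

#' Simulate paired-end restriction-digest reads from a genome
#'
#' Emulates RAD-style library preparation: for each restriction site and
#' side, fragments extend outward from the cut with lengths uniform in
#' \code{frag_range}; read 1 covers the cut end (starting with the post-cut
#' motif remnant), read 2 the sheared distal end on the opposite strand.
#' Sequencing errors are planted per base at \code{error_rate} with
#' qualities matching the error model; a fraction of pairs is replaced by
#' fragments from a random decoy (nuclear contamination). Every pair's
#' origin is recorded in the truth table.
#'
#' @param genome the individual's \code{GenomeSequence}.
#' @param sites 0-based motif positions on \code{genome}.
#' @param frag_range fragment length range (bp). The default \code{c(120,
#'   500)} represents a nominal 200-500 bp size selection together with the
#'   sub-nominal tail real gel extraction leaves; the tail is what lets the
#'   cut-proximal read of a short fragment overlap its mate, and the
#'   compact window keeps distal-read tiling dense enough at desk-scale
#'   depth for the tag-2 contig to reach the cut-proximal tag, reproducing
#'   the high overlap-tag rates seen in real libraries.
#' @param read_len read length (default 100, PE100).
#' @param depth library molecules per site and side.
#' @param error_rate per-base substitution error rate.
#' @param contamination_frac probability that a molecule is a decoy.
#' @param seed RNG seed.
#' @param motif,cut_offset restriction geometry (EcoRI defaults).
#' @return list with \code{pairs} (read-pair data.frame) and \code{truth}
#'   (per-pair data.frame: \code{id}, \code{origin} cp/nuclear,
#'   \code{site}, \code{side}, \code{frag_start}, \code{frag_end}).
#' @export
simulate_radseq <- function(genome, sites, frag_range = c(120L, 500L),
                            read_len = 100L, depth = 30L, error_rate = 0,
                            contamination_frac = 0, seed = 1L,
                            motif = "GAATTC", cut_offset = 1L) {
  if (read_len > frag_range[1])
    stop("read_len must not exceed the minimum fragment length")
  set.seed(seed)
  ml <- nchar(motif)
  co <- cut_offset
  g <- genome$residues
  circ <- genome$topology == "circular"
  qual_chr <- if (error_rate == 0) rawToChar(as.raw(40L + 33L))
              else rawToChar(as.raw(as.integer(round(-10 * log10(error_rate)))
                                    + 33L))
  sched <- expand.grid(side = c("left", "right"), site = sites,
                       rep = seq_len(depth), stringsAsFactors = FALSE)
  n <- nrow(sched)
  decoy_flag <- runif(n) < contamination_frac
  decoy <- random_bases(genome$length)
  flens <- sample(seq.int(frag_range[1], frag_range[2]), n, replace = TRUE)
  add_errors <- function(s) {
    if (error_rate == 0) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(v)) < error_rate)
    for (j in hit) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1L)
    paste(v, collapse = "")
  }
  r1 <- r2 <- character(n)
  frag_s <- frag_e <- integer(n)
  for (i in seq_len(n)) {
    fl <- flens[i]
    if (decoy_flag[i]) {
      st <- sample.int(genome$length - fl, 1L) - 1L
      frag <- substr(decoy, st + 1L, st + fl)
      r1[i] <- substr(frag, 1L, read_len)
      r2[i] <- revcomp(substr(frag, fl - read_len + 1L, fl))
      frag_s[i] <- st; frag_e[i] <- st + fl
    } else {
      p <- sched$site[i]
      if (sched$side[i] == "right") {
        fs <- p + co; fe <- fs + fl
        r1[i] <- circ_substr(g, fs, fs + read_len, circ)
        r2[i] <- revcomp(circ_substr(g, fe - read_len, fe, circ))
      } else {
        fe <- p + ml - co; fs <- fe - fl
        r1[i] <- revcomp(circ_substr(g, fe - read_len, fe, circ))
        r2[i] <- circ_substr(g, fs, fs + read_len, circ)
      }
      frag_s[i] <- fs; frag_e[i] <- fe
    }
    r1[i] <- add_errors(r1[i])
    r2[i] <- add_errors(r2[i])
  }
  ids <- sprintf("sim_%06d", seq_len(n))
  qual <- strrep(qual_chr, read_len)
  pairs <- read_pairs(ids, r1, rep(qual, n), r2, rep(qual, n))
  truth <- data.frame(id = ids,
                      origin = ifelse(decoy_flag, "nuclear", "cp"),
                      site = ifelse(decoy_flag, NA_integer_, sched$site),
                      side = ifelse(decoy_flag, NA_character_, sched$side),
                      frag_start = frag_s, frag_end = frag_e,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth)
}

#' Simulate a two-level population cohort with RAD-Seq reads
#'
#' Builds a circular reference with planted restriction sites, derives one
#' founder genome per population (shared substitutions) and individual
#' genomes on top of it (private substitutions), then simulates paired-end
#' restriction-digest reads per individual. Substitution-only divergence is
#' used at the population level so that loci stay column-aligned by their
#' reference anchors.
#'
#' @param ref_length,n_sites,min_spacing reference geometry (see
#'   [simulate_reference()]).
#' @param n_pops,n_per_pop cohort design (default 2 populations x 3).
#' @param pop_snp_rate,ind_snp_rate per-site substitution rates for
#'   population founders and individuals (defaults 0.003 / 0.001, matching
#'   the sub-percent SNP densities seen in intraspecific chloroplast data).
#' @param depth,error_rate,contamination_frac,read_len,frag_range read
#'   simulation settings (see [simulate_radseq()]).
#' @param seed RNG seed; all per-individual seeds derive from it.
#' @return list: \code{ref}, \code{sites}, \code{populations} (named vector
#'   per individual), \code{individuals} (per id: \code{genome},
#'   \code{truth}, \code{pairs}, \code{read_truth}).
#' @export
simulate_cohort <- function(ref_length = 30000L, n_sites = 12L,
                            min_spacing = 1000L, n_pops = 2L,
                            n_per_pop = 3L, pop_snp_rate = 0.003,
                            ind_snp_rate = 0.001, depth = 30L,
                            error_rate = 0, contamination_frac = 0,
                            read_len = 100L, frag_range = c(120L, 500L),
                            seed = 1L) {
  base <- simulate_reference(ref_length, n_sites, min_spacing, seed = seed)
  ref <- base$genome
  individuals <- list()
  populations <- character(0)
  k <- 0L
  for (pp in seq_len(n_pops)) {
    founder <- mutate_genome(ref, snp_rate = pop_snp_rate, indel_rate = 0,
                             seed = seed + 1000L * pp)
    for (ii in seq_len(n_per_pop)) {
      k <- k + 1L
      priv <- mutate_genome(founder$genome, snp_rate = ind_snp_rate,
                            indel_rate = 0,
                            seed = seed + 1000L * pp + ii)
      ## compose truths: private SNPs may overwrite founder SNPs
      truth <- rbind(founder$truth, priv$truth)
      truth <- truth[!duplicated(truth$pos, fromLast = TRUE), , drop = FALSE]
      truth <- truth[order(truth$pos), , drop = FALSE]
      id <- sprintf("pop%d_ind%d", pp, ii)
      reads <- simulate_radseq(priv$genome, base$sites,
                               frag_range = frag_range,
                               read_len = read_len, depth = depth,
                               error_rate = error_rate,
                               contamination_frac = contamination_frac,
                               seed = seed + 10000L * pp + 100L * ii)
      individuals[[id]] <- list(genome = priv$genome, truth = truth,
                                pairs = reads$pairs,
                                read_truth = reads$truth)
      populations[id] <- sprintf("pop%d", pp)
    }
  }
  list(ref = ref, sites = base$sites, populations = populations,
       individuals = individuals)
}
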