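## Pairwise polymorphism profile of two alignment rows: per-column SNP calls
## plus maximal single-sided gap runs (one indel event each). Columns gapped
## in both rows separate nothing: runs of the same side merge across them.
pair_profile <- function(aln, row_i, row_j) {
  a <- aln$matrix[row_i, ]
  b <- aln$matrix[row_j, ]
  ga <- a == GAP_CHAR
  gb <- b == GAP_CHAR
  snp <- !ga & !gb & (a != b | a == "N")
  state <- integer(length(a))
  state[ga & !gb] <- 1L
  state[gb & !ga] <- 2L
  idx <- which(!(ga & gb))
  ## one indel event per maximal same-side run; a run interrupted by
  ## both-gap columns is stored as several contiguous segments sharing one
  ## run id, so region counts only see the columns the event occupies
  segs <- data.frame(start = integer(0), end = integer(0), run = integer(0))
  if (length(idx)) {
    r <- rle(state[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_id <- 0L
    out <- list()
    for (k in which(r$values > 0L)) {
      run_id <- run_id + 1L
      cols <- idx[starts[k]:ends[k]] - 1L       # 0-based columns
      brk <- c(0L, which(diff(cols) > 1L), length(cols))
      for (s in seq_len(length(brk) - 1L)) {
        cs <- cols[(brk[s] + 1L):brk[s + 1L]]
        out[[length(out) + 1L]] <- c(cs[1], cs[length(cs)] + 1L, run_id)
      }
    }
    if (length(out)) {
      m <- do.call(rbind, out)
      segs <- data.frame(start = m[, 1], end = m[, 2], run = m[, 3])
    }
  }
  list(snp = snp, segs = segs)
}

#' Potentially informative characters (PIC) between two rows of an alignment
#'
#' PIC is the number of substitution columns plus the number of indel events
#' in a region: a SNP is a column where both rows carry differing non-gap
#' residues (\code{N} mismatches everything, itself included), and an indel
#' event is a maximal run of columns gapped in exactly one of the two rows.
#' Columns gapped in both rows are ignored. An indel run crossing the region
#' boundary still counts once inside the region.
#'
#' @param aln a \code{MultiAlignment}.
#' @param row_i,row_j row ids.
#' @param start,end region bounds, 0-based half-open consensus columns;
#'   \code{end <= start} encodes a wrap around the alignment origin, scored
#'   as the two linear pieces.
#' @return data.frame with one row: \code{row_i}, \code{row_j},
#'   \code{snp_count}, \code{indel_count}, \code{pic}.
#' @export
pairwise_pic <- function(aln, row_i, row_j, start = 0L, end = aln$L) {
  p <- pair_profile(aln, row_i, row_j)
  pic_from_profile(p, start, end, aln$L, row_i, row_j)
}

pic_from_profile <- function(p, start, end, L, row_i = NA, row_j = NA) {
  if (start < 0 || end > L) stop("region out of range [0, ", L, ")")
  pieces <- if (end > start) list(c(start, end))
            else list(c(start, L), c(0L, end))   # wrapped region
  snp <- 0L; hit_runs <- integer(0)
  for (sg in pieces) {
    if (sg[2] <= sg[1]) next
    snp <- snp + sum(p$snp[seq.int(sg[1] + 1L, sg[2])])
    if (nrow(p$segs))
      hit_runs <- c(hit_runs,
                    p$segs$run[p$segs$start < sg[2] & p$segs$end > sg[1]])
  }
  indel <- length(unique(hit_runs))    # one event per run, even if wrapped
  data.frame(row_i = row_i, row_j = row_j, snp_count = snp,
             indel_count = as.integer(indel), pic = snp + as.integer(indel))
}

#' PIC for all row pairs of a grouping over one region
#'
#' @inheritParams pairwise_pic
#' @param grouping list with elements \code{ingroup} (>=2 row ids) and
#'   \code{outgroup} (row ids, may be empty).
#' @return data.frame of [pairwise_pic()] rows for every ingroup pair and
#'   every ingroup-vs-outgroup pair.
#' @export
pic_all_pairs <- function(aln, grouping, start = 0L, end = aln$L) {
  prs <- grouping_pairs(grouping)
  do.call(rbind, lapply(seq_len(nrow(prs)), function(k)
    pairwise_pic(aln, prs$row_i[k], prs$row_j[k], start, end)))
}

grouping_pairs <- function(grouping) {
  ing <- grouping$ingroup
  outg <- grouping$outgroup
  if (length(ing) < 2) stop("grouping needs >=2 ingroup rows")
  within <- t(utils::combn(ing, 2))
  between <- if (length(outg))
    as.matrix(expand.grid(row_i = ing, row_j = outg,
                          stringsAsFactors = FALSE))
  else matrix(character(0), ncol = 2)
  data.frame(row_i = c(within[, 1], between[, 1]),
             row_j = c(within[, 2], between[, 2]),
             level = c(rep("intrageneric", nrow(within)),
                       rep("intergeneric", nrow(between))),
             stringsAsFactors = FALSE)
}

#' Aggregate pairwise PIC into intrageneric / intergeneric means
#'
#' The intrageneric PIC of a region is the arithmetic mean PIC over all
#' within-ingroup pairs; the intergeneric PIC is the mean over all
#' ingroup-vs-outgroup pairs. Per-100-bp normalizations divide by the region
#' length.
#'
#' @param records data.frame of pairwise PIC rows (from [pic_all_pairs()]).
#' @param grouping list with \code{ingroup} and \code{outgroup} row ids.
#' @param region_length region length in columns, for per-100-bp values.
#' @return one-row data.frame: \code{intrageneric_pic},
#'   \code{intergeneric_pic}, \code{intrageneric_per100},
#'   \code{intergeneric_per100}.
#' @export
aggregate_pic <- function(records, grouping, region_length = NA_integer_) {
  prs <- grouping_pairs(grouping)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(records$row_i, records$row_j)
  want <- key(prs$row_i, prs$row_j)
  missing <- setdiff(want, have)
  if (length(missing))
    stop("missing PIC record(s) for pair(s): ", paste(missing, collapse = "; "))
  pic_of <- records$pic[match(want, have)]
  intra <- mean(pic_of[prs$level == "intrageneric"])
  inter <- if (any(prs$level == "intergeneric"))
    mean(pic_of[prs$level == "intergeneric"]) else NA_real_
  data.frame(intrageneric_pic = intra, intergeneric_pic = inter,
             intrageneric_per100 = 100 * intra / region_length,
             intergeneric_per100 = 100 * inter / region_length)
}

#' PIC summaries for a table of regions
#'
#' @param aln a \code{MultiAlignment}.
#' @param regions data.frame with \code{start}, \code{end} (0-based half-open,
#'   wrap encoded as \code{end <= start}) and optionally \code{name}.
#' @param grouping list with \code{ingroup} and \code{outgroup} row ids.
#' @return the input regions with \code{length}, per-pair totals and
#'   [aggregate_pic()] columns appended.
#' @export
region_pic_table <- function(aln, regions, grouping) {
  prs <- grouping_pairs(grouping)
  profiles <- lapply(seq_len(nrow(prs)), function(k)
    pair_profile(aln, prs$row_i[k], prs$row_j[k]))
  L <- aln$L
  res <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    len <- region_length(s, e, L)
    recs <- do.call(rbind, lapply(seq_along(profiles), function(k)
      pic_from_profile(profiles[[k]], s, e, L, prs$row_i[k], prs$row_j[k])))
    cbind(length = len, aggregate_pic(recs, grouping, len))
  })
  cbind(regions, do.call(rbind, res))
}

#' Sliding-window PIC along the consensus
#'
#' Windows start at multiples of \code{step}; the final window is truncated
#' at the alignment end. Indel runs are counted once in every window they
#' intersect.
#'
#' @param aln a \code{MultiAlignment}.
#' @param grouping list with \code{ingroup} and \code{outgroup} row ids.
#' @param window,step window and step sizes in columns (defaults 100 / 25).
#' @return data.frame (one row per window): \code{start}, \code{end} (0-based
#'   half-open), \code{length}, intrageneric/intergeneric PIC and per-100-bp
#'   values. Per-pair PIC columns are attached as attribute \code{pairs}.
#' @export
sliding_window_pic <- function(aln, grouping, window = 100L, step = 25L) {
  L <- aln$L
  if (step < 1 || window < step) stop("need window >= step >= 1")
  if (window > L) stop("window exceeds alignment length")
  starts <- seq.int(0L, by = step,
                    length.out = ceiling((L - window) / step) + 1L)
  ends <- pmin(starts + window, L)
  prs <- grouping_pairs(grouping)
  picm <- matrix(0, nrow = length(starts), ncol = nrow(prs))
  for (k in seq_len(nrow(prs))) {
    p <- pair_profile(aln, prs$row_i[k], prs$row_j[k])
    cum <- c(0L, cumsum(p$snp))
    cnt <- cum[ends + 1L] - cum[starts + 1L]
    if (nrow(p$segs)) {
      for (rid in unique(p$segs$run)) {
        sg <- p$segs[p$segs$run == rid, , drop = FALSE]
        hit <- unique(unlist(lapply(seq_len(nrow(sg)), function(q)
          which(starts < sg$end[q] & ends > sg$start[q]))))
        cnt[hit] <- cnt[hit] + 1L
      }
    }
    picm[, k] <- cnt
  }
  intra <- rowMeans(picm[, prs$level == "intrageneric", drop = FALSE])
  inter <- if (any(prs$level == "intergeneric"))
    rowMeans(picm[, prs$level == "intergeneric", drop = FALSE]) else NA_real_
  out <- data.frame(start = starts, end = ends, length = ends - starts,
                    intrageneric_pic = intra, intergeneric_pic = inter,
                    intrageneric_per100 = 100 * intra / (ends - starts),
                    intergeneric_per100 = 100 * inter / (ends - starts))
  colnames(picm) <- paste(prs$row_i, prs$row_j, sep = ":")
  attr(out, "pairs") <- picm
  out
}

#' Grand mean PIC per 100 bp over a set of regions or windows
#'
#' The default is the unweighted mean of the per-region per-100-bp values;
#' \code{weighted = TRUE} instead divides total PIC by total length
#' (length-weighted mean).
#'
#' @param tbl output of [region_pic_table()] or [sliding_window_pic()].
#' @param weighted length-weight the mean?
#' @return named numeric vector \code{c(intrageneric, intergeneric)}.
#' @export
mean_pic_per100 <- function(tbl, weighted = FALSE) {
  if (weighted) {
    c(intrageneric = 100 * sum(tbl$intrageneric_pic) / sum(tbl$length),
      intergeneric = 100 * sum(tbl$intergeneric_pic) / sum(tbl$length))
  } else {
    c(intrageneric = mean(tbl$intrageneric_per100),
      intergeneric = mean(tbl$intergeneric_per100))
  }
}

#' Rank candidate marker regions by polymorphism
#'
#' Regions longer than \code{max_len} (the effective span of one or two
#' Sanger reactions once primer annealing sites are reserved: 700 and 1500
#' bp) are excluded; the rest are sorted by the chosen PIC level descending,
#' with ties broken by per-100-bp PIC, then by start coordinate.
#'
#' @param tbl a [region_pic_table()] result.
#' @param level \code{"intrageneric"} or \code{"intergeneric"}.
#' @param max_len length cutoff in bp (e.g. 700, 1500, or \code{Inf}).
#' @return the filtered table, ranked, with a \code{rank} column prepended.
#' @export
rank_marker_regions <- function(tbl, level = c("intrageneric", "intergeneric"),
                                max_len = Inf) {
  level <- match.arg(level)
  pic <- tbl[[paste0(level, "_pic")]]
  per100 <- tbl[[paste0(level, "_per100")]]
  keep <- tbl$length <= max_len
  tbl <- tbl[keep, , drop = FALSE]
  ord <- order(-pic[keep], -per100[keep], tbl$start)
  tbl <- tbl[ord, , drop = FALSE]
  rownames(tbl) <- NULL
  cbind(rank = seq_len(nrow(tbl)), tbl)
}

#' Join seas separated only by short islands
#'
#' For marker design, adjacent variable regions separated by a conserved
#' island shorter than \code{max_island_len} can be fused into one candidate
#' region (the short island becomes part of the marker). Off by default in
#' the pipeline drivers.
#'
#' @param seas sea table from [find_con_seas()].
#' @param islands island table from [find_con_islands()].
#' @param L consensus length.
#' @param max_island_len islands strictly shorter than this are bridged.
#' @return a region data.frame (\code{name}, \code{start}, \code{end},
#'   \code{length}) of joined seas.
#' @export
join_adjacent_seas <- function(seas, islands, L = attr(seas, "L"),
                               max_island_len = 100L) {
  if (nrow(seas) < 2) return(seas)
  s <- seas[order(seas$start), , drop = FALSE]
  short <- islands[islands$length < max_island_len, , drop = FALSE]
  is_short_island <- function(gs, ge) {
    any((short$start == gs %% L) & (short$end %% L == ge %% L))
  }
  merged <- list(); cur <- s[1, ]
  for (i in seq_len(nrow(s))[-1]) {
    gap_s <- cur$end; gap_e <- s$start[i]
    if (is_short_island(gap_s, gap_e)) {
      cur$end <- s$end[i]
      cur$length <- region_length(cur$start, cur$end, L)
      cur$name <- paste(cur$name, s$name[i], sep = "+")
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- s[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  attr(out, "L") <- L
  out
}
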