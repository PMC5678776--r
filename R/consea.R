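#' Label conserved alignment columns
#'
#' A column is conserved within a row subset when every subset row carries the
#' identical non-gap residue. By default \code{N} is treated as a mismatch to
#' everything, itself included, so columns containing \code{N} are never
#' conserved; set \code{n_matches = TRUE} to let identical \code{N}s count.
#' Columns where any subset row is gapped are never conserved.
#'
#' @param aln a \code{MultiAlignment}.
#' @param subset row ids to compare (default: all rows); at least 2.
#' @param n_matches should an all-\code{N} column count as conserved?
#' @return logical vector of length \code{L} (\code{TRUE} = conserved), with
#'   attribute \code{subset}.
#' @export
label_conserved <- function(aln, subset = names(aln$seqs), n_matches = FALSE) {
  unknown <- setdiff(subset, names(aln$seqs))
  if (length(unknown)) stop("unknown row id(s): ", paste(unknown, collapse = ", "))
  if (length(subset) < 2) stop("need at least 2 rows to label conservation")
  m <- aln$matrix[subset, , drop = FALSE]
  ref <- m[1, ]
  ok <- ref != GAP_CHAR
  if (!n_matches) ok <- ok & ref != "N"
  for (k in seq_len(nrow(m))[-1]) ok <- ok & (m[k, ] == ref)
  attr(ok, "subset") <- subset
  ok
}

#' Find conserved islands (maximal conserved runs)
#'
#' Con_Islands are maximal runs of at least \code{min_island_len} consecutive
#' conserved columns. Under circular topology a run spanning the origin is a
#' single island (encoded with \code{end <= start}).
#'
#' @param mask logical conservation mask (from [label_conserved()]).
#' @param min_island_len minimum run length (default 50).
#' @param topology \code{"circular"} or \code{"linear"} adjacency.
#' @return data.frame with columns \code{name}, \code{start}, \code{end}
#'   (0-based half-open; \code{end <= start} encodes an origin wrap),
#'   \code{length}, sorted by \code{start}.
#' @export
find_con_islands <- function(mask, min_island_len = 50L,
                             topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (min_island_len < 1) stop("min_island_len must be >= 1")
  L <- length(mask)
  if (L < min_island_len) stop("mask shorter than min_island_len")
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based half-open [start, end)
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     length = r$lengths[r$values])
  if (topology == "circular" && nrow(runs) >= 2 &&
      mask[1] && mask[L] && !all(mask)) {
    ## merge the run touching L with the run starting at 0 across the origin
    first <- runs[1, ]; last <- runs[nrow(runs), ]
    runs <- runs[-c(1, nrow(runs)), , drop = FALSE]
    runs <- rbind(runs, data.frame(start = last$start, end = first$end,
                                   length = last$length + first$length))
  }
  runs <- runs[runs$length >= min_island_len, , drop = FALSE]
  runs <- runs[order(runs$start), , drop = FALSE]
  rownames(runs) <- NULL
  if (nrow(runs))
    runs <- cbind(name = sprintf("Con_Island_%d", seq_len(nrow(runs))), runs)
  else
    runs <- data.frame(name = character(0), start = integer(0),
                       end = integer(0), length = integer(0))
  attr(runs, "L") <- L
  attr(runs, "topology") <- topology
  runs
}

#' Find conserved seas (regions between adjacent islands)
#'
#' A Con_Sea is the region lying strictly between two adjacent Con_Islands;
#' conserved runs shorter than the island threshold fall inside seas. Under
#' circular topology adjacency wraps the origin, so with two or more islands
#' every non-empty inter-island gap yields one sea and island and sea counts
#' coincide. Seas are numbered \code{Con_Sea_1, ...} in consensus order.
#'
#' @param islands island table from [find_con_islands()].
#' @param L number of consensus columns.
#' @param topology \code{"circular"} or \code{"linear"}.
#' @return data.frame with \code{name}, \code{start}, \code{end} (0-based
#'   half-open, wrap encoded as \code{end <= start}), \code{length}.
#' @export
find_con_seas <- function(islands, L = attr(islands, "L"),
                          topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  n <- nrow(islands)
  empty <- data.frame(name = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  if (n == 0) return(empty)
  s <- islands$start; e <- islands$end
  ## normalize ends onto the line for overlap checking
  e_lin <- ifelse(e > s, e, e + L)
  if (n >= 2) {
    ord <- order(s)
    s <- s[ord]; e <- e[ord]; e_lin <- e_lin[ord]
    if (any(e_lin[-n] > s[-1]) || e_lin[n] > s[1] + L)
      stop("islands overlap; they must be maximal and disjoint")
  }
  gaps <- if (topology == "circular") {
    gs <- e %% L
    ge <- c(s[-1], s[1])
    len <- (ge - gs) %% L
    if (n == 1 && len[1] == 0 && islands$length[1] < L) len[1] <- 0  # degenerate
    data.frame(start = gs, end = ge, length = len)
  } else {
    if (n < 2) return(empty)
    data.frame(start = e[-n], end = s[-1], length = s[-1] - e[-n])
  }
  gaps <- gaps[gaps$length > 0, , drop = FALSE]
  gaps <- gaps[order(gaps$start), , drop = FALSE]
  rownames(gaps) <- NULL
  if (nrow(gaps))
    gaps <- cbind(name = sprintf("Con_Sea_%d", seq_len(nrow(gaps))), gaps)
  else gaps <- empty
  attr(gaps, "L") <- L
  gaps
}
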