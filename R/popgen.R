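## gaps and N are missing data for population-genetic purposes
is_missing_base <- function(ch) ch == GAP_CHAR | ch == "N"

#' Select loci conserved across all individuals
#'
#' From per-individual sub-assembly results, keeps the loci (paired-overlap
#' tags, keyed by their restriction site) recovered in every individual and
#' trims each to the reference interval covered in all individuals, so that
#' the per-locus sequences are column-aligned by their common anchor.
#' Chloroplast loci recovered this way are near-identical across
#' conspecifics; alignment is by anchor coordinates (substitution-level
#' divergence), not a gapped realignment.
#'
#' @param results named list of [sacring_individual()] results (or any list
#'   with a \code{products} data.frame per individual).
#' @param populations named character vector: population label per
#'   individual.
#' @param type product type to use as the locus unit (default \code{"poT"}).
#' @return a \code{LocusMatrix}: list with \code{loci} (data.frame:
#'   \code{locus}, \code{site}, \code{start}, \code{end}, \code{length}),
#'   \code{seqs} (list per locus of named per-individual sequences),
#'   \code{concat} (named per-individual concatenated sequences, loci in
#'   reference order), \code{populations}.
#' @export
select_conserved_loci <- function(results, populations = NULL,
                                  type = "poT") {
  if (length(results) < 2) stop("need >=2 individuals")
  ids <- names(results)
  tabs <- lapply(results, function(r) {
    pr <- r$products
    pr[pr$type == type, , drop = FALSE]
  })
  shared <- Reduce(intersect, lapply(tabs, function(t) t$site))
  if (!length(shared)) {
    warning("no locus shared by all individuals")
    return(list(loci = data.frame(locus = character(0), site = integer(0),
                                  start = integer(0), end = integer(0),
                                  length = integer(0)),
                seqs = list(), concat = setNames(rep("", length(ids)), ids),
                populations = populations))
  }
  shared <- sort(shared)
  loci <- list(); seqs <- list()
  for (p in shared) {
    recs <- lapply(tabs, function(t) t[t$site == p, ][1, ])
    starts <- vapply(recs, function(r) r$fwd_start, numeric(1))
    ends <- vapply(recs, function(r) r$fwd_start + r$length, numeric(1))
    cs <- max(starts); ce <- min(ends)
    if (ce - cs < 1) next
    sq <- vapply(ids, function(id) {
      r <- recs[[id]]
      off <- cs - r$fwd_start
      substr(r$seq, off + 1L, off + (ce - cs))
    }, character(1))
    nm <- sprintf("%s-%d", type, p)
    loci[[length(loci) + 1L]] <- data.frame(
      locus = nm, site = p, start = cs, end = ce, length = ce - cs)
    seqs[[nm]] <- sq
  }
  loci <- do.call(rbind, loci)
  concat <- vapply(ids, function(id)
    paste(vapply(seqs, `[[`, character(1), id), collapse = ""),
    character(1))
  list(loci = loci, seqs = seqs, concat = concat, populations = populations)
}

#' Segregating sites of an aligned sequence set
#'
#' Columns carrying at least two distinct non-missing residues; columns
#' containing a gap or \code{N} in any sequence are excluded.
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @return list with \code{S} (count), \code{positions} (0-based column
#'   indices) and \code{n_sites} (gap-free columns considered).
#' @export
segregating_sites <- function(seqs) {
  if (length(seqs) < 2) stop("need >=2 sequences")
  m <- seq_char_matrix(seqs)
  complete <- colSums(is_missing_base(m)) == 0
  varying <- apply(m, 2, function(col) length(unique(col)) > 1)
  seg <- complete & varying
  list(S = sum(seg), positions = which(seg) - 1L, n_sites = sum(complete))
}

## mean pairwise difference per site over all sequence pairs, with pairwise
## deletion of missing columns
pi_pairwise <- function(m, idx_a, idx_b = NULL) {
  within <- is.null(idx_b)
  prs <- if (within) {
    if (length(idx_a) < 2) return(NA_real_)
    t(utils::combn(idx_a, 2))
  } else as.matrix(expand.grid(idx_a, idx_b))
  vals <- apply(prs, 1, function(pr) {
    a <- m[pr[1], ]; b <- m[pr[2], ]
    ok <- !is_missing_base(a) & !is_missing_base(b)
    if (!any(ok)) return(NA_real_)
    sum(a[ok] != b[ok]) / sum(ok)
  })
  mean(vals, na.rm = TRUE)
}

#' Nucleotide diversity, Watterson's theta and pairwise FST
#'
#' Nucleotide diversity (pi) is the mean per-site pairwise difference over
#' all sequence pairs (pairwise deletion of gap/N columns). Watterson's
#' estimator is \eqn{\theta_W = S / (a_n \cdot sites)} with
#' \eqn{a_n = \sum_{i=1}^{n-1} 1/i}, where \eqn{S} and the site count use
#' the gap-free columns. Between-population differentiation uses Hudson's
#' estimator \eqn{F_{ST} = 1 - \bar{\pi}_{within} / \pi_{between}} by
#' default; Nei's \eqn{G_{ST}} is available via \code{fst_method = "nei"}.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (e.g. the \code{concat} element of [select_conserved_loci()]).
#' @param populations named character vector of population labels per
#'   sequence id.
#' @param fst_method \code{"hudson"} (default) or \code{"nei"}.
#' @return list: \code{n}, \code{n_sites}, \code{S}, \code{pi},
#'   \code{theta_w}, \code{per_population} (data.frame), \code{fst}
#'   (symmetric matrix, \code{NA} diagonal), \code{fst_method}.
#' @export
diversity <- function(seqs, populations, fst_method = c("hudson", "nei")) {
  fst_method <- match.arg(fst_method)
  if (is.null(names(seqs))) stop("sequences must be named by individual")
  populations <- populations[names(seqs)]
  m <- seq_char_matrix(seqs)
  seg <- segregating_sites(seqs)
  n <- length(seqs)
  a_n <- sum(1 / seq_len(n - 1))
  theta_all <- if (seg$n_sites > 0) seg$S / (a_n * seg$n_sites) else NA_real_
  pi_all <- pi_pairwise(m, seq_len(n))
  pops <- unique(populations)
  per_pop <- do.call(rbind, lapply(pops, function(p) {
    idx <- which(populations == p)
    np <- length(idx)
    if (np < 2)
      return(data.frame(population = p, n = np, S = NA_integer_,
                        pi = NA_real_, theta_w = NA_real_))
    sp <- segregating_sites(seqs[idx])
    ap <- sum(1 / seq_len(np - 1))
    data.frame(population = p, n = np, S = sp$S,
               pi = pi_pairwise(m, idx),
               theta_w = if (sp$n_sites > 0) sp$S / (ap * sp$n_sites)
                         else NA_real_)
  }))
  fst <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
  if (length(pops) >= 2) {
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in seq.int(i + 1L, length(pops))) {
        ia <- which(populations == pops[i])
        ib <- which(populations == pops[j])
        fst[i, j] <- fst[j, i] <-
          if (fst_method == "hudson") fst_hudson(m, ia, ib)
          else fst_nei(m, ia, ib)
      }
    }
  }
  list(n = n, n_sites = seg$n_sites, S = seg$S, pi = pi_all,
       theta_w = theta_all, per_population = per_pop, fst = fst,
       fst_method = fst_method)
}

fst_hudson <- function(m, idx_a, idx_b) {
  pi_b <- pi_pairwise(m, idx_a, idx_b)
  if (is.na(pi_b) || pi_b == 0) return(NA_real_)
  pi_w <- mean(c(pi_pairwise(m, idx_a), pi_pairwise(m, idx_b)), na.rm = TRUE)
  1 - pi_w / pi_b
}

## per-site Nei GST averaged over segregating gap-free columns
fst_nei <- function(m, idx_a, idx_b) {
  idx <- c(idx_a, idx_b)
  sub <- m[idx, , drop = FALSE]
  complete <- colSums(is_missing_base(sub)) == 0
  cols <- which(complete & apply(sub, 2, function(c) length(unique(c)) > 1))
  if (!length(cols)) return(NA_real_)
  het <- function(col) 1 - sum((table(col) / length(col))^2)
  gst <- vapply(cols, function(j) {
    ht <- het(sub[, j])
    hs <- mean(c(het(m[idx_a, j]), het(m[idx_b, j])))
    if (ht == 0) return(NA_real_)
    (ht - hs) / ht
  }, numeric(1))
  mean(gst, na.rm = TRUE)
}
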