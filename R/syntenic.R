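## extract a per-exon table (gene, exon_rank, start0, end0) from one GFF3
## annotation (path or GRanges). Exon/CDS features are used when present,
## otherwise whole-gene features count as single exons.
gff_exon_table <- function(x) {
  gr <- if (is.character(x)) rtracklayer::import(x) else x
  md <- S4Vectors::mcols(gr)
  gene_of <- function(i) {
    for (f in c("gene", "Name", "ID"))
      if (!is.null(md[[f]]) && !is.na(md[[f]][i]) && nzchar(md[[f]][i]))
        return(as.character(md[[f]][i]))
    NA_character_
  }
  type <- as.character(gr$type)
  use <- which(type %in% c("exon", "CDS"))
  if (!length(use)) use <- which(type == "gene")
  if (!length(use)) stop("annotation contains no exon/CDS/gene features")
  df <- data.frame(gene = vapply(use, gene_of, character(1)),
                   start0 = BiocGenerics::start(gr)[use] - 1L,
                   end0 = BiocGenerics::end(gr)[use],
                   stringsAsFactors = FALSE)
  if (anyNA(df$gene)) stop("feature without a gene/Name/ID attribute")
  ## collapse duplicate exon records (exon + CDS of the same span)
  df <- unique(df)
  df <- df[order(df$start0), , drop = FALSE]
  spl <- split(df, df$gene)
  df$exon_rank <- NA_integer_
  for (g in names(spl))
    df$exon_rank[df$gene == g] <- seq_len(sum(df$gene == g))
  df
}

#' Classify syntenic coding and noncoding loci on the consensus
#'
#' Exon features from each genome's annotation are projected through the
#' coordinate maps into consensus-column space; per exon, the projections
#' from all genomes are unioned (an indel shifting an exon in one genome
#' widens the consensus locus). Overlapping coding projections merge into
#' one coding locus. Every maximal gap between consecutive coding loci is a
#' noncoding locus, named \code{"geneA-geneB"} for intergenic spacers or
#' \code{"geneA intron k"} when both flanks belong to the same gene.
#'
#' @param aln a \code{MultiAlignment}.
#' @param annotations named list (by row id) of GFF3 paths or \code{GRanges};
#'   gene names and gene order must agree across genomes.
#' @return data.frame of loci in consensus order: \code{name}, \code{kind}
#'   (\code{coding}/\code{noncoding}), \code{start}, \code{end} (0-based
#'   half-open), \code{length}.
#' @export
classify_syntenic_loci <- function(aln, annotations) {
  rows <- names(annotations)
  unknown <- setdiff(rows, names(aln$seqs))
  if (length(unknown)) stop("unknown row id(s): ", paste(unknown, collapse = ", "))
  tabs <- lapply(annotations, gff_exon_table)
  ## gene order must be consistent across genomes
  orders <- lapply(tabs, function(t) unique(t$gene[order(t$start0)]))
  for (k in seq_along(orders)[-1]) {
    common <- intersect(orders[[1]], orders[[k]])
    a <- orders[[1]][orders[[1]] %in% common]
    b <- orders[[k]][orders[[k]] %in% common]
    if (!identical(a, b)) {
      bad <- common[which(a != b)[1]]
      stop("gene order conflict between '", rows[1], "' and '", rows[k],
           "' at gene ", bad)
    }
  }
  ## project exons to consensus columns and union across genomes
  proj <- do.call(rbind, lapply(rows, function(rid) {
    t <- tabs[[rid]]
    cs <- vapply(t$start0, function(p) consensus_column(aln, rid, p), integer(1))
    ce <- vapply(t$end0 - 1L, function(p) consensus_column(aln, rid, p),
                 integer(1)) + 1L
    data.frame(gene = t$gene, exon_rank = t$exon_rank, cstart = cs, cend = ce)
  }))
  agg <- stats::aggregate(cbind(cstart, cend) ~ gene + exon_rank, proj,
                          function(v) v[1])
  agg$cstart <- stats::aggregate(cstart ~ gene + exon_rank, proj, min)$cstart
  agg$cend <- stats::aggregate(cend ~ gene + exon_rank, proj, max)$cend
  agg <- agg[order(agg$cstart), , drop = FALSE]
  ## merge overlapping coding projections into maximal coding loci
  coding <- list()
  cur <- list(genes = agg$gene[1], start = agg$cstart[1], end = agg$cend[1])
  for (i in seq_len(nrow(agg))[-1]) {
    if (agg$cstart[i] < cur$end) {
      cur$end <- max(cur$end, agg$cend[i])
      cur$genes <- union(cur$genes, agg$gene[i])
    } else {
      coding[[length(coding) + 1L]] <- cur
      cur <- list(genes = agg$gene[i], start = agg$cstart[i],
                  end = agg$cend[i])
    }
  }
  coding[[length(coding) + 1L]] <- cur
  cod <- data.frame(
    name = vapply(coding, function(x) paste(x$genes, collapse = "/"),
                  character(1)),
    kind = "coding",
    start = vapply(coding, function(x) as.integer(x$start), integer(1)),
    end = vapply(coding, function(x) as.integer(x$end), integer(1)))
  ## noncoding = gaps between consecutive coding loci (plus the two ends)
  flank_gene <- function(i, side) {
    g <- coding[[i]]$genes
    if (side == "r") g[length(g)] else g[1]
  }
  intron_counter <- new.env()
  non <- list()
  add_non <- function(s, e, left, right) {
    if (e <= s) return()
    if (!is.na(left) && !is.na(right) && left == right) {
      k <- (get0(left, intron_counter, ifnotfound = 0L)) + 1L
      assign(left, k, intron_counter)
      nm <- sprintf("%s intron %d", left, k)
    } else {
      nm <- paste(ifelse(is.na(left), "start", left),
                  ifelse(is.na(right), "end", right), sep = "-")
    }
    non[[length(non) + 1L]] <<- data.frame(name = nm, kind = "noncoding",
                                           start = s, end = e)
  }
  add_non(0L, cod$start[1], NA_character_, flank_gene(1, "l"))
  if (nrow(cod) > 1) {
    for (i in seq_len(nrow(cod) - 1))
      add_non(cod$end[i], cod$start[i + 1],
              flank_gene(i, "r"), flank_gene(i + 1, "l"))
  }
  add_non(cod$end[nrow(cod)], aln$L, flank_gene(nrow(cod), "r"),
          NA_character_)
  out <- rbind(cod, do.call(rbind, non))
  out <- out[order(out$start), , drop = FALSE]
  out$length <- out$end - out$start
  rownames(out) <- NULL
  out
}
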