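#' Read a row-id to group mapping
#'
#' Two-column tab-separated file: row id, group label (\code{ingroup} /
#' \code{outgroup}).
#'
#' @param path TSV path (no header).
#' @return list with \code{ingroup} and \code{outgroup} id vectors.
#' @export
read_grouping <- function(path) {
  g <- read.delim(path, header = FALSE, col.names = c("id", "group"),
                  stringsAsFactors = FALSE)
  bad <- setdiff(unique(g$group), c("ingroup", "outgroup"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ingroup/outgroup)")
  list(ingroup = g$id[g$group == "ingroup"],
       outgroup = g$id[g$group == "outgroup"])
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## region table with 1-based inclusive report coordinates prepended
report_regions <- function(df, L) {
  cbind(df[, "name", drop = FALSE],
        start_1based = df$start + 1L,
        end_1based = ifelse(df$end > df$start, df$end, df$end + L),
        df[, setdiff(names(df), "name"), drop = FALSE])
}

#' Conserved-region and polymorphism analysis of a plastome alignment
#'
#' End-to-end driver for the first marker-development strategy: conserved
#' column labeling, island/sea identification, per-region and per-window
#' PIC, optional syntenic-locus classification, and marker ranking. All
#' tables are written as TSV (coordinates reported 1-based inclusive;
#' BED files keep 0-based half-open convention) to \code{out_dir}.
#'
#' @param aln a \code{MultiAlignment}, or a path to a gapped FASTA.
#' @param grouping list with \code{ingroup}/\code{outgroup} ids, or a path
#'   to a grouping TSV (see [read_grouping()]).
#' @param out_dir output directory (created if missing); \code{NULL} skips
#'   writing.
#' @param min_island_len minimum conserved-run length (default 50).
#' @param topology island/sea adjacency (default circular).
#' @param window,step sliding-window geometry (defaults 100 / 25).
#' @param annotations optional named list of GFF3 paths/GRanges for
#'   syntenic-locus classification.
#' @param max_len length bound for the ranked marker table (default 700,
#'   one Sanger reaction).
#' @param join_short_islands if positive, seas separated by islands shorter
#'   than this are joined before ranking (off by default).
#' @return (invisibly) list with all computed tables and a \code{summary}.
#' @export
run_consea <- function(aln, grouping, out_dir = NULL, min_island_len = 50L,
                       topology = "circular", window = 100L, step = 25L,
                       annotations = NULL, max_len = 700L,
                       join_short_islands = 0L) {
  if (is.character(aln)) aln <- read_alignment(aln)
  if (is.character(grouping)) grouping <- read_grouping(grouping)
  all_ids <- c(grouping$ingroup, grouping$outgroup)
  mask_all <- label_conserved(aln, all_ids)
  mask_in <- label_conserved(aln, grouping$ingroup)
  islands <- find_con_islands(mask_all, min_island_len, topology)
  seas <- find_con_seas(islands, aln$L, topology)
  sea_pic <- region_pic_table(aln, seas, grouping)
  windows <- sliding_window_pic(aln, grouping, window, step)
  rank_tbl <- if (join_short_islands > 0) {
    joined <- join_adjacent_seas(seas, islands, aln$L, join_short_islands)
    rank_marker_regions(region_pic_table(aln, joined, grouping),
                        max_len = max_len)
  } else rank_marker_regions(sea_pic, max_len = max_len)
  loci <- if (!is.null(annotations)) {
    lt <- classify_syntenic_loci(aln, annotations)
    region_pic_table(aln, lt, grouping)
  } else NULL
  summary <- list(
    L = aln$L,
    conserved_all = sum(mask_all),
    conserved_ingroup = sum(mask_in),
    n_islands = nrow(islands),
    longest_island = if (nrow(islands)) max(islands$length) else 0L,
    n_seas = nrow(seas),
    longest_sea = if (nrow(seas)) max(seas$length) else 0L,
    seas_len1 = sum(seas$length == 1),
    n_windows = nrow(windows),
    window_mean_per100 = mean_pic_per100(windows),
    sea_mean_per100 = mean_pic_per100(sea_pic),
    sea_mean_per100_weighted = mean_pic_per100(sea_pic, weighted = TRUE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f <- function(x) file.path(out_dir, x)
    write_bed(islands, f("con_islands.bed"), L = aln$L)
    write_bed(seas, f("con_seas.bed"), L = aln$L)
    write_tsv(report_regions(islands, aln$L), f("con_islands.tsv"))
    write_tsv(report_regions(sea_pic, aln$L), f("con_seas_pic.tsv"))
    write_tsv(windows, f("window_pic.tsv"))
    write_tsv(report_regions(rank_tbl, aln$L), f("ranked_markers.tsv"))
    if (!is.null(loci)) write_tsv(loci, f("syntenic_loci_pic.tsv"))
  }
  invisible(list(mask_all = mask_all, mask_ingroup = mask_in,
                 islands = islands, seas = seas, sea_pic = sea_pic,
                 windows = windows, ranked = rank_tbl,
                 syntenic = loci, summary = summary))
}

#' Sub-assembly of chloroplast fragments for a cohort
#'
#' Runs [sacring_individual()] for every individual, writes per-individual
#' tag FASTAs (ids encode the restriction-site position, e.g.
#' \code{poT-1234}), the sub-super-marker scaffold, a per-cohort statistics
#' table and the poT length matrix (individuals x sites).
#'
#' @param cohort named list of read-pair data.frames (one per individual),
#'   or the \code{individuals} element of [simulate_cohort()] output.
#' @param ref reference \code{GenomeSequence}.
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @param params parameter list from [sacring_params()].
#' @param denominator_length see [sacring_individual()].
#' @return (invisibly) list with \code{results} (per individual),
#'   \code{report} (cohort table) and \code{pot_matrix}.
#' @export
run_sacring <- function(cohort, ref, out_dir = NULL,
                        params = sacring_params(),
                        denominator_length = ref$length) {
  get_pairs <- function(x) if (is.data.frame(x)) x else x$pairs
  results <- lapply(cohort, function(x)
    sacring_individual(get_pairs(x), ref, params, denominator_length))
  report <- do.call(rbind, lapply(names(results), function(id)
    cbind(individual = id, results[[id]]$report)))
  all_sites <- sort(unique(unlist(lapply(results, function(r)
    r$products$site[r$products$type == "poT"]))))
  pot_matrix <- matrix(NA_integer_, nrow = length(results),
                       ncol = length(all_sites),
                       dimnames = list(names(results),
                                       sprintf("poT-%d", all_sites)))
  for (id in names(results)) {
    pr <- results[[id]]$products
    pr <- pr[pr$type == "poT", , drop = FALSE]
    pot_matrix[id, sprintf("poT-%d", pr$site)] <- pr$length
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(results)) {
      r <- results[[id]]
      d <- file.path(out_dir, id)
      dir.create(d, showWarnings = FALSE)
      if (nrow(r$tags1))
        write_fasta(setNames(r$tags1$fwd,
                             sprintf("Tag1-%d-%s", r$tags1$site,
                                     r$tags1$side)),
                    file.path(d, "tag1.fasta"))
      if (nrow(r$products))
        write_fasta(setNames(r$products$seq,
                             sprintf("%s-%d", sub("_.*", "",
                                                  r$products$type),
                                     r$products$site)),
                    file.path(d, "tags.fasta"))
      if (nrow(r$cpcontigs))
        write_fasta(setNames(r$cpcontigs$contig,
                             sprintf("CpContig-%d", r$cpcontigs$ref_start)),
                    file.path(d, "cpcontigs.fasta"))
      write_fasta(setNames(r$scaffold$scaffold,
                           paste0(id, "_sub_super_marker")),
                  file.path(d, "sub_super_marker.fasta"))
    }
    write_tsv(report, file.path(out_dir, "cohort_report.tsv"))
    write_tsv(cbind(individual = rownames(pot_matrix),
                    as.data.frame(pot_matrix)),
              file.path(out_dir, "pot_length_matrix.tsv"))
  }
  invisible(list(results = results, report = report,
                 pot_matrix = pot_matrix))
}
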