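q40 <- function(n) strrep("I", n)          # Phred 40
qlow <- function(n) strrep("$", n)         # Phred 3

test_that("QC keeps pairs only when both mates pass", {
  pairs <- read_pairs(
    id = c("ok", "lowq2", "many_n"),
    read1 = c(strrep("A", 50), strrep("A", 50),
              paste0(strrep("N", 3), strrep("A", 47))),
    qual1 = c(q40(50), q40(50), q40(50)),
    read2 = c(strrep("C", 50), strrep("C", 50), strrep("C", 50)),
    qual2 = c(q40(50), qlow(50), q40(50)))
  res <- qc_filter(pairs)
  expect_equal(res$pairs$id, "ok")        # 6% N and bad-mate pairs dropped
  expect_equal(res$report$reads_kept, 1L)
  expect_equal(res$report$q30_read1, 1)

  ## matches per-read brute-force evaluation on a simulated stream
  set.seed(111)
  n <- 60
  mk_read <- function() random_seq(50)
  mk_qual <- function() phred_encode(list(sample(c(10L, 40L), 50, TRUE,
                                                 prob = c(.2, .8))))
  pairs2 <- read_pairs(paste0("r", 1:n),
                       replicate(n, mk_read()), replicate(n, mk_qual()),
                       replicate(n, mk_read()), replicate(n, mk_qual()))
  res2 <- qc_filter(pairs2)
  brute <- vapply(seq_len(n), function(i) {
    ok <- function(q) mean(unlist(phred_decode(q)) >= 20) >= 0.90
    ok(pairs2$qual1[i]) && ok(pairs2$qual2[i])
  }, logical(1))
  expect_equal(res2$pairs$id, pairs2$id[brute])
})

test_that("restriction sites are found on linear and circular sequences", {
  lin <- genome_sequence("g", "GGAATTCC", "linear")
  expect_equal(find_re_sites(lin), 1L)

  ## occurrence spanning the origin: rotation carries GAATTC across the join
  circ <- genome_sequence("g", "ATTCGGGGGGGA", "circular")
  expect_equal(find_re_sites(circ), 10L)
  expect_equal(find_re_sites(genome_sequence("g", "ATTCGGGGGGGA", "linear")),
               integer(0))

  sim <- simulate_reference(4000, 5, 300, seed = 5)
  expect_equal(find_re_sites(sim$genome), sim$sites)
})

test_that("cut-anchored extraction keeps true pairs and drops decoys", {
  sim <- simulate_reference(6000, 4, 500, seed = 9)
  reads <- simulate_radseq(sim$genome, sim$sites, depth = 6,
                           contamination_frac = 0.4, seed = 9)
  cp <- extract_cp_pairs(reads$pairs, sim$genome, sim$sites)
  truth <- reads$truth
  expect_setequal(cp$id, truth$id[truth$origin == "cp"])
  got <- merge(cp[, c("id", "site", "side")], truth, by = "id")
  expect_equal(got$site.x, got$site.y)
  expect_equal(got$side.x, got$side.y)
  ## read 1 carries the post-cut motif remnant
  expect_true(all(substr(cp$read1, 1, 5) == "AATTC"))
})

test_that("tag clustering takes the majority and enforces depth", {
  ref <- simulate_reference(3000, 2, 500, seed = 3)$genome
  sites <- find_re_sites(ref)
  p <- sites[1]
  true_r1 <- circ_substr(ref$residues, p + 1, p + 101)
  err <- true_r1
  substr(err, 40, 40) <- if (substr(err, 40, 40) == "A") "C" else "A"
  mk <- function(reads, site, side) {
    df <- read_pairs(paste0("r", seq_along(reads)), reads,
                     rep(q40(100), length(reads)),
                     rep(strrep("A", 100), length(reads)),
                     rep(q40(100), length(reads)))
    df$site <- site; df$side <- side
    df
  }
  ## 9 clean + 1 errored read: consensus is the majority base
  tags <- cluster_tag1(mk(c(rep(true_r1, 9), err), p, "right"), ref)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$consensus, true_r1)
  expect_equal(tags$depth, 10L)
  expect_false(tags$flagged)
  expect_equal(tags$fwd_start, p + 1L)

  ## below min_depth the group is discarded
  expect_equal(nrow(cluster_tag1(mk(rep(true_r1, 2), p, "right"), ref)), 0L)

  ## two deep haplotype clusters: deeper one kept, flagged
  other <- paste(rev(strsplit(true_r1, "")[[1]]), collapse = "")
  tags2 <- cluster_tag1(mk(c(rep(true_r1, 6), rep(other, 4)), p, "right"),
                        ref)
  expect_equal(nrow(tags2), 1L)
  expect_equal(tags2$consensus, true_r1)
  expect_true(tags2$flagged)

  ## left-side tags anchor forward of the cut on the reverse strand
  left_r1 <- revcomp(circ_substr(ref$residues, p + 5 - 100, p + 5))
  tagsL <- cluster_tag1(mk(rep(left_r1, 5), p, "left"), ref)
  expect_equal(tagsL$fwd, circ_substr(ref$residues, p + 5 - 100, p + 5))
  expect_equal(tagsL$fwd_start, p + 5L - 100L)
})

test_that("greedy read-2 assembly merges overlaps and respects thresholds", {
  set.seed(22)
  g <- random_seq(170)
  r1 <- substr(g, 1, 100)
  r2 <- substr(g, 71, 170)              # 30 bp exact overlap
  t2 <- assemble_tag2(c(r1, r2))
  expect_equal(t2$contig, g)

  ## disjoint equal-length reads cannot merge: no tag-2
  expect_null(assemble_tag2(c(substr(g, 1, 80), substr(g, 91, 170))))

  ## tiling reads reconstruct the window exactly
  set.seed(23)
  win <- random_seq(400)
  starts <- seq(1, 301, by = 60)
  reads <- vapply(starts, function(s) substr(win, s, s + 99), character(1))
  t3 <- assemble_tag2(reads)
  expect_equal(t3$contig, win)
})

test_that("pT, oT and poT form with correct spans on error-free data", {
  sim <- simulate_reference(8000, 3, 800, seed = 31)
  reads <- simulate_radseq(sim$genome, sim$sites, depth = 30, seed = 31)
  r <- sacring_individual(reads$pairs, sim$genome)
  g2 <- paste0(sim$genome$residues, sim$genome$residues)
  for (ty in unique(r$products$type)) {
    sub <- r$products[r$products$type == ty, ]
    expect_true(all(vapply(sub$seq, grepl, logical(1), x = g2,
                           fixed = TRUE)),
                info = paste("type", ty))
  }
  pts <- r$products[r$products$type == "pT", ]
  ## every pT contains the recognition motif and spans the cut
  expect_true(all(grepl("GAATTC", pts$seq)))
  for (k in seq_len(nrow(pts)))
    expect_equal(pts$seq[k],
                 circ_substr(sim$genome$residues, pts$fwd_start[k],
                             pts$fwd_start[k] + pts$length[k]))
  ## containment chain: poT contains its pT
  for (p in pts$site) {
    pot <- r$products[r$products$site == p & r$products$type == "poT", ]
    if (nrow(pot))
      expect_true(grepl(pts$seq[pts$site == p], pot$seq, fixed = TRUE))
  }
  ## counting chain per individual
  expect_lte(sum(r$products$type == "poT"), sum(r$products$type == "pT"))
  expect_lte(sum(r$products$type == "pT"),
             length(unique(r$tags1$site)))
})

test_that("CpContigs are disjoint and the scaffold mirrors their union", {
  sim <- simulate_reference(8000, 3, 800, seed = 31)
  reads <- simulate_radseq(sim$genome, sim$sites, depth = 30, seed = 31)
  r <- sacring_individual(reads$pairs, sim$genome)
  cc <- r$cpcontigs
  expect_false(any(grepl("[-N]", cc$contig)))
  if (nrow(cc) > 1) {
    cc2 <- cc[order(cc$ref_start), ]
    expect_true(all(cc2$ref_start[-1] >= cc2$ref_end[-nrow(cc2)]))
  }
  sc <- r$scaffold
  expect_equal(nchar(sc$scaffold), sim$genome$length)
  expect_equal(sc$covered_fraction,
               sum(cc$length) / sim$genome$length)
  ## non-gap positions are exactly the union of anchor intervals
  nc <- which(strsplit(sc$scaffold, "")[[1]] != "-") - 1L
  want <- sort(unique(unlist(lapply(seq_len(nrow(cc)), function(i)
    (cc$ref_start[i]:(cc$ref_end[i] - 1L)) %% sim$genome$length))))
  expect_equal(nc, want)

  ## no contigs: all-gap scaffold
  empty <- build_sub_super_marker(cc[0, ], sim$genome)
  expect_equal(empty$covered_fraction, 0)
  expect_equal(unique(strsplit(empty$scaffold, "")[[1]]), "-")
})

test_that("the pipeline is deterministic for fixed inputs", {
  sim <- simulate_reference(6000, 2, 800, seed = 77)
  reads <- simulate_radseq(sim$genome, sim$sites, depth = 12, seed = 77)
  r1 <- sacring_individual(reads$pairs, sim$genome)
  r2 <- sacring_individual(reads$pairs, sim$genome)
  expect_identical(r1$products, r2$products)
  expect_identical(r1$scaffold$scaffold, r2$scaffold$scaffold)
})
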