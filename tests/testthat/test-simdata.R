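test_that("simulated references carry exactly the requested motif count", {
  sim <- simulate_reference(10000, 8, 500, seed = 13)
  expect_equal(length(find_re_sites(sim$genome)), 8L)
  expect_equal(find_re_sites(sim$genome), sim$sites)
  gaps <- diff(c(sim$sites, sim$sites[1] + 10000))
  expect_true(all(gaps >= 500 + 6))

  none <- simulate_reference(5000, 0, 100, seed = 13)
  expect_equal(length(find_re_sites(none$genome)), 0L)

  a <- simulate_reference(8000, 6, 400, seed = 99)
  b <- simulate_reference(8000, 6, 400, seed = 99)
  expect_identical(a$genome$residues, b$genome$residues)

  expect_error(simulate_reference(1000, 10, 500, seed = 1), "infeasible")
})

test_that("planted mutations are recorded faithfully", {
  ref <- simulate_reference(10000, 4, 800, seed = 21)$genome
  m0 <- mutate_genome(ref, snp_rate = 0, indel_rate = 0, seed = 2)
  expect_identical(m0$genome$residues, ref$residues)
  expect_equal(nrow(m0$truth), 0L)

  m <- mutate_genome(ref, snp_rate = 0.01, indel_rate = 0.002, seed = 2)
  ## truth round-trip reproduces the mutant exactly
  expect_identical(apply_truth(ref$residues, m$truth), m$genome$residues)
  ## motif occurrences survive mutation
  expect_equal(length(find_re_sites(m$genome)), 4L)
  ## SNP count within 3 sigma of the binomial expectation
  n_snp <- sum(m$truth$type == "snp")
  expect_lt(abs(n_snp - 100), 3 * sqrt(100 * 0.99) + 15)

  expect_error(mutate_genome(ref, snp_rate = 0.5, seed = 1), "rates")
})

test_that("true alignments mirror their edit scripts", {
  ref <- simulate_reference(4000, 2, 800, seed = 33)$genome
  dg <- simulate_divergent_genomes(ref, 3, snp_rate = 0.01,
                                   indel_rate = 0.003, seed = 33)
  aln <- simulate_alignment(ref, dg$truths)
  ## each gapped row degaps to its genome
  for (id in names(dg$genomes))
    expect_identical(ungapped_sequence(aln, id),
                     dg$genomes[[id]]$residues)
  ## consensus length = reference length + total insertions
  ins_len <- sum(vapply(dg$truths, function(t)
    sum(t$len[t$type == "ins"]), numeric(1)))
  expect_equal(aln$L, ref$length + ins_len)

  ## no mutations: identical rows, zero gaps
  aln0 <- simulate_alignment(ref, list(x = dg$truths$g1[0, ],
                                       y = dg$truths$g1[0, ]))
  expect_equal(aln0$seqs[["x"]], ref$residues)
  expect_false(grepl("-", aln0$seqs[["y"]], fixed = TRUE))

  ## one 3 bp deletion: exactly one 3-column gap run
  tdel <- data.frame(type = "del", pos = 100L,
                     ref = substr(ref$residues, 101, 103), alt = "",
                     len = 3L)
  aln1 <- simulate_alignment(ref, list(d = tdel, w = tdel[0, ]))
  expect_equal(gregexpr("-+", aln1$seqs[["d"]])[[1]][1], 101L)
  expect_equal(attr(gregexpr("-+", aln1$seqs[["d"]])[[1]], "match.length"),
               3L)
})

test_that("pairwise PIC on true alignments equals planted event counts", {
  ref <- simulate_reference(5000, 3, 600, seed = 44)$genome
  dg <- simulate_divergent_genomes(ref, 4, snp_rate = 0.008,
                                   indel_rate = 0.002, seed = 44)
  aln <- simulate_alignment(ref, dg$truths)
  ids <- names(dg$truths)
  for (i in 1:3) for (j in (i + 1):4) {
    got <- pairwise_pic(aln, ids[i], ids[j])$pic
    expect_equal(got, nrow(dg$truths[[i]]) + nrow(dg$truths[[j]]))
  }
})

test_that("read simulation respects geometry, errors and contamination", {
  sim <- simulate_reference(8000, 4, 700, seed = 55)
  reads <- simulate_radseq(sim$genome, sim$sites, depth = 10, seed = 55)
  g2 <- paste0(sim$genome$residues, sim$genome$residues)
  ## error-free read 1s are exact cut-anchored substrings (left-side reads
  ## read the reverse strand)
  expect_true(all(vapply(reads$pairs$read1, function(r)
    grepl(r, g2, fixed = TRUE) || grepl(revcomp(r), g2, fixed = TRUE),
    logical(1))))
  expect_true(all(substr(reads$pairs$read1, 1, 5) == "AATTC"))
  ## every cp fragment abuts a cut
  tr <- reads$truth
  right <- tr[tr$side == "right", ]
  expect_true(all(right$frag_start == right$site + 1L))
  left <- tr[tr$side == "left", ]
  expect_true(all(left$frag_end == left$site + 5L))

  ## contamination volume is binomial around its expectation
  mixed <- simulate_radseq(sim$genome, sim$sites, depth = 125,
                           contamination_frac = 0.5, seed = 56)
  n <- nrow(mixed$pairs)
  n_dec <- sum(mixed$truth$origin == "nuclear")
  expect_equal(n, 1000L)
  expect_lt(abs(n_dec - 500), 3 * sqrt(1000 * 0.25))

  ## errors appear at roughly the requested rate, qualities match
  noisy <- simulate_radseq(sim$genome, sim$sites, depth = 10,
                           error_rate = 0.01, seed = 57)
  q <- unique(unlist(phred_decode(noisy$pairs$qual1)))
  expect_equal(q, 20L)
  g <- sim$genome$residues
  clean1 <- vapply(seq_len(nrow(noisy$truth)), function(i) {
    p <- noisy$truth$site[i]
    if (noisy$truth$side[i] == "right") circ_substr(g, p + 1, p + 101)
    else revcomp(circ_substr(g, p + 5 - 100, p + 5))
  }, character(1))
  n_err <- sum(mapply(function(a, b) sum(strsplit(a, "")[[1]] !=
                                           strsplit(b, "")[[1]]),
                      noisy$pairs$read1, clean1))
  n_base <- sum(nchar(noisy$pairs$read1))
  expect_lt(abs(n_err / n_base - 0.01), 0.004)

  expect_identical(simulate_radseq(sim$genome, sim$sites, depth = 5,
                                   seed = 77)$pairs,
                   simulate_radseq(sim$genome, sim$sites, depth = 5,
                                   seed = 77)$pairs)
})

test_that("the cohort generator is deterministic and structured", {
  a <- simulate_cohort(ref_length = 12000, n_sites = 6, min_spacing = 600,
                       depth = 8, seed = 66)
  b <- simulate_cohort(ref_length = 12000, n_sites = 6, min_spacing = 600,
                       depth = 8, seed = 66)
  expect_identical(a$individuals[["pop1_ind2"]]$pairs,
                   b$individuals[["pop1_ind2"]]$pairs)
  expect_equal(names(a$populations),
               names(a$individuals))
  ## within-population individuals share their founder substitutions
  t1 <- a$individuals[["pop1_ind1"]]$truth
  t2 <- a$individuals[["pop1_ind2"]]$truth
  t3 <- a$individuals[["pop2_ind1"]]$truth
  expect_gt(length(intersect(t1$pos, t2$pos)),
            length(intersect(t1$pos, t3$pos)))
  ## truth round-trips to the genome through the reference
  expect_identical(apply_truth(a$ref$residues, t1),
                   a$individuals[["pop1_ind1"]]$genome$residues)
})
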