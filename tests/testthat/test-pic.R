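test_that("pairwise PIC counts substitutions and indel events", {
  aln <- make_aln(a = "ACGTAC", b = "ACGTAC")
  r <- pairwise_pic(aln, "a", "b")
  expect_equal(c(r$snp_count, r$indel_count, r$pic), c(0L, 0L, 0L))

  ## one substitution and one 2-column gap run
  aln2 <- make_aln(a = "AC--GT", b = "ACTAGA")
  r2 <- pairwise_pic(aln2, "a", "b")
  expect_equal(r2$snp_count, 1L)
  expect_equal(r2$indel_count, 1L)
  expect_equal(r2$pic, 2L)

  ## a gap run in each row; N mismatches even against N
  aln3 <- make_aln(a = "AANT--G", b = "A-NTCCG")
  r3 <- pairwise_pic(aln3, "a", "b")
  expect_equal(r3$snp_count, 1L)      # the N/N column
  expect_equal(r3$indel_count, 2L)    # one run per side
})

test_that("pairwise PIC is symmetric, zero on the diagonal, and additive", {
  set.seed(505)
  for (rep in 1:30) {
    L <- sample(20:120, 1)
    mk <- function() paste(sample(c("A", "C", "G", "T", "-"), L, TRUE,
                                  prob = c(.22, .22, .22, .22, .12)),
                           collapse = "")
    a <- mk(); b <- mk()
    ## avoid all-gap columns
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    both <- av == "-" & bv == "-"
    av[both] <- "A"
    aln <- new_alignment(c(a = paste(av, collapse = ""),
                           b = paste(bv, collapse = "")))
    ab <- pairwise_pic(aln, "a", "b")
    ba <- pairwise_pic(aln, "b", "a")
    expect_equal(ab$pic, ba$pic)
    expect_equal(pairwise_pic(aln, "a", "a")$pic, 0L)
    ## additive over a split where neither row is gap
    cand <- which(av != "-" & bv != "-")
    cand <- cand[cand > 1 & cand < L]
    if (length(cand)) {
      cut <- sample(cand, 1) - 1L   # 0-based split point
      left <- pairwise_pic(aln, "a", "b", 0L, cut)
      right <- pairwise_pic(aln, "a", "b", cut, L)
      expect_equal(left$pic + right$pic, ab$pic)
    }
  }
})

test_that("pairwise PIC matches the column-by-column reference", {
  set.seed(606)
  for (rep in 1:200) {
    L <- sample(10:200, 1)
    mk <- function() paste(sample(c("A", "C", "G", "T", "N", "-"), L, TRUE,
                                  prob = c(.2, .2, .2, .2, .05, .15)),
                           collapse = "")
    av <- strsplit(mk(), "")[[1]]; bv <- strsplit(mk(), "")[[1]]
    both <- av == "-" & bv == "-"
    av[both] <- "C"
    a <- paste(av, collapse = ""); b <- paste(bv, collapse = "")
    aln <- new_alignment(c(a = a, b = b))
    s <- sample(0:(L - 1), 1); e <- sample(seq.int(s + 1, L), 1)
    if (e <= s) e <- L
    got <- pairwise_pic(aln, "a", "b", s, e)
    ora <- oracle_pic(a, b, s, e)
    expect_equal(got$snp_count, unname(ora["snp"]))
    expect_equal(got$indel_count, unname(ora["indel"]))
  }
})

test_that("intrageneric/intergeneric aggregation averages the right pairs", {
  grouping <- list(ingroup = c("p1", "p2", "p3"), outgroup = "o")
  recs <- data.frame(row_i = c("p1", "p1", "p2", "p1", "p2", "p3"),
                     row_j = c("p2", "p3", "p3", "o", "o", "o"),
                     pic = c(1, 2, 3, 3, 6, 9))
  s <- aggregate_pic(recs, grouping, region_length = 100L)
  expect_equal(s$intrageneric_pic, 2)
  expect_equal(s$intergeneric_pic, 6)
  expect_equal(s$intrageneric_per100, 2)
  expect_equal(s$intergeneric_per100, 6)

  expect_error(aggregate_pic(recs[-1, ], grouping, 100L), "missing PIC")

  zero <- transform(recs, pic = 0)
  s0 <- aggregate_pic(zero, grouping, 100L)
  expect_equal(c(s0$intrageneric_pic, s0$intergeneric_pic), c(0, 0))
})

test_that("sliding windows tile correctly and match per-window recomputation", {
  aln <- make_aln(a = strrep("ACGT", 60), b = strrep("ACGT", 60),
                  c = strrep("ACGT", 60), o = strrep("ACGT", 60))
  grouping <- list(ingroup = c("a", "b", "c"), outgroup = "o")
  w <- sliding_window_pic(aln, grouping, 100, 25)
  expect_equal(w$start, seq(0, 150, by = 25))
  expect_equal(w$end[nrow(w)], 240)
  expect_true(all(w$intrageneric_pic == 0))

  ## window counts equal a direct regional recomputation
  set.seed(707)
  L <- 173
  mk <- function() paste(sample(c("A", "C", "G", "T", "-"), L, TRUE,
                                prob = c(.22, .22, .22, .22, .12)),
                         collapse = "")
  rows <- replicate(4, mk())
  m <- do.call(rbind, strsplit(rows, ""))
  m[1, colSums(m == "-") == 4] <- "G"
  rows <- apply(m, 1, paste, collapse = "")
  aln2 <- new_alignment(setNames(rows, c("a", "b", "c", "o")))
  w2 <- sliding_window_pic(aln2, grouping, 40, 15)
  for (k in seq_len(nrow(w2))) {
    direct <- region_pic_table(aln2,
                               data.frame(start = w2$start[k],
                                          end = w2$end[k]), grouping)
    expect_equal(w2$intrageneric_pic[k], direct$intrageneric_pic)
    expect_equal(w2$intergeneric_pic[k], direct$intergeneric_pic)
  }

  expect_error(sliding_window_pic(aln, grouping, 500, 25), "exceeds")
})

test_that("marker ranking orders by PIC with documented tie-breaks", {
  tbl <- data.frame(name = c("r1", "r2", "r3"), start = c(0, 50, 120),
                    end = c(30, 90, 160), length = c(30, 40, 40),
                    intrageneric_pic = c(5, 9, 7),
                    intergeneric_pic = c(1, 1, 1),
                    intrageneric_per100 = c(5, 9, 7) / c(30, 40, 40) * 100,
                    intergeneric_per100 = c(1, 1, 1) / c(30, 40, 40) * 100)
  r <- rank_marker_regions(tbl)
  expect_equal(r$name, c("r2", "r3", "r1"))

  ## all PIC equal: per-100bp breaks the tie, then start
  tbl$intrageneric_pic <- c(4, 4, 4)
  tbl$intrageneric_per100 <- 100 * tbl$intrageneric_pic / tbl$length
  r2 <- rank_marker_regions(tbl)
  expect_equal(r2$name, c("r1", "r2", "r3"))

  ## length cutoff removes long regions
  r3 <- rank_marker_regions(tbl, max_len = 35)
  expect_equal(r3$name, "r1")
})

test_that("adjacent seas can be joined across short islands", {
  mask <- rep(TRUE, 300)
  mask[101:110] <- FALSE    # sea 1 (len 10)
  mask[161:190] <- FALSE    # sea 2 (len 30), separated by 50-col island
  isl <- find_con_islands(mask, 20, "circular")
  seas <- find_con_seas(isl, 300, "circular")
  expect_equal(nrow(seas), 2L)
  joined <- join_adjacent_seas(seas, isl, 300, max_island_len = 60)
  expect_equal(nrow(joined), 1L)
  expect_equal(joined$length, 10L + 50L + 30L)
  joined2 <- join_adjacent_seas(seas, isl, 300, max_island_len = 30)
  expect_equal(nrow(joined2), 2L)
})
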