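test_that("conserved-column labeling follows the identity rule", {
  aln <- make_aln(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGTAC")
  expect_true(all(label_conserved(aln)))

  aln2 <- make_aln(a = "ACGT", b = "ACGA", c = "ACG-")
  expect_equal(which(label_conserved(aln2)), 1:3)

  ## subsets matter: dropping the divergent row restores conservation
  expect_equal(which(label_conserved(aln2, c("a", "b"))), 1:3)
  expect_error(label_conserved(aln2, "a"), "at least 2 rows")
  expect_error(label_conserved(aln2, c("a", "zz")), "unknown row")

  ## N is a mismatch to everything including N, unless toggled
  aln3 <- make_aln(a = "ANGT", b = "ANGT")
  expect_equal(which(label_conserved(aln3)), c(1, 3, 4))
  expect_equal(which(label_conserved(aln3, n_matches = TRUE)), 1:4)
})

test_that("island finding handles runs, thresholds and circular wrap", {
  mask <- rep(TRUE, 200)
  isl <- find_con_islands(mask, 50, "circular")
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$length, 200L)

  mask2 <- rep(FALSE, 200)
  mask2[1:60] <- TRUE; mask2[71:130] <- TRUE
  isl2 <- find_con_islands(mask2, 50, "linear")
  expect_equal(nrow(isl2), 2L)
  expect_equal(isl2$start, c(0L, 70L))
  expect_equal(isl2$length, c(60L, 60L))

  ## a run spanning the origin is one island under circular topology
  mask3 <- rep(FALSE, 100)
  mask3[c(71:100, 1:30)] <- TRUE
  isl3c <- find_con_islands(mask3, 50, "circular")
  expect_equal(nrow(isl3c), 1L)
  expect_equal(isl3c$start, 70L)
  expect_equal(isl3c$end, 30L)         # wrap encoded as end <= start
  expect_equal(isl3c$length, 60L)
  isl3l <- find_con_islands(mask3, 50, "linear")
  expect_equal(nrow(isl3l), 0L)        # both halves < 50

  expect_error(find_con_islands(mask, 0), "min_island_len")
})

test_that("sea finding yields the inter-island complement", {
  ## two islands on a circle -> two seas covering everything else
  mask <- rep(FALSE, 300)
  mask[11:80] <- TRUE; mask[151:220] <- TRUE
  isl <- find_con_islands(mask, 50, "circular")
  seas <- find_con_seas(isl, 300, "circular")
  expect_equal(nrow(seas), 2L)
  expect_equal(sum(isl$length) + sum(seas$length), 300L)
  expect_equal(seas$name, c("Con_Sea_1", "Con_Sea_2"))

  ## abutting islands leave no sea at their junction
  isl2 <- data.frame(name = c("i1", "i2"), start = c(0L, 61L),
                     end = c(60L, 120L), length = c(60L, 59L))
  seas2 <- find_con_seas(isl2, 120, "circular")
  expect_equal(nrow(seas2), 1L)
  expect_equal(seas2$start, 60L)
  expect_equal(seas2$length, 1L)

  expect_error(find_con_seas(data.frame(start = c(0L, 30L), end = c(40L, 80L),
                                        length = c(40L, 50L)), 100),
               "overlap")
})

test_that("island/sea finding matches exhaustive run enumeration", {
  set.seed(202)
  for (rep in 1:60) {
    L <- sample(60:500, 1)
    p <- runif(1, 0.5, 0.95)
    mask <- runif(L) < p
    minl <- sample(c(3L, 5L, 10L, 50L), 1)
    for (topo in c("circular", "linear")) {
      isl <- find_con_islands(mask, minl, topo)
      ora <- oracle_islands(mask, minl, topo)
      expect_equal(isl$start, ora$start)
      expect_equal(isl$length, ora$length)
      seas <- find_con_seas(isl, L, topo)
      ose <- oracle_seas(isl, L, topo)
      expect_equal(seas$start, ose$start)
      expect_equal(seas$length, ose$length)
      if (topo == "circular" && nrow(isl) >= 2)
        expect_equal(nrow(seas), nrow(isl))
    }
  }
})

test_that("lowering the island threshold is monotone", {
  set.seed(303)
  for (rep in 1:20) {
    mask <- runif(300) < 0.85
    isl_hi <- find_con_islands(mask, 30, "circular")
    isl_lo <- find_con_islands(mask, 10, "circular")
    expect_gte(nrow(isl_lo), nrow(isl_hi))
    seas_hi <- find_con_seas(isl_hi, 300, "circular")
    seas_lo <- find_con_seas(isl_lo, 300, "circular")
    ## every low-threshold sea fits inside some high-threshold sea
    if (nrow(seas_lo) && nrow(seas_hi))
      expect_lte(max(seas_lo$length), max(seas_hi$length))
  }
})

test_that("islands and seas partition the circle", {
  set.seed(404)
  for (rep in 1:20) {
    L <- sample(100:400, 1)
    mask <- runif(L) < 0.8
    isl <- find_con_islands(mask, 20, "circular")
    seas <- find_con_seas(isl, L, "circular")
    covered <- rep(0L, L)
    mark <- function(df) for (i in seq_len(nrow(df))) {
      idx <- (df$start[i] + seq_len(df$length[i]) - 1L) %% L
      covered[idx + 1L] <<- covered[idx + 1L] + 1L
    }
    mark(isl); mark(seas)
    if (nrow(isl) > 0)
      expect_true(all(covered == 1L))   # exact cover, no overlap
  }
})
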