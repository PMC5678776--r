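## Independent brute-force oracles, deliberately written as plain scans so
## they share no code path with the package implementations.

## maximal conserved runs by explicit per-column scanning; circular masks
## are rotated so the scan starts at a non-conserved column
oracle_islands <- function(mask, min_len, topology = "circular") {
  L <- length(mask)
  if (topology == "circular" && all(mask))
    return(data.frame(start = 0L, end = L, length = L))
  off <- 0L
  m <- mask
  if (topology == "circular" && mask[1]) {
    off <- which(!mask)[1] - 1L
    m <- mask[c((off + 1L):L, seq_len(off))]
  }
  runs <- list()
  i <- 1L
  while (i <= L) {
    if (m[i]) {
      j <- i
      while (j < L && m[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) {
        s <- (i - 1L + off) %% L
        e <- s + (j - i + 1L)
        runs[[length(runs) + 1L]] <-
          data.frame(start = s, end = if (e > L) e - L else e,
                     length = j - i + 1L)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  out <- do.call(rbind, runs)
  out[order(out$start), , drop = FALSE]
}

## seas as the contiguous complement intervals between islands
oracle_seas <- function(islands, L, topology = "circular") {
  if (nrow(islands) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  covered <- rep(FALSE, L)
  for (i in seq_len(nrow(islands))) {
    s <- islands$start[i]
    idx <- (s + seq_len(islands$length[i]) - 1L) %% L
    covered[idx + 1L] <- TRUE
  }
  comp <- oracle_islands(!covered, 1L, topology)
  if (topology == "linear" && nrow(comp)) {
    ## only intervals flanked by islands on both sides
    keep <- comp$start > 0 & comp$end < L &
      comp$end > comp$start   # no wraps in linear mode
    comp <- comp[keep, , drop = FALSE]
  }
  comp[order(comp$start), , drop = FALSE]
}

## column-by-column PIC with an explicit state machine
oracle_pic <- function(a, b, start = 0L, end = nchar(a)) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  snp <- 0L; indel <- 0L; prev <- "none"
  for (k in seq.int(start + 1L, end)) {
    ga <- av[k] == "-"; gb <- bv[k] == "-"
    if (ga && gb) next                       # ignored entirely
    state <- if (ga) "gapA" else if (gb) "gapB" else "none"
    if (state == "none") {
      if (av[k] != bv[k] || av[k] == "N") snp <- snp + 1L
    } else if (state != prev) indel <- indel + 1L
    prev <- state
  }
  c(snp = snp, indel = indel, pic = snp + indel)
}

## nucleotide diversity / Watterson / Hudson FST by naive pair loops
oracle_popgen <- function(seqs, populations) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  miss <- m == "-" | m == "N"
  n <- nrow(m)
  pair_pi <- function(i, j) {
    ok <- !miss[i, ] & !miss[j, ]
    if (!any(ok)) return(NA_real_)
    sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) vals <- c(vals, pair_pi(i, j))
  pi_all <- mean(vals, na.rm = TRUE)
  complete <- colSums(miss) == 0
  S <- 0L
  for (k in which(complete))
    if (length(unique(m[, k])) > 1) S <- S + 1L
  a_n <- sum(1 / 1:(n - 1))
  theta <- if (sum(complete) > 0) S / (a_n * sum(complete)) else NA_real_
  pops <- unique(populations)
  fst <- NA_real_
  if (length(pops) == 2) {
    ia <- which(populations == pops[1]); ib <- which(populations == pops[2])
    between <- c()
    for (i in ia) for (j in ib) between <- c(between, pair_pi(i, j))
    within <- c()
    for (grp in list(ia, ib)) {
      if (length(grp) < 2) next
      v <- c()
      for (i in grp[-length(grp)])
        for (j in grp[grp > i]) v <- c(v, pair_pi(i, j))
      within <- c(within, mean(v, na.rm = TRUE))
    }
    pb <- mean(between, na.rm = TRUE)
    if (!is.na(pb) && pb > 0) fst <- 1 - mean(within) / pb
  }
  list(S = S, pi = pi_all, theta_w = theta, fst = fst)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## small alignment constructor for tests
make_aln <- function(..., groups = NULL) {
  new_alignment(c(...), groups = groups)
}
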