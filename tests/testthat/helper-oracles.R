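# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized implementations: explicit loops, their own indexing
# arithmetic, and straightforward enumeration.

ORACLE_PT <- c("AU", "CG", "GC", "GU", "UA", "UG")

oraclePairCode <- function(a, b) {
  p <- paste0(a, b)
  if (p %in% ORACLE_PT) match(p, ORACLE_PT) - 1L else NA_integer_
}

# Brute-force enumeration of all set feature bits of a sample.
oracleEncode <- function(mic, cts) {
  m <- strsplit(mic, "")[[1]]
  s <- strsplit(cts, "")[[1]]
  bits <- integer(0)
  for (i in 0:24) for (j in 0:24) {
    t1 <- oraclePairCode(m[i + 1], s[j + 1])
    if (!is.na(t1)) bits <- c(bits, i * 150L + j * 6L + t1)
  }
  for (i in 0:24) for (d in -2:2) {
    j <- i + d
    if (j < 0 || j > 23 || i > 23) next
    t1 <- oraclePairCode(m[i + 1], s[j + 1])
    t2 <- oraclePairCode(m[i + 2], s[j + 2])
    if (!is.na(t1) && !is.na(t2))
      bits <- c(bits, 3750L + i * 180L + (d + 2L) * 36L + t1 * 6L + t2)
  }
  for (i in 0:24) for (d in -1:1) {
    j <- i + d
    if (j < 0 || j > 22 || i > 22) next
    t1 <- oraclePairCode(m[i + 1], s[j + 1])
    t2 <- oraclePairCode(m[i + 2], s[j + 2])
    t3 <- oraclePairCode(m[i + 3], s[j + 3])
    if (!is.na(t1) && !is.na(t2) && !is.na(t3))
      bits <- c(bits, 8250L + i * 648L + (d + 1L) * 216L + t1 * 36L +
                  t2 * 6L + t3)
  }
  sort(bits)
}

# Exhaustive optimum over all monotone non-crossing structures, enumerated as
# chains of 1-3-pair runs (never pairing position 0 of either strand), each
# run scored via scoreLookup. Memoized on the last paired position.
oracleBestWeight <- function(mic, cts, sd) {
  m <- strsplit(mic, "")[[1]]
  s <- strsplit(cts, "")[[1]]
  runs <- list()
  for (sr in 1:24) for (sc in 1:24) for (k in 1:3) {
    er <- sr + k - 1L; ec <- sc + k - 1L
    if (er > 24 || ec > 24) next
    tt <- character(k); ok <- TRUE
    for (q in 0:(k - 1L)) {
      cd <- oraclePairCode(m[sr + q + 1L], s[sc + q + 1L])
      if (is.na(cd)) { ok <- FALSE; break }
      tt[q + 1L] <- ORACLE_PT[cd + 1L]
    }
    if (!ok) next
    runs[[length(runs) + 1L]] <-
      list(sr = sr, sc = sc, er = er, ec = ec,
           w = scoreLookup(sd, er, ec, tt))
  }
  memo <- matrix(NA_real_, 26, 26)
  best <- function(lr, lc) {
    if (!is.na(memo[lr + 1L, lc + 1L])) return(memo[lr + 1L, lc + 1L])
    v <- 0
    for (rn in runs)
      if (rn$sr > lr && rn$sc > lc)
        v <- max(v, rn$w + best(rn$er, rn$ec))
    memo[lr + 1L, lc + 1L] <<- v
    v
  }
  best(0L, 0L)
}

# Per-threshold recomputation of the 100-point precision-recall grid and the
# plain trapezoid sum over it.
oraclePRCurve <- function(labels, probs) {
  th <- seq(1, 0, length.out = 100)
  P <- R <- numeric(100)
  for (k in 1:100) {
    pred <- probs >= th[k]
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    fn <- sum(!pred & labels == 1)
    P[k] <- if (tp + fp == 0) 1 else tp / (tp + fp)
    R[k] <- tp / (tp + fn)
  }
  data.frame(threshold = th, precision = P, recall = R)
}

oracleAUPRC <- function(P, R) {
  a <- 0
  for (k in 1:(length(R) - 1))
    a <- a + (R[k + 1] - R[k]) * (P[k + 1] + P[k]) / 2
  min(max(a, 0), 1)
}

# Random padded sample pair with an embedded unpadded region of given length.
randomPairedSeqs <- function(len) {
  pad <- strrep("-", 25 - len)
  list(mic = paste0(paste(sample(c("A", "C", "G", "U"), len, TRUE),
                          collapse = ""), pad),
       cts = paste0(paste(sample(c("A", "C", "G", "U"), len, TRUE),
                          collapse = ""), pad))
}

# Small random ScoreDict: standard-normal weights everywhere.
randomScoreDict <- function() scoreDict(rnorm(24450))
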