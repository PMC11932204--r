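## The duplex-structure dynamic program. For a 25-symbol microRNA and
## candidate site it fills three 25x25 tables: S1 (cumulative best structure
## weight over the prefixes), BT1 (backpointers) and MFE1 (Turner free energy
## of the structure backtracked from each cell), then reconstructs the
## weight-optimal non-crossing structure.
##
## Recursion over 0-based cells (i, j), borders at row/column 0 fixed to zero:
##   S1[i][j] = max( S1[i-1][j],                              (skip mic base)
##                   S1[i][j-1],                              (skip site base)
##                   S1[i-k][j-k] + runWeight(end = (i, j), k) ) for k in 1..3
## A k-run pairs mic[i-k+1 .. i] with cts[j-k+1 .. j]; every pair of the run
## must be canonical and pad-free. Because the predecessor cell (i-k, j-k)
## must exist, no run can ever pair position 0 of either strand. Ties are
## broken with fixed precedence diag-3 > diag-2 > diag-1 > up > left, which
## favors longer matched runs and makes backtracking deterministic.

BT_STOP <- 0L; BT_LEFT <- 1L; BT_UP <- 2L
BT_D1 <- 3L; BT_D2 <- 4L; BT_D3 <- 5L

## helix-end penalty per pair-type code (AU/UA and GU/UG termini qualify)
.endPenVec <- function(turner) {
  p <- numeric(6)
  p[match(c("AU", "UA", "GU", "UG"), PAIR_TYPES)] <- turner@auEndDg
  p
}

## Vectorized run-weight matrices for one sample under a ScoreDict.
## Wk[i+1, j+1] = weight of the k-run ENDING at 0-based (i, j), NA where the
## run is infeasible (non-canonical pair, pad, or would pair position 0).
.runWeightMatrices <- function(tcode, sd) {
  w <- sd@w
  n <- SAMPLE_LEN
  i0 <- matrix(0:(n - 1L), n, n)        # mic position of the cell
  j0 <- t(i0)                           # site position of the cell
  W1 <- matrix(NA_real_, n, n)
  ok <- !is.na(tcode)
  W1[ok] <- w[i0[ok] * 150L + j0[ok] * 6L + (tcode[ok] - 1L) + 1L]

  shift <- function(m, by) {            # value at (i-by, j-by), NA off-grid
    out <- matrix(NA_real_, n, n)
    out[(by + 1L):n, (by + 1L):n] <- m[1:(n - by), 1:(n - by)]
    out
  }
  tc <- tcode
  tc1 <- shift(tc, 1L); tc2 <- shift(tc, 2L)
  d <- j0 - i0

  ## k = 2: pairs at (i-1, j-1) and (i, j); run must not touch position 0,
  ## so it needs i >= 2 and j >= 2 (predecessor cell (i-2, j-2) exists).
  W2 <- matrix(NA_real_, n, n)
  ok2 <- !is.na(tc) & !is.na(tc1) & i0 >= 2L & j0 >= 2L
  inw <- ok2 & abs(d) <= 2L
  if (any(inw))
    W2[inw] <- w[3750L + (i0[inw] - 1L) * 180L + (d[inw] + 2L) * 36L +
                   (tc1[inw] - 1L) * 6L + (tc[inw] - 1L) + 1L]
  outw <- ok2 & abs(d) > 2L
  if (any(outw)) {
    W1s <- shift(W1, 1L)
    W2[outw] <- W1s[outw] + W1[outw]
  }

  ## k = 3: pairs at (i-2, j-2), (i-1, j-1), (i, j); needs i, j >= 3.
  W3 <- matrix(NA_real_, n, n)
  ok3 <- !is.na(tc) & !is.na(tc1) & !is.na(tc2) & i0 >= 3L & j0 >= 3L
  inw3 <- ok3 & abs(d) <= 1L
  if (any(inw3))
    W3[inw3] <- w[8250L + (i0[inw3] - 2L) * 648L + (d[inw3] + 1L) * 216L +
                    (tc2[inw3] - 1L) * 36L + (tc1[inw3] - 1L) * 6L +
                    (tc[inw3] - 1L) + 1L]
  outw3 <- ok3 & abs(d) > 1L
  if (any(outw3)) {
    W1s <- shift(W1, 1L); W1ss <- shift(W1, 2L)
    W3[outw3] <- W1ss[outw3] + W1s[outw3] + W1[outw3]
  }
  list(W1 = W1, W2 = W2, W3 = W3)
}

#' Fill the duplex DP tables for one microRNA/site pair
#'
#' Computes the 25x25 scoring table \code{S1} (maximum total structure weight
#' over all non-crossing structures of the two prefixes), the backpointer
#' table \code{BT1}, and \code{MFE1}, the Turner free energy of the structure
#' backtracked from each cell. Row and column 0 are zero; computation starts
#' at cell (1, 1), so position 0 of either strand never pairs.
#'
#' @param mic,cts 25-symbol padded sequences over \code{A, C, G, U, -}.
#' @param sd A \code{\link{ScoreDict-class}} of run weights.
#' @param turner A \code{TurnerParams} object.
#' @return A \code{\link{DPTables-class}} object.
#' @export
fillDPTables <- function(mic, cts, sd, turner = turnerParams()) {
  checkSeq25(mic, "mic"); checkSeq25(cts, "cts")
  tcode <- .pairTypeMatrix(mic, cts)
  W <- .runWeightMatrices(tcode, sd)
  n <- SAMPLE_LEN
  S <- matrix(0, n, n)
  BT <- matrix(BT_STOP, n, n)
  E <- matrix(0, n, n)                 # energy of backtracked structure
  lastR <- matrix(-1L, n, n)           # last paired mic position (0-based)
  lastC <- matrix(-1L, n, n)
  lastT <- matrix(0L, n, n)            # type code of the last pair
  stackM <- turner@stackDg
  pen <- .endPenVec(turner)
  init <- turner@initDg
  bulge <- turner@bulgeDg; internal <- turner@internalDg
  nTab <- length(bulge)
  loopE <- function(tab, size) {
    if (size <= nTab) tab[[size]] else tab[[nTab]] + 1.07856 * log(size / nTab)
  }

  for (ii in 2:n) {          # R row index = 0-based i + 1
    for (jj in 2:n) {
      cand <- c(
        if (ii >= 4L && jj >= 4L && !is.na(W$W3[ii, jj]))
          S[ii - 3L, jj - 3L] + W$W3[ii, jj] else -Inf,
        if (ii >= 3L && jj >= 3L && !is.na(W$W2[ii, jj]))
          S[ii - 2L, jj - 2L] + W$W2[ii, jj] else -Inf,
        if (!is.na(W$W1[ii, jj]))
          S[ii - 1L, jj - 1L] + W$W1[ii, jj] else -Inf,
        S[ii - 1L, jj],
        S[ii, jj - 1L])
      pick <- which.max(cand)          # first max = precedence d3,d2,d1,up,left
      S[ii, jj] <- cand[pick]
      code <- c(BT_D3, BT_D2, BT_D1, BT_UP, BT_LEFT)[pick]
      BT[ii, jj] <- code
      if (code == BT_UP) {
        E[ii, jj] <- E[ii - 1L, jj]
        lastR[ii, jj] <- lastR[ii - 1L, jj]
        lastC[ii, jj] <- lastC[ii - 1L, jj]
        lastT[ii, jj] <- lastT[ii - 1L, jj]
      } else if (code == BT_LEFT) {
        E[ii, jj] <- E[ii, jj - 1L]
        lastR[ii, jj] <- lastR[ii, jj - 1L]
        lastC[ii, jj] <- lastC[ii, jj - 1L]
        lastT[ii, jj] <- lastT[ii, jj - 1L]
      } else {
        k <- code - 2L
        pi_ <- ii - k; pj <- jj - k     # predecessor cell (R indices)
        runT <- tcode[cbind((ii - k + 1L):ii, (jj - k + 1L):jj)]
        innerStack <- if (k > 1L)
          sum(stackM[cbind(runT[-k], runT[-1L])]) else 0
        pLastR <- lastR[pi_, pj]
        if (pLastR < 0L) {
          e <- init + pen[runT[1L]] + innerStack + pen[runT[k]]
        } else {
          dr <- (ii - k + 1L - 1L) - pLastR - 1L   # gap on mic strand
          dc <- (jj - k + 1L - 1L) - lastC[pi_, pj] - 1L
          eprev <- E[pi_, pj]
          if (dr == 0L && dc == 0L) {
            e <- eprev - pen[lastT[pi_, pj]] +
              stackM[lastT[pi_, pj], runT[1L]] + innerStack + pen[runT[k]]
          } else if (dr == 0L || dc == 0L) {
            e <- eprev + loopE(bulge, dr + dc) + pen[runT[1L]] +
              innerStack + pen[runT[k]]
          } else {
            e <- eprev + loopE(internal, dr + dc) + pen[runT[1L]] +
              innerStack + pen[runT[k]]
          }
        }
        E[ii, jj] <- e
        lastR[ii, jj] <- ii - 1L        # 0-based position of the last pair
        lastC[ii, jj] <- jj - 1L
        lastT[ii, jj] <- runT[k]
      }
    }
  }
  methods::new("DPTables", S1 = S, BT1 = BT, MFE1 = E, mic = mic, cts = cts)
}

#' @describeIn DPTables-class Display a short summary.
#' @param object A \code{DPTables} object.
#' @export
setMethod("show", "DPTables", function(object) {
  cat("DPTables 25x25 | best weight ", signif(object@S1[25, 25], 5),
      " | dG37 of optimum ", signif(object@MFE1[25, 25], 5), " kcal/mol\n",
      sep = "")
})

#' Backtrack the weight-optimal structure from a DP cell
#'
#' Follows the backpointers from cell \code{from} (default the last cell) and
#' reconstructs the ordered set of base pairs; a diag-k pointer at (i, j)
#' contributes k pairs at positions (i-k+1 .. i, j-k+1 .. j). The returned
#' total weight is recomputed from the run decomposition via
#' \code{\link{scoreLookup}} and equals \code{S1[from]} exactly.
#'
#' @param tables A \code{\link{DPTables-class}} object.
#' @param sd The \code{ScoreDict} the tables were filled with.
#' @param from 0-based cell \code{c(i, j)} to start from (default
#'   \code{c(24, 24)}).
#' @return A \code{\link{DuplexStructure-class}} object.
#' @export
backtrackDuplex <- function(tables, sd, from = c(24L, 24L)) {
  tcode <- .pairTypeMatrix(tables@mic, tables@cts)
  ii <- from[1] + 1L; jj <- from[2] + 1L
  rs <- integer(0); cs <- integer(0); tw <- 0
  while (ii > 1L && jj > 1L) {
    code <- tables@BT1[ii, jj]
    if (code == BT_STOP) break
    if (code == BT_UP) { ii <- ii - 1L }
    else if (code == BT_LEFT) { jj <- jj - 1L }
    else {
      k <- code - 2L
      runR <- (ii - k + 1L):ii; runC <- (jj - k + 1L):jj
      runT <- PAIR_TYPES[tcode[cbind(runR, runC)]]
      tw <- tw + scoreLookup(sd, ii - 1L, jj - 1L, runT)
      rs <- c(runR - 1L, rs); cs <- c(runC - 1L, cs)
      ii <- ii - k; jj <- jj - k
    }
  }
  if (length(rs) > 1L && (any(diff(rs) <= 0L) || any(diff(cs) <= 0L)))
    stop("internal inconsistency: backtracked pairs are not monotone")
  types <- if (length(rs))
    PAIR_TYPES[tcode[cbind(rs + 1L, cs + 1L)]] else character(0)
  methods::new("DuplexStructure",
    pairs = data.frame(r = rs, c = cs, type = types,
                       stringsAsFactors = FALSE),
    totalWeight = tw,
    dg37 = tables@MFE1[from[1] + 1L, from[2] + 1L])
}

#' @describeIn DuplexStructure-class Display the structure.
#' @param object A \code{DuplexStructure} object.
#' @export
setMethod("show", "DuplexStructure", function(object) {
  cat("DuplexStructure: ", nrow(object@pairs), " base pairs | total weight ",
      signif(object@totalWeight, 5), " | dG37 ", signif(object@dg37, 5),
      " kcal/mol\n", sep = "")
  if (nrow(object@pairs))
    cat(paste0("  (", object@pairs$r, ",", object@pairs$c, ",",
               object@pairs$type, ")", collapse = " "), "\n")
})

#' @describeIn DuplexStructure-class Number of base pairs.
#' @param x A \code{DuplexStructure} object.
#' @export
setMethod("length", "DuplexStructure", function(x) nrow(x@pairs))

#' Turner free energy of a duplex structure
#'
#' Evaluates the structure's free energy at 37 C as the sum of the
#' intermolecular initiation term, nearest-neighbor stacks for adjacent pairs
#' with no gap on either strand, bulge terms for one-sided gaps, internal-loop
#' terms for two-sided gaps, and a weak-end penalty at every helix terminus
#' closed by an AU/UA/GU/UG pair (a lone pair is a helix with two coinciding
#' termini and is penalized at both). An empty structure has no initiation
#' event and energy 0.
#'
#' @param structure A \code{\link{DuplexStructure-class}} object.
#' @param mic,cts The 25-symbol sequences the structure belongs to.
#' @param turner A \code{TurnerParams} object.
#' @return The free energy in kcal/mol.
#' @export
duplexDg37 <- function(structure, mic, cts, turner = turnerParams()) {
  p <- structure@pairs
  if (nrow(p) == 0L) return(0)
  mch <- seqChars(mic); sch <- seqChars(cts)
  seqType <- canonicalPairType(mch[p$r + 1L], sch[p$c + 1L])
  if (any(is.na(seqType)) || any(seqType != p$type))
    stop("structure pair types are inconsistent with the sequences")
  tcode <- match(p$type, PAIR_TYPES)
  stackM <- turner@stackDg
  pen <- .endPenVec(turner)
  e <- turner@initDg
  helixStart <- 1L
  if (nrow(p) > 1L) {
    dr <- diff(p$r) - 1L
    dc <- diff(p$c) - 1L
    for (k in seq_len(nrow(p) - 1L)) {
      if (dr[k] == 0L && dc[k] == 0L) {
        e <- e + stackM[tcode[k], tcode[k + 1L]]
      } else {
        if (dr[k] == 0L || dc[k] == 0L)
          e <- e + loopEnergy("bulge", dr[k] + dc[k], turner)
        else
          e <- e + loopEnergy("internal", dr[k] + dc[k], turner)
        ## pair k closes a helix, pair k+1 opens the next one
        e <- e + pen[tcode[helixStart]] + pen[tcode[k]]
        helixStart <- k + 1L
      }
    }
  }
  e + pen[tcode[helixStart]] + pen[tcode[nrow(p)]]
}

#' Predict the duplex structure of a microRNA/site pair
#'
#' Convenience wrapper: fills the DP tables, backtracks from the last cell and
#' evaluates the Turner free energy of the resulting structure.
#'
#' @inheritParams fillDPTables
#' @return A \code{\link{DuplexStructure-class}} object.
#' @export
predictDuplex <- function(mic, cts, sd, turner = turnerParams()) {
  tabs <- fillDPTables(mic, cts, sd, turner)
  st <- backtrackDuplex(tabs, sd)
  st@dg37 <- duplexDg37(st, mic, cts, turner)
  st
}

#' Render a duplex structure as text
#'
#' Produces a two-line alignment with pairing bars plus a machine-readable
#' pair list that \code{\link{parseDuplex}} can read back.
#'
#' @param structure A \code{DuplexStructure}.
#' @param mic,cts The 25-symbol sequences.
#' @return Character vector of text lines.
#' @export
renderDuplex <- function(structure, mic, cts) {
  bars <- rep(" ", SAMPLE_LEN)
  p <- structure@pairs
  ## a bar marks a paired microRNA position (site partner may be offset)
  if (nrow(p)) bars[p$r + 1L] <- "|"
  c(paste0("mic 5' ", mic, " 3'"),
    paste0("       ", paste(bars, collapse = "")),
    paste0("cts 3' ", cts, " 5'"),
    sprintf("# total_weight\t%.17g", structure@totalWeight),
    sprintf("# dg37\t%.17g", structure@dg37),
    if (nrow(p)) sprintf("# pair\t%d\t%d\t%s", p$r, p$c, p$type))
}

#' Parse a duplex rendering back into a structure
#' @param lines Character vector from \code{\link{renderDuplex}}.
#' @return A \code{DuplexStructure} object.
#' @export
parseDuplex <- function(lines) {
  getNum <- function(tag) {
    ln <- grep(paste0("^# ", tag, "\t"), lines, value = TRUE)
    as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]][2])
  }
  pl <- grep("^# pair\t", lines, value = TRUE)
  if (length(pl)) {
    parts <- do.call(rbind, strsplit(pl, "\t", fixed = TRUE))
    pairs <- data.frame(r = as.integer(parts[, 2]),
                        c = as.integer(parts[, 3]),
                        type = parts[, 4], stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(r = integer(0), c = integer(0),
                        type = character(0), stringsAsFactors = FALSE)
  }
  methods::new("DuplexStructure", pairs = pairs,
               totalWeight = getNum("total_weight"), dg37 = getNum("dg37"))
}
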