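## The 24,450-bit base-pair feature encoding of a microRNA/CTS pair:
## every possible single, double and triple canonical base pair between the
## two 25-symbol sequences. Layout (0-based feature indices):
##   singles  [0, 3750):    idx = i*150 + j*6 + t
##   doubles  [3750, 8250):  idx = 3750 + i*180 + (d+2)*36 + t1*6 + t2,
##                           d = j - i in [-2, 2]
##   triples  [8250, 24450): idx = 8250 + i*648 + (d+1)*216 + t1*36 + t2*6 + t3,
##                           d = j - i in [-1, 1]
## where i/j are the microRNA/site positions of the FIRST pair of the run,
## t* are pair-type codes 0..5 in the fixed order AU, CG, GC, GU, UA, UG, and
## runs occupy consecutive positions on both strands. Runs that would cross
## position 24 on either strand have no feasible bit (they stay 0).

FEATURE_BLOCKS <- c(singles = 3750L, doubles = 4500L, triples = 16200L)

#' Canonical pair type of two nucleotides
#'
#' Returns the ordered canonical pair type (microRNA base first) among
#' \code{AU, CG, GC, GU, UA, UG}, or \code{NA} when the two bases do not form
#' a canonical pair or either symbol is the pad. Vectorized.
#'
#' @param x Nucleotide(s) on the microRNA strand.
#' @param y Nucleotide(s) on the target-site strand.
#' @return Character vector of pair types or \code{NA}.
#' @examples
#' canonicalPairType("G", "U")  # "GU"
#' canonicalPairType("A", "G")  # NA
#' @export
canonicalPairType <- function(x, y) {
  p <- paste0(x, y)
  ifelse(p %in% PAIR_TYPES, p, NA_character_)
}

#' Sizes of the base-pair feature blocks
#'
#' @return Named integer vector with the three block sizes and the total:
#'   singles 3750, doubles 4500, triples 16200, total 24450.
#' @export
featureCount <- function() {
  c(FEATURE_BLOCKS, total = sum(FEATURE_BLOCKS))
}

#' 0-based feature index of a single/double/triple base-pair feature
#'
#' @param kind \code{"single"}, \code{"double"} or \code{"triple"}.
#' @param i MicroRNA position (0-based) of the (first) pair of the run.
#' @param j Site position (0-based) of the (first) pair of the run. For
#'   doubles the offset \code{j - i} must lie in \code{[-2, 2]}, for triples
#'   in \code{[-1, 1]}.
#' @param types Character vector of 1, 2 or 3 pair types (first pair first).
#' @return The 0-based feature index.
#' @export
featureIndex <- function(kind = c("single", "double", "triple"), i, j, types) {
  kind <- match.arg(kind)
  i <- as.integer(i); j <- as.integer(j)
  t <- match(types, PAIR_TYPES) - 1L
  if (anyNA(t)) stop("unknown pair type in: ", paste(types, collapse = ","))
  if (i < 0L || i > 24L || j < 0L || j > 24L)
    stop("positions must lie in [0, 24]")
  d <- j - i
  switch(kind,
    single = {
      stopifnot(length(t) == 1L)
      i * 150L + j * 6L + t
    },
    double = {
      stopifnot(length(t) == 2L)
      if (abs(d) > 2L) stop("double offset j - i must lie in [-2, 2]")
      3750L + i * 180L + (d + 2L) * 36L + t[1] * 6L + t[2]
    },
    triple = {
      stopifnot(length(t) == 3L)
      if (abs(d) > 1L) stop("triple offset j - i must lie in [-1, 1]")
      8250L + i * 648L + (d + 1L) * 216L + t[1] * 36L + t[2] * 6L + t[3]
    })
}

#' Decode a 0-based feature index back to its block, positions and types
#'
#' Inverse of \code{\link{featureIndex}}; useful for reporting the largest
#' learned weights.
#'
#' @param idx Integer vector of 0-based feature indices.
#' @return data.frame with columns \code{idx, kind, i, j, types}.
#' @export
decodeFeatureIndex <- function(idx) {
  idx <- as.integer(idx)
  if (any(idx < 0L | idx >= 24450L)) stop("feature index out of range")
  out <- data.frame(idx = idx, kind = "", i = 0L, j = 0L, types = "",
                    stringsAsFactors = FALSE)
  for (k in seq_along(idx)) {
    v <- idx[k]
    if (v < 3750L) {
      i <- v %/% 150L; r <- v %% 150L; j <- r %/% 6L; t <- r %% 6L
      out[k, -1] <- list("single", i, j, PAIR_TYPES[t + 1L])
    } else if (v < 8250L) {
      v <- v - 3750L
      i <- v %/% 180L; r <- v %% 180L; d <- r %/% 36L - 2L; r <- r %% 36L
      out[k, -1] <- list("double", i, i + d,
                         paste(PAIR_TYPES[c(r %/% 6L, r %% 6L) + 1L],
                               collapse = ","))
    } else {
      v <- v - 8250L
      i <- v %/% 648L; r <- v %% 648L; d <- r %/% 216L - 1L; r <- r %% 216L
      out[k, -1] <- list("triple", i, i + d,
                         paste(PAIR_TYPES[c(r %/% 36L, (r %/% 6L) %% 6L,
                                            r %% 6L) + 1L], collapse = ","))
    }
  }
  out
}

## 25x25 matrix of pair-type codes (1..6, NA where non-canonical or pad) for
## one mic/cts pair; rows = microRNA position + 1, cols = site position + 1.
.pairTypeMatrix <- function(mic, cts) {
  m <- seqChars(mic); s <- seqChars(cts)
  matrix(match(as.vector(outer(m, s, paste0)), PAIR_TYPES),
         SAMPLE_LEN, SAMPLE_LEN)
}

#' Encode one duplex sample as its set base-pair feature bits
#'
#' Computes which of the 24,450 binary features are set for a
#' microRNA/candidate-site pair: a bit is 1 iff every constituent position is
#' in range, none is the pad, and each position pair forms the named canonical
#' type.
#'
#' @param mic,cts 25-symbol padded sequences.
#' @return Sorted integer vector of 0-based indices of the set bits.
#' @export
encodeFeatures <- function(mic, cts) {
  checkSeq25(mic, "mic"); checkSeq25(cts, "cts")
  tm <- .pairTypeMatrix(mic, cts)
  hit <- which(!is.na(tm), arr.ind = TRUE)
  out <- integer(0)
  if (nrow(hit)) {
    i0 <- hit[, 1] - 1L; j0 <- hit[, 2] - 1L
    t0 <- tm[hit] - 1L
    out <- i0 * 150L + j0 * 6L + t0
    ## doubles: run starts where this cell and its lower-right diagonal
    ## neighbor both pair, and the start offset is within the window
    ok2 <- hit[, 1] <= 24L & hit[, 2] <= 24L & abs(j0 - i0) <= 2L
    if (any(ok2)) {
      h <- hit[ok2, , drop = FALSE]
      t2 <- tm[cbind(h[, 1] + 1L, h[, 2] + 1L)]
      keep <- !is.na(t2)
      if (any(keep)) {
        h <- h[keep, , drop = FALSE]
        d <- (h[, 2] - h[, 1])
        out <- c(out, 3750L + (h[, 1] - 1L) * 180L + (d + 2L) * 36L +
                   (tm[h] - 1L) * 6L + (t2[keep] - 1L))
      }
    }
    ok3 <- hit[, 1] <= 23L & hit[, 2] <= 23L & abs(j0 - i0) <= 1L
    if (any(ok3)) {
      h <- hit[ok3, , drop = FALSE]
      tb <- tm[cbind(h[, 1] + 1L, h[, 2] + 1L)]
      tc <- tm[cbind(h[, 1] + 2L, h[, 2] + 2L)]
      keep <- !is.na(tb) & !is.na(tc)
      if (any(keep)) {
        h <- h[keep, , drop = FALSE]
        d <- (h[, 2] - h[, 1])
        out <- c(out, 8250L + (h[, 1] - 1L) * 648L + (d + 1L) * 216L +
                   (tm[h] - 1L) * 36L + (tb[keep] - 1L) * 6L +
                   (tc[keep] - 1L))
      }
    }
  }
  sort(unname(out))
}

#' Sparse feature matrix for a sample set
#'
#' Encodes every sample of a \code{DuplexSampleSet} and assembles the results
#' into an n x 24,450 sparse binary matrix (rows = samples, columns = feature
#' index + 1).
#'
#' @param samples A \code{DuplexSampleSet}.
#' @return A \code{Matrix::sparseMatrix} of 0/1 values.
#' @export
encodeFeatureMatrix <- function(samples) {
  n <- length(samples)
  idx <- lapply(seq_len(n), function(k)
    encodeFeatures(samples@mic[k], samples@cts[k]))
  Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lengths(idx)),
    j = unlist(idx) + 1L, x = 1,
    dims = c(n, 24450L),
    dimnames = list(samples@id, NULL))
}
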