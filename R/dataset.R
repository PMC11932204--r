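## Sample construction: candidate-site extraction, negative generation from
## 3'UTR windows with a thermodynamic-plausibility filter, deduplication,
## stratified splitting, and a synthetic corpus generator that emulates the
## study design (seed-complementary implants, optional 3'-compensatory
## pairing, energetically bindable decoy windows) without any downloads.

#' Built-in stability-oriented ScoreDict for corpus generation
#'
#' Negative-sample filtering needs a duplex predictor before any preference
#' model exists. This fixed dictionary scores a matched run by the negated
#' Turner stacking energy of its internal steps minus a constant run-opening
#' cost, so the DP favors contiguous stable helices over scattered isolated
#' pairs — the behavior expected of a generic thermodynamic folding tool.
#'
#' @param openCost Cost subtracted per run (default 0.6).
#' @param turner A \code{TurnerParams} object.
#' @return A \code{\link{ScoreDict-class}} object.
#' @export
stabilityScoreDict <- function(openCost = 0.6, turner = turnerParams()) {
  w <- numeric(24450L)
  st <- turner@stackDg
  ## singles: opening a one-pair run is never rewarded
  w[seq_len(3750L)] <- -openCost
  ## doubles: one internal stack
  for (t1 in 0:5) for (t2 in 0:5) {
    val <- -st[t1 + 1L, t2 + 1L] - openCost
    base <- 3750L + t1 * 6L + t2
    ## all positions i and offsets d share the type-dependent value
    for (d in 0:4)
      w[base + (0:24) * 180L + d * 36L + 1L] <- val
  }
  ## triples: two internal stacks
  for (t1 in 0:5) for (t2 in 0:5) for (t3 in 0:5) {
    val <- -st[t1 + 1L, t2 + 1L] - st[t2 + 1L, t3 + 1L] - openCost
    base <- 8250L + t1 * 36L + t2 * 6L + t3
    for (d in 0:2)
      w[base + (0:24) * 648L + d * 216L + 1L] <- val
  }
  methods::new("ScoreDict", w = w)
}

#' Extract the positive sample of a corpus record
#'
#' Cuts the 25-nt candidate target site starting at the validated site
#' location and pairs it with the (right-padded) microRNA, labeled 1.
#'
#' @param micSeq MicroRNA sequence, 18-25 nt.
#' @param utrSeq 3'UTR sequence.
#' @param siteStart 0-based offset of the validated site in the UTR.
#' @param id Sample identifier.
#' @return A one-sample \code{DuplexSampleSet} with label 1.
#' @export
extractPositive <- function(micSeq, utrSeq, siteStart, id = "pos") {
  utrSeq <- normalizeSeq(utrSeq)
  if (siteStart < 0L || siteStart + SAMPLE_LEN > nchar(utrSeq))
    stop("site window [", siteStart, ", ", siteStart + SAMPLE_LEN,
         ") lies outside the UTR (length ", nchar(utrSeq), ")")
  cts <- substr(utrSeq, siteStart + 1L, siteStart + SAMPLE_LEN)
  duplexSampleSet(micSeq, cts, 1L, id = id)
}

#' Generate up to max_n negative samples from a 3'UTR
#'
#' Randomly draws non-overlapping 25-nt windows from the UTR (excluding any
#' window overlapping the positive site), keeps only windows whose
#' DP-predicted duplex with the microRNA has free energy below zero —
#' thermodynamically plausible decoys that are not validated sites — and
#' stops after \code{maxN} acceptances. Deterministic given \code{seed}; may
#' return fewer than \code{maxN} samples (possibly zero).
#'
#' @param micSeq MicroRNA sequence (18-25 nt).
#' @param utrSeq 3'UTR sequence (>= 25 nt).
#' @param sd ScoreDict for the duplex predictor (default the built-in
#'   stability dictionary).
#' @param turner A \code{TurnerParams} object.
#' @param maxN Maximum number of negatives (default 10).
#' @param seed Integer seed.
#' @param siteStart Optional 0-based positive-site offset to exclude.
#' @param idPrefix Prefix for sample identifiers.
#' @return A \code{DuplexSampleSet} of label-0 samples (attribute
#'   \code{starts} holds their 0-based window offsets).
#' @export
generateNegatives <- function(micSeq, utrSeq, sd = stabilityScoreDict(),
                              turner = turnerParams(), maxN = 10L,
                              seed = 1L, siteStart = NA_integer_,
                              idPrefix = "neg") {
  utrSeq <- normalizeSeq(utrSeq)
  L <- nchar(utrSeq)
  if (L < SAMPLE_LEN) stop("UTR must be at least ", SAMPLE_LEN, " nt")
  micPad <- padTo25(normalizeSeq(micSeq))
  cand <- 0:(L - SAMPLE_LEN)
  if (!is.na(siteStart))
    cand <- cand[cand + SAMPLE_LEN <= siteStart |
                   cand >= siteStart + SAMPLE_LEN]
  set.seed(seed)
  cand <- sample(cand)
  chosen <- integer(0)
  seqs <- character(0)
  for (s in cand) {
    if (length(chosen) >= maxN) break
    if (any(abs(chosen - s) < SAMPLE_LEN)) next  # overlap with accepted
    cts <- substr(utrSeq, s + 1L, s + SAMPLE_LEN)
    st <- predictDuplex(micPad, cts, sd, turner)
    if (st@dg37 < 0) {
      chosen <- c(chosen, s)
      seqs <- c(seqs, cts)
    }
  }
  out <- duplexSampleSet(rep(micSeq, length(chosen)), seqs,
                         rep(0L, length(chosen)),
                         id = paste0(idPrefix, "_", chosen))
  attr(out, "starts") <- chosen
  out
}

#' Remove exact duplicate samples
#'
#' Collapses samples with identical (microRNA, site, label) triples to their
#' first occurrence. Identical sequences with different labels are kept.
#'
#' @param samples A \code{DuplexSampleSet}.
#' @return The deduplicated \code{DuplexSampleSet}.
#' @export
deduplicateSamples <- function(samples) {
  key <- paste(samples@mic, samples@cts, samples@label, sep = "\r")
  samples[!duplicated(key)]
}

#' Stratified train/validation/test split
#'
#' Splits each class separately by the given fractions with largest-remainder
#' rounding, so every split keeps the global class ratio to within one
#' sample. Deterministic given \code{seed}; the three parts are disjoint and
#' exhaustive.
#'
#' @param samples A \code{DuplexSampleSet} with both classes.
#' @param fractions Numeric(3) summing to 1 (default \code{c(0.7, 0.1, 0.2)}).
#' @param seed Integer seed for the within-class shuffles.
#' @return Named list of \code{DuplexSampleSet}s: \code{train},
#'   \code{validation}, \code{test}.
#' @export
stratifiedSplit <- function(samples, fractions = c(0.7, 0.1, 0.2),
                            seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three numbers summing to 1")
  if (length(unique(samples@label)) < 2L)
    stop("both classes must be present")
  set.seed(seed)
  assign3 <- function(idx) {
    n <- length(idx)
    idx <- idx[sample.int(n)]
    exact <- fractions * n
    cnt <- floor(exact)
    rem <- n - sum(cnt)
    if (rem > 0) {
      extra <- order(exact - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1L
    }
    split(idx, rep.int(1:3, cnt))
  }
  parts <- lapply(split(seq_along(samples@label), samples@label), assign3)
  pick <- function(k) {
    sel <- sort(unlist(lapply(parts, `[[`, as.character(k)),
                       use.names = FALSE))
    samples[sel]
  }
  list(train = pick(1), validation = pick(2), test = pick(3))
}

.COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

.randSeq <- function(n) paste(sample(NUCS, n, replace = TRUE), collapse = "")

#' Generate a synthetic microRNA target-site corpus
#'
#' Emulates the study's corpus design so every downstream stage is testable
#' without downloads. Each positive record carries a random microRNA (20-25
#' nt) and a random 3'UTR with one implanted site: the implant is the
#' position-wise complement of the microRNA across its seed region
#' (positions 1-7), plus — with probability 0.5 — its 3'-compensatory region
#' (the last four unpadded positions), with 0-2 random mismatches among the
#' remaining complementary positions. Negatives are energetically bindable
#' windows of the same UTRs drawn via \code{\link{generateNegatives}}.
#' Implant coordinates are recorded as ground truth.
#'
#' Site windows are stored in the 3'-to-5' orientation of the mRNA so that
#' microRNA position i faces site position i, the convention of all duplex
#' samples in this package.
#'
#' @param nPos Number of positive records.
#' @param nNegPerPos Maximum negatives drawn per positive (default 5).
#' @param utrLen Length of each synthetic 3'UTR (default 300).
#' @param seed Integer seed; the full corpus is reproducible from it.
#' @param mismatches Maximum number of random mismatches per implant (0-2).
#' @param sd ScoreDict for the negative filter (default
#'   \code{\link{stabilityScoreDict}}).
#' @param turner A \code{TurnerParams} object.
#' @return List with \code{samples} (a \code{DuplexSampleSet}),
#'   \code{records} (data.frame: micId, micSeq, utrId, utrSeq, siteStart) and
#'   \code{truth} (data.frame of implant coordinates, 0-based half-open).
#' @export
synthCorpus <- function(nPos = 100L, nNegPerPos = 5L, utrLen = 300L,
                        seed = 1L, mismatches = 2L,
                        sd = stabilityScoreDict(), turner = turnerParams()) {
  set.seed(seed)
  micLens <- sample(20:25, nPos, replace = TRUE)
  mics <- vapply(micLens, .randSeq, "")
  utrs <- vapply(rep.int(utrLen, nPos), .randSeq, "")
  siteStarts <- sample(0:(utrLen - SAMPLE_LEN), nPos, replace = TRUE)
  comp3 <- stats::runif(nPos) < 0.5
  nMis <- sample(0:mismatches, nPos, replace = TRUE)
  negSeeds <- sample.int(2^30, nPos)
  allSamples <- NULL
  for (k in seq_len(nPos)) {
    mic <- mics[k]; L <- micLens[k]
    ch <- seqChars(mic)
    site <- sample(NUCS, SAMPLE_LEN, replace = TRUE)  # non-aligned tail
    compPos <- 1:(L - 1L)                  # position 0 never pairs
    site[compPos + 1L] <- unname(.COMPLEMENT[ch[compPos + 1L]])
    free <- setdiff(compPos, 1:7)          # seed stays perfect
    comp3Region <- (L - 4L):(L - 1L)
    if (!comp3[k])                         # no 3'-compensatory pairing:
      for (p in comp3Region)               #   randomize the microRNA 3' end
        site[p + 1L] <- sample(NUCS, 1L)
    mism <- setdiff(free, comp3Region)     # mismatches land in the middle
    if (nMis[k] > 0L && length(mism))
      for (p in sample(mism, min(nMis[k], length(mism))))
        site[p + 1L] <- sample(NUCS, 1L)
    siteStr <- paste(site, collapse = "")
    utr <- paste0(substr(utrs[k], 1L, siteStarts[k]), siteStr,
                  substr(utrs[k], siteStarts[k] + SAMPLE_LEN + 1L, utrLen))
    utrs[k] <- utr
    pos <- extractPositive(mic, utr, siteStarts[k],
                           id = sprintf("pos_%03d", k))
    neg <- generateNegatives(mic, utr, sd, turner, maxN = nNegPerPos,
                             seed = negSeeds[k], siteStart = siteStarts[k],
                             idPrefix = sprintf("neg_%03d", k))
    allSamples <- if (is.null(allSamples)) c(pos, neg) else
      c(allSamples, pos, neg)
  }
  allSamples <- deduplicateSamples(allSamples)
  list(samples = allSamples,
       records = data.frame(micId = sprintf("mir_%03d", seq_len(nPos)),
                            micSeq = mics,
                            utrId = sprintf("utr_%03d", seq_len(nPos)),
                            utrSeq = utrs, siteStart = siteStarts,
                            stringsAsFactors = FALSE),
       truth = data.frame(utrId = sprintf("utr_%03d", seq_len(nPos)),
                          start = siteStarts,
                          end = siteStarts + SAMPLE_LEN))
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readBStringSet} that uppercases and
#' converts T to U.
#'
#' @param path FASTA file path.
#' @return Named character vector of RNA sequences.
#' @export
readFastaSeqs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(normalizeSeq(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFastaSeqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
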