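# A tiny corpus where one feature index separates the classes perfectly:
# positives pair G:C at position (1,1), negatives cannot pair there.
separableCorpus <- function(n = 40) {
  stopifnot(n %% 2 == 0)
  mics <- cts <- character(n)
  labs <- integer(n)
  set.seed(7)
  for (k in seq_len(n)) {
    pos <- k <= n / 2
    base <- sample(c("A", "C"), 23, TRUE)       # A:C never pairs
    mic <- c("A", "G", base)
    site <- sample(c("A", "C"), 25, TRUE)
    site[2] <- if (pos) "C" else "A"            # G:C pairs, G:A does not
    mics[k] <- paste(mic, collapse = "")
    cts[k] <- paste(site, collapse = "")
    labs[k] <- as.integer(pos)
  }
  duplexSampleSet(mics, cts, labs)
}

test_that("a perfectly separating feature attains the top weight", {
  corpus <- separableCorpus()
  pw <- trainPreference(corpus, epochs = 60, batch = 8, seed = 1)
  sepIdx <- featureIndex("single", 1, 1, "GC")
  expect_identical(which.max(pw@w) - 1L, sepIdx)
  expect_gt(pw@w[sepIdx + 1], 0)
  ## loss decreases on this separable toy corpus
  expect_lt(tail(pw@meta$loss, 1), pw@meta$loss[1])
})

test_that("training contracts: finite weights, determinism, input checks", {
  corpus <- separableCorpus(20)
  expect_error(trainPreference(corpus, epochs = 0), "epochs")
  pw1 <- trainPreference(corpus, epochs = 1, batch = 4, seed = 3)
  expect_false(any(!is.finite(pw1@w)))
  pw2 <- trainPreference(corpus, epochs = 1, batch = 4, seed = 3)
  expect_identical(pw1@w, pw2@w)
  expect_identical(pw1@b, pw2@b)
  onlyPos <- corpus[sampleLabel(corpus) == 1]
  expect_error(trainPreference(onlyPos), "both classes")
})

test_that("grid search maximizes validation AUPRC with deterministic
           tie-breaking", {
  corpus <- separableCorpus(60)
  sp <- stratifiedSplit(corpus, c(0.6, 0.4, 0), seed = 2)
  gs <- gridSearchPreference(sp$train, sp$validation,
                             epochGrid = c(2L, 8L), batchGrid = c(4L, 16L),
                             seed = 1)
  ## the winner's AUPRC matches an independent recomputation and dominates
  for (k in seq_len(nrow(gs$grid))) {
    pw <- trainPreference(sp$train, epochs = gs$grid$epochs[k],
                          batch = gs$grid$batch[k], seed = 1)
    a <- auprc(prCurve(sampleLabel(sp$validation),
                       predictPreference(pw, sp$validation)))
    expect_equal(a, gs$grid$auprc[k])
    expect_lte(a, gs$auprc + 1e-12)
  }
  ## degenerate 1x1 grid returns that configuration
  g1 <- gridSearchPreference(sp$train, sp$validation, epochGrid = 3L,
                             batchGrid = 8L, seed = 1)
  expect_identical(c(g1$epochs, g1$batch), c(3L, 8L))
  expect_error(gridSearchPreference(sp$train, sp$validation[0],
                                    epochGrid = 2L, batchGrid = 4L),
               "non-empty")
})

test_that("score lookup returns stored rules, window fallbacks and zeros", {
  w <- numeric(24450)
  w[featureIndex("single", 1, 1, "AU") + 1] <- 0.2
  sd <- scoreDict(w)
  expect_equal(scoreLookup(sd, 1, 1, "AU"), 0.2)
  ## out-of-window double ending at (10, 20): sum of its single weights
  w2 <- rnorm(24450)
  sd2 <- scoreDict(w2)
  expect_equal(scoreLookup(sd2, 10, 20, c("CG", "GC")),
               w2[featureIndex("single", 9, 19, "CG") + 1] +
                 w2[featureIndex("single", 10, 20, "GC") + 1])
  ## in-window double hits its own feature weight
  expect_equal(scoreLookup(sd2, 10, 11, c("CG", "GC")),
               w2[featureIndex("double", 9, 10, c("CG", "GC")) + 1])
  ## out-of-window triple
  expect_equal(scoreLookup(sd2, 10, 20, c("AU", "CG", "GC")),
               w2[featureIndex("single", 8, 18, "AU") + 1] +
                 w2[featureIndex("single", 9, 19, "CG") + 1] +
                 w2[featureIndex("single", 10, 20, "GC") + 1])
  ## all-zero dictionary: every query scores 0
  z <- scoreDict(numeric(24450))
  expect_identical(scoreLookup(z, 5, 5, c("AU", "AU")), 0)
  expect_error(scoreLookup(sd, 5, 5, rep("AU", 4)), "1 to 3")
})

test_that("seed-region enrichment shows up in the learned weights", {
  ## corpus with seed-aligned G/C-rich implants: positives complement the
  ## microRNA at positions 1-7, negatives are shuffled sites
  set.seed(11)
  n <- 120
  mics <- cts <- character(n); labs <- integer(n)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (k in seq_len(n)) {
    mic <- sample(c("G", "C"), 22, TRUE)
    mic[sample(9:22, 6)] <- sample(c("A", "U"), 6, TRUE)
    site <- sample(c("A", "C", "G", "U"), 25, TRUE)
    if (k <= n / 2) site[2:8] <- unname(comp[mic[2:8]])
    mics[k] <- paste(mic, collapse = ""); cts[k] <- paste(site, collapse = "")
    labs[k] <- as.integer(k <= n / 2)
  }
  corpus <- duplexSampleSet(mics, cts, labs)
  pw <- trainPreference(corpus, epochs = 10, batch = 16, seed = 1)
  dec <- decodeFeatureIndex(seq_len(3750) - 1L)
  seedFeat <- dec$i <= 7
  expect_gt(mean(pw@w[which(seedFeat)]), mean(pw@w[which(!seedFeat)]))
  ## with G/C-dominated seeds, CG/GC types dominate the top of the list
  top <- topWeights(pw, 100)
  topSingles <- top[top$kind == "single", ]
  expect_gt(mean(topSingles$types %in% c("CG", "GC")), 0.5)
})

test_that("preference weights round-trip through the text format", {
  corpus <- separableCorpus(20)
  pw <- trainPreference(corpus, epochs = 2, batch = 8, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePreferenceWeights(pw, path)
  pw2 <- readPreferenceWeights(path)
  expect_identical(pw2@w, pw@w)
  expect_identical(pw2@b, pw@b)
  sd1 <- scoreDict(pw); sd2 <- scoreDict(pw2)
  expect_identical(sd1@w, sd2@w)
})
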