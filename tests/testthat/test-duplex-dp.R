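# Toy pair in which only cell (1,1) can form a pair (A:U); every other
# letter combination is non-canonical.
toyPair <- function() {
  list(mic = paste0("CA", strrep("C", 23)),
       cts = paste0("CU", strrep("C", 23)))
}

test_that("sequences without canonical pairs give zero tables and an empty
           structure", {
  sd <- randomScoreDict()
  tabs <- fillDPTables(strrep("A", 25), strrep("A", 25), sd)
  expect_true(all(tabs@S1 == 0))
  expect_true(all(tabs@MFE1 == 0))
  st <- backtrackDuplex(tabs, sd)
  expect_identical(nrow(st@pairs), 0L)
  expect_identical(st@totalWeight, 0)
  expect_identical(st@dg37, 0)
})

test_that("a single positive rule yields exactly that pair and weight", {
  tp <- toyPair()
  w <- numeric(24450)
  w[featureIndex("single", 1, 1, "AU") + 1] <- 0.2
  sd <- scoreDict(w)
  tabs <- fillDPTables(tp$mic, tp$cts, sd)
  expect_equal(tabs@S1[25, 25], 0.2)
  ## borders stay zero
  expect_true(all(tabs@S1[1, ] == 0) && all(tabs@S1[, 1] == 0))
  ## S1 is non-decreasing along rows and columns
  expect_true(all(apply(tabs@S1, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(tabs@S1, 2, function(r) all(diff(r) >= 0))))
  st <- backtrackDuplex(tabs, sd)
  expect_identical(st@pairs$r, 1L)
  expect_identical(st@pairs$c, 1L)
  expect_identical(st@pairs$type, "AU")
  expect_equal(st@totalWeight, 0.2)
})

test_that("a diag-k pointer contributes k consecutive pairs", {
  ## complementary run at positions 1..3 with a dominant triple rule
  mic <- paste0("CAGC", strrep("C", 21))
  cts <- paste0("CUCC", strrep("C", 21))   # pairs: (1,1)AU (2,2)GC (3,3)CC? no
  ## make positions 1..3 pair: mic A G C vs cts U C G
  mic <- paste0("CAGC", strrep("A", 21))
  cts <- paste0("CUCG", strrep("A", 21))
  w <- numeric(24450)
  w[featureIndex("triple", 1, 1, c("AU", "GC", "CG")) + 1] <- 1
  sd <- scoreDict(w)
  st <- backtrackDuplex(fillDPTables(mic, cts, sd), sd)
  expect_identical(st@pairs$r, 1:3)
  expect_identical(st@pairs$c, 1:3)
  expect_identical(st@pairs$type, c("AU", "GC", "CG"))
  expect_equal(st@totalWeight, 1)
})

test_that("DP optimum matches exhaustive enumeration on random instances", {
  set.seed(301)
  for (rep in 1:20) {
    len <- sample(4:8, 1)
    sq <- randomPairedSeqs(len)
    sd <- randomScoreDict()
    tabs <- fillDPTables(sq$mic, sq$cts, sd)
    st <- backtrackDuplex(tabs, sd)
    oracle <- oracleBestWeight(sq$mic, sq$cts, sd)
    expect_equal(tabs@S1[25, 25], oracle, tolerance = 1e-12)
    expect_equal(st@totalWeight, oracle, tolerance = 1e-12)
    ## no structure ever pairs position 0 of either strand
    if (nrow(st@pairs)) {
      expect_true(all(st@pairs$r >= 1))
      expect_true(all(st@pairs$c >= 1))
    }
  }
})

test_that("free energies compose initiation, stacks and end penalties", {
  sdz <- scoreDict(numeric(24450))
  mkStruct <- function(r, c, type) {
    methods::new("DuplexStructure",
                 pairs = data.frame(r = r, c = c, type = type,
                                    stringsAsFactors = FALSE),
                 totalWeight = 0, dg37 = 0)
  }
  expect_identical(duplexDg37(mkStruct(integer(0), integer(0), character(0)),
                              strrep("A", 25), strrep("A", 25)), 0)
  ## two stacked GC-type pairs: initiation + one stack, no end penalties
  mic <- paste0("AGGA", strrep("A", 21))
  cts <- paste0("ACCA", strrep("A", 21))
  st <- mkStruct(1:2, 1:2, c("GC", "GC"))
  expect_equal(duplexDg37(st, mic, cts), 4.09 + stackEnergy("GC", "GC"))
  ## helix of two AU-type pairs: both termini are penalized
  mic2 <- paste0("CAAC", strrep("C", 21))
  cts2 <- paste0("CUUC", strrep("C", 21))
  st2 <- mkStruct(1:2, 1:2, c("AU", "AU"))
  expect_equal(duplexDg37(st2, mic2, cts2),
               4.09 + stackEnergy("AU", "AU") + 2 * 0.45)
  ## bulge between two helices: loop term plus end penalties at the gap
  mic3 <- paste0("AGGGGA", strrep("A", 19))
  cts3 <- paste0("ACCACCA", strrep("A", 18))   # site gap of one at position 3
  st3 <- mkStruct(c(1:2, 3:4), c(1:2, 4:5), rep("GC", 4))
  expect_equal(duplexDg37(st3, mic3, cts3),
               4.09 + 2 * stackEnergy("GC", "GC") + loopEnergy("bulge", 1))
  ## inconsistent pair type is rejected
  stBad <- mkStruct(1L, 1L, "AU")
  expect_error(duplexDg37(stBad, mic, cts), "inconsistent")
})

test_that("MFE1 equals the energy of the backtracked substructure at random
           cells", {
  set.seed(302)
  sq <- randomPairedSeqs(25)
  pw <- scoreDict(rnorm(24450, mean = 0.05, sd = 0.3))
  tabs <- fillDPTables(sq$mic, sq$cts, pw)
  cells <- cbind(sample(0:24, 20, TRUE), sample(0:24, 20, TRUE))
  for (k in seq_len(nrow(cells))) {
    st <- backtrackDuplex(tabs, pw, from = cells[k, ])
    expect_equal(duplexDg37(st, sq$mic, sq$cts),
                 tabs@MFE1[cells[k, 1] + 1, cells[k, 2] + 1],
                 tolerance = 1e-10, info = paste(cells[k, ], collapse = ","))
  }
})

test_that("backtrack weight always reproduces the last scoring cell", {
  set.seed(303)
  for (rep in 1:10) {
    sq <- randomPairedSeqs(sample(10:25, 1))
    sd <- randomScoreDict()
    tabs <- fillDPTables(sq$mic, sq$cts, sd)
    st <- backtrackDuplex(tabs, sd)
    expect_equal(st@totalWeight, tabs@S1[25, 25], tolerance = 1e-12)
  }
})

test_that("full complementarity pairs every position except position 0", {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  set.seed(304)
  mic <- paste(sample(c("A", "C", "G", "U"), 8, TRUE), collapse = "")
  cts <- paste(unname(comp[strsplit(mic, "")[[1]]]), collapse = "")
  micP <- paste0(mic, strrep("-", 17))
  ctsP <- paste0(cts, strrep("-", 17))
  w <- numeric(24450); w[seq_len(3750)] <- 1   # uniform positive singles
  sd <- scoreDict(w)
  st <- backtrackDuplex(fillDPTables(micP, ctsP, sd), sd)
  expect_identical(st@pairs$r, 1:7)
  expect_identical(st@pairs$c, 1:7)
})

test_that("padded positions never enter a structure", {
  set.seed(306)
  for (rep in 1:10) {
    lenM <- sample(5:15, 1); lenC <- sample(5:15, 1)
    mic <- paste0(paste(sample(c("A", "C", "G", "U"), lenM, TRUE),
                        collapse = ""), strrep("-", 25 - lenM))
    cts <- paste0(paste(sample(c("A", "C", "G", "U"), lenC, TRUE),
                        collapse = ""), strrep("-", 25 - lenC))
    st <- predictDuplex(mic, cts, randomScoreDict())
    if (nrow(st@pairs)) {
      expect_true(all(st@pairs$r < lenM))
      expect_true(all(st@pairs$c < lenC))
    }
  }
})

test_that("renderings round-trip through the parser", {
  set.seed(305)
  for (rep in 1:3) {
    sq <- randomPairedSeqs(sample(6:12, 1))
    sd <- randomScoreDict()
    st <- predictDuplex(sq$mic, sq$cts, sd)
    txt <- renderDuplex(st, sq$mic, sq$cts)
    st2 <- parseDuplex(txt)
    expect_identical(st2@pairs$r, st@pairs$r)
    expect_identical(st2@pairs$c, st@pairs$c)
    expect_identical(st2@pairs$type, st@pairs$type)
    expect_equal(st2@totalWeight, st@totalWeight)
    expect_equal(st2@dg37, st@dg37)
  }
})
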