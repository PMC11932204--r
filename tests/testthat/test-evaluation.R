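test_that("confusion counts follow the >= threshold rule and always sum to
           n", {
  cc <- confusionCounts(c(1, 0), c(0.9, 0.1), 0.5)
  expect_identical(cc, c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  ## at threshold 0 everything is called positive
  cc0 <- confusionCounts(c(1, 0, 0, 1), c(0.2, 0.8, 0.1, 0.9), 0)
  expect_identical(unname(cc0["FP"]), 2L)
  expect_identical(unname(cc0["FN"]), 0L)
  set.seed(601)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    cc <- confusionCounts(rbinom(n, 1, 0.4), runif(n), runif(1))
    expect_identical(sum(cc), n)
  }
  ## boundary scores count as positive calls
  ccB <- confusionCounts(c(1, 0), c(0.5, 0.5), 0.5)
  expect_identical(unname(ccB[c("TP", "FP")]), c(1L, 1L))
})

test_that("metric formulas reproduce published precision/recall/F1 triples", {
  ## F1 recomputed from reported precision and recall pairs
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(round(f1(0.8725, 0.8703), 4), 0.8714)
  expect_equal(round(f1(0.7659, 0.7818), 4), 0.7738)
  cc <- c(TP = 10L, FP = 10L, TN = 10L, FN = 10L)
  m <- classificationMetrics(cc)
  expect_equal(unname(m["accuracy"]), 0.5)
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["NPV"]), 0.5)
  ## F1 is algebraically consistent with the returned precision/recall
  set.seed(602)
  for (rep in 1:10) {
    cc <- confusionCounts(rbinom(40, 1, 0.5), runif(40), runif(1))
    m <- classificationMetrics(cc)
    if (m["precision"] + m["recall"] > 0)
      expect_equal(unname(m["F1"]),
                   f1(unname(m["precision"]), unname(m["recall"])))
  }
  ## empty denominators follow the stated conventions
  mEmpty <- classificationMetrics(c(TP = 0L, FP = 0L, TN = 3L, FN = 2L))
  expect_identical(unname(mEmpty["precision"]), 1)
})

test_that("the PR grid has 100 points from 1 down to 0 including 21/99", {
  labels <- c(1, 1, 0, 0)
  probs <- c(0.9, 0.8, 0.3, 0.1)
  cv <- prCurve(labels, probs)
  expect_identical(nrow(cv), 100L)
  expect_identical(cv$threshold[1], 1)
  expect_identical(cv$threshold[100], 0)
  expect_true(any(abs(cv$threshold - 21 / 99) < 1e-12))
  ## recall is non-increasing as the threshold increases
  expect_true(all(diff(cv$recall) >= 0))      # rows ordered 1 -> 0
  expect_identical(cv$recall[100], 1)         # threshold 0 calls everything
  ## a perfect 0/1 scorer keeps precision 1 at every positive threshold
  ## (only true positives clear the >= cut there)
  perfect <- prCurve(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_true(all(perfect$precision[perfect$threshold > 0] == 1))
})

test_that("the curve matches a per-threshold recomputation exactly", {
  set.seed(603)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- runif(n)
    cv <- prCurve(labels, probs)
    oc <- oraclePRCurve(labels, probs)
    expect_equal(cv$precision, oc$precision, tolerance = 1e-12)
    expect_equal(cv$recall, oc$recall, tolerance = 1e-12)
  }
})

test_that("AUPRC follows the fixed-grid trapezoid and its baselines", {
  perfect <- prCurve(c(1, 1, 0, 0), c(0.99, 0.95, 0.03, 0.01))
  expect_equal(auprc(perfect), 1, tolerance = 0.01)
  ## a random (uninformative) scorer's AUPRC approaches the positive
  ## prevalence at n = 1000
  set.seed(604)
  labels <- rbinom(1000, 1, 0.3)
  rnd <- prCurve(labels, runif(1000))
  expect_equal(auprc(rnd), mean(labels), tolerance = 0.05)
  for (rep in 1:20) {
    n <- sample(30:300, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    probs <- runif(n)
    cv <- prCurve(labels, probs)
    oc <- oraclePRCurve(labels, probs)
    expect_lt(abs(auprc(cv) - oracleAUPRC(oc$precision, oc$recall)), 1e-9)
  }
})

test_that("threshold selection sits at the precision/recall crossing on the
           grid", {
  ## perfectly scored data: precision = recall = 1 on every calling
  ## threshold; the tie rule picks the smallest tied grid threshold
  cv <- prCurve(c(1, 1, 0, 0), c(0.99, 0.95, 0.03, 0.01))
  opt <- optimalThreshold(cv)
  gap <- abs(cv$precision - cv$recall)
  f1 <- 2 * cv$precision * cv$recall /
    pmax(cv$precision + cv$recall, 1e-12)
  tied <- which(gap <= min(gap) + 1e-12 & f1 >= max(f1) - 1e-12)
  expect_equal(opt$threshold, min(cv$threshold[tied]))
  ## the returned threshold is always a grid member k/99
  set.seed(605)
  labels <- rbinom(200, 1, 0.4)
  probs <- plogis(rnorm(200, mean = labels))
  opt2 <- optimalThreshold(prCurve(labels, probs))
  expect_true(any(abs(opt2$threshold - (0:99) / 99) < 1e-12))
  ## a toy set with a hand-built crossing: the selection lands within one
  ## grid step of the dense-grid crossing region
  labT <- c(1, 1, 1, 1, 0, 0, 0, 0)
  prT <- c(0.9, 0.8, 0.7, 0.35, 0.6, 0.3, 0.2, 0.1)
  optT <- optimalThreshold(prCurve(labT, prT))
  dense <- seq(1, 0, length.out = 991)
  gapD <- vapply(dense, function(t) {
    m <- classificationMetrics(confusionCounts(labT, prT, t))
    abs(unname(m["precision"]) - unname(m["recall"]))
  }, 0)
  crossRegion <- range(dense[gapD <= min(gapD) + 1e-12])
  expect_gte(optT$threshold, crossRegion[1] - 1 / 99 - 1e-9)
  expect_lte(optT$threshold, crossRegion[2] + 1 / 99 + 1e-9)
})

test_that("bootstrap comparison is deterministic, well-ordered and detects a
           planted difference", {
  set.seed(606)
  n <- 1000
  labels <- rbinom(n, 1, 0.3)
  good <- plogis(rnorm(n, mean = 2.2 * labels - 1))
  weak <- plogis(rnorm(n, mean = 0.8 * labels - 0.4))
  bs <- bootstrapCompare(labels, good, weak, iterations = 200, seed = 11)
  expect_lte(bs$pValue, 0.05)
  expect_gt(bs$meanDiff, 0)
  expect_lte(bs$ciA[1], bs$auprcA); expect_gte(bs$ciA[2], bs$auprcA)
  expect_lte(bs$ciB[1], bs$auprcB); expect_gte(bs$ciB[2], bs$auprcB)
  expect_gt(bs$ciA[2] - bs$ciA[1], 0)
  bs2 <- bootstrapCompare(labels, good, weak, iterations = 200, seed = 11)
  expect_identical(bs2, bs)
  ## both relative-difference conventions are reported consistently
  expect_equal(bs$pctDiffMean, 100 * bs$meanDiff / bs$auprcB)
  expect_equal(bs$pctDiffPoint, 100 * (bs$auprcA - bs$auprcB) / bs$auprcB)
  ## identical scorers: difference 0 everywhere, so p = 1 under the <= 0
  ## convention
  bsSame <- bootstrapCompare(labels, good, good, iterations = 50, seed = 2)
  expect_identical(bsSame$meanDiff, 0)
  expect_identical(bsSame$pValue, 1)
})
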