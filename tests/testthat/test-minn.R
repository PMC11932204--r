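# Small synthetic stack sets with a planted, strongly separable pattern:
# positives carry a bright diagonal band in the first channel.
plantedStacks <- function(n, seed) {
  set.seed(seed)
  arr <- array(stats::runif(25 * 25 * 4 * n, 0, 0.3), c(25, 25, 4, n),
               dimnames = list(NULL, NULL, c("mx1", "dps", "dpm", "bp"),
                               NULL))
  labs <- rep_len(c(1L, 0L), n)
  for (k in which(labs == 1L))
    for (d in 2:8) arr[d, d, 1, k] <- arr[d, d, 1, k] + 0.9
  methods::new("FeatureStackSet", data = arr,
               id = paste0("p", seq_len(n)), label = labs)
}

tinyCfg <- function(...) {
  minnConfig(convFilters = c(2L, 3L, 4L), denseUnits = c(8L, 4L),
             epochs = 2L, batch = 8L, seed = 1L, ...)
}

test_that("configuration defaults mirror the published architecture", {
  cfg <- minnConfig()
  expect_identical(cfg$convFilters, c(32L, 64L, 128L))
  expect_identical(cfg$kernel, 3L)
  expect_identical(cfg$denseUnits, c(128L, 64L))
  expect_identical(cfg$headDropout, 0.25)
  expect_identical(cfg$epochs, 20L)
  expect_identical(cfg$batch, 256L)
  expect_error(minnConfig(kernel = 26L), "exceeds")
})

test_that("the spatial plan pools 25 -> 12 -> 6 -> 3 per branch", {
  expect_identical(MINNTarget:::.GRIDS$H, c(25L, 12L, 6L))
  expect_identical(25L %/% 2L, 12L)
  expect_identical(12L %/% 2L, 6L)
  expect_identical(6L %/% 2L, 3L)
  ## flattened branch width = 3*3 spatial cells times last filter count
  cfg <- tinyCfg()
  p <- buildMinn(cfg)
  expect_identical(dim(p$d.W1)[1], 4L * 9L * cfg$convFilters[3])
})

test_that("builds are deterministic and outputs are probabilities", {
  cfg <- tinyCfg()
  p1 <- buildMinn(cfg); p2 <- buildMinn(cfg)
  expect_identical(p1, p2)
  st <- plantedStacks(6, seed = 2)
  X <- MINNTarget:::.stacksToInputs(st)
  out <- MINNTarget:::.minnForward(p1, X, 6L, cfg)$prob
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(length(out), 6L)
})

test_that("backpropagation matches finite differences", {
  cfg <- tinyCfg()
  p <- buildMinn(cfg)
  set.seed(42)
  B <- 3L
  X <- lapply(1:4, function(ch) matrix(rnorm(B * 625), ncol = 1))
  y <- c(1, 0, 1)
  lg <- MINNTarget:::.minnLossGrad(p, X, y, cfg, training = FALSE)
  eps <- 1e-5
  set.seed(43)
  for (nm in names(p)) {
    i <- sample(length(p[[nm]]), 1)
    p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (MINNTarget:::.minnLossGrad(p1, X, y, cfg, training = FALSE)$loss -
            MINNTarget:::.minnLossGrad(p2, X, y, cfg, training = FALSE)$loss) /
      (2 * eps)
    ana <- lg$grads[[nm]][i]
    expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-5)
  }
})

test_that("training runs exactly cfg$epochs epochs and fits a planted
           signal", {
  train <- plantedStacks(200, seed = 3)
  val <- plantedStacks(60, seed = 4)
  cfg <- minnConfig(convFilters = c(4L, 6L, 8L), denseUnits = c(16L, 8L),
                    epochs = 6L, batch = 16L, seed = 1L)
  m <- trainMinn(train, val, cfg)
  expect_identical(nrow(m@history), 6L)       # no early stopping
  prTrain <- predict(m, train)
  expect_gte(auprc(prCurve(stackLabel(train), prTrain)), 0.95)
  ## same seed, same data: identical final loss
  m2 <- trainMinn(train, val, cfg)
  expect_identical(m2@history$loss, m@history$loss)
  expect_identical(predict(m2, val), predict(m, val))
  ## single-class split is refused
  onlyPos <- train[stackLabel(train) == 1L]
  expect_error(trainMinn(onlyPos, val, cfg), "both classes")
})

test_that("batch prediction equals concatenated per-sample prediction", {
  st <- plantedStacks(7, seed = 5)
  cfg <- tinyCfg()
  m <- trainMinn(plantedStacks(24, seed = 6), plantedStacks(12, seed = 7),
                 cfg)
  whole <- predict(m, st)
  single <- vapply(seq_len(7), function(k) unname(predict(m, st[k])), 0)
  expect_equal(unname(whole), single, tolerance = 1e-12)
  ## duplicated samples give duplicated outputs
  dup <- st[c(1, 1, 2)]
  prDup <- unname(predict(m, dup))
  expect_identical(prDup[1], prDup[2])
})

test_that("persisted models reload and predict bit-identically", {
  cfg <- tinyCfg()
  m <- trainMinn(plantedStacks(24, seed = 8), plantedStacks(12, seed = 9),
                 cfg, scoreDict = randomScoreDict())
  dir <- withr::local_tempdir()
  saveMinn(m, dir)
  m2 <- loadMinn(dir)
  st <- plantedStacks(10, seed = 10)
  expect_identical(predict(m2, st), predict(m, st))
  expect_identical(m2@threshold, m@threshold)
  expect_identical(m2@scoreDict@w, m@scoreDict@w)
  expect_true(file.exists(file.path(dir, "config.json")))
})

test_that("grid search picks the best validation AUPRC over the grid", {
  train <- plantedStacks(60, seed = 11)
  val <- plantedStacks(30, seed = 12)
  gs <- gridSearchMinn(train, val, tinyCfg(), epochGrid = c(1L, 3L),
                       batchGrid = 16L)
  expect_true(all(gs$grid$auprc <= gs$auprc + 1e-12))
  expect_identical(nrow(gs$grid), 2L)
})

test_that("UTR scanning windows, coordinates and errors behave", {
  sdz <- scoreDict(numeric(24450))
  cfg <- tinyCfg()
  m <- trainMinn(plantedStacks(24, seed = 13), plantedStacks(12, seed = 14),
                 cfg, scoreDict = sdz)
  mic <- "ACGUACGUACGUACGUACGU"
  utr25 <- paste(rep("A", 25), collapse = "")
  res <- scanUtr(m, mic, utr25, step = 1)
  expect_identical(nrow(res), 1L)
  expect_identical(res$start, 0L)
  expect_identical(res$end, 25L)
  utr30 <- paste(rep("A", 30), collapse = "")
  expect_identical(nrow(scanUtr(m, mic, utr30, step = 1)), 6L)
  expect_error(scanUtr(m, mic, strrep("A", 20)), "25")
})
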