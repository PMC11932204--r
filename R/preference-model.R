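## The base-pairing preference model: a single sigmoid output neuron over the
## 24,450 binary base-pair features, trained with minibatch Adam on binary
## cross-entropy. Its learned weights, viewed positionally, are the scoring
## dictionary of the duplex DP.

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train the single-neuron base-pairing preference network
#'
#' Fits a logistic model (24,450 inputs, one sigmoid output) by minimizing
#' binary cross-entropy with minibatch Adam. Weights are zero-initialized, so
#' training is fully determined by the data order, which is reshuffled each
#' epoch under \code{seed}.
#'
#' @param samples A \code{DuplexSampleSet} containing both classes, or a
#'   precomputed sparse feature matrix (then \code{labels} must be given).
#' @param epochs Number of passes over the data (>= 1). Default 5, the grid
#'   optimum reported for this model.
#' @param batch Minibatch size (>= 1). Default 128.
#' @param seed Integer seed controlling shuffling.
#' @param lr Adam learning rate (default 1e-3).
#' @param labels Optional 0/1 vector when \code{samples} is a matrix.
#' @return A \code{\link{PreferenceWeights-class}} object.
#' @export
trainPreference <- function(samples, epochs = 5L, batch = 128L, seed = 1L,
                            lr = 1e-3, labels = NULL) {
  if (methods::is(samples, "DuplexSampleSet")) {
    X <- encodeFeatureMatrix(samples)
    y <- as.numeric(samples@label)
  } else {
    X <- samples
    y <- as.numeric(labels)
  }
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch < 1L) stop("batch size must be >= 1")
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes (labels 0 and 1)")
  n <- nrow(X); p <- ncol(X)
  w <- numeric(p); b <- 0
  mW <- vW <- numeric(p); mB <- vB <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  lossTrace <- numeric(epochs)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch)) {
      rows <- ord[start:min(start + batch - 1L, n)]
      Xb <- X[rows, , drop = FALSE]
      yb <- y[rows]
      pb <- .sigmoid(as.numeric(Xb %*% w) + b)
      g <- (pb - yb) / length(rows)
      gW <- as.numeric(Matrix::crossprod(Xb, g))
      gB <- sum(g)
      tstep <- tstep + 1
      mW <- beta1 * mW + (1 - beta1) * gW
      vW <- beta2 * vW + (1 - beta2) * gW^2
      mB <- beta1 * mB + (1 - beta1) * gB
      vB <- beta2 * vB + (1 - beta2) * gB^2
      corr1 <- 1 - beta1^tstep; corr2 <- 1 - beta2^tstep
      w <- w - lr * (mW / corr1) / (sqrt(vW / corr2) + eps)
      b <- b - lr * (mB / corr1) / (sqrt(vB / corr2) + eps)
    }
    pAll <- .sigmoid(as.numeric(X %*% w) + b)
    pAll <- pmin(pmax(pAll, 1e-12), 1 - 1e-12)
    lossTrace[ep] <- -mean(y * log(pAll) + (1 - y) * log(1 - pAll))
  }
  methods::new("PreferenceWeights", w = w, b = b,
               meta = list(epochs = as.integer(epochs),
                           batch = as.integer(batch),
                           seed = as.integer(seed), lr = lr,
                           loss = lossTrace))
}

#' @describeIn PreferenceWeights-class Display a short summary.
#' @param object A \code{PreferenceWeights} object.
#' @export
setMethod("show", "PreferenceWeights", function(object) {
  cat("PreferenceWeights: 24,450 feature weights, bias ",
      signif(object@b, 4), "\n  trained ", object@meta$epochs,
      " epochs, batch ", object@meta$batch, ", final loss ",
      signif(utils::tail(object@meta$loss, 1), 4), "\n", sep = "")
})

#' Predict target probabilities with the preference model
#'
#' @param pw A \code{PreferenceWeights} object.
#' @param samples A \code{DuplexSampleSet} or sparse feature matrix.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predictPreference <- function(pw, samples) {
  X <- if (methods::is(samples, "DuplexSampleSet"))
    encodeFeatureMatrix(samples) else samples
  .sigmoid(as.numeric(X %*% pw@w) + pw@b)
}

#' Grid search over preference-training epochs and batch size
#'
#' Trains the preference model at every grid point and keeps the configuration
#' maximizing validation AUPRC; ties are broken toward fewer epochs, then the
#' smaller batch. The default grids are epochs {5, 10, 20, 30, 40} and batch
#' {32, 64, 128, 256}.
#'
#' @param train,validation \code{DuplexSampleSet}s (validation non-empty, both
#'   classes present in train).
#' @param epochGrid,batchGrid Integer vectors of candidate values.
#' @param seed,lr Passed to \code{\link{trainPreference}}.
#' @return List with \code{epochs}, \code{batch}, \code{auprc}, \code{weights}
#'   (the winning \code{PreferenceWeights}), and the full \code{grid}
#'   data.frame of validation AUPRCs.
#' @export
gridSearchPreference <- function(train, validation,
                                 epochGrid = c(5L, 10L, 20L, 30L, 40L),
                                 batchGrid = c(32L, 64L, 128L, 256L),
                                 seed = 1L, lr = 1e-3) {
  if (!length(epochGrid) || !length(batchGrid))
    stop("epoch and batch grids must be non-empty")
  if (length(validation) == 0L) stop("validation set must be non-empty")
  Xtr <- encodeFeatureMatrix(train); ytr <- train@label
  Xva <- encodeFeatureMatrix(validation); yva <- validation@label
  grid <- expand.grid(epochs = sort(epochGrid), batch = sort(batchGrid))
  grid <- grid[order(grid$epochs, grid$batch), ]
  grid$auprc <- NA_real_
  best <- NULL; bestA <- -Inf
  for (k in seq_len(nrow(grid))) {
    pw <- trainPreference(Xtr, epochs = grid$epochs[k], batch = grid$batch[k],
                          seed = seed, lr = lr, labels = ytr)
    a <- auprc(prCurve(yva, predictPreference(pw, Xva)))
    grid$auprc[k] <- a
    if (a > bestA + 1e-15) { bestA <- a; best <- list(k = k, pw = pw) }
  }
  list(epochs = grid$epochs[best$k], batch = grid$batch[best$k],
       auprc = bestA, weights = best$pw, grid = grid)
}

#' Report the k largest learned weights with their decoded features
#'
#' @param pw A \code{PreferenceWeights} or \code{ScoreDict}.
#' @param k Number of entries.
#' @return data.frame of the top-k weights joined with
#'   \code{\link{decodeFeatureIndex}}.
#' @export
topWeights <- function(pw, k = 100L) {
  w <- pw@w
  ord <- order(w, decreasing = TRUE)[seq_len(min(k, length(w)))]
  cbind(decodeFeatureIndex(ord - 1L), weight = w[ord])
}

## ---- ScoreDict -------------------------------------------------------------

#' Build a ScoreDict from preference weights or a raw weight vector
#'
#' The dictionary excludes the bias: a constant offset per matched run would
#' distort the DP maximization.
#'
#' @param x A \code{PreferenceWeights} object or numeric vector of length
#'   24,450.
#' @return A \code{\link{ScoreDict-class}} object.
#' @export
scoreDict <- function(x) {
  w <- if (methods::is(x, "PreferenceWeights")) x@w else as.numeric(x)
  methods::new("ScoreDict", w = w)
}

#' @describeIn ScoreDict-class Display a short summary.
#' @param object A \code{ScoreDict} object.
#' @export
setMethod("show", "ScoreDict", function(object) {
  cat("ScoreDict over 24,450 base-pair features; ",
      sum(object@w != 0), " nonzero weights\n", sep = "")
})

#' Look up the weight of a run of base pairs ending at a position
#'
#' Returns the learned weight of a run of 1-3 consecutive base pairs whose
#' LAST pair sits at microRNA position \code{i} and site position \code{j}
#' (0-based). Runs of length 2 (3) whose offset \code{j - i} falls outside the
#' double (triple) feature window score as the sum of their single-pair
#' weights, which are defined at every position combination.
#'
#' @param sd A \code{ScoreDict}.
#' @param i,j 0-based end positions on the microRNA / site.
#' @param run Character vector of 1-3 pair types, first pair of the run first.
#' @return The run weight (a scalar; 0 for an all-zero dictionary).
#' @export
scoreLookup <- function(sd, i, j, run) {
  k <- length(run)
  if (k < 1L || k > 3L) stop("run must contain 1 to 3 pair types")
  t <- match(run, PAIR_TYPES) - 1L
  if (anyNA(t)) stop("unknown pair type in run")
  if (i - k + 1L < 0L || j - k + 1L < 0L || i > 24L || j > 24L)
    stop("run does not fit in [0, 24] at end position (", i, ", ", j, ")")
  d <- j - i
  w <- sd@w
  single <- function(ii, jj, tt) w[ii * 150L + jj * 6L + tt + 1L]
  if (k == 1L) return(single(i, j, t[1]))
  if (k == 2L) {
    if (abs(d) <= 2L)
      return(w[3750L + (i - 1L) * 180L + (d + 2L) * 36L +
                 t[1] * 6L + t[2] + 1L])
    return(single(i - 1L, j - 1L, t[1]) + single(i, j, t[2]))
  }
  if (abs(d) <= 1L)
    return(w[8250L + (i - 2L) * 648L + (d + 1L) * 216L +
               t[1] * 36L + t[2] * 6L + t[3] + 1L])
  single(i - 2L, j - 2L, t[1]) + single(i - 1L, j - 1L, t[2]) +
    single(i, j, t[3])
}

#' Persist preference weights as plain text
#'
#' Writes a two-column TSV (0-based feature index, weight; zero weights
#' omitted) plus a JSON sidecar with the bias and training metadata.
#'
#' @param pw A \code{PreferenceWeights}.
#' @param path Path of the weights TSV; the sidecar gets \code{.json} added.
#' @return Invisibly, \code{path}.
#' @export
writePreferenceWeights <- function(pw, path) {
  nz <- which(pw@w != 0)
  ## the bias rides along as pseudo-index -1 so the text file alone restores
  ## the model exactly
  tab <- data.frame(index = c(-1L, nz - 1L),
                    weight = sprintf("%.17g", c(pw@b, pw@w[nz])))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(pw@meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read preference weights written by \code{writePreferenceWeights}
#' @param path Path of the weights TSV.
#' @return A \code{PreferenceWeights} object.
#' @export
readPreferenceWeights <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  biasRow <- tab$index == -1L
  w <- numeric(24450L)
  w[tab$index[!biasRow] + 1L] <- as.numeric(tab$weight[!biasRow])
  b <- if (any(biasRow)) as.numeric(tab$weight[biasRow][1]) else 0
  metaPath <- paste0(path, ".json")
  meta <- if (file.exists(metaPath))
    jsonlite::read_json(metaPath, simplifyVector = TRUE) else list()
  methods::new("PreferenceWeights", w = w, b = b, meta = as.list(meta))
}
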