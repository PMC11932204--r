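## The multi-input convolutional classifier: four parallel branches with
## identical architecture (3x3 conv -> ReLU -> 2x2 max-pool -> dropout, three
## times, filters f1/f2/f3), flattened and concatenated into a dense head
## (128 -> 64 -> dropout -> single sigmoid unit). Spatial plan per branch
## with floor pooling: 25 -> 12 -> 6 -> 3.

.GRIDS <- list(H = c(25L, 12L, 6L), len = c(625L, 144L, 36L))
.FLAT <- 9L  # 3 x 3 spatial positions after the third pool

#' Configuration of the multi-input classifier
#'
#' Defaults follow the selected architecture and training setup: three
#' convolutional layers with 32/64/128 filters and a uniform 3x3 kernel,
#' dropout 0.25, dense layers of 128 and 64 units, 20 epochs with batch size
#' 256, and no early stopping.
#'
#' @param convFilters Integer(3): filters of the three conv layers.
#' @param kernel Kernel side; the architecture uses 3 (the only size
#'   implemented). Values exceeding the 25-cell input side are rejected.
#' @param convDropout Dropout rate after each pooling stage.
#' @param denseUnits Integer(2): sizes of the two dense layers.
#' @param headDropout Dropout rate before the output unit.
#' @param epochs Training epochs (no early stopping; the history always has
#'   exactly this many rows).
#' @param batch Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param scale Fit and apply the per-channel min-max scaler (TRUE) or feed
#'   raw channels (FALSE).
#' @return A validated list of class \code{minnConfig}.
#' @export
minnConfig <- function(convFilters = c(32L, 64L, 128L), kernel = 3L,
                       convDropout = 0.25, denseUnits = c(128L, 64L),
                       headDropout = 0.25, epochs = 20L, batch = 256L,
                       lr = 1e-3, seed = 1L, scale = TRUE) {
  if (kernel > SAMPLE_LEN)
    stop("kernel size ", kernel, " exceeds the 25-cell input side")
  if (kernel != 3L)
    stop("only the 3x3 kernel of the published architecture is implemented")
  if (length(convFilters) != 3L || any(convFilters < 1L))
    stop("convFilters must be three positive integers")
  if (length(denseUnits) != 2L || any(denseUnits < 1L))
    stop("denseUnits must be two positive integers")
  if (epochs < 1L || batch < 1L) stop("epochs and batch must be >= 1")
  structure(list(convFilters = as.integer(convFilters), kernel = 3L,
                 convDropout = convDropout,
                 denseUnits = as.integer(denseUnits),
                 headDropout = headDropout, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, seed = as.integer(seed),
                 scale = isTRUE(scale)),
            class = "minnConfig")
}

#' Initialize untrained classifier parameters
#'
#' He-normal initialization seeded by \code{cfg$seed}; two builds with the
#' same seed yield identical parameters.
#'
#' @param cfg A \code{\link{minnConfig}}.
#' @return Named list of parameter matrices; the attribute \code{nParams}
#'   reports the total parameter count.
#' @export
buildMinn <- function(cfg) {
  set.seed(cfg$seed)
  f <- cfg$convFilters; d <- cfg$denseUnits
  p <- list()
  for (br in 1:4) {
    cin <- c(1L, f[1], f[2])
    for (l in 1:3) {
      p[[sprintf("b%d.W%d", br, l)]] <- .heInit(9L * cin[l], f[l], 9L * cin[l])
      p[[sprintf("b%d.b%d", br, l)]] <- numeric(f[l])
    }
  }
  nIn <- 4L * .FLAT * f[3]
  p[["d.W1"]] <- .heInit(nIn, d[1], nIn);  p[["d.b1"]] <- numeric(d[1])
  p[["d.W2"]] <- .heInit(d[1], d[2], d[1]); p[["d.b2"]] <- numeric(d[2])
  p[["d.Wo"]] <- .heInit(d[2], 1L, d[2]);  p[["d.bo"]] <- 0
  attr(p, "nParams") <- sum(vapply(p, length, 0L))
  p
}

## inputs: list of 4 matrices (B*625) x 1, sample-major rows
.stacksToInputs <- function(stacks, rows = seq_len(length(stacks))) {
  lapply(1:4, function(ch)
    matrix(as.vector(stacks@data[, , ch, rows, drop = FALSE]), ncol = 1L))
}

## Full forward pass; returns output probabilities and (optionally) all the
## caches needed for backprop. Dropout masks are drawn here when training.
.minnForward <- function(params, X, B, cfg, training = FALSE,
                         keepCache = FALSE) {
  f <- cfg$convFilters
  cache <- list(branch = vector("list", 4L))
  flat <- vector("list", 4L)
  for (br in 1:4) {
    A <- X[[br]]
    brc <- list()
    for (l in 1:3) {
      H <- .GRIDS$H[l]
      cidx <- .cachedIdx("conv", H, H, B)
      fwc <- .convForward(A, params[[sprintf("b%d.W%d", br, l)]],
                          params[[sprintf("b%d.b%d", br, l)]], cidx)
      pidx <- .cachedIdx("pool", H, H, B)
      fwp <- .poolForward(fwc$out, pidx)
      A <- fwp$out
      mask <- NULL
      if (training && cfg$convDropout > 0) {
        mask <- .dropoutMask(nrow(A), ncol(A), cfg$convDropout)
        A <- A * mask
      }
      brc[[l]] <- list(conv = fwc, pool = fwp, drop = mask,
                       nConvRows = B * .GRIDS$len[l])
    }
    cache$branch[[br]] <- brc
    Fb <- do.call(cbind, lapply(seq_len(.FLAT), function(pp)
      A[(seq_len(B) - 1L) * .FLAT + pp, , drop = FALSE]))
    flat[[br]] <- Fb
  }
  Fc <- do.call(cbind, flat)
  Z1 <- Fc %*% params$d.W1 + rep(params$d.b1, each = B)
  A1 <- pmax(Z1, 0)
  Z2 <- A1 %*% params$d.W2 + rep(params$d.b2, each = B)
  A2 <- pmax(Z2, 0)
  hMask <- NULL
  A2d <- A2
  if (training && cfg$headDropout > 0) {
    hMask <- .dropoutMask(nrow(A2), ncol(A2), cfg$headDropout)
    A2d <- A2 * hMask
  }
  zo <- as.numeric(A2d %*% params$d.Wo) + params$d.bo
  prob <- .sigmoid(zo)
  if (!keepCache) return(list(prob = prob))
  cache$Fc <- Fc; cache$Z1 <- Z1; cache$A1 <- A1; cache$Z2 <- Z2
  cache$A2d <- A2d; cache$hMask <- hMask; cache$flatDims <-
    vapply(flat, ncol, 0L)
  list(prob = prob, cache = cache)
}

## loss and full gradient for one minibatch
.minnLossGrad <- function(params, X, y, cfg, training = TRUE) {
  B <- length(y)
  fw <- .minnForward(params, X, B, cfg, training = training,
                     keepCache = TRUE)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  g <- list()
  cache <- fw$cache
  dzo <- matrix((fw$prob - y) / B, ncol = 1L)
  g$d.Wo <- crossprod(cache$A2d, dzo)
  g$d.bo <- sum(dzo)
  dA2 <- dzo %*% t(params$d.Wo)
  if (!is.null(cache$hMask)) dA2 <- dA2 * cache$hMask
  dZ2 <- dA2 * (cache$Z2 > 0)
  g$d.W2 <- crossprod(cache$A1, dZ2)
  g$d.b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(params$d.W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  g$d.W1 <- crossprod(cache$Fc, dZ1)
  g$d.b1 <- colSums(dZ1)
  dFc <- dZ1 %*% t(params$d.W1)
  off <- 0L
  for (br in 1:4) {
    nc <- cache$flatDims[br]
    dFb <- dFc[, (off + 1L):(off + nc), drop = FALSE]
    off <- off + nc
    nch <- nc %/% .FLAT
    dA <- matrix(0, B * .FLAT, nch)
    for (pp in seq_len(.FLAT))
      dA[(seq_len(B) - 1L) * .FLAT + pp, ] <-
        dFb[, ((pp - 1L) * nch + 1L):(pp * nch), drop = FALSE]
    for (l in 3:1) {
      brc <- cache$branch[[br]][[l]]
      H <- .GRIDS$H[l]
      if (!is.null(brc$drop)) dA <- dA * brc$drop
      pidx <- .cachedIdx("pool", H, H, B)
      dA <- .poolBackward(dA, brc$pool, pidx, brc$nConvRows,
                          ncol(dA))
      cidx <- .cachedIdx("conv", H, H, B)
      bk <- .convBackward(dA, brc$conv, params[[sprintf("b%d.W%d", br, l)]],
                          cidx, B * .GRIDS$len[l])
      g[[sprintf("b%d.W%d", br, l)]] <- bk$dW
      g[[sprintf("b%d.b%d", br, l)]] <- bk$db
      dA <- bk$dA
    }
  }
  list(loss = loss, grads = g, prob = fw$prob)
}

#' Train the multi-input classifier
#'
#' Trains for exactly \code{cfg$epochs} epochs (no early stopping) with
#' minibatch Adam on binary cross-entropy, recording training loss and
#' validation AUPRC per epoch. The classification threshold is selected
#' afterwards on the validation predictions by the precision/recall
#' intersection rule.
#'
#' @param train,validation \code{FeatureStackSet}s with both classes present.
#' @param cfg A \code{\link{minnConfig}}.
#' @param scoreDict Optional \code{ScoreDict} stored with the model so new
#'   sequences can be featurized at prediction time.
#' @return A \code{\link{MinnModel-class}} object.
#' @export
trainMinn <- function(train, validation, cfg = minnConfig(),
                      scoreDict = NULL) {
  for (s in list(train, validation))
    if (length(s) == 0L || length(unique(s@label)) < 2L)
      stop("train and validation sets must be non-empty with both classes")
  scaler <- fitChannelScaler(train, enabled = cfg$scale)
  trainS <- applyScaler(train, scaler)
  valS <- applyScaler(validation, scaler)
  params <- buildMinn(cfg)   # seeds the RNG stream
  mom1 <- lapply(params, function(m) m * 0)
  mom2 <- lapply(params, function(m) m * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0
  n <- length(trainS)
  y <- as.numeric(trainS@label)
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                     valAUPRC = NA_real_)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = cfg$batch)) {
      rows <- ord[start:min(start + cfg$batch - 1L, n)]
      X <- .stacksToInputs(trainS, rows)
      lg <- .minnLossGrad(params, X, y[rows], cfg, training = TRUE)
      losses <- c(losses, lg$loss)
      tstep <- tstep + 1
      c1 <- 1 - beta1^tstep; c2 <- 1 - beta2^tstep
      for (nm in names(params)) {
        gm <- lg$grads[[nm]]
        mom1[[nm]] <- beta1 * mom1[[nm]] + (1 - beta1) * gm
        mom2[[nm]] <- beta2 * mom2[[nm]] + (1 - beta2) * gm^2
        params[[nm]] <- params[[nm]] -
          cfg$lr * (mom1[[nm]] / c1) / (sqrt(mom2[[nm]] / c2) + eps)
      }
    }
    valProb <- .predictScaled(params, valS, cfg)
    hist$loss[ep] <- mean(losses)
    hist$valAUPRC[ep] <- auprc(prCurve(valS@label, valProb))
  }
  valProb <- .predictScaled(params, valS, cfg)
  thr <- optimalThreshold(prCurve(valS@label, valProb))$threshold
  sdStore <- if (is.null(scoreDict))
    methods::new("ScoreDict", w = numeric(24450L)) else scoreDict
  methods::new("MinnModel", params = params, cfg = unclass(cfg),
               scaler = scaler, threshold = thr, history = hist,
               scoreDict = sdStore)
}

## predict on an ALREADY-scaled stack set, chunked to bound memory
.predictScaled <- function(params, stacks, cfg, chunk = 256L) {
  n <- length(stacks)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    X <- .stacksToInputs(stacks, rows)
    out[rows] <- .minnForward(params, X, length(rows), cfg)$prob
  }
  out
}

#' @describeIn MinnModel-class Predict binding probabilities for stacks.
#' @param object A trained \code{MinnModel}.
#' @param newdata A \code{FeatureStackSet} of raw (unscaled) stacks.
#' @param ... Ignored.
#' @return Named numeric vector of probabilities in [0, 1].
#' @export
setMethod("predict", "MinnModel", function(object, newdata, ...) {
  scaled <- applyScaler(newdata, object@scaler)
  out <- .predictScaled(object@params, scaled, object@cfg)
  names(out) <- newdata@id
  out
})

#' @describeIn MinnModel-class Display a short summary.
#' @param object A \code{MinnModel}.
#' @export
setMethod("show", "MinnModel", function(object) {
  cat("MinnModel: four-branch convolutional classifier\n",
      "  filters ", paste(object@cfg$convFilters, collapse = "/"),
      ", dense ", paste(object@cfg$denseUnits, collapse = "/"),
      ", epochs ", object@cfg$epochs, ", batch ", object@cfg$batch, "\n",
      "  threshold ", signif(object@threshold, 4), " | final val AUPRC ",
      signif(utils::tail(object@history$valAUPRC, 1), 4), "\n", sep = "")
})

#' Scan a 3'UTR for target sites of a microRNA
#'
#' Slides a 25-nt window across the 3'UTR with the given step, featurizes
#' every window against the microRNA using the model's stored ScoreDict, and
#' reports the binding probability and the call at the model's threshold.
#' Coordinates are 0-based half-open on the given UTR string.
#'
#' @param model A trained \code{MinnModel}.
#' @param mic MicroRNA sequence (18-25 nt).
#' @param utr 3'UTR sequence, at least 25 nt.
#' @param step Window step in nt (>= 1).
#' @param turner A \code{TurnerParams} object.
#' @return data.frame with columns \code{start, end, prob, call}.
#' @export
scanUtr <- function(model, mic, utr, step = 1L, turner = turnerParams()) {
  utr <- normalizeSeq(utr)
  L <- nchar(utr)
  if (L < SAMPLE_LEN)
    stop("UTR must be at least ", SAMPLE_LEN, " nt (got ", L, ")")
  if (step < 1L) stop("step must be >= 1")
  starts <- seq(0L, L - SAMPLE_LEN, by = as.integer(step))
  wins <- substring(utr, starts + 1L, starts + SAMPLE_LEN)
  samples <- duplexSampleSet(rep(mic, length(starts)), wins,
                             rep(0L, length(starts)),
                             id = paste0("win_", starts))
  stacks <- buildStackSet(samples, model@scoreDict, turner)
  prob <- unname(predict(model, stacks))
  data.frame(start = starts, end = starts + SAMPLE_LEN, prob = prob,
             call = prob >= model@threshold)
}

#' Grid search over classifier epochs and batch size
#'
#' Trains the classifier at every grid point and keeps the configuration
#' maximizing validation AUPRC (ties toward fewer epochs, then the smaller
#' batch). Default grids: epochs {5, 20, 30, 40}, batch {32, 64, 128, 256,
#' 512}.
#'
#' @param train,validation \code{FeatureStackSet}s.
#' @param cfg Base configuration whose epochs/batch are overridden.
#' @param epochGrid,batchGrid Candidate values.
#' @param scoreDict Stored with the winning model.
#' @return List with \code{epochs}, \code{batch}, \code{auprc}, \code{model}
#'   and the \code{grid} data.frame.
#' @export
gridSearchMinn <- function(train, validation, cfg = minnConfig(),
                           epochGrid = c(5L, 20L, 30L, 40L),
                           batchGrid = c(32L, 64L, 128L, 256L, 512L),
                           scoreDict = NULL) {
  if (!length(epochGrid) || !length(batchGrid))
    stop("epoch and batch grids must be non-empty")
  grid <- expand.grid(epochs = sort(epochGrid), batch = sort(batchGrid))
  grid <- grid[order(grid$epochs, grid$batch), ]
  grid$auprc <- NA_real_
  best <- NULL; bestA <- -Inf
  for (k in seq_len(nrow(grid))) {
    ck <- cfg; ck$epochs <- grid$epochs[k]; ck$batch <- grid$batch[k]
    m <- trainMinn(train, validation, ck, scoreDict = scoreDict)
    a <- utils::tail(m@history$valAUPRC, 1)
    grid$auprc[k] <- a
    if (a > bestA + 1e-15) { bestA <- a; best <- list(k = k, model = m) }
  }
  list(epochs = grid$epochs[best$k], batch = grid$batch[best$k],
       auprc = bestA, model = best$model, grid = grid)
}

#' Save / load a trained classifier
#'
#' The model directory holds the exact parameters (\code{params.rds}) plus a
#' human-readable \code{config.json} with the architecture, threshold,
#' scaler ranges and training history. Reloading reproduces predictions
#' bit-identically.
#'
#' @param model A \code{MinnModel}.
#' @param dir Directory to create/read.
#' @return \code{loadMinn} returns the \code{MinnModel}; \code{saveMinn}
#'   invisibly returns \code{dir}.
#' @export
saveMinn <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(params = model@params, scoreDictW = model@scoreDict@w,
               scalerLo = model@scaler@lo, scalerHi = model@scaler@hi,
               scalerEnabled = model@scaler@enabled,
               threshold = model@threshold, history = model@history,
               cfg = model@cfg),
          file.path(dir, "params.rds"))
  jsonlite::write_json(
    list(cfg = model@cfg, threshold = model@threshold,
         scaler = list(lo = model@scaler@lo, hi = model@scaler@hi,
                       enabled = model@scaler@enabled),
         history = model@history,
         nParams = sum(vapply(model@params, length, 0L))),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  invisible(dir)
}

#' @rdname saveMinn
#' @export
loadMinn <- function(dir) {
  x <- readRDS(file.path(dir, "params.rds"))
  methods::new("MinnModel", params = x$params, cfg = x$cfg,
               scaler = methods::new("ChannelScaler", lo = x$scalerLo,
                                     hi = x$scalerHi,
                                     enabled = x$scalerEnabled),
               threshold = x$threshold, history = x$history,
               scoreDict = scoreDict(x$scoreDictW))
}
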