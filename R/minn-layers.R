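## Internal neural-network machinery for the multi-input classifier:
## im2col 3x3 same-padding convolution, 2x2 floor max-pooling, inverted
## dropout and dense layers, with hand-derived backpropagation. Activations
## for a batch of B samples on an H x W grid with C channels are stored as a
## (B*H*W) x C matrix, rows ordered sample-major, positions column-major
## (pos = r + (c-1)*H).

## 3x3 neighborhood map on an H x W grid; 0 marks off-grid (zero padding).
.convNbrMap <- function(H, W) {
  pos <- seq_len(H * W)
  r <- (pos - 1L) %% H + 1L
  cc <- (pos - 1L) %/% H + 1L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  out <- matrix(0L, H * W, 9L)
  for (k in 1:9) {
    rr <- r + offs$dr[k]; ccc <- cc + offs$dc[k]
    ok <- rr >= 1L & rr <= H & ccc >= 1L & ccc <= W
    out[ok, k] <- rr[ok] + (ccc[ok] - 1L) * H
  }
  out
}

## 2x2 floor-pooling map: 4 columns of input positions per output position.
.poolMap <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  pos2 <- seq_len(H2 * W2)
  r2 <- (pos2 - 1L) %% H2 + 1L
  c2 <- (pos2 - 1L) %/% H2 + 1L
  cbind((2L * r2 - 1L) + (2L * c2 - 2L) * H,
        (2L * r2)      + (2L * c2 - 2L) * H,
        (2L * r2 - 1L) + (2L * c2 - 1L) * H,
        (2L * r2)      + (2L * c2 - 1L) * H)
}

## Expand a per-position index map to batch row indices. For conv maps the
## indices address rbind(0, A) (off-grid entries point at the zero row,
## index 1); pool maps have no off-grid entries and address A directly.
.batchIdx <- function(map, B, gridLen, pad) {
  nOut <- nrow(map); K <- ncol(map)
  base <- rep((seq_len(B) - 1L) * gridLen, each = nOut)
  out <- matrix(0L, B * nOut, K)
  for (k in seq_len(K)) {
    v <- rep.int(map[, k], B)
    out[, k] <- if (pad) ifelse(v == 0L, 1L, v + base + 1L) else v + base
  }
  out
}

## cache of batch index matrices keyed by layer geometry and batch size
.idxCache <- new.env(parent = emptyenv())

.cachedIdx <- function(kind, H, W, B) {
  key <- paste(kind, H, W, B, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  map <- if (kind == "conv") .convNbrMap(H, W) else .poolMap(H, W)
  val <- .batchIdx(map, B, H * W, pad = (kind == "conv"))
  .idxCache[[key]] <- val
  val
}

.convForward <- function(A, Wm, bias, idx) {
  Cin <- ncol(A)
  A0 <- rbind(0, A)
  C <- matrix(0, nrow(idx), 9L * Cin)
  for (k in 1:9)
    C[, ((k - 1L) * Cin + 1L):(k * Cin)] <- A0[idx[, k], , drop = FALSE]
  Z <- C %*% Wm
  Z <- Z + rep(bias, each = nrow(Z))
  list(out = pmax(Z, 0), C = C, mask = Z > 0)
}

.convBackward <- function(dOut, fw, Wm, idx, nInRows) {
  dZ <- dOut * fw$mask
  dW <- crossprod(fw$C, dZ)
  db <- colSums(dZ)
  dC <- dZ %*% t(Wm)
  Cin <- ncol(dC) %/% 9L
  dA0 <- matrix(0, nInRows + 1L, Cin)
  for (k in 1:9) {
    rows <- idx[, k]
    dA0[rows, ] <- dA0[rows, ] +
      dC[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE]
  }
  list(dA = dA0[-1L, , drop = FALSE], dW = dW, db = db)
}

.poolForward <- function(A, idx) {
  cur <- A[idx[, 1], , drop = FALSE]
  am <- matrix(1L, nrow(cur), ncol(cur))
  for (k in 2:4) {
    g <- A[idx[, k], , drop = FALSE]
    upd <- g > cur
    am[upd] <- k
    cur[upd] <- g[upd]
  }
  list(out = cur, argmax = am)
}

.poolBackward <- function(dOut, fw, idx, nInRows, nChan) {
  dA <- matrix(0, nInRows, nChan)
  for (k in 1:4) {
    contrib <- dOut * (fw$argmax == k)
    rows <- idx[, k]
    dA[rows, ] <- dA[rows, ] + contrib
  }
  dA
}

## inverted dropout; returns the mask so backprop reuses it
.dropoutMask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

## He-normal initializer
.heInit <- function(nr, nc, fanin) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fanin)), nr, nc)
}
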