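## The four 25x25 input matrices per sample: the predicted duplex structure
## valued by base-pair probabilities (mx1), the DP scoring table (dps), the
## DP substructure free energies (dpm) and the full base-pair probability
## matrix (bp). Rows index microRNA positions, columns site positions.

CHANNELS <- c("mx1", "dps", "dpm", "bp")

#' Build the four-channel feature stack of one sample
#'
#' @param mic,cts 25-symbol padded sequences.
#' @param sd A \code{ScoreDict}.
#' @param turner A \code{TurnerParams} object.
#' @return A 25 x 25 x 4 numeric array with channels
#'   \code{mx1, dps, dpm, bp}.
#' @export
buildStack <- function(mic, cts, sd, turner = turnerParams()) {
  tabs <- fillDPTables(mic, cts, sd, turner)
  st <- backtrackDuplex(tabs, sd)
  mch <- seqChars(mic); sch <- seqChars(cts)
  bp <- outer(mch, sch, bpProbability)
  mx1 <- matrix(0, SAMPLE_LEN, SAMPLE_LEN)
  if (nrow(st@pairs))
    mx1[cbind(st@pairs$r + 1L, st@pairs$c + 1L)] <-
      bp[cbind(st@pairs$r + 1L, st@pairs$c + 1L)]
  out <- array(0, c(SAMPLE_LEN, SAMPLE_LEN, 4L),
               dimnames = list(NULL, NULL, CHANNELS))
  out[, , "mx1"] <- mx1
  out[, , "dps"] <- tabs@S1
  out[, , "dpm"] <- tabs@MFE1
  out[, , "bp"] <- bp
  out
}

#' Build feature stacks for a whole sample set
#'
#' @param samples A \code{DuplexSampleSet}.
#' @param sd A \code{ScoreDict}.
#' @param turner A \code{TurnerParams} object.
#' @return A \code{\link{FeatureStackSet-class}} object.
#' @export
buildStackSet <- function(samples, sd, turner = turnerParams()) {
  n <- length(samples)
  arr <- array(0, c(SAMPLE_LEN, SAMPLE_LEN, 4L, n),
               dimnames = list(NULL, NULL, CHANNELS, NULL))
  for (k in seq_len(n))
    arr[, , , k] <- buildStack(samples@mic[k], samples@cts[k], sd, turner)
  methods::new("FeatureStackSet", data = arr, id = samples@id,
               label = samples@label)
}

#' @describeIn FeatureStackSet-class Number of samples.
#' @param x A \code{FeatureStackSet}.
#' @export
setMethod("length", "FeatureStackSet", function(x) dim(x@data)[4])

#' @describeIn FeatureStackSet-class Subset samples.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "FeatureStackSet", function(x, i, j, ..., drop = TRUE) {
  methods::new("FeatureStackSet", data = x@data[, , , i, drop = FALSE],
               id = x@id[i], label = x@label[i])
})

#' @describeIn FeatureStackSet-class Display a short summary.
#' @param object A \code{FeatureStackSet}.
#' @export
setMethod("show", "FeatureStackSet", function(object) {
  cat("FeatureStackSet: ", length(object), " samples x 4 channels (",
      paste(CHANNELS, collapse = ", "), ") x 25 x 25\n", sep = "")
})

#' Accessors for FeatureStackSet
#' @param x A \code{FeatureStackSet}.
#' @param channel One of \code{"mx1", "dps", "dpm", "bp"}.
#' @param sample Sample index.
#' @return \code{stackChannel} returns one 25x25 matrix; \code{stackLabel}
#'   the label vector.
#' @export
stackChannel <- function(x, channel, sample = 1L) {
  x@data[, , match.arg(channel, CHANNELS), sample]
}

#' @rdname stackChannel
#' @export
stackLabel <- function(x) x@label

## ---- channel scaling -------------------------------------------------------

#' Fit a per-channel min-max scaler on training stacks
#'
#' The four channels have incompatible natural ranges (probabilities in
#' [0, 1], free energies in kcal/mol, unbounded DP weights); the scaler maps
#' each channel affinely onto [0, 1] using the minima/maxima of the fit set.
#' A degenerate (constant) channel gets an identity map with a warning.
#'
#' @param stacks A \code{FeatureStackSet} (>= 1 sample).
#' @param enabled When FALSE the scaler is a recorded no-op.
#' @return A \code{\link{ChannelScaler-class}} object.
#' @export
fitChannelScaler <- function(stacks, enabled = TRUE) {
  if (length(stacks) < 1L) stop("need at least one training stack")
  lo <- hi <- numeric(4)
  for (ch in 1:4) {
    v <- stacks@data[, , ch, ]
    lo[ch] <- min(v); hi[ch] <- max(v)
    if (hi[ch] <= lo[ch]) {
      warning("channel '", CHANNELS[ch],
              "' is constant on the fit set; using identity map")
      lo[ch] <- 0; hi[ch] <- 1
    }
  }
  methods::new("ChannelScaler", lo = lo, hi = hi, enabled = enabled)
}

#' Apply (or bypass) a fitted channel scaler
#'
#' @param stacks A \code{FeatureStackSet} or a single 25x25x4 array.
#' @param scaler A \code{ChannelScaler}; when disabled, input is returned
#'   unchanged (bit-identical).
#' @return Object of the same shape as the input.
#' @export
applyScaler <- function(stacks, scaler) {
  if (!scaler@enabled) return(stacks)
  scale1 <- function(a) {
    for (ch in 1:4)
      a[, , ch] <- (a[, , ch] - scaler@lo[ch]) /
        (scaler@hi[ch] - scaler@lo[ch])
    a
  }
  if (methods::is(stacks, "FeatureStackSet")) {
    for (ch in 1:4)
      stacks@data[, , ch, ] <- (stacks@data[, , ch, ] - scaler@lo[ch]) /
        (scaler@hi[ch] - scaler@lo[ch])
    stacks
  } else scale1(stacks)
}

#' @describeIn ChannelScaler-class Display the fitted ranges.
#' @param object A \code{ChannelScaler}.
#' @export
setMethod("show", "ChannelScaler", function(object) {
  cat("ChannelScaler (", if (object@enabled) "enabled" else "disabled",
      ")\n", sep = "")
  for (ch in 1:4)
    cat(sprintf("  %-4s [%.4g, %.4g]\n", CHANNELS[ch], object@lo[ch],
                object@hi[ch]))
})

## ---- serialization ---------------------------------------------------------

#' Write / read feature stacks as a single TSV archive
#'
#' Long-format TSV with columns \code{id, label, channel, row, col, value}
#' (0-based row/col, zero cells omitted) — lossless for ids, labels and all
#' four matrices.
#'
#' @param stacks A \code{FeatureStackSet}.
#' @param path File path.
#' @return \code{readStacks} returns a \code{FeatureStackSet};
#'   \code{writeStacks} invisibly returns \code{path}.
#' @export
writeStacks <- function(stacks, path) {
  n <- length(stacks)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    nz <- which(stacks@data[, , , k] != 0, arr.ind = TRUE)
    rows[[k]] <- data.frame(
      id = stacks@id[k], label = stacks@label[k],
      channel = CHANNELS[nz[, 3]],
      row = nz[, 1] - 1L, col = nz[, 2] - 1L,
      value = sprintf("%.17g", stacks@data[, , , k][nz]))
  }
  tab <- do.call(rbind, c(rows, list(
    data.frame(id = character(0), label = integer(0), channel = character(0),
               row = integer(0), col = integer(0), value = character(0)))))
  con <- file(path, "w")
  writeLines(paste0("# samples\t", paste(stacks@id, collapse = "\t")), con)
  writeLines(paste0("# labels\t", paste(stacks@label, collapse = "\t")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeStacks
#' @export
readStacks <- function(path) {
  hdr <- readLines(path, n = 2L)
  ids <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-1]
  labs <- as.integer(strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-1])
  ids[is.na(ids)] <- ""
  tab <- utils::read.delim(path, comment.char = "#",
                           colClasses = c(id = "character"))
  n <- length(ids)
  arr <- array(0, c(SAMPLE_LEN, SAMPLE_LEN, 4L, n),
               dimnames = list(NULL, NULL, CHANNELS, NULL))
  if (nrow(tab)) {
    k <- match(tab$id, ids)
    ch <- match(tab$channel, CHANNELS)
    arr[cbind(tab$row + 1L, tab$col + 1L, ch, k)] <- as.numeric(tab$value)
  }
  methods::new("FeatureStackSet", data = arr, id = ids,
               label = if (n) labs else integer(0))
}
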