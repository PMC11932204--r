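## Constructor, accessors and TSV I/O for DuplexSampleSet.

#' Construct a DuplexSampleSet
#'
#' Sequences are normalized (uppercase, T to U) and the microRNA is
#' right-padded to 25 symbols; candidate sites must already be 25 nt (they are
#' windows of a 3'UTR) but are padded too if shorter.
#'
#' @param mic Character vector of microRNA sequences (18-25 nt, or padded).
#' @param cts Character vector of candidate-target-site sequences.
#' @param label Numeric/integer vector of 0/1 labels.
#' @param id Optional identifiers; defaults to \code{sample_1..n}.
#' @return A \code{\link{DuplexSampleSet-class}} object.
#' @examples
#' duplexSampleSet("ACGUACGUACGUACGUACGU", strrep("U", 25), 1)
#' @export
duplexSampleSet <- function(mic, cts, label, id = NULL) {
  mic <- vapply(normalizeSeq(as.character(mic)), padTo25, "",
                USE.NAMES = FALSE)
  cts <- vapply(normalizeSeq(as.character(cts)), padTo25, "",
                USE.NAMES = FALSE)
  if (is.null(id)) id <- paste0("sample_", seq_along(mic))
  methods::new("DuplexSampleSet", id = as.character(id), mic = mic,
               cts = cts, label = as.integer(label))
}

#' @describeIn DuplexSampleSet-class Number of samples.
#' @param x A \code{DuplexSampleSet}.
#' @export
setMethod("length", "DuplexSampleSet", function(x) length(x@id))

#' @describeIn DuplexSampleSet-class Subset samples.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "DuplexSampleSet", function(x, i, j, ..., drop = TRUE) {
  methods::new("DuplexSampleSet", id = x@id[i], mic = x@mic[i],
               cts = x@cts[i], label = x@label[i])
})

#' @describeIn DuplexSampleSet-class Display a short summary.
#' @param object A \code{DuplexSampleSet}.
#' @export
setMethod("show", "DuplexSampleSet", function(object) {
  n <- length(object)
  cat("DuplexSampleSet with ", n, " samples (",
      sum(object@label == 1L), " positive / ",
      sum(object@label == 0L), " negative)\n", sep = "")
  if (n) {
    k <- min(3L, n)
    for (i in seq_len(k))
      cat("  ", object@id[i], "  ", object@mic[i], " | ", object@cts[i],
          "  label=", object@label[i], "\n", sep = "")
    if (n > k) cat("  ...\n")
  }
})

#' Accessors for DuplexSampleSet columns
#'
#' @param x A \code{DuplexSampleSet}.
#' @return Character or integer vectors of per-sample fields.
#' @name sample-accessors
NULL

#' @rdname sample-accessors
#' @export
micSeq <- function(x) x@mic

#' @rdname sample-accessors
#' @export
ctsSeq <- function(x) x@cts

#' @rdname sample-accessors
#' @export
sampleLabel <- function(x) x@label

#' @rdname sample-accessors
#' @export
sampleId <- function(x) x@id

#' Combine sample sets
#' @param x,... \code{DuplexSampleSet} objects.
#' @export
setMethod("c", "DuplexSampleSet", function(x, ...) {
  rest <- list(...)
  methods::new("DuplexSampleSet",
    id    = c(x@id,    unlist(lapply(rest, function(s) s@id))),
    mic   = c(x@mic,   unlist(lapply(rest, function(s) s@mic))),
    cts   = c(x@cts,   unlist(lapply(rest, function(s) s@cts))),
    label = c(x@label, unlist(lapply(rest, function(s) s@label))))
})

#' Read / write labeled duplex samples as TSV
#'
#' The on-disk schema has columns \code{id}, \code{mic_seq}, \code{cts_seq},
#' \code{label}; lines starting with \code{#} are comments. The pad symbol is
#' written as \code{-}.
#'
#' @param path File path.
#' @return \code{readSampleTSV} returns a \code{DuplexSampleSet};
#'   \code{writeSampleTSV} invisibly returns \code{path}.
#' @export
readSampleTSV <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(id = "character"))
  need <- c("id", "mic_seq", "cts_seq", "label")
  if (!all(need %in% names(tab)))
    stop("sample TSV needs columns: ", paste(need, collapse = ", "))
  duplexSampleSet(tab$mic_seq, tab$cts_seq, tab$label, id = tab$id)
}

#' @rdname readSampleTSV
#' @param samples A \code{DuplexSampleSet}.
#' @export
writeSampleTSV <- function(samples, path) {
  tab <- data.frame(id = samples@id, mic_seq = samples@mic,
                    cts_seq = samples@cts, label = samples@label)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
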