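## Fixed numerical tables: rRNA-derived base-pair probabilities and the
## Turner 2004 thermodynamic parameter subset used for duplex free energies.

## Cache environment so the TSVs are parsed once per session.
.constCache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "MINNTarget")
  if (path == "") {
    ## during development (pkgload) inst/ may still be on the search path
    path <- system.file("inst", "extdata", file, package = "MINNTarget")
  }
  if (path == "") stop("packaged data file not found: ", file)
  path
}

#' Base-pair formation probabilities from rRNA structures
#'
#' Returns the symmetric 4x4 probability table of all 10 unordered nucleotide
#' pair types (canonical and non-canonical), estimated from base-pair
#' frequencies observed in human rRNA crystal structures. Values are
#' dimensionless probabilities in \code{[0, 1]}.
#'
#' @param path Optional path to a TSV with columns \code{base1}, \code{base2},
#'   \code{prob}; defaults to the table shipped with the package.
#' @return A named 4x4 numeric matrix with rows/columns \code{A, C, G, U}.
#' @examples
#' basePairProbTable()["A", "U"]  # 0.4965
#' @export
basePairProbTable <- function(path = NULL) {
  if (is.null(path) && !is.null(.constCache$bp)) return(.constCache$bp)
  p <- if (is.null(path)) .extdata("bp_prob.tsv") else path
  tab <- utils::read.delim(p, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("base1", "base2", "prob") %in% names(tab)))
  m <- matrix(NA_real_, 4, 4, dimnames = list(NUCS, NUCS))
  for (k in seq_len(nrow(tab))) {
    m[tab$base1[k], tab$base2[k]] <- tab$prob[k]
    m[tab$base2[k], tab$base1[k]] <- tab$prob[k]
  }
  if (anyNA(m)) stop("base-pair probability table is incomplete")
  if (any(m < 0 | m > 1)) stop("base-pair probabilities must lie in [0, 1]")
  if (is.null(path)) .constCache$bp <- m
  m
}

#' Probability that two nucleotides form a base pair
#'
#' Looks up the unordered pair \code{{x, y}} in the rRNA-derived probability
#' table. The pad character \code{"-"} never pairs: any query involving it
#' returns exactly 0. Vectorized over \code{x} and \code{y}.
#'
#' @param x,y Nucleotide symbols in \code{A, C, G, U} or the pad \code{"-"}.
#' @return Numeric vector of probabilities.
#' @examples
#' bpProbability("A", "U")   # 0.4965
#' bpProbability("-", "G")   # 0
#' @export
bpProbability <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(as.character(x), n)
  y <- rep_len(as.character(y), n)
  known <- c(NUCS, PAD)
  bad <- which(!(x %in% known) | !(y %in% known))
  if (length(bad))
    stop("unknown nucleotide symbol '",
         c(x[bad[1]], y[bad[1]])[!(c(x[bad[1]], y[bad[1]]) %in% known)][1],
         "'", call. = FALSE)
  out <- numeric(n)
  ok <- x %in% NUCS & y %in% NUCS
  if (any(ok)) {
    m <- basePairProbTable()
    out[ok] <- m[cbind(x[ok], y[ok])]
  }
  out
}

#' Turner 2004 thermodynamic parameters for duplex free energies
#'
#' Loads the parameter subset needed to evaluate the free energy of an
#' intermolecular RNA duplex at 37 degrees C: the intermolecular initiation
#' term (+4.09 kcal/mol), the weak-end (AU/GU terminal pair) penalty
#' (+0.45 kcal/mol per qualifying helix end), the 6x6 nearest-neighbor
#' stacking table over canonical pairs including GU wobble, and the
#' length-dependent bulge and internal-loop initiation tables (sizes 1..30,
#' extended logarithmically beyond 30).
#'
#' @param stackPath,loopPath Optional TSV paths overriding the packaged tables.
#' @return A \code{TurnerParams} object.
#' @export
turnerParams <- function(stackPath = NULL, loopPath = NULL) {
  cached <- is.null(stackPath) && is.null(loopPath)
  if (cached && !is.null(.constCache$turner)) return(.constCache$turner)
  sp <- if (is.null(stackPath)) .extdata("turner_stack.tsv") else stackPath
  lp <- if (is.null(loopPath)) .extdata("turner_loops.tsv") else loopPath
  st <- utils::read.delim(sp, comment.char = "#", stringsAsFactors = FALSE)
  lo <- utils::read.delim(lp, comment.char = "#", stringsAsFactors = FALSE)
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  stack[cbind(st$pair1, st$pair2)] <- st$dg37
  if (anyNA(stack)) stop("stacking table is incomplete")
  obj <- methods::new("TurnerParams",
    initDg   = 4.09,
    auEndDg  = 0.45,
    stackDg  = stack,
    bulgeDg  = stats::setNames(lo$bulge, lo$size),
    internalDg = stats::setNames(lo$internal, lo$size))
  if (cached) .constCache$turner <- obj
  obj
}

#' @describeIn TurnerParams-class Display a short summary.
#' @param object A \code{TurnerParams} object.
#' @export
setMethod("show", "TurnerParams", function(object) {
  cat("TurnerParams (37 C, kcal/mol)\n",
      "  intermolecular initiation: +", object@initDg, "\n",
      "  weak helix-end penalty:    +", object@auEndDg, "\n",
      "  stacking steps: ", sum(!is.na(object@stackDg)),
      " | loop sizes tabulated: 1..", length(object@bulgeDg), "\n", sep = "")
})

## reverse of a pair type: "AU" -> "UA"
.revPair <- function(p) {
  vapply(p, function(q) paste0(substr(q, 2, 2), substr(q, 1, 1)), "")
}

#' Nearest-neighbor stacking free energy of a helix step
#'
#' Free energy (kcal/mol, 37 C) of stacking two adjacent canonical base pairs,
#' written 5' to 3' on the microRNA strand: \code{pair1} closes the step on the
#' 5' side, \code{pair2} on the 3' side. The table is symmetric under
#' 180-degree rotation, so \code{stackEnergy(p1, p2)} equals
#' \code{stackEnergy(rev(p2), rev(p1))}.
#'
#' @param pair1,pair2 Pair-type strings among \code{AU, CG, GC, GU, UA, UG}
#'   (microRNA base first). Vectorized.
#' @param turner A \code{TurnerParams} object.
#' @return Numeric vector of stacking free energies.
#' @examples
#' stackEnergy("GC", "CG")  # the most stabilizing Watson-Crick step
#' @export
stackEnergy <- function(pair1, pair2, turner = turnerParams()) {
  pair1 <- as.character(pair1); pair2 <- as.character(pair2)
  bad <- c(pair1[!(pair1 %in% PAIR_TYPES)], pair2[!(pair2 %in% PAIR_TYPES)])
  if (length(bad))
    stop("non-canonical pair in stacking step: '", bad[1], "'", call. = FALSE)
  turner@stackDg[cbind(pair1, pair2)]
}

#' Loop initiation free energy
#'
#' Length-dependent initiation penalty (kcal/mol, 37 C) for a bulge (unpaired
#' stretch on one strand) or internal loop (unpaired on both strands; size is
#' the two strands summed). Tabulated for sizes 1..30 and extended beyond 30
#' with the Jacobson-Stockmayer logarithmic form
#' \code{dG(n) = dG(30) + 1.07856 * log(n / 30)}.
#'
#' @param kind \code{"bulge"} or \code{"internal"}.
#' @param size Number of unpaired nucleotides, an integer >= 1. Vectorized.
#' @param turner A \code{TurnerParams} object.
#' @return Numeric vector of loop free energies.
#' @export
loopEnergy <- function(kind = c("bulge", "internal"), size,
                       turner = turnerParams()) {
  kind <- match.arg(kind)
  size <- as.numeric(size)
  if (any(is.na(size)) || any(size < 1) || any(size != floor(size)))
    stop("loop size must be an integer >= 1", call. = FALSE)
  tab <- if (kind == "bulge") turner@bulgeDg else turner@internalDg
  nTab <- length(tab)
  out <- numeric(length(size))
  small <- size <= nTab
  out[small] <- tab[size[small]]
  if (any(!small))
    out[!small] <- tab[nTab] + 1.07856 * log(size[!small] / nTab)
  unname(out)
}

#' Write Turner parameters to a directory of TSV files
#'
#' Serializes the stacking and loop tables in the same plain-text format the
#' package ships, so they round-trip bit-exactly through
#' \code{\link{readTurnerParams}}.
#'
#' @param turner A \code{TurnerParams} object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths written.
#' @export
writeTurnerParams <- function(turner, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "turner_stack.tsv")
  lp <- file.path(dir, "turner_loops.tsv")
  idx <- expand.grid(pair2 = PAIR_TYPES, pair1 = PAIR_TYPES,
                     stringsAsFactors = FALSE)[, c("pair1", "pair2")]
  st <- data.frame(idx, dg37 = turner@stackDg[cbind(idx$pair1, idx$pair2)])
  utils::write.table(format(st, digits = 15), sp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lo <- data.frame(size = seq_along(turner@bulgeDg),
                   bulge = unname(turner@bulgeDg),
                   internal = unname(turner@internalDg))
  utils::write.table(format(lo, digits = 15), lp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(sp, lp))
}

#' Read Turner parameters written by \code{writeTurnerParams}
#' @param dir Directory holding \code{turner_stack.tsv} and
#'   \code{turner_loops.tsv}.
#' @return A \code{TurnerParams} object.
#' @export
readTurnerParams <- function(dir) {
  turnerParams(stackPath = file.path(dir, "turner_stack.tsv"),
               loopPath  = file.path(dir, "turner_loops.tsv"))
}
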