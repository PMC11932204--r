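## S4 class definitions. Positions throughout the package are 0-based, the
## convention of the feature layout and DP tables; the documentation of each
## accessor repeats this where it matters.

#' TurnerParams: duplex thermodynamic parameter subset
#'
#' Holds the Turner 2004 terms needed for intermolecular duplex free energy at
#' 37 degrees C: initiation, weak-end penalty, the 6x6 nearest-neighbor
#' stacking table over canonical pair types (AU, CG, GC, GU, UA, UG), and
#' bulge/internal-loop initiation by loop size.
#'
#' @slot initDg Intermolecular initiation free energy (kcal/mol).
#' @slot auEndDg Penalty per helix end closed by an AU/UA/GU/UG pair (kcal/mol).
#' @slot stackDg 6x6 numeric matrix of stacking free energies.
#' @slot bulgeDg,internalDg Named numeric vectors, loop sizes 1..30.
#' @name TurnerParams-class
#' @exportClass TurnerParams
setClass("TurnerParams", representation(
  initDg = "numeric", auEndDg = "numeric", stackDg = "matrix",
  bulgeDg = "numeric", internalDg = "numeric"))

setValidity("TurnerParams", function(object) {
  msg <- character()
  if (!identical(dim(object@stackDg), c(6L, 6L)))
    msg <- c(msg, "stackDg must be 6x6")
  if (length(object@bulgeDg) < 1 ||
      length(object@bulgeDg) != length(object@internalDg))
    msg <- c(msg, "bulge and internal loop tables must have equal length >= 1")
  if (length(msg)) msg else TRUE
})

#' DuplexSampleSet: labeled microRNA / candidate-target-site pairs
#'
#' A column-oriented container of fixed-length duplex samples: a microRNA
#' (18-25 nt, right-padded to 25 with \code{"-"}) paired with a 25-nt candidate
#' target site (CTS), a binary label (1 = experimentally validated target,
#' 0 = non-target), and a free-text identifier.
#'
#' @slot id Character vector of sample identifiers.
#' @slot mic Character vector of padded 25-symbol microRNA sequences.
#' @slot cts Character vector of 25-symbol candidate-site sequences.
#' @slot label Integer vector of 0/1 labels.
#' @name DuplexSampleSet-class
#' @exportClass DuplexSampleSet
setClass("DuplexSampleSet", representation(
  id = "character", mic = "character", cts = "character", label = "integer"))

setValidity("DuplexSampleSet", function(object) {
  n <- length(object@id)
  if (length(object@mic) != n || length(object@cts) != n ||
      length(object@label) != n)
    return("id, mic, cts and label must have equal length")
  if (n == 0L) return(TRUE)
  if (any(nchar(object@mic) != SAMPLE_LEN) ||
      any(nchar(object@cts) != SAMPLE_LEN))
    return("all sequences must be exactly 25 symbols")
  for (s in c(object@mic, object@cts)) {
    bad <- firstBadSymbol(s)
    if (bad > 0L)
      return(sprintf("invalid symbol '%s' at position %d (0-based) in '%s'",
                     substr(s, bad, bad), bad - 1L, s))
    if (!padIsSuffix(s))
      return(sprintf("pad symbols must form a 3' (right) suffix in '%s'", s))
  }
  micLen <- vapply(object@mic, unpaddedLength, 0L)
  if (any(micLen < 18L | micLen > 25L))
    return("unpadded microRNA length must be in [18, 25]")
  if (!all(object@label %in% c(0L, 1L)))
    return("labels must be 0 or 1")
  TRUE
})

#' PreferenceWeights: the trained single-neuron base-pairing preference model
#'
#' @slot w Numeric vector of 24,450 feature weights (one per bit of the
#'   single/double/triple canonical base-pair feature layout).
#' @slot b The bias of the output neuron.
#' @slot meta List of training metadata: epochs, batch, seed, learning rate,
#'   and the per-epoch loss trace.
#' @name PreferenceWeights-class
#' @exportClass PreferenceWeights
setClass("PreferenceWeights", representation(
  w = "numeric", b = "numeric", meta = "list"))

setValidity("PreferenceWeights", function(object) {
  if (length(object@w) != 24450L)
    return("w must have exactly 24,450 entries")
  if (length(object@b) != 1L) return("b must be a scalar")
  TRUE
})

#' ScoreDict: positional base-pairing weight lookup for the duplex DP
#'
#' A lookup view over preference weights (bias excluded): given the end
#' position of a run of 1-3 consecutive base pairs and the ordered pair types,
#' it returns the learned weight. Runs of length 2-3 whose target offset falls
#' outside the feature window score as the sum of their single-pair weights.
#'
#' @slot w Numeric vector of 24,450 feature weights.
#' @name ScoreDict-class
#' @exportClass ScoreDict
setClass("ScoreDict", representation(w = "numeric"))

setValidity("ScoreDict", function(object) {
  if (length(object@w) != 24450L) return("w must have exactly 24,450 entries")
  TRUE
})

#' DPTables: scoring, backtracking and free-energy tables of the duplex DP
#'
#' @slot S1 25x25 numeric matrix of cumulative best structure weights.
#' @slot BT1 25x25 integer matrix of backpointers (0 stop, 1 left, 2 up,
#'   3/4/5 diagonal runs of length 1/2/3).
#' @slot MFE1 25x25 numeric matrix: free energy (kcal/mol) of the structure
#'   obtained by backtracking from each cell.
#' @slot mic,cts The 25-symbol sequences the tables were computed for.
#' @name DPTables-class
#' @exportClass DPTables
setClass("DPTables", representation(
  S1 = "matrix", BT1 = "matrix", MFE1 = "matrix",
  mic = "character", cts = "character"))

setValidity("DPTables", function(object) {
  d <- c(SAMPLE_LEN, SAMPLE_LEN)
  if (!identical(dim(object@S1), d) || !identical(dim(object@BT1), d) ||
      !identical(dim(object@MFE1), d))
    return("all tables must be 25x25")
  TRUE
})

#' DuplexStructure: a predicted microRNA/target-site duplex
#'
#' An ordered, non-crossing set of base pairs with the total DP weight and the
#' Turner free energy of the structure. Positions are 0-based; position 0 of
#' either strand never pairs.
#'
#' @slot pairs data.frame with columns \code{r} (microRNA position), \code{c}
#'   (site position), \code{type} (canonical pair type), rows ordered by
#'   strictly increasing \code{r} and \code{c}.
#' @slot totalWeight Total structure weight under the ScoreDict that built it.
#' @slot dg37 Free energy of the structure (kcal/mol), 0 when empty.
#' @name DuplexStructure-class
#' @exportClass DuplexStructure
setClass("DuplexStructure", representation(
  pairs = "data.frame", totalWeight = "numeric", dg37 = "numeric"))

setValidity("DuplexStructure", function(object) {
  p <- object@pairs
  if (!all(c("r", "c", "type") %in% names(p)))
    return("pairs needs columns r, c, type")
  if (nrow(p) > 1L) {
    if (any(diff(p$r) <= 0) || any(diff(p$c) <= 0))
      return("pairs must be strictly increasing in both r and c")
  }
  if (nrow(p) && (any(p$r < 1L) || any(p$c < 1L)))
    return("position 0 of either strand never pairs")
  if (nrow(p) && !all(p$type %in% PAIR_TYPES))
    return("pair types must be canonical")
  TRUE
})

#' ChannelScaler: per-channel affine min-max normalization
#'
#' @slot lo,hi Numeric(4): per-channel minima and maxima from the fit set.
#' @slot enabled When FALSE, application is the identity.
#' @name ChannelScaler-class
#' @exportClass ChannelScaler
setClass("ChannelScaler", representation(
  lo = "numeric", hi = "numeric", enabled = "logical"))

#' FeatureStackSet: the four 25x25 input matrices per sample
#'
#' Stores, per sample, the four classifier input channels: \code{mx1}
#' (predicted duplex structure, pair-probability-valued), \code{dps} (DP
#' scoring table), \code{dpm} (DP substructure free energies) and \code{bp}
#' (base-pair probability matrix). Rows index microRNA positions, columns
#' site positions (both 0-based).
#'
#' @slot data Numeric array of dimension \code{c(25, 25, 4, n)} with channel
#'   order \code{mx1, dps, dpm, bp}.
#' @slot id Character vector of sample identifiers.
#' @slot label Integer vector of 0/1 labels.
#' @name FeatureStackSet-class
#' @exportClass FeatureStackSet
setClass("FeatureStackSet", representation(
  data = "array", id = "character", label = "integer"))

setValidity("FeatureStackSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L || !all(d[1:3] == c(25L, 25L, 4L)))
    return("data must be a 25 x 25 x 4 x n array")
  if (d[4] != length(object@id) || d[4] != length(object@label))
    return("id/label length must match the number of samples")
  TRUE
})

#' MinnModel: the trained four-branch multi-input convolutional classifier
#'
#' @slot params List of parameter matrices (four convolutional branches and
#'   the dense head).
#' @slot cfg The \code{\link{minnConfig}} list used for training.
#' @slot scaler The fitted \code{ChannelScaler} applied before prediction.
#' @slot threshold Classification threshold selected on validation data.
#' @slot history data.frame with one row per epoch (loss, validation AUPRC).
#' @slot scoreDict The \code{ScoreDict} used to featurize samples, kept with
#'   the model so new sequences (e.g. 3'UTR scan windows) can be featurized
#'   consistently at prediction time.
#' @name MinnModel-class
#' @exportClass MinnModel
setClass("MinnModel", representation(
  params = "list", cfg = "list", scaler = "ChannelScaler",
  threshold = "numeric", history = "data.frame", scoreDict = "ScoreDict"))
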