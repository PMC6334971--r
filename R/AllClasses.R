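#' Profile hidden Markov model
#'
#' A local-mode protein profile HMM built from a curated multiple sequence
#' alignment, the engine behind the Tom40/Tom22/Tom7 orthologue searches.
#' Match and insert states emit over the 20-residue alphabet; transition rows
#' cover the successors of each state (for match states: next match, insert,
#' delete, and exit).  All probability rows sum to one.
#'
#' @slot nMatch number of match states (alignment columns kept).
#' @slot matchEmissions \code{nMatch x 20} row-stochastic matrix.
#' @slot insertEmissions \code{nMatch x 20} row-stochastic matrix (by default
#'   every insert row equals the background).
#' @slot transM \code{nMatch x 4} matrix, columns \code{MM, MI, MD, ME}.
#' @slot transI \code{nMatch x 2} matrix, columns \code{IM, II}.
#' @slot transD \code{nMatch x 2} matrix, columns \code{DM, DD}.
#' @slot background length-20 probability vector.
#'
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(nMatch = "integer",
                 matchEmissions = "matrix",
                 insertEmissions = "matrix",
                 transM = "matrix",
                 transI = "matrix",
                 transD = "matrix",
                 background = "numeric"))

setValidity("ProfileHMM", function(object) {
  m <- object@nMatch
  msg <- character()
  if (m < 1L) msg <- c(msg, "nMatch must be >= 1")
  chkRows <- function(x, what) {
    if (nrow(x) != m) return(sprintf("%s must have nMatch rows", what))
    if (any(abs(rowSums(x) - 1) > 1e-9))
      return(sprintf("%s rows must sum to 1 (+/- 1e-9)", what))
    NULL
  }
  for (w in c("matchEmissions", "insertEmissions", "transM", "transI",
              "transD")) {
    e <- chkRows(slot(object, w), w)
    if (!is.null(e)) msg <- c(msg, e)
  }
  if (ncol(object@matchEmissions) != 20L ||
      !identical(colnames(object@matchEmissions), AA_ALPHABET))
    msg <- c(msg, "matchEmissions must have the 20 canonical residue columns")
  if (abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn ProfileHMM compact display
#' @param object a \code{ProfileHMM}
#' @export
setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM with %d match states\n", object@nMatch))
  top <- AA_ALPHABET[apply(object@matchEmissions, 1L, which.max)]
  cons <- paste(top, collapse = "")
  if (nchar(cons) > 60) cons <- paste0(substr(cons, 1, 57), "...")
  cat("  consensus:", cons, "\n")
})

#' Accessor: number of match states
#' @param x a \code{ProfileHMM}
#' @return integer scalar
#' @export
nMatch <- function(x) {
  stopifnot(is(x, "ProfileHMM"))
  x@nMatch
}

#' Accessor: background residue distribution
#' @param x a \code{ProfileHMM}
#' @return named numeric vector over the 20 residues
#' @export
hmmBackground <- function(x) {
  stopifnot(is(x, "ProfileHMM"))
  x@background
}

#' E-value calibration from decoy score distribution
#'
#' Gumbel (extreme-value) location/scale fitted by maximum likelihood to the
#' forward scores of i.i.d. background decoy sequences.  Stands in for
#' HMMER's internal calibration; E-values are
#' \code{E(s) = N * exp(-lambda * (s - mu))} clipped to \code{[0, N]}.
#'
#' @slot mu Gumbel location (bits).
#' @slot lambda Gumbel inverse scale (1/bits), positive.
#' @slot nDecoys number of decoys used in the fit.
#' @slot decoyLength decoy sequence length.
#' @slot seed RNG seed used to generate the decoys.
#'
#' @exportClass EvalueCalibration
setClass("EvalueCalibration",
  representation(mu = "numeric", lambda = "numeric", nDecoys = "integer",
                 decoyLength = "integer", seed = "integer"))

setValidity("EvalueCalibration", function(object) {
  if (object@lambda <= 0) "lambda must be > 0" else TRUE
})

#' @describeIn EvalueCalibration compact display
#' @param object an \code{EvalueCalibration}
#' @export
setMethod("show", "EvalueCalibration", function(object) {
  cat(sprintf(
    "EvalueCalibration: mu = %.3f bits, lambda = %.3f (n = %d decoys, seed %d)\n",
    object@mu, object@lambda, object@nDecoys, object@seed))
})

#' Degenerate residue-class motif pattern
#'
#' A compiled class pattern such as the beta-signal \code{PxGxxHxH}
#' (P = polar, G = glycine, H = hydrophobic, x = any residue), resolved
#' against a residue class table into one allowed residue set per position.
#'
#' @slot spec the pattern string, e.g. \code{"PxGxxHxH"}.
#' @slot classes character vector of per-position class labels.
#' @slot sets list of allowed residue sets, one per position.
#'
#' @exportClass MotifPattern
setClass("MotifPattern",
  representation(spec = "character", classes = "character", sets = "list"))

setValidity("MotifPattern", function(object) {
  if (length(object@sets) < 1L) return("pattern must have length >= 1")
  if (any(lengths(object@sets) == 0L))
    return("every position must map to a nonempty residue set")
  TRUE
})

#' @describeIn MotifPattern compact display
#' @param object a \code{MotifPattern}
#' @export
setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern \"%s\" (%d positions)\n",
              object@spec, length(object@sets)))
})

#' Length of a compiled motif pattern
#' @param x a \code{MotifPattern}
#' @export
setMethod("length", "MotifPattern", function(x) length(x@sets))
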