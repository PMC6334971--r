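# Transmembrane segment prediction from hydropathy, and anchor topology.
#
# An explicit, inspectable stand-in for a trained topology predictor: the
# normalised Kyte-Doolittle sliding-window profile is thresholded into
# candidate helices, and single-span proteins are classified as
# tail-anchored (C-terminal TMD) or signal-anchored (N-terminal TMD).  The
# published workflow's posterior cutoff (0.3 on a trained HMM) is not
# numerically transferable to this scale; the strictness knob here is the
# normalised-hydropathy cutoff (default 0.8, "relaxed" preset 0.7).

#' Normalised hydropathy profile
#'
#' Sliding-window mean of Kyte-Doolittle values, affinely rescaled so that
#' -4.5 maps to 0 and +4.5 maps to 1.  Windows shrink near the sequence
#' ends.
#'
#' @param sequence amino-acid string of length at least 7.
#' @param window odd window size, at least 7 (default 19, the canonical
#'   helix-spanning window).
#' @return numeric vector of per-residue scores in [0, 1].
#' @export
hydropathyProfile <- function(sequence, window = 19L) {
  if (window < 7L || window %% 2L == 0L)
    stop("window must be odd and >= 7")
  res <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(res)
  if (L < 7L) stop("sequence shorter than 7 residues")
  kd <- unname(KD_SCALE[res])
  kd[is.na(kd)] <- 0                       # unknown residues: neutral
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(kd))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  means <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  (means + 4.5) / 9
}

#' Predict transmembrane spans
#'
#' Maximal runs of residues whose normalised hydropathy exceeds the cutoff;
#' runs separated by at most \code{mergeGap} residues are merged, and runs
#' shorter than \code{minLen} are discarded.  Lowering the cutoff never
#' shrinks a predicted span.
#'
#' @param sequence amino-acid string.
#' @param cutoff normalised hydropathy threshold in (0, 1); default 0.8,
#'   relaxed preset 0.7.
#' @param minLen minimum span length in residues.
#' @param mergeGap maximum below-cutoff gap bridged between runs.
#' @param window hydropathy window (see \code{\link{hydropathyProfile}}).
#' @return an \code{IRanges} of spans with metadata column
#'   \code{meanScore}; empty for sequences shorter than 7 residues.
#' @export
predictTmds <- function(sequence, cutoff = 0.8, minLen = 15L,
                        mergeGap = 3L, window = 19L) {
  stopifnot(cutoff > 0, cutoff < 1)
  emptyIR <- IRanges::IRanges()
  if (nchar(sequence) < 7L) return(emptyIR)
  prof <- hydropathyProfile(sequence, window)
  above <- prof > cutoff
  if (!any(above)) return(emptyIR)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by <= mergeGap
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
    last <- nrow(merged)
    if (runs[i, 1L] - merged[last, 2L] - 1L <= mergeGap)
      merged[last, 2L] <- runs[i, 2L]
    else merged <- rbind(merged, runs[i, ])
  }
  keep <- (merged[, 2L] - merged[, 1L] + 1L) >= minLen
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(emptyIR)
  ir <- IRanges::IRanges(start = merged[, 1L], end = merged[, 2L])
  S4Vectors::mcols(ir)$meanScore <- vapply(seq_len(nrow(merged)), function(i)
    mean(prof[merged[i, 1L]:merged[i, 2L]]), numeric(1L))
  ir
}

#' Classify anchor topology
#'
#' Tail-anchored proteins carry exactly one TMD ending within the C-terminal
#' window (short lumenal tail, functional domain cytosolic); signal-anchored
#' proteins carry exactly one TMD starting within the N-terminal window.
#' Two or more spans are polytopic; a single mid-protein span, or no span,
#' is \code{none}.
#'
#' @param sequence the amino-acid string the spans were predicted on.
#' @param spans an \code{IRanges} from \code{\link{predictTmds}}.
#' @param ctermWindow,ntermWindow window sizes in residues (default 35).
#' @return list with \code{category} (one of \code{tail_anchored},
#'   \code{signal_anchored}, \code{polytopic}, \code{none}) and the input
#'   \code{spans}.
#' @export
classifyAnchor <- function(sequence, spans, ctermWindow = 35L,
                           ntermWindow = 35L) {
  L <- nchar(sequence)
  n <- length(spans)
  category <- if (n == 0L) "none"
  else if (n >= 2L) "polytopic"
  else if (end(spans) >= L - ctermWindow + 1L) "tail_anchored"
  else if (start(spans) <= ntermWindow) "signal_anchored"
  else "none"
  list(category = category, spans = spans)
}
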