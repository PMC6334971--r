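# Profile HMM construction and search.
#
# Desk-scale stand-in for an hmmbuild + single-round jackhmmer workflow:
# build a local-mode profile from a curated alignment (e.g. 24 well-annotated
# Tom40 sequences), score a proteome in bits against the background null,
# and convert scores to E-values with an explicit Gumbel fit on decoys.
#
# Model conventions (see the vignette for the full account): match columns
# are alignment columns whose non-gap fraction reaches the occupancy
# threshold; emissions are background-mixture pseudocounted; insert
# emissions equal the background (insert log-odds 0); entry is uniform over
# match states, exit probability 1/nMatch is folded into every match
# transition row; delete states are interior only.

.alignmentMatrix <- function(alignment) {
  seqs <- toupper(as.character(alignment))
  if (!length(seqs)) stop("alignment has no rows")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows must have equal length")
  do.call(rbind, strsplit(seqs, ""))
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' @param alignment gapped \code{AAStringSet} (equal widths, gap \code{-}).
#' @param occupancyThreshold columns whose non-gap fraction is at least this
#'   become match states; in (0, 1].
#' @param pseudocountWeight weight of the background-mixture pseudocount
#'   added to each match emission column.
#' @return a \code{\linkS4class{ProfileHMM}}.
#' @examples
#' aln <- Biostrings::AAStringSet(c(a = "MKLV", b = "MKIV"))
#' buildProfileHMM(aln)
#' @export
buildProfileHMM <- function(alignment, occupancyThreshold = 0.5,
                            pseudocountWeight = 1.0) {
  stopifnot(occupancyThreshold > 0, occupancyThreshold <= 1,
            pseudocountWeight >= 0)
  M <- .alignmentMatrix(alignment)
  isRes <- M != "-" & M != "."
  occ <- colMeans(isRes)
  matchCols <- which(occ >= occupancyThreshold)
  m <- length(matchCols)
  if (m == 0L) stop("no alignment column reaches the occupancy threshold")

  # Laplace-smoothed background from all residues of the alignment
  resAll <- M[isRes]
  resAll <- resAll[resAll %in% AA_ALPHABET]
  bg <- (table(factor(resAll, levels = AA_ALPHABET)) + 1) /
    (length(resAll) + 20)
  bg <- as.numeric(bg)
  names(bg) <- AA_ALPHABET

  emit <- matrix(0, m, 20, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(m)) {
    col <- M[, matchCols[j]]
    cnt <- table(factor(col[col %in% AA_ALPHABET], levels = AA_ALPHABET))
    v <- as.numeric(cnt) + pseudocountWeight * bg
    emit[j, ] <- v / sum(v)
  }
  insert <- matrix(rep(bg, each = m), m, 20,
                   dimnames = list(NULL, AA_ALPHABET))

  # transition counts from the implied state path of each row
  cM <- matrix(0, m, 3, dimnames = list(NULL, c("MM", "MI", "MD")))
  cI <- matrix(0, m, 2, dimnames = list(NULL, c("IM", "II")))
  cD <- matrix(0, m, 2, dimnames = list(NULL, c("DM", "DD")))
  colState <- integer(ncol(M))          # match index per column, 0 = insert
  colState[matchCols] <- seq_len(m)
  for (r in seq_len(nrow(M))) {
    types <- character(0); ks <- integer(0)
    seen <- 0L
    for (cc in seq_len(ncol(M))) {
      k <- colState[cc]
      if (k > 0L) {
        seen <- k
        types <- c(types, if (isRes[r, cc]) "M" else "D"); ks <- c(ks, k)
      } else if (isRes[r, cc] && seen >= 1L && seen < m) {
        types <- c(types, "I"); ks <- c(ks, seen)
      }
    }
    # local model: trim leading/trailing deletes (fragment rows)
    keep <- which(types != "D")
    if (!length(keep)) next
    rng <- keep[1L]:keep[length(keep)]
    types <- types[rng]; ks <- ks[rng]
    if (length(types) < 2L) next
    for (t in seq_len(length(types) - 1L)) {
      a <- types[t]; b <- types[t + 1L]; k <- ks[t]
      if (a == "M" && b == "M") cM[k, "MM"] <- cM[k, "MM"] + 1
      else if (a == "M" && b == "I") cM[k, "MI"] <- cM[k, "MI"] + 1
      else if (a == "M" && b == "D") cM[k, "MD"] <- cM[k, "MD"] + 1
      else if (a == "I" && b == "M") cI[k, "IM"] <- cI[k, "IM"] + 1
      else if (a == "I" && b == "I") cI[k, "II"] <- cI[k, "II"] + 1
      else if (a == "D" && b == "M") cD[k, "DM"] <- cD[k, "DM"] + 1
      else if (a == "D" && b == "D") cD[k, "DD"] <- cD[k, "DD"] + 1
    }
  }

  pExit <- 1 / m
  transM <- matrix(0, m, 4, dimnames = list(NULL, c("MM", "MI", "MD", "ME")))
  transI <- matrix(0, m, 2, dimnames = list(NULL, c("IM", "II")))
  transD <- matrix(0, m, 2, dimnames = list(NULL, c("DM", "DD")))
  for (k in seq_len(m)) {
    if (k == m) { transM[k, ] <- c(0, 0, 0, 1) }
    else {
      allowI <- k <= m - 1          # I_k exists for k < m
      allowD <- k + 1L <= m         # D_{k+1} exists
      v <- cM[k, ] + c(1, if (allowI) 1 else 0, if (allowD) 1 else 0)
      v <- v / sum(v)
      transM[k, ] <- c(v * (1 - pExit), pExit)
    }
    if (k < m) { v <- cI[k, ] + 1; transI[k, ] <- v / sum(v) }
    else transI[k, ] <- c(1, 0)
    if (k > 1L && k < m) { v <- cD[k, ] + 1; transD[k, ] <- v / sum(v) }
    else transD[k, ] <- c(1, 0)     # D_1 absent, D_m is a (disallowed) end
  }

  new("ProfileHMM", nMatch = m, matchEmissions = emit,
      insertEmissions = insert, transM = transM, transI = transI,
      transD = transD, background = bg)
}

# Precompute log2 tables for the DP kernels.
.hmmLogTables <- function(hmm) {
  list(ltrM = log2(hmm@transM), ltrI = log2(hmm@transI),
       ltrD = log2(hmm@transD), lentry = log2(1 / hmm@nMatch),
       lodEmit = log2(hmm@matchEmissions) -
         matrix(log2(hmm@background), hmm@nMatch, 20, byrow = TRUE,
                dimnames = list(NULL, AA_ALPHABET)))
}

# Per-residue log-odds matrices (L x m); unknown residues score 0.
.seqLogOdds <- function(hmm, sequence, tabs) {
  res <- strsplit(toupper(sequence), "")[[1L]]
  L <- length(res)
  if (!L) stop("sequence must be non-empty")
  idx <- match(res, AA_ALPHABET)
  lodM <- matrix(0, L, hmm@nMatch)
  known <- !is.na(idx)
  if (any(known)) lodM[known, ] <- t(tabs$lodEmit)[idx[known], , drop = FALSE]
  list(lodM = lodM, lodI = matrix(0, L, hmm@nMatch))
}

#' Viterbi bit score of a sequence against a profile
#'
#' Best local alignment log2-odds score versus the background null.
#'
#' @param hmm a \code{\linkS4class{ProfileHMM}}.
#' @param sequence amino-acid string.
#' @return numeric bit score.
#' @export
viterbiScore <- function(hmm, sequence) {
  .viterbiHit(hmm, sequence)$score
}

.viterbiHit <- function(hmm, sequence, tabs = .hmmLogTables(hmm)) {
  lo <- .seqLogOdds(hmm, sequence, tabs)
  .hmmViterbiC(lo$lodM, lo$lodI, tabs$ltrM, tabs$ltrI, tabs$ltrD,
               tabs$lentry)
}

#' Forward bit score of a sequence against a profile
#'
#' Total log2-odds over all local alignments; always at least the Viterbi
#' score.
#'
#' @inheritParams viterbiScore
#' @return numeric bit score.
#' @export
forwardScore <- function(hmm, sequence) {
  tabs <- .hmmLogTables(hmm)
  lo <- .seqLogOdds(hmm, sequence, tabs)
  .hmmForwardC(lo$lodM, lo$lodI, tabs$ltrM, tabs$ltrI, tabs$ltrD,
               tabs$lentry)
}

#' Calibrate E-values on background decoys
#'
#' Scores \code{nDecoys} i.i.d. background sequences with the forward
#' algorithm and fits a Gumbel distribution by maximum likelihood.
#' E-values are then \code{E(s) = N * exp(-lambda * (s - mu))}, clipped to
#' \code{[0, N]} for a database of N sequences.
#'
#' @param hmm a \code{\linkS4class{ProfileHMM}}.
#' @param nDecoys number of decoys (at least 50).
#' @param decoyLength decoy length in residues.
#' @param seed RNG seed; the fit is reproducible given the seed.
#' @return an \code{\linkS4class{EvalueCalibration}}.
#' @export
calibrateEvalues <- function(hmm, nDecoys = 200L, decoyLength = 150L,
                             seed = 1L) {
  stopifnot(nDecoys >= 50L, decoyLength >= 1L)
  tabs <- .hmmLogTables(hmm)
  scores <- withSeed(seed, {
    vapply(seq_len(nDecoys), function(i) {
      s <- paste(sample(AA_ALPHABET, decoyLength, replace = TRUE,
                        prob = hmm@background), collapse = "")
      lo <- .seqLogOdds(hmm, s, tabs)
      .hmmForwardC(lo$lodM, lo$lodI, tabs$ltrM, tabs$ltrI, tabs$ltrD,
                   tabs$lentry)
    }, numeric(1L))
  })
  if (sd(scores) < 1e-12) stop("degenerate decoy scores (zero variance)")
  beta0 <- sd(scores) * sqrt(6) / pi
  mu0 <- mean(scores) - 0.5772156649 * beta0
  nll <- function(p) {
    beta <- exp(p[2L]); z <- (scores - p[1L]) / beta
    length(scores) * log(beta) + sum(z + exp(-z))
  }
  fit <- optim(c(mu0, log(beta0)), nll, method = "BFGS")
  new("EvalueCalibration", mu = fit$par[1L], lambda = 1 / exp(fit$par[2L]),
      nDecoys = as.integer(nDecoys), decoyLength = as.integer(decoyLength),
      seed = as.integer(seed))
}

#' E-value for a bit score
#'
#' @param calibration an \code{\linkS4class{EvalueCalibration}}.
#' @param score bit score(s).
#' @param dbSize number of sequences in the searched database.
#' @return expected number of false positives at this score, in [0, dbSize].
#' @export
evalueFromScore <- function(calibration, score, dbSize) {
  pmin(pmax(dbSize * exp(-calibration@lambda * (score - calibration@mu)), 0),
       dbSize)
}

#' Search a proteome with a profile HMM
#'
#' Scores every record (forward bit score for ranking, Viterbi traceback for
#' the aligned span), ranks by bit score descending with ties broken by
#' record id, and attaches decoy-calibrated E-values.
#'
#' @param hmm a \code{\linkS4class{ProfileHMM}}.
#' @param records an \code{AAStringSet}.
#' @param calibration an \code{\linkS4class{EvalueCalibration}}.
#' @param dbSize database size for the E-value; defaults to
#'   \code{length(records)}.
#' @return a \code{DataFrame} with columns \code{id}, \code{bitScore},
#'   \code{evalue}, \code{start}, \code{end}, ranked best first.
#' @export
searchProteome <- function(hmm, records, calibration,
                           dbSize = length(records)) {
  if (!length(records))
    return(S4Vectors::DataFrame(id = character(), bitScore = numeric(),
                                evalue = numeric(), start = integer(),
                                end = integer()))
  tabs <- .hmmLogTables(hmm)
  ids <- recordIds(records)
  seqs <- as.character(records)
  fwd <- numeric(length(seqs)); st <- en <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    lo <- .seqLogOdds(hmm, seqs[i], tabs)
    fwd[i] <- .hmmForwardC(lo$lodM, lo$lodI, tabs$ltrM, tabs$ltrI,
                           tabs$ltrD, tabs$lentry)
    v <- .hmmViterbiC(lo$lodM, lo$lodI, tabs$ltrM, tabs$ltrI, tabs$ltrD,
                      tabs$lentry)
    st[i] <- v$start; en[i] <- v$end
  }
  ord <- order(-fwd, ids)
  S4Vectors::DataFrame(
    id = ids[ord], bitScore = fwd[ord],
    evalue = evalueFromScore(calibration, fwd[ord], dbSize),
    start = st[ord], end = en[ord])
}
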