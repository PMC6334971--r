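# Candidate triage: Venn decomposition of enriched sets against the
# membrane proteome, tiered candidate ranking, Hsp20-TPR-TMD domain
# architecture, and Tom22-like sequence feature checks.

#' Venn region decomposition of 2-3 named sets
#'
#' Exact partition of the union by membership signature; region counts sum
#' to the size of the union and every accession falls in exactly one
#' region.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return data.frame with columns \code{signature} (e.g. \code{"A&B"}),
#'   \code{count}, and list-column \code{members}.
#' @export
vennRegions <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
    stop("sets must be a named list of 2 or 3 accession vectors")
  nm <- names(sets)
  if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
    stop("sets must have unique non-empty names")
  sets <- lapply(sets, unique)
  uni <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) uni %in% s, logical(length(uni)))
  if (length(uni) == 1L) member <- matrix(member, 1L,
                                          dimnames = list(NULL, nm))
  if (length(uni) == 0L) member <- matrix(logical(), 0L, length(nm),
                                          dimnames = list(NULL, nm))
  sig <- apply(member, 1L, function(r) paste(nm[r], collapse = "&"))
  sigs <- unlist(lapply(seq_along(nm), function(k)
    apply(combn(nm, k), 2L, paste, collapse = "&")))
  out <- data.frame(signature = sigs,
                    count = vapply(sigs, function(s) sum(sig == s),
                                   integer(1L)),
                    row.names = NULL)
  out$members <- lapply(sigs, function(s) sort(uni[sig == s]))
  out
}

#' Tiered candidate triage
#'
#' Mirrors the intersection logic used to nominate complex members: tier 1
#' candidates are enriched under both crosslinking and native conditions
#' and present in the membrane proteome; tier 2 are crosslink-only
#' membrane-proteome hits (the route by which loosely associated receptors
#' surface); tier 3 are native-only membrane-proteome hits.  Each candidate
#' carries its anchor-topology category.
#'
#' @param crosslinkEnriched,nativeEnriched accession vectors of enriched
#'   proteins under the two coIP conditions.
#' @param membraneProteome accession vector of the organellar membrane
#'   proteome list.
#' @param anchorCalls optional named character vector of anchor categories
#'   (from \code{\link{classifyAnchor}}) keyed by accession.
#' @return data.frame with columns \code{accession}, \code{tier},
#'   \code{inCrosslink}, \code{inNative}, \code{anchor}, ranked by tier
#'   then accession.
#' @export
triageCandidates <- function(crosslinkEnriched, nativeEnriched,
                             membraneProteome, anchorCalls = NULL) {
  cl <- unique(trimws(crosslinkEnriched))
  nat <- unique(trimws(nativeEnriched))
  mem <- unique(trimws(membraneProteome))
  both <- intersect(intersect(cl, nat), mem)
  clOnly <- setdiff(intersect(cl, mem), nat)
  natOnly <- setdiff(intersect(nat, mem), cl)
  acc <- c(sort(both), sort(clOnly), sort(natOnly))
  if (!length(acc))
    return(data.frame(accession = character(), tier = integer(),
                      inCrosslink = logical(), inNative = logical(),
                      anchor = character()))
  tier <- rep(1:3, c(length(both), length(clOnly), length(natOnly)))
  anchor <- rep(NA_character_, length(acc))
  if (!is.null(anchorCalls)) {
    hit <- match(acc, names(anchorCalls))
    anchor[!is.na(hit)] <- unname(anchorCalls[hit[!is.na(hit)]])
  }
  data.frame(accession = acc, tier = tier, inCrosslink = acc %in% cl,
             inNative = acc %in% nat, anchor = anchor)
}

# best domain hit of one HMM inside a subsequence; NULL if nothing scores
.bestDomainHit <- function(hmm, tabs, calibration, sequence, offset,
                           evalueCutoff) {
  if (nchar(sequence) < 5L) return(NULL)
  lo <- .seqLogOdds(hmm, sequence, tabs)
  v <- .hmmViterbiC(lo$lodM, lo$lodI, tabs$ltrM, tabs$ltrI, tabs$ltrD,
                    tabs$lentry)
  ev <- evalueFromScore(calibration, v$score, 1L)
  if (ev > evalueCutoff) return(NULL)
  list(start = v$start + offset, end = v$end + offset, score = v$score,
       evalue = ev)
}

#' Classify Hsp20-TPR-TMD domain architecture
#'
#' Greedy non-overlapping assignment of profile-HMM domain hits (Hsp20-like
#' chaperone domain, TPR repeats) by descending bit score above a
#' per-domain E-value cutoff, plus the C-terminal TMD from the anchor call.
#' The receptor architecture of interest renders as
#' \code{"Hsp20-TPR(3)-TMD"}.
#'
#' @param sequence amino-acid string.
#' @param domainHmms named list of \code{\linkS4class{ProfileHMM}}s, e.g.
#'   \code{list(Hsp20 = ..., TPR = ...)}.
#' @param calibrations named list of matching
#'   \code{\linkS4class{EvalueCalibration}}s.
#' @param anchorCall result of \code{\link{classifyAnchor}} on the same
#'   sequence (supplies the TMD span), or NULL.
#' @param evalueCutoff per-domain E-value cutoff (default 0.01).
#' @return list with \code{domains} (data.frame label/start/end/score) and
#'   \code{architecture} (string such as \code{"Hsp20-TPR(3)-TMD"} or
#'   \code{"other"}).
#' @export
classifyArchitecture <- function(sequence, domainHmms, calibrations,
                                 anchorCall = NULL, evalueCutoff = 0.01) {
  stopifnot(identical(names(domainHmms), names(calibrations)))
  tabsL <- lapply(domainHmms, .hmmLogTables)
  hits <- data.frame(label = character(), start = integer(),
                     end = integer(), score = numeric())
  # free segments as (start, end) pairs, shrink as hits are accepted
  segs <- list(c(1L, nchar(sequence)))
  repeat {
    best <- NULL
    for (d in names(domainHmms)) for (sg in segs) {
      if (sg[2L] - sg[1L] + 1L < 5L) next
      h <- .bestDomainHit(domainHmms[[d]], tabsL[[d]], calibrations[[d]],
                          substr(sequence, sg[1L], sg[2L]), sg[1L] - 1L,
                          evalueCutoff)
      if (!is.null(h) && (is.null(best) || h$score > best$score)) {
        best <- h; best$label <- d
      }
    }
    if (is.null(best)) break
    hits <- rbind(hits, data.frame(label = best$label, start = best$start,
                                   end = best$end, score = best$score))
    newSegs <- list()
    for (sg in segs) {
      if (best$start > sg[2L] || best$end < sg[1L]) {
        newSegs <- c(newSegs, list(sg)); next
      }
      if (best$start > sg[1L])
        newSegs <- c(newSegs, list(c(sg[1L], best$start - 1L)))
      if (best$end < sg[2L])
        newSegs <- c(newSegs, list(c(best$end + 1L, sg[2L])))
    }
    segs <- newSegs
    if (!length(segs)) break
  }
  if (!is.null(anchorCall) && length(anchorCall$spans) == 1L &&
      anchorCall$category %in% c("tail_anchored", "signal_anchored")) {
    hits <- rbind(hits, data.frame(label = "TMD",
                                   start = start(anchorCall$spans),
                                   end = end(anchorCall$spans),
                                   score = NA_real_))
  }
  if (!nrow(hits))
    return(list(domains = hits, architecture = "other"))
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  # collapse consecutive repeats of the same label: TPR,TPR,TPR -> TPR(3)
  r <- rle(hits$label)
  arch <- paste(ifelse(r$lengths > 1L,
                       sprintf("%s(%d)", r$values, r$lengths), r$values),
                collapse = "-")
  list(domains = hits, architecture = arch)
}

#' Tom22-like sequence feature report
#'
#' Positional checks for the conserved Tom22 TMD motif: tryptophan at motif
#' position 2 (motif anchored at the TMD start plus \code{motifOffset}),
#' at least one hydroxylated residue (S/T/Y) within the three residues
#' after that tryptophan, serine at W+4, and an invariant proline inside
#' the TMD.  \code{passesAll} is the conjunction of all flags.
#'
#' @param sequence amino-acid string.
#' @param spans \code{IRanges} of predicted TMDs for the same sequence.
#' @param motifOffset offset of the motif origin from the TMD start
#'   (default 0: position 1 is the first TMD residue).
#' @param ctermWindow window for the C-terminal-TMD check (default 35).
#' @return list of logical flags (\code{hasCtermTmd}, \code{trpAtMotifPos2},
#'   \code{hydroxylatedRunAfterTrp}, \code{serAtPlus4}, \code{proInTmd},
#'   \code{passesAll}) plus \code{lengthAa}.
#' @export
tom22Features <- function(sequence, spans, motifOffset = 0L,
                          ctermWindow = 35L) {
  L <- nchar(sequence)
  out <- list(lengthAa = L, hasCtermTmd = FALSE, trpAtMotifPos2 = FALSE,
              hydroxylatedRunAfterTrp = FALSE, serAtPlus4 = FALSE,
              proInTmd = FALSE, passesAll = FALSE)
  if (length(spans) != 1L) return(out)
  tmStart <- start(spans); tmEnd <- end(spans)
  out$hasCtermTmd <- tmEnd >= L - ctermWindow + 1L
  res <- strsplit(toupper(sequence), "")[[1L]]
  p1 <- tmStart + motifOffset
  wPos <- p1 + 1L
  out$trpAtMotifPos2 <- wPos <= L && res[wPos] == "W"
  if (out$trpAtMotifPos2) {
    after <- res[seq(wPos + 1L, min(wPos + 3L, L))]
    out$hydroxylatedRunAfterTrp <- any(after %in% c("S", "T", "Y"))
    out$serAtPlus4 <- wPos + 4L <= L && res[wPos + 4L] == "S"
  }
  out$proInTmd <- any(res[tmStart:tmEnd] == "P")
  out$passesAll <- out$hasCtermTmd && out$trpAtMotifPos2 &&
    out$hydroxylatedRunAfterTrp && out$serAtPlus4 && out$proInTmd
  out
}
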