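# Independent oracles used to cross-check the implementation.  These are
# deliberately written as naive brute-force procedures that share no code
# with the package internals.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Robinson-Robinson natural residue frequencies, for random sequences that
# should resemble real proteins
ROBFREQS <- c(0.0781, 0.0193, 0.0536, 0.0629, 0.0396, 0.0737, 0.0219,
              0.0514, 0.0574, 0.0901, 0.0224, 0.0449, 0.0520, 0.0426,
              0.0512, 0.0712, 0.0584, 0.0644, 0.0132, 0.0321)

randSeq <- function(n, freqs = NULL) {
  paste(sample(AA20, n, replace = TRUE, prob = freqs), collapse = "")
}

# --- motif scanning: overlapping regex oracle -------------------------------

oracleMotifStarts <- function(sequence, spec = "PxGxxHxH",
                              table = residueClassTable()) {
  cls <- list(P = table$polar, G = "G", H = table$hydrophobic, x = AA20)
  letterSets <- cls[strsplit(spec, "")[[1]]]
  re <- paste0(vapply(letterSets, function(s)
    paste0("[", paste(s, collapse = ""), "]"), character(1)), collapse = "")
  m <- gregexpr(paste0("(?=", re, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# --- Smith-Waterman: naive dynamic programming ------------------------------

# affine gaps: a gap of length k costs gapOpen + k * gapExtend
oracleSW <- function(a, b, submat, gapOpen, gapExtend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- E <- F <- matrix(0, n + 1, m + 1)
  E[] <- F[] <- -Inf
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gapOpen - gapExtend,
                     E[i, j - 1] - gapExtend)
      F[i, j] <- max(H[i - 1, j] - gapOpen - gapExtend,
                     F[i - 1, j] - gapExtend)
      H[i, j] <- max(0, H[i - 1, j - 1] + submat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- TMD runs: position-by-position oracle ----------------------------------

oracleTmdSpans <- function(profile, cutoff, minLen, mergeGap) {
  above <- which(profile > cutoff)
  if (!length(above)) return(matrix(integer(), 0, 2))
  groups <- list(); cur <- c(above[1], above[1])
  for (p in above[-1]) {
    if (p - cur[2] - 1 <= mergeGap) cur[2] <- p
    else { groups <- c(groups, list(cur)); cur <- c(p, p) }
  }
  groups <- c(groups, list(cur))
  keep <- Filter(function(g) g[2] - g[1] + 1 >= minLen, groups)
  if (!length(keep)) return(matrix(integer(), 0, 2))
  do.call(rbind, keep)
}

# --- graph components: flood fill -------------------------------------------

oracleComponents <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- edges$id1[r]; b <- edges$id2[r]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (s in nodes) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, adj[[v]])
    }
  }
  comp
}

# --- profile HMM: exhaustive path enumeration -------------------------------

# Enumerates every local path (enter at a match state, exit from a match
# state) of a ProfileHMM on a short sequence, accumulating log2-odds.
# Returns the max (Viterbi) and log2-sum (forward) over all paths.
oracleEnumeratePaths <- function(hmm, sequence) {
  m <- nMatch(hmm)
  bg <- hmmBackground(hmm)
  res <- strsplit(sequence, "")[[1]]
  L <- length(res)
  lodM <- function(i, k) {
    a <- res[i]
    if (!a %in% names(bg)) return(0)
    log2(hmm@matchEmissions[k, a]) - log2(bg[[a]])
  }
  lodI <- function(i, k) {
    a <- res[i]
    if (!a %in% names(bg)) return(0)
    log2(hmm@insertEmissions[k, a]) - log2(bg[[a]])
  }
  lM <- log2(hmm@transM); lI <- log2(hmm@transI); lD <- log2(hmm@transD)
  lentry <- log2(1 / m)
  scores <- numeric(0)
  rec <- function(state, k, pos, acc) {
    if (state == "M") {
      scores <<- c(scores, acc + lM[k, "ME"])
      if (k < m && pos < L)
        rec("M", k + 1, pos + 1, acc + lM[k, "MM"] + lodM(pos + 1, k + 1))
      if (k < m && pos < L)
        rec("I", k, pos + 1, acc + lM[k, "MI"] + lodI(pos + 1, k))
      if (k + 1 <= m)
        rec("D", k + 1, pos, acc + lM[k, "MD"])
    } else if (state == "I") {
      if (pos < L)
        rec("I", k, pos + 1, acc + lI[k, "II"] + lodI(pos + 1, k))
      if (k < m && pos < L)
        rec("M", k + 1, pos + 1, acc + lI[k, "IM"] + lodM(pos + 1, k + 1))
    } else {                                   # "D": interior only
      if (k < m && pos < L)
        rec("M", k + 1, pos + 1, acc + lD[k, "DM"] + lodM(pos + 1, k + 1))
      if (k + 1 <= m)
        rec("D", k + 1, pos, acc + lD[k, "DD"])
    }
  }
  for (i0 in seq_len(L)) for (k0 in seq_len(m))
    rec("M", k0, i0, lentry + lodM(i0, k0))
  vit <- max(scores)
  fwd <- {
    mx <- max(scores)
    mx + log2(sum(2^(scores - mx)))
  }
  list(viterbi = vit, forward = fwd)
}

# random small profile for property tests (built through the constructor so
# rows are guaranteed stochastic)
randomToyHmm <- function(m, alphaEmit = 0.7) {
  nr <- m + 2L
  aln <- vapply(seq_len(nr), function(i) randSeq(m), character(1))
  buildProfileHMM(Biostrings::AAStringSet(setNames(aln, paste0("r", 1:nr))))
}

# --- Dollo parsimony: exhaustive single-gain minimisation -------------------

# For a tree and a complete presence/absence vector over its leaves, find
# the minimum number of losses over all gain placements by enumerating loss
# edge subsets of increasing size.
oracleDolloMin <- function(tree, present) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  desc <- function(v) {                       # tip descendants
    if (v <= ntip) return(v)
    unlist(lapply(kids[[v]], desc))
  }
  subtreeNodes <- function(v) {               # all nodes incl. v
    if (v <= ntip) return(v)
    c(v, unlist(lapply(kids[[v]], subtreeNodes)))
  }
  pres <- which(present)
  if (!length(pres)) return(0L)
  bestOverall <- Inf
  for (g in seq_len(nn)) {
    tips <- desc(g)
    if (!all(pres %in% tips)) next      # gain must cover all present leaves
    # edges strictly below g, identified by their child node
    below <- setdiff(subtreeNodes(g), g)
    # leaf x candidate-loss-edge incidence: does the edge sit on the path?
    onPath <- sapply(below, function(e) {
      tipsE <- desc(e)
      seq_len(ntip) %in% tipsE
    })
    if (is.null(dim(onPath))) onPath <- matrix(onPath, ncol = length(below))
    inClade <- seq_len(ntip) %in% tips
    found <- FALSE
    for (k in 0:length(below)) {
      if (k >= bestOverall) break
      combos <- if (k == 0) list(integer(0)) else
        asplit(combn(seq_along(below), k), 2)
      for (cb in combos) {
        cut <- if (length(cb))
          rowSums(onPath[, cb, drop = FALSE]) > 0 else rep(FALSE, ntip)
        implied <- inClade & !cut
        if (identical(implied, unname(present))) {
          bestOverall <- min(bestOverall, k); found <- TRUE; break
        }
      }
      if (found) break
    }
  }
  as.integer(bestOverall)
}
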