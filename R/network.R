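# CLANS-style sequence similarity network.
#
# All-against-all Smith-Waterman scores are turned into Karlin-Altschul
# p-values; pairs below the inclusion cutoff become undirected edges whose
# attraction is -log10(p) (capped), and a force-directed 2D embedding
# separates sequence families.  Absolute p-values differ from BLAST's, but
# the ordering is comparable; the default constants (BLOSUM62, gap open
# 11 / extend 1, lambda = 0.267, K = 0.041) are the documented ungapped-to-
# gapped convention and are configurable.

.substMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Local alignment score of two sequences
#'
#' Smith-Waterman score under an affine gap model (a gap of length k costs
#' \code{gapOpen + k * gapExtend}); \code{gapOpen = 0} gives linear gap
#' costs.
#'
#' @param a,b amino-acid strings.
#' @param matrix substitution matrix name (e.g. \code{"BLOSUM62"},
#'   \code{"BLOSUM50"}).
#' @param gapOpen,gapExtend gap penalties (positive costs).
#' @return numeric alignment score.
#' @examples
#' localAlignmentScore("HEAGAWGHEE", "PAWHEAE", "BLOSUM50",
#'                     gapOpen = 0, gapExtend = 8)  # 28
#' @export
localAlignmentScore <- function(a, b, matrix = "BLOSUM62", gapOpen = 11,
                                gapExtend = 1) {
  sm <- .substMatrix(matrix)
  as.numeric(pairwiseAlignment(a, b, type = "local",
                               substitutionMatrix = sm,
                               gapOpening = gapOpen,
                               gapExtension = gapExtend,
                               scoreOnly = TRUE))
}

#' Pairwise similarity edges
#'
#' Scores every unordered pair, assigns a Karlin-Altschul p-value
#' \code{p = 1 - exp(-K * m * n * exp(-lambda * S))} with search space
#' \code{m * n}, and keeps pairs with \code{p < keepP} (default 0.1, the
#' inclusion rule used to assemble the published 1,114-sequence data set).
#'
#' @param records an \code{AAStringSet} of at least 2 sequences.
#' @param matrix,gapOpen,gapExtend see \code{\link{localAlignmentScore}}.
#' @param lambda,K Karlin-Altschul constants.
#' @param keepP p-value inclusion cutoff; edges at or above it are dropped.
#' @param attractionCap cap on \code{-log10(p)} (default 200).
#' @return data.frame with columns \code{id1}, \code{id2}, \code{score},
#'   \code{pValue}, \code{attraction} (id1 < id2, no self-edges).
#' @export
pairwiseSimilarity <- function(records, matrix = "BLOSUM62", gapOpen = 11,
                               gapExtend = 1, lambda = 0.267, K = 0.041,
                               keepP = 0.1, attractionCap = 200) {
  if (length(records) < 2L) stop("need at least 2 records")
  ids <- recordIds(records)
  seqs <- as.character(records)
  lens <- nchar(seqs)
  sm <- .substMatrix(matrix)
  n <- length(seqs)
  rows <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    sc <- as.numeric(pairwiseAlignment(
      rep(seqs[i], length(js)), seqs[js], type = "local",
      substitutionMatrix = sm, gapOpening = gapOpen,
      gapExtension = gapExtend, scoreOnly = TRUE))
    ev <- K * lens[i] * lens[js] * exp(-lambda * sc)
    p <- -expm1(-ev)
    p <- pmin(pmax(p, 1e-300), 1)
    rows[[i]] <- data.frame(id1 = ids[i], id2 = ids[js], score = sc,
                            pValue = p)
  }
  out <- do.call(rbind, rows)
  # canonical order within pair
  swap <- out$id1 > out$id2
  tmp <- out$id1[swap]; out$id1[swap] <- out$id2[swap]; out$id2[swap] <- tmp
  out <- out[out$pValue < keepP, , drop = FALSE]
  out$attraction <- pmin(-log10(out$pValue), attractionCap)
  rownames(out) <- NULL
  out
}

#' Force-directed 2D layout of a similarity network
#'
#' Nodes start uniformly at random in the unit square (seeded); each
#' iteration applies attraction along edges proportional to
#' \code{attraction * distance} and 1/distance pairwise repulsion, with a
#' damped, cooled update (step 0.1 decayed by 0.999 per iteration).
#' Deterministic under a fixed seed; forces depend only on coordinate
#' differences, so translating the initial coordinates translates the
#' result.
#'
#' @param edges data.frame from \code{\link{pairwiseSimilarity}} (columns
#'   id1, id2, attraction).
#' @param nodes character vector of node ids (superset of edge endpoints).
#' @param nIter iterations (default 10000).
#' @param seed RNG seed for the initial placement.
#' @param step0,decay cooling schedule constants.
#' @param init optional n x 2 matrix of starting coordinates (overrides the
#'   seeded random initialisation).
#' @return data.frame with columns \code{id}, \code{x}, \code{y}.
#' @export
networkLayout <- function(edges, nodes, nIter = 10000L, seed = 1L,
                          step0 = 0.1, decay = 0.999, init = NULL) {
  stopifnot(nIter >= 1L)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  n <- length(nodes)
  if (is.null(init)) {
    init <- withSeed(seed, matrix(runif(2L * n), n, 2L))
  } else {
    init <- as.matrix(init)
    stopifnot(nrow(init) == n, ncol(init) == 2L)
  }
  ei <- match(edges$id1, nodes); ej <- match(edges$id2, nodes)
  if (any(is.na(ei)) || any(is.na(ej)))
    stop("edge endpoints missing from nodes")
  xy <- .clansLayoutC(init, ei - 1L, ej - 1L,
                      as.numeric(edges$attraction), as.integer(nIter),
                      step0, decay)
  data.frame(id = nodes, x = xy[, 1L], y = xy[, 2L])
}

#' Strongest edge subset
#'
#' The \code{ceiling(fraction * nEdges)} edges with highest attraction,
#' ties broken by lexicographic (id1, id2) — the "only the strongest
#' connections are shown" display rule.
#'
#' @param edges data.frame with columns id1, id2, attraction.
#' @param fraction in (0, 1]; default 0.2.
#' @return the selected rows of \code{edges}.
#' @export
topEdgeFraction <- function(edges, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!nrow(edges)) return(edges)
  k <- ceiling(fraction * nrow(edges))
  ord <- order(-edges$attraction, edges$id1, edges$id2)
  out <- edges[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connected components of the kept-edge graph
#'
#' Cluster membership at the inclusion cutoff: sequence families appear as
#' connected components.
#'
#' @param edges data.frame with columns id1, id2.
#' @param nodes character vector of all node ids.
#' @return named integer vector of component labels (1-based, numbered by
#'   first appearance in \code{nodes}).
#' @export
networkComponents <- function(edges, nodes) {
  nodes <- as.character(nodes)
  g <- igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges[, c("id1", "id2")] else
      data.frame(id1 = character(), id2 = character()),
    directed = FALSE,
    vertices = data.frame(name = nodes))
  memb <- igraph::components(g)$membership[nodes]
  # renumber by first appearance for order-invariance of labels
  lab <- match(memb, unique(memb))
  names(lab) <- nodes
  lab
}
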