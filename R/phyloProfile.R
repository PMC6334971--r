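# Presence/absence profiling and Dollo parsimony gain/loss mapping.
#
# A phylogenetic profile records, for each component (e.g. each TOM
# subunit) and each taxon, whether an orthologue was found (1), confidently
# absent (0), or uncertain (?).  Under the Dollo model each component is
# gained exactly once and may be lost any number of times below the gain;
# the minimal-loss history places the gain at the MRCA of the present taxa
# and cuts the maximal subtrees that contain absences but no presence.

#' Read and validate a species tree
#'
#' Newick parsing is delegated to \pkg{ape}; this wrapper enforces unique
#' leaf labels, a single root, and labels any unnamed internal nodes
#' (\code{node1, node2, ...}) so gain/loss events can be reported by name.
#' Polytomies are allowed.
#'
#' @param x Newick string or path to a Newick file.
#' @return an \pkg{ape} \code{phylo} object.
#' @examples
#' readSpeciesTree("((A,B),(C,D));")
#' @export
readSpeciesTree <- function(x) {
  tr <- tryCatch({
    if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x))
      ape::read.tree(x)
    else ape::read.tree(text = x)
  }, error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("invalid Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  if (is.null(tr$node.label) ||
      any(is.na(tr$node.label)) || any(!nzchar(tr$node.label))) {
    lab <- if (is.null(tr$node.label))
      rep("", tr$Nnode) else tr$node.label
    empty <- is.na(lab) | !nzchar(lab)
    lab[empty] <- paste0("node", which(empty))
    tr$node.label <- lab
  }
  tr
}

#' Serialise a species tree to Newick
#'
#' @param tree a \code{phylo} object.
#' @return Newick string.
#' @export
newickString <- function(tree) {
  ape::write.tree(tree)
}

# label of node number v (tips 1..n, internals n+1..)
.nodeLabel <- function(tree, v) {
  n <- length(tree$tip.label)
  ifelse(v <= n, tree$tip.label[v], tree$node.label[v - n])
}

.nodeNumber <- function(tree, label) {
  n <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (is.na(j)) stop("unknown node label: ", label)
  j + n
}

# list of children per node number
.childList <- function(tree) {
  n <- length(tree$tip.label)
  ch <- vector("list", n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1L]]] <- c(ch[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  ch
}

#' Construct a phylogenetic profile matrix
#'
#' @param states character (or numeric) matrix, rows = components, columns
#'   = taxa, entries in \code{1} (present), \code{0} (absent), \code{?}
#'   (uncertain).
#' @param tree optional \code{phylo}; taxa must then be a subset of its
#'   leaves.
#' @return character matrix with entries \code{"1"}, \code{"0"}, \code{"?"}.
#' @export
phyloProfile <- function(states, tree = NULL) {
  m <- as.matrix(states)
  m[] <- as.character(m)
  m[is.na(m)] <- "?"
  bad <- setdiff(unique(as.vector(m)), c("1", "0", "?"))
  if (length(bad))
    stop("profile entries must be 1, 0 or ?; found: ",
         paste(bad, collapse = ", "))
  if (is.null(colnames(m)) || (nrow(m) > 0L && is.null(rownames(m))))
    stop("profile needs component rownames and taxon colnames")
  if (!is.null(tree)) {
    miss <- setdiff(colnames(m), tree$tip.label)
    if (length(miss))
      stop("profile taxa missing from the tree: ",
           paste(miss, collapse = ", "))
  }
  m
}

#' Read a profile TSV (rows = components, columns = taxa)
#' @param path TSV path; cells in \{1, 0, ?\}.
#' @return character matrix as in \code{\link{phyloProfile}}.
#' @export
readPhyloProfile <- function(path) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE,
                   colClasses = "character")
  phyloProfile(as.matrix(df))
}

#' Dollo gain/loss map for one component
#'
#' Single-gain scenario with minimal losses: the gain sits at the most
#' recent common ancestor of all present leaves, and one loss is charged
#' per maximal subtree below the gain that contains a confident absence but
#' no presence (uncertain leaves are free and are resolved to minimise
#' losses; on a polytomy each lost child clade counts one edge).
#'
#' @param tree a \code{phylo} with labelled internal nodes (see
#'   \code{\link{readSpeciesTree}}).
#' @param profile matrix from \code{\link{phyloProfile}}.
#' @param component row name of the component to map.
#' @return list: \code{component}, \code{gainNode} (label, NA when the
#'   component is absent everywhere), \code{lossEdges} (labels of the child
#'   nodes of cut edges), \code{nGains}, \code{nLosses}, and
#'   \code{leafStates} (the implied presence/absence per leaf).
#' @export
dolloMap <- function(tree, profile, component) {
  if (!component %in% rownames(profile))
    stop("unknown component: ", component)
  states <- profile[component, ]
  n <- length(tree$tip.label)
  st <- setNames(rep("?", n), tree$tip.label)
  st[names(states)] <- states
  presentTips <- which(tree$tip.label %in% names(states)[states == "1"])
  if (!length(presentTips))
    return(list(component = component, gainNode = NA_character_,
                lossEdges = character(), nGains = 0L, nLosses = 0L,
                leafStates = setNames(rep("0", n), tree$tip.label)))
  gain <- if (length(presentTips) == 1L) presentTips
  else ape::getMRCA(tree, presentTips)
  ch <- .childList(tree)
  nn <- n + tree$Nnode
  hasPresent <- hasAbsent <- logical(nn)
  # postorder aggregation of confident states
  ord <- rev(.preorder(tree, ch))
  for (v in ord) {
    if (v <= n) {
      hasPresent[v] <- st[tree$tip.label[v]] == "1"
      hasAbsent[v] <- st[tree$tip.label[v]] == "0"
    } else {
      hasPresent[v] <- any(hasPresent[ch[[v]]])
      hasAbsent[v] <- any(hasAbsent[ch[[v]]])
    }
  }
  lossEdges <- character()
  lost <- logical(nn)
  walk <- gain
  while (length(walk)) {
    v <- walk[1L]; walk <- walk[-1L]
    for (c_ in ch[[v]]) {
      if (hasPresent[c_]) walk <- c(walk, c_)
      else if (hasAbsent[c_]) {
        lossEdges <- c(lossEdges, .nodeLabel(tree, c_))
        lost[c_] <- TRUE
      }
      # subtree with only uncertain leaves: resolved present (no loss)
    }
  }
  # implied leaf states
  inGain <- logical(nn); inGain[gain] <- TRUE
  for (v in .preorder(tree, ch))
    if (inGain[v]) for (c_ in ch[[v]]) inGain[c_] <- TRUE
  cut <- logical(nn)
  for (lbl in lossEdges) cut[.nodeNumber(tree, lbl)] <- TRUE
  below <- logical(nn)
  for (v in .preorder(tree, ch)) {
    if (cut[v]) below[v] <- TRUE
    if (below[v]) for (c_ in ch[[v]]) below[c_] <- TRUE
  }
  leafStates <- ifelse(inGain[seq_len(n)] & !below[seq_len(n)], "1", "0")
  names(leafStates) <- tree$tip.label
  list(component = component, gainNode = .nodeLabel(tree, gain),
       lossEdges = sort(lossEdges), nGains = 1L,
       nLosses = length(lossEdges), leafStates = leafStates)
}

# preorder node numbers from the root
.preorder <- function(tree, ch = .childList(tree)) {
  n <- length(tree$tip.label)
  root <- n + 1L
  out <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    if (v > n) stack <- c(stack, rev(ch[[v]]))
  }
  out
}

#' Gain/loss report for a whole profile
#'
#' Runs \code{\link{dolloMap}} on every component and tabulates events,
#' with a totals row.  Components that are uncertain-only or absent
#' everywhere get a zero-event entry flagged in the \code{note} column.
#'
#' @param tree a \code{phylo}.
#' @param profile matrix from \code{\link{phyloProfile}}.
#' @return data.frame: component, gainNode, nGains, nLosses, lossEdges
#'   (";"-collapsed), note; final row is the totals.
#' @export
profileReport <- function(tree, profile) {
  comps <- rownames(profile)
  if (!length(comps))
    return(data.frame(component = character(), gainNode = character(),
                      nGains = integer(), nLosses = integer(),
                      lossEdges = character(), note = character()))
  rows <- lapply(comps, function(cp) {
    gm <- dolloMap(tree, profile, cp)
    note <- if (gm$nGains == 0L) {
      if (all(profile[cp, ] == "?")) "uncertain-only" else "absent-everywhere"
    } else ""
    data.frame(component = cp,
               gainNode = ifelse(is.na(gm$gainNode), "", gm$gainNode),
               nGains = gm$nGains, nLosses = gm$nLosses,
               lossEdges = paste(gm$lossEdges, collapse = ";"),
               note = note)
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    component = "TOTAL", gainNode = "",
    nGains = sum(vapply(rows, function(r) r$nGains, integer(1L))),
    nLosses = sum(vapply(rows, function(r) r$nLosses, integer(1L))),
    lossEdges = "", note = ""))))
  rownames(out) <- NULL
  out
}
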