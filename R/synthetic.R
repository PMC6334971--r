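# Seeded synthetic inputs with the statistical structure the pipeline
# assumes: proteomes with planted beta-barrel, Hsp20-TPR-TMD, Tom22-like
# and tail-anchored families among i.i.d. decoys; LFQ replicate tables with
# bait-specific enrichment and control-side missingness; species trees with
# single-gain / multiple-loss presence histories.  Every generator is fully
# determined by (spec, seed) and emits a machine-readable truth table.
#
# Templates are fixed synthetic consensus sequences (built once from an
# internal constant seed); they are stand-ins designed to carry the
# diagnostic features of the real families (C-terminal beta-signal window,
# Hsp20-TPR(3)-TMD domain order, short Tom22-like protein with the
# W/hydroxylated/S(+4)/P TMD motif), not copies of database entries.

.TEMPLATE_SEED <- 3000098L

.randomPeptide <- function(n, freqs = NULL) {
  paste(sample(AA_ALPHABET, n, replace = TRUE, prob = freqs), collapse = "")
}

# strongly hydrophobic membrane-spanning block
.tmdBlock <- function(n) {
  paste(sample(c("L", "I", "V"), n, replace = TRUE,
               prob = c(0.5, 0.35, 0.15)), collapse = "")
}

#' Synthetic family templates
#'
#' The fixed consensus sequences behind the planted families:
#' \describe{
#'   \item{barrel}{190 aa, ends with the beta-signal window
#'     \code{NAGVVLAI} (PxGxxHxH-positive).}
#'   \item{tom36}{Hsp20-like segment, three TPR-like repeats, C-terminal
#'     TMD: architecture Hsp20-TPR(3)-TMD, tail-anchored.}
#'   \item{tom22}{short (~6.4 kDa) protein with a C-terminal TMD carrying
#'     the conserved motif: W at TMD position 2, hydroxylated residues
#'     after it, S at W+4, invariant P inside the TMD.}
#'   \item{homp19}{tail-anchored protein with no recognisable domain.}
#'   \item{hsp20Domain, tprDomain}{domain consensus segments used to build
#'     the Hsp20/TPR seed profiles.}
#' }
#'
#' @return named list of amino-acid strings.
#' @export
syntheticTemplates <- function() {
  rf <- unname(ROBINSON_FREQS)   # templates look like natural proteins
  withSeed(.TEMPLATE_SEED, {
    hsp20 <- .randomPeptide(85, rf)
    tpr <- .randomPeptide(34, rf)
    # the last 40 residues carry exactly one glycine (inside the terminal
    # beta-signal window), so the terminal window is the only possible
    # PxGxxHxH match in the C-terminal region by construction
    noG <- setdiff(AA_ALPHABET, "G")
    rfNoG <- rf[AA_ALPHABET != "G"] / sum(rf[AA_ALPHABET != "G"])
    ctermNoG <- paste(sample(noG, 32, replace = TRUE, prob = rfNoG),
                      collapse = "")
    barrel <- paste0(.randomPeptide(150, rf), ctermNoG, "NAGVVLAI")
    tom36 <- paste0(hsp20, .randomPeptide(6, rf),
                    tpr, .randomPeptide(4, rf), tpr, .randomPeptide(4, rf),
                    tpr, .randomPeptide(8, rf), .tmdBlock(29),
                    .randomPeptide(4, rf))
    # Tom22-like: short cis domain, then a TMD opening "L W S L L S"
    # (W at TMD position 2, hydroxylated residues after it, S at W+4), an
    # invariant proline in the hydrophobic core, and a 2-residue trans tail
    tom22tm <- paste0("LWSLLS", "LLIVLIVL", "P", "LIVLLIVLLIVLLI")
    tom22 <- paste0(.randomPeptide(26, rf), tom22tm, "KW")
    homp19 <- paste0(.randomPeptide(136, rf), .tmdBlock(29),
                     .randomPeptide(4, rf))
    list(hsp20Domain = hsp20, tprDomain = tpr, barrel = barrel,
         tom36 = tom36, tom22 = tom22, homp19 = homp19)
  })
}

# mutate a template at per-site rate, never touching `preserve` positions
.mutate <- function(template, rate, preserve = integer(), freqs = NULL) {
  res <- strsplit(template, "")[[1L]]
  hit <- which(runif(length(res)) < rate)
  hit <- setdiff(hit, preserve)
  if (length(hit))
    res[hit] <- sample(AA_ALPHABET, length(hit), replace = TRUE,
                       prob = freqs)
  paste(res, collapse = "")
}

#' Default planted-family specification
#'
#' Emulates the study's inputs: seven barrel paralogues of which one
#' carries the motif-breaking terminal serine; three Hsp20-TPR(3)-TMD
#' receptor-like tail-anchored paralogues; one Tom22-like short protein;
#' one domain-less tail-anchored protein.
#'
#' @return list of family descriptors (template name, member count,
#'   per-site mutation rate, preserved windows).
#' @export
defaultFamilies <- function() {
  tpl <- syntheticTemplates()
  barrelLen <- nchar(tpl$barrel)
  tom36Len <- nchar(tpl$tom36)
  tom22Len <- nchar(tpl$tom22)
  homp19Len <- nchar(tpl$homp19)
  list(
    tom40 = list(template = "barrel", n = 7L, rate = 0.15,
                 preserve = seq(barrelLen - 39L, barrelLen)),
    tom36like = list(template = "tom36", n = 3L, rate = 0.08,
                     preserve = seq(tom36Len - 32L, tom36Len)),
    tom22like = list(template = "tom22", n = 1L, rate = 0.03,
                     preserve = seq(tom22Len - 30L, tom22Len)),
    homp19like = list(template = "homp19", n = 1L, rate = 0.05,
                      preserve = seq(homp19Len - 32L, homp19Len)))
}

#' Generate a synthetic proteome with planted families
#'
#' Family members are per-site mutations of fixed templates with the
#' diagnostic windows preserved; decoys are i.i.d. from the background
#' residue distribution.  Barrel paralogue 3 carries the terminal
#' hydrophobic-to-serine substitution and is the single motif-negative
#' member, mirroring the seven-paralogue screen.
#'
#' @param seed integer seed; output is fully determined by (arguments,
#'   seed).
#' @param nDecoys number of decoy sequences.
#' @param decoyLength decoy length in residues.
#' @param families family descriptors (see \code{\link{defaultFamilies}}).
#' @param background \code{"uniform"} or \code{"robinson"} residue
#'   frequencies for decoys and mutations.
#' @return list with \code{records} (\code{AAStringSet}) and \code{truth}
#'   (data.frame: id, family, motifPositive, tailAnchored, tmdStart — the
#'   designed first TMD residue for planted membrane proteins, NA
#'   otherwise).
#' @export
simProteome <- function(seed, nDecoys = 100L, decoyLength = 150L,
                        families = defaultFamilies(),
                        background = c("uniform", "robinson")) {
  background <- match.arg(background)
  freqs <- if (background == "uniform") NULL else unname(ROBINSON_FREQS)
  tpl <- syntheticTemplates()
  # designed first TMD residue, by template (block + short tail)
  tmdStartOf <- c(tom36 = nchar(tpl$tom36) - 32L,
                  tom22 = nchar(tpl$tom22) - 30L,
                  homp19 = nchar(tpl$homp19) - 32L)
  withSeed(seed, {
    ids <- character(); seqs <- character()
    fam <- character(); motifPos <- logical(); ta <- logical()
    tmdStart <- integer()
    for (fname in names(families)) {
      f <- families[[fname]]
      for (i in seq_len(f$n)) {
        s <- .mutate(tpl[[f$template]], f$rate, f$preserve, freqs)
        isNeg <- FALSE
        if (fname == "tom40" && i == 3L) {
          # terminal hydrophobic residue replaced by serine
          substr(s, nchar(s), nchar(s)) <- "S"
          isNeg <- TRUE
        }
        ids <- c(ids, sprintf("%s_%02d", toupper(fname), i))
        seqs <- c(seqs, s)
        fam <- c(fam, fname)
        motifPos <- c(motifPos,
                      if (fname == "tom40") !isNeg else NA)
        ta <- c(ta, fname %in% c("tom36like", "tom22like", "homp19like"))
        tmdStart <- c(tmdStart,
                      if (f$template %in% names(tmdStartOf))
                        tmdStartOf[[f$template]] else NA_integer_)
      }
    }
    for (i in seq_len(nDecoys)) {
      ids <- c(ids, sprintf("DECOY_%03d", i))
      seqs <- c(seqs, .randomPeptide(decoyLength, freqs))
      fam <- c(fam, "decoy"); motifPos <- c(motifPos, NA); ta <- c(ta, FALSE)
      tmdStart <- c(tmdStart, NA_integer_)
    }
    records <- AAStringSet(setNames(seqs, ids))
    list(records = records,
         truth = data.frame(id = ids, family = fam,
                            motifPositive = motifPos, tailAnchored = ta,
                            tmdStart = tmdStart))
  })
}

#' Generate a training alignment for a planted family
#'
#' Ungapped alignment of mutated copies of one template (the synthetic
#' analogue of a curated orthologue alignment, e.g. 24 well-annotated
#' barrel sequences used to build the search profile).
#'
#' @param seed integer seed.
#' @param template template name from \code{\link{syntheticTemplates}}.
#' @param n number of rows (default 24).
#' @param rate per-site mutation rate.
#' @param preserve positions never mutated (default: the barrel's
#'   C-terminal beta-signal window when \code{template = "barrel"}).
#' @return an \code{AAStringSet} alignment (equal widths, no gaps).
#' @export
simFamilyAlignment <- function(seed, template = "barrel", n = 24L,
                               rate = 0.1, preserve = NULL) {
  tpl <- syntheticTemplates()[[template]]
  if (is.null(preserve) && template == "barrel")
    preserve <- seq(nchar(tpl) - 7L, nchar(tpl))
  withSeed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      .mutate(tpl, rate, if (is.null(preserve)) integer() else preserve),
      character(1L))
    AAStringSet(setNames(seqs, sprintf("%s_ref_%02d", template,
                                       seq_len(n))))
  })
}

#' Generate a synthetic LFQ co-IP table
#'
#' Background proteins draw all eight log2 intensities from
#' \code{Normal(mu_i, noiseSd)} with protein-level baselines
#' \code{mu_i ~ Uniform(baselineRange)}; bait-complex members get the test
#' arm shifted by \code{deltaLog2} and each control cell dropped with
#' probability \code{controlMissingness}.
#'
#' @param seed integer seed.
#' @param nProteins table size.
#' @param members accessions of bait-complex members, or an integer count
#'   (members are then drawn at random).
#' @param deltaLog2 bait-specific enrichment effect in log2 units.
#' @param noiseSd replicate noise standard deviation (log2 units).
#' @param controlMissingness per-cell probability that a member's control
#'   intensity is not quantified.
#' @param baselineRange range of protein-level baseline log2 intensities.
#' @param accessions optional accession vector (default \code{P0001...}).
#' @return list with \code{experiment} (a \code{SummarizedExperiment}) and
#'   \code{truth} (data.frame: accession, member).
#' @export
simLfq <- function(seed, nProteins = 200L, members = 12L, deltaLog2 = 3,
                   noiseSd = 0.5, controlMissingness = 0.7,
                   baselineRange = c(20, 30), accessions = NULL) {
  stopifnot(controlMissingness >= 0, controlMissingness <= 1)
  withSeed(seed, {
    if (is.null(accessions))
      accessions <- sprintf("P%04d", seq_len(nProteins))
    stopifnot(length(accessions) == nProteins)
    if (is.numeric(members) && length(members) == 1L)
      members <- sample(accessions, members)
    stopifnot(all(members %in% accessions))
    mu <- runif(nProteins, baselineRange[1L], baselineRange[2L])
    ints <- matrix(rnorm(nProteins * 8L, mean = mu, sd = noiseSd),
                   nProteins, 8L,
                   dimnames = list(accessions,
                                   c(LFQ_TEST_COLS, LFQ_CTRL_COLS)))
    isMem <- accessions %in% members
    ints[isMem, LFQ_TEST_COLS] <- ints[isMem, LFQ_TEST_COLS] + deltaLog2
    drop <- matrix(runif(sum(isMem) * 4L) < controlMissingness,
                   sum(isMem), 4L)
    ctl <- ints[isMem, LFQ_CTRL_COLS, drop = FALSE]
    ctl[drop] <- NA_real_
    ints[isMem, LFQ_CTRL_COLS] <- ctl
    list(experiment = LfqExperiment(ints),
         truth = data.frame(accession = accessions, member = isMem))
  })
}

# Canonicality of a simulated history, checked with set operations on the
# simulated events only (independent of the dolloMap inference):
# (i) a leaf gain must survive; (ii) an internal gain must keep present
# leaves under at least two of its children (so the gain is the MRCA of the
# survivors); (iii) every loss edge's parent must keep a present leaf
# through a sibling (the loss is irreducible).  Because every surviving
# root-to-leaf path ends in a present leaf, (ii) + (iii) guarantee the
# recorded events are exactly the minimal single-gain history.
.historyCanonical <- function(tree, gain, lossEdges, presentLeaves, ch, n) {
  if (!length(presentLeaves)) return(FALSE)
  if (gain <= n) return(gain %in% presentLeaves)
  under <- vapply(ch[[gain]], function(k)
    any(.leavesUnder(tree, k, ch, n) %in% presentLeaves), logical(1L))
  if (sum(under) < 2L) return(FALSE)
  for (le in lossEdges) {
    par <- tree$edge[tree$edge[, 2L] == le, 1L]
    sibs <- setdiff(ch[[par]], le)
    sibPresent <- any(vapply(sibs, function(s)
      any(.leavesUnder(tree, s, ch, n) %in% presentLeaves), logical(1L)))
    if (!sibPresent) return(FALSE)
  }
  TRUE
}

.leavesUnder <- function(tree, v, ch, n) {
  if (v <= n) return(v)
  out <- integer(0); stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (u <= n) out <- c(out, u) else stack <- c(stack, ch[[u]])
  }
  out
}

#' Simulate a species tree with gain/loss histories
#'
#' Draws a random rooted tree, places one gain per component, and loses the
#' component independently on each edge below the gain (a lost clade stays
#' lost).  Histories are redrawn until they are canonical — the gain is the
#' MRCA of the surviving present taxa and every loss is irreducible — so
#' that, absent homoplasy, the recorded events are exactly the minimal
#' single-gain history.  With \code{lossProb = 1} the degenerate all-lost
#' history is returned flagged instead.
#'
#' @param seed integer seed.
#' @param nTaxa number of leaves (labelled \code{t1..}).
#' @param components character vector of component names.
#' @param lossProb per-edge loss probability below the gain.
#' @param gainAtRoot logical (recycled): place the gain at the root
#'   (ancestral component) or at a random node.
#' @return list: \code{tree} (\code{phylo}, labelled internal nodes),
#'   \code{profile} (matrix, see \code{\link{phyloProfile}}), \code{truth}
#'   (per component: gainNode, lossEdges, degenerate flag).
#' @export
simTreeProfile <- function(seed, nTaxa = 8L,
                           components = c("Tom40", "Tom22", "Tom7",
                                          "Tom36"),
                           lossProb = 0.2,
                           gainAtRoot = c(TRUE, TRUE, FALSE, FALSE)) {
  stopifnot(nTaxa >= 3L, lossProb >= 0, lossProb <= 1)
  gainAtRoot <- rep(gainAtRoot, length.out = length(components))
  withSeed(seed, {
    tree <- ape::rtree(nTaxa, tip.label = paste0("t", seq_len(nTaxa)))
    tree$node.label <- paste0("node", seq_len(tree$Nnode))
    n <- nTaxa
    ch <- .childList(tree)
    root <- n + 1L
    pre <- .preorder(tree, ch)
    prof <- matrix("0", length(components), n,
                   dimnames = list(components, tree$tip.label))
    truth <- vector("list", length(components))
    names(truth) <- components
    for (ci in seq_along(components)) {
      for (try_ in seq_len(200L)) {
        gain <- if (gainAtRoot[ci]) root
        else sample(c(seq_len(n), (n + 1L):(n + tree$Nnode)), 1L)
        lost <- logical(n + tree$Nnode)
        lossEdges <- integer(0)
        inClade <- logical(n + tree$Nnode); inClade[gain] <- TRUE
        for (v in pre) {
          if (!inClade[v]) next
          if (v > n) for (c_ in ch[[v]]) {
            inClade[c_] <- TRUE
            if (lost[v]) lost[c_] <- TRUE
            else if (runif(1L) < lossProb) {
              lost[c_] <- TRUE
              lossEdges <- c(lossEdges, c_)
            }
          }
        }
        presentLeaves <- which(inClade[seq_len(n)] & !lost[seq_len(n)])
        degenerate <- !length(presentLeaves)
        if (lossProb >= 1) break
        if (.historyCanonical(tree, gain, lossEdges, presentLeaves, ch, n))
          break
        if (try_ == 200L)
          stop("could not draw a canonical gain/loss history; ",
               "lower lossProb")
      }
      states <- rep("0", n)
      states[presentLeaves] <- "1"
      prof[ci, ] <- states
      truth[[ci]] <- list(
        gainNode = if (degenerate) NA_character_ else .nodeLabel(tree, gain),
        lossEdges = if (degenerate) character() else
          sort(vapply(lossEdges, function(v) .nodeLabel(tree, v),
                      character(1L))),
        degenerate = degenerate)
    }
    list(tree = tree, profile = phyloProfile(prof, tree), truth = truth)
  })
}
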