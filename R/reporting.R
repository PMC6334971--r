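# Class-average pore accounting, run configuration, and the end-to-end
# pipeline driver.

#' Pore-class fractions from EM class-average particle counts
#'
#' Particle-count bookkeeping for 2D class averages representing complexes
#' with one, two or three translocation pores: per-class fraction of the
#' total and the nearest-integer percent (half away from zero).  Raw
#' fractions are always reported alongside the rounded percents because
#' rounding conventions differ between reports.
#'
#' @param counts named numeric vector of particle counts per class (names
#'   e.g. \code{"1-pore"}).
#' @param total denominator; defaults to \code{sum(counts)}.
#' @return data.frame with columns \code{class}, \code{n}, \code{fraction},
#'   \code{percent}; fractions sum to \code{sum(counts)/total}.
#' @examples
#' classFractions(c(`1-pore` = 1175, `2-pore` = 1377, `3-pore` = 860))
#' @export
classFractions <- function(counts, total = NULL) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(total)) total <- sum(counts)
  if (total <= 0) stop("total must be > 0")
  frac <- counts / total
  data.frame(class = names(counts), n = unname(counts),
             fraction = unname(frac),
             percent = unname(roundHalfUp(100 * frac)))
}

#' Default run configuration
#'
#' Every tunable of every stage, with the package defaults.  The
#' \code{tmd$tmhmmPosteriorCutoff} entry records the published workflow's
#' posterior cutoff (0.3) for provenance only; the operative strictness
#' knob of the hydropathy predictor is \code{tmd$cutoff}.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 17L,
    proteome = list(nDecoys = 60L, decoyLength = 150L,
                    background = "uniform"),
    motif = list(pattern = "PxGxxHxH", ctermWindow = 40L),
    hmm = list(occupancyThreshold = 0.5, pseudocountWeight = 1.0,
               trainN = 24L, trainRate = 0.1, nDecoys = 100L,
               decoyLength = 150L),
    tmd = list(cutoff = 0.8, minLen = 15L, mergeGap = 3L, window = 19L,
               ctermWindow = 35L, ntermWindow = 35L,
               tmhmmPosteriorCutoff = 0.3),
    lfq = list(deltaLog2 = 3, noiseSd = 0.5, controlMissingness = 0.7,
               fcThreshold = 1.0, minPresentTest = 2L,
               maxPresentControlForAbsence = 0L, fcScale = "linear"),
    network = list(nIter = 2000L, keepP = 0.1, showTop = 0.2,
                   matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                   lambda = 0.267, K = 0.041),
    tree = list(nTaxa = 8L, lossProb = 0.2))
}

# merge a partial config into the defaults, rejecting unknown keys
.resolveConfig <- function(config, defaults = defaultRunConfig(),
                           path = "") {
  if (is.null(config)) return(defaults)
  if (!is.list(config)) stop("config must be a list")
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  out <- defaults
  for (k in names(config)) {
    out[[k]] <- if (is.list(defaults[[k]]))
      .resolveConfig(config[[k]], defaults[[k]], paste0(path, ".", k))
    else config[[k]]
  }
  out
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected before execution; missing keys take package
#' defaults.
#'
#' @param path YAML file path.
#' @return fully resolved configuration list.
#' @export
readRunConfig <- function(path) {
  .resolveConfig(yaml::read_yaml(path))
}

#' Run the whole discovery pipeline on synthetic inputs
#'
#' Executes the stages in order on generated data — proteome simulation,
#' beta-motif scan, profile-HMM build/calibrate/search, TMD and anchor
#' classification, LFQ enrichment under crosslinking-like and native-like
#' conditions, candidate triage against the membrane list, similarity
#' network with layout and components, and gain/loss profiling — and
#' writes one TSV per stage plus a JSON summary and the fully resolved
#' configuration.  Byte-identical outputs under a fixed configuration.
#'
#' @param config partial configuration (see \code{\link{defaultRunConfig}});
#'   unknown keys are rejected before any stage runs.
#' @param outdir output directory (created if needed), or NULL to skip
#'   writing files.
#' @return (invisibly) list with the per-stage results and the summary.
#' @export
runPipeline <- function(config = list(), outdir = NULL) {
  cfg <- .resolveConfig(config)
  seeds <- subSeeds(cfg$seed, 8L)

  prot <- simProteome(seeds[1L], nDecoys = cfg$proteome$nDecoys,
                      decoyLength = cfg$proteome$decoyLength,
                      background = cfg$proteome$background)

  # beta-signal screen of the barrel paralogue candidates (the planted
  # analogue of checking the seven Tom40-like proteins)
  pattern <- compileMotif(cfg$motif$pattern)
  barrelIds <- prot$truth$id[prot$truth$family == "tom40"]
  motifCls <- classifyMotifCandidates(
    prot$records[match(barrelIds, recordIds(prot$records))], pattern,
    cfg$motif$ctermWindow)

  trainAln <- simFamilyAlignment(seeds[2L], "barrel",
                                 n = cfg$hmm$trainN,
                                 rate = cfg$hmm$trainRate)
  hmm <- buildProfileHMM(trainAln, cfg$hmm$occupancyThreshold,
                         cfg$hmm$pseudocountWeight)
  calib <- calibrateEvalues(hmm, cfg$hmm$nDecoys, cfg$hmm$decoyLength,
                            seed = seeds[3L])
  ranking <- searchProteome(hmm, prot$records, calib)

  seqs <- as.character(prot$records)
  ids <- recordIds(prot$records)
  anchors <- vapply(seqs, function(s) {
    sp <- predictTmds(s, cfg$tmd$cutoff, cfg$tmd$minLen, cfg$tmd$mergeGap,
                      cfg$tmd$window)
    classifyAnchor(s, sp, cfg$tmd$ctermWindow, cfg$tmd$ntermWindow)$category
  }, character(1L))
  names(anchors) <- ids

  # bait complex: planted families; native-like coIP misses the loosely
  # associated receptors (crosslink-only tier, cf. receptor candidates that
  # only co-purify under crosslinking)
  membersAll <- prot$truth$id[prot$truth$family != "decoy"]
  looseIds <- prot$truth$id[prot$truth$family == "tom36like"][-1L]
  membersNative <- setdiff(membersAll, looseIds)
  nProt <- length(ids)
  lfqX <- simLfq(seeds[4L], nProteins = nProt, members = membersAll,
                 deltaLog2 = cfg$lfq$deltaLog2, noiseSd = cfg$lfq$noiseSd,
                 controlMissingness = cfg$lfq$controlMissingness,
                 accessions = ids)
  lfqN <- simLfq(seeds[5L], nProteins = nProt, members = membersNative,
                 deltaLog2 = cfg$lfq$deltaLog2, noiseSd = cfg$lfq$noiseSd,
                 controlMissingness = cfg$lfq$controlMissingness,
                 accessions = ids)
  enrX <- computeEnrichment(lfqX$experiment, cfg$lfq$fcThreshold,
                            cfg$lfq$minPresentTest,
                            cfg$lfq$maxPresentControlForAbsence,
                            cfg$lfq$fcScale)
  enrN <- computeEnrichment(lfqN$experiment, cfg$lfq$fcThreshold,
                            cfg$lfq$minPresentTest,
                            cfg$lfq$maxPresentControlForAbsence,
                            cfg$lfq$fcScale)
  membraneList <- withSeed(seeds[6L],
    sort(c(membersAll, sample(prot$truth$id[prot$truth$family == "decoy"],
                              min(10L, cfg$proteome$nDecoys)))))
  triage <- triageCandidates(enrichedSet(enrX), enrichedSet(enrN),
                             membraneList, anchors)

  # similarity network over the planted families plus a few decoys
  netIds <- c(prot$truth$id[prot$truth$family %in% c("tom40", "tom36like")],
              head(prot$truth$id[prot$truth$family == "decoy"], 6L))
  netRecs <- prot$records[match(netIds, ids)]
  edges <- pairwiseSimilarity(netRecs, matrix = cfg$network$matrix,
                              gapOpen = cfg$network$gapOpen,
                              gapExtend = cfg$network$gapExtend,
                              lambda = cfg$network$lambda,
                              K = cfg$network$K, keepP = cfg$network$keepP)
  coords <- networkLayout(edges, netIds, nIter = cfg$network$nIter,
                          seed = seeds[7L])
  comp <- networkComponents(edges, netIds)
  coords$component <- unname(comp[coords$id])

  treeSim <- simTreeProfile(seeds[8L], nTaxa = cfg$tree$nTaxa,
                            lossProb = cfg$tree$lossProb)
  gl <- profileReport(treeSim$tree, treeSim$profile)

  tier1 <- triage$accession[triage$tier == 1L]
  summary <- list(
    nRecords = nProt,
    motifPositive = length(motifCls$motifPositive),
    motifNegative = length(motifCls$motifNegative),
    topHmmHit = ranking$id[1L],
    nEnrichedCrosslink = length(enrichedSet(enrX)),
    nEnrichedNative = length(enrichedSet(enrN)),
    nTier1 = length(tier1),
    tier1 = tier1,
    nNetworkComponents = length(unique(comp)),
    totalLosses = gl$nLosses[gl$component == "TOTAL"])

  res <- list(config = cfg, proteome = prot, motif = motifCls,
              ranking = ranking, anchors = anchors,
              enrichment = list(crosslink = enrX, native = enrN),
              membraneList = membraneList, triage = triage,
              network = list(edges = edges, layout = coords,
                             components = comp),
              gainLoss = gl, summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, name)
      write.table(df, file.path(outdir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    wtsv(data.frame(id = c(motifCls$motifPositive, motifCls$motifNegative),
                    motifPositive = rep(c(TRUE, FALSE),
                                        c(length(motifCls$motifPositive),
                                          length(motifCls$motifNegative)))),
         "motif_scan.tsv")
    wtsv(as.data.frame(ranking), "hmm_search.tsv")
    wtsv(data.frame(id = ids, anchor = unname(anchors)), "anchors.tsv")
    wtsv(as.data.frame(enrX), "enrichment_crosslink.tsv")
    wtsv(as.data.frame(enrN), "enrichment_native.tsv")
    wtsv(triage, "triage.tsv")
    wtsv(edges, "network_edges.tsv")
    wtsv(coords, "network_layout.tsv")
    wtsv(gl, "gain_loss.tsv")
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(cfg, file.path(outdir, "config_resolved.yaml"))
  }
  invisible(res)
}
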