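# Label-free quantitative co-IP enrichment.
#
# Replicate intensity tables have four test (bait pull-down) and four
# control (wild-type pull-down) log2 intensities per protein, replicates
# A-D.  A protein is considered enriched either if it is present only in
# the test arm and absent in the control, or if its fold change exceeds the
# threshold; means are arithmetic means of the present log2 intensities
# (no imputation), n is mean(test) - mean(control), fold change is 2^n.

LFQ_TEST_COLS <- paste0("test_", c("A", "B", "C", "D"))
LFQ_CTRL_COLS <- paste0("ctrl_", c("A", "B", "C", "D"))

#' Assemble an LFQ experiment
#'
#' Wraps a proteins x 8 matrix of log2 intensities (columns
#' \code{test_A..test_D, ctrl_A..ctrl_D}; \code{NA} = not quantified) into a
#' \code{SummarizedExperiment} with arm/replicate column metadata.
#'
#' @param intensities numeric matrix with the eight intensity columns and
#'   accession rownames.
#' @param rowAnnotation optional data.frame of per-protein annotation.
#' @return a \code{SummarizedExperiment} with assay \code{log2intensity}.
#' @export
LfqExperiment <- function(intensities, rowAnnotation = NULL) {
  intensities <- as.matrix(intensities)
  need <- c(LFQ_TEST_COLS, LFQ_CTRL_COLS)
  if (!all(need %in% colnames(intensities)))
    stop("missing required intensity columns: ",
         paste(setdiff(need, colnames(intensities)), collapse = ", "))
  intensities <- intensities[, need, drop = FALSE]
  if (any(is.infinite(intensities)))
    stop("log2 intensities must be finite where present")
  cd <- S4Vectors::DataFrame(
    condition = rep(c("test", "control"), each = 4L),
    replicate = rep(c("A", "B", "C", "D"), 2L),
    row.names = need)
  rd <- if (is.null(rowAnnotation)) NULL else S4Vectors::DataFrame(rowAnnotation)
  SummarizedExperiment(assays = list(log2intensity = intensities),
                       colData = cd, rowData = rd)
}

#' Read an LFQ intensity table from TSV
#'
#' Expects columns \code{accession}, optional annotation columns, and the
#' eight intensity columns \code{test_A..test_D}, \code{ctrl_A..ctrl_D}.
#' Empty cells, \code{0}, \code{NA} and \code{NaN} are treated as "not
#' quantified".  Duplicate accessions with identical rows are collapsed;
#' conflicting duplicates are an error.
#'
#' @param path TSV file path.
#' @return a \code{SummarizedExperiment} (see \code{\link{LfqExperiment}}).
#' @export
readLfqTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("accession", LFQ_TEST_COLS, LFQ_CTRL_COLS)
  if (!all(need %in% colnames(df)))
    stop("missing required columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  if (nrow(df)) {
    df$accession <- trimws(df$accession)
    if (anyDuplicated(df$accession)) {
      key <- df$accession
      uniq <- !duplicated(key)
      for (acc in unique(key[duplicated(key)])) {
        rows <- df[key == acc, , drop = FALSE]
        if (nrow(unique(rows)) > 1L)
          stop("conflicting duplicate rows for accession ", acc)
      }
      df <- df[uniq, , drop = FALSE]
    }
  }
  toNum <- function(v) {
    v <- suppressWarnings(as.numeric(v))
    v[!is.na(v) & v == 0] <- NA_real_
    v
  }
  ints <- vapply(c(LFQ_TEST_COLS, LFQ_CTRL_COLS),
                 function(cn) toNum(df[[cn]]), numeric(nrow(df)))
  if (nrow(df) == 1L) ints <- matrix(ints, nrow = 1L,
                                     dimnames = list(NULL, names(ints)))
  if (nrow(df) == 0L)
    ints <- matrix(numeric(), 0L, 8L,
                   dimnames = list(NULL, c(LFQ_TEST_COLS, LFQ_CTRL_COLS)))
  rownames(ints) <- df$accession
  ann <- df[, setdiff(colnames(df), c("accession", LFQ_TEST_COLS,
                                      LFQ_CTRL_COLS)), drop = FALSE]
  LfqExperiment(ints, if (ncol(ann)) ann else NULL)
}

#' Apply the co-IP enrichment rule
#'
#' A protein is \emph{presence-only} enriched when it is quantified in at
#' least \code{minPresentTest} test replicates and in at most
#' \code{maxPresentControlForAbsence} control replicates.  Otherwise, when
#' both arm means are computable, it is enriched when its fold change
#' exceeds \code{fcThreshold} (literal reading: linear ratio \code{2^n}
#' with \code{n = mean(test) - mean(control)}; set \code{fcScale = "log2"}
#' for the stricter reading \code{n > fcThreshold}).
#'
#' @param x a \code{SummarizedExperiment} from \code{\link{LfqExperiment}}
#'   or \code{\link{readLfqTable}}.
#' @param fcThreshold fold-change threshold (default 1: "fold change > 1").
#' @param minPresentTest replicates (of 4) required for "present".
#' @param maxPresentControlForAbsence control replicates tolerated for
#'   "absent".
#' @param fcScale \code{"linear"} (default, the legend's literal reading) or
#'   \code{"log2"}.
#' @return a \code{DataFrame}: accession, nPresentTest, nPresentControl,
#'   meanTest, meanControl, n, foldChange, presenceOnly, enriched.
#' @export
computeEnrichment <- function(x, fcThreshold = 1.0, minPresentTest = 2L,
                              maxPresentControlForAbsence = 0L,
                              fcScale = c("linear", "log2")) {
  fcScale <- match.arg(fcScale)
  stopifnot(minPresentTest >= 1L, minPresentTest <= 4L)
  a <- assay(x, "log2intensity")
  tst <- a[, LFQ_TEST_COLS, drop = FALSE]
  ctl <- a[, LFQ_CTRL_COLS, drop = FALSE]
  npT <- rowSums(!is.na(tst))
  npC <- rowSums(!is.na(ctl))
  mT <- ifelse(npT > 0, rowMeans(tst, na.rm = TRUE), NA_real_)
  mC <- ifelse(npC > 0, rowMeans(ctl, na.rm = TRUE), NA_real_)
  presenceOnly <- npT >= minPresentTest & npC <= maxPresentControlForAbsence
  n <- ifelse(presenceOnly, NA_real_, mT - mC)
  fc <- 2^n
  byFold <- !presenceOnly & npT >= minPresentTest & !is.na(mT) & !is.na(mC) &
    (if (fcScale == "linear") fc > fcThreshold else n > fcThreshold)
  S4Vectors::DataFrame(
    accession = rownames(a), nPresentTest = unname(npT),
    nPresentControl = unname(npC), meanTest = unname(mT),
    meanControl = unname(mC), n = unname(n), foldChange = unname(fc),
    presenceOnly = unname(presenceOnly),
    enriched = unname(presenceOnly | byFold))
}

#' Enriched accession set
#'
#' @param results a \code{DataFrame} from \code{\link{computeEnrichment}}.
#' @return character vector of enriched accessions.
#' @export
enrichedSet <- function(results) {
  as.character(results$accession[results$enriched])
}
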