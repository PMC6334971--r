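# Sequence I/O and basic protein statistics.
#
# Collections of protein records are plain Biostrings::AAStringSet objects:
# names(x) hold the FASTA headers, recordIds(x) the accession (first header
# token).  Gapped alignments are AAStringSets of equal width with '-' gaps.

#' Read a protein FASTA file
#'
#' Reads plain or aligned FASTA into an \code{AAStringSet}.  Sequences are
#' uppercased and trailing stop characters (\code{*}) are stripped.  Records
#' with empty sequences and duplicated accessions are rejected.
#'
#' @param path path to a FASTA text file.
#' @param ungap drop gap characters (\code{-}) after parsing; keep the
#'   default \code{FALSE} when reading alignments.
#' @return an \code{AAStringSet}; record accessions via \code{recordIds()}.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">A tiny", "MKLV", ">B", "GGSA"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, ungap = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) return(Biostrings::AAStringSet())
  x <- tryCatch(readAAStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(x))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  if (ungap) seqs <- gsub("-", "", seqs, fixed = TRUE)
  if (any(!nzchar(seqs))) {
    bad <- names(x)[!nzchar(seqs)][1L]
    ln <- grep(paste0("^>", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", bad)),
               readLines(path))[1L]
    stop(sprintf("empty sequence for record '%s' (header at line %s)",
                 bad, ifelse(is.na(ln), "?", ln)))
  }
  out <- AAStringSet(seqs)
  names(out) <- names(x)
  ids <- recordIds(out)
  if (anyDuplicated(ids))
    stop("duplicated record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out
}

#' Write protein records to FASTA
#'
#' @param x an \code{AAStringSet} (names are written as headers).
#' @param path output file path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  writeXStringSet(AAStringSet(x), filepath = path, width = width)
  invisible(path)
}

#' Record accessions of a sequence collection
#'
#' The accession is the first whitespace-delimited token of the FASTA
#' header, trimmed; TrichDB-style ids (\code{TVAG_332970}) are treated as
#' opaque strings.
#'
#' @param x an \code{AAStringSet} or named character vector.
#' @return character vector of accessions.
#' @export
recordIds <- function(x) {
  nm <- names(x)
  if (is.null(nm)) stop("records have no names/headers")
  sub("\\s.*$", "", trimws(nm))
}

#' Predicted molecular weight
#'
#' Sum of average residue masses plus one water, in kDa, the convention
#' behind a "predicted molecular weight" (e.g. a short Tom22-like protein of
#' about 6.4 kDa).  Unknown residues (including \code{X}) are an error.
#'
#' @param sequence amino-acid string(s) over the 20-letter alphabet, or an
#'   \code{AAStringSet}.
#' @return numeric vector of masses in kDa.
#' @examples
#' molecularWeight("G")   # 0.0750672
#' @export
molecularWeight <- function(sequence) {
  if (is(sequence, "XStringSet")) sequence <- as.character(sequence)
  vapply(sequence, function(s) {
    if (!nzchar(s)) stop("molecularWeight: empty sequence")
    res <- strsplit(toupper(s), "")[[1L]]
    bad <- which(!res %in% names(AA_MASS_AVG))
    if (length(bad))
      stop(sprintf("molecularWeight: unknown residue '%s' at position %d",
                   res[bad[1L]], bad[1L]))
    (sum(AA_MASS_AVG[res]) + WATER_MASS) / 1000
  }, numeric(1L), USE.NAMES = !is.null(names(sequence)))
}

#' Residue class table for degenerate motifs
#'
#' The class sets behind degenerate motif letters: P = polar, G = glycine,
#' H = hydrophobic, x = any.  Glycine is always \code{{G}}; polar and
#' hydrophobic sets are configurable but must be disjoint.  Serine is polar
#' under any admissible configuration used here (the diagnostic for the
#' motif-breaking substitution in one Tom40 paralogue).
#'
#' @param polar,hydrophobic character vectors of single residues.
#' @return a list with elements \code{polar}, \code{hydrophobic},
#'   \code{glycine}, \code{any}.
#' @export
residueClassTable <- function(
    polar = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T", "Y"),
    hydrophobic = c("A", "F", "I", "L", "M", "V", "W")) {
  polar <- toupper(polar); hydrophobic <- toupper(hydrophobic)
  if (length(intersect(polar, hydrophobic)))
    stop("polar and hydrophobic residue sets must be disjoint")
  if ("G" %in% c(polar, hydrophobic))
    stop("glycine belongs to its own class")
  list(polar = polar, hydrophobic = hydrophobic, glycine = "G",
       any = AA_ALPHABET)
}

#' Classify a residue
#'
#' Deterministic, total lookup: \code{polar}, \code{hydrophobic},
#' \code{glycine}, or \code{other} (any letter outside the configured sets,
#' including unknowns).
#'
#' @param residue single uppercase letter(s).
#' @param table a \code{\link{residueClassTable}}.
#' @return character vector of class labels.
#' @export
residueClass <- function(residue, table = residueClassTable()) {
  residue <- toupper(residue)
  out <- rep("other", length(residue))
  out[residue %in% table$polar] <- "polar"
  out[residue %in% table$hydrophobic] <- "hydrophobic"
  out[residue == "G"] <- "glycine"
  out
}
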