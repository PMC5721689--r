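# Alignment input/output: FASTA (Biostrings) and sequential PHYLIP (ape),
# with strict validation. Characters are uppercased and U is mapped to T
# on input.

#' Read an alignment from FASTA or sequential PHYLIP
#'
#' @param path readable file path.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @return a validated [SequenceAlignment-class].
#' @export
readAlignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e)
                      stop("cannot parse FASTA '", path, "': ",
                           conditionMessage(e), call. = FALSE))
    if (length(set) == 0) stop("empty FASTA file: ", path)
    if (length(set) == 1) stop("alignment needs at least 2 sequences")
    ids <- sub("\\s.*$", "", names(set))
    if (anyDuplicated(ids))
      stop("duplicate sequence id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    widths <- Biostrings::width(set)
    if (length(unique(widths)) > 1) {
      off <- which(widths != widths[1])
      stop(sprintf(
        "unequal sequence lengths: record %d ('%s') has %d sites, expected %d",
        off[1], ids[off[1]], widths[off[1]], widths[1]))
    }
    if (widths[1] == 0) stop("zero-length sequences in ", path)
    sequenceAlignment(as.character(set), ids = ids)
  } else {
    dna <- tryCatch(ape::read.dna(path, format = "sequential",
                                  as.character = TRUE),
                    error = function(e)
                      stop("cannot parse sequential PHYLIP '", path, "': ",
                           conditionMessage(e), call. = FALSE))
    ids <- trimws(rownames(dna))
    if (anyDuplicated(ids))
      stop("duplicate sequence id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    sequenceAlignment(toupper(unname(dna)), ids = ids)
  }
}

#' Write an alignment to FASTA or sequential PHYLIP
#'
#' @param aln a [SequenceAlignment-class].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "phylip")) {
  stopifnot(is(aln, "SequenceAlignment"))
  format <- match.arg(format)
  seqs <- apply(aln@chars, 1, paste, collapse = "")
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(seqs)
    names(set) <- aln@ids
    Biostrings::writeXStringSet(set, path)
  } else {
    mat <- aln@chars
    rownames(mat) <- aln@ids
    ape::write.dna(mat, path, format = "sequential", colsep = "")
  }
  invisible(path)
}
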