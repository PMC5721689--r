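# Sequence alignments, IUPAC handling and site-pattern compression.

# leaf partial-likelihood rows for every recognized character
.IUPAC <- local({
  tab <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"),
    N = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T"),
    `?` = c("A", "C", "G", "T"))
  out <- sapply(tab, function(b) as.numeric(c("A", "C", "G", "T") %in% b))
  rownames(out) <- c("A", "C", "G", "T")
  out
})

# unique columns with multiplicities and the pruning leaf array
.compress_patterns <- function(chars) {
  m <- nrow(chars)
  l <- ncol(chars)
  if (l == 0) {
    return(list(counts = numeric(0), index = integer(0),
                tipLik = array(numeric(0), dim = c(4L, m, 0L))))
  }
  key <- apply(chars, 2, paste, collapse = "")
  index <- match(key, unique(key))
  counts <- as.numeric(tabulate(index, nbins = max(index)))
  first <- match(seq_along(counts), index)
  tipLik <- array(0, dim = c(4L, m, length(counts)))
  for (p in seq_along(counts)) {
    col <- chars[, first[p]]
    tipLik[, , p] <- .IUPAC[, col]
  }
  list(counts = counts, index = index, tipLik = tipLik)
}

#' Construct a sequence alignment
#'
#' Characters are uppercased and `U` is mapped to `T`; anything outside
#' A/C/G/T, the IUPAC ambiguity codes, `N`, `-` and `?` is rejected. Site
#' patterns (unique columns with multiplicities) and the pruning leaf
#' partial-likelihood array are compressed and cached at construction.
#' A zero-column matrix is accepted and represents "no data"
#' (log-likelihood identically 0).
#'
#' @param chars m x l character matrix, or a character vector of length-m
#'   strings.
#' @param ids sequence identifiers; defaults to rownames or "s1".."sm".
#' @return a [SequenceAlignment-class].
#' @export
sequenceAlignment <- function(chars, ids = NULL) {
  if (is.character(chars) && is.null(dim(chars))) {
    if (is.null(ids)) ids <- names(chars)
    split <- strsplit(chars, "")
    if (length(unique(lengths(split))) > 1)
      stop("sequences have unequal lengths: ",
           paste(lengths(split), collapse = ", "))
    chars <- do.call(rbind, split)
  }
  if (!is.matrix(chars)) stop("chars must be a matrix or character vector")
  if (is.null(ids)) ids <- rownames(chars)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(chars)))
  chars <- toupper(chars)
  chars[chars == "U"] <- "T"
  bad <- matrix(!chars %in% colnames(.IUPAC), nrow = nrow(chars))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid character '%s' in sequence %s (site %d)",
                 chars[bad][1], ids[w[1]], w[2]))
  }
  dimnames(chars) <- NULL
  aln <- new("SequenceAlignment", ids = as.character(ids), chars = chars,
             patterns = .compress_patterns(chars))
  validObject(aln)
  aln
}

#' @describeIn sequenceAlignment number of sequences
#' @param x a `SequenceAlignment`
#' @export
setMethod("nSequences", "SequenceAlignment", function(x) length(x@ids))

#' @describeIn sequenceAlignment alignment length (sites)
#' @export
setMethod("nSites", "SequenceAlignment", function(x) ncol(x@chars))

#' @describeIn sequenceAlignment compressed site patterns: a list with the
#'   unique columns (`columns`, m x npat), their multiplicities (`counts`,
#'   summing to l) and the site-to-pattern map (`index`); expanding
#'   `columns[, index]` reproduces the alignment matrix exactly
#' @export
setMethod("sitePatterns", "SequenceAlignment", function(x) {
  p <- x@patterns
  first <- match(seq_along(p$counts), p$index)
  list(columns = x@chars[, first, drop = FALSE],
       counts = p$counts, index = p$index)
})

setMethod("show", "SequenceAlignment", function(object) {
  cat("SequenceAlignment:", nSequences(object), "sequences x",
      nSites(object), "sites;", length(object@patterns$counts),
      "site patterns\n")
})
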