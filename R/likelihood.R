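# Phylogenetic likelihood Pr(D | genealogy, lambda) by Felsenstein
# pruning over compressed site patterns (C++ kernel, per-node scaling).

# order the alignment rows to match the genealogy tip order
.match_tips <- function(aln, gen) {
  idx <- match(tipLabels(gen), aln@ids)
  if (anyNA(idx))
    stop("genealogy tip labels do not match alignment ids: missing ",
         paste(tipLabels(gen)[is.na(idx)], collapse = ", "))
  idx
}

# 4 x m x npat leaf array reordered to tip order; 0-based parents and
# edge lengths for the C++ kernel
.pruning_inputs <- function(aln, gen) {
  idx <- .match_tips(aln, gen)
  tipLik <- aln@patterns$tipLik[, idx, , drop = FALSE]
  parent0 <- gen@parent - 1L  # -1 at root
  edgelen <- numeric(length(gen@parent))
  nr <- gen@parent != 0L
  edgelen[nr] <- gen@times[gen@parent[nr]] - gen@times[nr]
  list(tipLik = tipLik, parent0 = parent0, edgelen = edgelen,
       counts = aln@patterns$counts)
}

#' Pruning log-likelihood of an alignment on a genealogy
#'
#' Computes `log Pr(D | gen, params)` by post-order propagation of
#' per-state partial likelihoods, evaluated once per unique site pattern
#' and weighted by multiplicity, with per-node scaling so the result stays
#' finite for long alignments and small Theta. The root is summed against
#' the stationary distribution; under reversibility the value is
#' independent of root placement on the unrooted tree.
#'
#' @param aln a [SequenceAlignment-class]; ids must match the genealogy
#'   tip labels (any order).
#' @param gen a [Genealogy-class].
#' @param params a [SubstitutionModel-class].
#' @return log-likelihood scalar (0 for a zero-site alignment).
#' @export
pruningLoglik <- function(aln, gen, params) {
  stopifnot(is(aln, "SequenceAlignment"), is(gen, "Genealogy"),
            is(params, "SubstitutionModel"))
  inp <- .pruning_inputs(aln, gen)
  .pruning_loglik_cpp(inp$parent0, inp$edgelen, inp$tipLik, inp$counts,
                      nSequences(aln), .MODEL_ID[[params@model]],
                      params@kappa, params@pi)
}

# likelihood on an arbitrary rooted binary tree given explicitly by
# 1-based parents (0 at root) and per-node edge lengths; used for
# root-placement (pulley) checks where the tree need not be ultrametric
.pruning_loglik_edges <- function(aln, parent, edgelen, tipOrder, params) {
  idx <- match(tipOrder, aln@ids)
  tipLik <- aln@patterns$tipLik[, idx, , drop = FALSE]
  parent0 <- as.integer(parent) - 1L
  parent0[parent == 0] <- -1L
  .pruning_loglik_cpp(parent0, as.numeric(edgelen), tipLik,
                      aln@patterns$counts, length(tipOrder),
                      .MODEL_ID[[params@model]], params@kappa, params@pi)
}
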