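# Coalescent / finite-sites sequence simulator with known truth. The
# genealogy is drawn from the coalescent prior and sequences evolve along
# it site by site under the chosen substitution model (root drawn from the
# stationary distribution), which reproduces the classical
# tree-simulator -> sequence-simulator chain in-process.

#' Construct a simulation specification
#'
#' @param thetaTrue generating scaled mutation rate (> 0).
#' @param m sample size (>= 2).
#' @param l sites (>= 1).
#' @param model generating [SubstitutionModel-class]; defaults to K80 with
#'   kappa = 2, the conventional generator value.
#' @param seed integer seed.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(thetaTrue, m, l,
                           model = substitutionModel("K80", kappa = 2),
                           seed = 1L) {
  obj <- new("SimulationSpec", thetaTrue = as.numeric(thetaTrue),
             m = as.integer(m), l = as.integer(l), model = model,
             seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Evolve sequences along a genealogy
#'
#' The root sequence is drawn from the stationary distribution; each
#' branch then mutates every site independently according to the row of
#' the branch's transition-probability matrix indexed by the parent state.
#'
#' @param gen a [Genealogy-class].
#' @param model a [SubstitutionModel-class].
#' @param l number of sites.
#' @return a [SequenceAlignment-class] with ids = `tipLabels(gen)`.
#' @export
evolveSequences <- function(gen, model, l) {
  stopifnot(is(gen, "Genealogy"), is(model, "SubstitutionModel"))
  l <- as.integer(l)
  if (l < 1) stop("l must be >= 1")
  bases <- c("A", "C", "G", "T")
  m <- nTips(gen)
  nnode <- 2L * m - 1L
  root <- which(gen@parent == 0L)
  states <- matrix(0L, nnode, l)
  states[root, ] <- sample.int(4L, l, replace = TRUE, prob = model@pi)
  # preorder: internal nodes by decreasing time, then tips
  ord <- order(gen@times, decreasing = TRUE)
  ord <- ord[ord != root]
  for (v in ord) {
    p <- gen@parent[v]
    P <- transitionMatrix(model, gen@times[p] - gen@times[v])
    parentState <- states[p, ]
    out <- integer(l)
    for (s in 1:4) {
      at <- which(parentState == s)
      if (length(at))
        out[at] <- sample.int(4L, length(at), replace = TRUE, prob = P[s, ])
    }
    states[v, ] <- out
  }
  chars <- matrix(bases[states[seq_len(m), , drop = FALSE]], nrow = m)
  sequenceAlignment(chars, ids = tipLabels(gen))
}

#' Simulate a dataset with known truth
#'
#' Draws a coalescent genealogy for `m` tips at `thetaTrue` and evolves
#' `l` sites along it under the generating substitution model.
#' Reproducible: the seed stored in `spec` is applied at entry.
#'
#' @param spec a [SimulationSpec-class].
#' @return list with elements `alignment` (a
#'   [SequenceAlignment-class]) and `genealogy` (the true
#'   [Genealogy-class]).
#' @export
simulateDataset <- function(spec) {
  stopifnot(is(spec, "SimulationSpec"))
  set.seed(spec@seed)
  gen <- sampleGenealogy(spec@m, spec@thetaTrue)
  aln <- evolveSequences(gen, spec@model, spec@l)
  list(alignment = aln, genealogy = gen)
}

#' Expected number of segregating sites
#'
#' Infinite-sites expectation `Theta * l * sum_{i=1}^{m-1} 1/i`; a test
#' oracle for the simulator (finite-sites repeat mutation deflates the
#' realized count when `Theta * l` is large).
#'
#' @param theta per-site scaled mutation rate.
#' @param m sample size.
#' @param l sites.
#' @return expected segregating-site count.
#' @export
expectedSegregatingSites <- function(theta, m, l) {
  if (theta < 0) stop("theta must be nonnegative")
  if (m < 2) stop("m must be >= 2")
  theta * l * sum(1 / seq_len(m - 1))
}
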