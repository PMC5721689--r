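# S4 class definitions and validity methods for the core containers.

#' Aligned DNA sequences with compressed site patterns
#'
#' Holds `m >= 2` aligned sequences of common length `l` over the DNA
#' alphabet (A, C, G, T), IUPAC ambiguity codes, `N` and gaps. On
#' construction the unique site patterns are cached together with their
#' multiplicities and the 4 x m x npat leaf partial-likelihood array used
#' by the pruning algorithm (ambiguity codes contribute 1 for every
#' compatible base; gaps and N are fully missing, all ones).
#'
#' @slot ids character vector of sequence identifiers (unique).
#' @slot chars m x l character matrix of uppercase bases.
#' @slot patterns list with elements `counts` (pattern multiplicities,
#'   summing to `l`), `index` (length-`l` map from site to pattern) and
#'   `tipLik` (4 x m x npat numeric array of leaf partial likelihoods).
#' @exportClass SequenceAlignment
setClass("SequenceAlignment",
  representation(ids = "character", chars = "matrix", patterns = "list"))

setValidity("SequenceAlignment", function(object) {
  msg <- character()
  m <- length(object@ids)
  if (m < 2) msg <- c(msg, "need at least 2 sequences")
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate sequence ids")
  if (!is.character(object@chars)) msg <- c(msg, "chars must be character")
  if (nrow(object@chars) != m) msg <- c(msg, "ids/chars dimension mismatch")
  l <- ncol(object@chars)
  p <- object@patterns
  if (!all(c("counts", "index", "tipLik") %in% names(p))) {
    msg <- c(msg, "patterns cache incomplete")
  } else {
    if (length(p$index) != l) msg <- c(msg, "pattern index length != l")
    if (l > 0 && abs(sum(p$counts) - l) > 0)
      msg <- c(msg, "pattern multiplicities must sum to l")
    if (length(p$counts) > 0 &&
        !identical(dim(p$tipLik), c(4L, m, length(p$counts))))
      msg <- c(msg, "tipLik dimensions inconsistent")
  }
  if (length(msg)) msg else TRUE
})

#' Rooted ultrametric coalescent genealogy
#'
#' A rooted binary tree with `m` labeled leaves at time 0 and `m - 1`
#' internal nodes with strictly positive times (time measured backwards
#' from the present in mutation units, i.e. expected substitutions per
#' site). Nodes are indexed 1..2m-1 with tips first; `parent` is 0 at the
#' root. The epoch durations `d_k` (time during which exactly k lineages
#' exist, k = m..2) are stored and validated against the node times.
#'
#' @slot parent integer vector of parent indices (0 at the root).
#' @slot times numeric node times, 0 at the tips.
#' @slot tipLabels character labels of the m tips (node order 1..m).
#' @slot intervals numeric vector of length m-1; `intervals[i]` is
#'   `d_{i+1}`, the duration with i+1 lineages.
#' @exportClass Genealogy
setClass("Genealogy",
  representation(parent = "integer", times = "numeric",
                 tipLabels = "character", intervals = "numeric"))

setValidity("Genealogy", function(object) {
  m <- length(object@tipLabels)
  nnode <- 2L * m - 1L
  msg <- character()
  if (m < 2) return("need at least 2 tips")
  if (length(object@parent) != nnode || length(object@times) != nnode)
    return("parent/times must have length 2m-1")
  if (sum(object@parent == 0L) != 1L) return("exactly one root required")
  if (any(object@times[seq_len(m)] != 0)) msg <- c(msg, "tips must be at time 0")
  tab <- tabulate(object@parent, nbins = nnode)
  if (any(tab[seq_len(m)] != 0L)) msg <- c(msg, "tips cannot be parents")
  if (any(tab[(m + 1L):nnode] != 2L)) msg <- c(msg, "internal nodes need 2 children")
  nonroot <- which(object@parent != 0L)
  if (any(object@times[nonroot] >= object@times[object@parent[nonroot]]))
    msg <- c(msg, "node times must strictly increase towards the root")
  if (any(object@intervals < 0)) msg <- c(msg, "negative interval")
  recomputed <- .intervals_from_times(object@times[(m + 1L):nnode])
  if (length(object@intervals) != m - 1L ||
      max(abs(recomputed - object@intervals)) > 1e-9 * max(1, max(object@times)))
    msg <- c(msg, "stored intervals do not match node times")
  if (length(msg)) msg else TRUE
})

#' Nucleotide substitution model parameters (lambda)
#'
#' K80 (equal base frequencies, free transition/transversion ratio kappa)
#' or F84 (free frequencies pi and kappa). `kappa` is the expected
#' transition/transversion ratio under the stationary law in both models,
#' so a single prior U(0, kappaMax) refers to the same quantity.
#'
#' @slot model `"K80"` or `"F84"`.
#' @slot kappa nonnegative transition/transversion ratio.
#' @slot pi stationary base frequencies (A, C, G, T); fixed at 0.25 each
#'   for K80.
#' @exportClass SubstitutionModel
setClass("SubstitutionModel",
  representation(model = "character", kappa = "numeric", pi = "numeric"))

setValidity("SubstitutionModel", function(object) {
  msg <- character()
  if (!object@model %in% c("K80", "F84")) msg <- c(msg, "model must be K80 or F84")
  if (length(object@kappa) != 1 || object@kappa < 0)
    msg <- c(msg, "kappa must be a nonnegative scalar")
  if (length(object@pi) != 4 || any(object@pi < 0))
    msg <- c(msg, "pi must be 4 nonnegative frequencies")
  if (abs(sum(object@pi) - 1) > 1e-12) msg <- c(msg, "pi must sum to 1")
  if (object@model == "K80" && any(object@pi != 0.25))
    msg <- c(msg, "K80 requires pi = (0.25, 0.25, 0.25, 0.25)")
  if (length(msg)) msg else TRUE
})

#' Prior specification for (Theta, kappa, pi)
#'
#' Uniform priors Theta ~ U(0, thetaMax) and kappa ~ U(0, kappaMax), and a
#' Dirichlet(alpha) prior on the base frequencies (F84 only).
#'
#' @slot thetaMax upper bound of the uniform prior on Theta; may be
#'   `NA_real_` meaning "resolve from the data" as
#'   `max(10 * wattersonTheta(aln), 0.1)`.
#' @slot kappaMax upper bound of the uniform prior on kappa.
#' @slot alpha Dirichlet concentration (length 4, strictly positive).
#' @exportClass PriorSpec
setClass("PriorSpec",
  representation(thetaMax = "numeric", kappaMax = "numeric", alpha = "numeric"))

setValidity("PriorSpec", function(object) {
  msg <- character()
  if (length(object@thetaMax) != 1 ||
      (!is.na(object@thetaMax) && object@thetaMax <= 0))
    msg <- c(msg, "thetaMax must be positive (or NA for data-driven)")
  if (length(object@kappaMax) != 1 || object@kappaMax <= 0)
    msg <- c(msg, "kappaMax must be positive")
  if (length(object@alpha) != 4 || any(object@alpha <= 0))
    msg <- c(msg, "alpha must be 4 positive concentrations")
  if (length(msg)) msg else TRUE
})

#' One point of the augmented state space
#'
#' H = (Theta, lambda, genealogy) with cached log-likelihood and cached
#' coalescent log-prior.
#'
#' @slot theta scalar Theta.
#' @slot params a [SubstitutionModel-class].
#' @slot gen a [Genealogy-class].
#' @slot cachedLoglik log Pr(D | gen, lambda).
#' @slot cachedLogPrior log p(gen | theta).
#' @exportClass ModelState
setClass("ModelState",
  representation(theta = "numeric", params = "SubstitutionModel",
                 gen = "Genealogy", cachedLoglik = "numeric",
                 cachedLogPrior = "numeric"))

#' Tempered SMC configuration
#'
#' @slot model substitution model id, `"K80"` or `"F84"`.
#' @slot kappaFixed,piFixed values used when the corresponding update is
#'   disabled (`NA` = draw once from the prior).
#' @slot nParticles particle count N (the default 500 follows the guided
#'   initialization setting under which that count suffices).
#' @slot epsilons nondecreasing tempering schedule with eps[1] = 0 and
#'   eps[T] = 1; default quadratic with T = 50.
#' @slot rMcmc MH sweeps per particle per temperature.
#' @slot essThreshold resampling trigger as a fraction of N.
#' @slot priors a [PriorSpec-class].
#' @slot seed integer seed governing the whole run.
#' @slot initMode `"upgma_guided"` (UPGMA topology, coalescent-prior node
#'   times) or `"prior"` (full joint prior draws).
#' @slot thetaScale,kappaScale lognormal random-walk scales.
#' @slot piConcentration Dirichlet proposal concentration for pi.
#' @slot rTree genealogy moves per sweep.
#' @slot updateKappa,updatePi logical switches to fix lambda components.
#' @exportClass SMCConfig
setClass("SMCConfig",
  representation(model = "character", nParticles = "integer",
                 epsilons = "numeric",
                 rMcmc = "integer", essThreshold = "numeric",
                 priors = "PriorSpec", seed = "integer",
                 initMode = "character",
                 thetaScale = "numeric", kappaScale = "numeric",
                 piConcentration = "numeric", rTree = "integer",
                 updateKappa = "logical", updatePi = "logical",
                 kappaFixed = "numeric", piFixed = "numeric"))

setValidity("SMCConfig", function(object) {
  msg <- character()
  if (!object@model %in% c("K80", "F84"))
    msg <- c(msg, "model must be K80 or F84")
  if (object@nParticles < 2) msg <- c(msg, "need N >= 2 particles")
  e <- object@epsilons
  if (length(e) < 2 || e[1] != 0 || e[length(e)] != 1 || any(diff(e) < 0))
    msg <- c(msg, "epsilons must be nondecreasing from 0 to 1, length >= 2")
  if (object@rMcmc < 1) msg <- c(msg, "rMcmc must be >= 1")
  if (object@essThreshold <= 0 || object@essThreshold > 1)
    msg <- c(msg, "essThreshold must be in (0, 1]")
  if (!object@initMode %in% c("prior", "upgma_guided"))
    msg <- c(msg, "initMode must be 'prior' or 'upgma_guided'")
  if (length(msg)) msg else TRUE
})

#' MH-MCMC baseline configuration
#'
#' Defaults reproduce the comparator budget: burn-in 50000 sweeps, 20000
#' retained sweeps, thinning 1.
#'
#' @slot burnIn discarded iterations.
#' @slot chainLength retained iterations.
#' @slot thinning keep-every.
#' @slot seed integer seed.
#' @slot thetaScale,kappaScale,piConcentration,rTree move tuning, as in
#'   [SMCConfig-class].
#' @slot updateKappa,updatePi logical switches.
#' @exportClass MCMCConfig
setClass("MCMCConfig",
  representation(burnIn = "integer", chainLength = "integer",
                 thinning = "integer", seed = "integer",
                 thetaScale = "numeric", kappaScale = "numeric",
                 piConcentration = "numeric", rTree = "integer",
                 updateKappa = "logical", updatePi = "logical"))

setValidity("MCMCConfig", function(object) {
  msg <- character()
  if (object@burnIn < 0) msg <- c(msg, "burnIn must be >= 0")
  if (object@chainLength < 1) msg <- c(msg, "chainLength must be >= 1")
  if (object@thinning < 1) msg <- c(msg, "thinning must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Weighted particle system
#'
#' N weighted states of the augmented space stored column-wise for speed:
#' per-particle Theta, kappa, pi, genealogy (parent pointers and node
#' times), cached log-likelihood and coalescent log-prior, plus
#' unnormalized log-weights, the current temperature index and the running
#' log-evidence estimate. Use [particleWeights()] for normalized weights
#' and [modelState()] to materialize one particle as a
#' [ModelState-class].
#'
#' @exportClass ParticleSystem
setClass("ParticleSystem",
  representation(theta = "numeric", kappa = "numeric", pi = "matrix",
                 parent = "matrix", times = "matrix",
                 loglik = "numeric", logCoal = "numeric",
                 logWeights = "numeric", t = "integer",
                 logEvidence = "numeric", tipLabels = "character",
                 model = "character"))

setValidity("ParticleSystem", function(object) {
  N <- length(object@theta)
  msg <- character()
  if (length(object@logWeights) != N) msg <- c(msg, "logWeights length != N")
  if (ncol(object@parent) != N || ncol(object@times) != N)
    msg <- c(msg, "genealogy matrices must have N columns")
  w <- particleWeights(object)
  if (abs(sum(w) - 1) > 1e-12) msg <- c(msg, "weights do not normalize")
  ess <- 1 / sum(w^2)
  if (ess < 1 - 1e-9 || ess > N + 1e-9) msg <- c(msg, "ESS outside [1, N]")
  if (length(msg)) msg else TRUE
})

#' Posterior sample of (Theta, lambda, genealogy)
#'
#' Weighted draws returned by [runSMC()] (final particle cloud) or
#' [runMCMC()] (equally weighted post-burn-in chain states). Summaries via
#' [posteriorSummary()].
#'
#' @slot theta,kappa numeric sample vectors.
#' @slot pi sample matrix (draws x 4).
#' @slot weights normalized weights.
#' @slot logEvidence SMC log-evidence estimate (NA for MCMC).
#' @slot essTrace per-temperature ESS (SMC only).
#' @slot epsilons tempering schedule used (SMC only).
#' @slot acceptRates named acceptance-rate vector from the move kernels.
#' @slot trees list of [Genealogy-class] draws (possibly empty).
#' @slot method `"smc"` or `"mcmc"`.
#' @exportClass PosteriorResult
setClass("PosteriorResult",
  representation(theta = "numeric", kappa = "numeric", pi = "matrix",
                 weights = "numeric", logEvidence = "numeric",
                 essTrace = "numeric", epsilons = "numeric",
                 acceptRates = "numeric", trees = "list",
                 method = "character"))

#' Simulation specification with known truth
#'
#' @slot thetaTrue generating scaled mutation rate.
#' @slot m sample size (sequences).
#' @slot l sites.
#' @slot model generating [SubstitutionModel-class].
#' @slot seed integer seed.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(thetaTrue = "numeric", m = "integer", l = "integer",
                 model = "SubstitutionModel", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@thetaTrue <= 0) msg <- c(msg, "thetaTrue must be positive")
  if (object@m < 2) msg <- c(msg, "m must be >= 2")
  if (object@l < 1) msg <- c(msg, "l must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Experiment grid over (Theta, l, model)
#'
#' @slot thetas true Theta values.
#' @slot lengths sequence lengths.
#' @slot m sample size.
#' @slot models character vector of model ids.
#' @slot replicates replicate datasets per cell.
#' @slot seed top-level seed; per-cell substream seeds are derived from it.
#' @exportClass ExperimentGrid
setClass("ExperimentGrid",
  representation(thetas = "numeric", lengths = "integer", m = "integer",
                 models = "character", replicates = "integer",
                 seed = "integer"))

setValidity("ExperimentGrid", function(object) {
  msg <- character()
  if (!length(object@thetas) || any(object@thetas <= 0))
    msg <- c(msg, "thetas must be positive and nonempty")
  if (!length(object@lengths) || any(object@lengths < 1))
    msg <- c(msg, "lengths must be positive and nonempty")
  if (object@m < 2) msg <- c(msg, "m must be >= 2")
  if (!length(object@models) || !all(object@models %in% c("K80", "F84")))
    msg <- c(msg, "models must be among K80, F84")
  if (object@replicates < 1) msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})
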