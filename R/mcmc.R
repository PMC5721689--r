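# MH-MCMC baseline: a single chain targeting the full posterior
# p(Theta, lambda, genealogy | D), using exactly the SMC mutation kernel
# at tempering power 1, so the comparison between the two samplers is
# move-matched.

#' Construct an MCMC configuration
#'
#' Defaults reproduce the comparator budget: 50000 burn-in sweeps and
#' 20000 retained sweeps (thinning 1).
#'
#' @param burnIn discarded sweeps.
#' @param chainLength retained sweeps.
#' @param thinning keep every `thinning`-th sweep after burn-in.
#' @param seed integer seed.
#' @param thetaScale,kappaScale,piConcentration,rTree move tuning; same
#'   meaning as in [smcConfig()].
#' @param updateKappa,updatePi estimate these lambda components.
#' @return an [MCMCConfig-class].
#' @export
mcmcConfig <- function(burnIn = 50000, chainLength = 20000, thinning = 1,
                       seed = 1, thetaScale = 0.2, kappaScale = 0.2,
                       piConcentration = 200, rTree = 3,
                       updateKappa = TRUE, updatePi = TRUE) {
  obj <- new("MCMCConfig", burnIn = as.integer(burnIn),
             chainLength = as.integer(chainLength),
             thinning = as.integer(thinning), seed = as.integer(seed),
             thetaScale = as.numeric(thetaScale),
             kappaScale = as.numeric(kappaScale),
             piConcentration = as.numeric(piConcentration),
             rTree = as.integer(rTree),
             updateKappa = as.logical(updateKappa),
             updatePi = as.logical(updatePi))
  validObject(obj)
  obj
}

#' Run the MH-MCMC baseline sampler
#'
#' A single chain over (Theta, lambda, genealogy) initialized from the
#' joint prior (optionally from a supplied state), using the same move
#' kernel as the SMC sampler at eps = 1. Summaries come from the
#' post-burn-in, thinned sweep states with equal weights.
#'
#' @param aln a [SequenceAlignment-class].
#' @param model substitution model id, `"K80"` or `"F84"`.
#' @param priors a [PriorSpec-class].
#' @param mcfg an [MCMCConfig-class].
#' @param init optional [ModelState-class] to start from (default: a
#'   joint prior draw).
#' @param kappaFixed optional fixed kappa when `updateKappa = FALSE`.
#' @return a [PosteriorResult-class] (method `"mcmc"`).
#' @export
runMCMC <- function(aln, model = c("K80", "F84"), priors = priorSpec(),
                    mcfg = mcmcConfig(), init = NULL,
                    kappaFixed = NA_real_) {
  stopifnot(is(aln, "SequenceAlignment"), is(mcfg, "MCMCConfig"))
  model <- match.arg(model)
  set.seed(mcfg@seed)
  thetaMax <- .resolve_theta_max(priors, aln)
  m <- nSequences(aln)
  if (is.null(init)) {
    theta0 <- runif(1, 0, thetaMax)
    lam <- sampleLambdaPrior(model, priors)
    if (!mcfg@updateKappa && !is.na(kappaFixed))
      lam <- substitutionModel(model, kappa = kappaFixed, pi = lam@pi)
    gen0 <- sampleGenealogy(m, theta0, tipLabels = aln@ids)
  } else {
    stopifnot(is(init, "ModelState"))
    theta0 <- init@theta
    lam <- init@params
    gen0 <- init@gen
  }
  inp <- .pruning_inputs(aln, gen0)
  res <- .mcmc_chain_cpp(theta0, lam@kappa, lam@pi,
                         inp$parent0, gen0@times, inp$tipLik, inp$counts,
                         m, .MODEL_ID[[model]], 1.0, mcfg@burnIn,
                         mcfg@chainLength, mcfg@thinning,
                         thetaMax, priors@kappaMax, priors@alpha,
                         mcfg@thetaScale, mcfg@kappaScale,
                         mcfg@piConcentration, mcfg@rTree, TRUE,
                         mcfg@updateKappa, model == "F84" && mcfg@updatePi)
  n <- length(res$theta)
  acc <- vapply(res$accept, function(a) a[1] / max(a[2], 1), numeric(1))
  parent1 <- res$finalParent + 1L
  parent1[res$finalParent < 0L] <- 0L
  finalTree <- genealogy(parent1, res$finalTimes, tipLabels(gen0))
  new("PosteriorResult", theta = res$theta, kappa = res$kappa,
      pi = res$pi, weights = rep(1 / n, n), logEvidence = NA_real_,
      essTrace = numeric(0), epsilons = numeric(0), acceptRates = acc,
      trees = list(finalTree), method = "mcmc")
}
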