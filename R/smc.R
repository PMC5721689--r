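# Likelihood-tempered sequential Monte Carlo over H = (Theta, lambda,
# genealogy). The intermediate targets are pi_t(H) \propto p(H) p(D|H)^eps_t
# with a nondecreasing schedule eps_1 = 0, ..., eps_T = 1. With
# pi_t-invariant MCMC forward kernels and the matching backward-kernel
# choice, the incremental weight collapses to p(D|H_{t-1})^(eps_t -
# eps_{t-1}), so only cached log-likelihoods enter the reweighting.
# Degeneracy is monitored by ESS = 1/sum(w^2) and countered by systematic
# resampling below a threshold fraction of N.

.log_sum_exp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

#' Quadratic tempering schedule
#'
#' `eps_t = ((t-1)/(T-1))^2`, concentrating temperature steps at low
#' powers where the target changes fastest.
#'
#' @param T number of temperatures (>= 2).
#' @return numeric schedule from 0 to 1.
#' @export
quadraticSchedule <- function(T = 50) {
  if (T < 2) stop("need at least 2 temperatures")
  ((seq_len(T) - 1) / (T - 1))^2
}

#' Construct an SMC configuration
#'
#' Defaults: N = 500 particles, quadratic schedule with T = 50 powers,
#' 5 MH sweeps per particle per temperature, systematic resampling below
#' ESS = N/2, UPGMA-guided initialization.
#'
#' @param model substitution model id, `"K80"` or `"F84"`.
#' @param nParticles particle count N.
#' @param epsilons tempering schedule (0 to 1, nondecreasing).
#' @param rMcmc MH sweeps per particle per temperature.
#' @param essThreshold resample when ESS < essThreshold * N.
#' @param priors a [PriorSpec-class].
#' @param seed integer seed for the whole run.
#' @param initMode `"upgma_guided"` or `"prior"`.
#' @param thetaScale,kappaScale lognormal random-walk scales.
#' @param piConcentration Dirichlet proposal concentration.
#' @param rTree genealogy moves per sweep.
#' @param updateKappa,updatePi estimate these lambda components
#'   (`updatePi` only applies to F84).
#' @param kappaFixed,piFixed values used when the corresponding update is
#'   switched off (default: drawn once from the prior).
#' @return an [SMCConfig-class].
#' @export
smcConfig <- function(model = c("K80", "F84"), nParticles = 500,
                      epsilons = quadraticSchedule(50), rMcmc = 5,
                      essThreshold = 0.5, priors = priorSpec(), seed = 1,
                      initMode = c("upgma_guided", "prior"),
                      thetaScale = 0.2, kappaScale = 0.2,
                      piConcentration = 200, rTree = 3,
                      updateKappa = TRUE, updatePi = TRUE,
                      kappaFixed = NA_real_, piFixed = NA_real_) {
  model <- match.arg(model)
  initMode <- match.arg(initMode)
  obj <- new("SMCConfig", model = model,
             nParticles = as.integer(nParticles),
             epsilons = as.numeric(epsilons), rMcmc = as.integer(rMcmc),
             essThreshold = as.numeric(essThreshold), priors = priors,
             seed = as.integer(seed), initMode = initMode,
             thetaScale = as.numeric(thetaScale),
             kappaScale = as.numeric(kappaScale),
             piConcentration = as.numeric(piConcentration),
             rTree = as.integer(rTree),
             updateKappa = as.logical(updateKappa),
             updatePi = as.logical(updatePi),
             kappaFixed = as.numeric(kappaFixed),
             piFixed = as.numeric(piFixed))
  validObject(obj)
  obj
}

#' @describeIn smcConfig particle count of a particle system
#' @param x a `ParticleSystem`
#' @export
setMethod("nParticles", "ParticleSystem", function(x) length(x@theta))

#' @describeIn smcConfig normalized particle weights
#' @export
setMethod("particleWeights", "ParticleSystem", function(x) {
  lw <- x@logWeights - .log_sum_exp(x@logWeights)
  exp(lw)
})

#' @describeIn smcConfig running log-evidence estimate
#' @export
setMethod("logEvidence", "ParticleSystem", function(x) x@logEvidence)

#' @describeIn smcConfig materialize particle `i` as a
#'   [ModelState-class] (caches included)
#' @param i particle index
#' @export
setMethod("modelState", "ParticleSystem", function(x, i) {
  m <- length(x@tipLabels)
  gen <- genealogy(x@parent[, i], x@times[, i], x@tipLabels)
  params <- substitutionModel(x@model, kappa = x@kappa[i], pi = x@pi[i, ])
  new("ModelState", theta = x@theta[i], params = params, gen = gen,
      cachedLoglik = x@loglik[i], cachedLogPrior = x@logCoal[i])
})

setMethod("show", "ParticleSystem", function(object) {
  w <- particleWeights(object)
  cat("ParticleSystem:", nParticles(object), "particles (", object@model,
      "), temperature index", object@t, ", ESS =",
      format(1 / sum(w^2), digits = 5), "\n")
})

# per-particle pruning log-likelihoods for the columnar arrays
.loglik_columns <- function(tipLik, counts, m, modelId, parent, times,
                            kappa, pi) {
  N <- ncol(parent)
  out <- numeric(N)
  for (n in seq_len(N)) {
    p0 <- parent[, n] - 1L  # -1 at root
    el <- numeric(length(p0))
    nr <- parent[, n] != 0L
    el[nr] <- times[parent[nr, n], n] - times[nr, n]
    out[n] <- .pruning_loglik_cpp(p0, el, tipLik, counts, m, modelId,
                                  kappa[n], pi[n, ])
  }
  out
}

.coal_columns <- function(parent, times, theta, m) {
  N <- ncol(parent)
  nnode <- nrow(parent)
  vapply(seq_len(N), function(n)
    .coal_log_prior_cpp(times[(m + 1L):nnode, n], m, theta[n]), numeric(1))
}

#' Initialize the particle system at eps = 0
#'
#' Draws N states from the joint prior p(lambda) p(Theta) p(gen | Theta)
#' with equal weights 1/N. Under UPGMA-guided initialization every
#' particle shares the UPGMA topology while its node times are redrawn
#' from the coalescent prior (given the particle's Theta) in the
#' topology's rank order.
#'
#' @param aln a [SequenceAlignment-class].
#' @param cfg an [SMCConfig-class].
#' @return a [ParticleSystem-class] at temperature index 1.
#' @export
initParticles <- function(aln, cfg) {
  stopifnot(is(aln, "SequenceAlignment"), is(cfg, "SMCConfig"))
  N <- cfg@nParticles
  m <- nSequences(aln)
  nnode <- 2L * m - 1L
  thetaMax <- .resolve_theta_max(cfg@priors, aln)
  theta <- runif(N, 0, thetaMax)
  kappa <- numeric(N)
  pim <- matrix(0.25, N, 4)
  for (n in seq_len(N)) {
    lam <- sampleLambdaPrior(cfg@model, cfg@priors)
    kappa[n] <- lam@kappa
    pim[n, ] <- lam@pi
  }
  if (!cfg@updateKappa && !is.na(cfg@kappaFixed)) kappa[] <- cfg@kappaFixed
  if (cfg@model == "F84" && !cfg@updatePi && !anyNA(cfg@piFixed))
    pim <- matrix(cfg@piFixed, N, 4, byrow = TRUE)

  guide <- if (cfg@initMode == "upgma_guided") upgmaTree(aln) else NULL
  parent <- matrix(0L, nnode, N)
  times <- matrix(0, nnode, N)
  for (n in seq_len(N)) {
    gen <- if (is.null(guide)) {
      sampleGenealogy(m, theta[n], tipLabels = aln@ids)
    } else {
      .redraw_times(guide, theta[n])
    }
    parent[, n] <- gen@parent
    times[, n] <- gen@times
  }
  loglik <- .loglik_columns(aln@patterns$tipLik, aln@patterns$counts, m,
                            .MODEL_ID[[cfg@model]], parent, times, kappa, pim)
  logCoal <- .coal_columns(parent, times, theta, m)
  ps <- new("ParticleSystem", theta = theta, kappa = kappa, pi = pim,
            parent = parent, times = times, loglik = loglik,
            logCoal = logCoal, logWeights = rep(0, N), t = 1L,
            logEvidence = 0, tipLabels = aln@ids, model = cfg@model)
  validObject(ps)
  ps
}

#' Incremental log-weights for a temperature step
#'
#' With MCMC forward kernels and the matching backward kernels the
#' incremental weight of particle n is `p(D|H_n)^(epsNext - epsPrev)`,
#' evaluated at the current (pre-move) state via its cached
#' log-likelihood.
#'
#' @param ps a [ParticleSystem-class].
#' @param epsPrev,epsNext previous and next tempering powers
#'   (`epsNext >= epsPrev`).
#' @return N-vector of incremental log-weights (to be added to the
#'   existing log-weights).
#' @export
incrementalLogWeights <- function(ps, epsPrev, epsNext) {
  stopifnot(is(ps, "ParticleSystem"))
  if (epsNext < epsPrev) stop("epsNext must be >= epsPrev")
  (epsNext - epsPrev) * ps@loglik
}

#' Effective sample size of normalized weights
#'
#' `ESS = 1 / sum(w^2)`, between 1 (degenerate) and N (uniform).
#'
#' @param weights normalized weights (must sum to 1).
#' @return scalar in [1, N].
#' @export
effectiveSampleSize <- function(weights) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be normalized (nonnegative, summing to 1)")
  1 / sum(weights^2)
}

#' Systematic resampling
#'
#' Draws N particles with expected copy count `N * w_n` using a single
#' uniform offset (lowest-variance standard scheme); weights reset to 1/N.
#' The running log-evidence is unaffected.
#'
#' @param ps a [ParticleSystem-class].
#' @return the resampled [ParticleSystem-class].
#' @export
resampleParticles <- function(ps) {
  stopifnot(is(ps, "ParticleSystem"))
  N <- nParticles(ps)
  w <- particleWeights(ps)
  idx <- .systematic_indices(w)
  initialize(ps, theta = ps@theta[idx], kappa = ps@kappa[idx],
             pi = ps@pi[idx, , drop = FALSE],
             parent = ps@parent[, idx, drop = FALSE],
             times = ps@times[, idx, drop = FALSE],
             loglik = ps@loglik[idx], logCoal = ps@logCoal[idx],
             logWeights = rep(0, N))
}

.systematic_indices <- function(w) {
  N <- length(w)
  u <- (runif(1) + seq_len(N) - 1) / N
  cw <- cumsum(w)
  cw[N] <- 1  # guard against rounding
  findInterval(u, cw, left.open = TRUE) + 1L
}

# mutation pass: cfg-specified MH sweeps for every particle at power eps
.mutate_particles <- function(ps, aln, cfg, eps, thetaMax, nSweeps) {
  res <- .smc_pass_cpp(ps@theta, ps@kappa, ps@pi,
                       ps@parent - 1L,  # 0-based, -1 at root
                       ps@times, ps@loglik, ps@logCoal,
                       aln@patterns$tipLik, aln@patterns$counts,
                       length(ps@tipLabels), .MODEL_ID[[ps@model]], eps,
                       nSweeps, thetaMax, cfg@priors@kappaMax,
                       cfg@priors@alpha, cfg@thetaScale, cfg@kappaScale,
                       cfg@piConcentration, cfg@rTree, TRUE,
                       cfg@updateKappa, ps@model == "F84" && cfg@updatePi)
  parent1 <- res$parent + 1L
  parent1[res$parent < 0L] <- 0L
  list(ps = initialize(ps, theta = res$theta, kappa = res$kappa,
                       pi = res$pi, parent = parent1, times = res$times,
                       loglik = res$loglik, logCoal = res$logCoal),
       accept = res$accept)
}

#' One pi_t-invariant MH sweep on a single model state
#'
#' Applies the SMC mutation kernel (Theta walk, kappa walk, pi proposal
#' for F84, then `rTree` genealogy moves) once to `state`, targeting
#' `p(H) p(D|H)^eps`. Rejected proposals leave the corresponding
#' component unchanged; caches are refreshed on return.
#'
#' @param state a [ModelState-class].
#' @param eps tempering power in [0, 1].
#' @param aln the [SequenceAlignment-class].
#' @param cfg an [SMCConfig-class].
#' @return the updated [ModelState-class].
#' @export
mcmcMove <- function(state, eps, aln, cfg) {
  stopifnot(is(state, "ModelState"))
  if (eps < 0 || eps > 1) stop("eps must lie in [0, 1]")
  gen <- state@gen
  ps <- new("ParticleSystem", theta = state@theta,
            kappa = state@params@kappa,
            pi = matrix(state@params@pi, 1, 4),
            parent = matrix(gen@parent, ncol = 1),
            times = matrix(gen@times, ncol = 1),
            loglik = state@cachedLoglik, logCoal = state@cachedLogPrior,
            logWeights = 0, t = 1L, logEvidence = 0,
            tipLabels = gen@tipLabels, model = state@params@model)
  thetaMax <- .resolve_theta_max(cfg@priors, aln)
  out <- .mutate_particles(ps, aln, cfg, eps, thetaMax, nSweeps = 1L)
  modelState(out$ps, 1L)
}

#' Run the tempered SMC sampler
#'
#' Initializes N particles at eps = 0, then for each subsequent power:
#' reweights by the cached likelihoods raised to the power increment,
#' updates the running log-evidence, resamples systematically when the
#' ESS drops below the threshold, and applies `rMcmc` pi_t-invariant MH
#' sweeps to every particle. The final weighted cloud targets the joint
#' posterior p(Theta, lambda, genealogy | D). Deterministic given the
#' config seed.
#'
#' @param aln a [SequenceAlignment-class].
#' @param cfg an [SMCConfig-class].
#' @param verbose log per-temperature ESS, resampling events and
#'   acceptance rates via `message()`.
#' @return a [PosteriorResult-class] (method `"smc"`).
#' @export
runSMC <- function(aln, cfg, verbose = FALSE) {
  stopifnot(is(aln, "SequenceAlignment"), is(cfg, "SMCConfig"))
  set.seed(cfg@seed)
  thetaMax <- .resolve_theta_max(cfg@priors, aln)
  ps <- initParticles(aln, cfg)
  if (all(!is.finite(ps@loglik)))
    stop("all initial particles have log-likelihood -Inf; check the ",
         "alignment and model")
  eps <- cfg@epsilons
  N <- cfg@nParticles
  essTrace <- numeric(length(eps))
  essTrace[1] <- N
  accTot <- NULL
  logZ <- 0
  for (t in 2:length(eps)) {
    incr <- incrementalLogWeights(ps, eps[t - 1], eps[t])
    lw <- ps@logWeights - .log_sum_exp(ps@logWeights)  # log normalized
    logZ <- logZ + .log_sum_exp(lw + incr)
    ps@logWeights <- ps@logWeights + incr
    w <- particleWeights(ps)
    ess <- effectiveSampleSize(w)
    resampled <- ess < cfg@essThreshold * N
    if (resampled) ps <- resampleParticles(ps)
    out <- .mutate_particles(ps, aln, cfg, eps[t], thetaMax,
                             nSweeps = cfg@rMcmc)
    ps <- out$ps
    ps@t <- t
    essTrace[t] <- ess
    accTot <- if (is.null(accTot)) out$accept else
      Map(`+`, accTot, out$accept)
    if (verbose)
      message(sprintf(
        "t=%d eps=%.4f ESS=%.1f%s acc(theta=%.2f kappa=%.2f tree=%.2f)",
        t, eps[t], ess, if (resampled) " [resampled]" else "",
        out$accept$theta[1] / max(out$accept$theta[2], 1),
        out$accept$kappa[1] / max(out$accept$kappa[2], 1),
        (out$accept$slide[1] + out$accept$exchange[1]) /
          max(out$accept$slide[2] + out$accept$exchange[2], 1)))
  }
  ps@logEvidence <- logZ
  w <- particleWeights(ps)
  acc <- vapply(accTot, function(a) a[1] / max(a[2], 1), numeric(1))
  trees <- lapply(seq_len(N), function(n)
    genealogy(ps@parent[, n], ps@times[, n], ps@tipLabels))
  new("PosteriorResult", theta = ps@theta, kappa = ps@kappa, pi = ps@pi,
      weights = w, logEvidence = logZ, essTrace = essTrace,
      epsilons = eps, acceptRates = acc, trees = trees, method = "smc")
}

# ---------------------------------------------------------------------------
# Posterior summaries
# ---------------------------------------------------------------------------

.weighted_mean_sd <- function(x, w) {
  mu <- sum(w * x)
  c(mean = mu, sd = sqrt(max(sum(w * (x - mu)^2), 0)))
}

# weighted empirical-CDF quantile, lower interpolation: smallest sample
# value whose cumulative weight reaches p
.weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  cw <- cumsum(w[ord])
  vapply(probs, function(p) x[ord][which(cw >= p - 1e-12)[1]], numeric(1))
}

.summary_table <- function(theta, kappa, pim, w) {
  pars <- cbind(theta = theta, kappa = kappa,
                piA = pim[, 1], piC = pim[, 2], piG = pim[, 3],
                piT = pim[, 4])
  probs <- c(0.025, 0.5, 0.975)
  out <- t(apply(pars, 2, function(x) {
    ms <- .weighted_mean_sd(x, w)
    c(ms, .weighted_quantile(x, w, probs))
  }))
  colnames(out) <- c("mean", "sd", "q2.5", "q50", "q97.5")
  as.data.frame(out)
}

#' @describeIn posteriorSummary weighted posterior moments and quantiles
#'   (lower-interpolation empirical CDF) of Theta and each lambda
#'   component from a particle system
#' @param object a `ParticleSystem` or `PosteriorResult`
#' @param ... unused
#' @export
setMethod("posteriorSummary", "ParticleSystem", function(object, ...) {
  .summary_table(object@theta, object@kappa, object@pi,
                 particleWeights(object))
})

#' @describeIn posteriorSummary same, from a posterior result
#' @export
setMethod("posteriorSummary", "PosteriorResult", function(object, ...) {
  .summary_table(object@theta, object@kappa, object@pi, object@weights)
})

setMethod("show", "PosteriorResult", function(object) {
  s <- posteriorSummary(object)
  cat("PosteriorResult (", object@method, "), ", length(object@theta),
      " draws\n", sep = "")
  cat(sprintf("  Theta: mean %.6g, sd %.3g, 95%% CrI [%.6g, %.6g]\n",
              s["theta", "mean"], s["theta", "sd"], s["theta", "q2.5"],
              s["theta", "q97.5"]))
  if (is.finite(object@logEvidence))
    cat(sprintf("  log-evidence: %.4f\n", object@logEvidence))
})
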