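# Finite-sites substitution models (K80, F84) and priors on their
# parameters.
#
# kappa convention (both models): the expected transition/transversion
# ratio under the stationary distribution, so the prior U(0, kappaMax)
# always refers to the same observable quantity. For K80 this maps to
# per-unit instantaneous rates alpha = kappa/(kappa+1) (transition) and
# beta = 1/(2 kappa + 2) (each transversion), i.e. alpha/beta = 2 kappa.
# For F84 the internal shape parameter is solved from (kappa, pi); see
# src/coalsmc_core.cpp. Branch lengths are expected substitutions per
# site in both models (rate matrices normalized to unit expected rate).

.MODEL_ID <- c(K80 = 0L, F84 = 1L)

#' Construct substitution-model parameters
#'
#' @param model `"K80"` or `"F84"`.
#' @param kappa expected transition/transversion ratio (>= 0).
#' @param pi base frequencies (A, C, G, T); ignored (fixed at 1/4) for
#'   K80.
#' @return a [SubstitutionModel-class].
#' @export
substitutionModel <- function(model = c("K80", "F84"), kappa = 2,
                              pi = rep(0.25, 4)) {
  model <- match.arg(model)
  if (model == "K80") pi <- rep(0.25, 4)
  obj <- new("SubstitutionModel", model = model, kappa = as.numeric(kappa),
             pi = as.numeric(pi))
  validObject(obj)
  obj
}

setMethod("show", "SubstitutionModel", function(object) {
  cat(object@model, "model: kappa =", format(object@kappa, digits = 4),
      "pi = (", paste(format(object@pi, digits = 3), collapse = ", "), ")\n")
})

#' Transition-probability matrix
#'
#' Closed-form K80 or F84 (a Tamura-Nei special case) transition
#' probabilities for a branch of length `t` expected substitutions per
#' site. Rows index the ancestral state in order A, C, G, T.
#'
#' @param params a [SubstitutionModel-class].
#' @param t nonnegative branch length.
#' @return 4 x 4 row-stochastic matrix satisfying detailed balance with
#'   respect to `params@pi`.
#' @export
transitionMatrix <- function(params, t) {
  stopifnot(is(params, "SubstitutionModel"))
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop("branch length t must be a nonnegative scalar")
  P <- .transition_matrix_cpp(.MODEL_ID[[params@model]], params@kappa,
                              params@pi, t)
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

#' Construct a prior specification
#'
#' @param thetaMax upper bound of Theta ~ U(0, thetaMax); `NA` means
#'   "resolve from the data at run time" as
#'   `max(10 * wattersonTheta(aln), 0.1)`, a weakly informative,
#'   Watterson-anchored bound.
#' @param kappaMax upper bound of kappa ~ U(0, kappaMax).
#' @param alpha Dirichlet concentration for pi (F84).
#' @return a [PriorSpec-class].
#' @export
priorSpec <- function(thetaMax = NA_real_, kappaMax = 20,
                      alpha = c(1, 1, 1, 1)) {
  obj <- new("PriorSpec", thetaMax = as.numeric(thetaMax),
             kappaMax = as.numeric(kappaMax), alpha = as.numeric(alpha))
  validObject(obj)
  obj
}

# resolve a possibly data-driven thetaMax
.resolve_theta_max <- function(priors, aln) {
  if (!is.na(priors@thetaMax)) return(priors@thetaMax)
  max(10 * wattersonTheta(aln), 0.1)
}

.ldirichlet <- function(x, alpha) {
  if (any(x <= 0)) return(-Inf)
  lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * log(x))
}

# does (kappa, pi) lie inside the F84 support (nonnegative rates)?
.f84_supported <- function(kappa, pi) {
  piR <- pi[1] + pi[3]; piY <- pi[2] + pi[4]
  if (piR <= 0 || piY <= 0) return(FALSE)
  den <- pi[1] * pi[3] / piR + pi[2] * pi[4] / piY
  if (den <= 0) return(FALSE)
  kF <- (kappa * piR * piY - pi[1] * pi[3] - pi[2] * pi[4]) / den
  (1 + kF / piR > 0) && (1 + kF / piY > 0)
}

#' Log prior density of the substitution parameters
#'
#' Uniform on kappa plus, for F84, Dirichlet(alpha) on pi; `-Inf` outside
#' the support (including (kappa, pi) combinations for which the F84 rate
#' matrix would have negative entries).
#'
#' @param params a [SubstitutionModel-class].
#' @param priors a [PriorSpec-class].
#' @return log-density scalar (possibly `-Inf`).
#' @export
logPriorLambda <- function(params, priors) {
  stopifnot(is(params, "SubstitutionModel"), is(priors, "PriorSpec"))
  if (params@kappa < 0 || params@kappa > priors@kappaMax) return(-Inf)
  lp <- -log(priors@kappaMax)
  if (params@model == "F84") {
    if (!.f84_supported(params@kappa, params@pi)) return(-Inf)
    lp <- lp + .ldirichlet(params@pi, priors@alpha)
  }
  lp
}

#' Draw substitution parameters from the prior
#'
#' kappa ~ U(0, kappaMax); pi ~ Dirichlet(alpha) for F84 (redrawn until
#' inside the F84 support), fixed at 1/4 for K80.
#'
#' @param model `"K80"` or `"F84"`.
#' @param priors a [PriorSpec-class].
#' @return a [SubstitutionModel-class] draw.
#' @export
sampleLambdaPrior <- function(model = c("K80", "F84"), priors = priorSpec()) {
  model <- match.arg(model)
  repeat {
    kappa <- runif(1, 0, priors@kappaMax)
    if (model == "K80") return(substitutionModel("K80", kappa = kappa))
    g <- rgamma(4, shape = priors@alpha, rate = 1)
    pi <- g / sum(g)
    if (all(pi > 1e-8) && .f84_supported(kappa, pi))
      return(substitutionModel("F84", kappa = kappa, pi = pi))
  }
}
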