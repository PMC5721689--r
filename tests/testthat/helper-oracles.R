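# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: rate matrices are exponentiated with
# Matrix::expm, likelihoods are obtained by exhaustive enumeration over
# internal states, UPGMA by a naive O(m^3) agglomeration, and the
# two-sequence posterior by dense 2-D quadrature.

# --- rate matrices (A, C, G, T; transitions A<->G, C<->T) -------------------

# K80 rate matrix normalized to one expected substitution per unit time,
# with kappa the expected ts/tv ratio (alpha/beta = 2 kappa)
oracle_k80_Q <- function(kappa) {
  a <- kappa / (kappa + 1)
  b <- 1 / (2 * kappa + 2)
  Q <- matrix(b, 4, 4)
  Q[1, 3] <- Q[3, 1] <- Q[2, 4] <- Q[4, 2] <- a
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# F84 rate matrix; the shape parameter is found numerically from the
# expected ts/tv ratio (independent of the package's algebraic mapping)
oracle_f84_Q <- function(kappa, pi) {
  piR <- pi[1] + pi[3]
  piY <- pi[2] + pi[4]
  tsRatio <- function(kF) {
    aR <- 1 + kF / piR
    aY <- 1 + kF / piY
    (pi[1] * pi[3] * aR + pi[2] * pi[4] * aY) / (piR * piY)
  }
  lower <- -min(piR, piY) + 1e-9
  kF <- uniroot(function(k) tsRatio(k) - kappa, c(lower, 1e4))$root
  aR <- 1 + kF / piR
  aY <- 1 + kF / piY
  purine <- c(TRUE, FALSE, TRUE, FALSE)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) if (i != j) {
    Q[i, j] <- if (purine[i] == purine[j])
      pi[j] * (if (purine[i]) aR else aY) else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  Q / -sum(pi * diag(Q))
}

oracle_pmat <- function(params, t) {
  Q <- if (params@model == "K80") oracle_k80_Q(params@kappa)
       else oracle_f84_Q(params@kappa, params@pi)
  as.matrix(Matrix::expm(Q * t))
}

# --- exhaustive-likelihood oracle -------------------------------------------

# log Pr(D | gen, params) by brute-force summation over all internal-node
# state assignments, one site at a time
oracle_loglik <- function(aln, gen, params) {
  m <- nSequences(aln)
  nnode <- 2L * m - 1L
  root <- which(gen@parent == 0L)
  internal <- (m + 1L):nnode
  base <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  # per-node transition matrices (package transitionMatrix is itself
  # oracle-checked against expm, so use expm here too)
  P <- vector("list", nnode)
  for (v in seq_len(nnode)) {
    if (gen@parent[v] != 0L)
      P[[v]] <- oracle_pmat(params, gen@times[gen@parent[v]] - gen@times[v])
  }
  grid <- as.matrix(expand.grid(rep(list(1:4), m - 1L)))
  ll <- 0
  for (site in seq_len(nSites(aln))) {
    obs <- base[aln@chars[, site]]
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(nnode)
      st[seq_len(m)] <- obs
      st[internal] <- grid[g, ]
      pr <- params@pi[st[root]]
      for (v in seq_len(nnode)) {
        if (v == root) next
        pr <- pr * P[[v]][st[gen@parent[v]], st[v]]
      }
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# --- brute-force UPGMA -------------------------------------------------------

# naive average-linkage agglomeration with lowest-index tie-breaking;
# returns a Newick string (heights halved into times)
oracle_upgma_newick <- function(D, labels) {
  m <- nrow(D)
  sizes <- rep(1, m)
  reps <- as.list(labels)
  heights <- rep(0, m)
  act <- seq_len(m)
  Dm <- D
  for (step in seq_len(m - 1)) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(act)[-length(act)]) {
      for (j in (i + 1):length(act)) {
        if (Dm[act[i], act[j]] < bestd - 1e-15) {
          bestd <- Dm[act[i], act[j]]
          best <- c(i, j)
        }
      }
    }
    a <- act[best[1]]
    b <- act[best[2]]
    h <- bestd / 2
    lab <- sprintf("(%s:%.15g,%s:%.15g)", reps[[a]], h - heights[a],
                   reps[[b]], h - heights[b])
    # merged cluster reuses slot a with size-weighted average distances
    newrow <- (sizes[a] * Dm[a, ] + sizes[b] * Dm[b, ]) /
      (sizes[a] + sizes[b])
    Dm[a, ] <- newrow
    Dm[, a] <- newrow
    Dm[a, a] <- 0
    sizes[a] <- sizes[a] + sizes[b]
    reps[[a]] <- lab
    heights[a] <- h
    act <- act[-best[2]]
  }
  paste0(reps[[act]], ";")
}

same_topology <- function(gen1, gen2) {
  ape::dist.topo(ape::unroot(asPhylo(gen1)), ape::unroot(asPhylo(gen2))) == 0
}

# --- two-sequence quadrature oracle -----------------------------------------

# K80 mismatch probabilities along total separation 2d, written out
# independently of the package kernels
oracle_k80_site_lik <- function(d2, kappa) {
  t <- 2 * d2
  a <- kappa / (kappa + 1)
  b <- 1 / (2 * kappa + 2)
  e1 <- exp(-4 * b * t)
  e2 <- exp(-2 * (a + b) * t)
  c(same = 0.25 * (0.25 + 0.25 * e1 + 0.5 * e2),
    ts = 0.25 * (0.25 + 0.25 * e1 - 0.5 * e2),
    tv = 0.25 * (0.25 - 0.25 * e1))
}

# pattern counts (same / transition / transversion) for an m=2 alignment
count_m2_patterns <- function(aln) {
  stopifnot(nSequences(aln) == 2)
  a <- aln@chars[1, ]
  b <- aln@chars[2, ]
  ts_pair <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
  c(same = sum(a == b), ts = sum(ts_pair(a, b)),
    tv = sum(a != b & !ts_pair(a, b)))
}

# dense trapezoid quadrature over (theta, d2) for the two-sequence model
# with fixed kappa; returns posterior mean of theta and the log-evidence
oracle_m2_quadrature <- function(counts, kappa, thetaMax,
                                 nTheta = 1200, nD = 1600, dMax = NULL) {
  if (is.null(dMax)) dMax <- 6 * thetaMax
  theta <- seq(thetaMax / nTheta, thetaMax, length.out = nTheta)
  d <- seq(dMax / nD, dMax, length.out = nD)
  sl <- vapply(d, function(x) {
    p <- oracle_k80_site_lik(x, kappa)
    counts["same"] * log(p["same"]) + counts["ts"] * log(p["ts"]) +
      counts["tv"] * log(p["tv"])
  }, numeric(1))
  # log joint on the grid: U(0,thetaMax) x Exp(2/theta) x likelihood
  lj <- outer(theta, d, function(th, dd)
    -log(thetaMax) + log(2 / th) - 2 * dd / th) +
    matrix(sl, nTheta, nD, byrow = TRUE)
  mx <- max(lj)
  f <- exp(lj - mx)
  wTheta <- rep(theta[2] - theta[1], nTheta)
  wD <- rep(d[2] - d[1], nD)
  wTheta[c(1, nTheta)] <- wTheta[1] / 2
  wD[c(1, nD)] <- wD[1] / 2
  Z <- as.numeric(t(wTheta) %*% f %*% wD)
  meanTheta <- as.numeric(t(wTheta * theta) %*% f %*% wD) / Z
  list(mean = meanTheta, logZ = log(Z) + mx)
}

# --- misc --------------------------------------------------------------------

random_alignment <- function(m, l, ids = paste0("s", seq_len(m))) {
  sequenceAlignment(matrix(sample(c("A", "C", "G", "T"), m * l,
                                  replace = TRUE), nrow = m), ids = ids)
}

# small SMC config for fast stochastic checks
test_smc_config <- function(model = "K80", seed = 1, ...) {
  smcConfig(model, nParticles = 150, epsilons = quadraticSchedule(25),
            rMcmc = 3, seed = seed, ...)
}
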