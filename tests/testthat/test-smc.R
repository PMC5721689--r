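# SMC machinery: initialization, weights, ESS, resampling, move kernel
# invariance, degenerate schedules, determinism, summaries.

test_that("initial particles are equally weighted prior draws", {
  set.seed(101)
  aln <- random_alignment(4, 30)
  cfg <- smcConfig("K80", nParticles = 400, initMode = "prior",
                   priors = priorSpec(thetaMax = 0.8), seed = 2)
  ps <- initParticles(aln, cfg)
  w <- particleWeights(ps)
  expect_true(all(abs(w - 1 / 400) < 1e-15))
  expect_equal(effectiveSampleSize(w), 400)
  # theta ~ U(0, thetaMax)
  expect_lt(abs(mean(ps@theta) - 0.4), 3 * sd(ps@theta) / sqrt(400))
  # caches agree with from-scratch recomputation
  for (i in c(1, 57, 400)) {
    st <- modelState(ps, i)
    expect_equal(st@cachedLoglik,
                 pruningLoglik(aln, st@gen, st@params), tolerance = 1e-9)
    expect_equal(st@cachedLogPrior,
                 coalescentLogPrior(st@gen, st@theta), tolerance = 1e-9)
  }
})

test_that("guided initialization shares the UPGMA topology with varying times", {
  set.seed(103)
  gen0 <- sampleGenealogy(5, 0.3)
  aln <- evolveSequences(gen0, substitutionModel("K80", kappa = 2), 500)
  cfg <- smcConfig("K80", nParticles = 50, initMode = "upgma_guided",
                   priors = priorSpec(thetaMax = 1), seed = 3)
  ps <- initParticles(aln, cfg)
  ut <- upgmaTree(aln)
  for (i in c(1, 25, 50))
    expect_true(same_topology(modelState(ps, i)@gen, ut))
  expect_gt(var(ps@times[nrow(ps@times), ]), 0)  # root times differ
})

test_that("incremental weights implement the tempered-likelihood power", {
  set.seed(107)
  aln <- random_alignment(3, 20)
  cfg <- smcConfig("K80", nParticles = 10, seed = 4,
                   priors = priorSpec(thetaMax = 0.5))
  ps <- initParticles(aln, cfg)
  expect_equal(incrementalLogWeights(ps, 0.3, 0.3), rep(0, 10))
  expect_equal(incrementalLogWeights(ps, 0.1, 0.4), 0.3 * ps@loglik)
  expect_error(incrementalLogWeights(ps, 0.4, 0.1), ">=")
  # equal log-likelihoods leave normalized weights unchanged
  ps@loglik <- rep(-50, 10)
  ps@logWeights <- log(runif(10))
  w0 <- particleWeights(ps)
  ps@logWeights <- ps@logWeights + incrementalLogWeights(ps, 0, 0.5)
  expect_equal(particleWeights(ps), w0, tolerance = 1e-12)
})

test_that("two-particle reweighting reproduces the hand-computed softmax", {
  # logliks (-10, -12), delta eps 0.1 -> softmax(-1.0, -1.2)
  w <- exp(c(-1.0, -1.2))
  w <- w / sum(w)
  expect_equal(round(w, 4), c(0.5498, 0.4502))
  set.seed(109)
  aln <- random_alignment(3, 10)
  cfg <- smcConfig("K80", nParticles = 2, seed = 5,
                   priors = priorSpec(thetaMax = 0.5))
  ps <- initParticles(aln, cfg)
  ps@loglik <- c(-10, -12)
  ps@logWeights <- ps@logWeights + incrementalLogWeights(ps, 0.2, 0.3)
  expect_equal(particleWeights(ps), w, tolerance = 1e-12)
})

test_that("effective sample size matches direct arithmetic", {
  expect_equal(effectiveSampleSize(rep(1 / 500, 500)), 500)
  expect_equal(effectiveSampleSize(c(1, rep(0, 9))), 1)
  expect_equal(effectiveSampleSize(c(0.5, 0.25, 0.25)), 1 / 0.375)
  expect_error(effectiveSampleSize(c(0.4, 0.4)), "normalized")
})

test_that("systematic resampling has the right copy counts", {
  set.seed(113)
  aln <- random_alignment(3, 10)
  cfg <- smcConfig("K80", nParticles = 10, seed = 6,
                   priors = priorSpec(thetaMax = 0.5))
  ps <- initParticles(aln, cfg)
  # equal weights: every particle copied exactly once
  rs <- resampleParticles(ps)
  expect_equal(sort(rs@theta), sort(ps@theta))
  # a degenerate weight vector: N copies of the heavy particle
  ps2 <- ps
  ps2@logWeights <- c(0, rep(-Inf, 9))
  rs2 <- resampleParticles(ps2)
  expect_true(all(rs2@theta == ps@theta[1]))
  expect_equal(particleWeights(rs2), rep(0.1, 10))
  # weights (0.7, 0.3, 0, ..., 0) at N=10: mean copy counts 7 and 3
  w <- c(0.7, 0.3, rep(0, 8))
  counts <- replicate(2000, sum(coalsmc:::.systematic_indices(w) == 1L))
  expect_lt(abs(mean(counts) - 7), 3 * sd(counts) / sqrt(2000) + 1e-12)
  expect_true(all(counts %in% c(7, 8)))  # systematic: floor/ceil of N*w
})

test_that("MH sweeps at eps = 0 leave the prior invariant", {
  set.seed(127)
  aln <- random_alignment(4, 12)
  cfg <- smcConfig("K80", nParticles = 4000, initMode = "prior",
                   priors = priorSpec(thetaMax = 0.6), rTree = 2, seed = 8)
  ps <- initParticles(aln, cfg)
  out <- coalsmc:::.mutate_particles(ps, aln, cfg, eps = 0,
                                     thetaMax = 0.6, nSweeps = 3L)
  # particles remain independent draws; theta must stay U(0, 0.6)
  ks <- suppressWarnings(ks.test(out$ps@theta, "punif", 0, 0.6))
  expect_gt(ks$p.value, 0.001)
  # kappa stays U(0, kappaMax)
  ks2 <- suppressWarnings(ks.test(out$ps@kappa, "punif", 0, 20))
  expect_gt(ks2$p.value, 0.001)
  # root times follow the prior mean E[TMRCA] = E[theta] (1 - 1/m)
  rt <- out$ps@times[7, ]
  expect_lt(abs(mean(rt) - 0.3 * 0.75), 4 * sd(rt) / sqrt(4000))
})

test_that("zero-scale proposals leave the state unchanged", {
  set.seed(131)
  gen0 <- sampleGenealogy(4, 0.2)
  aln <- evolveSequences(gen0, substitutionModel("K80", kappa = 2), 30)
  cfg <- smcConfig("K80", thetaScale = 0, kappaScale = 0, rTree = 0,
                   priors = priorSpec(thetaMax = 1), seed = 9)
  st <- new("ModelState", theta = 0.2,
            params = substitutionModel("K80", kappa = 2), gen = gen0,
            cachedLoglik = pruningLoglik(aln, gen0,
                                         substitutionModel("K80", kappa = 2)),
            cachedLogPrior = coalescentLogPrior(gen0, 0.2))
  moved <- mcmcMove(st, eps = 0.7, aln, cfg)
  expect_identical(moved@theta, st@theta)
  expect_identical(moved@params@kappa, st@params@kappa)
  expect_identical(moved@gen@times, st@gen@times)
})

test_that("with no data the sampler returns the prior exactly", {
  # zero-length alignment: likelihood identically 1, so every tempered
  # target is the prior and the evidence is 1
  set.seed(137)
  thetaMax <- 0.8
  aln0 <- sequenceAlignment(matrix(character(0), nrow = 5, ncol = 0),
                            ids = paste0("s", 1:5))
  cfg0 <- smcConfig("K80", nParticles = 600,
                    epsilons = quadraticSchedule(10), rMcmc = 2,
                    initMode = "prior",
                    priors = priorSpec(thetaMax = thetaMax), seed = 10)
  res <- runSMC(aln0, cfg0)
  expect_equal(res@logEvidence, 0, tolerance = 1e-9)
  s <- posteriorSummary(res)
  expect_lt(abs(s["theta", "mean"] - thetaMax / 2),
            3 * s["theta", "sd"] / sqrt(effectiveSampleSize(res@weights)))
  ks <- suppressWarnings(ks.test(res@theta, "punif", 0, thetaMax))
  expect_gt(ks$p.value, 0.001)
})

test_that("identical seeds give bit-identical runs", {
  set.seed(139)
  gen0 <- sampleGenealogy(6, 0.1)
  aln <- evolveSequences(gen0, substitutionModel("K80", kappa = 2), 80)
  cfg <- smcConfig("K80", nParticles = 60, epsilons = quadraticSchedule(8),
                   rMcmc = 2, seed = 77)
  r1 <- runSMC(aln, cfg)
  r2 <- runSMC(aln, cfg)
  expect_identical(posteriorSummary(r1), posteriorSummary(r2))
  expect_identical(r1@logEvidence, r2@logEvidence)
  r3 <- runSMC(aln, smcConfig("K80", nParticles = 60,
                              epsilons = quadraticSchedule(8), rMcmc = 2,
                              seed = 78))
  expect_false(identical(posteriorSummary(r1), posteriorSummary(r3)))
})

test_that("weights stay normalized and ESS bounded along a run", {
  set.seed(149)
  gen0 <- sampleGenealogy(5, 0.2)
  aln <- evolveSequences(gen0, substitutionModel("K80", kappa = 2), 60)
  cfg <- smcConfig("K80", nParticles = 80, epsilons = quadraticSchedule(12),
                   rMcmc = 2, seed = 21)
  res <- runSMC(aln, cfg)
  expect_true(all(res@essTrace >= 1 - 1e-9 & res@essTrace <= 80 + 1e-9))
  expect_equal(sum(res@weights), 1, tolerance = 1e-12)
  expect_true(all(res@weights >= 0))
})

test_that("posterior summaries match brute-force weighted moments", {
  # all particles identical
  theta <- rep(0.3, 5)
  w <- rep(0.2, 5)
  s <- coalsmc:::.summary_table(theta, rep(2, 5), matrix(0.25, 5, 4), w)
  expect_equal(s["theta", "mean"], 0.3)
  expect_equal(s["theta", "sd"], 0)
  # two particles, equal weights
  s2 <- coalsmc:::.summary_table(c(0, 1), c(1, 3), matrix(0.25, 2, 4),
                                 c(0.5, 0.5))
  expect_equal(s2["theta", "mean"], 0.5)
  expect_equal(s2["theta", "sd"], 0.5)
  # random weighted set against direct arithmetic
  set.seed(151)
  x <- rnorm(40)
  w <- runif(40); w <- w / sum(w)
  s3 <- coalsmc:::.summary_table(x, x, matrix(0.25, 40, 4), w)
  mu <- sum(w * x)
  expect_equal(s3["theta", "mean"], mu, tolerance = 1e-12)
  expect_equal(s3["theta", "sd"], sqrt(sum(w * (x - mu)^2)),
               tolerance = 1e-12)
  ord <- order(x)
  cw <- cumsum(w[ord])
  expect_equal(s3["theta", "q50"], x[ord][which(cw >= 0.5)[1]])
})
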