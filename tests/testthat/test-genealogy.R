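# Coalescent prior, genealogy simulation, UPGMA and Watterson's estimator.

make_gen_m2 <- function(d2) {
  genealogy(parent = c(3L, 3L, 0L), times = c(0, 0, d2),
            tipLabels = c("a", "b"))
}

test_that("coalescent log prior matches closed-form hand evaluations", {
  # m=2: density of Exp(2/theta) at d2=0 is 2/theta
  expect_equal(coalescentLogPrior(make_gen_m2(1e-12), theta = 1), log(2),
               tolerance = 1e-9)
  expect_equal(coalescentLogPrior(make_gen_m2(1e-12), theta = 2), 0,
               tolerance = 1e-9)
  # m=3, theta=0.5, d3=0.1, d2=0.2: hand-evaluated product of exponentials
  gen3 <- genealogy(parent = c(4L, 4L, 5L, 5L, 0L),
                    times = c(0, 0, 0, 0.1, 0.3),
                    tipLabels = c("a", "b", "c"))
  expect_equal(intervals(gen3), c(0.2, 0.1))  # d2, d3
  hand <- (log(6 / 0.5) - 6 * 0.1 / 0.5) + (log(2 / 0.5) - 2 * 0.2 / 0.5)
  expect_equal(coalescentLogPrior(gen3, 0.5), hand, tolerance = 1e-12)
})

test_that("coalescent prior rejects bad inputs", {
  expect_error(coalescentLogPrior(make_gen_m2(0.1), theta = 0), "positive")
  expect_error(coalescentLogPrior(make_gen_m2(0.1), theta = -1), "positive")
  expect_error(genealogy(parent = c(3L, 3L, 0L), times = c(0, 0.2, 0.1),
                         tipLabels = c("a", "b")))
})

test_that("coalescent prior integrates to one (importance check)", {
  # sample intervals from mismatched exponentials and average the ratio
  set.seed(42)
  m <- 4
  theta <- 0.3
  nrep <- 20000
  propRate <- 5
  ratios <- replicate(nrep, {
    d <- rexp(m - 1, rate = propRate)  # d for k = 2..m (any order)
    times <- cumsum(rev(d))
    gen <- genealogy(parent = c(5L, 5L, 6L, 7L, 6L, 7L, 0L),
                     times = c(0, 0, 0, 0, times),
                     tipLabels = paste0("t", 1:4))
    lq <- sum(dexp(d, propRate, log = TRUE))
    exp(coalescentLogPrior(gen, theta) - lq)
  })
  se <- sd(ratios) / sqrt(nrep)
  expect_lt(abs(mean(ratios) - 1), 3 * se)
})

test_that("sampled genealogies have coalescent interval moments", {
  set.seed(7)
  m <- 5
  theta <- 0.4
  nrep <- 10000
  ints <- t(replicate(nrep, intervals(sampleGenealogy(m, theta))))
  # E[d_k] = theta / (k(k-1)); column i holds d_{i+1}
  for (k in 2:m) {
    d <- ints[, k - 1]
    expect_lt(abs(mean(d) - theta / (k * (k - 1))),
              3 * sd(d) / sqrt(nrep))
  }
  roots <- rowSums(ints)
  expect_lt(abs(mean(roots) - theta * (1 - 1 / m)),
            3 * sd(roots) / sqrt(nrep))
})

test_that("sampled genealogies satisfy the class invariants", {
  set.seed(11)
  for (m in c(2, 3, 7, 20)) {
    gen <- sampleGenealogy(m, 0.1)
    expect_true(validObject(gen))
    expect_equal(sum(intervals(gen)), rootTime(gen))
    expect_equal(length(intervals(gen)), m - 1)
  }
  expect_error(sampleGenealogy(1, 0.1), "m must be")
  expect_error(sampleGenealogy(5, 0), "positive")
})

test_that("UPGMA joins the closest pair and halves distances", {
  # two sequences differing at 2 of 100 sites: single join at half the
  # (JC-corrected) pairwise distance
  s1 <- paste(rep("A", 100), collapse = "")
  s2 <- paste(c(rep("A", 98), "C", "C"), collapse = "")
  aln <- sequenceAlignment(c(a = s1, b = s2))
  gen <- upgmaTree(aln)
  d <- -0.75 * log(1 - 4 * 0.02 / 3)
  expect_equal(rootTime(gen), d / 2, tolerance = 1e-9)

  # three sequences: A and B close, C far from both -> ((A,B),C)
  base <- rep("A", 100)
  sA <- base
  sB <- base; sB[1:10] <- "C"
  sC <- base; sC[41:80] <- "G"
  aln3 <- sequenceAlignment(rbind(sA, sB, sC), ids = c("A", "B", "C"))
  gen3 <- upgmaTree(aln3)
  # closest pair (A, B) joins first: their common ancestor is below the root
  expect_lt(nodeTimes(gen3)[gen3@parent[1]], rootTime(gen3))
  expect_equal(gen3@parent[1], gen3@parent[2])
  expect_true(same_topology(gen3, genealogyFromPhylo(
    ape::read.tree(text = "((A:1,B:1):1,C:2);"))))
})

test_that("UPGMA agrees with a brute-force agglomeration oracle", {
  set.seed(13)
  for (rep in 1:5) {
    aln <- random_alignment(5, 300)
    gen <- upgmaTree(aln)
    D <- coalsmc:::.jc_distance(aln)
    nwk <- oracle_upgma_newick(D, aln@ids)
    oracleGen <- genealogyFromPhylo(ape::read.tree(text = nwk))
    expect_true(same_topology(gen, oracleGen))
    # heights agree too (topology-independent check on root time)
    expect_equal(rootTime(gen), rootTime(oracleGen), tolerance = 1e-6)
  }
})

test_that("UPGMA recovers the generating topology from ultrametric data", {
  set.seed(19)
  gen0 <- sampleGenealogy(6, 0.3)
  aln <- evolveSequences(gen0, substitutionModel("K80", kappa = 2), 4000)
  expect_true(same_topology(upgmaTree(aln), gen0))
})

test_that("upgmaTree requires at least two sequences", {
  expect_error(sequenceAlignment(matrix("A", 1, 5)), "at least 2")
})

test_that("Watterson's estimator matches direct arithmetic", {
  mono <- sequenceAlignment(matrix("A", 2, 100))
  expect_equal(wattersonTheta(mono), 0)
  # m=2, S=3, l=100 -> 0.03
  s1 <- rep("A", 100)
  s2 <- s1; s2[1:3] <- "G"
  expect_equal(wattersonTheta(sequenceAlignment(rbind(s1, s2))), 0.03)
  # m=4, S=5, l=100 -> 5 / (100 * (1 + 1/2 + 1/3))
  mat <- matrix("A", 4, 100)
  mat[1, 1:5] <- "T"
  aln <- sequenceAlignment(mat)
  expect_equal(wattersonTheta(aln), 5 / (100 * (1 + 1 / 2 + 1 / 3)),
               tolerance = 1e-12)
})

test_that("Watterson's estimator is invariant to order and monomorphic padding", {
  set.seed(23)
  aln <- random_alignment(5, 60)
  perm <- sample(5)
  alnP <- sequenceAlignment(aln@chars[perm, ], ids = aln@ids[perm])
  expect_equal(wattersonTheta(aln), wattersonTheta(alnP))
  # padding with monomorphic columns rescales by l/(l+pad)
  pad <- matrix("C", 5, 40)
  alnPad <- sequenceAlignment(cbind(aln@chars, pad), ids = aln@ids)
  expect_equal(wattersonTheta(alnPad), wattersonTheta(aln) * 60 / 100)
})

test_that("Newick round trip preserves topology, times and labels", {
  set.seed(29)
  gen <- sampleGenealogy(8, 0.2)
  path <- tempfile(fileext = ".nwk")
  writeNewick(gen, path)
  back <- readNewick(path)
  expect_true(same_topology(gen, back))
  expect_setequal(tipLabels(back), tipLabels(gen))
  expect_equal(rootTime(back), rootTime(gen), tolerance = 1e-6)
  expect_equal(sort(intervals(back)), sort(intervals(gen)),
               tolerance = 1e-5)
})
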