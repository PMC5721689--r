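# Pruning likelihood: closed forms, exhaustive enumeration, invariances,
# pattern compression.

two_tip_gen <- function(t) {
  genealogy(parent = c(3L, 3L, 0L), times = c(0, 0, t),
            tipLabels = c("a", "b"))
}

test_that("two identical one-site sequences at zero branch lengths give log 1/4", {
  aln <- sequenceAlignment(rbind("A", "A"), ids = c("a", "b"))
  # strictly positive root time required; make it negligibly small
  gen <- two_tip_gen(1e-14)
  expect_equal(pruningLoglik(aln, gen, substitutionModel("K80", kappa = 2)),
               log(0.25), tolerance = 1e-9)
})

test_that("two-tip likelihood equals the direct closed-form sum", {
  set.seed(31)
  params <- substitutionModel("F84", kappa = 3, pi = c(0.35, 0.15, 0.3, 0.2))
  base <- c("A", "C", "G", "T")
  for (pair in list(c("A", "A"), c("A", "G"), c("C", "A"), c("T", "C"))) {
    t1t2 <- runif(2, 0.01, 0.6)
    gen <- two_tip_gen(max(t1t2))
    # two-tip tree is ultrametric: equal branch lengths t
    t <- rootTime(gen)
    P <- oracle_pmat(params, t)
    i <- match(pair[1], base); j <- match(pair[2], base)
    direct <- log(sum(params@pi * P[, i] * P[, j]))
    aln <- sequenceAlignment(rbind(pair[1], pair[2]), ids = c("a", "b"))
    expect_equal(pruningLoglik(aln, gen, params), direct, tolerance = 1e-9)
  }
})

test_that("pruning equals exhaustive enumeration over internal states", {
  set.seed(37)
  for (m in 3:5) {
    for (rep in 1:3) {
      gen <- sampleGenealogy(m, 0.4)
      params <- if (rep == 1) substitutionModel("K80", kappa = runif(1, 1, 5))
                else {
                  g <- rgamma(4, 5)
                  substitutionModel("F84", kappa = runif(1, 1, 5),
                                    pi = g / sum(g))
                }
      aln <- evolveSequences(gen, params, 4)
      expect_equal(pruningLoglik(aln, gen, params),
                   oracle_loglik(aln, gen, params),
                   tolerance = 1e-9)
    }
  }
})

test_that("likelihood is invariant to sequence and site permutations", {
  set.seed(41)
  gen <- sampleGenealogy(6, 0.2)
  params <- substitutionModel("K80", kappa = 2)
  aln <- evolveSequences(gen, params, 80)
  ll <- pruningLoglik(aln, gen, params)
  perm <- sample(6)
  alnP <- sequenceAlignment(aln@chars[perm, ], ids = aln@ids[perm])
  expect_equal(pruningLoglik(alnP, gen, params), ll, tolerance = 1e-9)
  sperm <- sample(80)
  alnS <- sequenceAlignment(aln@chars[, sperm], ids = aln@ids)
  expect_equal(pruningLoglik(alnS, gen, params), ll, tolerance = 1e-9)
})

test_that("a monomorphic site adds exactly its single-column log-likelihood", {
  set.seed(43)
  gen <- sampleGenealogy(5, 0.3)
  params <- substitutionModel("F84", kappa = 2, pi = c(0.3, 0.25, 0.25, 0.2))
  aln <- evolveSequences(gen, params, 30)
  one <- sequenceAlignment(matrix("G", 5, 1), ids = aln@ids)
  joint <- sequenceAlignment(cbind(aln@chars, "G"), ids = aln@ids)
  expect_equal(pruningLoglik(joint, gen, params),
               pruningLoglik(aln, gen, params) +
                 pruningLoglik(one, gen, params),
               tolerance = 1e-9)
})

test_that("rerooting along the root branch leaves the likelihood unchanged", {
  # pulley principle for reversible models: slide the root along the path
  # between its two children (tree no longer ultrametric; use the
  # edge-length interface)
  set.seed(47)
  gen <- sampleGenealogy(5, 0.3)
  params <- substitutionModel("F84", kappa = 3, pi = c(0.2, 0.3, 0.1, 0.4))
  aln <- evolveSequences(gen, params, 40)
  ll0 <- pruningLoglik(aln, gen, params)
  root <- which(gen@parent == 0L)
  kids <- which(gen@parent == root)
  el <- numeric(length(gen@parent))
  nr <- gen@parent != 0L
  el[nr] <- gen@times[gen@parent[nr]] - gen@times[nr]
  total <- el[kids[1]] + el[kids[2]]
  for (f in c(0.1, 0.5, 0.9)) {
    el2 <- el
    el2[kids[1]] <- f * total
    el2[kids[2]] <- (1 - f) * total
    ll <- coalsmc:::.pruning_loglik_edges(aln, gen@parent, el2,
                                          tipLabels(gen), params)
    expect_equal(ll, ll0, tolerance = 1e-9)
  }
})

test_that("ambiguity codes marginalize over compatible bases", {
  params <- substitutionModel("K80", kappa = 2)
  gen <- two_tip_gen(0.2)
  llR <- pruningLoglik(sequenceAlignment(rbind("R", "C"), ids = c("a", "b")),
                       gen, params)
  llA <- pruningLoglik(sequenceAlignment(rbind("A", "C"), ids = c("a", "b")),
                       gen, params)
  llG <- pruningLoglik(sequenceAlignment(rbind("G", "C"), ids = c("a", "b")),
                       gen, params)
  expect_equal(llR, log(exp(llA) + exp(llG)), tolerance = 1e-9)
  # N and gap are fully missing: the remaining tip determines the site
  llN <- pruningLoglik(sequenceAlignment(rbind("N", "C"), ids = c("a", "b")),
                       gen, params)
  expect_equal(llN, log(0.25), tolerance = 1e-9)
})

test_that("site-pattern compression is lossless", {
  # all-identical columns: one pattern with multiplicity l
  aln1 <- sequenceAlignment(matrix("A", 3, 17))
  p1 <- sitePatterns(aln1)
  expect_equal(length(p1$counts), 1L)
  expect_equal(p1$counts, 17)
  # all-distinct columns
  mat <- rbind(c("A", "C", "G"), c("C", "G", "T"), c("G", "T", "A"))
  p2 <- sitePatterns(sequenceAlignment(mat))
  expect_equal(length(p2$counts), 3L)
  expect_true(all(p2$counts == 1))
  # round trip on a random matrix
  set.seed(53)
  aln <- random_alignment(5, 50)
  p <- sitePatterns(aln)
  expect_equal(sum(p$counts), 50)
  expect_identical(p$columns[, p$index], aln@chars)
})

test_that("label mismatches and invalid characters are rejected", {
  aln <- random_alignment(4, 10)
  gen <- sampleGenealogy(4, 0.1, tipLabels = c("x1", "x2", "x3", "x4"))
  expect_error(pruningLoglik(aln, gen, substitutionModel("K80")),
               "do not match")
  expect_error(sequenceAlignment(rbind("AZA", "AAA")), "invalid character")
  expect_error(sequenceAlignment(c("ACGT", "ACG")), "unequal")
})

test_that("uracil maps to T and lowercase input is uppercased", {
  aln <- sequenceAlignment(c(a = "acgu", b = "ACGT"))
  expect_identical(aln@chars[1, ], aln@chars[2, ])
  expect_equal(wattersonTheta(aln), 0)
})
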