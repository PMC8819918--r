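test_that("paired compositions apply pseudocounts and drop thin samples", {
  qpcr <- mkTable(matrix(c(1000, 1000, NA,
                           2000, NA, NA), 2, byrow = TRUE),
                  unit = "copies_per_ul", taxa = c("A", "B", "C"))
  ngs <- mkTable(matrix(c(90, 0, 5,
                          10, 10, 10), 2, byrow = TRUE),
                 taxa = c("A", "B", "C"))
  expect_warning(pc <- buildPairedCompositions(qpcr, ngs), "S02")
  # S01: subset {A, B}; the observed zero for B becomes pseudocount 1
  expect_equal(pc@observed$S01, c(A = 90 / 91, B = 1 / 91))
  expect_equal(pc@reference$S01, c(A = 0.5, B = 0.5))
  # NGS-only taxon C is excluded from the subset entirely
  expect_false("C" %in% names(pc@observed$S01))

  # no zeros: the pseudocount value is irrelevant
  full <- mkTable(matrix(c(60, 40), 1), taxa = c("A", "B"))
  qful <- mkTable(matrix(c(500, 500), 1), unit = "copies_per_ul",
                  taxa = c("A", "B"))
  p1 <- buildPairedCompositions(qful, full, pseudocount = 1)
  p9 <- buildPairedCompositions(qful, full, pseudocount = 9)
  expect_equal(p1@observed, p9@observed)
})

test_that("bias estimates reproduce hand and identifiability oracles", {
  # observed = reference -> no bias
  q <- mkTable(matrix(c(500, 500, 300, 700), 2, byrow = TRUE),
               unit = "copies_per_ul", taxa = c("A", "B"))
  n <- mkTable(matrix(c(50, 50, 30, 70), 2, byrow = TRUE),
               taxa = c("A", "B"))
  flat <- estimateBias(buildPairedCompositions(q, n))
  expect_equal(unname(biasEstimates(flat)), c(1, 1), tolerance = 1e-12)

  # one sample, observed (0.8, 0.2) vs reference (0.5, 0.5):
  # ratios (1.6, 0.4), centered by their geometric mean 0.8 -> (2, 0.5)
  q1 <- mkTable(matrix(c(1000, 1000), 1), unit = "copies_per_ul",
                taxa = c("A", "B"))
  n1 <- mkTable(matrix(c(80, 20), 1), taxa = c("A", "B"))
  hand <- estimateBias(buildPairedCompositions(q1, n1))
  expect_equal(biasEstimates(hand), c(A = 2, B = 0.5), tolerance = 1e-12)

  # noise-free identifiability: observed = reference x B recovers B
  set.seed(21)
  B <- c(2, 1, 0.5)
  ref <- matrix(stats::runif(6, 0.1, 1), 2, 3)
  obs <- sweep(ref, 2L, B, "*")
  qf <- mkTable(ref * 1e4, unit = "copies_per_ul",
                taxa = c("A", "B", "C"))
  nf <- mkTable(obs * 1e4, taxa = c("A", "B", "C"))
  est <- estimateBias(buildPairedCompositions(qf, nf))
  expect_equal(biasEstimates(est),
               c(A = 2, B = 1, C = 0.5) / exp(mean(log(B))),
               tolerance = 1e-10)
})

test_that("ragged least squares recovers exactly from connected subsets", {
  # noise-free ragged design: taxa appear in overlapping subsets only
  set.seed(22)
  taxa <- c("A", "B", "C", "D")
  B <- exp(c(0.7, -0.2, 0.4, -0.9))
  subsets <- list(S01 = c("A", "B"), S02 = c("B", "C"),
                  S03 = c("C", "D"), S04 = c("A", "D"),
                  S05 = c("A", "B", "C", "D"))
  q <- matrix(NA_real_, 5, 4, dimnames = list(names(subsets), taxa))
  n <- matrix(0, 5, 4, dimnames = list(names(subsets), taxa))
  for (s in names(subsets)) {
    ref <- stats::runif(length(subsets[[s]]), 0.2, 1)
    q[s, subsets[[s]]] <- ref * 1e4
    n[s, subsets[[s]]] <- ref * B[match(subsets[[s]], taxa)] * 1e5
  }
  est <- estimateBias(buildPairedCompositions(
    abundanceTable(q, "copies_per_ul"), abundanceTable(n, "reads")))
  expected <- B / exp(mean(log(B)))
  names(expected) <- taxa
  expect_equal(biasEstimates(est)[taxa], expected, tolerance = 1e-10)

  # disconnected co-occurrence graph is rejected
  qd <- mkTable(matrix(c(10, 10, NA, NA, NA, NA, 10, 10) * 100,
                       2, byrow = TRUE),
                unit = "copies_per_ul", taxa = c("A", "B", "C", "D"))
  nd <- mkTable(matrix(c(5, 5, 0, 0, 0, 0, 5, 5), 2, byrow = TRUE),
                taxa = c("A", "B", "C", "D"))
  expect_error(estimateBias(buildPairedCompositions(qd, nd)),
               "disconnected")
})

test_that("closed-form estimator matches the least-squares fit", {
  set.seed(23)
  for (i in 1:5) {
    p <- randomPairedTables(7, 5)
    pc <- buildPairedCompositions(p$qpcr, p$ngs)
    ls <- biasEstimates(estimateBias(pc))
    cf <- estimateBiasClosedForm(pc)
    expect_equal(ls, cf[names(ls)], tolerance = 1e-10)
    # and both match the hand-rolled oracle on raw matrices
    expect_equal(ls, oracleBias(abundValues(p$ngs),
                                abundValues(p$qpcr))[names(ls)],
                 tolerance = 1e-10)
  }
})

test_that("bootstrap GSEs are deterministic and collapse for identical samples", {
  one <- matrix(c(80, 20), 1)
  q <- mkTable(one[rep(1, 6), ] * 100, unit = "copies_per_ul",
               taxa = c("A", "B"))
  n <- mkTable(matrix(c(60, 40), 1)[rep(1, 6), ], taxa = c("A", "B"))
  est <- bootstrapGSE(buildPairedCompositions(q, n), nReps = 50,
                      seed = 3)
  expect_equal(unname(biasGSE(est)), c(1, 1), tolerance = 1e-12)

  set.seed(24)
  p <- randomPairedTables(8, 4)
  pc <- buildPairedCompositions(p$qpcr, p$ngs)
  a <- bootstrapGSE(pc, nReps = 100, seed = 7)
  b <- bootstrapGSE(pc, nReps = 100, seed = 7)
  expect_identical(biasGSE(a), biasGSE(b))
  expect_true(all(biasGSE(a) >= 1))
  expect_error(bootstrapGSE(pc, nReps = 1), "at least 2")
})

test_that("bootstrap GSE matches the delta-method rate for two taxa", {
  # per-cell lognormal noise sd sigma on the observed composition; for
  # two taxa the centered log-ratio halves the noise difference, so
  # sd(log B_t) = sigma / sqrt(2 n); checked within 25%
  set.seed(25)
  nS <- 50
  sigma <- 0.4
  ref <- matrix(stats::runif(nS * 2, 0.2, 1), nS, 2)
  obs <- ref * exp(matrix(stats::rnorm(nS * 2, 0, sigma), nS, 2))
  q <- mkTable(ref * 1e4, unit = "copies_per_ul", taxa = c("A", "B"))
  n <- mkTable(obs * 1e4, taxa = c("A", "B"))
  est <- bootstrapGSE(buildPairedCompositions(q, n), nReps = 400,
                      seed = 11)
  target <- exp(sigma / sqrt(2 * nS))
  expect_lt(max(abs(log(biasGSE(est)) / log(target) - 1)), 0.25)
})

test_that("single-sample taxa get no GSE", {
  q <- mkTable(matrix(c(1000, 1000, NA,
                        1000, 1000, NA,
                        1000, 1000, 1000), 3, byrow = TRUE),
               unit = "copies_per_ul", taxa = c("A", "B", "C"))
  n <- mkTable(matrix(c(50, 50, 0,
                        60, 40, 0,
                        30, 30, 40), 3, byrow = TRUE),
               taxa = c("A", "B", "C"))
  est <- bootstrapGSE(buildPairedCompositions(q, n), nReps = 50,
                      seed = 2)
  expect_true(is.na(biasGSE(est)[["C"]]))
  expect_false(anyNA(biasGSE(est)[c("A", "B")]))
})

test_that("two-GSE intervals are multiplicative around the estimate", {
  est <- new("BiasEstimate",
             estimate = c(A = 2, B = 1) / exp(mean(log(c(2, 1)))),
             gse = c(A = 1, B = 1.2), nBootstrap = 10L,
             nSamplesUsed = c(A = 5L, B = 5L))
  iv <- gseInterval(est)
  a <- iv[iv$taxon == "A", ]
  expect_equal(a$low, a$estimate)
  expect_equal(a$high, a$estimate)
  b <- iv[iv$taxon == "B", ]
  expect_equal(b$high / b$estimate, 1.44, tolerance = 1e-12)
  expect_equal(b$estimate / b$low, 1.44, tolerance = 1e-12)
  expect_true(all(iv$low <= iv$estimate & iv$estimate <= iv$high))
})
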