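test_that("detection cells classify into the five categories", {
  qpcr <- mkTable(matrix(c(32000, NA, NA,
                           900, 1200, NA), 2, byrow = TRUE),
                  unit = "copies_per_ul", taxa = c("A", "B", "C"))
  ngs <- mkTable(matrix(c(15000, 12, 0, 40,
                          0, 3000, 0, 0), 2, byrow = TRUE),
                 taxa = c("A", "B", "C", "D"))
  det <- classifyDetections(qpcr, ngs)  # panel = A, B, C
  cm <- det@categories
  expect_equal(cm["S01", "A"], "shared_positive", ignore_attr = TRUE)
  expect_equal(cm["S01", "B"], "ngs_only", ignore_attr = TRUE)
  expect_equal(cm["S01", "C"], "undetected", ignore_attr = TRUE)
  expect_equal(cm["S01", "D"], "ngs_exclusive", ignore_attr = TRUE)
  expect_equal(cm["S02", "A"], "qpcr_only", ignore_attr = TRUE)
  expect_equal(cm["S02", "B"], "shared_positive", ignore_attr = TRUE)
  expect_equal(cm["S02", "D"], "undetected", ignore_attr = TRUE)

  # categories partition all cells
  expect_equal(sum(detectionCounts(det)), prod(dim(cm)))

  bad <- mkTable(matrix(1, 1, 3), samples = "S99", taxa = c("A", "B", "C"))
  expect_error(classifyDetections(qpcr, bad), "same samples")
})

test_that("coverage percentages summarize shared-species reads", {
  ngs <- mkTable(matrix(c(90, 10, 0,
                          25, 25, 50), 2, byrow = TRUE),
                 taxa = c("A", "B", "C"))
  cov <- coverageStats(ngs, list(S01 = c("A", "B"), S02 = c("A", "B")))
  expect_equal(unname(cov$perSample), c(100, 50))
  expect_equal(cov$mean, 75)
  # pure arithmetic: mean of per-sample values equals the summary
  expect_equal(cov$mean, mean(cov$perSample), tolerance = 1e-12)

  zero <- mkTable(matrix(c(1, 1, 0, 0), 2, byrow = TRUE),
                  taxa = c("A", "B"))
  expect_error(coverageStats(zero, list(S01 = "A", S02 = "A")), "S02")
})

test_that("R^2 behaves on collinear, anti-ordered and rescaled pairs", {
  expect_equal(logLogR2(c(1, 10, 100), c(2, 20, 200)), 1,
               tolerance = 1e-12)
  # hand OLS on log10 pairs (0,0),(1,2),(2,1): Sxy = 1, Sxx = Syy = 2,
  # so R^2 = 1/4 (the correlation is 1/2)
  expect_equal(logLogR2(c(1, 10, 100), c(1, 100, 10)), 0.25,
               tolerance = 1e-12)
  # scale invariance: a log shift cannot change R^2
  set.seed(9)
  x <- stats::rlnorm(20, 5, 1)
  y <- x^0.8 * stats::rlnorm(20, 0, 0.2)
  expect_equal(logLogR2(x, y), logLogR2(x * 1e3, y), tolerance = 1e-12)
  expect_error(logLogR2(c(0, 1, 2), c(1, 2, 3)), "positive")
  expect_error(logLogR2(1:2, 1:2), "at least 3")
})

test_that("Bray-Curtis matches hand values and metric properties", {
  expect_equal(brayCurtis(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(brayCurtis(c(1, 0), c(0, 1)), 1)
  expect_equal(brayCurtis(c(0.7, 0.3), c(0.5, 0.5)), 0.2)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(brayCurtis(c(1, 0), c(1, 0, 0)), "length")

  set.seed(10)
  for (i in 1:50) {
    x <- stats::runif(6); y <- stats::runif(6); z <- stats::runif(6)
    dxy <- brayCurtis(x, y)
    expect_gte(dxy, 0); expect_lte(dxy, 1)
    expect_equal(dxy, brayCurtis(y, x), tolerance = 1e-14)
    # triangle inequality on proportion vectors
    px <- x / sum(x); py <- y / sum(y); pz <- z / sum(z)
    expect_lte(brayCurtis(px, py),
               brayCurtis(px, pz) + brayCurtis(pz, py) + 1e-12)
  }
})

test_that("Bray-Curtis agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(stats::runif(40), 8, 5)
  ours <- brayCurtisMatrix(m)
  ref <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("UPGMA reproduces hand merges and ultrametric inputs", {
  # two leaves at distance d: tips sit at height d/2, cophenetic = d
  d2 <- matrix(c(0, 0.6, 0.6, 0), 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgmaTree(d2)
  expect_equal(unname(ape::cophenetic.phylo(t2)["A", "B"]), 0.6,
               tolerance = 1e-12)
  expect_equal(unname(t2$edge.length), c(0.3, 0.3), tolerance = 1e-12)

  # brute force over the 3 possible first merges: A,B at 0.1 first,
  # then C joins at the mean distance 0.4
  d3 <- matrix(c(0, 0.1, 0.4,
                 0.1, 0, 0.4,
                 0.4, 0.4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgmaTree(d3)
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(unname(cp["A", "B"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(cp["A", "C"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(cp["B", "C"]), 0.4, tolerance = 1e-12)

  # an ultrametric matrix is reproduced exactly
  set.seed(13)
  m <- matrix(stats::runif(70), 10, 7)
  um <- ape::cophenetic.phylo(upgmaTree(brayCurtisMatrix(m)))
  again <- ape::cophenetic.phylo(upgmaTree(um))
  expect_equal(again[rownames(um), colnames(um)], um, tolerance = 1e-9)

  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(upgmaTree(asym), "symmetric")
  expect_error(upgmaTree(matrix(c(1, 0, 0, 1), 2)), "diagonal")
})

test_that("paired method profiles cluster as siblings when they agree", {
  set.seed(14)
  p <- randomPairedTables(6, 5)
  taxa <- taxonNames(p$qpcr)
  # identical tables: every sample's two profiles merge at height 0
  same <- clusterMethodProfiles(
    p$qpcr, abundanceTable(abundValues(p$qpcr), "reads"), taxa = taxa)
  expect_true(all(same$siblings))
  expect_equal(same$siblingRate, 1)

  # replace one sample's sequencing profile by another community
  v <- abundValues(p$qpcr)
  v["S03", ] <- rev(v["S03", ]) * c(100, 1, 1, 1, 100)
  diverged <- clusterMethodProfiles(p$qpcr, abundanceTable(v, "reads"),
                                    taxa = taxa)
  expect_false(diverged$siblings[["S03"]])
  expect_s3_class(diverged$tree, "phylo")
})
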