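# fixture builders shared across test files; everything is generated in
# code, no files on disk

mkTable <- function(values, unit = "reads",
                    samples = sprintf("S%02d", seq_len(nrow(values))),
                    taxa = sprintf("t%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(samples, taxa)
  abundanceTable(values, unit = unit)
}

# random strictly positive paired tables over a common taxon set
randomPairedTables <- function(nSamples, nTaxa) {
  q <- matrix(exp(stats::rnorm(nSamples * nTaxa, log(1e4), 1)),
              nSamples, nTaxa)
  n <- matrix(stats::rpois(nSamples * nTaxa, 500) + 1L, nSamples, nTaxa)
  list(qpcr = mkTable(q, unit = "copies_per_ul"),
       ngs = mkTable(n * 1.0, unit = "reads"))
}

# a minimal CommunityTruth built directly (bypasses simulateTruth so the
# measurement model can be probed with hand-picked numbers)
mkTruth <- function(abund, efficiency = rep(1, ncol(abund)),
                    copyNumber = rep(5, ncol(abund)),
                    depth = 1e5, detectionLimit = 1, seed = 1L) {
  samples <- sprintf("S%02d", seq_len(nrow(abund)))
  taxa <- sprintf("t%02d", seq_len(ncol(abund)))
  dimnames(abund) <- list(samples, taxa)
  names(efficiency) <- names(copyNumber) <- taxa
  new("CommunityTruth", samples = samples, taxa = taxa,
      trueAbundance = abund, efficiency = efficiency,
      copyNumber = copyNumber, depth = rep(depth, nrow(abund)),
      detectionLimit = detectionLimit, seed = as.integer(seed))
}

# closed-form two-way bias oracle, independent of the package's fit:
# center each sample's log ratio vector, then average per taxon
# (complete data only)
oracleBias <- function(obsMat, refMat) {
  logr <- log(obsMat / rowSums(obsMat)) - log(refMat / rowSums(refMat))
  centered <- logr - rowMeans(logr)
  exp(colMeans(centered) - mean(colMeans(centered)))
}
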