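#' Default simulated qPCR standard curve
#'
#' Slope -3.3219 (= -1/log10(2), a perfectly doubling assay, efficiency
#' 1.0) and intercept 38, valid from 1e3 to 1e7 copies/ul. Analytically
#' convenient: 10^4 copies/ul maps to Cq 24.7123.
#'
#' @param assay assay identifier stored on the curve.
#' @return A [StandardCurve-class].
#' @export
defaultStandardCurve <- function(assay = "simulated") {
  new("StandardCurve", assay = assay, slope = -1 / log10(2),
      intercept = 38, rSquared = 1, validRange = c(1e3, 1e7))
}

#' Simulate the ground truth of a cheese-like microbial community
#'
#' Draws a known community state emulating the structure of a 21-sample
#' semi-hard raw-milk cheese survey: per-(sample, taxon) genome
#' abundances are lognormal with independent random absences (ragged
#' detection pattern around a shared core), per-taxon sequencing
#' efficiencies are lognormal renormalized to geometric mean 1, and
#' per-taxon mean 16S copy numbers are drawn uniformly from 3-9 copies
#' per genome, the range typical of the prevalent dairy species. Rows
#' violating the requirement of at least two taxa above the detection
#' limit are redrawn.
#'
#' @param nSamples number of samples (default 21).
#' @param nTaxa number of taxa (default 20); at least 2.
#' @param abundanceLogMean,abundanceLogSd natural-log mean/sd of the
#'   lognormal genome abundances, copies/ul (defaults log(2e4) and 2,
#'   spanning roughly 1e3-1e7 copies/ul).
#' @param efficiencyLogSd natural-log sd of the sequencing efficiencies
#'   (0 forces all efficiencies to 1).
#' @param depth total reads per sample (default 471184, a realistic mean
#'   amplicon depth).
#' @param zeroProb probability a (sample, taxon) cell is absent
#'   (default 0.2).
#' @param copyNumberChoices integer 16S copies per genome sampled
#'   uniformly per taxon (default 3:9).
#' @param detectionLimit qPCR censoring threshold, copies/ul (default
#'   800).
#' @param seed root seed; child streams are derived per operation so
#'   partial reruns reproduce.
#'
#' @return A [CommunityTruth-class].
#' @export
simulateTruth <- function(nSamples = 21, nTaxa = 20,
                          abundanceLogMean = log(2e4),
                          abundanceLogSd = 2,
                          efficiencyLogSd = 0.5,
                          depth = 471184L, zeroProb = 0.2,
                          copyNumberChoices = 3:9,
                          detectionLimit = 800, seed = 1) {
  if (nSamples < 1) stop("'nSamples' must be >= 1")
  if (nTaxa < 2) stop("the bias model needs at least 2 taxa")
  if (any(depth < 1)) stop("'depth' must be >= 1")
  if (zeroProb < 0 || zeroProb >= 1) stop("'zeroProb' must be in [0, 1)")
  samples <- sprintf("S%02d", seq_len(nSamples))
  taxa <- sprintf("taxon%02d", seq_len(nTaxa))
  withSeed(childSeed(seed, 1L), {
    drawRow <- function() {
      a <- stats::rlnorm(nTaxa, abundanceLogMean, abundanceLogSd)
      a[stats::runif(nTaxa) < zeroProb] <- 0
      a
    }
    A <- matrix(0, nSamples, nTaxa, dimnames = list(samples, taxa))
    for (i in seq_len(nSamples)) {
      row <- drawRow()
      tries <- 1L
      while (sum(row > detectionLimit) < 2L) {
        if ((tries <- tries + 1L) > 1000L)
          stop("could not draw a sample with >= 2 detectable taxa; ",
               "raise 'abundanceLogMean' or lower 'zeroProb'")
        row <- drawRow()
      }
      A[i, ] <- row
    }
    eff <- if (efficiencyLogSd == 0) rep(1, nTaxa) else
      stats::rnorm(nTaxa, 0, efficiencyLogSd)
    if (efficiencyLogSd > 0) eff <- exp(eff - mean(eff))
    cn <- as.numeric(sample(copyNumberChoices, nTaxa, replace = TRUE))
  })
  names(eff) <- names(cn) <- taxa
  new("CommunityTruth", samples = samples, taxa = taxa,
      trueAbundance = A, efficiency = eff, copyNumber = cn,
      depth = rep_len(as.numeric(depth), nSamples),
      detectionLimit = detectionLimit, seed = as.integer(seed))
}

#' @describeIn simulateTruth accessors for the truth slots.
#' @param truth a \code{CommunityTruth}.
#' @export
trueAbundance <- function(truth) truth@trueAbundance

#' @rdname simulateTruth
#' @export
taxonEfficiency <- function(truth) truth@efficiency

#' @rdname simulateTruth
#' @export
taxonCopyNumber <- function(truth) truth@copyNumber

#' True sequencing bias of a simulated community
#'
#' Under the simulator's measurement model, sequencing observes taxon
#' proportions proportional to abundance x 16S copy number x efficiency,
#' while qPCR measures abundance directly; the true per-taxon bias of
#' sequencing relative to qPCR is therefore copy number x efficiency,
#' renormalized to geometric mean 1 over the taxa being compared.
#'
#' @param truth a [CommunityTruth-class].
#' @param taxa taxa to renormalize over (default all).
#'
#' @return Named per-taxon true bias (geometric mean 1).
#' @export
trueBias <- function(truth, taxa = taxonNames(truth)) {
  stopifnot(is(truth, "CommunityTruth"))
  b <- (truth@copyNumber * truth@efficiency)[taxa]
  b / geomMean(b)
}

#' Simulate amplicon sequencing of a known community
#'
#' Draws each sample's read counts from a multinomial with size equal to
#' the sample's depth and probabilities proportional to true abundance x
#' 16S copy number x sequencing efficiency. Absent taxa (zero abundance)
#' get zero probability and hence zero reads.
#'
#' @param truth a [CommunityTruth-class].
#'
#' @return An [AbundanceTable-class] with \code{unit = "reads"}; each row
#'   sums exactly to the sample's depth.
#' @export
observeNGS <- function(truth) {
  stopifnot(is(truth, "CommunityTruth"))
  w <- sweep(truth@trueAbundance, 2L,
             truth@copyNumber * truth@efficiency, "*")
  bad <- rowSums(w) <= 0
  if (any(bad))
    stop("all-zero abundance row(s): ",
         paste(truth@samples[bad], collapse = ", "))
  counts <- matrix(0L, nrow(w), ncol(w), dimnames = dimnames(w))
  withSeed(childSeed(truth@seed, 2L), {
    for (i in seq_len(nrow(w)))
      counts[i, ] <- stats::rmultinom(1L, size = truth@depth[i],
                                      prob = w[i, ])[, 1L]
  })
  abundanceTable(counts, unit = "reads")
}

#' Simulate HT-qPCR reactions of a known community
#'
#' Emits technical triplicates for every (sample, assayed taxon): each
#' replicate measures the true abundance under multiplicative lognormal
#' noise with mean 1 and coefficient of variation \code{cv}, converted to
#' a Cq through the simulated standard curve. Reactions are emitted even
#' below the detection limit -- censoring is the quantification step's
#' job, not the simulator's. Measurements too dilute to amplify within
#' the 30-cycle run (Cq > 30, about 250 copies/ul under the default
#' curve) and absent taxa yield no-amplification records (\code{NA} Cq).
#'
#' @param truth a [CommunityTruth-class].
#' @param assayedTaxa taxa covered by the assay panel (subset of the
#'   truth's taxa; others produce no records).
#' @param cv per-reaction coefficient of variation of the measured
#'   copies (default 0.1; 0 = noiseless).
#' @param curve the simulated [StandardCurve-class] used to convert
#'   copies to Cq.
#' @param nReplicates technical replicates per (sample, assay).
#'
#' @return A long-format data.frame with columns \code{sample},
#'   \code{assay}, \code{replicate}, \code{cq}, \code{flagged}.
#' @export
observeQPCR <- function(truth, assayedTaxa = taxonNames(truth), cv = 0.1,
                        curve = defaultStandardCurve(),
                        nReplicates = 3L) {
  stopifnot(is(truth, "CommunityTruth"), cv >= 0)
  unknown <- setdiff(assayedTaxa, truth@taxa)
  if (length(unknown))
    stop("assayed taxa unknown to the truth: ",
         paste(unknown, collapse = ", "))
  maxCq <- 30  # run length: no amplification past the last cycle
  sdlog <- sqrt(log(1 + cv^2))
  grid <- expand.grid(replicate = seq_len(nReplicates),
                      assay = assayedTaxa, sample = truth@samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  a <- truth@trueAbundance[cbind(grid$sample, grid$assay)]
  withSeed(childSeed(truth@seed, 3L), {
    noise <- if (cv == 0) rep(1, nrow(grid)) else
      stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
  measured <- a * noise
  cq <- ifelse(measured > 0, cqFromCopies(measured, curve), NA_real_)
  cq[!is.na(cq) & cq > maxCq] <- NA_real_
  data.frame(sample = grid$sample, assay = grid$assay,
             replicate = grid$replicate, cq = cq, flagged = FALSE,
             row.names = NULL)
}

#' Write a simulated data set as tab-delimited text
#'
#' Writes \code{truth.tsv} (true abundances), \code{ngs_counts.tsv},
#' \code{qpcr_reactions.tsv} (long format) and \code{copy_numbers.tsv}
#' into a directory.
#'
#' @param truth a [CommunityTruth-class].
#' @param ngs the matching read-count [AbundanceTable-class].
#' @param reactions the matching long-format reaction table.
#' @param dir output directory (created if missing).
#'
#' @return Invisibly, the paths written.
#' @export
writeSimulation <- function(truth, ngs, reactions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("truth.tsv", "ngs_counts.tsv",
                            "qpcr_reactions.tsv", "copy_numbers.tsv"))
  writeAbundanceTable(
    abundanceTable(truth@trueAbundance, "copies_per_ul"), paths[1L])
  writeAbundanceTable(ngs, paths[2L])
  utils::write.table(reactions, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(taxon = truth@taxa, mean_copies = truth@copyNumber),
    paths[4L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
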